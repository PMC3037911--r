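condition,amplicon,C,D,P,VC,E
G0,a,+,+,+,-,-
G0,b,+,+,-,-,-
G0,c,+,+,-,-,-
G0,d,+,+,+,-,-
G0,e,+,+,-,-,-
G0,f,+,+,-,-,-
G0,g,+,+,-,-,-
G0,h,+,+,+,-,-
G0,i,+,+,-,-,-
G0,j,+,+,-,-,-
G0,k,+,+,+,-,-
G0,l,+,+,-,-,-
G0,m,+,+,+,-,-
G0,n,+,+,-,-,-
G0,o,+,+,+,-,-
PHx24,a,+,+,+,+,-*
PHx24,b,+,+,+,+*,-
PHx24,c,+,+,+,-*,-
PHx24,d,+,+,+,+,-
PHx24,e,+,+,+,+*,-
PHx24,f,+,+,+,+,-
PHx24,g,+,+,+,-*,-
PHx24,h,+,+,+,+,-
PHx24,i,+,+,+,+,-
PHx24,j,+,+,+,+,-
PHx24,k,+,+,+,+,-*
PHx24,l,+,+,+,+*,-
PHx24,m,+,+,+,+*,-
PHx24,n,+,+,+,+*,-
PHx24,o,+,+,+,+,-*
PHx7D,a,+,+,-*,-,-
PHx7D,b,+,+,-,-,-
PHx7D,c,+,+,-,-,-
PHx7D,d,+,+,+*,-,-
PHx7D,e,+,-*,-,-,-
PHx7D,f,+,+,-,-,-
PHx7D,g,+,+,-*,-,-
PHx7D,h,+,+,-*,-,-
PHx7D,i,+,+,-,-,-
PHx7D,j,+,+,-*,-,-
PHx7D,k,+,+,-*,-,-
PHx7D,l,+,+,-,-,-
PHx7D,m,+,+,+*,-,-
PHx7D,n,+,+,-,-,-
PHx7D,o,+,+,+*,-,-
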