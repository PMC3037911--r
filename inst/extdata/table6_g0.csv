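condition,amplicon,C,D,P,VC,E
G0,Fyn,+,+,-,-,-
G0,CD23,+,+,-,-,-
G0,GFAP,+,+,-,-,-
G0,MPZ,+,+,+,-,-
PHx24,Fyn,+,+,+,+,-
PHx24,CD23,+,+,+,+,-
PHx24,GFAP,+,+,+,+,-
PHx24,MPZ,+,+,+,+,-*
PHx7D,Fyn,+,+,-,-,-
PHx7D,CD23,+,+,-,-,-
PHx7D,GFAP,+,+*,-,-,-
PHx7D,MPZ,+,+,+*,-,-
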