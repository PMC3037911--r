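condition,amplicon,C,D,P,VC,E,n_experiments
G0_boost6,a,+,+,+,+,+,4
G0_boost6,b,+,+,+,+,+/-,2
G0_boost6,c,+,+,+,+,+/-,2
G0_boost6,d,+,+,+,+,+,4
G0_boost6,e,+,+,+,+,+/-,2
G0_boost6,f,+,+,+,+,-,2
G0_boost6,g,+,+,+,+/-,-,2
G0_boost6,h,+,+,+,+,+,4
G0_boost6,i,+,+,+,+,+,2
G0_boost6,j,+,+,+,+,+/-,2
G0_boost6,k,+,+,+,+,+,3
G0_boost6,l,+,+,+,+,+/-,3
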