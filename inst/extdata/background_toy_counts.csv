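probe_id,code_class,S1,S2,S3,S4
BGP1,Endogenous,100,100,100,100
BGP2,Endogenous,10,10,100,100
BGP3,Endogenous,29,31,35,40
BGP4,Endogenous,5,8,2,1
BGP5,Endogenous,30,30,30,29
BGP6,Endogenous,31,29,29,100
HK1,Housekeeping,512,512,512,512
HK2,Housekeeping,256,256,256,256
POSA,Positive,1024,1024,1024,1024
POSB,Positive,256,256,256,256
POSC,Positive,64,64,64,64
POSD,Positive,16,16,16,16
POSE,Positive,4,4,4,4
POSF,Positive,1,1,1,1
NEG1,Negative,10,5,15,6
NEG2,Negative,10,5,15,6
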