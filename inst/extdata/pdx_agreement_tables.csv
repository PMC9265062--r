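marker,combination,n_nn,n_ny,n_yn,n_yy,kappa,ci_low,ci_high
TP53,IHC,5,2,4,9,0.381,-0.021,0.784
TP53,CNV,7,8,2,3,0.048,-0.309,0.405
TP53,SNV,7,3,2,8,0.500,0.122,0.878
TP53,CNV+SNV,5,2,4,9,0.381,-0.021,0.784
TP53,CNV+SNV+IHC,2,0,7,11,0.239,-0.056,0.534
TP53,SNV+IHC,4,0,5,11,0.468,0.126,0.810
RB1,IHC,9,1,2,8,0.700,0.389,1.000
RB1,CNV,7,0,4,9,0.612,0.298,0.925
RB1,SNV,10,8,1,1,0.022,-0.265,0.309
RB1,CNV+SNV,6,0,5,9,0.519,0.199,0.839
RB1,CNV+SNV+IHC,6,0,5,9,0.519,0.199,0.839
RB1,CNV+IHC,7,0,4,9,0.612,0.298,0.925
PTEN,IHC,10,3,2,5,0.468,0.071,0.865
PTEN,CNV,9,2,3,6,0.490,0.106,0.874
PTEN,CNV+IHC,8,2,4,6,0.400,0.006,0.794
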