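"state","cost","cost_dist","daly_weight","daly_lo","daly_hi"
"A",0,"point(0)",0,0,0
"B",0,"point(0)",0,0,0
"C",0,"point(0)",0,0,0
"D",0,"point(0)",0.041,0.026,0.062
"E",0,"point(0)",0.179,0.122,0.251
"F",25.84,"gamma_shared",0.012,0.004,0.02
"G",93.93,"gamma_shared",0.006,0.002,0.012
"H",337.47,"gamma_shared",0.041,0.026,0.062
"I",854,"gamma_shared",0.179,0.122,0.251
"RG",93.93,"gamma_shared",0,0,0
"RH",337.47,"gamma_shared",0,0,0
"RI",854,"gamma_shared",0,0,0
"K",854,"gamma_shared",0.049,0.031,0.072
"X",4120.51,"gamma_shared",0.08,0.05,0.11
"Z",0,"point(0)",0,0,0
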