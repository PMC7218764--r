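"from","to","probability","dist"
"A","B","0.0050000000000000001","beta_mean_n(0.0050000000000000001,100)"
"A","C","0.00125","beta_mean_n(0.00125,100)"
"A","Z","0.001","beta_mean_n(0.001,100)"
"B","A","0.20000000000000001","beta_mean_n(0.20000000000000001,100)"
"B","C","0.10000000000000001","beta_mean_n(0.10000000000000001,100)"
"B","Z","0.001","beta_mean_n(0.001,100)"
"C","D","0.084999999999999992","beta_mean_n(0.084999999999999992,100)"
"C","X","0.02","beta_mean_n(0.02,100)"
"C","Z","0.02","beta_mean_n(0.02,100)"
"D","E","0.11499999999999999","beta_mean_n(0.11499999999999999,100)"
"D","H","0.15000000000000002","beta_mean_n(0.15000000000000002,100)"
"D","X","0.035000000000000003","beta_mean_n(0.035000000000000003,100)"
"D","Z","0.029999999999999999","beta_mean_n(0.029999999999999999,100)"
"E","I","0.15000000000000002","beta_mean_n(0.15000000000000002,100)"
"E","X","0.15000000000000002","beta_mean_n(0.15000000000000002,100)"
"E","Z","0.15000000000000002","beta_mean_n(0.15000000000000002,100)"
"F","A","0.20000000000000001","beta_mean_n(0.20000000000000001,100)"
"F","G","0.10000000000000001","beta_mean_n(0.10000000000000001,100)"
"F","Z","0.001","beta_mean_n(0.001,100)"
"G","H","0.084999999999999992","beta_mean_n(0.084999999999999992,100)"
"G","RG","0.050000000000000003","beta_mean_n(0.050000000000000003,100)"
"G","X","0.012500000000000001","beta_mean_n(0.012500000000000001,100)"
"G","Z","0.012500000000000001","beta_mean_n(0.012500000000000001,100)"
"H","I","0.11499999999999999","beta_mean_n(0.11499999999999999,100)"
"H","RH","0.050000000000000003","beta_mean_n(0.050000000000000003,100)"
"H","X","0.040000000000000001","beta_mean_n(0.040000000000000001,100)"
"H","Z","0.02","beta_mean_n(0.02,100)"
"I","X","0.15000000000000002","beta_mean_n(0.15000000000000002,100)"
"I","RI","0.030000000000000002","beta_mean_n(0.030000000000000002,100)"
"I","Z","0.10000000000000001","beta_mean_n(0.10000000000000001,100)"
"RG","Z","0.001","beta_mean_n(0.001,100)"
"RH","Z","0.002","beta_mean_n(0.002,100)"
"RI","Z","0.01","beta_mean_n(0.01,100)"
"K","X","0.02","beta_mean_n(0.02,100)"
"K","Z","0.02","beta_mean_n(0.02,100)"
"X","K","0.89999999999999991","beta_mean_n(0.89999999999999991,100)"
"X","Z","0.10000000000000009","beta_mean_n(0.10000000000000009,100)"
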