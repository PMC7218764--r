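"from","to"
"A","B"
"A","C"
"A","Z"
"B","A"
"B","C"
"B","Z"
"C","D"
"C","X"
"C","Z"
"D","E"
"D","H"
"D","X"
"D","Z"
"E","I"
"E","X"
"E","Z"
"F","A"
"F","G"
"F","Z"
"G","H"
"G","RG"
"G","X"
"G","Z"
"H","I"
"H","RH"
"H","X"
"H","Z"
"I","X"
"I","RI"
"I","Z"
"RG","Z"
"RH","Z"
"RI","Z"
"K","X"
"K","Z"
"X","K"
"X","Z"
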