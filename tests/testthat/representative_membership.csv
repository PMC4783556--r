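"cluster_1","cluster_2"
0.999999996475438,3.52456231407449e-09
0.999999996475438,3.52456231407449e-09
0.999016040308797,0.000983959691202908
1.44277063270256e-35,1
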