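feature,value_a,value_b,delta
F1,x,x,0
F1,x,y,0.666666666666667
F1,y,y,0
F2,a,a,0
F2,a,b,0.5
F2,b,b,0
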