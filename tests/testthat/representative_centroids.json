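{"cluster_1":{"F1":{"x":1,"y":1.57999145457942e-39},"F2":{"a":0.666907264456283,"b":0.333092735543717}},"cluster_2":{"F1":{"x":0.000492110424075963,"y":0.999507889575924},"F2":{"a":1.00607821693746e-09,"b":0.999999998993922}}}
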