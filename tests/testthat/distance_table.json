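{"kind":"cooccurrence","distances":{"F1":{"x":{"x":0,"y":0.666666666666667},"y":{"x":0.666666666666667,"y":0}},"F2":{"a":{"a":0,"b":0.5},"b":{"a":0.5,"b":0}}}}
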