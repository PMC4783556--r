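{"n":3,"matched":3,"error":0,"mapping":{"1":"y","2":"x"}}
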