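{"runs":3,"final_objectives":[0.666841616743297,0.672825542986403,0.666841616745689]}
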