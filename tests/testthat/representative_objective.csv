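"iteration","objective"
1,1.56733992323937
2,0.710310748623432
3,0.66713594340715
4,0.666844188110414
5,0.666841639702763
6,0.666841616743297
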