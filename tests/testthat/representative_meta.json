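{"K":2,"m":1.1,"epsilon":1e-06,"max_iter":100,"distance":"cooccurrence","centroid":"fuzzy","seed":5,"iterations":6,"converged":true,"final_objective":0.666841616743297}
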