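{"command":"cluster","input":"/tmp/Rtmpqu9Bdt/file31d531f8317.csv","input_md5":"1ac99b94758c49857a56439f8caf6d6b","config":{"K":2,"m":1.1,"epsilon":1e-06,"max_iter":100,"distance":"cooccurrence","centroid":"fuzzy","seed":5},"runs":3,"seeds":[5,6,7],"per_run":[{"iterations":6,"converged":true,"final_objective":0.666841616743297},{"iterations":9,"converged":true,"final_objective":0.672825542986403},{"iterations":8,"converged":true,"final_objective":0.666841616745689}],"package_version":"0.1.0","timestamp":"2026-09-21T21:04:21+0000"}
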