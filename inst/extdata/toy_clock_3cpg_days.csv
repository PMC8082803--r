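#clock=toy3_days;unit=days
cpg,weight
(Intercept),277
cgA,7
cgB,14
cgC,-3
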