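iron,cluster1,cluster2,cluster3
positive,1,7,1
negative,6,3,9
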