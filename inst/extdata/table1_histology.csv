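histology,cluster1,cluster2,cluster3
Control,1,0,4
MASL,3,3,2
MASH F0-1,3,3,1
MASH F2-3,0,4,3
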