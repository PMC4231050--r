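location	di	tri	tetra	penta	hexa
exon	130	3588	117	206	1303
exon_intron	7	27	4	4	31
intron	7158	1959	2343	1878	2476
intergenic	54853	24841	19584	19956	19853
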