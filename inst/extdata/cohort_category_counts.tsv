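compartment	non_synonymous	synonymous	indel	vus
ovary	264	73	7	337
synchronous	130	28	32	152
shared	22	5	6	75
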