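category	reads
generated	86350000
aligned	37270000
filtered	41530000
multi	4110000
unique	33160000
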