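population	individual	two_c_pg
Galbraith	1	2.08
Galbraith	2	2.03
Galbraith	3	1.88
12Mile	1	2.09
12Mile	2	2.17
EaglePeak	1	2.04
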