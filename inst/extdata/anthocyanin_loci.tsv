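locus	cds_length	assembly_length	utr5_extra_bp	utr3_extra_bp
PAL1	2178	2035	0	25
CHS	1185	1185	54	175
F3H	1185	976	18	0
FLS	1011	1011	14	109
DFR	1128	1105	51	0
ANS	1173	1071	86	6
3GT	1350	1142	0	0
MYB111	1056	655	0	287
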