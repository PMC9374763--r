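cell_line	type	pfkfb3_overexpressed
IMR-5	neuroblastoma	1
IMR-32	neuroblastoma	1
SK-N-AS	neuroblastoma	1
SK-N-BE(2)	neuroblastoma	0
A-172	glioblastoma	0
M059J	glioblastoma	0
M059K	glioblastoma	0
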