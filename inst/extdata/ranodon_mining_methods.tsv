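approach	software	n_contigs
similarity	RepeatMasker	75381
similarity	TE-HMMER	3108
structure	HelSearch	1
structure	LTRharvest	84
structure	MGEScan-non-LTR	0
structure	MITE-Hunter	7
structure	SINE-finder	48
repetitiveness	TEdenovo	306
repetitiveness	RepeatScout	3671
repeat-building	dnaPipeTE	24090
repeat-building	RepeatModeler	3213
total	all	109909
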