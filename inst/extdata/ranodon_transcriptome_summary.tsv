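category	contigs_ovary	tpm_ovary	contigs_testis	tpm_testis
endogenous_gene	51647	678366	58041	513783
autonomous_te	26358	17890	41421	43694
non_autonomous_te	1700	5538	2348	12151
gene_autonomous_te	722	2618	1001	5748
gene_non_autonomous_te	168	2779	189	1073
unannotated	215508	292828	334533	423550
total	296103	1000029	437533	999999
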