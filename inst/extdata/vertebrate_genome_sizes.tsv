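species	genome_size_gb
Platyplectrum ornatum	1.0
Gallus gallus	1.3
Danio rerio	1.4
Xenopus tropicalis	1.7
Anolis carolinensis	2.2
Mus musculus	2.5
Geotrypetes seraphini	3.8
Rhinatrema bivittatum	5.3
Caecilia tentaculata	5.5
Pleurodeles waltl	20
Ranodon sibiricus	21
Ambystoma mexicanum	32
Protopterus annectens	43
Cynops orientalis	44
Protopterus aethiopicus	130
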