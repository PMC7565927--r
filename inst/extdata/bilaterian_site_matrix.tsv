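# O-fucosylation consensus per EGF-LD slot; 1=present 0=absent -=domain_missing ?=unknown
species	taxon_group	I	II	III	IV	V
Mus_musculus	deuterostome	0	0	1	0	1
Homo_sapiens	deuterostome	0	0	1	0	1
Danio_rerio	deuterostome	0	0	1	0	1
Xenopus_tropicalis	deuterostome	0	0	1	0	1
Ornithorhynchus_anatinus	deuterostome	1	0	0	0	1
Ochotona_princeps	deuterostome	0	0	0	0	1
Dasypus_novemcinctus	deuterostome	0	0	1	0	0
Gekko_japonicus	deuterostome	0	0	1	0	0
Python_bivittatus	deuterostome	0	0	0	0	0
Thamnophis_sirtalis	deuterostome	0	0	0	0	0
Strongylocentrotus_purpuratus	deuterostome	0	1	0	?	?
Saccoglossus_kowalevskii	deuterostome	0	1	0	?	?
Drosophila_melanogaster	protostome	0	1	0	0	0
Tribolium_castaneum	protostome	0	1	0	0	0
Folsomia_candida	protostome	0	1	0	0	0
Daphnia_pulex	protostome	0	1	0	0	0
Limulus_polyphemus	protostome	0	1	0	0	0
Lingula_anatina	protostome	0	0	1	1	0
Crassostrea_gigas	protostome	0	1	0	0	-
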