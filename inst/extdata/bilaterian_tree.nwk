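(((((((((Mus_musculus:1,Ochotona_princeps:1):1,Homo_sapiens:1):1,Dasypus_novemcinctus:1):1,Ornithorhynchus_anatinus:1):1,(Gekko_japonicus:1,(Python_bivittatus:1,Thamnophis_sirtalis:1):1):1):1,Xenopus_tropicalis:1):1,Danio_rerio:1):1,(Strongylocentrotus_purpuratus:1,Saccoglossus_kowalevskii:1):1):1,((((Drosophila_melanogaster:1,Tribolium_castaneum:1):1,Folsomia_candida:1):1,(Daphnia_pulex:1,Limulus_polyphemus:1):1):1,(Lingula_anatina:1,Crassostrea_gigas:1):1):1);
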