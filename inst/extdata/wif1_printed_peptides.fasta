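>egf3_tryptic
ANCSTTCFNGGTCFYPGK
>egf5_tryptic
GYQGDLCSKPVCEPGCGAHGTCHEPNK
>egf3_codigest
FNGGTC
>egf5_codigest
VCEPGCGAHGTCHEPNK
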