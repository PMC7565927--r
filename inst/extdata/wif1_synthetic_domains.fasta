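>egf3_synthetic
CSTTCFNGGTCFYPGKCVCNSGYSGDRC
>egf5_synthetic
CEPGCGAHGTCHEPNKCQCRSSGDNYGC
>platypus_egf1_synthetic
CTTACRNGGSCNDGKCVCNSGYSGDRC
>platypus_egf3_synthetic
CSTTCFNGGACFYPGKCVCNSGYSGDRC
>notch1_egf12_synthetic
CSTTCQNDATCFYPGKCVCNSGYSGDRC
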