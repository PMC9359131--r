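group,total_mu,small_weight
BL02,739.80,0.3235
BL04,843.03,0.1570
BL06,776.97,0.2410
BL08,728.17,0.3275
BL10,701.71,0.3950
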