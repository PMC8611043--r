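stratum	count	total
exac_control_minor_alleles	3079	133480
ukb_control_carriers	532	4822
ukb_control_second_hit_carriers	206	4822
case_second_hit_carriers	8	62
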