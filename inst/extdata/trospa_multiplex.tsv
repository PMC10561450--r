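name	sequence	role	expected_size	annealing_c
Trospa_Iric_F1	GTAAACATCGGCCTAATGG	fwd_A	362	52
Trospa_Iric_R2	GGAAAAAATAATGTTAAAACACC	rev_A	362	52
Trospa_Iino_F2	GTTGTTCACAGCGAATACT	fwd_B	233	52
Trospa_Iino_R1	GAAAAAAATATTAGAACATTAACACTC	rev_B	233	52
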