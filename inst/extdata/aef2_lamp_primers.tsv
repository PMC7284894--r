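target_genus	oligo_name	sequence	tm	length
Methanoculleus	F3_aEF2_Mcu	TAYCTBATCAACATGATYGAT	48.0	21
Methanoculleus	FLc_aEF2_Mcu	ACCGCRTCCACSACRAC	58.4	17
Methanoculleus	FIP_aEF2_Mcu	GTCTCCGTCTGKGGCATGGTTTTTGACGTGACYCGYGCCATG	70.9	42
Methanoculleus	B3_aEF2_Mcu	TYYTCGTTCATDCCCTTGAT	52.3	20
Methanoculleus	BL_aEF2_Mcu	ACGAGCAGGAGATGCAGATC	56.8	20
Methanoculleus	BIP_aEF2_Mcu	ACCGGCTGRTCAACGAGTTTTTTGACCTTRTCGATCAC	65.8	38
Methanothermobacter	F3_aEF2_Mth	ATTAAGGAGCTCATGTACCA	50.6	20
Methanothermobacter	FLc_aEF2_Mth	CAAGGAARCGCTGATCCC	54.9	18
Methanothermobacter	FIP_aEF2_Mth	CCTTGCCTGTTCCTGTTCTTTTGACAACCTCCTGGCTGGTGC	69.7	42
Methanothermobacter	B3_aEF2_Mth	GCATTATRCCCTCAACKGC	54.0	19
Methanothermobacter	BL_aEF2_Mth	TCAATGGTCCACTCCTA	49.1	17
Methanothermobacter	BIP_aEF2_Mth	ACCATTGACGCTGCRAACGTTTTTCCTCATKGCCCTTGTAACGT	69.1	44
Methanococcus	F3_aEF2_Mco	ATGGGAAGAAGAGCAAAAATG	51.3	21
Methanococcus	FLc_aEF2_Mco	ATCATWCCWGCWCCTGC	52.0	17
Methanococcus	FIP_aEF2_Mco	CAAGYTGGTCTCCWGCTTTTCATYGACCACGGTAAAAC	65.1	38
Methanococcus	B3_aEF2_Mco	CTCATTGCTCTTGTAACGTC	51.1	20
Methanococcus	BL_aEF2_Mco	CTGCAAACGTKTCAATGGT	52.7	19
Methanococcus	BIP_aEF2_Mco	GAAGAAGCWGCAAGAGGTATTTTTTCAACGTGACCWGGGGTRTC	66.4	44
Methanobrevibacter	F3_aEF2_Mbr	GAAACTGTAYTYAGACAA	43.5	18
Methanobrevibacter	FLc_aEF2_Mbr	TCAGGAGCCATGTTYTTGATTA	53.1	22
Methanobrevibacter	FIP_aEF2_Mbr	GCTGAACCRAAWGCTACACTTTTTAATCAACGARTTAAAATTA	60.6	43
Methanobrevibacter	B3_aEF2_Mbr	AAGTGTTCTACTACCATAC	45.6	19
Methanobrevibacter	BL_aEF2_Mbr	ATYATTGATTAYTGTAATG	39.4	19
Methanobrevibacter	BIP_aEF2_Mbr	TGGGCTATYAAYGTTCCTTTTGGTACTTTTTKAGCTAATTC	61.7	41
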