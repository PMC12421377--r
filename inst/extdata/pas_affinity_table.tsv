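oligo	hexamer	labeled	frequency_percent	kd_nM	ratio_printed
FAM-UGCAAUAAACAA	AAUAAA	TRUE	60.76	19	0.5
UGCAAUAAACAA	AAUAAA	FALSE	60.76	40	1
UGCAUUAAACAA	AUUAAA	FALSE	16.76	79	2
UGCAGUAAACAA	AGUAAA	FALSE	3.29	194	5
UGCUAUAAACAA	UAUAAA	FALSE	2.92	520	13
UGCAAUAUACAA	AAUAUA	FALSE	2.85	2500	62
UGCAAUACACAA	AAUACA	FALSE	2.18	2200	55
UGCAAGAAACAA	AAGAAA	FALSE	1.58	1870	47
UGCAAUGAACAA	AAUGAA	FALSE	1.57	1180	30
UGCCAUAAACAA	CAUAAA	FALSE	1.49	780	20
UGCGAUAAACAA	GAUAAA	FALSE	1.23	580	14
UGCAACAAACAA	AACAAA	FALSE	1.13	13000	325
UGCAAUAAUCAA	AAUAAU	FALSE	1.12	1170	29
UGCAAUAGACAA	AAUAGA	FALSE	0.71	2000	50
UGCAUUAUACAA	AUUAUA	FALSE	0.58	2140	54
UGCACUAAACAA	ACUAAA	FALSE	0.56	2700	68
UGCAAUAAGCAA	AAUAAG	FALSE	0.53	11500	288
UGCAUUACACAA	AUUACA	FALSE	0.40	NA	NA
UGCAACAAGCAA	AACAAG	FALSE	0.34	NA	NA
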