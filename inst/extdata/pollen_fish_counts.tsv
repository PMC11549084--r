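variant	total	none	vn_only	sn_only	all_nuclei
1Bk-1	195	103	0	0	92
2Bk-2	77	15	3	55	4
2Bk-3	101	20	0	0	81
2Bs	112	11	6	91	4
2Bk	122	21	6	92	3
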