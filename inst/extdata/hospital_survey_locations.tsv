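location	surface_area_cm2	atp_mean	atp_sd	atp_min	atp_max	n_atp	tpc_mean	tpc_sd	tpc_min	tpc_max	n_tpc	s_aureus_pct	enterococci_pct	gram_negatives_pct
Common area table	100	1.2	1.2	0.1	3.9	11	3.6	7.1	0.5	29	14	7.1	7.1	0
Chair armrest emergency unit	47-53	6.0	5.0	0.1	16	16	7.8	16.6	0.5	85	24	8.3	0.0	0
Chair armrest childrens unit	44						6.4	7.5	0.5	37	34	2.9	8.8	0
Toilet door handle	23-25	1.4	1.9	0.0	6.0	9	6.2	8.6	0.5	7.0	6	33.3	16.7	0
Toilet door puller	64	4.9	4.5	0.2	14	8	1.3	0.8	0.5	3.0	10	20	0	0
Toilet door lock	37						21.5	48.4	1.0	190	14	35.7	7	0
Total		3.6	4.3	0.0	16	44	7.8	20.4	0.5	190	112	11.6	5	0
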