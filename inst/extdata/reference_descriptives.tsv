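reporter_group	seriousness	variable	count	mean	sd	min	q25	q50	q75	max
HP	NON_SERIOUS	reaction_cnt	2193	2.03	1.40	1	1	2	3	17
HP	NON_SERIOUS	suspect_drug_cnt	2193	1.39	1.30	1	1	1	1	25
HP	NON_SERIOUS	concomitant_drug_cnt	2193	1.50	2.87	0	0	0	2	29
HP	NON_SERIOUS	suspect_and_concomitant_cnt	2193	2.89	3.16	1	1	1	4	30
NON_HP	NON_SERIOUS	reaction_cnt	1049	2.56	1.94	1	1	2	3	18
NON_HP	NON_SERIOUS	suspect_drug_cnt	1049	1.31	0.86	1	1	1	1	13
NON_HP	NON_SERIOUS	concomitant_drug_cnt	1049	0.98	1.80	0	0	0	1	20
NON_HP	NON_SERIOUS	suspect_and_concomitant_cnt	1049	2.29	2.04	1	1	1	3	21
HP	SERIOUS	reaction_cnt	7183	3.50	4.90	1	1	2	4	61
HP	SERIOUS	suspect_drug_cnt	7183	3.00	3.84	1	1	2	3	42
HP	SERIOUS	concomitant_drug_cnt	7183	2.64	4.26	0	0	0	4	47
HP	SERIOUS	suspect_and_concomitant_cnt	7183	5.64	6.12	1	2	4	8	63
NON_HP	SERIOUS	reaction_cnt	2317	4.00	4.59	1	1	3	5	55
NON_HP	SERIOUS	suspect_drug_cnt	2317	2.65	3.20	1	1	1	3	46
NON_HP	SERIOUS	concomitant_drug_cnt	2317	2.10	4.59	0	0	0	2	51
NON_HP	SERIOUS	suspect_and_concomitant_cnt	2317	4.75	6.52	1	1	2	5	55
HP	ALL	reaction_cnt	9376	3.16	4.39	1	1	2	3	61
HP	ALL	suspect_drug_cnt	9376	2.62	3.48	1	1	1	3	42
HP	ALL	concomitant_drug_cnt	9376	2.38	4.01	0	0	0	4	47
HP	ALL	suspect_and_concomitant_cnt	9376	5.00	5.69	1	1	3	7	63
NON_HP	ALL	reaction_cnt	3366	3.55	4.01	1	1	2	4	55
NON_HP	ALL	suspect_drug_cnt	3366	2.23	2.77	1	1	1	2	46
NON_HP	ALL	concomitant_drug_cnt	3366	1.75	3.97	0	0	0	2	51
NON_HP	ALL	suspect_and_concomitant_cnt	3366	3.98	5.64	1	1	2	4	55
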