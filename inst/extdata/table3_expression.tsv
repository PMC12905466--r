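patient	inheritance	gene	early_other_mean	late_other_mean	early_cerebellum_mean	late_cerebellum_mean
1	de_novo	LAMA5	2.3	2.15	5.74	7.17
1	autosomal_recessive	REV3L	5.93	2.2	7.39	5.94
1	autosomal_recessive	KREMEN2	0.29	0.88	0.17	0.14
1	autosomal_recessive	KATNIP	2.22	2.14	2.64	1.75
1	autosomal_recessive	ADAMTS10	7.47	2.64	5.84	0.77
1	x_linked_recessive	MOSPD2	1.81	3.61	2.50	2.63
1	x_linked_recessive	NXF5	0.01	0.02	0	0.02
1	x_linked_recessive	MCTS1	9.79	7.93	6.80	4.12
1	x_linked_recessive	IGSF1	1.72	4.49	2.17	1.27
1	x_linked_recessive	MAGEC3	0.06	0.14	0.09	0.03
2	de_novo	FOXN4	0.86	0.03	0.67	0.04
2	autosomal_recessive	GPR25	0.10	0.03	0.14	0
2	autosomal_recessive	FCHSD1	1.85	3.66	2.87	4.65
2	autosomal_recessive	SFMBT2	1.67	1.78	4.93	2.36
2	autosomal_recessive	PGPEP1L	0.05	0.13	0.05	0.02
2	autosomal_recessive	GPI	35.96	55.1	38.31	70.11
2	x_linked_recessive	ARSF	0.87	1.6	0.32	0.19
2	x_linked_recessive	SMS	19.77	10.17	11.41	11.81
2	x_linked_recessive	NOX1	0.17	0.18	0.21	0.29
3	de_novo	USP17L2	0.01	0.02	0.01	0.01
3	de_novo	LRRK2	0.49	1.73	0.57	0.62
3	autosomal_recessive	LAMB1	5.61	3.85	11.82	7.60
3	autosomal_recessive	MYH13	0.01	0.02	0.02	0
3	autosomal_recessive	CRYBA4	0.05	0.1	0.1	0
3	x_linked_recessive	PHKA2	2.64	1.45	2.81	2.26
3	x_linked_recessive	P2RY4	0.01	0.01	0.02	0.01
3	x_linked_recessive	ADGRG4	0	0	0.01	0
3	x_linked_recessive	ZNF185	1.81	1.19	2.60	1.06
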