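patient	inheritance	chrom	pos	ref	alt	gene	pli	effect	impact	freq	cadd	rsid	hgvs_c	hgvs_p
1	de_novo	20	62346191	C	T	LAMA5	0	missense	MODERATE	1.2e-05	21.9	NA	ENST00000252999.7:c.1307C>T	ENSP00000252999.3:p.Thr436Met
1	autosomal_recessive	6	111372921	G	C	REV3L	1	missense	MODERATE	1.4e-02	18.5	rs3218599	ENST00000358835.7:c.5434G>C	ENSP00000351697.3:p.Asp1812His
1	autosomal_recessive	16	2964989	C	A	KREMEN2	0	missense	MODERATE	1.7e-02	17.3	rs62032326	ENST00000303746.9:c.225C>A	ENSP00000304422.5:p.Ser75Arg
1	autosomal_recessive	16	27749614	G	A	KATNIP	0	missense	MODERATE	1.4e-02	22.6	rs16976970	ENST00000261588.8:c.2654G>A	ENSP00000261588.4:p.Arg885Gln
1	autosomal_recessive	19	8605262	G	A	ADAMTS10	1	missense	MODERATE	3.1e-02	23.2	rs62621197	ENST00000270328.8:c.185G>A	ENSP00000270328.4:p.Arg62Gln
1	x_linked_recessive	X	14911253	G	A	MOSPD2	NA	missense	MODERATE	2.6e-02	23.5	rs35164803	ENST00000380492.7:c.719G>A	ENSP00000369860.3:p.Ser240Asn
1	x_linked_recessive	X	101841958	A	G	NXF5	NA	missense	MODERATE	1.9e-02	23.0	rs55756985	ENST00000473265.2:c.67A>G	ENSP00000426978.1:p.Lys23Glu
1	x_linked_recessive	X	120605465	G	T	MCTS1	NA	missense	MODERATE	7.4e-04	26.8	rs143806871	ENST00000371315.3:c.73G>T	ENSP00000360365.3:p.Gly25Cys
1	x_linked_recessive	X	131285348	G	C	IGSF1	NA	missense	MODERATE	4.8e-04	22.7	rs201255931	ENST00000370903.7:c.498G>C	ENSP00000359940.3:p.Glu166Asp
1	x_linked_recessive	X	141897457	G	T	MAGEC3	NA	missense	MODERATE	4.7e-03	10.6	rs143730187	ENST00000298296.1:c.1699G>T	ENSP00000298296.1:p.Val567Phe
2	de_novo	12	109285446	G	A	FOXN4	1	synonymous	MODERATE	0	17.9	NA	ENST00000299162.9:c.759G>A	ENSP00000299162.5:p.Lys253=
2	autosomal_recessive	1	200873513	C	T	GPR25	0.005	missense	MODERATE	1.6e-02	21.0	rs144298915	ENST00000304244.4:c.476C>T	ENSP00000301917.2:p.Ser159Leu
2	autosomal_recessive	5	141641727	A	C	FCHSD1	0	missense	MODERATE	2.0e-02	23.2	rs116772138	ENST00000435817.6:c.1982A>C	ENSP00000399259.2:p.Asp661Ala
2	autosomal_recessive	10	7171965	G	A	SFMBT2	1	missense	MODERATE	2.3e-03	24.4	rs201963815	ENST00000397167.5:c.2345G>A	ENSP00000380353.1:p.Arg782His
2	autosomal_recessive	15	98971106	T	C	PGPEP1L	0	missense	MODERATE	1.1e-02	23.7	rs116915938	ENST00000378919.6:c.74T>C	ENSP00000368199.6:p.Leu25Pro
2	autosomal_recessive	19	34377871	T	C	GPI	0	missense	MODERATE	1.6e-02	24.7	rs8191371	ENST00000588991.7:c.656T>C	ENSP00000465858.3:p.Ile219Thr
2	x_linked_recessive	X	3076561	G	C	ARSF	NA	missense	MODERATE	4.5e-04	23.0	rs111289343	ENST00000381127.5:c.175G>C	ENSP00000370519.1:p.Asp59His
2	x_linked_recessive	X	21992652	G	A	SMS	NA	missense	MODERATE	4.9e-05	15.2	rs199670083	ENST00000404933.6:c.1001G>A	ENSP00000385746.2:p.Arg334His
2	x_linked_recessive	X	100850206	G	A	NOX1	NA	missense	MODERATE	1.9e-02	22.9	rs34688635	ENST00000372966.7:c.1078G>A	ENSP00000362057.3:p.Asp360Asn
3	de_novo	8	12138512	G	C	USP17L2	0	missense	MODERATE	1.1e-03	10.7	rs200186296	ENST00000333796.3:c.249G>C	ENSP00000333329.3:p.Gln83His
3	de_novo	12	40278097	A	C	LRRK2	0	missense	MODERATE	0	19.7	NA	ENST00000298910.11:c.2077A>C	ENSP00000298910.7:p.Asn693His
3	autosomal_recessive	7	107929517	T	C	LAMB1	0	missense	MODERATE	1.9e-02	27.3	rs35915664	ENST00000222399.10:c.4640T>C	ENSP00000222399.6:p.Ile1547Thr
3	autosomal_recessive	17	10309647	G	C	MYH13	0	missense	MODERATE	1.4e-02	24.4	rs35069886	ENST00000418404.8:c.4840G>C	ENSP00000404570.3:p.Asp1614His
3	autosomal_recessive	22	26623300	G	A	CRYBA4	0	missense	MODERATE	1.7e-02	23.6	rs35520672	ENST00000354760.3:c.106G>A	ENSP00000346805.3:p.Val36Met
3	x_linked_recessive	X	18954379	G	C	PHKA2	NA	missense	MODERATE	2.0e-02	18.8	rs17313469	ENST00000379942.4:c.112G>C	ENSP00000369274.4:p.Glu38Gln
3	x_linked_recessive	X	70258582	G	A	P2RY4	NA	stop_gained	HIGH	1.3e-02	36.0	rs41310667	ENST00000374519.3:c.1043G>A	ENSP00000363643.2:p.Trp348Ter
3	x_linked_recessive	X	136414167	C	A	ADGRG4	NA	missense	MODERATE	3.3e-03	16.0	rs140250794	ENST00000394143.5:c.9045C>A	ENSP00000377699.1:p.Ser3015Arg
3	x_linked_recessive	X	152945346	G	A	ZNF185	NA	missense	MODERATE	3.3e-04	13.4	rs377079307	ENST00000535861.5:c.1384G>A	ENSP00000440847.1:p.Gly462Ser
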