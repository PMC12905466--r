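tf	target
MYC	MCTS1
MYC	MAGEC3
MYC	GPR25
MYC	SFMBT2
MYC	GPI
MYC	USP17L2
NFKB	PGPEP1L
NFKB	ARSF
NFKB	SMS
NFKB	NOX1
NFKB	LRRK2
ELK1	MYH13
ELK1	P2RY4
ELK1	ADGRG4
ELK1	ZNF185
ELK1	LAMB1
E2F1	REV3L
E2F1	KREMEN2
E2F1	ADAMTS10
E2F1	MOSPD2
E2F1	NXF5
E2F1	CDK6
SP1	GPI
STAT3	CDK6
STAT3	USP17L2
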