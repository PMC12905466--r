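a	b	channel	directed
LAMA5	LAMB1	experimental_ppi	FALSE
LAMA5	LAMB1	curated	FALSE
LAMA5	LAMB1	coexpression	FALSE
LAMA5	LAMB1	textmining	FALSE
CDK6	LAMA5	curated	FALSE
CDK6	FOXN4	textmining	FALSE
CDK6	LRRK2	experimental_ppi	FALSE
CDK6	USP17L2	experimental_ppi	FALSE
CDK6	RB1	curated	FALSE
CDK6	MARK2	experimental_ppi	FALSE
MARK2	LRRK2	experimental_ppi	FALSE
ITGB1	LAMA5	experimental_ppi	FALSE
ITGB1	LAMB1	experimental_ppi	FALSE
FOXN4	PHKA2	tf_target	TRUE
FOXN4	IGSF1	tf_target	TRUE
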