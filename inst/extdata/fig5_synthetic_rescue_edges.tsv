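a	b	channel
FCHSD1	LRRK2	predicted_ppi
CRYBA4	RB1	predicted_ppi
RB1	CDK6	curated
KATNIP	ICK	predicted_ppi
ICK	CDK6	predicted_ppi
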