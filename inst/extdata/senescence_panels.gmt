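CELLULAR_SENESCENCE	senescence markers (LMNB1 expected down)	CDKN1A	TP53	NFKBIA	GLB1	PTGS2	H2AX	LMNB1
SASP	senescence-associated secretory phenotype	IL1A	IL1B	CCL4	CCL2	CXCL8	CXCL12	MMP2	CTSB	ICAM1	TNFRSF1B	TNFRSF12A
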