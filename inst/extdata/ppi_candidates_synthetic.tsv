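gene_a	cell_type_a	gene_b	cell_type_b	database_score	experimental_score	textmining_score
BMP2	EC	BMPR1A	MSC	0.960	0.948	0.987
BMP4	EC	BMPR1A	MSC	0.951	0.923	0.978
IL1B	EC	IL1R1	MSC	0.990	0.962	0.991
BMP2	EC	PDGFRB	MSC	0.960	0.421	0.887
NOTCH4	EC	BMPR1A	MSC	0.312	0.150	0.640
IL1B	EC	PDGFRB	MSC	0.410	0.238	0.515
VEGFA	EC	KDR	MSC	0.982	0.955	0.990
BMP2	EC	IL1R1	MSC	0.905	0.868	0.733
IL1B	EC	IL1R1	EC	0.990	0.962	0.991
BMP4	EC	BMPR1A	MSC	0.951	0.890	0.978
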