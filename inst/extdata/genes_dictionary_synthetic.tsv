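gene_id	symbol	tax_id
59272	ACE2	9606
7113	TMPRSS2	9606
3569	IL6	9606
1401	CRP	9606
7124	TNF	9606
920	CD4	9606
1636	ACE	9606
925	CD8A	9606
3458	IFNG	9606
5045	FURIN	9606
3627	CXCL10	9606
4938	OAS1	9606
4939	OAS2	9606
4940	OAS3	9606
9636	ISG15	9606
3661	IRF3	9606
7128	TNFAIP3	9606
3434	IFIT1	9606
8519	IFITM1	9606
4599	MX1	9606
282617	IFNL3	9606
6347	CCL2	9606
6352	CCL5	9606
3553	IL1B	9606
3659	IRF1	9606
10561	IFI44	9606
10964	IFI44L	9606
3437	IFIT3	9606
8638	OASL	9606
6279	S100A8	9606
70008	Ace2	10090
21926	Tnf	10090
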