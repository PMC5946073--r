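syn	i	i1	i2	snp1	gene1	pathway1	chr1	snp2	gene2	pathway2	chr2
0.0199	0.0246	0.0034	0.0013	rs3212961	ERCC1	DNA_repair	19	rs762562	ERCC1	DNA_repair	19
0.0181	0.0297	0.0112	0.0004	rs2267723	GHRHR	IIS	7	rs4988505	GHRHR	IIS	7
0.0159	0.0214	0.0001	0.0054	rs2038526	PTPN1	IIS	20	rs6067484	PTPN1	IIS	20
0.0143	0.0178	0.0034	0.0001	rs3212961	ERCC1	DNA_repair	19	rs3212964	ERCC1	DNA_repair	19
0.0140	0.0182	0.0041	0.0001	rs12680687	NBN	DNA_repair	8	rs2735385	NBN	DNA_repair	8
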