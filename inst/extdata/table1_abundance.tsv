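accession	te_class	order	superfamily	family	n_clusters	n_clusters_young	size_mb
acc11	I	LTR	Copia		38	15	93.59
acc11	I	LTR	Gypsy		31	6	85.86
acc11	I	LTR			4	0	8.96
acc11	I	LINE			1	1	1.77
acc11	I	ParaRetrovirus			1	1	1.13
acc11	I				1	0	2.10
acc11	II				5	1	10.67
acc11	unclassified				12	4	26.93
acc11	tandem				1	1	1.13
acc11	rDNA				2	2	4.46
acc8	I	LTR	Copia		37	12	84.05
acc8	I	LTR	Gypsy		28	8	78.05
acc8	I	LTR			5	0	13.44
acc8	I	LINE			0	0	0.00
acc8	I	ParaRetrovirus			0	0	0.00
acc8	I				4	0	9.62
acc8	II				6	3	23.55
acc8	unclassified				14	8	31.51
acc8	tandem				0	0	0.00
acc8	rDNA				2	2	3.66
acc12	I	LTR	Copia		36	14	97.63
acc12	I	LTR	Gypsy		46	22	152.89
acc12	I	LTR			5	4	18.76
acc12	I	LINE			0	0	0.00
acc12	I	ParaRetrovirus			0	0	0.00
acc12	I				1	0	3.15
acc12	II				8	3	23.16
acc12	unclassified				8	5	16.50
acc12	tandem				1	1	1.65
acc12	rDNA				9	9	19.98
acc13	I	LTR	Copia		36	14	99.99
acc13	I	LTR	Gypsy		32	14	104.24
acc13	I	LTR			10	5	26.92
acc13	I	LINE			0	0	0.00
acc13	I	ParaRetrovirus			0	0	0.00
acc13	I				0	0	0.00
acc13	II				14	6	41.12
acc13	unclassified				8	5	32.87
acc13	tandem				2	2	2.84
acc13	rDNA				9	9	18.45
acc3	I	LTR	Copia		38	16	97.32
acc3	I	LTR	Gypsy		36	14	103.73
acc3	I	LTR			5	1	11.55
acc3	I	LINE			2	0	4.52
acc3	I	ParaRetrovirus			0	0	0.00
acc3	I				7	6	26.58
acc3	II				12	5	32.14
acc3	unclassified				10	7	24.25
acc3	tandem				1	1	1.45
acc3	rDNA				7	7	14.65
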