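rsid	effect_allele	other_allele	eaf	weight	gene
rsV1007	C	T	0.11	-1.602	GC
rsV1014	C	T	0.44	0.825	GC
rsV1021	A	G	0.73	0.995	GC
rsV1028	T	G	0.29	-1.723	GC
rsV1035	C	G	0.11	0.849	GC
rsV1042	T	C	0.79	1.492	GC
rsV1049	C	G	0.29	2.208	DHCR7
rsV1056	A	G	0.21	1.638	DHCR7
rsV1063	A	G	0.26	1.347	DHCR7
rsV1070	G	C	0.47	1.371	DHCR7
rsV1077	G	A	0.3	1.796	CYP2R1
rsV1084	T	C	0.11	-2.475	CYP2R1
rsV1091	G	C	0.21	1.007	CYP2R1
rsV1098	T	C	0.3	2.33	CYP2R1
rsV1105	G	A	0.23	0.946	CYP2R1
rsV1112	C	A	0.13	-0.777	CYP2R1
rsV1119	G	A	0.82	1.917	CYP24A1
rsV1126	A	C	0.74	1.917	CYP24A1
rsV1133	C	A	0.75	0.728	CYP24A1
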