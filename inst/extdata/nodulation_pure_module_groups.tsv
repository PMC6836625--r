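group	gene	description	modules	log2fc	padj
24U	Medtr8g042900	Pectinesterase/pectinesterase inhibitor	M0004	3.23	4.17E-07
24U	Medtr7g102770	Pollen Ole e I family allergens	M0004,6	2.82	1.23E-04
24U	Medtr3g071470	Pollen Ole e I family allergens	M0004, 6	2.76	7.86E-04
24U	Medtr4g074960	Endo-1,4-beta-glucanase	M0004	2.62	5.99E-03
24U	Medtr2g035120	Disease-resistance response protein	M0004	1.73	8.41E-03
24U	Medtr4g074960	Endo-1,4-beta-glucanase	M0006	2.62	5.99E-03
24U	Medtr4g109880	Adenine nucleotide alpha hydrolase superfamily protein	M0006	1.98	1.33E-02
24D	Medtr3g070860	Leucoanthocyanidin dioxygenase-like protein	M0021,55,72	-4.36	6.33E-05
24D	Medtr2g008380	Somatic embryogenesis receptor-like kinase	M0021	-2.70	8.74E-05
24D	Medtr3g013890	3-Oxo-delta(4,5)-steroid 5-beta-reductase-like protein	M0021,55	-2.28	4.85E-04
24D	Medtr3g102730	3-Oxo-delta(4,5)-steroid 5-beta-reductase-like protein	M0021,55	-2.00	1.60E-03
24D	Medtr8g018570	Seed linoleate 9S-lipoxygenase	M0055,72	-4.82	3.12E-08
24D	Medtr7g417750	Allene oxide cyclase	M0055	-2.63	1.97E-02
24D	Medtr1g112230	Mevalonate diphosphate decarboxylase	M0064	-2.49	4.97E-11
24D	Medtr2g027300	Geranylgeranyl pyrophosphate synthase	M0064	-1.71	2.50E-20
24D	Medtr7g080060	Isopentenyl-diphosphate delta-isomerase	M0064	-1.70	9.35E-04
24D	Medtr7g085120	Nod factor-binding lectin-nucleotide phosphohydrolase	M0072	-3.82	1.37E-06
24D	Medtr7g417750	Allene oxide cyclase	M0072	-2.63	1.97E-02
48D	Medtr5g014100	Anionic peroxidase swpb3 protein	M0032	-3.28	3.71E-05
48D	Medtr2g062600	Lipid transfer protein	M0032, 132	-3.24	1.54E-06
48D	Medtr8g089300	CASP POPTRDRAFT-like protein	M0032, 132	-2.88	4.25E-03
48D	Medtr5g070010	Cytochrome P450 family-dependent fatty acid hydroxylase	M0032, 132	-2.87	1.72E-05
48D	Medtr5g064530	Leguminosin group485 secreted peptide	M0118, 132	-3.13	1.75E-06
48D	Medtr0097s0070	CASP POPTRDRAFT-like protein	M0118, 132	-3.04	4.96E-06
48D	Medtr4g415290	Glycerol-3-phosphate acyltransferase	M0118, 132	-2.80	1.20E-05
48D	Medtr1g071720	Lipid transfer protein	M0118	-2.46	4.90E-03
48D	Medtr2g009450	Leguminosin group485 secreted peptide	M0132	-3.10	1.22E-05
48D	Medtr8g079050	GDSL-like lipase/acylhydrolase	M0132	-3.00	2.61E-08
48D	Medtr3g463060	Cytochrome P450 family-dependent fatty acid hydroxylase	M0132	-2.68	2.61E-06
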