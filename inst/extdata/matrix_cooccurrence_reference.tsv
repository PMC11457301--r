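substance	with_technique	total	sm_pp	sm_op	is_curated_matrix
alpha-cyano-4-hydroxycinnamic acid	9178	11431	0.16	0.53	TRUE
2,5-dihydroxybenzoic acid	4293	7687	0.24	0.51	TRUE
trans-sinapic acid	517	4688	0.24	0.51	TRUE
3-hydroxypicolinic acid	505	626	0.20	0.40	TRUE
9-aminoacridine	459	2183	0.38	1.05	TRUE
2',4',6'-trihydroxyacetophenone	421	641	0.25	0.49	TRUE
1,5-diaminonaphthalene	241	452	0.33	1.24	FALSE
trans-2-[3-(4-tert-butylphenyl)-2-methyl-2-propenylidene]malononitrile	195	199	0.35	0.22	TRUE
2,5-dihydroxyacetophenone	181	267	0.26	0.62	FALSE
1,3-benzothiazole-2-thiol	152	952	0.27	0.80	FALSE
4-chloro-alpha-cyanocinnamic acid	80	83	0.27	1.11	FALSE
2-(4-hydroxyphenylazo)benzoic acid	75	137	0.39	0.43	TRUE
terthiophene	62	837	0.82	0.38	FALSE
1,8-bis(dimethylamino)naphthalene	42	233	0.54	0.94	FALSE
9,10-diphenylanthracene	34	524	0.36	0.31	FALSE
2,4-diphenyl-pyranylium	20	24	0.58	1.22	FALSE
poly(phenylenevinylene) polymer	19	314	1.00	0.32	FALSE
meso-tetrakis(pentafluorophenyl)porphyrin	18	69	0.91	1.11	FALSE
4-phenyl-alpha-cyanocinnamic acid amide	13	13	0.58	0.88	FALSE
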