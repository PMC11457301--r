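# Reference logP values for the Wildman-Crippen cross-implementation check.
# ref_logp computed with RDKit 2024.09.2 (Crippen.MolLogP), an independent
# implementation of the same published atomic-contribution method;
# ref_mw computed with RDKit Descriptors.MolWt.
name	smiles	ref_logp	ref_mw
alpha-cyano-4-hydroxycinnamic acid	C1=CC(=CC=C1/C=C(\C#N)/C(=O)O)O	1.38378	189.170
2,5-dihydroxybenzoic acid	OC1=CC=C(O)C(=C1)C(O)=O	0.79600	154.121
trans-sinapic acid	COc1cc(/C=C/C(O)=O)cc(OC)c1O	1.50720	224.212
3-hydroxypicolinic acid	Oc1cccnc1C(O)=O	0.48540	139.110
9-aminoacridine	Nc1c2ccccc2nc2ccccc12	2.97020	194.237
2,4,6-trihydroxyacetophenone	CC(=O)c1c(O)cc(O)cc1O	1.00600	168.148
1,5-diaminonaphthalene	Nc1cccc2c(N)cccc12	2.00420	158.204
2,5-dihydroxyacetophenone	CC(=O)c1cc(O)ccc1O	1.30040	152.149
2-mercaptobenzothiazole	Sc1nc2ccccc2s1	2.58500	167.258
4-chloro-alpha-cyanocinnamic acid	OC(=O)C(=Cc1ccc(Cl)cc1)C#N	2.33158	207.616
HABA	OC(=O)c1ccccc1/N=N/c1ccc(O)cc1	3.50580	242.234
2,2':5',2''-terthiophene	c1ccc(s1)-c1ccc(s1)-c1cccs1	5.20510	248.397
DMAN	CN(C)c1cccc2cccc(N(C)C)c12	2.97180	214.312
9,10-diphenylanthracene	c1ccc(cc1)-c1c2ccccc2c(-c2ccccc2)c2ccccc12	7.32700	330.430
dithranol	Oc1cccc2c1C(=O)c1c(O)cccc1C2	2.23300	226.231
norharmane	c1ccc2c(c1)[nH]c1cnccc21	2.71610	168.199
ferulic acid	COc1cc(/C=C/C(O)=O)ccc1O	1.49860	194.186
caffeic acid	Oc1ccc(/C=C/C(O)=O)cc1O	1.19560	180.159
nicotinic acid	OC(=O)c1cccnc1	0.77980	123.111
anthranilic acid	Nc1ccccc1C(O)=O	0.96700	137.138
adenosine	Nc1ncnc2c1ncn2[C@@H]1O[C@H](CO)[C@@H](O)[C@H]1O	-1.98000	267.245
alanine	C[C@H](N)C(O)=O	-0.58180	89.094
ascorbic acid	OC[C@H](O)[C@H]1OC(=O)C(=C1O)O	-1.40740	176.124
cholesterol	CC(C)CCC[C@@H](C)[C@H]1CC[C@H]2[C@@H]3CC=C4C[C@@H](O)CC[C@]4(C)[C@H]3CC[C@]12C	7.38870	386.664
cocaine	COC(=O)[C@H]1[C@@H](OC(=O)c2ccccc2)C[C@@H]2CC[C@H]1N2C	1.86770	303.358
glucose	OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1O	-3.22140	180.156
nicotine	CN1CCC[C@H]1c1cccnc1	1.84830	162.236
water	O	-0.82470	18.015
methanol	CO	-0.39150	32.042
acetonitrile	CC#N	0.52988	41.053
ethanol	CCO	-0.00140	46.069
acetic acid	CC(O)=O	0.09090	60.052
caffeine	Cn1cnc2c1c(=O)n(C)c(=O)n2C	-1.02930	194.194
aspirin	CC(=O)Oc1ccccc1C(O)=O	1.31010	180.159
ibuprofen	CC(C)Cc1ccc(cc1)C(C)C(O)=O	3.07320	206.285
paracetamol	CC(=O)Nc1ccc(O)cc1	1.35060	151.165
citric acid	OC(=O)CC(O)(CC(O)=O)C(O)=O	-1.24850	192.123
urea	NC(N)=O	-0.97620	60.056
tryptophan	N[C@@H](Cc1c[nH]c2ccccc12)C(O)=O	1.12230	204.229
phenylalanine	N[C@@H](Cc1ccccc1)C(O)=O	0.64100	165.192
sucrose	OC[C@H]1O[C@@](CO)(O[C@H]2O[C@H](CO)[C@@H](O)[C@H](O)[C@H]2O)[C@@H](O)[C@@H]1O	-5.39560	342.297
cellobiose	OC[C@H]1O[C@@H](O[C@H]2[C@H](O)[C@@H](O)C(O)O[C@@H]2CO)[C@H](O)[C@@H](O)[C@@H]1O	-5.39720	342.297
maltoheptaose-fragment (maltose)	OC[C@H]1O[C@H](O[C@H]2[C@H](O)[C@@H](O)C(O)O[C@@H]2CO)[C@H](O)[C@@H](O)[C@@H]1O	-5.39720	342.297
glycerol	OCC(O)CO	-1.66810	92.094
palmitic acid	CCCCCCCCCCCCCCCC(O)=O	5.55230	256.430
cholic acid	C[C@H](CCC(O)=O)[C@H]1CC[C@H]2[C@@H]3[C@H](O)C[C@@H]4C[C@H](O)CC[C@]4(C)[C@H]3C[C@H](O)[C@]12C	3.44870	408.579
serotonin	NCCc1c[nH]c2ccc(O)cc12	1.37470	176.219
dopamine	NCCc1ccc(O)c(O)c1	0.59900	153.181
chloroquine	CCN(CC)CCC[C@@H](C)Nc1ccnc2cc(Cl)ccc12	4.81060	319.880
sulfamethoxazole	Cc1cc(NS(=O)(=O)c2ccc(N)cc2)no1	1.36602	253.283
penicillin G	CC1(C)S[C@@H]2[C@H](NC(=O)Cc3ccccc3)C(=O)N2[C@H]1C(O)=O	0.86080	334.397
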