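name	synonyms	chebi_id	group	is_curated_matrix
alpha-cyano-4-hydroxycinnamic acid	CHCA;HCCA;4-hydroxy-alpha-cyanocinnamic acid		matrix	TRUE
2,5-dihydroxybenzoic acid	DHB;gentisic acid		matrix	TRUE
trans-sinapic acid	sinapic acid;sinapinic acid		matrix	TRUE
3-hydroxypicolinic acid	3-HPA		matrix	TRUE
9-aminoacridine	9-AA;aminacrine		matrix	TRUE
2',4',6'-trihydroxyacetophenone	THAP;trihydroxyacetophenone		matrix	TRUE
1,5-diaminonaphthalene	1,5-DAN		matrix	FALSE
trans-2-[3-(4-tert-butylphenyl)-2-methyl-2-propenylidene]malononitrile	DCTB		matrix	TRUE
2,5-dihydroxyacetophenone	DHAP		matrix	FALSE
1,3-benzothiazole-2-thiol	2-mercaptobenzothiazole;MBT		matrix	FALSE
4-chloro-alpha-cyanocinnamic acid	CCICA;ClCCA		matrix	FALSE
2-(4-hydroxyphenylazo)benzoic acid	HABA		matrix	TRUE
terthiophene	2,2':5',2''-terthiophene		matrix	FALSE
1,8-bis(dimethylamino)naphthalene	DMAN;proton sponge		matrix	FALSE
9,10-diphenylanthracene			matrix	FALSE
2,4-diphenyl-pyranylium	2,4-diphenylpyranylium		matrix	FALSE
poly(phenylenevinylene) polymer	PPV		matrix	FALSE
meso-tetrakis(pentafluorophenyl)porphyrin	F20TPP		matrix	FALSE
4-phenyl-alpha-cyanocinnamic acid amide	PhCCAA		matrix	FALSE
adenosine			nonmatrix	FALSE
alanine			nonmatrix	FALSE
ascorbic acid	vitamin C		nonmatrix	FALSE
chlorophyll			nonmatrix	FALSE
cholesterol			nonmatrix	FALSE
cisplatin			nonmatrix	FALSE
cocaine			nonmatrix	FALSE
glucose			nonmatrix	FALSE
nicotine			nonmatrix	FALSE
water			nonmatrix	FALSE
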