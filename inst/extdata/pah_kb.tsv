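# Curated drug-gene interaction knowledge base for six approved PAH drugs.
# One row per drug-gene edge. mechanism: inhibitor|inducer. pathology_role is a
# curation default: pathological unless the gene is regarded as compensatory
# (upregulated to alleviate pathology); see package documentation.
drug	drug_class	gene_symbol	gene_name	mechanism	pathology_role	refs
Ambrisentan	era	CCL19	C-C motif chemokine ligand 19	inhibitor	pathological	r14
Ambrisentan	era	CCL2	C-C motif chemokine ligand 2	inhibitor	pathological	r14
Ambrisentan	era	CCL5	C-C motif chemokine ligand 5	inhibitor	pathological	r14
Ambrisentan	era	EDN1	endothelin 1	inhibitor	pathological	r20
Ambrisentan	era	EDNRA	endothelin receptor type A	inhibitor	pathological	r20;r24
Ambrisentan	era	IL6	interleukin 6	inhibitor	pathological	r14
Ambrisentan	era	NOS3	nitric oxide synthase 3	inducer	compensatory	r20
Bosentan	era	CCL19	C-C motif chemokine ligand 19	inhibitor	pathological	r14
Bosentan	era	CCL2	C-C motif chemokine ligand 2	inhibitor	pathological	r14
Bosentan	era	CCL5	C-C motif chemokine ligand 5	inhibitor	pathological	r14
Bosentan	era	COL1A1	collagen type I alpha 1 chain	inhibitor	pathological	r26
Bosentan	era	EDN1	endothelin 1	inhibitor	pathological	r21
Bosentan	era	EDNRA	endothelin receptor type A	inhibitor	pathological	r21
Bosentan	era	EDNRB	endothelin receptor type B	inhibitor	pathological	r30
Bosentan	era	FN1	fibronectin 1	inhibitor	pathological	r26;r31
Bosentan	era	FST	follistatin	inhibitor	pathological	r26
Bosentan	era	IL6	interleukin 6	inhibitor	pathological	r14;r32
Bosentan	era	LGALS3	galectin 3	inhibitor	pathological	r26
Bosentan	era	INHBA	inhibin subunit beta A	inhibitor	pathological	r26
Bosentan	era	MMP2	matrix metallopeptidase 2	inhibitor	pathological	r34
Bosentan	era	NPPA	natriuretic peptide A	inhibitor	pathological	r26
Bosentan	era	NPPB	natriuretic peptide B	inhibitor	pathological	r26
Bosentan	era	PGIS	prostaglandin I2 synthase	inhibitor	compensatory	r35
Bosentan	era	TIMP1	TIMP metallopeptidase inhibitor 1	inhibitor	pathological	r26;r34
Macitentan	era	COL1A1	collagen type I alpha 1 chain	inhibitor	pathological	r26
Macitentan	era	EDNRA	endothelin receptor type A	inhibitor	pathological	r36;r37
Macitentan	era	EDNRB	endothelin receptor type B	inhibitor	pathological	r36;r37
Macitentan	era	FN1	fibronectin 1	inhibitor	pathological	r26
Macitentan	era	FST	follistatin	inhibitor	pathological	r26
Macitentan	era	LGALS3	galectin 3	inhibitor	pathological	r26
Macitentan	era	INHBA	inhibin subunit beta A	inhibitor	pathological	r26
Macitentan	era	MMP2	matrix metallopeptidase 2	inhibitor	pathological	r33
Macitentan	era	MMP9	matrix metallopeptidase 9	inhibitor	pathological	r33
Macitentan	era	NPPA	natriuretic peptide A	inhibitor	pathological	r26
Macitentan	era	NPPB	natriuretic peptide B	inhibitor	pathological	r26
Macitentan	era	TIMP1	TIMP metallopeptidase inhibitor 1	inhibitor	pathological	r26
Sildenafil	pde5_inhibitor	ANGPT1	angiopoietin 1	inhibitor	pathological	r38
Sildenafil	pde5_inhibitor	AT-1	angiotensin II receptor type 1	inhibitor	pathological	r38
Sildenafil	pde5_inhibitor	AT-2	angiotensin II receptor type 2	inhibitor	pathological	r38
Sildenafil	pde5_inhibitor	EDN1	endothelin 1	inhibitor	pathological	r38
Sildenafil	pde5_inhibitor	ECE1	endothelin converting enzyme 1	inhibitor	pathological	r38
Sildenafil	pde5_inhibitor	EDNRB	endothelin receptor type B	inhibitor	pathological	r38
Sildenafil	pde5_inhibitor	NOS2	nitric oxide synthase 2	inhibitor	pathological	r38
Sildenafil	pde5_inhibitor	NOS3	nitric oxide synthase 3	inhibitor	compensatory	r38
Sildenafil	pde5_inhibitor	PDE5A	phosphodiesterase 5A	inhibitor	pathological	r38
Sildenafil	pde5_inhibitor	VEGFA	vascular endothelial growth factor A	inhibitor	pathological	r38
Iloprost	prostacyclin	COL1A1	collagen type I alpha 1 chain	inhibitor	pathological	r28
Iloprost	prostacyclin	COL3A1	collagen type III alpha 1 chain	inhibitor	pathological	r28
Iloprost	prostacyclin	CCN2/CTGF	cellular communication network factor 2	inhibitor	pathological	r28
Iloprost	prostacyclin	ID1	inhibitor of DNA binding 1	inducer	compensatory	r39
Iloprost	prostacyclin	IL6	interleukin 6	inhibitor	pathological	r40
Iloprost	prostacyclin	MMP9	matrix metallopeptidase 9	inducer	pathological	r28
Iloprost	prostacyclin	TGFB1	transforming growth factor beta 1	inhibitor	pathological	r42
Iloprost	prostacyclin	TNF	tumor necrosis factor	inhibitor	pathological	r40
Treprostinil	prostacyclin	COL1A1	collagen type I alpha 1 chain	inhibitor	pathological	r27;r41
Treprostinil	prostacyclin	COL3A1	collagen type III alpha 1 chain	inhibitor	pathological	r27
Treprostinil	prostacyclin	FN1	fibronectin 1	inhibitor	pathological	r41
Treprostinil	prostacyclin	ID1	inhibitor of DNA binding 1	inducer	compensatory	r39
Treprostinil	prostacyclin	IL6	interleukin 6	inhibitor	pathological	r40
Treprostinil	prostacyclin	PPARA	peroxisome proliferator activated receptor alpha	inducer	compensatory	r43
Treprostinil	prostacyclin	PPARD	peroxisome proliferator activated receptor delta	inducer	compensatory	r44
Treprostinil	prostacyclin	PPARG	peroxisome proliferator activated receptor gamma	inducer	compensatory	r46
Treprostinil	prostacyclin	TIMP1	TIMP metallopeptidase inhibitor 1	inhibitor	pathological	r47
Treprostinil	prostacyclin	TGFB1	transforming growth factor beta 1	inhibitor	pathological	r41;r47
Treprostinil	prostacyclin	TNF	tumor necrosis factor	inhibitor	pathological	r40
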