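substrate	id	test_type	predicted	experimental
Glucose	glc	carbon	+	+
Cellobiose	cellb	carbon	+	+
Sorbitol	srb	carbon	+	-
Fructose	fru	carbon	+	+
Galactose	gal	carbon	+	-
Maltose	malt	carbon	+	+
Mannose	man	carbon	+	-
Sucrose	sucr	carbon	+	+
Xylose	xyl	carbon	+	-
Arabinose	arab	carbon	-	-
Rhamnose	rmn	carbon	-	-
Pyruvate	pyr	carbon	-	-
Succinate	succ	carbon	-	-
Citrate	cit	carbon	-	-
Glycerol	glyc	carbon	-	-
Pectin	pectin	carbon	-	-
Cellulose	cellul	carbon	+	+
Lignocellulose	lignoc	carbon	+	+
Acetate	ac	carbon	-	-
Fumarate	fum	carbon	-	-
N-Acetyl-glucosamine	glcnac	carbon	-	-
Lactate	lac	carbon	-	-
Maltodextrin	mdx	carbon	+	+
Methanol	meoh	carbon	-	-
Oxaloacetate	oaa	carbon	-	-
Xylan	xylan	carbon	+	+
Ethanol	etoh	carbon	-	-
Malate	mal	carbon	-	-
Formate	for	carbon	-	-
Raffinose	raff	carbon	+	+
Phenylalanine	phe	carbon	-	-
Arginine	arg	carbon	-	-
Leucine	leu	carbon	-	-
Proline	pro	carbon	-	-
Serine	ser	carbon	-	-
Threonine	thr	carbon	-	-
Pyridoxine	pydxn	vitamin	+	+
p-Aminobenzoic acid	pab	vitamin	-	-
Biotin	btn	vitamin	-	+
Cyanocobalamin	cbl	vitamin	+	+
Riboflavin	ribflv	vitamin	+	+
Folic acid	fol	vitamin	+	+
Pantothenate	pnto	vitamin	+	+
Nicotinic acid	nac	vitamin	+	+
Thiamin	thm	vitamin	+	+
Heme	pheme	vitamin	-	-
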