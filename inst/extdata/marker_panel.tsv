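ko_id	gene_symbol	pathway_group	metabolism_class
K15230	aclA	rTCA cycle	carbon-fixation
K15231	aclB	rTCA cycle	carbon-fixation
K15039	hbd	hydroxypropionate-hydroxybutyrate cycle	carbon-fixation
K15016	paaF	dicarboxylate-hydroxybutyrate and hydroxypropionate-hydroxybutyrate cycles	carbon-fixation
K00855	prkA	Calvin cycle	carbon-fixation
K01601	rbcL	Calvin cycle	carbon-fixation
K01602	rbcS	Calvin cycle	carbon-fixation
K08691	mcl	3-hydroxypropionate bi-cycle and ethylmalonyl pathway and formaldehyde assimilation	carbon-fixation
K14468	mcr	3-hydroxypropionate bi-cycle	carbon-fixation
K14470	mct	3-hydroxypropionate bi-cycle	carbon-fixation
K09709	meh	3-hydroxypropionate bi-cycle	carbon-fixation
K03520	coxL	CO oxidation	CO
K03519	coxM	CO oxidation	CO
K03518	coxS	CO oxidation	CO
K00436	hoxH	H2 oxidation	hydrogen
K16158	mmoX	methane oxidation	methane/C1
K05979	comB	coenzyme M biosynthesis	methane/C1
K06034	comC	coenzyme M biosynthesis	methane/C1
K08097	comA	coenzyme M biosynthesis	methane/C1
K13039	comE	coenzyme M biosynthesis	methane/C1
K00320	mer	C1 metabolism and methanogenesis	methane/C1
K00200	fwdA	C1 metabolism and methanogenesis	methane/C1
K00201	fwdB	C1 metabolism and methanogenesis	methane/C1
K00202	fwdC	C1 metabolism and methanogenesis	methane/C1
K00672	ftr	C1 metabolism and methanogenesis	methane/C1
K03390	hmd	C1 metabolism and methanogenesis	methane/C1
K14083	mtbA	C1 metabolism and methanogenesis	methane/C1
K00577	mtrA	C1 metabolism and methanogenesis	methane/C1
K10944	amoA	nitrification and methane oxidation	nitrogen
K10945	amoB	nitrification and methane oxidation	nitrogen
K10946	amoC	nitrification and methane oxidation	nitrogen
K02588	nifH	nitrogen fixation	nitrogen
K00370	narG	nitrification and denitrification and dissimilatory nitrate reduction	nitrogen
K00371	narH	nitrification and denitrification and dissimilatory nitrate reduction	nitrogen
K00362	nirB	dissimilatory nitrate reduction (DNRA)	nitrogen
K00363	nirD	dissimilatory nitrate reduction (DNRA)	nitrogen
K00374	narI	denitrification and dissimilatory nitrate reduction	nitrogen
K02567	napA	denitrification and dissimilatory nitrate reduction	nitrogen
K02568	napB	denitrification and dissimilatory nitrate reduction	nitrogen
K00368	nirK	denitrification	nitrogen
K15864	nirS	denitrification	nitrogen
K04561	norB	denitrification	nitrogen
K02305	norC	denitrification	nitrogen
K00376	nosZ	denitrification	nitrogen
K00367	narB	assimilatory nitrate reduction	nitrogen
K00372	nasA	assimilatory nitrate reduction	nitrogen
K00394	aprA	dissimilatory sulfate reduction	sulfur
K00395	aprB	dissimilatory sulfate reduction	sulfur
K11181	dsrB	dissimilatory sulfate reduction	sulfur
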