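clade	species	n_ligands	egf_like	nrg_like
Ctenophora	M. leidyi	1	1	0
Porifera	A. queenslandica	1	1	0
Placozoa	T. adhaerens	1	1	0
Cnidaria	N. vectensis	0	-	-
Cnidaria	H. magnipapillata	0	-	-
Xenacoelomorpha	X. bocki	2	1	1
Xenacoelomorpha	M. stichopi	5	4	1
Xenacoelomorpha	I. pulchra	5	2	3
Xenacoelomorpha	C. macropyga	2	0	2
Priapulida	P. caudatus	1	1	0
Priapulida	H. spinulosus	2	1	1
Nematoda	C. elegans	1	1	0
Arthropoda	T. castaneum	1	1	0
Arthropoda	D. melanogaster	4	3	1
Gastrotricha	L. squamata	2	2	0
Platyhelminthes	M. lignano	2	1	1
Platyhelminthes	P. vittatus	9	7	2
Platyhelminthes	S. mediterranea	9	8	1
Platyhelminthes	S. mansoni	1	0	1
Platyhelminthes	E. multilocularis	2	1	1
Mollusca	L. gigantea	1	1	0
Mollusca	C. gigas	1	0	1
Annelida	O. fusiformis	3	2	1
Annelida	C. teleta	4	4	0
Annelida	H. robusta	4	3	1
Nemertea	L. ruber	4	3	1
Bryozoa	M. membranacea	2	1	1
Brachiopoda	T. transversa	1	1	0
Brachiopoda	N. anomala	1	1	0
Hemichordata	S. kowalevskii	2	1	1
Echinodermata	S. purpuratus	1	0	1
Chordata	B. floridae	5	4	1
Chordata	C. intestinalis	2	2	0
Chordata	H. sapiens	11	7	4
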