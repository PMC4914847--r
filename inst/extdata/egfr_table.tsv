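clade	species	n_egfr	tm	sp	cys_rich	inactive_tk
Ctenophora	M. leidyi	1	1	Yes	3	No
Porifera	A. queenslandica	1	1	?	1	No
Placozoa	T. adhaerens	0	-	-	-	-
Cnidaria	N. vectensis	0	-	-	-	-
Cnidaria	H. magnipapillata	0	-	-	-	-
Xenacoelomorpha	X. bocki	2	1(2)	Yes	2(1), 3(1)	No
Xenacoelomorpha	M. stichopi	3	1(3)	Yes	2(1), 3(1), 4(1)	No
Xenacoelomorpha	I. pulchra	5	1(4), ?(1)	Yes(3), ?(2)	1(2), 3(2), ?(1)	No
Xenacoelomorpha	C. macropyga	3	1(3)	Yes	4(2), 1(1)	No
Priapulida	P. caudatus	1	1	?	3	No
Priapulida	H. spinulosus	1	1	Yes	3	No
Nematoda	C. elegans	1	1	Yes	3	No
Arthropoda	T. castaneum	1	1	Yes	2	No
Arthropoda	D. melanogaster	1	1	Yes	3	No
Gastrotricha	L. squamata	0	-	-	-	-
Platyhelminthes	M. lignano	8	1(6), ?(2)	Yes(5), ?(3)	1(1), 2(2), 3(1), 4(1), ?(3)	No
Platyhelminthes	P. vittatus	6	1(6)	Yes(5), ?(1)	2(2), 3(4)	No
Platyhelminthes	S. mediterranea	6	1(6)	Yes(5), ?(1)	3(4), 4(2)	No(5), Yes(1)
Platyhelminthes	S. mansoni	3	1(3)	Yes(1), ?(2)	3(1), 5(2)	No
Platyhelminthes	E. multilocularis	3	1(3)	Yes(1), ?(2)	3(2), 4(1)	No
Mollusca	L. gigantea	2	1(1), ?(1)	Yes(1), ?(1)	2(1), 3(1)	No(1), Yes(1)
Mollusca	C. gigas	2	1(1), ?(1)	?(2)	?	No
Annelida	O. fusiformis	1	1	Yes	3	No
Annelida	C. teleta	1	1	?	3	No
Annelida	H. robusta	6	1(4), ?(2)	?(6)	2(1), 3(1), 4(2), ?(2)	No
Nemertea	L. ruber	1	1	Yes	3	No
Bryozoa	M. membranacea	3	1(2), 2(1)	Yes(2), ?(1)	3	No
Brachiopoda	T. transversa	1	1	Yes	3	No
Brachiopoda	N. anomala	1	1	Yes	3	No
Phoronida	P. harmeri	1	?	?	?	No
Hemichordata	S. kowalevskii	1	1	?	4	No
Echinodermata	S. purpuratus	1	1	?	4	No
Chordata	B. floridae	1	?	?	?	No
Chordata	C. intestinalis	2	1	Yes(1), ?(1)	1(1), 3(1)	No
Chordata	H. sapiens	4	1	Yes	2	No(3), Yes(1)
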