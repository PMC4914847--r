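Package: EGFRcomplement
Title: Comparative Inference of the EGFR Pathway Complement Across Metazoa
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based identification and classification of epidermal growth
    factor receptors (EGFRs) and EGF ligands from protein domain architecture,
    with lightweight sequence scanners (EGF six-cysteine motif, transmembrane
    segments by Kyte-Doolittle hydropathy, signal peptides, cysteine-rich
    clusters, tyrosine-kinase domains with a catalytic-residue audit),
    similarity-based ligand clustering, and Dollo/Sankoff parsimony
    reconstruction of ancestral pathway complements, gains, losses and
    expansions on a fixed metazoan species tree. Includes a deterministic
    synthetic-proteome generator that instantiates published per-species
    domain-architecture surveys as test fixtures, the transcribed species-by-
    complement tables, and an end-to-end pipeline producing standard-format
    outputs (FASTA, GFF3, TSV, Newick, JSON).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    ape,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: Phylogenetics, Classification, SequenceMatching, Software
RoxygenNote: 7.3.3
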