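Package: transpoly
Title: Trans-Species Polymorphism Analysis for Cloned Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for detecting trans-species polymorphism in
    PCR-cloned gene-family sequence libraries, motivated by antimicrobial
    cathelicidin genes of Atlantic cod and related gadids. Provides
    singleton-based PCR-error screening and representative selection for
    clone libraries, paralog cluster assignment, sliding-window nucleotide
    diversity and Tajima's D, pairwise linkage disequilibrium D', a
    counting-based per-codon selection test with Fitch ancestral
    reconstruction, a permutation test quantifying allele-versus-species
    clustering on phylogenies, discriminant analysis of principal
    components on SNP matrices, and a synthetic clone-library generator
    with known paralog structure, balanced trans-species allele classes
    and injected PCR errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    MASS,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Biostrings,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
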