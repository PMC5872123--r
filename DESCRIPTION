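Package: smgcpan
Title: Pan-Genome Analysis and Gain/Loss Dynamics of Secondary Metabolite
    Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R:
    person("smgcpan", "developers", email = "smgcpan@example.org",
           role = c("aut", "cre"))
Description: Annotation-independent comparison of secondary metabolite
    biosynthetic gene clusters (SMGCs) across closely related bacterial
    genomes. Genes from predicted cluster regions are grouped into
    orthologous groups by Smith-Waterman protein alignment, maxbit score
    normalization and Markov clustering; clusters are then grouped into
    non-redundant SMGC families by binary Jaccard dissimilarity of their
    ortholog-group content. Downstream analyses partition the pan-SMGC
    repertoire into conserved core, clade-specific core, accessory and
    strain-specific families, compute frequency spectra, class tallies and
    enrichment statistics, and infer family gain and loss events on a
    phylogeny by Fitch and Dollo parsimony. A synthetic-evolution
    generator produces fully specified test datasets (phylogeny, evolving
    cluster repertoires, protein sequences, and ground truth) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
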