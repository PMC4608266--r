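Package: lincmir
Title: Discovery of lincRNAs Acting as miRNA Targets or Decoys
Version: 0.1.0
Authors@R:
    person("lincmir", "developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome-wide discovery of long intergenic noncoding RNAs (lincRNAs)
    that are cleaved by miRNAs or that sequester miRNAs as decoys (target
    mimics). Implements complementarity scanning of mature miRNAs against
    transcripts with nearest-neighbor hybridization energies (MFEsite,
    MFEperfect, MFEratio), plant-style target and decoy rule classification,
    degradome (PARE) cleavage validation with t-plot categories and empirical
    p-values, cross-species conservation tests of binding sites, assembly of
    miRNA-lincRNA-mRNA regulatory networks, and lincRNA function inference via
    co-expression and the competing endogenous RNA (ceRNA) hypothesis. Ships a
    synthetic-data module that generates rule-conformant inputs with known
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    igraph,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
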