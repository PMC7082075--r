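Package: sbmhunt
Title: Discovery of SNX-BAR-Binding Motifs in Membrane-Protein Cytoplasmic Tails
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Topology-restricted discovery of the bipartite SNX-BAR-binding
    motif (SBM) in the cytoplasmic tails of membrane proteins. Implements the
    variable-gap Type I ([ILMV]X[FY]X[RK]X{2-13}PhiXPhi) and Type II
    ([FYW]X[FY]X{3-15}PhiXPhi) motif grammars, cytoplasmic-region extraction
    from transmembrane topology, secondary-structure filter rules backed by a
    trainable GOR-style predictor or external predictions, folded-domain
    exclusion, hypergeometric GO-term enrichment of the candidate set, and
    single-site ("one set of sites") isothermal titration calorimetry fitting.
    Includes seeded synthetic-data generators (proteomes with planted motifs
    and rule-specific decoys, GO annotations with a planted enriched term,
    noisy thermograms) for end-to-end validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
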