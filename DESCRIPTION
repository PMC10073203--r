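Package: microorigin
Title: Dating the Evolutionary Origin of Human Microproteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the evolutionary origin of human small open reading
    frames (sORFs/"microproteins"). Given per-species orthologous sequences of
    an ORF and a rooted species tree with named human-lineage ancestors, the
    package aligns the region, fits branch lengths on the fixed topology,
    reconstructs marginal ancestral sequences (with indel states), dates ORF
    formation with a length-ratio intactness rule, dates transcriptional
    activation by Dollo parsimony over annotation, sequence-similarity and
    expression evidence (with a TPM-threshold escalation rule), combines the
    two into a putative origin, classifies the mode of origination (de novo
    versus undetermined), and scores origin-aware coding signatures
    (hexamer bias, codon-aware alignments, dN/dS, likelihood-ratio coding
    scores). A synthetic-data generator with known ground truth makes every
    stage testable without external genome-scale resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
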