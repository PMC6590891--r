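Package: slc6tools
Title: In Silico Characterization of SLC6 Transporter Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence-level characterization of solute carrier family 6
    (SLC6) membrane transporters: Kyte-Doolittle hydropathy and
    transmembrane-segment annotation, N-glycosylation sequon and cysteine
    inventories, affine-gap global alignment with BLOSUM62 and
    identity/similarity statistics, progressive multiple alignment with
    terminus trimming, projection of structural-template Na+/Cl-/substrate
    binding residues onto query sequences with a deterministic
    ion-dependence classification, neighbor-joining phylogenetics with
    nonparametric bootstrap supports and subfamily cluster assignment, and
    IUPAC degenerate-primer in silico PCR with nested-amplicon arithmetic.
    Includes seeded synthetic-data generators (protein families evolved on
    trees with invariant binding-site columns, membrane proteins with
    planted transmembrane segments, DNA templates with planted primer
    sites) so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
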