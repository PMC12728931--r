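Package: massembly
Title: Exact Molecular Assembly Indices and Joint Assembly Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the molecular assembly index (MA) of
    hydrogen-suppressed molecular graphs exactly: the fewest joining
    operations needed to construct a molecule from single-bond building
    blocks when previously assembled fragments can be reused. Duplicatable
    subgraphs are enumerated once and organised in a growth DAG; the
    assembly-state search combines dynamic programming over hashed states
    with a conditional addition-chain branch-and-bound, returning anytime
    upper bounds and a reconstructed minimal pathway. Joint assembly spaces
    over molecule sets and the Joint Assembly Overlap (JAO) similarity are
    built on the same engine. Includes SMILES/SDF ingestion, synthetic
    fixture generators and brute-force oracles for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: C++17
Imports:
    Rcpp,
    jsonlite,
    ChemmineR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
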