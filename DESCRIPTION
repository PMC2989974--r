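Package: editevol
Title: Evolution of RNA Editing Sites on Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the gain and loss of C-to-U RNA editing sites
    in plant mitochondrial genes on a fixed phylogeny. Calls edited sites from
    genomic DNA/cDNA alignment pairs, predicts them from protein conservation
    profiles, maps gains and losses by Fitch parsimony with ACCTRAN/DELTRAN
    resolution, estimates per-branch synonymous substitution rates by codon
    counting, dates trees by non-parametric rate smoothing, compares C-to-T
    change rates at edited sites against third codon positions with exact
    tests, correlates editing dynamics with substitution rate through
    sister-clade contrasts and phylogenetically independent contrasts, and
    scans branches for clustered losses consistent with retroprocessing
    (gene conversion with a cDNA copy). Includes a sequence simulator with
    full ground-truth event logs so every stage can be validated against
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
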