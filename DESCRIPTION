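Package: csabtools
Title: Scaffold Detection, Anchored Alignment and Subfamily Classification
    for CSab Defensins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative sequence analysis of cysteine-stabilised alpha-beta
    (CSab) defensins and defensin-like bacteriocins such as actifensin.
    Detects the six-cysteine three-disulphide scaffold, trims precursors to
    mature peptides, builds deterministic multiple alignments anchored on the
    scaffold cysteines, classifies peptides into the GXGCP and XTCD
    structural subfamilies by N-terminal motif and loop-length rules, scores
    conservation of the plectasin lipid II binding mechanism residues, and
    summarises subfamily spread across a supplied taxonomy. Includes a
    seeded synthetic corpus generator with planted motifs and a truth table
    so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
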