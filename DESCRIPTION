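Package: dosagemap
Title: Deterministic Linkage Mapping for Polyploids from Allele-Dosage Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds genetic linkage maps for diploid and polyploid mapping
    populations directly from integer allele-dosage genotypes. Pairwise
    recombination frequencies are estimated with a fast minimum-recombination
    heuristic, markers are grouped by single-linkage hierarchical clustering,
    ordered deterministically by optimal leaf ordering under the
    sum-of-adjacent-recombination-frequencies (SARF) criterion with a
    neighborhood extension for tie breaking, and spaced with the Haldane,
    Kosambi or Carter-Falconer mapping function. Linkage maps can be
    represented as dendrograms and compared with the Goodman-Kruskal gamma
    index, cophenetic correlation and permutation (Mantel-type) tests. A
    polyploid F2 meiosis simulator with configurable genotyping-error and
    missing-data rates supports validation studies end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
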