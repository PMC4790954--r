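Package: hetlink
Title: Intercross GBS Markers, Linkage Maps and QTL Mapping for Heterozygous Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls co-dominant intercross (hk x hk) markers from
    genotyping-by-sequencing data of a selfed-F1 (F2) family, builds a de novo
    genetic linkage map (EM two-point recombination fractions, LOD grouping,
    maximum-likelihood ordering, Kosambi distances, nearest-neighbour stress
    curation), and maps QTL for binary and quantitative traits: EM interval
    mapping, composite interval mapping, permutation thresholds, LOD support
    intervals, a joint two-trait mixed-model scan with cofactors and Li-Ji
    thresholding, and a causal model selection test. Includes a full F2/GBS
    simulator (read-depth-driven heterozygote undercalling, missingness, QTL
    trait architectures) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
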