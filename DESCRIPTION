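Package: refstab
Title: Reference-Gene Stability Analysis for RT-qPCR (geNorm, NormFinder,
    BestKeeper and Consensus Ranking)
Version: 0.1.0
Authors@R:
    person("refstab", "maintainers", email = "refstab@example.org",
           role = c("aut", "cre"))
Description: Tools for choosing stable reference (housekeeping) genes from
    RT-qPCR quantification-cycle (Cp/Cq) data. Reads wide or long delimited
    Cp tables with technical-replicate and group structure, converts Cp to
    relative quantities via amplification efficiencies (standard-curve
    estimation included), and ranks candidate genes with three established
    stability algorithms: geNorm (pairwise-variation M-values, stepwise
    exclusion and the V_n/n+1 criterion), NormFinder (model-based intra-
    and inter-group variance decomposition with an optimal two-gene
    combination), and BestKeeper (Cp-scale descriptives, the SD > 1 rule
    and correlation with the BestKeeper index). Per-method competition
    ranks are aggregated into a consensus ordering by the geometric mean
    of ranks. A seeded generator of grouped synthetic Cp matrices with
    known ground truth supports validation, and a command-line interface
    orchestrates the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
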