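Package: fungalcompete
Title: In Vitro Competition Analysis for Ectomycorrhizal Fungi
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse pairwise in vitro competition assays between
    ectomycorrhizal fungal strains grown at contrasting media pH. Estimates
    exponential-phase colony growth rates from log-linear fits, computes the
    effect-of-competition (EoC) ratio against self-vs-self baselines,
    growth-rate and patristic distance matrices, index-of-antagonism scores,
    and directed competitive networks, and compares phylogenetic-distance
    against growth-rate-distance crossed random-effects models of log EoC.
    Includes a synthetic-data generator that replicates the full experimental
    design with known ground truth so every stage is testable by parameter
    recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    lme4,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
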