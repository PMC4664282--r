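Package: mppscan
Title: QTL Mapping in Multiparent Recombinant Inbred Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for haplotype-based QTL mapping in multiparent panels of
    recombinant inbred lines (RILs), modelled on the two-panel design of the
    Drosophila Synthetic Population Resource. Includes parsing of TriKinetics
    DAM2 activity-monitor files and conversion of per-minute activity counts
    into per-fly death times; hidden Markov model inference of founder
    diplotype posteriors and their additive collapse; haplotype-regression
    genome scans with permutation-based genomewide thresholds and 2-LOD
    support intervals; broad-sense heritability from variance components;
    copy-number-variant imputation through the RIL haplotype mosaic and
    covariate-adjusted rescans; and a synthetic-data generator that emulates
    the statistical structure of such panels so that every stage of the
    pipeline can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
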