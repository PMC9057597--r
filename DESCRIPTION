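Package: trendcurve
Title: Dynamic Differential Expression for Time-Course RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies dynamic differentially expressed genes (DDEGs) in
    longitudinal bulk and pseudobulk RNA-seq experiments. Each gene's baseline
    fluctuation is modelled as a negative binomial (NB) count distribution with
    a per-gene dispersion, its non-baseline trajectory is fitted with a
    penalized NB smoothing spline, and fitted means are tested against the
    baseline 90 percent fluctuation interval; per-timepoint tail probabilities
    are combined with Fisher's method and adjusted across genes by
    Holm-Bonferroni. Fitted trajectories are segmented at break points (trend
    reversals) into human-readable patterns, summarised at the pathway level
    through a window-sliding TimeHeatmap with Fisher-exact enrichment, and
    compared between groups with a LOESS area-ratio permutation test. Includes
    pseudobulk construction from single-cell counts and a trajectory simulator
    with ground-truth labels for ROC benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    limma,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mgcv,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
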