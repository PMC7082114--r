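Package: chemoscreen
Title: Chemogenomic CRISPR Screen Scoring, Response Signatures and
    Spike-In Metagene Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for chemogenomic analysis of
    pooled CRISPR dropout screens run with and without a small-molecule
    inhibitor. Implements pairwise TMM normalization against the plasmid
    pool, negative-binomial fold-change estimation with fixed dispersion
    and prior counts, quantile normalization and first-quartile gene
    summarization; sensitizer/rescuer detection via negative-binomial
    generalized log-linear models with likelihood-ratio tests;
    sensitive-versus-insensitive expression response signatures with
    threshold-based target-set definition and multi-condition
    downregulation overlaps; spike-in-normalized strand-aware TSS
    metagene profiles with expression-matched control gene sets; and
    seeded synthetic-data generators with planted ground truth for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    edgeR,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
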