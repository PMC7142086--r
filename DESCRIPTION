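Package: msdendro
Title: Hierarchical Clustering of Untargeted MS/MS Spectra with Dynamic Ion Binning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Workflow for classifying untargeted LC-MS/MS features by their
    fragmentation patterns. Features are aligned to MS/MS spectra within m/z and
    retention-time tolerances, product ions are filtered by intensity and grouped
    by dynamic gap-based binning, and the resulting binary feature-by-ion
    occurrence matrix is clustered by complete linkage on Bray-Curtis or Jaccard
    distances with a threshold cut. Cluster ion-incidence tables and diagnostic-ion
    queries expose the signature fragments behind each cluster. Companion tools
    enumerate C/H/(N)/O elemental compositions for accurate fragment masses and
    compute adduct and aggregate-ion masses (M+H, M+NH4, M+ACN+H, 2M, 3M) with ppm
    errors, as used to classify firefly lucibufagin steroids. A deterministic
    synthetic-data generator with planted cluster structure supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mzR,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    ape,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
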