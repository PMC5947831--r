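Package: marshniche
Title: Gaussian-Process Niche Models for Saltmarsh Restoration Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether restored saltmarshes fail to match
    natural reference marshes because of environmental conditions (position
    in the tidal frame, sediment redox potential) or because of altered
    succession. Provides quadrat-survey ingestion with tidal-frame and redox
    standardization, a synthetic survey generator with known ground truth,
    Gaussian-process presence/absence niche models (probit link, Laplace
    approximation), repeated-split cross-validation with AUC, posterior
    transfer prediction to restored marshes, marsh-age effects at the latent
    optimum, hierarchical partitioning of predictor importance, and
    observed-versus-expected tidal-position analyses with rank-based tests
    and false-discovery-rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
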