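Package: ssfwalk
Title: Step-Selection Functions Coupled with Individual-Based Movement
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Fits step-selection functions (SSF) with latent internal-state
    covariates and drives a biased correlated random walk simulator with the
    fitted SSF, for large herbivores on gridded winter landscapes. Latent
    covariates (a 72-hour energy ledger and a bounded spatial-memory patch
    list) are generated by replaying GPS tracks through energetics and memory
    submodels. Provides conditional logistic estimation with cluster-robust
    sandwich variance and QIC model selection, k-fold rank-bin
    cross-validation, resource-selection-function and home-range
    emergent-pattern validation, hardwood-encroachment scenario transforms,
    and seeded synthetic landscape and track generators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
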