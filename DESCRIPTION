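Package: bioage
Title: Biomarker-Based Biological Age Estimation and Survival Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates sex-specific biological ages from clinical biomarker
    panels using varimax-rotated principal components and the Klemera-Doubal
    method, decomposes biomarker importance, and evaluates biological versus
    chronological age for predicting chronic-disease mortality and age-related
    hospital admissions via Cox partial-likelihood comparisons, Harrell's
    C-indices, and Kaplan-Meier stratification of age-acceleration groups.
    Includes a synthetic-cohort generator with a latent aging rate, block-
    correlated biomarkers, healthy-subset eligibility fields, and right-
    censored outcomes, so the full pipeline is testable without cohort access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
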