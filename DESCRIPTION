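Package: spotopls
Title: OPLS Regression of 2-DE Spot Intensities Against Clinical Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orthogonal projections to latent structures (OPLS) regression of
    two-dimensional gel electrophoresis (2-DE) spot-intensity tables against
    clinical outcomes such as pain intensity, psychological distress, body mass
    index and age. Implements the single-response OPLS algorithm with
    cross-validated Q2, variable-influence-on-projection (VIP) scores,
    jack-knifed coefficient confidence intervals, CV-ANOVA model validation,
    two-step VIP-based variable selection, PCA screening for multivariate
    outliers, shared-proteoform confounder compensation across models, and a
    synthetic cohort generator with planted latent associations for validating
    the full pipeline against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
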