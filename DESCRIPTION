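Package: promap
Title: Model-Based Differential Abundance Analysis of Isotope-Labeled
    Proteomic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical comparison of two isotope-labeled (iTRAQ/TMT)
    quantitative proteomic profiles without technical replicates. Builds an
    intensity-dependent error model directly from the profiles under
    comparison via a sliding-window quantile-quantile regression on the MA
    plot, fits a global exponential variance function, and assigns each
    protein a two-tailed P-value and Z-statistic for differential abundance.
    Includes trimmed-total-intensity normalization, multi-run integration
    (best and second-best P-values, Stouffer-style average Z), a
    permutation-based false discovery rate, a direction-consistency score
    against an external reference, and a synthetic-data generator emulating
    the model's assumptions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
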