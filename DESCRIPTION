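Package: oswm
Title: Spike-Train Analysis for Observational Spatial Working Memory Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for paired prefrontal (anterior cingulate,
    ACC) and hippocampal CA1 single-unit recordings in observational spatial
    working memory tasks. Provides trajectory-selectivity indices with
    permutation nulls, correct-versus-error difference indices, detection of
    sharp-wave-ripple-associated population burst events from multiunit
    activity, memoryless Poisson Bayesian replay decoding with time-bin
    shuffle significance, ACC-CA1 coupling statistics, a plain-text session
    bundle format, and a synthetic session generator with ground truth for
    end-to-end parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
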