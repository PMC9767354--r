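Package: litsim
Title: Simulating Published Scientific Literatures Under Selective Publication and Bias
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Monte Carlo model of a scientific literature produced by
    null-hypothesis significance testing combined with selective
    publication. True effect sizes (Cohen's d) follow configurable
    two-component normal mixtures; each simulated experiment draws two
    samples, applies a pooled-variance Student's t-test, and is published
    when significant, with a bias parameter governing how often
    non-significant experiments are re-run until significance. The
    resulting literatures are evaluated with diagnostic metrics: positive
    predictive value, type S (sign) error rates, type M (exaggeration)
    factors, and p-curves. Includes the closed-form bias-adjusted positive
    predictive value of the diagnostic-screening framework, named scenario
    presets, parameter sweeps, and reproducible seeded batch runners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
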