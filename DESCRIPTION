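Package: dustconv
Title: Conversion of Inhalable to Respirable Dust Concentrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating respirable dust concentrations from
    inhalable dust measurements in retrospective occupational exposure
    assessment. Pairs single-fraction workplace dust measurement records by
    a deterministic multi-variable matching procedure, assigns pairs to a
    taxonomy of working-activity, material, combined and heuristic groups,
    fits per-group power-law conversion functions c_R = c_I^k * exp(C0) by
    ordinary least squares in log space with confidence bands and residual
    diagnostics (Durbin-Watson, Monte-Carlo Lilliefors), and ships a
    registry of published conversion functions derived from the German MEGA
    exposure database together with a seeded synthetic-data generator that
    emulates its paired-measurement structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nortest,
    optparse,
    withr
Config/testthat/edition: 3
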