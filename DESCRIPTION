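Package: addisgraph
Title: Graphical Adaptive-Discarding Procedures for Online Error Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Online multiple testing with familywise error rate (FWER),
    per-family error rate (PFER) and false discovery rate (FDR) control for
    streams of hypotheses whose p-values may be locally dependent or tested
    asynchronously, as in platform trials with shared control arms.
    Implements adaptive-discarding graphical procedures (ADDIS-Graphs) that
    propagate unspent significance level along user-chosen transfer weights,
    their conflict-set adjusted versions, the ADDIS-Spending baseline they
    uniformly improve, closed (rejection-aware) variants, and an FDR graph
    with rejection-triggered wealth gains. Includes conflict-set derivation
    from lags, batches and treatment-arm timelines, a batch-dependent
    Gaussian p-value simulator with Monte-Carlo error-rate estimators, CSV
    input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
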