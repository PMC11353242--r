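Package: cinmetrics
Title: Quantifying Chromosomal Instability from Shallow Copy-Number
    Profiles, Karyotype Spreads and Microtubule Plus-End Tracking
Version: 0.1.0
Authors@R:
    person("cinmetrics", "developers", email = "cinmetrics@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for measuring chromosomal instability
    (CIN) in paired control versus knock-down cell lines. Provides a
    shallow whole-genome copy-number stage (GC-bias correction,
    median-of-ratios normalisation, recursive binary segmentation with
    permutation-calibrated splits, integer copy-number calls), a
    differential "distance from baseline" classifier that subtracts
    locus-matched log ratios and partitions the genome into regions
    closer to, further from, or unchanged relative to the control-defined
    zero baseline, karyotype and event-count statistics (variance F-test,
    Fisher's exact test, Mann-Whitney), and an EB3 comet-tracking chain
    (difference-of-Gaussians detection, sub-pixel localisation,
    linear-assignment linking, per-cell microtubule growth speeds).
    Every input can be produced by the included simulators with known
    ground truth, so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
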