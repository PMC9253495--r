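Package: circashift
Title: Circadian Rest-Activity and Temperature Rhythm Analysis for
    Shift-Worker Telemonitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying circadian and ultradian rhythm disruption
    in telemonitored shift workers from per-minute chest accelerometry and
    surface temperature.  Fits hidden Markov models whose transition
    probabilities are modulated by one or two circadian oscillators (work
    and free days), derives rest-quality summaries (p1-1, rest profile,
    rest amount, centre time of rest, Rhythm Index), estimates temperature
    spectra with bootstrap confidence intervals and ultradian sub-periods
    within decoded rest bouts, clusters daily rest profiles with Ward
    linkage, and relates paired work/free-day responses to subject
    covariates through bivariate copula regression with AICc model
    selection.  A synthetic-cohort generator emulating day- and night-shift
    schedules makes the whole pipeline testable without access to the
    request-only study data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
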