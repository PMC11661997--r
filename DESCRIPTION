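Package: waveanon
Title: K-Anonymity and T-Closeness for Clinical Waveform Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Anonymizes sets of clinical waveform curves (airway flow,
    airway pressure, oxygen saturation and similar single-channel
    physiological signals) by grouping whole curves into equivalence
    classes that satisfy k-anonymity and approach t-closeness, and
    releasing a per-class lower/upper hull instead of the raw curves.
    Curve similarity is measured with the discrete Frechet distance,
    distribution distance with the Earth Mover's Distance over a
    similarity clustering of the population, and information loss with a
    generalization loss metric on the released hull.  The time axis can
    be split into segments (fixed-length, manual, or by a windowed
    Frechet similarity heuristic) so that class assignment is a
    semi-local decision, and a privacy/utility report (information loss,
    median relative error, achieved t) is produced for every run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    boot,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
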