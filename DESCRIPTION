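Package: verpmark
Title: Visual Event-Related Potential Biomarkers for Cataract-Reversal
    Classification
Version: 0.1.0
Authors@R:
    person("VERP", "Maintainers", email = "maintainer@verpmark.org",
           role = c("aut", "cre"))
Description: Tools for developing and validating electrophysiological
    biomarkers of congenital visual deprivation from visual event-related
    potentials (VERPs). Implements the full pipeline: seeded synthetic EEG
    cohort simulation (evoked components, 1/f background, alpha activity,
    ocular artifacts), epoch preprocessing (average reference, zero-phase
    filtering, ocular and response-contamination rejection, left-field
    electrode mirroring), P1-wave feature extraction with across-electrode
    standard-score normalization, the mean posterior P1 (MPP1) biomarker,
    a linear support-vector-machine topography classifier (SVMP1), and the
    accompanying inferential machinery: ROC curves with Youden-J optimal
    thresholds, DeLong confidence intervals, stratified bootstrap AUC
    comparison, cluster-based permutation tests, Cohen's kappa, and group
    and confound regression models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
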