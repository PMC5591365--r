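Package: gbmgrade
Title: Pre-Operative MRI Complexity Grading for Supratentorial Glioblastoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a five-feature pre-operative MRI complexity grading
    system for supratentorial glioblastoma: periventricular location,
    corpus callosum or bilateral location, eloquent location, tumour size,
    and associated oedema, each scored one point and summed to a 0-5 score
    with low/moderate/high complexity classes. Provides geometric feature
    extraction from co-registered binary segmentation masks (anisotropic
    Euclidean distance transforms, exact 3D Feret diameter, midline
    crossing), the grading rules, cohort validation statistics
    (grade-stratified outcome summaries, Pearson chi-square association
    tests, Cohen's kappa inter-rater agreement with asymptotic standard
    error), and synthetic data generators: geometric phantoms with analytic
    ground truth and simulated cohorts with configurable feature
    prevalences, class-conditional outcome rates, and a noisy second rater.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
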