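Package: pelviQC
Title: Positioning Quality Assessment for Ventrodorsal Canine Pelvis Radiographs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools for objective positioning-quality control of ventrodorsal
    hip extended (VDHE) radiographs used in canine hip dysplasia screening.
    Segments the two obturator foramina, measures their areas and maximum
    medial-lateral widths together with iliac wing widths, converts left-right
    asymmetry into an estimate of pelvic longitudinal rotation via published
    regression calibrations, and classifies radiographs as acceptable or not
    against an asymmetry threshold. Includes a synthetic pelvis phantom
    generator with analytic ground truth, a compact trainable encoder-decoder
    segmentation network, and the statistical toolbox used in
    method-agreement studies of this kind: Welch's ANOVA with Games-Howell
    post hoc tests, effect sizes, Bland-Altman limits of agreement,
    intraclass correlation, standard error of measurement, and power/sample
    size calculators based on noncentral distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
biocViews: Software, Segmentation, StatisticalMethod
RoxygenNote: 7.3.3
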