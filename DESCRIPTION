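Package: morphid
Title: Subject Identification from Brain Morphometric Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies individual subjects from tabular brain-morphometric
    features measured at repeated scan sessions. Provides readers for
    FreeSurfer-style wide feature tables, a longitudinal synthetic-cohort
    generator with controllable between-subject signature variance,
    scan-rescan noise and annual drift, two identification engines
    (multi-class linear discriminant analysis with covariance shrinkage,
    and k-nearest-neighbour voting weighted by inverse squared Euclidean
    distance), a train/test time-point protocol with Gaussian-noise and
    sample-size robustness sweeps, forward stepwise discriminant feature
    selection under Wilks' lambda, and a repeated-measures comparison
    battery (Cochran's Q, exact McNemar, Bonferroni-Holm).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, MASS, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
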