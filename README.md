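# morphid

Subject identification from brain-morphometric feature tables.

Repeated structural MRI of the same people yields tabular anatomical
measures — regional cortical thickness, surface area and volume from a
cortical parcellation, plus global and subcortical composites — that are
remarkably stable within a person and variable between people. `morphid`
treats each subject as a class and asks whether a held-out scan can be
assigned back to the right person from those measures alone: a "brain
fingerprint" built from ordinary FreeSurfer-style tables rather than from
specialised shape descriptors. It is aimed at researchers studying the
individuality and test–retest stability of morphometric measures, and at
anyone who needs a reproducible harness for identification experiments on
longitudinal feature tables.

## What it implements

* **Feature tables and sets** — readers/writers for wide TSV/CSV tables
  (one row per subject-scan), and a packaged schema defining the five
  canonical anatomical feature sets: `THICKNESS`, `AREA`, `VOLUME` (148
  Destrieux regions each), `11LBR` (11 large-brain-region composites) and
  `ALL` (510 features).
* **Synthetic longitudinal cohorts** — a generative model
  `x_ijt = mu_j (1 + delta_j (t-1)) + a_ij + e_ijt` with a stable
  per-subject signature `a_ij ~ N(0, tau_j^2)`, scan–rescan noise
  `e_ijt ~ N(0, sigma_j^2)` and a small shared annual drift `delta_j`,
  so every stage is testable without access to any private cohort. The
  identifiability knob is the intraclass correlation
  `ICC = tau^2 / (tau^2 + sigma^2)` (default ≈ 0.94).
* **Two identification engines** — multi-class linear discriminant
  analysis with identity-target covariance shrinkage
  `S_lambda = (1-lambda) S + lambda (tr S / p) I`, and weighted k-nearest
  neighbours where each neighbour votes with weight `1/d^2` (inverse
  squared Euclidean distance).
* **The experiment protocol** — two of three annual scans train, the third
  tests; per-subject one-vs-rest confusion accounting with macro accuracy,
  sensitivity, specificity and F1; white-Gaussian-noise robustness sweeps
  over nine levels (0–40 % of the training SD) and sample-size sweeps over
  19 cohort sizes (10–190).
* **Stepwise feature selection** — greedy forward selection under Wilks'
  Λ = det(W)/det(T), capped at 11 features, with per-step test metrics.
* **The comparison battery** — Cochran's Q across feature sets and noise
  levels, exact McNemar tests between engines, Bonferroni–Holm adjustment
  across all 17 tests as one family.

## Worked example

```r
library(morphid)

cfg <- cohort_config(n_subjects = 191, seed = 1)
cfg
#> cohort_config: 191 subjects x 3 timepoints, 510 features (seed 1)
#> signature ICC: 0.941 (median across features); drift -0.50 %/yr

cohort <- generate_cohort(cfg)
run_identification(cohort, "11LBR", engine = "lda", seed = 7)
#> identification_report: lda on 11LBR (noise 0), N = 191
#>   ACC 1.000  SENS 1.000  SPEC 1.000  F1 1.000

run_identification(cohort, "11LBR", engine = "wknn", noise_level = 0.40, seed = 7)
#> identification_report: wknn on 11LBR (noise 0.4), N = 191
#>   ACC 0.999  SENS 0.921  SPEC 1.000  F1 0.902
```

The first run shows that with a stable anatomical signature (ICC ≈ 0.94)
even the 11 global composites identify all 191 subjects perfectly. The
second degrades the held-out scans with Gaussian noise at 40 % of each
feature's training SD: sensitivity (the fraction of subjects whose
held-out scan is correctly assigned) drops to 0.92, while macro accuracy
and specificity still round to 1.00 — with one test scan per subject and
191 classes, every one-vs-rest confusion table is dominated by true
negatives, so accuracy stays near 1 even when identification fails.

A command-line wrapper over the same functions ships in
`inst/cli/morphid.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "morphid.R", package = "morphid"))') \
  simulate --n 191 --seed 1 --out cohort.tsv
```

with subcommands `simulate`, `identify`, `sweep-noise`, `sweep-size`,
`stepwise` and `compare`; every run writes a JSON manifest recording its
seeds and options.

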