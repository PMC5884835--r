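---
title: "Identifying subjects from morphometric feature tables: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying subjects from morphometric feature tables: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphid)
```

# The identification problem

Classification assigns observations to a small number of classes with many
training samples each. Identification inverts the ratio: with N subjects
scanned M times, each subject is a class with M samples, the class count
equals the subject count, and each class's test set is a single held-out
scan. `morphid` implements this protocol for tabular brain-morphometric
features in the three-scan design: two annual scans train the engines, the
third is identified.

Evaluation is one-vs-rest per subject. Because each class has exactly one
positive test scan among N, the per-class confusion table is dominated by
true negatives, and macro *accuracy* and *specificity* stay near 1.00 even
when many subjects are misidentified. Macro *sensitivity* (the fraction of
subjects whose held-out scan is correctly assigned) and *F1* are the
discriminating metrics; the package reports all four so that this
asymmetry — a structural property of identification, not a bug — is
visible. The accounting identity `SPEC = 1 - (1 - SENS)/(N - 1)` (macro,
with one test row per class) links the two directly.

# The synthetic cohort generator

Real longitudinal cohorts of this kind are typically not public, so the
generator is a first-class module, not a test fixture. Feature j of
subject i at scan t is drawn as

$$x_{ijt} = \mu_j\,(1 + \delta_j (t-1)) + a_{ij} + e_{ijt},
\qquad a_{ij} \sim N(0, \tau_j^2),\quad e_{ijt} \sim N(0, \sigma_j^2),$$

independent across subjects, features and scans. The three terms encode
the premise that makes anatomical identification possible: a *stable*
per-subject signature $a_{ij}$ (constant over time), small *shared* aging
drift $\delta_j$ (deterministic, identical for everyone, so it carries no
identity information), and scan–rescan measurement noise $e_{ijt}$.

Defaults, and why:

* **Cohort shape**: 191 subjects × 3 annual scans — the scale of the
  longitudinal healthy-aging cohorts this design targets, and the minimum
  scan count that leaves two training scans per class.
* **Baselines** $\mu_j$: drawn once per configuration, log-uniform within
  physiological ranges per modality (cortical thickness ≈ 2–3 mm,
  regional areas 10²–3·10³ mm², volumes 10³–10⁵ mm³). Mixing units is
  deliberate: it is exactly what makes unstandardized Euclidean distances
  meaningless (see scaling below).
* **Signature and noise scales**: $\tau_j = 0.08\,\mu_j$,
  $\sigma_j = 0.02\,\mu_j$, giving an intraclass correlation
  $\mathrm{ICC} = \tau^2/(\tau^2+\sigma^2) \approx 0.94$ for every
  feature. Published test–retest studies of FreeSurfer-style measures
  report ICCs mostly in the 0.8–0.95 range; 0.94 represents a
  good-quality single-site cohort. ICC is the single knob governing
  identifiability, and the robustness tests sweep it explicitly.
* **Drift**: −0.5 %/yr, inside the ≤ 1 %/yr envelope reported for
  anatomical change in older adults. Drift is applied multiplicatively to
  $\mu_j$, not to $a_{ij}$, so the signature itself is time-invariant.

What the generator deliberately does **not** emulate: inter-feature
correlation (real regional measures are strongly correlated through head
size and global atrophy; here features are independent given the subject),
heavy-tailed or skewed measurement error, site/scanner effects, and
missing scans. Consequently the default cohort is an *easier*
identification problem than real data at the same ICC — passing the test
suite demonstrates that the pipeline is correct and that its qualitative
behaviour (noise degradation, sample-size trends, accuracy/sensitivity
asymmetry) is right, not that real cohorts would yield the same numbers.

One subtlety the generator exposed: in a *zero-signature* cohort
($\tau = 0$) the shared drift makes identification slightly *worse* than
chance, because a subject's own training scans are never at the held-out
time point (their mean differs by the drift step) while two-thirds of the
other subjects have a training scan exactly there. The chance-level
controls therefore set the drift to 0, and replicate over independent
cohort draws so that the binomial error bar applies.

# The identification engines

**Shrinkage LDA.** Class means are per-subject training means; the pooled
within-class covariance S (divisor n − K) is shrunk towards a scaled
identity, $S_\lambda = (1-\lambda) S + \lambda\,(\mathrm{tr}\,S/p)\,I$,
and the Gaussian equal-covariance discriminant
$\delta_k(x) = x^\top S_\lambda^{-1}\mu_k - \tfrac12 \mu_k^\top
S_\lambda^{-1}\mu_k + \log \pi_k$ is maximized. Shrinkage is necessary,
not cosmetic: with 510 features and 191 classes × 2 training scans the
within-class scatter has rank at most 191 and plain LDA is undefined. The
identity-target form is the simplest convex combination that guarantees
positive definiteness for any $\lambda \in (0,1]$ when
$\mathrm{tr}\,S > 0$ and reduces exactly to classic LDA at $\lambda = 0$;
the default $\lambda = 0.1$ is deliberately mild, since with balanced
classes the decision rule is insensitive to the precise value. Priors are
uniform (every subject contributes the same number of scans). Two
degenerate-input rules: if $\mathrm{tr}\,S = 0$ (no within-class variation
anywhere, e.g. noise-free repeat scans) the target falls back to the plain
identity, making the rule Euclidean nearest-mean — the correct limit — and
score ties are resolved to the earliest class label under a small relative
tolerance (1e-9), so that analytically exact ties (e.g. a query equidistant
from two class means) resolve deterministically despite rounding.

**Weighted KNN.** Training scans are stored verbatim; the k nearest
exemplars by Euclidean distance vote with weight $1/d^2$. A query
coinciding with an exemplar (d = 0) is assigned that exemplar's class
immediately — the exact-match semantics we prefer over an
$1/(d^2+\varepsilon)$ regularization, which would blur it. The default
k = 3 keeps the neighbourhood no larger than one subject's scan count, so
a subject's own scans can dominate their query. Tie rules are
deterministic and order-free: exemplars tied with the k-th distance all
enter; score ties break by the smallest single neighbour distance, then by
earliest label. Predictions are therefore invariant to training-row
permutation, which the suite checks.

**Standardization.** Features are z-scored on training mean/SD (sample
convention, n − 1) before either engine, by default. Raw features mix mm,
mm² and mm³ so unscaled Euclidean distances would be dominated by the
largest volumes; LDA decisions are unaffected in exact arithmetic (affine
invariance, also tested), so one shared default keeps the two engines
comparable. `scale = FALSE` restores raw features.

# Noise and sample-size robustness

"Adding x % noise" is defined as adding independent Gaussian noise to each
*test* feature with SD equal to x % of that feature's *training* SD.
Alternatives (signal-power SNR, percent of raw magnitude) are less
portable across features with wildly different units; the training-SD
convention is scale-free, exactly reproducible, and monotone in the level.
Noise is applied after standardization (equivalently, relative to the
training spread) and never touches the training scans. The canonical sweep
uses the nine levels 0, 5 %, …, 40 %; the size sweep subsamples subjects
without replacement at 10, 20, …, 190 (clipped to the cohort). Sweeps
accept replicate counts with derived seed streams; the single-draw default
mirrors the original protocol.

The time-point split defaults to `per_subject_random` — each subject's
held-out scan drawn independently — as the most general reading of a
random train/test selection; `global_random` (one shared held-out wave)
and `fixed` are available, and the split seed is recorded in every report.

# Stepwise feature selection

Forward selection under Wilks' Λ = det(W)/det(T): at each step the
candidate minimizing Λ of the augmented subset joins, computed on training
data only; after each step the shrinkage discriminant is refit on the
selected subset and scored on the held-out scans. Λ is the standard
stepwise-discriminant criterion; entry/removal F-thresholds are
deliberately omitted in favour of the hard cap of 11 features, the only
selection bound the protocol specifies (selection also stops early when no
candidate improves Λ by more than 1e−12 — on an easy cohort fewer than 11
steps may be taken). On subsets where the total scatter is singular the
same identity-target shrinkage as the classifier is applied to both
scatter matrices before taking determinants; a subset with zero
within-class scatter and separated means scores Λ = 0, the perfect-
separation limit.

# The comparison battery

Per-subject correct/incorrect flags are the only dichotomous per-subject
outcome the protocol yields, and they are matched across conditions
whenever the same subjects and split are reused. The battery assembles:
per engine, Cochran's Q across the five feature sets at no noise (2
tests); per engine × feature set, Cochran's Q across the nine noise levels
(10 tests); per feature set, McNemar between the engines at no noise (5
tests) — 17 tests, Holm-adjusted as one family (entry threshold
0.05/17 ≈ 0.0029). McNemar defaults to the exact doubled binomial tail —
conservative and verifiable by full sign-flip enumeration — with the
continuity-corrected chi-square as an option. A Cochran's Q denominator of
zero (every subject constant across conditions) is reported as statistic
0, p = 1, flagged degenerate: there is no discordance to test.

# Numerical and testing choices

* All randomness flows through explicit integer seeds; sub-seeds for
  replicate streams are derived by a fixed 32-bit LCG step so parallel
  axes never share a stream. Same seed ⇒ bit-identical outputs.
* Tables are written at full double precision (`%.17g`), so a write/read
  round trip is exact.
* The test suite exercises the same code paths as the full 510-feature
  schema on reduced schemas (2–4 regions, 8–14 features) and cohorts of
  10–30 subjects; the full-width checks (510-feature selection, stepwise
  under the 11-step cap, the 191-subject grid) run at the canonical sizes.
  Monte-Carlo checks (moment recovery at n = 500, chance-level nulls at
  n = 100 × 20 seeds, 200 null batteries for family-wise error) use fixed
  seeds and error bands of 3–4 standard errors.
* The extra-measure list completing the 510-feature schema is a
  reconstruction from standard FreeSurfer aseg/global names (the original
  supplement is not public); it is flagged as such in the schema
  documentation and everything downstream is name-agnostic.

# Known limitations

Independent features make the synthetic default cohort easier than real
data; identification metrics near 1.0 on it are a property of the
generative model at ICC 0.94, not a claim about any real cohort. The
battery's chi-square reference for Cochran's Q is asymptotic and can be
anticonservative for very small cohorts (< ~20 subjects); the exact
McNemar option has no such caveat. No cross-validation machinery beyond
the 2-train/1-test design is provided, and identification scores are not
calibrated into probabilities.
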