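#' Configuration of a synthetic longitudinal morphometric cohort
#'
#' Defines the generative model for a cohort of `n_subjects` scanned at
#' `n_timepoints` annual sessions. Each feature j follows
#'
#'   x_ijt = mu_j * (1 + delta_j * (t - 1)) + a_ij + e_ijt
#'
#' with a stable per-subject anatomical signature a_ij ~ N(0, tau_j^2),
#' independent scan-rescan measurement error e_ijt ~ N(0, sigma_j^2), and a
#' deterministic annual drift of `annual_drift_fraction` (fraction of mu_j
#' per year, shared by all subjects). The signature is constant over time —
#' the premise that makes identification possible — while the drift models
#' the small common aging trend of older-adult anatomy (about 1 % per year
#' or less).
#'
#' Default population means are scaled per modality (cortical thickness
#' around 2.5 mm, areas in the hundreds of mm^2, volumes from 10^3 to 10^5
#' mm^3); default signature and noise scales are tau_j = 0.08 mu_j and
#' sigma_j = 0.02 mu_j, giving an intraclass correlation
#' tau^2 / (tau^2 + sigma^2) of about 0.94 for every feature.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param seed integer seed; fixes both the sampled baselines and the cohort
#'   draw in [generate_cohort()].
#' @param n_timepoints number of annual scans per subject (default 3).
#' @param schema a [feature_schema()]; defaults to the packaged
#'   [destrieux_schema()] (510 features).
#' @param signature_scale tau_j as a fraction of mu_j (default 0.08).
#' @param noise_scale sigma_j as a fraction of mu_j (default 0.02).
#' @param annual_drift_fraction per-year drift as a (signed) fraction of
#'   mu_j (default -0.005, i.e. -0.5 %/yr shrinkage).
#' @return An object of class `cohort_config` with per-feature vectors
#'   `population_mean`, `between_subject_sd`, `scan_noise_sd`, `drift`.
#' @examples
#' cfg <- cohort_config(20, seed = 1, schema = feature_schema(c("lh_A", "rh_A")))
#' cohort <- generate_cohort(cfg)
#' @export
cohort_config <- function(n_subjects, seed, n_timepoints = 3L,
                          schema = destrieux_schema(),
                          signature_scale = 0.08, noise_scale = 0.02,
                          annual_drift_fraction = -0.005) {
  if (!is_count(n_subjects, min = 2L)) {
    stop_morphid("n_subjects must be an integer >= 2 (one class per subject needs company)")
  }
  if (!is_count(n_timepoints, min = 2L)) {
    stop_morphid("n_timepoints must be >= 2 (training needs at least one scan besides the test scan)")
  }
  stopifnot(inherits(schema, "feature_schema"))
  feats <- schema$set_definitions$ALL
  p <- length(feats)
  if (signature_scale < 0 || noise_scale < 0) {
    stop_morphid("signature_scale and noise_scale must be non-negative")
  }
  mu <- with_seed(derive_seed(seed, 1L), {
    base <- vapply(feats, feature_modality, character(1L))
    out <- numeric(p)
    # log-uniform baselines inside each modality's physiological range
    out[base == "thickness"] <- stats::runif(sum(base == "thickness"), 2.0, 3.0)
    out[base == "area"] <- exp(stats::runif(sum(base == "area"), log(1e2), log(3e3)))
    out[base == "volume"] <- exp(stats::runif(sum(base == "volume"), log(1e3), log(1e5)))
    out
  })
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_timepoints = as.integer(n_timepoints),
         schema = schema, feature_names = feats,
         population_mean = stats::setNames(mu, feats),
         between_subject_sd = stats::setNames(signature_scale * mu, feats),
         scan_noise_sd = stats::setNames(noise_scale * mu, feats),
         drift = stats::setNames(rep(annual_drift_fraction, p), feats),
         seed = as.integer(seed)),
    class = "cohort_config")
}

# Classify a feature name into a measurement modality (drives baseline scale
# and unit tags).
feature_modality <- function(name) {
  if (grepl("_thickness$", name)) "thickness"
  else if (grepl("_area$", name)) "area"
  else "volume"
}

#' @export
print.cohort_config <- function(x, ...) {
  icc <- x$between_subject_sd^2 / (x$between_subject_sd^2 + x$scan_noise_sd^2)
  cat(sprintf("cohort_config: %d subjects x %d timepoints, %d features (seed %d)\n",
              x$n_subjects, x$n_timepoints, length(x$feature_names), x$seed))
  cat(sprintf("signature ICC: %.3f (median across features); drift %.2f %%/yr\n",
              stats::median(icc), 100 * x$drift[1L]))
  invisible(x)
}

#' Intraclass correlation implied by a cohort configuration
#'
#' tau^2 / (tau^2 + sigma^2) per feature: the fraction of cross-sectional
#' feature variance attributable to stable between-subject differences, the
#' single knob governing identifiability.
#'
#' @param config a [cohort_config()].
#' @return Named numeric vector, one ICC per feature.
#' @export
cohort_icc <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  t2 <- config$between_subject_sd^2
  s2 <- config$scan_noise_sd^2
  ifelse(t2 + s2 == 0, 0, t2 / (t2 + s2))
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws a [feature_table()] from the generative model described in
#' [cohort_config()]. The draw is fully determined by the config's seed:
#' the same config always yields a bit-identical cohort.
#'
#' @param config a [cohort_config()].
#' @return A [feature_table()] with `n_subjects * n_timepoints` rows,
#'   subjects labelled `sub001`, `sub002`, ...
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  tps <- config$n_timepoints
  p <- length(config$feature_names)
  subjects <- sprintf("sub%03d", seq_len(n))
  with_seed(derive_seed(config$seed, 2L), {
    sig <- matrix(stats::rnorm(n * p), n, p)
    sig <- sweep(sig, 2L, config$between_subject_sd, "*")
    rows <- vector("list", n * tps)
    vals <- matrix(0, n * tps, p)
    subj <- character(n * tps)
    tp <- integer(n * tps)
    r <- 0L
    for (i in seq_len(n)) {
      for (t in seq_len(tps)) {
        r <- r + 1L
        base <- config$population_mean * (1 + config$drift * (t - 1L))
        noise <- stats::rnorm(p) * config$scan_noise_sd
        vals[r, ] <- base + sig[i, ] + noise
        subj[r] <- subjects[i]
        tp[r] <- t
      }
    }
    units <- vapply(config$feature_names, function(nm) {
      switch(feature_modality(nm), thickness = "mm", area = "mm^2", "mm^3")
    }, character(1L))
    feature_table(subj, tp, vals, feature_names = config$feature_names,
                  units = unname(units))
  })
}
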