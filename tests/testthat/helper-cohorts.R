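# Shared fixtures: small schemas and cohorts built in code.

# A reduced schema with `n_regions` bilateral cortical regions and two
# global extras; keeps tests fast while exercising the same code paths as
# the full 510-feature schema.
tiny_schema <- function(n_regions = 2L) {
  regions <- c(paste0("lh_R", seq_len(n_regions)),
               paste0("rh_R", seq_len(n_regions)))
  feature_schema(regions, extra_names = c("TotalGrayVol", "CSF"),
                 lbr_names = c("TotalGrayVol", "CSF"))
}

# A small synthetic cohort; signature_scale / noise_scale expose the
# identifiability knob directly.
tiny_cohort <- function(n_subjects = 10L, seed = 1L, n_regions = 2L,
                        signature_scale = 0.08, noise_scale = 0.02,
                        annual_drift_fraction = -0.005, n_timepoints = 3L) {
  cfg <- cohort_config(n_subjects, seed = seed, n_timepoints = n_timepoints,
                       schema = tiny_schema(n_regions),
                       signature_scale = signature_scale,
                       noise_scale = noise_scale,
                       annual_drift_fraction = annual_drift_fraction)
  generate_cohort(cfg)
}

# Build a grid of identification reports from a subjects x engines x
# datasets x noise-levels binary outcome array (for battery tests that need
# controlled per-subject correctness).
reports_from_flags <- function(correct_array, subjects, engines, datasets,
                               levels) {
  reports <- list()
  for (e in seq_along(engines)) for (d in seq_along(datasets)) {
    for (l in seq_along(levels)) {
      flags <- correct_array[, e, d, l]
      pred <- ifelse(flags == 1, subjects, "WRONG")
      reports[[length(reports) + 1L]] <-
        compute_metrics(subjects, pred, engine = engines[e],
                        dataset = datasets[d], noise_level = levels[l])
    }
  }
  reports
}

# A labelled feature table straight from matrices (for hand-worked cases).
ft_from_matrix <- function(values, labels, timepoints = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  if (is.null(timepoints)) {
    timepoints <- stats::ave(seq_along(labels), labels, FUN = seq_along)
  }
  feature_table(labels, timepoints, values)
}
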