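#' Assign scan time points to training and test sets
#'
#' In a three-scan design every subject is a class with three samples: two
#' scans train the engines, the remaining one is the test scan. The test
#' point can be drawn independently per subject (`"per_subject_random"`,
#' the default), once for the whole cohort (`"global_random"`), or fixed by
#' the caller (`"fixed"`). Draws are reproducible for a fixed seed.
#'
#' @param table a [feature_table()] where every subject shares the same set
#'   of >= 2 time points.
#' @param mode split mode, see above.
#' @param seed integer seed for the random modes.
#' @param test_timepoint the held-out time point when `mode = "fixed"`.
#' @return An object of class `split_plan`: a named integer vector of test
#'   time points per subject plus the mode and seed.
#' @export
split_timepoints <- function(table,
                             mode = c("per_subject_random", "global_random", "fixed"),
                             seed = NULL, test_timepoint = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "feature_table"))
  tps_by_subj <- split(table$timepoint, table$subject_id)
  tp_sets <- unique(lapply(tps_by_subj, sort))
  if (length(tp_sets) != 1L) {
    stop_morphid("all subjects must share the same time-point set")
  }
  tps <- tp_sets[[1L]]
  if (length(tps) < 2L) stop_morphid("need >= 2 time points per subject to split")
  subjects <- sort(unique(table$subject_id))
  test <- switch(mode,
    fixed = {
      if (is.null(test_timepoint) || !test_timepoint %in% tps) {
        stop_morphid("mode 'fixed' needs test_timepoint among: ",
                     paste(tps, collapse = ", "))
      }
      rep(as.integer(test_timepoint), length(subjects))
    },
    global_random = with_seed(seed, rep(sample(tps, 1L), length(subjects))),
    per_subject_random = with_seed(seed, sample(tps, length(subjects), replace = TRUE)))
  structure(list(test_timepoint = stats::setNames(as.integer(test), subjects),
                 timepoints = tps, mode = mode, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan (%s): %d subjects, test point(s) {%s}, train = remaining %d scans\n",
              x$mode, length(x$test_timepoint),
              paste(sort(unique(x$test_timepoint)), collapse = ","),
              length(x$timepoints) - 1L))
  invisible(x)
}

# Materialize a plan: list(train=, test=) feature tables.
apply_split <- function(table, plan) {
  stopifnot(inherits(plan, "split_plan"))
  is_test <- table$timepoint == plan$test_timepoint[table$subject_id]
  list(train = ft_rows(table, !is_test), test = ft_rows(table, is_test))
}

#' Add white Gaussian noise to test scans
#'
#' Degrades the test data by adding independent Gaussian noise to every
#' feature: the noise SD for feature j is `level` times the sample SD of
#' that feature over the reference (training) rows, so "20 % noise" means
#' noise at one fifth of the feature's natural training spread. Training
#' data are never perturbed. Constant reference features are passed through
#' unchanged with a warning.
#'
#' @param test a [feature_table()] of test rows.
#' @param level noise level as a fraction (0 to ~0.40).
#' @param reference the training [feature_table()] supplying per-feature
#'   SDs; must share the test table's columns.
#' @param seed integer seed.
#' @return A [feature_table()] with perturbed values (identical to `test`
#'   at `level = 0`).
#' @export
add_gaussian_noise <- function(test, level, reference, seed = NULL) {
  stopifnot(inherits(test, "feature_table"), inherits(reference, "feature_table"))
  if (length(level) != 1L || !is.finite(level) || level < 0) {
    stop_morphid("noise level must be a single non-negative fraction")
  }
  if (!identical(test$feature_names, reference$feature_names)) {
    stop_morphid("test and reference feature columns differ")
  }
  if (level == 0) return(test)
  s <- apply(reference$values, 2L, stats::sd)
  if (any(s == 0)) {
    warning("constant reference feature(s) passed through unperturbed: ",
            paste(utils::head(test$feature_names[s == 0], 5L), collapse = ", "))
  }
  with_seed(seed, {
    eta <- matrix(stats::rnorm(length(test$values)), nrow(test$values),
                  ncol(test$values))
    eta <- sweep(eta, 2L, level * s, "*")
    feature_table(test$subject_id, test$timepoint, test$values + eta,
                  feature_names = test$feature_names, units = test$units)
  })
}

#' Per-subject identification metrics
#'
#' One-vs-rest confusion accounting for the identification setting where
#' each of the N classes contributes exactly one test scan. For class c
#' with TP_c in \{0,1\} and FP_c the number of other subjects' scans
#' predicted as c: sensitivity_c = TP_c, specificity_c = TN_c / (N - 1),
#' accuracy_c = (TP_c + TN_c) / N, precision_c = TP_c / (TP_c + FP_c)
#' (0 when the denominator is 0), and F1_c the harmonic mean of precision
#' and sensitivity (0 when both are 0). Reported metrics are macro
#' (unweighted) means over classes — the averaging under which accuracy can
#' round to 1.00 while sensitivity is much lower, because true negatives
#' dominate every one-vs-rest table.
#'
#' @param truth character vector of true labels, one test row per class.
#' @param predicted character vector of predicted labels, same length.
#' @param engine,dataset,noise_level,seed optional metadata recorded in the
#'   report.
#' @return An object of class `identification_report` with macro
#'   `accuracy`, `sensitivity`, `specificity`, `f1`, the per-subject
#'   `correct` flag vector (named by subject), and the metadata.
#' @export
compute_metrics <- function(truth, predicted, engine = NA_character_,
                            dataset = NA_character_, noise_level = NA_real_,
                            seed = NA_integer_) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) stop_morphid("label length mismatch")
  if (anyDuplicated(truth)) {
    stop_morphid("identification expects exactly one test row per class")
  }
  classes <- sort(truth)
  N <- length(classes)
  tp <- as.integer(predicted == truth)
  names(tp) <- truth
  tp <- tp[classes]
  fp <- vapply(classes, function(c) sum(predicted == c & truth != c), integer(1L))
  tn <- (N - 1L) - fp
  sens <- tp
  spec <- tn / (N - 1L)
  acc <- (tp + tn) / N
  prec <- ifelse(tp + fp == 0L, 0, tp / (tp + fp))
  f1 <- ifelse(prec + sens == 0, 0, 2 * prec * sens / (prec + sens))
  structure(
    list(accuracy = mean(acc), sensitivity = mean(sens),
         specificity = mean(spec), f1 = mean(f1),
         correct = stats::setNames(tp == 1L, classes),
         n_subjects = N, engine = engine, dataset = dataset,
         noise_level = noise_level, seed = seed),
    class = "identification_report")
}

#' @export
print.identification_report <- function(x, digits = 3L, ...) {
  cat(sprintf("identification_report: %s on %s (noise %s), N = %d\n",
              ifelse(is.na(x$engine), "?", x$engine),
              ifelse(is.na(x$dataset), "?", x$dataset),
              ifelse(is.na(x$noise_level), "0", format(x$noise_level)),
              x$n_subjects))
  cat(sprintf("  ACC %.*f  SENS %.*f  SPEC %.*f  F1 %.*f\n",
              digits, x$accuracy, digits, x$sensitivity,
              digits, x$specificity, digits, x$f1))
  invisible(x)
}

#' @export
as.data.frame.identification_report <- function(x, ...) {
  data.frame(engine = x$engine, dataset = x$dataset,
             noise_level = x$noise_level, n_subjects = x$n_subjects,
             accuracy = x$accuracy, sensitivity = x$sensitivity,
             specificity = x$specificity, f1 = x$f1,
             stringsAsFactors = FALSE)
}

#' Run one end-to-end identification experiment
#'
#' The full protocol on one feature set with one engine: select the feature
#' set, split time points into train/test, standardize on the training
#' statistics, optionally degrade the test scans with Gaussian noise, fit
#' the engine on the training scans, predict the held-out scans, and score
#' the per-subject results. Every random stage is driven by `seed`, so a
#' (seed, configuration) pair always reproduces the identical report.
#'
#' @param table a [feature_table()] (e.g. from [generate_cohort()]).
#' @param set_name feature set to use, see [select_feature_set()].
#' @param engine `"lda"` or `"wknn"`.
#' @param schema a [feature_schema()]; default [destrieux_schema()].
#' @param lambda LDA shrinkage weight (default 0.1).
#' @param k WKNN neighbour count (default 3).
#' @param split_mode see [split_timepoints()].
#' @param test_timepoint for `split_mode = "fixed"`.
#' @param noise_level Gaussian noise fraction applied to test scans
#'   (default 0).
#' @param scale standardize features on training statistics (default TRUE).
#' @param seed integer seed driving the split and the noise draw.
#' @return An [compute_metrics()] `identification_report`.
#' @export
run_identification <- function(table, set_name, engine = c("lda", "wknn"),
                               schema = destrieux_schema(), lambda = 0.1,
                               k = 3L,
                               split_mode = "per_subject_random",
                               test_timepoint = NULL, noise_level = 0,
                               scale = TRUE, seed = 1L) {
  engine <- match.arg(engine)
  tab <- select_feature_set(table, set_name, schema)
  plan <- split_timepoints(tab, mode = split_mode,
                           seed = derive_seed(seed, 11L),
                           test_timepoint = test_timepoint)
  parts <- apply_split(tab, plan)
  train <- parts$train
  test <- parts$test
  if (scale) {
    sc <- feature_scaler(train)
    train <- predict(sc, train)
    test <- predict(sc, test)
  }
  test <- add_gaussian_noise(test, noise_level, train,
                             seed = derive_seed(seed, 12L))
  model <- switch(engine,
                  lda = morph_lda(train, lambda = lambda),
                  wknn = morph_wknn(train, k = k))
  pred <- predict(model, test)
  compute_metrics(test$subject_id, pred, engine = engine,
                  dataset = set_name, noise_level = noise_level, seed = seed)
}
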