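#' Cochran's Q test for matched binary outcomes
#'
#' Tests whether the proportion of correctly identified subjects is equal
#' across k matched conditions (datasets, noise levels, or engines), given
#' a subjects-by-conditions matrix of 0/1 outcomes. With column totals C_j,
#' row totals R_i and grand total N:
#'
#'   Q = (k - 1) * (k * sum(C_j^2) - N^2) / (k * N - sum(R_i^2))
#'
#' referred to a chi-square distribution with k - 1 degrees of freedom.
#' Rows that are constant across conditions (all 0 or all 1) carry no
#' information; if every row is constant the statistic is undefined and the
#' test reports p = 1 with `degenerate = TRUE`. At k = 2 the statistic
#' equals the uncorrected McNemar statistic (b - c)^2 / (b + c).
#'
#' @param m integer/logical matrix, rows = subjects, columns = conditions,
#'   cells 0/1 (correct/incorrect identification).
#' @return An object of class `morphid_test` with `statistic`, `df`,
#'   `p_value`, condition labels, and test name.
#' @export
cochran_q <- function(m) {
  m <- as.matrix(m)
  if (is.logical(m)) storage.mode(m) <- "integer"
  if (!all(m %in% c(0, 1))) stop_morphid("cells must be binary (0/1)")
  k <- ncol(m)
  if (k < 2L) stop_morphid("need >= 2 conditions")
  Cj <- colSums(m)
  Ri <- rowSums(m)
  N <- sum(m)
  denom <- k * N - sum(Ri^2)
  if (denom == 0) {
    # every row constant across conditions: no discordance, statistic 0
    return(morphid_test("cochran_q", statistic = 0, df = k - 1L,
                        p_value = 1, conditions = colnames(m),
                        degenerate = TRUE))
  }
  Q <- (k - 1) * (k * sum(Cj^2) - N^2) / denom
  morphid_test("cochran_q", statistic = Q, df = k - 1L,
               p_value = stats::pchisq(Q, df = k - 1L, lower.tail = FALSE),
               conditions = colnames(m))
}

#' McNemar's test for two matched binary conditions
#'
#' Compares two matched conditions through the discordant pairs b (correct
#' under the first only) and c (correct under the second only). The exact
#' test doubles the binomial tail: p = min(1, 2 P(X <= min(b, c))) with
#' X ~ Binomial(b + c, 1/2); `method = "chi2_cc"` gives the classic
#' continuity-corrected chi-square (|b - c| - 1)^2 / (b + c) on 1 df. With
#' no discordance (b + c = 0) the test is vacuous and p = 1.
#'
#' @param m binary matrix with exactly 2 columns (as in [cochran_q()]).
#' @param method `"exact"` (default) or `"chi2_cc"`.
#' @return A `morphid_test` with the discordant counts attached.
#' @export
mcnemar_test <- function(m, method = c("exact", "chi2_cc")) {
  method <- match.arg(method)
  m <- as.matrix(m)
  if (is.logical(m)) storage.mode(m) <- "integer"
  if (ncol(m) != 2L) stop_morphid("McNemar needs exactly 2 conditions")
  if (!all(m %in% c(0, 1))) stop_morphid("cells must be binary (0/1)")
  b <- sum(m[, 1L] == 1L & m[, 2L] == 0L)
  cc <- sum(m[, 1L] == 0L & m[, 2L] == 1L)
  n <- b + cc
  if (n == 0L) {
    return(morphid_test(paste0("mcnemar_", method), statistic = NA_real_,
                        df = if (method == "chi2_cc") 1L else NA_integer_,
                        p_value = 1, conditions = colnames(m),
                        degenerate = TRUE, b = b, c = cc))
  }
  if (method == "exact") {
    p <- min(1, 2 * stats::pbinom(min(b, cc), n, 0.5))
    morphid_test("mcnemar_exact", statistic = as.numeric(min(b, cc)),
                 df = NA_integer_, p_value = p, conditions = colnames(m),
                 b = b, c = cc)
  } else {
    stat <- (abs(b - cc) - 1)^2 / n
    morphid_test("mcnemar_chi2_cc", statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, 1L, lower.tail = FALSE),
                 conditions = colnames(m), b = b, c = cc)
  }
}

morphid_test <- function(name, statistic, df, p_value, conditions = NULL,
                         degenerate = FALSE, ...) {
  structure(list(test = name, statistic = statistic, df = df,
                 p_value = p_value, conditions = conditions,
                 degenerate = degenerate, ...),
            class = "morphid_test")
}

#' @export
print.morphid_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, df = %s, p = %.4g%s\n", x$test,
              format(x$statistic, digits = 4), format(x$df), x$p_value,
              if (isTRUE(x$degenerate)) " (degenerate: no discordance)" else ""))
  if (!is.null(x$conditions)) {
    cat("conditions:", paste(x$conditions, collapse = " vs "), "\n")
  }
  invisible(x)
}

#' Bonferroni-Holm step-down adjustment
#'
#' Holm's sequentially rejective procedure at family-wise level `alpha`:
#' the smallest of m p-values is tested at alpha / m, the next at
#' alpha / (m - 1), and so on; rejections stop at the first failure.
#' Adjusted p-values are the standard step-down maxima
#' (`stats::p.adjust(method = "holm")`), so `reject` is equivalent to
#' `adjusted <= alpha`.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @param alpha family-wise error level (default 0.05).
#' @return A data frame with `p`, `adjusted`, `reject`, and the step-down
#'   `threshold` each ordered p-value was compared against.
#' @export
holm_adjust <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_morphid("p-values must lie in [0, 1]")
  }
  m <- length(p)
  adj <- stats::p.adjust(p, method = "holm")
  ord <- order(p)
  thr <- numeric(m)
  thr[ord] <- alpha / (m - seq_len(m) + 1L)
  data.frame(p = p, adjusted = adj, reject = adj <= alpha, threshold = thr)
}

#' The full engine/dataset comparison battery
#'
#' Assembles the repeated-measures design comparing identification results:
#' for each engine a Cochran's Q across the five feature sets at the
#' no-noise condition (2 tests); for each engine and feature set a
#' Cochran's Q across the nine noise levels (10 tests, when noise-swept
#' reports are supplied); and for each feature set a McNemar test of LDA
#' versus WKNN at no noise (5 tests) — 17 tests in all, Holm-adjusted as
#' one family. All reports must come from the same subjects and the same
#' train/test split so outcomes are matched. Without noise-swept reports a
#' partial battery of 7 tests is returned (flagged `partial`).
#'
#' @param reports list of `identification_report`s covering both engines
#'   and all feature sets (and optionally all noise levels).
#' @param datasets feature-set names expected (default the five canonical
#'   sets).
#' @param noise_levels noise axis expected for the per-set Q tests; set to
#'   `NULL` to request the partial battery.
#' @param alpha family-wise level for the Holm adjustment (default 0.05).
#' @return An object of class `comparison_battery`: a data frame of labeled
#'   tests with raw and Holm-adjusted p-values, plus the `morphid_test`
#'   objects.
#' @export
comparison_battery <- function(reports,
                               datasets = c("ALL", "AREA", "THICKNESS",
                                            "VOLUME", "11LBR"),
                               noise_levels = seq(0, 0.40, by = 0.05),
                               alpha = 0.05) {
  engines <- c("lda", "wknn")
  key <- function(engine, dataset, noise) {
    sprintf("%s|%s|%.6f", engine, dataset, noise)
  }
  lut <- new.env(parent = emptyenv())
  for (r in reports) {
    stopifnot(inherits(r, "identification_report"))
    nz <- if (is.na(r$noise_level)) 0 else r$noise_level
    assign(key(r$engine, r$dataset, nz), r, envir = lut)
  }
  fetch <- function(engine, dataset, noise) {
    k <- key(engine, dataset, noise)
    if (!exists(k, envir = lut)) {
      stop_morphid("missing report for engine=", engine, ", dataset=",
                   dataset, ", noise=", noise)
    }
    get(k, envir = lut)
  }
  flags <- function(rpts) {
    subj <- names(rpts[[1L]]$correct)
    mat <- vapply(rpts, function(r) {
      if (!identical(names(r$correct), subj)) {
        stop_morphid("reports cover different subject sets; battery needs matched outcomes")
      }
      as.integer(r$correct)
    }, integer(length(subj)))
    rownames(mat) <- subj
    mat
  }
  tests <- list()
  label <- character()
  # per-engine Q across datasets at no noise
  for (e in engines) {
    m <- flags(lapply(datasets, function(d) fetch(e, d, 0)))
    colnames(m) <- datasets
    tests <- c(tests, list(cochran_q(m)))
    label <- c(label, sprintf("Q_datasets_%s", e))
  }
  partial <- is.null(noise_levels)
  if (!partial) {
    for (e in engines) {
      for (d in datasets) {
        m <- flags(lapply(noise_levels, function(nz) fetch(e, d, nz)))
        colnames(m) <- sprintf("noise_%g", noise_levels)
        tests <- c(tests, list(cochran_q(m)))
        label <- c(label, sprintf("Q_noise_%s_%s", e, d))
      }
    }
  }
  # per-dataset McNemar engine comparison at no noise
  for (d in datasets) {
    m <- flags(list(fetch("lda", d, 0), fetch("wknn", d, 0)))
    colnames(m) <- engines
    tests <- c(tests, list(mcnemar_test(m)))
    label <- c(label, sprintf("McNemar_lda_vs_wknn_%s", d))
  }
  p <- vapply(tests, function(t) t$p_value, numeric(1L))
  adj <- holm_adjust(p, alpha = alpha)
  out <- data.frame(label = label,
                    test = vapply(tests, function(t) t$test, character(1L)),
                    statistic = vapply(tests, function(t) t$statistic, numeric(1L)),
                    df = vapply(tests, function(t) as.integer(t$df), integer(1L)),
                    p = p, adjusted = adj$adjusted, reject = adj$reject,
                    stringsAsFactors = FALSE)
  structure(list(results = out, tests = tests, alpha = alpha,
                 partial = partial, n_tests = length(tests)),
            class = "comparison_battery")
}

#' @export
print.comparison_battery <- function(x, ...) {
  cat(sprintf("comparison_battery: %d tests%s, Holm at alpha = %g\n",
              x$n_tests, if (x$partial) " (partial: no noise axis)" else "",
              x$alpha))
  print(format(x$results, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.comparison_battery <- function(x, ...) x$results
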