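#' Wilks' lambda of a feature subset
#'
#' The classic stepwise-discriminant criterion: the ratio of the
#' determinants of the within-class scatter W and total scatter T over the
#' chosen feature subset, Lambda = det(W) / det(T). Values near 0 indicate
#' strong class separation, 1 means none. When W is numerically singular on
#' the subset, the same identity-target shrinkage as [morph_lda()] is
#' applied to both scatter matrices before taking determinants.
#'
#' @param train a [feature_table()]; `subject_id` is the class label.
#' @param features character vector of feature names (non-empty subset of
#'   the table's columns).
#' @param lambda shrinkage applied only if the plain determinant ratio is
#'   degenerate (default 1e-8).
#' @return Lambda in \[0, 1\].
#' @export
wilks_lambda <- function(train, features, lambda = 1e-8) {
  stopifnot(inherits(train, "feature_table"))
  if (length(features) == 0L) stop_morphid("empty feature subset")
  scat <- scatter_matrices(train)
  subset_lambda(scat, match(features, train$feature_names), lambda)
}

# Within-class and total scatter over all features, computed once.
scatter_matrices <- function(train) {
  X <- train$values
  labels <- sort(unique(train$subject_id))
  if (length(labels) < 2L) stop_morphid("need >= 2 classes")
  idx <- split(seq_len(nrow(X)), factor(train$subject_id, levels = labels))
  means <- do.call(rbind, lapply(idx, function(i) colMeans(X[i, , drop = FALSE])))
  centred <- X - means[match(train$subject_id, labels), , drop = FALSE]
  total <- sweep(X, 2L, colMeans(X), "-")
  list(W = crossprod(centred), T = crossprod(total))
}

# Lambda = det(W_s)/det(T_s) on a column subset, with identity-target
# shrinkage as a fallback when T is singular.
subset_lambda <- function(scat, cols, lambda = 1e-8) {
  if (anyNA(cols)) stop_morphid("feature name(s) not present in the table")
  Ws <- scat$W[cols, cols, drop = FALSE]
  Ts <- scat$T[cols, cols, drop = FALSE]
  ldet <- function(M) determinant(M, logarithm = TRUE)
  dT <- ldet(Ts)
  if (!is.finite(dT$modulus) || dT$sign <= 0) {
    p <- length(cols)
    tW <- max(sum(diag(Ws)) / p, .Machine$double.eps)
    tT <- max(sum(diag(Ts)) / p, .Machine$double.eps)
    diag(Ws) <- diag(Ws) * (1 - lambda) + lambda * tW
    diag(Ts) <- diag(Ts) * (1 - lambda) + lambda * tT
    Ws[row(Ws) != col(Ws)] <- Ws[row(Ws) != col(Ws)] * (1 - lambda)
    Ts[row(Ts) != col(Ts)] <- Ts[row(Ts) != col(Ts)] * (1 - lambda)
    dT <- ldet(Ts)
    if (!is.finite(dT$modulus) || dT$sign <= 0) stop_morphid("singular total scatter")
  }
  dW <- ldet(Ws)
  if (dW$sign <= 0 || !is.finite(dW$modulus)) return(0)
  val <- exp(as.numeric(dW$modulus - dT$modulus))
  min(max(val, 0), 1)
}

#' Forward stepwise discriminant feature selection
#'
#' Greedy forward selection under Wilks' lambda: at each step the candidate
#' feature whose addition minimizes Lambda of the augmented subset
#' (computed on training data only) is selected, until `cap` features are
#' chosen or no candidate lowers Lambda by more than a tolerance. After
#' each step the shrinkage discriminant is refit on the selected subset and
#' scored on the held-out test scans, producing a trace with one row per
#' step: step index, feature name, Lambda, and macro test
#' accuracy/sensitivity/specificity/F1.
#'
#' @param train,test standardized [feature_table()]s from the same split
#'   (e.g. via [split_timepoints()] and [feature_scaler()]).
#' @param cap maximum number of selected features (default 11).
#' @param set_name optional feature set to restrict candidates to,
#'   resolved against `schema`.
#' @param schema a [feature_schema()] used when `set_name` is given.
#' @param lambda shrinkage weight for the per-step discriminant refits
#'   (default 0.1).
#' @param tol minimum Lambda improvement to keep stepping (default 1e-12).
#' @return An object of class `stepwise_trace`; `as.data.frame()` yields
#'   the Step / Feature / Lambda / ACC / SENS / SPEC / F1 table.
#' @export
stepwise_lda <- function(train, test, cap = 11L, set_name = NULL,
                         schema = destrieux_schema(), lambda = 0.1,
                         tol = 1e-12) {
  stopifnot(inherits(train, "feature_table"), inherits(test, "feature_table"))
  if (!is.null(set_name)) {
    train <- select_feature_set(train, set_name, schema)
    test <- select_feature_set(test, set_name, schema)
  }
  if (!identical(train$feature_names, test$feature_names)) {
    stop_morphid("train and test feature columns differ")
  }
  p <- length(train$feature_names)
  if (!is_count(cap, min = 1L) || cap > p) {
    stop_morphid("cap must be an integer in [1, ", p, "]")
  }
  scat <- scatter_matrices(train)
  selected <- integer(0)
  rows <- list()
  last <- Inf
  for (step in seq_len(cap)) {
    cand <- setdiff(seq_len(p), selected)
    lam <- vapply(cand, function(j) subset_lambda(scat, c(selected, j)),
                  numeric(1L))
    best <- which.min(lam)
    if (is.finite(last) && lam[best] > last - tol) break
    selected <- c(selected, cand[best])
    last <- lam[best]
    feats <- train$feature_names[selected]
    fit <- morph_lda(ft_cols(train, feats), lambda = lambda)
    rpt <- compute_metrics(test$subject_id,
                           predict(fit, ft_cols(test, feats)),
                           engine = "lda", dataset = "stepwise")
    rows[[step]] <- data.frame(
      step = step, feature = train$feature_names[cand[best]],
      wilks_lambda = lam[best], accuracy = rpt$accuracy,
      sensitivity = rpt$sensitivity, specificity = rpt$specificity,
      f1 = rpt$f1, stringsAsFactors = FALSE)
  }
  structure(list(trace = do.call(rbind, rows),
                 selected = train$feature_names[selected],
                 cap = cap, lambda = lambda),
            class = "stepwise_trace")
}

#' @export
as.data.frame.stepwise_trace <- function(x, ...) x$trace

#' @export
print.stepwise_trace <- function(x, digits = 3L, ...) {
  cat(sprintf("stepwise_trace: %d step(s) (cap %d), Wilks' lambda criterion\n",
              nrow(x$trace), x$cap))
  print(format(x$trace, digits = digits), row.names = FALSE)
  invisible(x)
}
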