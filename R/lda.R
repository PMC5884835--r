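#' Multi-class linear discriminant identification with covariance shrinkage
#'
#' Fits the Gaussian equal-covariance discriminant used for subject
#' identification: one class per subject, class means estimated from that
#' subject's training scans, and a single pooled within-class covariance S
#' (divisor n - K). Because identification regimes routinely have more
#' features than within-class degrees of freedom (e.g. 510 features from
#' 191 subjects x 2 training scans), S is convexly shrunk towards a scaled
#' identity:
#'
#'   S_lambda = (1 - lambda) S + lambda (tr(S) / p) I
#'
#' which is positive definite for any lambda in (0, 1] whenever tr(S) > 0,
#' and reduces to classic LDA at lambda = 0. In the fully degenerate case
#' tr(S) = 0 (no within-class variation at all, e.g. noise-free repeat
#' scans) the shrinkage target falls back to the identity, making the rule
#' a Euclidean nearest-mean classifier.
#'
#' @param train a [feature_table()] of training rows; `train$subject_id` is
#'   the class label.
#' @param lambda shrinkage weight in \[0, 1\] (default 0.1).
#' @param priors per-class prior probabilities; default uniform (classes are
#'   balanced by design: every subject contributes the same number of
#'   training scans).
#' @return An object of class `morph_lda` holding class labels and means,
#'   the shrunk pooled covariance and its Cholesky factor, `lambda`, and
#'   priors.
#' @examples
#' tr <- feature_table(c("A", "A", "B", "B"), c(1, 2, 1, 2),
#'                     matrix(c(0, 1, 4, 5), 4, 1,
#'                            dimnames = list(NULL, "x")))
#' fit <- morph_lda(tr, lambda = 0)
#' predict(fit, feature_table("q", 1, matrix(2, 1, 1,
#'                            dimnames = list(NULL, "x"))))
#' @export
morph_lda <- function(train, lambda = 0.1, priors = NULL) {
  stopifnot(inherits(train, "feature_table"))
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0 || lambda > 1) {
    stop_morphid("lambda must be a single value in [0, 1]")
  }
  labels <- sort(unique(train$subject_id))
  K <- length(labels)
  if (K < 2L) stop_morphid("need >= 2 classes (subjects)")
  X <- train$values
  n <- nrow(X)
  p <- ncol(X)
  idx <- split(seq_len(n), factor(train$subject_id, levels = labels))
  sizes <- lengths(idx)
  if (any(sizes == 0L)) stop_morphid("class with 0 training rows")
  means <- do.call(rbind, lapply(idx, function(i) colMeans(X[i, , drop = FALSE])))
  centred <- X - means[match(train$subject_id, labels), , drop = FALSE]
  if (n > K) {
    S <- crossprod(centred) / (n - K)
  } else {
    S <- matrix(0, p, p)  # no within-class df; shrinkage target carries it
  }
  target <- sum(diag(S)) / p
  if (target <= 0) target <- 1  # degenerate: Euclidean nearest-mean
  S_lambda <- (1 - lambda) * S
  diag(S_lambda) <- diag(S_lambda) + lambda * target
  R <- tryCatch(chol(S_lambda), error = function(e) NULL)
  if (is.null(R)) {
    stop_morphid("shrunk covariance is numerically singular at lambda = ",
                 lambda, "; increase lambda")
  }
  if (is.null(priors)) priors <- rep(1 / K, K)
  if (length(priors) != K || any(priors < 0) || abs(sum(priors) - 1) > 1e-8) {
    stop_morphid("priors must be a length-", K, " non-negative vector summing to 1")
  }
  structure(
    list(class_labels = labels, class_means = means,
         pooled_covariance = S_lambda, chol = R,
         lambda = lambda, priors = priors,
         feature_names = train$feature_names, n_train = n),
    class = "morph_lda")
}

#' @export
print.morph_lda <- function(x, ...) {
  cat(sprintf("morph_lda: %d classes, %d features, lambda = %g (n = %d)\n",
              length(x$class_labels), length(x$feature_names), x$lambda,
              x$n_train))
  invisible(x)
}

#' @export
coef.morph_lda <- function(object, ...) {
  # discriminant weight matrix: columns are S_lambda^{-1} mu_k
  A <- backsolve(object$chol,
                 forwardsolve(t(object$chol), t(object$class_means)))
  colnames(A) <- object$class_labels
  rownames(A) <- object$feature_names
  A
}

# Discriminant values delta_k(x) = x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k
# for every row of X, vectorized over classes.
lda_scores_matrix <- function(model, X) {
  A <- backsolve(model$chol, forwardsolve(t(model$chol), t(model$class_means)))
  quad <- colSums(t(model$class_means) * A)  # mu_k' S^-1 mu_k
  sc <- X %*% A
  sweep(sc, 2L, 0.5 * quad - log(model$priors), "-")
}

#' Predict subject identity with a fitted discriminant model
#'
#' Each test row is assigned to the class with the largest discriminant
#' value; exact ties go to the earliest label in sorted class order, so
#' predictions never depend on training-row order.
#'
#' @param object a [morph_lda()] fit.
#' @param table a [feature_table()] with the model's feature columns.
#' @param type `"class"` (default) for predicted labels, `"scores"` for the
#'   full matrix of per-class discriminant values.
#' @param ... unused.
#' @return Character vector of predicted labels, or a numeric score matrix.
#' @export
predict.morph_lda <- function(object, table, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(table, "feature_table"))
  if (!identical(table$feature_names, object$feature_names)) {
    stop_morphid("test features do not match the model's feature columns")
  }
  sc <- lda_scores_matrix(object, table$values)
  colnames(sc) <- object$class_labels
  if (type == "scores") return(sc)
  # argmax with a small relative tolerance so analytic ties (equal
  # discriminants up to rounding) resolve to the earliest label
  object$class_labels[apply(sc, 1L, function(row) {
    m <- max(row)
    which(row >= m - 1e-9 * max(1, abs(m)))[1L]
  })]
}
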