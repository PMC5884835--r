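#' Weighted k-nearest-neighbour identification
#'
#' Stores the training scans verbatim as exemplars. At prediction time each
#' test scan is compared to every exemplar by Euclidean distance d, the k
#' nearest exemplars vote, and each vote carries weight 1 / d^2 (inverse
#' squared distance). A test scan exactly coinciding with an exemplar
#' (d = 0, infinite weight) is assigned that exemplar's class immediately.
#'
#' @param train a [feature_table()] of training rows; `train$subject_id`
#'   labels the exemplars.
#' @param k neighbour count, between 1 and the number of exemplars
#'   (default 3, so that one subject's scans can fill the whole
#'   neighbourhood in a three-scans-per-subject design).
#' @return An object of class `morph_wknn`.
#' @examples
#' tr <- feature_table(c("A", "A", "B"), c(1, 2, 1),
#'                     matrix(c(0, 1, 3), 3, 1, dimnames = list(NULL, "x")))
#' fit <- morph_wknn(tr, k = 3)
#' predict(fit, feature_table("q", 1, matrix(2, 1, 1,
#'                            dimnames = list(NULL, "x"))))  # "A"
#' @export
morph_wknn <- function(train, k = 3L) {
  stopifnot(inherits(train, "feature_table"))
  n <- nrow(train$values)
  if (!is_count(k, min = 1L) || k > n) {
    stop_morphid("k must be an integer in [1, ", n, "] (number of exemplars)")
  }
  structure(
    list(exemplars = train$values,
         exemplar_labels = train$subject_id,
         class_labels = sort(unique(train$subject_id)),
         k = as.integer(k),
         feature_names = train$feature_names),
    class = "morph_wknn")
}

#' @export
print.morph_wknn <- function(x, ...) {
  cat(sprintf("morph_wknn: %d exemplars, %d classes, %d features, k = %d (weight 1/d^2)\n",
              nrow(x$exemplars), length(x$class_labels),
              length(x$feature_names), x$k))
  invisible(x)
}

#' Predict subject identity with a fitted weighted-KNN model
#'
#' The neighbourhood is the k smallest distances; exemplars tied with the
#' k-th distance are all included. Class score is the sum of 1 / d^2 over
#' that class's neighbours. Score ties are broken by the smallest single
#' neighbour distance within the tied classes, then by earliest label in
#' sorted order — so predictions are independent of training-row order.
#'
#' @param object a [morph_wknn()] fit.
#' @param table a [feature_table()] with the model's feature columns.
#' @param ... unused.
#' @return Character vector of predicted labels, one per test row.
#' @export
predict.morph_wknn <- function(object, table, ...) {
  stopifnot(inherits(table, "feature_table"))
  if (!identical(table$feature_names, object$feature_names)) {
    stop_morphid("test features do not match the model's feature columns")
  }
  E <- object$exemplars
  X <- table$values
  # squared Euclidean cross-distances, clamped at 0 against rounding
  d2 <- outer(rowSums(X^2), rowSums(E^2), "+") - 2 * tcrossprod(X, E)
  d2[d2 < 0] <- 0
  labs <- object$exemplar_labels
  vapply(seq_len(nrow(X)), function(i) {
    di <- d2[i, ]
    hit <- which(di == 0)
    if (length(hit) > 0L) {
      # exact match: infinite weight, earliest label among exact matches
      return(sort(labs[hit])[1L])
    }
    kth <- sort(di, partial = object$k)[object$k]
    nb <- which(di <= kth)  # ties at the k-th distance all enter
    w <- tapply(1 / di[nb], labs[nb], sum)
    best <- names(w)[w == max(w)]
    if (length(best) > 1L) {
      dmin <- tapply(di[nb], labs[nb], min)[best]
      best <- best[dmin == min(dmin)]
    }
    sort(best)[1L]
  }, character(1L))
}
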