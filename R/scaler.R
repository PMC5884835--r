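#' Fit a per-feature standardizer
#'
#' Learns a training-set location (mean) and scale (sample standard
#' deviation, n - 1 denominator) per feature. Raw morphometric features mix
#' mm, mm^2 and mm^3, so Euclidean distances would be dominated by volume
#' measures; z-scoring on the training statistics puts every feature on a
#' comparable scale. It has no effect on LDA decisions in exact arithmetic
#' (the discriminant is affine-invariant) but is essential for the
#' distance-based engine.
#'
#' @param table a [feature_table()] of training rows (>= 2 rows).
#' @return An object of class `feature_scaler` with `center` and `scale`
#'   vectors.
#' @export
feature_scaler <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$values) < 2L) stop_morphid("need >= 2 rows to estimate a scale")
  ctr <- colMeans(table$values)
  scl <- apply(table$values, 2L, stats::sd)
  bad <- which(scl <= 0)
  if (length(bad) > 0L) {
    stop_morphid("constant feature(s), cannot scale: ",
                 paste(utils::head(table$feature_names[bad], 8L), collapse = ", "))
  }
  structure(list(center = ctr, scale = scl,
                 feature_names = table$feature_names),
            class = "feature_scaler")
}

#' @export
print.feature_scaler <- function(x, ...) {
  cat(sprintf("feature_scaler over %d features (training mean/SD)\n",
              length(x$center)))
  invisible(x)
}

#' Apply (or invert) a fitted standardizer
#'
#' @param object a [feature_scaler()].
#' @param table a [feature_table()] sharing the scaler's feature columns.
#' @param invert if `TRUE`, map standardized values back to the original
#'   units (the exact inverse of the forward transform).
#' @param ... unused.
#' @return A transformed [feature_table()].
#' @export
predict.feature_scaler <- function(object, table, invert = FALSE, ...) {
  stopifnot(inherits(table, "feature_table"))
  if (!identical(object$feature_names, table$feature_names)) {
    stop_morphid("scaler and table feature columns differ")
  }
  v <- table$values
  v <- if (invert) {
    sweep(sweep(v, 2L, object$scale, "*"), 2L, object$center, "+")
  } else {
    sweep(sweep(v, 2L, object$center, "-"), 2L, object$scale, "/")
  }
  feature_table(table$subject_id, table$timepoint, v,
                feature_names = table$feature_names, units = table$units)
}
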