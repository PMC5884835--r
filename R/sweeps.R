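#' Noise-robustness sweep
#'
#' Repeats [run_identification()] over the nine canonical noise conditions
#' (no noise, then 5 % to 40 % in 5 % steps), optionally replicated over
#' independent split/noise seeds.
#'
#' @param table,set_name,engine,schema,lambda,k,split_mode,scale as in
#'   [run_identification()].
#' @param levels noise fractions; default `seq(0, 0.40, by = 0.05)`
#'   (9 values).
#' @param replicates independent repetitions per level (default 1; the
#'   reference protocol drew a single split).
#' @param seed base seed; replicate r at level i runs under a sub-seed
#'   derived from it.
#' @return An object of class `sweep_result`: list of
#'   `identification_report`s plus the axis; `as.data.frame()` gives one
#'   row per (level, replicate).
#' @export
noise_sweep <- function(table, set_name, engine = c("lda", "wknn"),
                        schema = destrieux_schema(), lambda = 0.1, k = 3L,
                        split_mode = "per_subject_random", scale = TRUE,
                        levels = seq(0, 0.40, by = 0.05), replicates = 1L,
                        seed = 1L) {
  engine <- match.arg(engine)
  reports <- list()
  for (r in seq_len(replicates)) {
    for (i in seq_along(levels)) {
      # one split per replicate, shared across levels (matched conditions)
      rep_seed <- derive_seed(seed, 100L * r)
      rpt <- run_identification(table, set_name, engine, schema = schema,
                                lambda = lambda, k = k,
                                split_mode = split_mode,
                                noise_level = levels[i], scale = scale,
                                seed = rep_seed)
      rpt$replicate <- r
      reports[[length(reports) + 1L]] <- rpt
    }
  }
  structure(list(axis = "noise_level", values = levels,
                 replicates = replicates, reports = reports),
            class = "sweep_result")
}

#' Sample-size sweep
#'
#' Repeats the identification experiment on nested random subject subsets
#' of increasing size (by default 10, 20, ..., 190, clipped to the cohort
#' size), drawn without replacement.
#'
#' @inheritParams noise_sweep
#' @param sizes subject counts; default `seq(10, 190, by = 10)` (19 values).
#' @param noise_level noise fraction applied at every size (default 0).
#' @return A `sweep_result` over the size axis.
#' @export
size_sweep <- function(table, set_name, engine = c("lda", "wknn"),
                       schema = destrieux_schema(), lambda = 0.1, k = 3L,
                       split_mode = "per_subject_random", scale = TRUE,
                       sizes = seq(10L, 190L, by = 10L), noise_level = 0,
                       replicates = 1L, seed = 1L) {
  engine <- match.arg(engine)
  subjects <- sort(unique(table$subject_id))
  n <- length(subjects)
  sizes <- sizes[sizes <= n]
  if (length(sizes) == 0L) stop_morphid("no requested size fits the cohort (n = ", n, ")")
  reports <- list()
  for (r in seq_len(replicates)) {
    for (i in seq_along(sizes)) {
      m <- sizes[i]
      keep <- if (m == n) subjects else {
        with_seed(derive_seed(seed, 1000L * r + i), sample(subjects, m))
      }
      sub <- ft_rows(table, table$subject_id %in% keep)
      rpt <- run_identification(sub, set_name, engine, schema = schema,
                                lambda = lambda, k = k,
                                split_mode = split_mode,
                                noise_level = noise_level, scale = scale,
                                seed = derive_seed(seed, 100L * r))
      rpt$sample_size <- m
      rpt$replicate <- r
      reports[[length(reports) + 1L]] <- rpt
    }
  }
  structure(list(axis = "sample_size", values = sizes,
                 replicates = replicates, reports = reports),
            class = "sweep_result")
}

#' @export
as.data.frame.sweep_result <- function(x, ...) {
  rows <- lapply(x$reports, function(r) {
    df <- as.data.frame.identification_report(r)
    df$replicate <- if (is.null(r$replicate)) 1L else r$replicate
    if (!is.null(r$sample_size)) df$sample_size <- r$sample_size
    df
  })
  do.call(rbind, rows)
}

#' @export
print.sweep_result <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("sweep_result over %s (%d values x %d replicate(s))\n",
              x$axis, length(x$values), x$replicates))
  axis_col <- if (x$axis == "noise_level") "noise_level" else "sample_size"
  agg <- stats::aggregate(df[c("sensitivity", "f1")], by = df[axis_col],
                          FUN = mean)
  print(utils::head(agg, 20L), row.names = FALSE)
  invisible(x)
}

#' Plot a sweep curve
#'
#' Mean macro metric against the sweep axis, one line per metric, in base
#' graphics.
#'
#' @param x a `sweep_result`.
#' @param metrics which metrics to draw.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.sweep_result <- function(x, metrics = c("sensitivity", "f1"), ...) {
  df <- as.data.frame(x)
  axis_col <- if (x$axis == "noise_level") "noise_level" else "sample_size"
  agg <- stats::aggregate(df[metrics], by = df[axis_col], FUN = mean)
  graphics::matplot(agg[[axis_col]], as.matrix(agg[metrics]), type = "b",
                    pch = 19, lty = 1, xlab = axis_col,
                    ylab = "macro metric", ylim = c(0, 1), ...)
  graphics::legend("bottomleft", legend = metrics, col = seq_along(metrics),
                   pch = 19, lty = 1, bty = "n")
  invisible(x)
}
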