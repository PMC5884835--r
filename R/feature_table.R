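#' Morphometric feature tables
#'
#' A `feature_table` holds one row per subject-scan: opaque subject
#' identifiers, an integer time-point index per row (1-based scan number),
#' and a numeric matrix of named morphometric measures (regional cortical
#' thickness in mm, surface area in mm^2, volume in mm^3, or dimensionless
#' composites). It is the common currency passed between the cohort
#' generator, the identification engines and the experiment harness.
#'
#' Validity requires: unique (subject, timepoint) pairs, all values finite,
#' and a column count matching the feature names.
#'
#' @param subject_id character vector of subject identifiers, one per row.
#' @param timepoint integer vector of 1-based scan indices, one per row.
#' @param values numeric matrix, rows = subject-scans, columns = features.
#' @param feature_names optional character vector of feature (column) names;
#'   defaults to `colnames(values)`.
#' @param units optional character vector of per-feature unit tags
#'   (e.g. "mm", "mm^2", "mm^3", "1").
#' @return An object of class `feature_table`.
#' @examples
#' ft <- feature_table(
#'   subject_id = rep(c("s1", "s2"), each = 2),
#'   timepoint  = rep(1:2, 2),
#'   values     = matrix(rnorm(8), 4, 2,
#'                       dimnames = list(NULL, c("lh_thk", "rh_thk"))))
#' ft
#' @export
feature_table <- function(subject_id, timepoint, values, feature_names = NULL,
                          units = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_names)) feature_names <- colnames(values)
  if (is.null(feature_names)) {
    stop_morphid("feature names are required (set colnames(values) or pass feature_names)")
  }
  if (length(feature_names) != ncol(values)) {
    stop_morphid("length(feature_names) must equal ncol(values)")
  }
  subject_id <- as.character(subject_id)
  timepoint <- as.integer(timepoint)
  if (length(subject_id) != nrow(values) || length(timepoint) != nrow(values)) {
    stop_morphid("subject_id and timepoint must have one entry per row of values")
  }
  if (anyNA(timepoint) || any(timepoint < 1L)) {
    stop_morphid("timepoints must be positive integers (1-based scan index)")
  }
  key <- paste(subject_id, timepoint, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop_morphid("duplicate (subject, timepoint) pairs: ",
                 paste(gsub("\r", " t", dup), collapse = ", "))
  }
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    offenders <- apply(bad[seq_len(min(5L, nrow(bad))), , drop = FALSE], 1L,
                       function(ix) sprintf("row %d, column %s", ix[1L],
                                            feature_names[ix[2L]]))
    stop_morphid("non-finite/missing values at: ",
                 paste(offenders, collapse = "; "),
                 if (nrow(bad) > 5L) sprintf(" (and %d more)", nrow(bad) - 5L))
  }
  colnames(values) <- feature_names
  rownames(values) <- NULL
  if (!is.null(units) && length(units) != length(feature_names)) {
    stop_morphid("units must have one entry per feature")
  }
  structure(
    list(subject_id = subject_id, timepoint = timepoint, values = values,
         feature_names = feature_names, units = units),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d rows (%d subjects x up to %d timepoints), %d features\n",
              nrow(x$values), length(unique(x$subject_id)),
              max(x$timepoint), ncol(x$values)))
  show <- utils::head(x$feature_names, 4L)
  cat("features: ", paste(show, collapse = ", "),
      if (length(x$feature_names) > 4L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
as.data.frame.feature_table <- function(x, ...) {
  data.frame(subject_id = x$subject_id, timepoint = x$timepoint,
             as.data.frame(x$values), check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Subset the rows of a feature table
#'
#' @param table a [feature_table()].
#' @param i row index (integer or logical).
#' @return A `feature_table` with the selected rows.
#' @export
ft_rows <- function(table, i) {
  stopifnot(inherits(table, "feature_table"))
  feature_table(table$subject_id[i], table$timepoint[i],
                table$values[i, , drop = FALSE],
                feature_names = table$feature_names, units = table$units)
}

# Column subset keeping metadata aligned.
ft_cols <- function(table, names) {
  idx <- match(names, table$feature_names)
  feature_table(table$subject_id, table$timepoint,
                table$values[, idx, drop = FALSE],
                feature_names = names,
                units = if (!is.null(table$units)) table$units[idx])
}

#' Read a wide morphometric feature table
#'
#' Ingests tab- or comma-separated wide tables in the dialect emitted by
#' FreeSurfer's `aparcstats2table` / `asegstats2table`: one row per
#' subject-scan, first column an identifier, remaining columns numeric
#' measures. Time points are taken either from a dedicated integer column
#' named `timepoint` (or `tp`), or parsed from an identifier suffix of the
#' form `_t<N>` (e.g. `sub012_t2`); identifiers without either default to
#' time point 1. Rows are returned sorted by (subject, timepoint).
#'
#' @param path path to the file.
#' @param dialect `"tsv"` (default, FreeSurfer's native output) or `"csv"`.
#' @return A validated [feature_table()].
#' @export
read_feature_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_morphid("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_morphid("table needs an identifier column and at least one feature")
  ids <- df[[1L]]
  df <- df[-1L]
  tp_col <- which(tolower(names(df)) %in% c("timepoint", "tp"))
  if (length(tp_col) >= 1L) {
    tp <- suppressWarnings(as.integer(df[[tp_col[1L]]]))
    if (anyNA(tp)) stop_morphid("non-integer entries in the timepoint column")
    df <- df[-tp_col[1L]]
  } else if (all(grepl("_t[0-9]+$", ids))) {
    tp <- as.integer(sub("^.*_t([0-9]+)$", "\\1", ids))
    ids <- sub("_t[0-9]+$", "", ids)
  } else {
    tp <- rep(1L, length(ids))
  }
  if (ncol(df) < 1L) stop_morphid("no feature columns found")
  vals <- matrix(NA_real_, nrow(df), ncol(df),
                 dimnames = list(NULL, names(df)))
  for (j in seq_along(df)) {
    cell <- trimws(df[[j]])
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & nzchar(cell))
    if (length(bad) > 0L) {
      stop_morphid(sprintf("non-numeric cell at row %d, column %s: '%s'",
                           bad[1L], names(df)[j], cell[bad[1L]]))
    }
    blank <- which(!nzchar(cell))
    if (length(blank) > 0L) {
      stop_morphid("missing value at ",
                   paste(sprintf("row %d, column %s", blank, names(df)[j]),
                         collapse = "; "))
    }
    vals[, j] <- num
  }
  ord <- order(ids, tp)
  feature_table(ids[ord], tp[ord], vals[ord, , drop = FALSE])
}

#' Write a feature table to disk
#'
#' Writes the wide format accepted by [read_feature_table()]: an identifier
#' column of the form `<subject>_t<timepoint>` followed by the feature
#' columns. Values are written at full double precision so a write/read
#' round trip reproduces the table exactly.
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @export
write_feature_table <- function(table, path, dialect = c("tsv", "csv")) {
  stopifnot(inherits(table, "feature_table"))
  dialect <- match.arg(dialect)
  if (ncol(table$values) == 0L) stop_morphid("refusing to write a table with no feature columns")
  sep <- if (dialect == "tsv") "\t" else ","
  id <- sprintf("%s_t%d", table$subject_id, table$timepoint)
  body <- apply(table$values, 2L, function(col) sprintf("%.17g", col))
  if (nrow(table$values) == 1L) body <- matrix(body, nrow = 1L)
  lines <- c(paste(c("subject", table$feature_names), collapse = sep),
             apply(cbind(id, body), 1L, paste, collapse = sep))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
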