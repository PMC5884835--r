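test_that("feature_table validates its invariants", {
  v <- matrix(1:4, 2, 2, dimnames = list(NULL, c("a", "b")))
  ft <- feature_table(c("s1", "s1"), 1:2, v)
  expect_s3_class(ft, "feature_table")
  expect_equal(dim(ft), c(2L, 2L))
  # duplicate (subject, timepoint)
  expect_error(feature_table(c("s1", "s1"), c(1, 1), v), "duplicate")
  # non-finite values named by position
  v2 <- v; v2[2, 2] <- NA
  expect_error(feature_table(c("s1", "s2"), c(1, 1), v2), "row 2, column b")
  # column count must match names
  expect_error(feature_table("s1", 1, matrix(1, 1, 1), feature_names = c("a", "b")),
               "feature_names")
})

test_that("read_feature_table parses FreeSurfer-style wide tables", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject\ttp\tlh_thk\trh_thk",
               "s1\t1\t2.5\t2.6",
               "s1\t2\t2.4\t2.7",
               "s2\t1\t2.9\t2.8"), path)
  ft <- read_feature_table(path)
  expect_equal(ft$feature_names, c("lh_thk", "rh_thk"))
  expect_equal(nrow(ft$values), 3L)
  expect_equal(ft$timepoint, c(1L, 2L, 1L))

  # identifier-suffix timepoints
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject\tx", "s2_t2\t1.0", "s1_t1\t2.0"), path2)
  ft2 <- read_feature_table(path2)
  expect_equal(ft2$subject_id, c("s1", "s2"))  # sorted by (subject, tp)
  expect_equal(ft2$timepoint, c(1L, 2L))

  # error paths name the offending cell
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject\ta\tb", "s1_t1\t1.0\t", "s2_t1\t2.0\t3.0"), path3)
  expect_error(read_feature_table(path3), "row 1, column b")
  path4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject\ta", "s1_t1\tx9"), path4)
  expect_error(read_feature_table(path4), "non-numeric")
})

test_that("write/read round trip reproduces tables exactly", {
  set.seed(42)
  for (dialect in c("tsv", "csv")) {
    co <- tiny_cohort(5L, seed = 11L)
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_feature_table(co, path, dialect = dialect)
    back <- read_feature_table(path, dialect = dialect)
    expect_identical(back$values, co$values)
    expect_identical(back$subject_id, co$subject_id)
    expect_identical(back$timepoint, co$timepoint)
  }
  # full-width table round trip
  big <- generate_cohort(cohort_config(4L, seed = 3L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(big, path)
  expect_identical(read_feature_table(path)$values, big$values)
  # no-column table refused
  expect_error(write_feature_table(
    feature_table("s1", 1, matrix(0, 1, 0), feature_names = character()),
    withr::local_tempfile()), "no feature columns")
})

test_that("packaged schema defines the five canonical feature sets", {
  sch <- destrieux_schema()
  expect_equal(length(sch$set_definitions$THICKNESS), 148L)
  expect_equal(length(sch$set_definitions$AREA), 148L)
  expect_equal(length(sch$set_definitions$VOLUME), 148L)
  expect_equal(length(sch$set_definitions$`11LBR`), 11L)
  expect_equal(length(sch$set_definitions$ALL), 510L)
  # the LBR composites live inside ALL; modality sets are disjoint
  expect_true(all(sch$set_definitions$`11LBR` %in% sch$set_definitions$ALL))
  expect_length(intersect(sch$set_definitions$THICKNESS,
                          sch$set_definitions$AREA), 0L)
  expect_length(intersect(sch$set_definitions$AREA,
                          sch$set_definitions$VOLUME), 0L)
  # names referenced by the stepwise tables exist
  expect_true(all(c("rh_S_oc_middle_and_Lunatus_area",
                    "lh_S_oc_sup_and_transversal_area",
                    "EstimatedTotalIntraCranialVol", "TotalGrayVol", "CSF",
                    "WhiteSurfArea_area", "MeanThickness_thickness", "CC",
                    "WM-hypointensities") %in% sch$set_definitions$ALL))
})

test_that("select_feature_set subsets columns in schema order, idempotently", {
  co <- generate_cohort(cohort_config(3L, seed = 5L))
  sch <- destrieux_schema()
  all_tab <- select_feature_set(co, "ALL", sch)
  expect_equal(ncol(all_tab$values), 510L)
  thick <- select_feature_set(co, "THICKNESS", sch)
  expect_equal(ncol(thick$values), 148L)
  expect_identical(select_feature_set(thick, "THICKNESS", sch)$values,
                   thick$values)
  lbr <- select_feature_set(co, "11LBR", sch)
  expect_equal(lbr$feature_names, sch$set_definitions$`11LBR`)
  # missing columns are named
  dropped <- ft_rows(lbr, seq_len(nrow(lbr$values)))
  dropped$values <- dropped$values[, dropped$feature_names != "CC"]
  dropped$feature_names <- setdiff(dropped$feature_names, "CC")
  expect_error(select_feature_set(dropped, "11LBR", sch), "CC")
  expect_error(select_feature_set(co, "NOPE", sch), "unknown feature set")
})

test_that("schema JSON export round-trips the set definitions", {
  sch <- tiny_schema()
  path <- withr::local_tempfile(fileext = ".json")
  write_schema_json(sch, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$set_definitions$ALL, sch$set_definitions$ALL)
  expect_equal(back$regional_names, sch$regional_names)
})

test_that("scaler standardizes with the sample (n-1) convention and inverts", {
  tab <- ft_from_matrix(matrix(c(2, 4), 2, 1, dimnames = list(NULL, "x")),
                        c("a", "b"))
  sc <- feature_scaler(tab)
  expect_equal(unname(sc$center), 3)
  expect_equal(unname(sc$scale), sqrt(2))
  scaled <- predict(sc, tab)
  expect_equal(unname(scaled$values[, 1]), c(-0.7071068, 0.7071068),
               tolerance = 1e-6)
  # applied to its own fitting data: mean 0, SD 1
  co <- tiny_cohort(6L, seed = 2L)
  sc2 <- feature_scaler(co)
  z <- predict(sc2, co)
  expect_true(all(abs(colMeans(z$values)) < 1e-12))
  expect_equal(unname(apply(z$values, 2, sd)), rep(1, ncol(z$values)))
  # inverse recovers the original values
  expect_equal(predict(sc2, z, invert = TRUE)$values, co$values,
               tolerance = 1e-12)
  # constant columns are rejected by name
  const <- ft_from_matrix(matrix(c(1, 1, 2, 3), 2, 2,
                                 dimnames = list(NULL, c("flat", "ok"))),
                          c("a", "b"))
  expect_error(feature_scaler(const), "flat")
})

test_that("standardization does not change LDA predictions on full-rank data", {
  co <- tiny_cohort(8L, seed = 9L, n_regions = 1L)  # p = 8 < within-class df
  r_raw <- run_identification(co, "ALL", "lda", schema = tiny_schema(1L),
                              lambda = 0, scale = FALSE, seed = 4L)
  r_scaled <- run_identification(co, "ALL", "lda", schema = tiny_schema(1L),
                                 lambda = 0, scale = TRUE, seed = 4L)
  expect_identical(r_raw$correct, r_scaled$correct)
})
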