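test_that("time-point splits hold out exactly one scan per subject", {
  co <- tiny_cohort(5L, seed = 1L)
  plan <- split_timepoints(co, mode = "fixed", test_timepoint = 3L)
  expect_true(all(plan$test_timepoint == 3L))
  parts <- morphid:::apply_split(co, plan)
  expect_equal(nrow(parts$train$values), 10L)
  expect_equal(nrow(parts$test$values), 5L)
  expect_true(all(parts$test$timepoint == 3L))
  # random modes are seed-reproducible
  p1 <- split_timepoints(co, "per_subject_random", seed = 4L)
  p2 <- split_timepoints(co, "per_subject_random", seed = 4L)
  expect_identical(p1$test_timepoint, p2$test_timepoint)
  g <- split_timepoints(co, "global_random", seed = 4L)
  expect_equal(length(unique(g$test_timepoint)), 1L)
  expect_error(split_timepoints(co, "fixed"), "test_timepoint")
  # a subject with a single scan cannot be split
  solo <- ft_rows(co, co$timepoint == 1L)
  expect_error(split_timepoints(solo), ">= 2 time points")
})

test_that("random splits pick each timepoint about equally often", {
  co <- tiny_cohort(10L, seed = 2L)
  draws <- unlist(lapply(1:1000, function(s) {
    split_timepoints(co, "per_subject_random", seed = s)$test_timepoint
  }))
  # 10,000 subject-draws over 3 timepoints: binomial check at 1/3
  n <- length(draws)
  se <- sqrt((1 / 3) * (2 / 3) / n)
  for (t in 1:3) {
    expect_lt(abs(mean(draws == t) - 1 / 3), 3.5 * se)
  }
})

test_that("Gaussian noise scales with the training SD and only at level > 0", {
  co <- tiny_cohort(100L, seed = 3L, n_regions = 1L)
  parts <- morphid:::apply_split(co, split_timepoints(co, "fixed", test_timepoint = 3L))
  # level 0: untouched object
  expect_identical(add_gaussian_noise(parts$test, 0, parts$train, seed = 1L),
                   parts$test)
  noisy <- add_gaussian_noise(parts$test, 0.40, parts$train, seed = 9L)
  delta <- noisy$values - parts$test$values
  s <- apply(parts$train$values, 2, sd)
  emp <- apply(delta, 2, sd)
  se <- (0.40 * s) * sqrt(2 / (nrow(delta) - 1))
  expect_true(all(abs(emp - 0.40 * s) < 3.5 * se))
  # same seed, same draw
  expect_identical(noisy$values,
                   add_gaussian_noise(parts$test, 0.40, parts$train, seed = 9L)$values)
  expect_error(add_gaussian_noise(parts$test, -0.1, parts$train), "non-negative")
  # constant reference features pass through with a warning
  ref <- parts$train
  ref$values[, 1] <- 1
  expect_warning(out <- add_gaussian_noise(parts$test, 0.2, ref, seed = 1L),
                 "constant")
  expect_identical(out$values[, 1], parts$test$values[, 1])
})

test_that("macro metrics match a hand-filled confusion table", {
  perfect <- compute_metrics(letters[1:4], letters[1:4])
  expect_equal(c(perfect$accuracy, perfect$sensitivity,
                 perfect$specificity, perfect$f1), rep(1, 4))
  r <- compute_metrics(c("1", "2", "3", "4"), c("1", "2", "3", "3"))
  expect_equal(r$sensitivity, 0.75)
  expect_equal(r$specificity, (1 + 1 + 2 / 3 + 1) / 4)
  expect_equal(r$accuracy, 0.875)
  expect_equal(r$f1, (1 + 1 + 2 / 3 + 0) / 4)
  expect_equal(unname(r$correct), c(TRUE, TRUE, TRUE, FALSE))
  # collapsed predictor: high macro accuracy despite chance sensitivity,
  # because true negatives dominate every one-vs-rest table
  N <- 50L
  truth <- sprintf("s%02d", 1:N)
  all_one <- compute_metrics(truth, rep("s01", N))
  expect_equal(all_one$sensitivity, 1 / N)
  expect_gt(all_one$accuracy, 0.96)
  expect_error(compute_metrics(c("a", "a"), c("a", "b")), "one test row")
})

test_that("report invariants hold across random runs", {
  for (s in 1:5) {
    co <- tiny_cohort(12L, seed = 60L + s, noise_scale = 0.2)
    r <- run_identification(co, "ALL", engine = if (s %% 2) "lda" else "wknn",
                            schema = tiny_schema(), noise_level = 0.2, seed = s)
    expect_true(all(c(r$accuracy, r$sensitivity, r$specificity, r$f1) >= 0 &
                      c(r$accuracy, r$sensitivity, r$specificity, r$f1) <= 1))
    expect_equal(r$sensitivity, mean(r$correct))
    # accounting identity linking specificity to the misassigned mass
    N <- r$n_subjects
    expect_gte(r$specificity, 1 - N * (1 - r$sensitivity) / (N - 1) - 1e-12)
  }
})

test_that("the pipeline hits its degenerate limits", {
  # exact repeat scans: held-out scan equals a stored exemplar
  clean <- tiny_cohort(8L, seed = 21L, noise_scale = 0,
                       annual_drift_fraction = 0)
  for (engine in c("lda", "wknn")) {
    r <- run_identification(clean, "ALL", engine, schema = tiny_schema(),
                            seed = 5L)
    expect_equal(r$sensitivity, 1)
    expect_equal(r$f1, 1)
  }
  # no signatures: identification at chance (fresh cohort draw per seed so
  # the replicates are independent)
  sens <- vapply(1:10, function(s) {
    null_co <- tiny_cohort(50L, seed = 22L + s, signature_scale = 0,
                           annual_drift_fraction = 0)
    run_identification(null_co, "ALL", "wknn", schema = tiny_schema(),
                       seed = s)$sensitivity
  }, numeric(1))
  se <- sqrt(0.02 * 0.98 / 500)
  expect_lt(abs(mean(sens) - 0.02), 4 * se)
})

test_that("runs are exactly reproducible for a fixed seed", {
  co <- tiny_cohort(10L, seed = 8L)
  r1 <- run_identification(co, "ALL", "lda", schema = tiny_schema(),
                           noise_level = 0.2, seed = 77L)
  r2 <- run_identification(co, "ALL", "lda", schema = tiny_schema(),
                           noise_level = 0.2, seed = 77L)
  expect_identical(r1, r2)
})

test_that("sweeps cover the canonical axes", {
  co <- tiny_cohort(10L, seed = 14L)
  ns <- noise_sweep(co, "ALL", "lda", schema = tiny_schema(), seed = 3L)
  expect_equal(ns$values, seq(0, 0.40, by = 0.05))
  expect_length(ns$reports, 9L)
  # the level-0 cell equals a plain run under the same seed stream
  base <- run_identification(co, "ALL", "lda", schema = tiny_schema(),
                             noise_level = 0, seed = morphid:::derive_seed(3L, 100L))
  expect_equal(ns$reports[[1]]$correct, base$correct)
  df <- as.data.frame(ns)
  expect_equal(nrow(df), 9L)

  sz <- size_sweep(co, "ALL", "wknn", schema = tiny_schema(),
                   sizes = c(4L, 8L, 10L), seed = 3L)
  expect_equal(sz$values, c(4L, 8L, 10L))
  expect_equal(vapply(sz$reports, function(r) r$n_subjects, integer(1)),
               c(4L, 8L, 10L))
  # full-size cell uses every subject (no subsampling)
  expect_equal(sort(names(sz$reports[[3]]$correct)),
               sort(unique(co$subject_id)))
  # default axis is 10..190 by 10 clipped to the cohort
  big <- size_sweep(tiny_cohort(25L, seed = 15L), "ALL", "lda",
                    schema = tiny_schema(), sizes = seq(10L, 190L, 10L),
                    seed = 2L)
  expect_equal(big$values, c(10L, 20L))
})

test_that("sensitivity degrades with added noise on a marginal cohort", {
  # moderate-ICC cohort so noise has room to bite
  co <- tiny_cohort(15L, seed = 16L, signature_scale = 0.03,
                    noise_scale = 0.02)
  means <- vapply(c(0, 0.2, 0.4), function(level) {
    mean(vapply(1:10, function(s) {
      run_identification(co, "ALL", "wknn", schema = tiny_schema(),
                         noise_level = level, seed = s)$sensitivity
    }, numeric(1)))
  }, numeric(1))
  expect_lt(means[3], means[1])
})
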