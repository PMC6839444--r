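test_that("long and wide Ct tables parse to the same matrix", {
  dir <- withr::local_tempdir()
  long_path <- file.path(dir, "long.tsv")
  writeLines(c(
    "sample_id\tassay_id\tct",
    "s1\tm1\t20.5", "s1\tm2\tUndetermined",
    "s2\tm1\t21.0", "s2\tm2\t30.2",
    "s3\tm1\tNA", "s3\tm2\t29.9"
  ), long_path)
  m <- parse_ct_table(long_path, "long")
  expect_equal(dim(m), c(2L, 3L))
  expect_true(is.na(m$ct["m2", "s1"]))
  expect_true(is.na(m$ct["m1", "s3"]))
  expect_equal(m$ct["m1", "s2"], 21.0)

  wide_path <- file.path(dir, "wide.tsv")
  write_ct_table(m, wide_path, dialect = "wide")
  round_trip <- parse_ct_table(wide_path, "wide")
  expect_identical(round_trip$ct, m$ct)
})

test_that("parser rejects duplicates and malformed values with context", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "dup.tsv")
  writeLines(c("sample_id\tassay_id\tct", "s1\tm1\t20", "s1\tm1\t21"), p)
  expect_error(parse_ct_table(p, "long"), "duplicate")
  p2 <- file.path(dir, "bad.tsv")
  writeLines(c("sample_id\tassay_id\tct", "s1\tm1\ttwenty"), p2)
  expect_error(parse_ct_table(p2, "long"), "malformed")
})

test_that("detection filter applies the stricter rule and accounts exactly", {
  # 5 assays x 10 samples; assay 5 detected once only
  counts <- c(10, 10, 7, 2, 1)
  m <- ct_with_detected_counts(counts, 10)
  res <- detection_filter(m, min_samples = 2, min_fraction = 0.1)
  expect_identical(res$report$threshold, 2)
  expect_identical(res$report$n_retained, 4L)
  expect_identical(res$report$n_removed, 1L)
  expect_identical(res$report$n_retained + res$report$n_removed,
                   res$report$n_input)

  # boundary: threshold = n_samples keeps only fully detected assays
  res_all <- detection_filter(m, min_samples = 10, min_fraction = 1)
  expect_identical(res_all$report$n_retained, 2L)

  # Ct above the detection limit counts as undetected
  ct <- matrix(c(20, 20, 21, 36, 36, 36, 20, 20, 36), 3, 3, byrow = TRUE)
  m2 <- ct_matrix(ct, detection_limit = 35)
  res2 <- detection_filter(m2, min_samples = 2, min_fraction = 0.1)
  expect_identical(res2$report$n_retained, 2L)
  expect_true("assay_2" %in% res2$report$removed)
  # above-limit wells in retained assays are coerced to missing
  expect_true(is.na(res2$matrix$ct["assay_3", 3]))

  expect_error(detection_filter(ct_matrix(matrix(numeric(), 0, 0))), "empty")
})

test_that("detection filter is idempotent", {
  m <- simulate_cohort(small_config(seed = 8))$ct
  once <- detection_filter(m, 2, 0.15)
  twice <- detection_filter(once$matrix, 2, 0.15)
  expect_identical(once$matrix$ct, twice$matrix$ct)
  expect_identical(twice$report$n_removed, 0L)
})

test_that("the 303-of-750 detection accounting is reproduced on a fixture", {
  counts <- integer(750)
  counts[1:303] <- rep(c(10, 25, 40, 62), length.out = 303)  # >= 10 detected
  counts[304:750] <- rep(0:9, length.out = 447)              # below threshold
  m <- ct_with_detected_counts(counts, 62)
  res <- detection_filter(m, min_samples = 10, min_fraction = 0.15)
  expect_identical(res$report$threshold, 10)
  expect_identical(res$report$n_retained, 303L)
  expect_identical(res$report$n_removed, 447L)
  expect_equal(round(res$report$percent_retained, 1), 40.4)
})

test_that("global mean normalization removes per-sample shifts exactly", {
  set.seed(5)
  ct <- matrix(runif(60, 18, 30), 10, 6)
  m <- ct_matrix(ct)
  nm <- global_mean_normalize(m)
  # centering identity
  expect_true(all(abs(colMeans(nm$dct)) < 1e-9))
  # shift invariance: add a constant to one sample
  ct2 <- ct
  ct2[, 3] <- ct2[, 3] + 4.7
  nm2 <- global_mean_normalize(ct_matrix(ct2))
  expect_equal(nm$dct, nm2$dct, tolerance = 1e-12)
  expect_equal(nm2$sample_offsets[3] - nm$sample_offsets[3], 4.7,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("normalization bases handle missingness and degenerate samples", {
  ct <- matrix(c(20, 22, NA, 21, 23, 25, NA, NA, NA), 3, 3, byrow = FALSE)
  m <- ct_matrix(ct)
  expect_error(global_mean_normalize(m), "zero detected")
  m_ok <- ct_matrix(ct[, 1:2])
  per_sample <- global_mean_normalize(m_ok, "per_sample_detected")
  common <- global_mean_normalize(m_ok, "common_detected")
  # common basis = assays detected everywhere (rows 1 and 2)
  expect_equal(common$sample_offsets[1], mean(ct[1:2, 1]), ignore_attr = TRUE)
  expect_equal(per_sample$sample_offsets[1], mean(ct[1:3, 1], na.rm = TRUE),
               ignore_attr = TRUE)
})

test_that("a sparse planted effect survives normalization with small bias", {
  # 1 affected assay out of 100: the global mean moves by 1/100 of the
  # effect, so the recovered effect is biased by ~0.01 cycles, well under
  # the 0.03 tolerance
  set.seed(10)
  base <- runif(100, 18, 30)
  ct <- matrix(rep(base, 12), 100, 12)
  ct[1, 7:12] <- ct[1, 7:12] - 1  # 2-fold up in samples 7-12
  nm <- global_mean_normalize(ct_matrix(ct))
  est <- mean(nm$dct[1, 7:12]) - mean(nm$dct[1, 1:6])
  expect_lt(abs(est - (-1)), 0.03)
})

test_that("relative quantities follow the 2^-ddCt identities and an oracle", {
  set.seed(6)
  dct <- matrix(rnorm(24), 4, 6)
  nm <- make_nm(dct)
  em <- relative_quantity(nm, c("s1", "s2", "s3"))
  # brute-force element-wise oracle
  for (i in 1:4) {
    ref_mean <- mean(dct[i, 1:3])
    for (j in 1:6) {
      expect_equal(em$rq[i, j], 2^-(dct[i, j] - ref_mean), tolerance = 1e-12)
    }
  }
  # geometric mean over reference samples = 1 per assay
  geo <- apply(em$rq[, 1:3], 1L, function(v) exp(mean(log(v))))
  expect_true(all(abs(geo - 1) < 1e-9))
  # ddCt = 0 -> rq = 1; ddCt = +1 -> rq = 0.5
  nm1 <- make_nm(matrix(c(2, 2, 2, 3), 1, 4))
  em1 <- relative_quantity(nm1, c("s1", "s2", "s3"))
  expect_equal(unname(em1$rq[1, 1]), 1)
  expect_equal(unname(em1$rq[1, 4]), 0.5)
  # assay without reference data -> missing rq with warning
  dct_na <- dct
  dct_na[2, 1:3] <- NA
  expect_warning(em_na <- relative_quantity(make_nm(dct_na), c("s1", "s2", "s3")),
                 "no reference")
  expect_true(all(is.na(em_na$rq[2, ])))
})

test_that("assay CV matches the arithmetic oracle and scale conventions", {
  em <- make_em(matrix(log2(c(1, 1, 1.2,
                              2, 2, 2)), 2, 3, byrow = TRUE))
  cv <- assay_cv(em)
  expect_equal(cv$cv[2], 0)
  expect_equal(cv$cv[1], sd(c(1, 1, 1.2)) / mean(c(1, 1, 1.2)),
               tolerance = 1e-12)
  # low-noise synthetic: majority of assays below 5% CV on the linear scale
  set.seed(12)
  noise <- matrix(rnorm(50 * 20, sd = 0.05), 50, 20)
  em2 <- make_em(noise)
  cv2 <- assay_cv(em2)
  expect_gt(mean(cv2$cv < 0.05), 0.5)
  expect_error(assay_cv(em, sample_subset = character()), "empty")
})

test_that("standard-curve quantification matches its closed-form oracle", {
  # perfect 10-fold dilution series at 100% efficiency
  lq <- c(0, -1, -2, -3, -4)
  ct <- 20 - lq * log2(10)  # slope -log2(10) = -3.3219
  res <- standard_curve_quantify(list(log10_quantity = lq, ct = ct),
                                 unknowns = ct[2])
  expect_equal(res$curve$efficiency, 1, tolerance = 1e-3)
  expect_equal(res$quantities, 10^lq[2], tolerance = 1e-9)

  # noisy standards: least-squares closed form oracle
  set.seed(31)
  ctn <- ct + rnorm(5, sd = 0.2)
  fit <- standard_curve_quantify(list(log10_quantity = lq, ct = ctn))
  slope_oracle <- sum((lq - mean(lq)) * (ctn - mean(ctn))) /
    sum((lq - mean(lq))^2)
  intercept_oracle <- mean(ctn) - slope_oracle * mean(lq)
  expect_equal(fit$curve$slope, slope_oracle, tolerance = 1e-10)
  expect_equal(fit$curve$intercept, intercept_oracle, tolerance = 1e-10)

  expect_error(
    standard_curve_quantify(list(log10_quantity = c(0, -1, -2),
                                 ct = c(20, 23, 26) * -1 + 60)),
    "slope"
  )
  expect_error(
    standard_curve_quantify(list(log10_quantity = c(0, -0.5, -1),
                                 ct = c(20, 21, 22))),
    "span"
  )
})
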