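test_that("uncertainty filter flags exactly the strict exceedances of the 85th percentile", {
  rec <- make_records(10, seed = 21)     # 20 eyes, distinct SEs
  out <- filter_by_uncertainty(rec, percentile = 15)
  rel <- rec$se_phi_r / rec$phi_r
  expect_equal(sum(out$flag_high_uncertainty),
               sum(rel > naive_percentile(rel, 0.85)))
  expect_equal(sum(out$flag_high_uncertainty), 3)
})

test_that("tied uncertainties flag nobody and singletons error", {
  rec <- make_records(5, seed = 2)
  rec$se_phi_r <- 1; rec$phi_r <- 45
  out <- filter_by_uncertainty(rec)
  expect_equal(sum(out$flag_high_uncertainty), 0)
  expect_error(filter_by_uncertainty(make_records(5)[1, ]), "2 records")
})

test_that("best-eye selection keeps the lower-uncertainty unflagged eye", {
  rec <- make_records(2, seed = 3)
  rec$se_phi_r <- c(0.5, 0.3, 0.4, 0.6)
  rec$flag_high_uncertainty <- c(FALSE, FALSE, TRUE, FALSE)
  out <- select_best_eyes(rec)
  # pair 1: (0.5, 0.3) both unflagged -> first loses
  expect_equal(out$flag_not_best_eye[1:2], c(TRUE, FALSE))
  # pair 2: one flagged -> the other kept regardless of SE
  expect_equal(out$flag_not_best_eye[3:4], c(FALSE, FALSE))
  # singleton kept
  single <- make_records(1, seed = 4)[1, ]
  single$flag_high_uncertainty <- FALSE
  expect_false(select_best_eyes(single)$flag_not_best_eye)
})

test_that("best-eye ties break deterministically by laterality", {
  rec <- make_records(1, seed = 5)
  rec$se_phi_r <- c(0.4, 0.4)
  rec$flag_high_uncertainty <- FALSE
  out <- select_best_eyes(rec)
  expect_false(out$flag_not_best_eye[out$eye == "OD"])
  expect_true(out$flag_not_best_eye[out$eye == "OS"])
})

test_that("IQR rule reproduces the hand-computed fences", {
  v <- c(1, 2, 3, 4, 5, 100)
  # type-7 quartiles: Q1 = 2.25, Q3 = 4.75, upper fence 8.5
  expect_equal(remove_outliers_iqr(v), c(rep(FALSE, 5), TRUE))
  expect_equal(remove_outliers_iqr(rep(3, 6)), rep(FALSE, 6))
  expect_equal(remove_outliers_iqr(c(-2, -1, 0, 1, 2)), rep(FALSE, 5))
  expect_warning(remove_outliers_iqr(c(1, 2, 3)), "fewer than 4")
})

test_that("full cascade matches a naive reimplementation on random cohorts", {
  for (seed in 1:5) {
    rec <- do.call(rbind, lapply(1:4, function(s) {
      r <- make_records(6, strain = paste0("S", s), seed = seed * 10 + s)
      r
    }))
    out <- qc_cascade(rec)
    oracle <- naive_qc(rec)
    expect_equal(out$flag_high_uncertainty, oracle$high_uncertainty)
    expect_equal(out$flag_not_best_eye, oracle$not_best_eye)
    expect_equal(out$flag_strain_outlier, oracle$strain_outlier)
  }
})

test_that("cascade is idempotent and conserves record counts", {
  rec <- do.call(rbind, lapply(1:3, function(s) {
    make_records(8, strain = paste0("S", s), seed = 100 + s)
  }))
  out1 <- qc_cascade(rec)
  out2 <- qc_cascade(out1)
  expect_equal(out1$flag_high_uncertainty, out2$flag_high_uncertainty)
  expect_equal(out1$flag_not_best_eye, out2$flag_not_best_eye)
  expect_equal(out1$flag_strain_outlier, out2$flag_strain_outlier)
  expect_equal(out1$kept, out2$kept)
  rep <- attr(out1, "qc_report")
  expect_equal(rep$n_in, rep$n_high_uncertainty + rep$n_not_best_eye +
                 rep$n_strain_outlier + rep$n_kept)
  expect_equal(rep$n_in, nrow(rec))
})
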