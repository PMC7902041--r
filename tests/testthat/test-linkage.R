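toy_geno <- function(calls, cM, chr = "1") {
  # calls: strain x marker integer matrix (0 = B, 1 = D)
  map <- data.frame(marker = paste0("m", seq_along(cM)), chr = chr,
                    cM = cM, Mb = 3 + 2 * cM, stringsAsFactors = FALSE)
  ocuqtl:::new_genotype_matrix(
    matrix(calls, nrow = nrow(calls), ncol = ncol(calls),
           dimnames = list(paste0("S", seq_len(nrow(calls))), map$marker)),
    map, paste0("S", seq_len(nrow(calls))))
}

test_that("dosage is exact at typed markers and 0.5 at a B/D midpoint", {
  g <- toy_geno(rbind(c(0L, 1L), c(1L, 0L)), cM = c(0, 10))
  grid <- data.frame(chr = "1", cM = c(0, 5, 10), Mb = NA, marker = NA)
  d <- impute_dosage(g, grid = grid)$dosage
  expect_equal(unname(d[1, ]), c(0, 0.5, 1))
  expect_equal(unname(d[2, ]), c(1, 0.5, 0))
})

test_that("interior dosage matches enumeration of the two-interval RI chain", {
  R5 <- ri_expand(haldane_r(5))
  for (gl in 0:1) for (gr in 0:1) {
    g <- toy_geno(matrix(c(gl, gr), 1), cM = c(0, 10))
    grid <- data.frame(chr = "1", cM = 5, Mb = NA, marker = NA)
    d <- unname(impute_dosage(g, grid = grid)$dosage[1, 1])
    expect_equal(d, enum_mid_dosage(gl, gr, R5, R5), tolerance = 1e-12)
  }
  # both flanks B: the double-recombinant probability, strictly inside (0, 0.5)
  g <- toy_geno(matrix(c(0L, 0L), 1), cM = c(0, 10))
  grid <- data.frame(chr = "1", cM = 5, Mb = NA, marker = NA)
  d <- unname(impute_dosage(g, grid = grid)$dosage[1, 1])
  expect_equal(d, R5^2 / (R5^2 + (1 - R5)^2), tolerance = 1e-12)
  expect_gt(d, 0); expect_lt(d, 0.5)
})

test_that("dosages stay in [0,1], handle missing flanks and empty strains", {
  map <- sim_marker_map(n_chr = 2, length_cM = 50, spacing_cM = 10)
  g <- sim_ri_genotypes(map, 12, seed = 3)
  g$calls[1, map$chr == "1"] <- NA          # no typed markers on chr 1
  g$calls[2, 2] <- NA                       # single missing call
  expect_warning(d <- impute_dosage(g), "no typed markers")
  expect_true(all(d$dosage >= 0 & d$dosage <= 1))
  expect_true(all(d$dosage[1, d$grid$chr == "1"] == 0.5))
  typed <- which(!is.na(d$grid$marker))
  for (s in 3:12) {
    expect_true(all(d$dosage[s, typed] %in% c(0, 1)))
  }
})

test_that("LRS on the printed toy equals 4*ln(82)", {
  y <- c(S1 = 1.0, S2 = 1.1, S3 = 2.0, S4 = 1.9)
  g <- toy_geno(rbind(0L, 0L, 1L, 1L), cM = 0)
  scan <- scan_qtl(y, g)
  expect_equal(scan$table$lrs, 4 * log(82), tolerance = 1e-9)
  expect_equal(scan$table$lod, 4 * log(82) / (2 * log(10)), tolerance = 1e-9)
  expect_equal(scan$table$additive_effect, 0.9, tolerance = 1e-9)
  expect_equal(scan$table$half_effect, 0.45, tolerance = 1e-9)
  expect_equal(scan$table$variance_explained, 1 - 0.01 / 0.82,
               tolerance = 1e-9)
})

test_that("marker-level LRS equals the brute-force regression statistic", {
  map <- sim_marker_map(n_chr = 2, length_cM = 40, spacing_cM = 8)
  g <- sim_ri_genotypes(map, 16, seed = 5)
  set.seed(6)
  y <- setNames(rnorm(16, 2.4, 0.3), g$strains)
  scan <- scan_qtl(y, g)
  typed <- which(!is.na(scan$grid$marker))
  dos <- impute_dosage(g)$dosage
  for (j in typed[c(1, 4, 7, 10)]) {
    x <- dos[names(y), j]
    if (var(x) == 0) next
    fit <- lm(y ~ x)
    rss1 <- sum(resid(fit)^2)
    rss0 <- sum((y - mean(y))^2)
    expect_equal(scan$table$lrs[j], 16 * log(rss0 / rss1), tolerance = 1e-9)
  }
})

test_that("scan is invariant to affine phenotype transforms and relabeling", {
  map <- sim_marker_map(n_chr = 2, length_cM = 40, spacing_cM = 8)
  g <- sim_ri_genotypes(map, 14, seed = 8)
  set.seed(9)
  y <- setNames(rnorm(14, 2.4, 0.3), g$strains)
  s1 <- scan_qtl(y, g)
  s2 <- scan_qtl(3.2 * y - 1, g)
  expect_equal(s1$table$lrs, s2$table$lrs, tolerance = 1e-9)
  perm <- sample(names(y))
  s3 <- scan_qtl(y[perm], g)
  expect_equal(s1$table$lrs, s3$table$lrs, tolerance = 1e-9)
})

test_that("orthogonal phenotype gives LRS ~ 0 and monomorphic positions are flagged", {
  g <- toy_geno(rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L)),
                cM = c(0, 30))
  y <- c(S1 = 1, S2 = 2, S3 = 2, S4 = 1)   # orthogonal to marker 1 dosage
  scan <- scan_qtl(y, g)
  expect_lt(scan$table$lrs[1], 1e-9)
  g2 <- toy_geno(rbind(c(0L, 0L), c(0L, 1L), c(0L, 0L), c(0L, 1L)),
                 cM = c(0, 30))
  s2 <- scan_qtl(c(S1 = 1, S2 = 2, S3 = 1.5, S4 = 1.8), g2)
  expect_equal(s2$table$lrs[1], 0)
  expect_true(s2$table$monomorphic[1])
})

test_that("permutation thresholds are ordered, reproducible and seed-sensitive", {
  map <- sim_marker_map(n_chr = 3, length_cM = 50, spacing_cM = 5)
  g <- sim_ri_genotypes(map, 18, seed = 4)
  set.seed(5)
  y <- setNames(rnorm(18, 2.4, 0.25), g$strains)
  t1 <- permutation_thresholds(y, g, n_perm = 200, seed = 7)
  t2 <- permutation_thresholds(y, g, n_perm = 200, seed = 7)
  t3 <- permutation_thresholds(y, g, n_perm = 200, seed = 8)
  expect_gte(t1$significant, t1$suggestive)
  expect_identical(t1$max_lrs, t2$max_lrs)
  expect_false(identical(t1$max_lrs, t3$max_lrs))
  expect_error(permutation_thresholds(y, g, n_perm = 50), ">= 100")
})

test_that("flat null scans yield no peaks; planted signals yield localized peaks", {
  map <- sim_marker_map(n_chr = 3, length_cM = 60, spacing_cM = 5)
  g <- sim_ri_genotypes(map, 20, seed = 14)
  dos <- impute_dosage(g)
  set.seed(15)
  y_null <- setNames(rnorm(20, 2.4, 0.25), g$strains)
  scan0 <- scan_qtl(y_null, g, dosages = dos)
  thr <- permutation_thresholds(y_null, g, n_perm = 300, seed = 2,
                                dosages = dos)
  fake_hi <- list(suggestive = max(scan0$table$lrs) + 1,
                  significant = max(scan0$table$lrs) + 2)
  expect_equal(nrow(find_peaks(scan0, fake_hi)), 0)
  # two well-separated planted QTLs on different chromosomes
  typed <- d2 <- dos$dosage
  m1 <- which(dos$grid$chr == "1" & dos$grid$cM == 30)[1]
  m2 <- which(dos$grid$chr == "3" & dos$grid$cM == 30)[1]
  y2 <- setNames(2.4 + 0.8 * d2[, m1] - 0.8 * d2[, m2] +
                   rnorm(20, 0, 0.05), rownames(d2))
  scan2 <- scan_qtl(y2, g, dosages = dos)
  thr2 <- permutation_thresholds(y2, g, n_perm = 300, seed = 3,
                                 dosages = dos)
  peaks <- find_peaks(scan2, thr2)
  expect_gte(nrow(peaks), 2)
  expect_setequal(unique(peaks$chr[1:2]), c("1", "3"))
  # candidate window extends the marker bounds by 1 Mb on each side
  expect_true(all(peaks$window_lo_Mb == peaks$bound_lo_Mb - 1))
  expect_true(all(peaks$window_hi_Mb == peaks$bound_hi_Mb + 1))
  # opposite allele directions recovered
  p1 <- peaks[peaks$chr == "1", ][1, ]
  p3 <- peaks[peaks$chr == "3", ][1, ]
  expect_gt(p1$additive_effect, 0)
  expect_lt(p3$additive_effect, 0)
})
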