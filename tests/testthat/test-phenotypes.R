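test_that("strain aggregation handles degenerate and separated groups", {
  rec <- data.frame(strain = rep("A", 3), phi_norm = c(2, 2, 2),
                    method = "VF")
  expect_warning(agg <- aggregate_strains(rec), "single strain")
  expect_equal(agg$mean_phi_norm, 2)
  expect_equal(agg$sd, 0)
  expect_equal(agg$ci_lo, 2)
  expect_equal(agg$ci_hi, 2)
  rec2 <- data.frame(strain = rep(c("A", "B"), each = 4),
                     phi_norm = c(1.0, 1.1, 1.05, 0.95, 2.0, 2.1, 2.05, 1.95),
                     method = "VF")
  agg2 <- aggregate_strains(rec2)
  expect_lt(attr(agg2, "anova_p"), 0.05)
  expect_true(all(agg2$ci_lo < agg2$mean_phi_norm &
                    agg2$mean_phi_norm < agg2$ci_hi))
})

test_that("heritability follows the dispersion formula literally", {
  s <- data.frame(strain = c("A", "B", "C"), n_eyes = 5,
                  mean_phi_norm = c(2.0, 2.5, 3.0), sd = c(0.25, 0.25, 0.25))
  h <- heritability(s)
  expect_equal(h$vg, sd(c(2.0, 2.5, 3.0)))
  expect_equal(h$ve, 0.25)
  # symmetric case: Vg = Ve -> H2 = 0.5
  s2 <- s; s2$mean_phi_norm <- c(2.0, 2.25, 2.5)
  s2$sd <- sd(s2$mean_phi_norm)
  expect_equal(heritability(s2)$h2, 0.5, tolerance = 1e-12)
  # all means equal -> H2 = 0
  s3 <- s; s3$mean_phi_norm <- 2.4
  expect_equal(heritability(s3)$h2, 0)
})

test_that("heritability matches brute force, is scale-invariant and bounded", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    s <- data.frame(strain = paste0("S", 1:n), n_eyes = 6,
                    mean_phi_norm = rnorm(n, 2.4, 0.3),
                    sd = runif(n, 0.05, 0.5))
    h <- heritability(s)
    vg <- sqrt(sum((s$mean_phi_norm - mean(s$mean_phi_norm))^2) / (n - 1))
    ve <- sum(s$sd) / n
    expect_equal(h$h2, vg / (vg + ve), tolerance = 1e-12)
    expect_true(h$h2 >= 0 && h$h2 <= 1)
    sc <- s
    sc$mean_phi_norm <- sc$mean_phi_norm * 3.7
    sc$sd <- sc$sd * 3.7
    expect_equal(heritability(sc)$h2, h$h2, tolerance = 1e-12)
  }
})

test_that("variance-form heritability is available behind a switch", {
  s <- data.frame(strain = c("A", "B", "C"), n_eyes = 5,
                  mean_phi_norm = c(2.0, 2.5, 3.0), sd = c(0.2, 0.3, 0.4))
  h <- heritability(s, form = "variance")
  expect_equal(h$vg, var(s$mean_phi_norm), tolerance = 1e-12)
  expect_equal(h$ve, mean(s$sd^2), tolerance = 1e-12)
})

test_that("effective modulus reproduces the worked example and SI rederivation", {
  m <- effective_modulus(phi = 40, volume = 20000, thickness = 0.1,
                         pressure = 13)
  expect_equal(m$radius_mm, (3 * 20 / (4 * pi))^(1 / 3), tolerance = 1e-12)
  expect_equal(m$e_kPa, 863.7, tolerance = 1e-3)
  expect_equal(m$e_kPa, si_modulus_kPa(40, 20000, 0.1, 13), tolerance = 1e-9)
  # phi -> infinity limit: E -> 3R/(4t) * P
  m_inf <- effective_modulus(phi = 1e12, volume = 20000, thickness = 0.1,
                             pressure = 13)
  lim <- 3 * m$radius_mm / (4 * 0.1) * 13 * 0.133322
  expect_equal(m_inf$e_kPa, lim, tolerance = 1e-6)
  # doubling thickness halves E
  m2 <- effective_modulus(40, 20000, 0.2, 13)
  expect_equal(m2$e_kPa, m$e_kPa / 2, tolerance = 1e-12)
  expect_error(effective_modulus(-1, 20000, 0.1), "positive")
})

test_that("Bland-Altman summaries behave on constructed pairs", {
  x <- c(2.1, 2.3, 2.5, 2.7)
  ba0 <- compare_methods(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(unname(ba0$loa), c(0, 0))
  ba1 <- compare_methods(x + 0.2, x)
  expect_equal(ba1$bias, 0.2, tolerance = 1e-12)
  expect_equal(ba1$sd, 0)
  expect_error(compare_methods(x, x[1:3]), "unpaired")
})

test_that("correlation wrapper returns r, r2 and p with sane edge handling", {
  x <- c(1, 2, 3, 4, 5)
  ct <- correlate_traits(x, 2 * x)
  expect_equal(ct$r, 1, tolerance = 1e-12)
  expect_equal(ct$r2, 1, tolerance = 1e-12)
  set.seed(12)
  ct2 <- correlate_traits(rnorm(1000), rnorm(1000))
  expect_lt(abs(ct2$r), 0.1)
  expect_error(correlate_traits(x, rep(1, 5)), "zero variance")
  expect_error(correlate_traits(x[1:2], x[1:2]), "3 paired")
})
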