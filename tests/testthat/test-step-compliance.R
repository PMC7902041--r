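# Shared noise-free simulated eye for the estimator oracles.
sim_eye_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      eye <- ground_truth_eye(phi_r_true = 45, gamma_true = 10,
                              facility_true = 0.05)
      tr <- sim_perfusion(eye, quick_protocol(step_duration = 240), seed = 1)
      segs <- segment_steps(tr)
      fac <- estimate_facility(tr, segs)
      cache <<- list(eye = eye, trace = tr, segs = segs, fac = fac)
    }
    cache
  }
})

test_that("Volume Filling on a rectangle of inflow gives phi = dV/dP", {
  # constant 10 nl/s over a 10 s step, plateaus 10 -> 12 mmHg, C = 0
  n1 <- 40; n2 <- 41
  p2 <- c(seq(10, 12, length.out = n2 - 11), rep(12, 11))
  tr <- make_toy_trace(c(10, 12), c(n1, n2), dt = 0.25,
                       p_meas = c(rep(10, n1), p2),
                       q = c(rep(0, n1), rep(10, n2)))
  segs <- segment_steps(tr)
  fac <- structure(list(facility = 0, se = 0, intercept = 0,
                        n_plateaus = 2, negative = FALSE),
                   class = "facility_estimate")
  est <- vf_step_compliance(tr, segs[1, ], fac)
  expect_equal(est$delta_v, 100, tolerance = 1e-12)
  expect_equal(est$delta_p, 2, tolerance = 1e-12)
  expect_equal(est$phi, 50, tolerance = 1e-12)
  expect_equal(est$p_assign, 11)
})

test_that("Volume Filling matches the analytic secant on noise-free steps", {
  fx <- sim_eye_fixture()
  for (i in seq_len(nrow(fx$segs))) {
    est <- vf_step_compliance(fx$trace, fx$segs[i, ], fx$fac)
    expected <- secant_phi(45, 10, est$p_assign - est$delta_p / 2,
                           est$p_assign + est$delta_p / 2)
    expect_lt(abs(est$phi - expected) / expected, 0.005)
  }
})

test_that("ascending and descending mirrors agree on noise-free data", {
  fx <- sim_eye_fixture()
  asc <- fx$segs[fx$segs$direction == "ascending", ]
  des <- fx$segs[fx$segs$direction == "descending", ]
  # match by overlapping pressure interval (same levels up and down)
  for (i in seq_len(nrow(des))) {
    j <- which(abs(asc$p_start - des$p_end[i]) < 0.2 &
               abs(asc$p_end - des$p_start[i]) < 0.2)
    if (length(j) != 1) next
    phi_up <- vf_step_compliance(fx$trace, asc[j, ], fx$fac)$phi
    phi_dn <- vf_step_compliance(fx$trace, des[i, ], fx$fac)$phi
    expect_lt(abs(phi_up - phi_dn) / phi_up, 0.005)
  }
})

test_that("steps with too small a pressure change are rejected", {
  fx <- sim_eye_fixture()
  seg <- fx$segs[1, ]
  seg$p_end <- seg$p_start + 0.1
  expect_null(vf_step_compliance(fx$trace, seg, fx$fac))
})

test_that("Step Response round trip recovers the local compliance within 0.5%", {
  fx <- sim_eye_fixture()
  asc <- fx$segs[fx$segs$direction == "ascending", ]
  for (i in seq_len(nrow(asc))) {
    est <- sr_step_compliance(fx$trace, asc[i, ], 0.5, fx$fac)
    expected <- local_phi(45, 10, est$p_assign)
    expect_lt(abs(est$phi - expected) / expected, 0.005)
    expect_lt(abs(est$gamma_step - 10) / 10, 0.15)
  }
})

test_that("Step Response matches the exponential oracle in the linear limit", {
  eye <- ground_truth_eye(phi_r_true = 50, gamma_true = 1e7,
                          facility_true = 0, needle_resistance = 1)
  tr <- sim_perfusion(eye, quick_protocol(step_size = 2, n_steps_up = 1,
                                          n_steps_down = 0,
                                          step_duration = 600), seed = 1)
  segs <- segment_steps(tr)
  fac <- estimate_facility(tr, segs)
  est <- sr_step_compliance(tr, segs[1, ], 1, fac)
  # constant-compliance truth: phi = 50 regardless of anchor pressure
  expect_lt(abs(est$phi - 50) / 50, 0.005)
  # and the fitted transient matches the single-exponential relaxation
  idx <- segs$start[1]:(segs$end[1] - 1)
  t <- tr$time_s[idx] - tr$time_s[idx[1]]
  expect_lt(max(abs(tr$p_measured_mmHg[idx] - (10 - 2 * exp(-t / 50)))), 1e-4)
})

test_that("descending segments are refused by the Step Response estimator", {
  fx <- sim_eye_fixture()
  des <- fx$segs[fx$segs$direction == "descending", ][1, ]
  expect_error(sr_step_compliance(fx$trace, des, 0.5, fx$fac), "ascending")
})

test_that("step_compliances runs both estimators with one shared facility", {
  fx <- sim_eye_fixture()
  st <- step_compliances(fx$trace, method = "both")
  expect_setequal(unique(st$method), c("VF", "SR"))
  expect_true(all(st$direction[st$method == "SR"] == "ascending"))
  expect_s3_class(attr(st, "facility"), "facility_estimate")
})
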