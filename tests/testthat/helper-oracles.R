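# Independent oracles and fixture builders used across the suite. These are
# deliberately naive re-derivations (loops, hand formulas, enumeration) kept
# separate from the package implementation they check.

# Linear-interpolation percentile written from the order-statistics
# definition (not via stats::quantile).
naive_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# Naive QC cascade: loops and explicit rules, one method at a time.
naive_qc <- function(records, percentile = 15, k = 1.5) {
  rel <- records$se_phi_r / records$phi_r
  thr <- naive_percentile(rel, 1 - percentile / 100)
  f_unc <- rel > thr
  f_best <- rep(FALSE, nrow(records))
  for (an in unique(records$animal_id)) {
    i <- which(records$animal_id == an)
    if (length(i) < 2) next
    cand <- i[!f_unc[i]]
    if (length(cand) <= 1) next
    lat <- match(records$eye[cand], c("OD", "OS"))
    best <- cand[order(records$se_phi_r[cand], lat)][1]
    f_best[setdiff(cand, best)] <- TRUE
  }
  f_out <- rep(FALSE, nrow(records))
  for (s in unique(records$strain)) {
    i <- which(records$strain == s & !f_unc & !f_best)
    v <- records$phi_norm[i]
    if (length(v) < 4) next
    q1 <- naive_percentile(v, 0.25)
    q3 <- naive_percentile(v, 0.75)
    f_out[i] <- v < q1 - k * (q3 - q1) | v > q3 + k * (q3 - q1)
  }
  data.frame(high_uncertainty = f_unc, not_best_eye = f_best,
             strain_outlier = f_out)
}

# Analytic secant compliance of the pressure-compliance law over a step.
secant_phi <- function(phi_r, gam, p1, p2, p_ref = 13) {
  phi_r * (p_ref + gam) * log((p2 + gam) / (p1 + gam)) / (p2 - p1)
}

# Local compliance of the law at pressure p.
local_phi <- function(phi_r, gam, p, p_ref = 13) {
  phi_r * (p_ref + gam) / (p + gam)
}

# Effective-modulus rederivation in pure SI units (m, Pa), converted to kPa
# at the end.
si_modulus_kPa <- function(phi_nl_mmHg, volume_nl, thickness_mm,
                           pressure_mmHg) {
  V <- volume_nl * 1e-12            # m^3
  t <- thickness_mm * 1e-3          # m
  P <- pressure_mmHg * 133.322      # Pa
  phi <- phi_nl_mmHg * 1e-12 / 133.322   # m^3/Pa
  R <- (3 * V / (4 * pi))^(1 / 3)
  E <- 3 * R / (4 * t) * (V / phi + P)   # Pa
  E / 1000
}

# Enumeration of the two-interval RI chain: P(middle = D | flanks), with
# per-interval switching probabilities R1, R2.
enum_mid_dosage <- function(g1, g2, R1, R2) {
  tp <- function(a, b, R) if (a == b) 1 - R else R
  num <- tp(g1, 1, R1) * tp(1, g2, R2)
  den <- num + tp(g1, 0, R1) * tp(0, g2, R2)
  num / den
}

# Hand-built trace: a sequence of applied levels with explicit measured
# pressure and flow vectors (one value per sample).
make_toy_trace <- function(levels, n_per, p_meas, q, dt = 0.5,
                           mass_mg = 22.06) {
  n_per <- rep_len(n_per, length(levels))
  pa <- rep(levels, times = n_per)
  n <- length(pa)
  stopifnot(length(p_meas) == n, length(q) == n)
  tr <- data.frame(time_s = (seq_len(n) - 1) * dt, p_applied_mmHg = pa,
                   p_measured_mmHg = p_meas, q_nl_s = q)
  attr(tr, "meta") <- list(eye_id = "toy_a1_OD", strain = "TOY", eye = "OD",
                           mass_mg = mass_mg)
  class(tr) <- c("perfusion_trace", "data.frame")
  tr
}

# Short noise-free protocol for fast simulate-then-fit tests.
quick_protocol <- function(p_noise = 0, q_noise = 0, step_duration = 120,
                           ...) {
  perfusion_protocol(step_duration = step_duration, sampling_rate = 2,
                     pressure_noise_sd = p_noise, flow_noise_sd = q_noise,
                     ...)
}

# Synthetic eye-record table for QC tests.
make_records <- function(n_animals, strain = "S1", method = "VF", seed = 1) {
  set.seed(seed)
  n <- 2 * n_animals
  animal <- rep(sprintf("%s_a%02d", strain, seq_len(n_animals)), each = 2)
  data.frame(
    eye_id = paste0(animal, "_", rep(c("OD", "OS"), n_animals)),
    animal_id = animal, strain = strain,
    eye = rep(c("OD", "OS"), n_animals),
    mass_mg = 21, volume_ul = 21 / 1.103, method = method,
    phi_r = rnorm(n, 45, 3), se_phi_r = runif(n, 0.2, 2),
    gamma = 10, phi_norm = rnorm(n, 2.35, 0.2),
    se_phi_norm = NA_real_, n_steps = 17,
    stringsAsFactors = FALSE
  )
}
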