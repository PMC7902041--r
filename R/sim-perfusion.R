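# Forward simulation of stepped-pressure ocular perfusion experiments.
#
# The generator integrates the lumped-parameter model of a perfusion rig in
# series with an eye:
#
#   phi(P) dP/dt = Q_in - C * P - dVcreep/dt
#   Q_in         = (P_applied - P) / R_needle
#   phi(P)       = phi_r * (P_ref + gamma) / (P + gamma)      (P_ref = 13)
#   dVcreep/dt   = (creep_compliance * (P - baseline) - Vcreep) / creep_tau
#
# Units throughout: pressure mmHg, flow nl/s, volume nl, time s.

#' Stepped-pressure perfusion protocol
#'
#' Defaults give 9 ascending then 8 descending 1.5 mmHg steps from an
#' 8 mmHg baseline, 240 s per level at 2 Hz, so the plateau pressures
#' straddle the 13 mmHg reference pressure. Noise SDs default to 5% of the
#' step size (pressure) and 5% of the peak needle flow (flow).
#'
#' @param baseline_pressure starting applied pressure, mmHg
#' @param step_size pressure step magnitude, mmHg
#' @param n_steps_up,n_steps_down number of ascending / descending steps
#' @param step_duration seconds each applied level is held
#' @param sampling_rate samples per second, Hz
#' @param pressure_noise_sd Gaussian sensor noise on recorded pressure, mmHg
#' @param flow_noise_sd Gaussian sensor noise on recorded flow, nl/s
#' @return a `perfusion_protocol` list
#' @export
perfusion_protocol <- function(baseline_pressure = 8, step_size = 1.5,
                               n_steps_up = 9, n_steps_down = 8,
                               step_duration = 240, sampling_rate = 2,
                               pressure_noise_sd = 0.075,
                               flow_noise_sd = 0.15) {
  stop_if_not_scalar_pos(step_duration, "step_duration")
  stop_if_not_scalar_pos(sampling_rate, "sampling_rate")
  if (n_steps_up < 1) stop("n_steps_up must be >= 1", call. = FALSE)
  if (pressure_noise_sd < 0 || flow_noise_sd < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  structure(list(
    baseline_pressure = baseline_pressure, step_size = step_size,
    n_steps_up = n_steps_up, n_steps_down = n_steps_down,
    step_duration = step_duration, sampling_rate = sampling_rate,
    pressure_noise_sd = pressure_noise_sd, flow_noise_sd = flow_noise_sd
  ), class = "perfusion_protocol")
}

applied_levels <- function(protocol) {
  up <- protocol$baseline_pressure +
    protocol$step_size * (0:protocol$n_steps_up)
  down <- if (protocol$n_steps_down >= 1) {
    utils::tail(up, 1) - protocol$step_size * seq_len(protocol$n_steps_down)
  } else numeric(0)
  c(up, down)
}

#' Ground-truth eye for simulation
#'
#' @param eye_id,strain,eye,animal_id identifiers (laterality in `eye`)
#' @param mass eye mass, mg
#' @param phi_r_true compliance at the 13 mmHg reference pressure, nl/mmHg
#' @param gamma_true pressure-nonlinearity constant, mmHg
#' @param facility_true outflow facility C, nl/s/mmHg
#' @param needle_resistance perfusion needle + capillary resistance,
#'   mmHg*s/nl
#' @param creep_compliance quasi-static creep volume per unit pressure,
#'   nl/mmHg (0 disables viscoelastic creep)
#' @param creep_tau creep relaxation time constant, s
#' @return a `ground_truth_eye` list
#' @export
ground_truth_eye <- function(eye_id = "eye1", strain = "S1", eye = "OD",
                             animal_id = "a1", mass = 21.1,
                             phi_r_true = 45, gamma_true = 10,
                             facility_true = 0.05, needle_resistance = 0.5,
                             creep_compliance = 0, creep_tau = 60) {
  stop_if_not_scalar_pos(mass, "mass")
  stop_if_not_scalar_pos(phi_r_true, "phi_r_true")
  stop_if_not_scalar_pos(gamma_true, "gamma_true")
  stop_if_not_scalar_pos(needle_resistance, "needle_resistance")
  stop_if_not_scalar_pos(creep_tau, "creep_tau")
  if (facility_true < 0) stop("facility_true must be >= 0", call. = FALSE)
  if (creep_compliance < 0) stop("creep_compliance must be >= 0", call. = FALSE)
  structure(list(eye_id = eye_id, strain = strain, eye = eye,
                 animal_id = animal_id, mass = mass,
                 phi_r_true = phi_r_true, gamma_true = gamma_true,
                 facility_true = facility_true,
                 needle_resistance = needle_resistance,
                 creep_compliance = creep_compliance, creep_tau = creep_tau),
            class = "ground_truth_eye")
}

#' Simulate a perfusion trace for one eye
#'
#' Integrates the forward model with `deSolve::lsoda` level by level and
#' samples it at the protocol rate. Recorded pressure and flow carry
#' independent Gaussian sensor noise. The true parameters are attached as
#' attributes for test use only; the trace file writer never emits them.
#'
#' @param eye a [ground_truth_eye()]
#' @param protocol a [perfusion_protocol()]
#' @param seed integer seed for the sensor noise
#' @param p_ref reference pressure of the compliance law, mmHg
#' @return a `perfusion_trace` data frame with columns `time_s`,
#'   `p_applied_mmHg`, `p_measured_mmHg`, `q_nl_s`
#' @export
sim_perfusion <- function(eye, protocol = perfusion_protocol(), seed = 1L,
                          p_ref = 13) {
  levels <- applied_levels(protocol)
  dt <- 1 / protocol$sampling_rate
  m <- round(protocol$step_duration * protocol$sampling_rate)
  baseline <- protocol$baseline_pressure
  Rn <- eye$needle_resistance
  C <- eye$facility_true
  cc <- eye$creep_compliance
  tau <- eye$creep_tau
  phi_fun <- function(P) eye$phi_r_true * (p_ref + eye$gamma_true) /
    (P + eye$gamma_true)
  deriv <- function(t, y, parms) {
    P <- y[1]; Vc <- y[2]
    creepdot <- (cc * (P - baseline) - Vc) / tau
    qin <- (parms$pa - P) / Rn
    list(c((qin - C * P - creepdot) / phi_fun(P), creepdot))
  }
  P0 <- baseline / (1 + Rn * C)           # pre-perfusion equilibrium
  state <- c(P = P0, Vc = cc * (P0 - baseline))
  times_local <- seq(0, protocol$step_duration, by = dt)  # m samples + carry
  p_true <- q_true <- numeric(length(levels) * m)
  t_all <- (seq_len(length(levels) * m) - 1L) * dt
  pa_all <- rep(levels, each = m)
  for (k in seq_along(levels)) {
    sol <- tryCatch(
      deSolve::lsoda(state, times_local, deriv, parms = list(pa = levels[k]),
                     rtol = 1e-10, atol = 1e-8),
      warning = function(w) stop(sprintf(
        "ODE integration failed at applied level %d (%.3g mmHg): %s",
        k, levels[k], conditionMessage(w)), call. = FALSE),
      error = function(e) stop(sprintf(
        "ODE integration failed at applied level %d (%.3g mmHg): %s",
        k, levels[k], conditionMessage(e)), call. = FALSE)
    )
    if (any(!is.finite(sol[, "P"]))) {
      stop(sprintf("non-finite state at applied level %d (%.3g mmHg)",
                   k, levels[k]), call. = FALSE)
    }
    idx <- (k - 1L) * m + seq_len(m)
    p_true[idx] <- sol[seq_len(m), "P"]
    q_true[idx] <- (levels[k] - p_true[idx]) / Rn
    state <- sol[nrow(sol), c("P", "Vc")]
  }
  set.seed(seed)
  p_meas <- p_true + stats::rnorm(length(p_true), 0, protocol$pressure_noise_sd)
  q_meas <- q_true + stats::rnorm(length(q_true), 0, protocol$flow_noise_sd)
  trace <- data.frame(time_s = t_all, p_applied_mmHg = pa_all,
                      p_measured_mmHg = p_meas, q_nl_s = q_meas)
  attr(trace, "meta") <- list(eye_id = eye$eye_id, strain = eye$strain,
                              eye = eye$eye, animal_id = eye$animal_id,
                              mass_mg = eye$mass)
  attr(trace, "needle_resistance") <- Rn
  attr(trace, "truth") <- unclass(eye)
  class(trace) <- c("perfusion_trace", "data.frame")
  trace
}

#' @export
print.perfusion_trace <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("Perfusion trace: %d samples, %.0f s, applied %.3g-%.3g mmHg\n",
              nrow(x), max(x$time_s), min(x$p_applied_mmHg),
              max(x$p_applied_mmHg)))
  if (!is.null(meta)) {
    cat(sprintf("  eye %s (strain %s, %s, %.1f mg)\n",
                meta$eye_id, meta$strain, meta$eye, meta$mass_mg))
  }
  invisible(x)
}

#' @export
plot.perfusion_trace <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(x$time_s, x$p_measured_mmHg, type = "l", col = "grey40",
                 xlab = "time (s)", ylab = "pressure (mmHg)", ...)
  graphics::lines(x$time_s, x$p_applied_mmHg, col = "firebrick")
  graphics::plot(x$time_s, x$q_nl_s, type = "l", col = "grey40",
                 xlab = "time (s)", ylab = "flow (nl/s)")
  invisible(x)
}

#' Draw ground-truth eyes for a simulated cohort
#'
#' Converts the per-eye true normalized compliance from [sim_trait()] into
#' full biomechanical ground truth: eye masses are drawn around the
#' panel-typical 21.1 mg, volumes follow from the 1.103 mg/ul density, and
#' phi_r_true = phi_norm_true * volume. Nonlinearity and facility get mild
#' eye-to-eye variation.
#'
#' @param eyes per-eye table from [sim_trait()] (`$eyes`)
#' @param seed integer seed
#' @param mass_mean,mass_sd eye-mass distribution, mg
#' @param gamma_mean,gamma_sd nonlinearity distribution, mmHg
#' @param facility_mean mean outflow facility, nl/s/mmHg
#' @param facility_sdlog lognormal spread of facility
#' @param needle_resistance rig resistance, mmHg*s/nl
#' @param creep_compliance,creep_tau viscoelastic creep parameters
#' @param density eye density, mg/ul
#' @return list of [ground_truth_eye()] objects
#' @export
sim_eye_params <- function(eyes, seed = 1L, mass_mean = 21.1, mass_sd = 1.2,
                           gamma_mean = 10, gamma_sd = 1,
                           facility_mean = 0.05, facility_sdlog = 0.15,
                           needle_resistance = 0.5,
                           creep_compliance = 0, creep_tau = 60,
                           density = 1.103) {
  set.seed(derive_seed(seed, "mass"))
  n <- nrow(eyes)
  mass <- pmax(stats::rnorm(n, mass_mean, mass_sd), 0.5 * mass_mean)
  gam <- pmax(stats::rnorm(n, gamma_mean, gamma_sd), 2)
  fac <- facility_mean * stats::rlnorm(n, -facility_sdlog^2 / 2, facility_sdlog)
  lapply(seq_len(n), function(i) {
    vol <- mass[i] / density
    ground_truth_eye(
      eye_id = eyes$eye_id[i], strain = eyes$strain[i], eye = eyes$eye[i],
      animal_id = eyes$animal_id[i], mass = mass[i],
      phi_r_true = eyes$phi_norm_true[i] * vol, gamma_true = gam[i],
      facility_true = fac[i], needle_resistance = needle_resistance,
      creep_compliance = creep_compliance, creep_tau = creep_tau
    )
  })
}
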