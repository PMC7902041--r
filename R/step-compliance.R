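# Per-step compliance estimators.
#
# Volume Filling: integrate net inflow (measured inflow minus outflow C*P)
# over the step; compliance = volume change / pressure change, assigned at
# the step midpoint pressure. Used on ascending and descending steps.
#
# Step Response: fit the measured pressure transient after an ascending step
# to the lumped-parameter model
#   phi_local(P) dP/dt = (P_applied - P)/R_needle - C*P,
#   phi_local(P) = phi * (p_start + gamma_step) / (P + gamma_step),
# with (phi, gamma_step) free and C fixed. The governing equation is
# separable, giving the exact implicit solution
#   t(P) = A * ln( (P+g)(Pinf-P0) / ((P0+g)(Pinf-P)) ),
#   A = phi (p_start+g) / (beta (Pinf+g)),  beta = 1/Rn + C,
#   Pinf = Pa / (Rn beta),
# which the fit inverts with a monotone spline. The estimate is anchored at
# the pre-step plateau pressure (a local compliance), whereas Volume Filling
# gives a secant estimate at the step midpoint.

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Volume Filling compliance for one step
#'
#' @param trace a `perfusion_trace`
#' @param segment one row of [segment_steps()] output
#' @param facility a `facility_estimate`
#' @param dp_floor minimum |pressure change| (mmHg) for a usable step
#' @return one-row data frame (`method`, `phi`, `p_assign`, `se_phi`,
#'   `delta_v`, `delta_p`, ...) or NULL when the step is rejected
#' @export
vf_step_compliance <- function(trace, segment, facility, dp_floor = 0.2) {
  dp <- segment$p_end - segment$p_start
  if (abs(dp) < dp_floor) return(NULL)
  idx <- segment$start:(segment$end - 1L)
  t <- trace$time_s[idx]
  net <- trace$q_nl_s[idx] - facility$facility * trace$p_measured_mmHg[idx]
  dv <- trapz(t, net)
  phi <- dv / dp
  # uncertainty: integrated flow noise + facility uncertainty + plateau SEs
  dur <- t[length(t)] - t[1L]
  dt <- stats::median(diff(t))
  var_dv <- segment$q_sd^2 * dt * dur
  if (is.finite(facility$se)) {
    var_dv <- var_dv + (facility$se * trapz(t, trace$p_measured_mmHg[idx]))^2
  }
  se_dp <- sqrt(segment$p_start_se^2 + segment$p_end_se^2)
  se_phi <- abs(phi) * sqrt(var_dv / dv^2 + se_dp^2 / dp^2)
  data.frame(method = "VF", direction = segment$direction,
             phi = phi, p_assign = (segment$p_start + segment$p_end) / 2,
             se_phi = se_phi, delta_v = dv, delta_p = dp,
             gamma_step = NA_real_, converged = TRUE, gamma_pinned = FALSE,
             stringsAsFactors = FALSE)
}

# Predicted pressure transient of the step-response model at times t
# (seconds from step onset), by inversion of the closed-form t(P).
sr_predict <- function(t, phi, gam, P0, Pinf, beta, n_grid = 400L) {
  A <- phi * (P0 + gam) / (beta * (Pinf + gam))
  u <- seq(0, 30, length.out = n_grid)
  Pg <- Pinf - (Pinf - P0) * exp(-u)
  tg <- A * (u + log((Pg + gam) / (P0 + gam)))
  f <- stats::splinefun(tg, Pg, method = "hyman")
  out <- f(pmin(t, tg[n_grid]))
  out[t >= tg[n_grid]] <- Pinf
  out
}

#' Step Response compliance for one ascending step
#'
#' @param trace a `perfusion_trace`
#' @param segment one row of [segment_steps()] output (must be ascending)
#' @param needle_resistance rig resistance, mmHg*s/nl (from calibration)
#' @param facility a `facility_estimate` (held fixed in the fit)
#' @param gamma optional fixed nonlinearity; when NULL (default) gamma is a
#'   free fit parameter
#' @param gamma_bounds box for the free gamma parameter
#' @return one-row data frame as in [vf_step_compliance()], or NULL when the
#'   fit fails to converge
#' @export
sr_step_compliance <- function(trace, segment, needle_resistance, facility,
                               gamma = NULL, gamma_bounds = c(0.1, 1e4)) {
  if (segment$direction != "ascending") {
    stop("Step Response analysis uses ascending steps only", call. = FALSE)
  }
  idx <- segment$start:(segment$end - 1L)
  t <- trace$time_s[idx] - trace$time_s[idx[1L]]
  y <- trace$p_measured_mmHg[idx]
  Pa <- segment$level
  Rn <- needle_resistance
  beta <- 1 / Rn + facility$facility
  Pinf <- Pa / (Rn * beta)
  P0 <- segment$p_start
  if (Pinf <= P0) return(NULL)   # degenerate: no upward transient possible
  # initial phi from the initial slope: dP/dt(0) = beta (Pinf - P0) / phi
  k <- min(5L, length(t))
  s0 <- (y[k] - y[1L]) / (t[k] - t[1L])
  phi0 <- if (is.finite(s0) && s0 > 0) beta * (Pinf - P0) / s0 else 40
  phi0 <- min(max(phi0, 5), 500)
  resid_fun <- function(par) {
    g <- if (is.null(gamma)) par[2L] else gamma
    y - sr_predict(t, par[1L], g, P0, Pinf, beta)
  }
  phi_box <- c(1, 2000)
  lower <- if (is.null(gamma)) c(phi_box[1L], gamma_bounds[1L]) else phi_box[1L]
  upper <- if (is.null(gamma)) c(phi_box[2L], gamma_bounds[2L]) else phi_box[2L]
  starts <- if (is.null(gamma)) {
    c(lapply(c(3, 10, 30), function(g0) c(phi0, g0)),
      lapply(c(0.5, 2), function(f) c(min(max(phi0 * f, 2), 1000), 10)))
  } else {
    lapply(c(1, 0.5, 2), function(f) min(max(phi0 * f, 2), 1000))
  }
  fit <- NULL
  for (par0 in starts) {
    cand <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (!is.null(cand) && cand$info %in% 1:4 &&
        (is.null(fit) || cand$deviance < fit$deviance)) fit <- cand
  }
  if (is.null(fit)) return(NULL)
  par <- fit$par
  # a compliance stuck at its box is a failed fit, not an estimate
  if (par[1L] <= phi_box[1L] * 1.01 || par[1L] >= phi_box[2L] * 0.99) {
    return(NULL)
  }
  phi <- par[1L]
  g <- if (is.null(gamma)) par[2L] else gamma
  pinned <- is.null(gamma) &&
    (g <= gamma_bounds[1L] * 1.001 || g >= gamma_bounds[2L] * 0.999)
  # parameter covariance from a numerical Jacobian at the solution
  res <- resid_fun(par)
  dof <- length(res) - length(par)
  sigma2 <- sum(res^2) / max(dof, 1L)
  J <- vapply(seq_along(par), function(j) {
    h <- max(1e-6, 1e-6 * abs(par[j]))
    pp <- par; pp[j] <- pp[j] + h
    (resid_fun(pp) - res) / h
  }, numeric(length(res)))
  se_phi <- tryCatch(sqrt(sigma2 * solve(crossprod(J))[1L, 1L]),
                     error = function(e) NA_real_)
  data.frame(method = "SR", direction = segment$direction,
             phi = phi, p_assign = P0, se_phi = se_phi,
             delta_v = NA_real_, delta_p = NA_real_, gamma_step = g,
             converged = TRUE, gamma_pinned = pinned,
             stringsAsFactors = FALSE)
}

#' Per-step compliance estimates for a whole trace
#'
#' Runs Volume Filling on every step (both directions) and/or Step Response
#' on ascending steps, sharing one facility estimate per eye.
#'
#' @param trace a `perfusion_trace`
#' @param method one of "VF", "SR", "both"
#' @param needle_resistance rig resistance; defaults to the trace attribute
#' @param plateau_frac,dp_floor see [segment_steps()], [vf_step_compliance()]
#' @param sr_gamma optional fixed gamma for the Step Response fits
#' @return data frame of per-step estimates with the `facility_estimate`
#'   attached as attribute `facility`
#' @export
step_compliances <- function(trace, method = c("both", "VF", "SR"),
                             needle_resistance = NULL, plateau_frac = 0.25,
                             dp_floor = 0.2, sr_gamma = NULL) {
  method <- match.arg(method)
  if (is.null(needle_resistance)) {
    needle_resistance <- attr(trace, "needle_resistance")
  }
  segs <- segment_steps(trace, plateau_frac = plateau_frac)
  fac <- estimate_facility(trace, segs)
  out <- list()
  for (i in seq_len(nrow(segs))) {
    seg <- segs[i, ]
    if (method %in% c("both", "VF")) {
      out[[length(out) + 1L]] <- vf_step_compliance(trace, seg, fac, dp_floor)
    }
    if (method %in% c("both", "SR") && seg$direction == "ascending") {
      if (is.null(needle_resistance)) {
        stop("Step Response analysis needs a needle resistance", call. = FALSE)
      }
      out[[length(out) + 1L]] <- sr_step_compliance(
        trace, seg, needle_resistance, fac, gamma = sr_gamma)
    }
  }
  out <- do.call(rbind, out)
  attr(out, "facility") <- fac
  out
}
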