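# Reference-compliance fit: the empirical pressure-compliance law
#   phi(P) = phi_r * (P_ref + gamma) / (P + gamma)
# fitted to the per-step estimates by weighted nonlinear least squares,
# giving the compliance phi_r at the reference pressure (13 mmHg, the
# normal IOP of C57BL/6J mice) with a standard error.

#' Fit the pressure-compliance law to per-step estimates
#'
#' Weighted nonlinear least squares of `phi ~ phi_r*(p_ref+gamma)/(p+gamma)`
#' with weights 1/se^2 (unit weights when any SE is missing or zero), over a
#' multi-start grid of gamma initialisations; gamma is constrained positive.
#'
#' @param estimates data frame with columns `phi`, `p_assign` and optionally
#'   `se_phi` (e.g. from [step_compliances()], one method at a time)
#' @param p_ref reference pressure, mmHg
#' @param method label stored on the fit ("VF" or "SR")
#' @return object of class `compliance_fit`
#' @export
fit_compliance <- function(estimates, p_ref = 13, method = NULL) {
  est <- estimates[is.finite(estimates$phi) & is.finite(estimates$p_assign), ,
                   drop = FALSE]
  if (nrow(est) < 3L) stop("need at least 3 step estimates", call. = FALSE)
  if (length(unique(est$p_assign)) < 3L) {
    stop("need step estimates at >= 3 distinct pressures", call. = FALSE)
  }
  if (is.null(method)) {
    method <- if ("method" %in% names(est) && length(unique(est$method)) == 1L)
      est$method[1L] else "unknown"
  }
  se <- if ("se_phi" %in% names(est)) est$se_phi else rep(NA_real_, nrow(est))
  usable <- is.finite(se) & se > 0
  w <- if (all(usable)) 1 / se^2 else rep(1, nrow(est))
  dat <- data.frame(phi = est$phi, p = est$p_assign, w = w)
  phi0 <- dat$phi[which.min(abs(dat$p - p_ref))]
  best <- NULL
  for (g0 in c(1, 3, 10, 30, 100)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        phi ~ phi_r * (p_ref + gamma) / (p + gamma),
        data = dat, weights = w,
        start = list(phi_r = phi0, gamma = g0),
        lower = c(phi_r = 1e-6, gamma = 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (!is.null(fit)) {
      dev <- sum(w * stats::resid(fit)^2)
      if (is.null(best) || dev < best$dev) best <- list(fit = fit, dev = dev)
    }
  }
  if (is.null(best)) {
    stop("reference-compliance fit failed to converge over the multi-start grid",
         call. = FALSE)
  }
  fit <- best$fit
  co <- stats::coef(fit)
  ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) c(phi_r = NA_real_, gamma = NA_real_))
  structure(list(
    phi_r = unname(co["phi_r"]), gamma = unname(co["gamma"]),
    se_phi_r = unname(ses["phi_r"]), se_gamma = unname(ses["gamma"]),
    p_ref = p_ref, method = method,
    residual_rms = sqrt(mean(stats::resid(fit)^2)),
    n_steps_used = nrow(dat), data = dat, nls = fit
  ), class = "compliance_fit")
}

#' @export
print.compliance_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Reference-compliance fit (%s method, %d steps):\n",
              x$method, x$n_steps_used))
  cat(sprintf("  phi_r = %.*g +/- %.2g nl/mmHg at %.3g mmHg\n",
              digits, x$phi_r, x$se_phi_r, x$p_ref))
  cat(sprintf("  gamma = %.*g +/- %.2g mmHg\n", digits, x$gamma, x$se_gamma))
  cat(sprintf("  residual RMS %.3g nl/mmHg\n", x$residual_rms))
  invisible(x)
}

#' @export
coef.compliance_fit <- function(object, ...) {
  c(phi_r = object$phi_r, gamma = object$gamma)
}

#' Predict compliance at given pressures
#' @param object a `compliance_fit`
#' @param pressure pressures (mmHg); defaults to the fitted step pressures
#' @param ... unused
#' @export
predict.compliance_fit <- function(object, pressure = NULL, ...) {
  if (is.null(pressure)) pressure <- object$data$p
  object$phi_r * (object$p_ref + object$gamma) / (pressure + object$gamma)
}

#' @export
residuals.compliance_fit <- function(object, ...) {
  object$data$phi - predict.compliance_fit(object)
}

#' @export
summary.compliance_fit <- function(object, ...) {
  structure(list(fit = object,
                 rel_se = object$se_phi_r / object$phi_r),
            class = "summary.compliance_fit")
}

#' @export
print.summary.compliance_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  relative SE on phi_r: %.3g\n", x$rel_se))
  invisible(x)
}

#' @export
plot.compliance_fit <- function(x, ...) {
  p <- x$data$p
  graphics::plot(p, x$data$phi, xlab = "pressure (mmHg)",
                 ylab = "compliance (nl/mmHg)", ...)
  pp <- seq(min(p), max(p), length.out = 100)
  graphics::lines(pp, predict.compliance_fit(x, pp), col = "firebrick")
  graphics::abline(v = x$p_ref, lty = 3, col = "grey60")
  invisible(x)
}

#' Normalize a reference compliance by ocular volume
#'
#' Volume is eye mass divided by the published eye density 1.103 mg/ul;
#' `phi_norm = phi_r / volume`, and the SE scales by 1/volume.
#'
#' @param fit a `compliance_fit`, or a numeric phi_r (nl/mmHg)
#' @param mass eye mass, mg (> 0)
#' @param density eye density, mg/ul
#' @param se_phi_r SE of phi_r when `fit` is numeric
#' @return list with `volume_ul`, `phi_norm` (nl/mmHg/ul), `se_phi_norm`
#' @export
normalize_compliance <- function(fit, mass, density = 1.103,
                                 se_phi_r = NA_real_) {
  stop_if_not_scalar_pos(mass, "mass")
  stop_if_not_scalar_pos(density, "density")
  if (inherits(fit, "compliance_fit")) {
    phi_r <- fit$phi_r
    se_phi_r <- fit$se_phi_r
  } else {
    phi_r <- fit
  }
  volume <- mass / density
  list(volume_ul = volume, phi_norm = phi_r / volume,
       se_phi_norm = se_phi_r / volume)
}

#' Full per-eye estimation: steps, facility, fit, normalization
#'
#' @param trace a `perfusion_trace` with metadata (or supply `meta`)
#' @param method "VF", "SR" or "both"
#' @param needle_resistance rig resistance (defaults to trace attribute)
#' @param p_ref reference pressure, mmHg
#' @param density eye density, mg/ul
#' @param meta optional list with eye_id, animal_id, strain, eye, mass_mg
#' @param ... passed to [step_compliances()]
#' @return `eye_records` data frame, one row per method
#' @export
estimate_eye <- function(trace, method = c("both", "VF", "SR"),
                         needle_resistance = NULL, p_ref = 13,
                         density = 1.103, meta = NULL, ...) {
  method <- match.arg(method)
  if (is.null(meta)) meta <- attr(trace, "meta")
  if (is.null(meta)) stop("trace carries no metadata; supply 'meta'",
                          call. = FALSE)
  if (is.null(meta$animal_id)) {
    meta$animal_id <- sub("_(OD|OS)$", "", meta$eye_id)
  }
  steps <- step_compliances(trace, method = method,
                            needle_resistance = needle_resistance, ...)
  fac <- attr(steps, "facility")
  rows <- lapply(intersect(c("VF", "SR"), unique(steps$method)), function(m) {
    est <- steps[steps$method == m, , drop = FALSE]
    fit <- fit_compliance(est, p_ref = p_ref, method = m)
    nz <- normalize_compliance(fit, meta$mass_mg, density = density)
    data.frame(eye_id = meta$eye_id, animal_id = meta$animal_id,
               strain = meta$strain, eye = meta$eye, mass_mg = meta$mass_mg,
               volume_ul = nz$volume_ul, method = m,
               phi_r = fit$phi_r, se_phi_r = fit$se_phi_r, gamma = fit$gamma,
               phi_norm = nz$phi_norm, se_phi_norm = nz$se_phi_norm,
               n_steps = fit$n_steps_used,
               facility = fac$facility, facility_se = fac$se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("eye_records", "data.frame")
  out
}
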