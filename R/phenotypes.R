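# Strain-level phenotypes: aggregation with confidence intervals and ANOVA,
# heritability from strain dispersions, the thin-shell effective modulus,
# Bland-Altman method comparison, and trait correlations.

#' Aggregate QC'd eye records to strain means
#'
#' Per-strain mean, SD and t-based 95% confidence interval of phi_norm,
#' plus a one-way ANOVA across strains as a diagnostic.
#'
#' @param records QC'd `eye_records` (rows with `kept == FALSE` are dropped
#'   when a `kept` column is present); a single method at a time
#' @param conf confidence level
#' @return `strain_phenotypes` data frame with the ANOVA p-value attached as
#'   attribute `anova_p`
#' @export
aggregate_strains <- function(records, conf = 0.95) {
  if (!is.null(records$kept)) records <- records[records$kept, , drop = FALSE]
  if ("method" %in% names(records) && length(unique(records$method)) > 1L) {
    stop("aggregate one method at a time", call. = FALSE)
  }
  strains <- unique(records$strain)
  rows <- lapply(strains, function(s) {
    v <- records$phi_norm[records$strain == s]
    v <- v[is.finite(v)]
    if (length(v) == 0L) {
      warning(sprintf("strain %s has no usable eyes; omitted", s),
              call. = FALSE)
      return(NULL)
    }
    m <- mean(v)
    sdv <- if (length(v) > 1L) stats::sd(v) else NA_real_
    half <- if (length(v) > 1L && sdv > 0) {
      stats::qt(1 - (1 - conf) / 2, length(v) - 1L) * sdv / sqrt(length(v))
    } else 0
    data.frame(strain = s, n_eyes = length(v), mean_phi_norm = m,
               sd = sdv, ci_lo = m - half, ci_hi = m + half,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  anova_p <- NA_real_
  if (length(unique(records$strain)) >= 2L) {
    fit <- stats::lm(phi_norm ~ strain, data = records)
    anova_p <- stats::anova(fit)[["Pr(>F)"]][1L]
  } else {
    warning("single strain; ANOVA skipped", call. = FALSE)
  }
  attr(out, "anova_p") <- anova_p
  class(out) <- c("strain_phenotypes", "data.frame")
  out
}

#' Heritability from strain dispersions
#'
#' H^2 = Vg / (Vg + Ve) with, in the default (literal) form, Vg the standard
#' deviation of the strain means and Ve the mean of the within-strain
#' standard deviations. Note these are dispersions (SDs), not variances;
#' `form = "variance"` offers the variance-based variant.
#'
#' @param strains a `strain_phenotypes` data frame
#' @param form "sd" (default, literal) or "variance"
#' @return `heritability_result` list: `vg`, `ve`, `h2`, `form`, `n_strains`
#' @export
heritability <- function(strains, form = c("sd", "variance")) {
  form <- match.arg(form)
  ok <- is.finite(strains$sd)
  if (any(!ok)) {
    warning(sprintf("%d strain(s) lack a within-strain SD; excluded",
                    sum(!ok)), call. = FALSE)
  }
  s <- strains[ok, , drop = FALSE]
  if (nrow(s) < 2L) stop("need >= 2 strains with SDs", call. = FALSE)
  if (form == "sd") {
    vg <- stats::sd(s$mean_phi_norm)
    ve <- mean(s$sd)
  } else {
    vg <- stats::var(s$mean_phi_norm)
    ve <- mean(s$sd^2)
  }
  structure(list(vg = vg, ve = ve, h2 = vg / (vg + ve), form = form,
                 n_strains = nrow(s)),
            class = "heritability_result")
}

#' @export
print.heritability_result <- function(x, ...) {
  cat(sprintf("Heritability (%s form, %d strains): H2 = %.3f (Vg %.4g, Ve %.4g)\n",
              x$form, x$n_strains, x$h2, x$vg, x$ve))
  invisible(x)
}

#' Effective tensile modulus of the corneoscleral shell
#'
#' Thin-walled-sphere estimate E = 3R/(4t) * (V/phi + P), with the radius
#' from the sphere relation R = (3V/4pi)^(1/3). Assumes an isotropic,
#' incompressible, homogeneous thin shell. Evaluated in mmHg and converted
#' to kPa (1 mmHg = 0.133322 kPa).
#'
#' @param phi compliance at `pressure`, nl/mmHg
#' @param volume eye volume, nl
#' @param thickness shell thickness (CCT surrogate), mm
#' @param pressure evaluation pressure, mmHg
#' @return `modulus_result` data frame: `radius_mm`, `thickness_mm`,
#'   `pressure_mmHg`, `compliance_nl_mmHg`, `volume_nl`, `e_mmHg`, `e_kPa`
#' @export
effective_modulus <- function(phi, volume, thickness, pressure = 13) {
  if (any(phi <= 0) || any(volume <= 0) || any(thickness <= 0) ||
      any(pressure <= 0)) {
    stop("all modulus inputs must be positive", call. = FALSE)
  }
  radius <- (3 * (volume / 1000) / (4 * pi))^(1 / 3)   # nl -> mm^3 -> mm
  e_mmHg <- 3 * radius / (4 * thickness) * (volume / phi + pressure)
  out <- data.frame(radius_mm = radius, thickness_mm = thickness,
                    pressure_mmHg = pressure, compliance_nl_mmHg = phi,
                    volume_nl = volume, e_mmHg = e_mmHg,
                    e_kPa = e_mmHg * MMHG_TO_KPA)
  class(out) <- c("modulus_result", "data.frame")
  out
}

#' Bland-Altman comparison of the two compliance methods
#'
#' Paired differences VF - SR: mean bias, bias +/- 1.96 SD limits of
#' agreement, and the slope of difference on pairwise mean as a trend
#' diagnostic.
#'
#' @param vf,sr paired per-eye values (same length, same order)
#' @return `bland_altman` list
#' @export
compare_methods <- function(vf, sr) {
  if (length(vf) != length(sr)) stop("unpaired input", call. = FALSE)
  ok <- is.finite(vf) & is.finite(sr)
  vf <- vf[ok]; sr <- sr[ok]
  if (length(vf) < 2L) stop("need >= 2 pairs", call. = FALSE)
  d <- vf - sr
  m <- (vf + sr) / 2
  bias <- mean(d)
  sdd <- stats::sd(d)
  slope <- if (stats::var(m) > 0) unname(stats::coef(stats::lm(d ~ m))[2L])
           else NA_real_
  structure(list(n = length(d), bias = bias, sd = sdd,
                 loa = c(lower = bias - 1.96 * sdd, upper = bias + 1.96 * sdd),
                 trend_slope = slope, differences = d, means = m),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (VF - SR, n = %d): bias %.4g, LoA [%.4g, %.4g]\n",
              x$n, x$bias, x$loa[1L], x$loa[2L]))
  cat(sprintf("  trend slope (difference on mean): %.4g\n", x$trend_slope))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences, xlab = "pairwise mean",
                 ylab = "difference (VF - SR)", ...)
  graphics::abline(h = c(x$bias, x$loa), lty = c(1, 2, 2),
                   col = c("firebrick", "grey50", "grey50"))
  invisible(x)
}

#' Pearson correlation between two traits
#'
#' @param x,y paired finite values (n >= 3)
#' @return list: `r`, `r2`, `p`, `n`
#' @export
correlate_traits <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 paired values", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p = ct$p.value, n = length(x))
}
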