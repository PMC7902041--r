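# Step segmentation of a perfusion trace and plateau statistics.

plateau_idx <- function(a, b, frac) {
  n <- b - a + 1L
  seq.int(a + floor(n * (1 - frac)), b)
}

#' Segment a trace into pressure steps
#'
#' One segment per contiguous constant applied-pressure level after the
#' first; boundaries wherever the applied pressure changes. Plateau
#' statistics (trailing fraction of each level) of measured pressure and
#' flow are attached per segment, together with the pre-step plateau.
#'
#' @param trace a `perfusion_trace`
#' @param plateau_frac trailing fraction of each level used for steady-state
#'   statistics
#' @param min_samples minimum samples for a level to count as a plateau
#' @return a `step_segments` data frame (one row per step); the first
#'   level's plateau statistics are attached as attribute `first_plateau`
#' @export
segment_steps <- function(trace, plateau_frac = 0.25, min_samples = 4L) {
  pa <- trace$p_applied_mmHg
  runs <- rle(pa)
  if (length(runs$lengths) < 2L) stop("no steps found", call. = FALSE)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ok <- runs$lengths >= min_samples
  if (!any(ok[-1L])) stop("no steps found: no applied level is held long enough",
                          call. = FALSE)
  if (!ok[1L]) stop("first applied level too short to define a pre-step plateau",
                    call. = FALSE)
  pstat <- function(a, b) {
    w <- plateau_idx(a, b, plateau_frac)
    list(p = mean(trace$p_measured_mmHg[w]),
         p_sd = stats::sd(trace$p_measured_mmHg[w]),
         p_se = stats::sd(trace$p_measured_mmHg[w]) / sqrt(length(w)),
         q = mean(trace$q_nl_s[w]),
         q_sd = stats::sd(trace$q_nl_s[w]),
         n = length(w), a = w[1L], b = w[length(w)])
  }
  segs <- list()
  prev <- pstat(starts[1L], ends[1L])
  prev_level <- runs$values[1L]
  for (k in 2L:length(runs$lengths)) {
    if (!ok[k]) next
    cur <- pstat(starts[k], ends[k])
    segs[[length(segs) + 1L]] <- data.frame(
      direction = if (runs$values[k] > prev_level) "ascending" else "descending",
      start = starts[k], end = ends[k] + 1L,   # half-open [start, end)
      level = runs$values[k], prev_level = prev_level,
      p_start = prev$p, p_start_se = prev$p_se,
      p_end = cur$p, p_end_se = cur$p_se,
      q_start = prev$q, q_end = cur$q, q_sd = cur$q_sd, p_sd = cur$p_sd,
      pw_start = cur$a, pw_end = cur$b,
      stringsAsFactors = FALSE
    )
    prev <- cur
    prev_level <- runs$values[k]
  }
  if (length(segs) == 0L) stop("no steps found", call. = FALSE)
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  attr(out, "first_plateau") <- pstat(starts[1L], ends[1L])
  attr(out, "plateau_frac") <- plateau_frac
  class(out) <- c("step_segments", "data.frame")
  out
}

#' Outflow facility from plateau pressure-flow pairs
#'
#' Ordinary least squares of plateau-mean flow on plateau-mean measured
#' pressure across the first level and every segment plateau. The slope is
#' the outflow facility C (nl/s/mmHg); the intercept is retained as a
#' diagnostic. A negative fitted C is flagged but kept.
#'
#' @param trace a `perfusion_trace`
#' @param segments result of [segment_steps()]
#' @return a `facility_estimate` list: `facility`, `se`, `intercept`,
#'   `n_plateaus`, `negative`
#' @export
estimate_facility <- function(trace, segments) {
  fp <- attr(segments, "first_plateau")
  P <- c(fp$p, segments$p_end)
  Q <- c(fp$q, segments$q_end)
  if (length(P) < 2L) stop("need at least 2 plateaus to estimate facility",
                           call. = FALSE)
  fit <- stats::lm(Q ~ P)
  co <- stats::coef(fit)
  se <- if (length(P) > 2L) {
    suppressWarnings(summary(fit)$coefficients["P", "Std. Error"])
  } else NA_real_
  C <- unname(co["P"])
  neg <- C < 0
  if (neg) warning("fitted outflow facility is negative; value retained",
                   call. = FALSE)
  structure(list(facility = C, se = se, intercept = unname(co["(Intercept)"]),
                 n_plateaus = length(P), negative = neg),
            class = "facility_estimate")
}

#' @export
print.facility_estimate <- function(x, ...) {
  cat(sprintf("Outflow facility: C = %.4g nl/s/mmHg (se %.3g, %d plateaus)\n",
              x$facility, x$se, x$n_plateaus))
  invisible(x)
}
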