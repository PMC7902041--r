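# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# All percentile/quartile rules in the package use linear interpolation of
# order statistics (stats::quantile type 7), one convention throughout.
quantile_li <- function(x, probs) {
  stats::quantile(x, probs = probs, names = FALSE, type = 7, na.rm = FALSE)
}

# Deterministic per-stage seed derived from one master seed; keeps every
# derived seed a valid 32-bit integer.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  offsets <- c(
    genotypes = 1L, trait = 2L, perfusion = 3L, permutation = 4L,
    mass = 5L, noise = 6L
  )
  k <- offsets[[stage]]
  as.integer((abs(seed) + 97003L * k) %% 2147483629)
}

# mmHg -> kPa conversion used at reporting boundaries only.
MMHG_TO_KPA <- 0.133322

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
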