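# Quality-control cascade on per-eye records, applied per analysis method in
# a fixed order: (1) flag eyes in the top 15th percentile of relative
# uncertainty on phi_r; (2) keep the better (lower-uncertainty) unflagged eye
# of each pair; (3) flag per-strain 1.5-IQR outliers of phi_norm among the
# survivors. A record is "kept" iff it carries no flag; counts are conserved
# at every stage and every flag is attributable in the QC report.

#' Flag high-uncertainty eyes
#'
#' Flags records whose relative SE (se_phi_r/phi_r) strictly exceeds the
#' 85th percentile (linear interpolation of order statistics) of the whole
#' data set, separately per method.
#'
#' @param records `eye_records` data frame
#' @param percentile percent of eyes to target for elimination (top tail)
#' @return records with a logical `flag_high_uncertainty` column
#' @export
filter_by_uncertainty <- function(records, percentile = 15) {
  rel <- records$se_phi_r / records$phi_r
  if (all(!is.finite(rel))) stop("all uncertainty values missing", call. = FALSE)
  if (nrow(records) < 2L) stop("need at least 2 records", call. = FALSE)
  flag <- logical(nrow(records))
  for (m in unique(records$method)) {
    i <- which(records$method == m & is.finite(rel))
    if (length(i) < 2L) next
    thr <- quantile_li(rel[i], 1 - percentile / 100)
    flag[i] <- rel[i] > thr
  }
  records$flag_high_uncertainty <- flag
  records
}

#' Select the better eye of each pair
#'
#' Eyes sharing an `animal_id` form a pair. Among the uncertainty-unflagged
#' eyes of a pair the one with lower se_phi_r is kept; the other receives a
#' `flag_not_best_eye`. If only one eye of a pair is unflagged it is kept
#' regardless of SE. Singletons are kept. Ties break by laterality order
#' (OD before OS), deterministically.
#'
#' @param records output of [filter_by_uncertainty()]
#' @return records with a logical `flag_not_best_eye` column
#' @export
select_best_eyes <- function(records) {
  if (is.null(records$flag_high_uncertainty)) {
    records$flag_high_uncertainty <- FALSE
  }
  records$flag_not_best_eye <- FALSE
  for (m in unique(records$method)) {
    sel <- which(records$method == m)
    for (an in unique(records$animal_id[sel])) {
      i <- sel[records$animal_id[sel] == an]
      if (length(i) < 2L) next
      cand <- i[!records$flag_high_uncertainty[i]]
      if (length(cand) <= 1L) next   # 0 or 1 usable eye: nothing to drop
      ord <- order(records$se_phi_r[cand],
                   match(records$eye[cand], c("OD", "OS")))
      records$flag_not_best_eye[cand[-ord[1L]]] <- TRUE
    }
  }
  records
}

#' Tukey 1.5-IQR outlier flags
#'
#' Flags values outside [Q1 - k*IQR, Q3 + k*IQR], quartiles by linear
#' interpolation of order statistics. With fewer than 4 values nothing is
#' removed (a warning is raised).
#'
#' @param values numeric vector
#' @param k IQR multiplier
#' @return logical vector of outlier flags
#' @export
remove_outliers_iqr <- function(values, k = 1.5) {
  ok <- is.finite(values)
  if (sum(ok) < 4L) {
    warning("fewer than 4 values; no outlier removal", call. = FALSE)
    return(logical(length(values)))
  }
  q <- quantile_li(values[ok], c(0.25, 0.75))
  iqr <- q[2L] - q[1L]
  out <- values < q[1L] - k * iqr | values > q[2L] + k * iqr
  out & ok
}

#' Full QC cascade
#'
#' Applies the three rules in order per method. Re-running the cascade on
#' its own output reproduces the same flags (the rules are recomputed on the
#' full record set, so the cascade is idempotent).
#'
#' @param records `eye_records` data frame
#' @param percentile uncertainty-filter percentile
#' @param k IQR multiplier for the per-strain outlier rule
#' @return records with flag columns and a `kept` column; a per-method count
#'   table is attached as attribute `qc_report`
#' @export
qc_cascade <- function(records, percentile = 15, k = 1.5) {
  records <- filter_by_uncertainty(records, percentile = percentile)
  records <- select_best_eyes(records)
  records$flag_strain_outlier <- FALSE
  pre <- !records$flag_high_uncertainty & !records$flag_not_best_eye
  for (m in unique(records$method)) {
    for (s in unique(records$strain)) {
      i <- which(records$method == m & records$strain == s & pre)
      if (length(i) == 0L) next
      fl <- withCallingHandlers(
        remove_outliers_iqr(records$phi_norm[i], k = k),
        warning = function(w) invokeRestart("muffleWarning")
      )
      records$flag_strain_outlier[i] <- fl
    }
  }
  records$kept <- !records$flag_high_uncertainty &
    !records$flag_not_best_eye & !records$flag_strain_outlier
  report <- do.call(rbind, lapply(unique(records$method), function(m) {
    r <- records[records$method == m, ]
    data.frame(method = m, n_in = nrow(r),
               n_high_uncertainty = sum(r$flag_high_uncertainty),
               n_not_best_eye = sum(r$flag_not_best_eye),
               n_strain_outlier = sum(r$flag_strain_outlier),
               n_kept = sum(r$kept), stringsAsFactors = FALSE)
  }))
  attr(records, "qc_report") <- report
  records
}
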