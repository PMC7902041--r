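# End-to-end pipeline: (simulate or load) -> per-eye estimation -> QC ->
# strain aggregation -> heritability -> genome scan -> permutation
# thresholds -> peaks -> optional modulus and method comparison.

#' Run the full analysis pipeline
#'
#' With input files in the config the pipeline analyses them; otherwise it
#' simulates a cohort from the config's `sim` block (traces are generated
#' and analysed eye by eye; ground truth is kept on a separate stream and
#' never enters the estimators). Both the Volume Filling and Step Response
#' branches run when `method = "both"`. Fully deterministic given the seed.
#'
#' @param config a [run_config()]
#' @param out_dir optional output directory for the delimited result tables
#'   and the machine-readable run summary
#' @param quiet suppress stage logging (logs go to stderr)
#' @return an `ocuqtl_run` list: records, QC report, per-method strain
#'   phenotypes / heritability / scans / thresholds / peaks, method
#'   comparison, and (when simulated) the ground-truth stream
#' @export
run_pipeline <- function(config = run_config(), out_dir = config$out_dir,
                         quiet = FALSE) {
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed
  simulated <- is.null(config$trace_dir)

  protocol <- do.call(perfusion_protocol, config$protocol)
  truth <- NULL
  if (simulated) {
    log_msg("stage simulate: %d strains x %d eyes", config$sim$n_strains,
            config$sim$n_eyes_per_strain)
    map <- do.call(sim_marker_map, config$map)
    genotypes <- sim_ri_genotypes(map, config$sim$n_strains,
                                  seed = derive_seed(seed, "genotypes"))
    arch <- trait_architecture(
      qtl_chr = config$sim$qtl_chr, qtl_cM = config$sim$qtl_cM,
      variance_explained = config$sim$variance_explained,
      strain_env_sd = config$sim$strain_env_sd,
      eye_env_sd = config$sim$eye_env_sd
    )
    tr <- sim_trait(genotypes, arch, config$sim$n_eyes_per_strain,
                    base_phi_norm = config$sim$base_phi_norm, seed = seed)
    eyes <- sim_eye_params(tr$eyes, seed = seed,
                           needle_resistance = config$needle_resistance,
                           creep_compliance = config$sim$creep_compliance,
                           creep_tau = config$sim$creep_tau,
                           density = config$density)
    truth <- list(trait = tr, eyes = eyes, map = map)
    n_eyes_in <- length(eyes)
    log_msg("stage estimate: %d traces (%s)", n_eyes_in, config$method)
    records <- do.call(rbind, lapply(seq_along(eyes), function(i) {
      trace <- sim_perfusion(eyes[[i]], protocol,
                             seed = derive_seed(seed, "noise") + i)
      estimate_eye(trace, method = config$method, p_ref = config$p_ref,
                   density = config$density)
    }))
  } else {
    metadata <- read_eye_metadata(config$metadata_file)
    genotypes <- read_genotypes(config$genotype_file)
    n_eyes_in <- nrow(metadata)
    log_msg("stage estimate: %d trace files (%s)", n_eyes_in, config$method)
    records <- do.call(rbind, lapply(seq_len(nrow(metadata)), function(i) {
      path <- file.path(config$trace_dir,
                        paste0(metadata$eye_id[i], ".csv"))
      trace <- read_trace(path, meta = as.list(metadata[i, ]))
      estimate_eye(trace, method = config$method,
                   needle_resistance = config$needle_resistance,
                   p_ref = config$p_ref, density = config$density)
    }))
  }
  class(records) <- c("eye_records", "data.frame")

  log_msg("stage qc: percentile %.3g, IQR k %.3g", config$qc_percentile,
          config$iqr_k)
  records <- qc_cascade(records, percentile = config$qc_percentile,
                        k = config$iqr_k)
  report <- attr(records, "qc_report")
  stopifnot(all(report$n_in == report$n_high_uncertainty +
                  report$n_not_best_eye + report$n_strain_outlier +
                  report$n_kept))

  methods <- intersect(c("VF", "SR"), unique(records$method))
  dosages <- impute_dosage(genotypes, step_cM = config$step_cM)
  per_method <- lapply(methods, function(m) {
    r <- records[records$method == m, , drop = FALSE]
    strains <- aggregate_strains(r)
    h2 <- heritability(strains)
    log_msg("stage aggregate [%s]: %d strains kept, H2 = %.3f", m,
            nrow(strains), h2$h2)
    pheno <- stats::setNames(strains$mean_phi_norm, strains$strain)
    scan <- scan_qtl(pheno, genotypes, dosages = dosages)
    thr <- permutation_thresholds(pheno, genotypes, n_perm = config$n_perm,
                                  seed = derive_seed(seed, "permutation"),
                                  dosages = dosages)
    peaks <- find_peaks(scan, thr)
    log_msg("stage scan [%s]: max LRS %.2f, %d peak(s) at suggestive or better",
            m, max(scan$table$lrs), nrow(peaks))
    list(strains = strains, heritability = h2, scan = scan,
         thresholds = thr, peaks = peaks)
  })
  names(per_method) <- methods

  # effective modulus per eye, for strains with a thickness (CCT) value;
  # strains lacking one drop out of this analysis only
  modulus <- NULL
  if (!is.null(config$cct_file)) {
    cct <- utils::read.csv(config$cct_file, stringsAsFactors = FALSE)
    if (!all(c("strain", "thickness_mm") %in% names(cct))) {
      stop("CCT file needs columns strain, thickness_mm", call. = FALSE)
    }
    withcct <- merge(records[records$kept, , drop = FALSE], cct,
                     by = "strain")
    log_msg("stage modulus: %d eyes across %d strains with CCT",
            nrow(withcct), length(unique(withcct$strain)))
    modulus <- cbind(
      withcct[, c("eye_id", "strain", "method")],
      effective_modulus(withcct$phi_r, withcct$volume_ul * 1000,
                        withcct$thickness_mm, config$p_ref)
    )
  }

  comparison <- NULL
  if (all(c("VF", "SR") %in% methods)) {
    wide <- merge(
      records[records$method == "VF", c("eye_id", "phi_norm")],
      records[records$method == "SR", c("eye_id", "phi_norm")],
      by = "eye_id", suffixes = c("_vf", "_sr")
    )
    comparison <- compare_methods(wide$phi_norm_vf, wide$phi_norm_sr)
    log_msg("stage compare: Bland-Altman bias %.4g (n = %d)",
            comparison$bias, comparison$n)
  }

  summary <- list(
    package_version = as.character(utils::packageVersion("ocuqtl")),
    seed = seed, simulated = simulated,
    n_eyes_in = n_eyes_in, qc = report,
    n_strains = lapply(per_method, function(x) nrow(x$strains)),
    heritability = lapply(per_method, function(x) x$heritability$h2),
    config = unclass(config)
  )
  result <- structure(list(records = records, qc_report = report,
                           per_method = per_method, comparison = comparison,
                           modulus = modulus,
                           genotypes = genotypes, truth = truth,
                           summary = summary, config = config),
                      class = "ocuqtl_run")
  if (!is.null(out_dir)) write_run_outputs(result, out_dir)
  result
}

write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    utils::write.csv(as.data.frame(x), file.path(out_dir, name),
                     row.names = FALSE, quote = FALSE)
  }
  w(result$records, "eye_records.csv")
  w(result$qc_report, "qc_report.csv")
  for (m in names(result$per_method)) {
    pm <- result$per_method[[m]]
    w(pm$strains, sprintf("strain_phenotypes_%s.csv", m))
    w(pm$scan$table, sprintf("scan_%s.csv", m))
    w(pm$peaks, sprintf("peaks_%s.csv", m))
    w(data.frame(n_perm = pm$thresholds$n_perm,
                 significant = pm$thresholds$significant,
                 suggestive = pm$thresholds$suggestive),
      sprintf("thresholds_%s.csv", m))
  }
  h2 <- do.call(rbind, lapply(names(result$per_method), function(m) {
    h <- result$per_method[[m]]$heritability
    data.frame(method = m, vg = h$vg, ve = h$ve, h2 = h$h2)
  }))
  w(h2, "heritability.csv")
  if (!is.null(result$modulus)) w(result$modulus, "modulus.csv")
  if (!is.null(result$comparison)) {
    cmp <- result$comparison
    w(data.frame(n = cmp$n, bias = cmp$bias, sd = cmp$sd,
                 loa_lower = cmp$loa[1L], loa_upper = cmp$loa[2L],
                 trend_slope = cmp$trend_slope), "bland_altman.csv")
  }
  jsonlite::write_json(result$summary,
                       file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.ocuqtl_run <- function(x, ...) {
  cat("ocuqtl pipeline run\n")
  print(x$qc_report)
  for (m in names(x$per_method)) {
    pm <- x$per_method[[m]]
    cat(sprintf("[%s] %d strains, H2 = %.3f, max LRS %.2f (suggestive %.2f, significant %.2f), %d peak(s)\n",
                m, nrow(pm$strains), pm$heritability$h2,
                max(pm$scan$table$lrs), pm$thresholds$suggestive,
                pm$thresholds$significant, nrow(pm$peaks)))
  }
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
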