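# File formats: perfusion trace CSV, eye metadata table, GeneNetwork-style
# genotype text, and the YAML run configuration.

TRACE_COLS <- c("time_s", "p_applied_mmHg", "p_measured_mmHg", "q_nl_s")

#' Read a perfusion trace file
#'
#' Comma-delimited with header `time_s,p_applied_mmHg,p_measured_mmHg,q_nl_s`;
#' unknown columns are preserved.
#'
#' @param path file path
#' @param meta optional metadata list to attach
#' @return a `perfusion_trace` data frame
#' @export
read_trace <- function(path, meta = NULL) {
  x <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(TRACE_COLS, names(x))
  if (length(missing)) {
    stop(sprintf("trace file %s is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (is.unsorted(x$time_s, strictly = TRUE)) {
    stop(sprintf("trace file %s has non-monotone time", path), call. = FALSE)
  }
  if (!is.null(meta)) attr(x, "meta") <- meta
  class(x) <- c("perfusion_trace", "data.frame")
  x
}

#' Write a perfusion trace file
#'
#' Ground-truth annotations on simulated traces are attributes only and are
#' never written.
#'
#' @param trace a `perfusion_trace`
#' @param path output path
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write the eye metadata table
#'
#' Columns `eye_id,strain,eye,mass_mg` (plus optional `animal_id` and any
#' extra annotation columns, preserved).
#'
#' @param path file path
#' @return data frame
#' @export
read_eye_metadata <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("eye_id", "strain", "eye", "mass_mg")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop(sprintf("metadata file missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (is.null(x$animal_id)) x$animal_id <- sub("_(OD|OS)$", "", x$eye_id)
  x
}

#' @rdname read_eye_metadata
#' @param metadata data frame to write
#' @export
write_eye_metadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GeneNetwork-style genotype file
#'
#' Tab-delimited with columns `Chr,Locus,cM,Mb` followed by one column per
#' strain, calls coded B/D/H/U (H and U become missing). Rows are sorted
#' within chromosome by cM. Lines starting with `#` or `@` are ignored.
#'
#' @param path file path
#' @return a `genotype_matrix`
#' @export
read_genotypes <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  x <- x[!startsWith(as.character(x[[1L]]), "@"), , drop = FALSE]
  need <- c("Chr", "Locus", "cM", "Mb")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop(sprintf("genotype file missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(x$Locus)) {
    stop("duplicate locus names in genotype file", call. = FALSE)
  }
  x$cM <- suppressWarnings(as.numeric(x$cM))
  x$Mb <- suppressWarnings(as.numeric(x$Mb))
  if (any(!is.finite(x$cM)) || any(!is.finite(x$Mb))) {
    stop("unsortable (non-numeric) map positions in genotype file",
         call. = FALSE)
  }
  x <- x[order(match(x$Chr, unique(x$Chr)), x$cM, x$Mb), , drop = FALSE]
  strains <- setdiff(names(x), need)
  if (length(strains) == 0L) stop("no strain columns found", call. = FALSE)
  codes <- as.matrix(x[, strains, drop = FALSE])
  bad <- !codes %in% c("B", "D", "H", "U", NA)
  if (any(bad)) {
    stop(sprintf("unrecognised genotype code(s): %s",
                 paste(unique(codes[bad]), collapse = ", ")), call. = FALSE)
  }
  calls <- matrix(NA_integer_, length(strains), nrow(x),
                  dimnames = list(strains, x$Locus))
  calls[t(codes == "B")] <- 0L
  calls[t(codes == "D")] <- 1L
  map <- data.frame(marker = x$Locus, chr = as.character(x$Chr),
                    cM = x$cM, Mb = x$Mb, stringsAsFactors = FALSE)
  validate_marker_map(map)
  g <- new_genotype_matrix(calls, map, strains)
  attr(g, "n_heterozygous_or_unknown") <- sum(codes %in% c("H", "U"))
  g
}

#' Write a genotype matrix in GeneNetwork style
#'
#' @param genotypes a `genotype_matrix`
#' @param path output path
#' @export
write_genotypes <- function(genotypes, path) {
  codes <- t(genotypes$calls)
  txt <- matrix("U", nrow(codes), ncol(codes), dimnames = dimnames(codes))
  txt[!is.na(codes) & codes == 0L] <- "B"
  txt[!is.na(codes) & codes == 1L] <- "D"
  out <- cbind(
    data.frame(Chr = genotypes$map$chr, Locus = genotypes$map$marker,
               cM = genotypes$map$cM, Mb = genotypes$map$Mb,
               stringsAsFactors = FALSE),
    as.data.frame(txt, stringsAsFactors = FALSE)
  )
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Defaults follow the published analysis constants: reference pressure
#' 13 mmHg, eye density 1.103 mg/ul, 15th-percentile uncertainty filter,
#' 1.5-IQR outlier rule, suggestive/significant permutation thresholds.
#'
#' @param ... overrides of the default fields (see the returned list)
#' @return a `run_config` list
#' @export
run_config <- function(...) {
  cfg <- list(
    method = "both", p_ref = 13, density = 1.103,
    qc_percentile = 15, iqr_k = 1.5,
    needle_resistance = 0.5,
    n_perm = 2000, step_cM = 1, seed = 1L,
    # simulation block (used when no input files are given)
    sim = list(
      n_strains = 20, n_eyes_per_strain = 8, base_phi_norm = 2.35,
      variance_explained = 0.37, qtl_chr = "11", qtl_cM = 35,
      strain_env_sd = 0.21, eye_env_sd = 0.21,
      creep_compliance = 0, creep_tau = 60
    ),
    protocol = list(), map = list(),
    trace_dir = NULL, metadata_file = NULL, genotype_file = NULL,
    cct_file = NULL, out_dir = NULL
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% c("sim", "protocol", "map") && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  if (!cfg$method %in% c("VF", "SR", "both")) {
    stop("method must be one of VF, SR, both", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Read a YAML run configuration file
#'
#' @param path YAML file; keys mirror [run_config()] fields
#' @return a `run_config`
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}
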