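# Ground-truth trait architecture for the RI panel: one additive QTL plus
# strain-level and eye-level environmental noise, on the normalized-compliance
# scale (nl/mmHg/ul).

#' Trait architecture for simulation
#'
#' @param qtl_chr chromosome carrying the planted QTL (NULL for no QTL)
#' @param qtl_cM position of the QTL in cM
#' @param variance_explained fraction of strain-mean variance attributable to
#'   the QTL, in [0, 1)
#' @param strain_env_sd SD of non-genetic strain-level deviations (trait units)
#' @param eye_env_sd SD of eye-level deviations within a strain (trait units)
#' @param increasing_allele which parental allele increases the trait
#' @return a `trait_architecture` list
#' @export
trait_architecture <- function(qtl_chr = "11", qtl_cM = 35,
                               variance_explained = 0.37,
                               strain_env_sd = 0.21, eye_env_sd = 0.21,
                               increasing_allele = c("D", "B")) {
  increasing_allele <- match.arg(increasing_allele)
  if (variance_explained < 0 || variance_explained >= 1) {
    stop("variance_explained must lie in [0, 1)", call. = FALSE)
  }
  if (strain_env_sd < 0 || eye_env_sd < 0) stop("SDs must be >= 0", call. = FALSE)
  structure(list(qtl_chr = qtl_chr, qtl_cM = qtl_cM,
                 variance_explained = variance_explained,
                 strain_env_sd = strain_env_sd, eye_env_sd = eye_env_sd,
                 increasing_allele = increasing_allele),
            class = "trait_architecture")
}

#' Simulate per-eye true normalized compliance for an RI panel
#'
#' Strain genetic value = base + a * (QTL dosage - 0.5) + strain-level noise,
#' with the allelic effect `a` chosen so the QTL contributes the requested
#' fraction of strain-mean variance given the realized dosage variance and
#' `strain_env_sd`. Eye values add independent eye-level noise. The realized
#' variance fraction is reported alongside the table.
#'
#' @param genotypes a `genotype_matrix`
#' @param arch a [trait_architecture()]
#' @param n_eyes_per_strain eyes simulated per strain (2 per animal)
#' @param base_phi_norm panel-mean normalized compliance (nl/mmHg/ul)
#' @param seed integer seed
#' @return list: `eyes` (per-eye table with true values and pair structure),
#'   `strain_values` (named genetic values), `qtl_dosage`, `allelic_effect`,
#'   `realized_fraction`
#' @export
sim_trait <- function(genotypes, arch, n_eyes_per_strain = 8,
                      base_phi_norm = 2.35, seed = 1L) {
  map <- genotypes$map
  strains <- genotypes$strains
  f <- arch$variance_explained
  if (!is.null(arch$qtl_chr) && f > 0) {
    m <- map[map$chr == arch$qtl_chr, , drop = FALSE]
    if (nrow(m) == 0 || arch$qtl_cM < min(m$cM) || arch$qtl_cM > max(m$cM)) {
      stop("QTL position lies outside the map extent", call. = FALSE)
    }
    grid <- data.frame(chr = arch$qtl_chr, cM = arch$qtl_cM,
                       Mb = NA_real_, marker = NA_character_,
                       stringsAsFactors = FALSE)
    dos <- impute_dosage(genotypes, grid = grid)$dosage[, 1L]
  } else {
    dos <- rep(0.5, length(strains))
    names(dos) <- strains
  }
  vd <- stats::var(dos)
  if (f > 0 && arch$strain_env_sd <= 0) {
    stop("variance_explained > 0 requires strain_env_sd > 0", call. = FALSE)
  }
  if (f > 0 && vd <= 0) {
    stop("QTL is monomorphic in this panel; cannot impose an effect",
         call. = FALSE)
  }
  a <- if (f > 0) arch$strain_env_sd * sqrt(f / ((1 - f) * vd)) else 0
  if (arch$increasing_allele == "B") a <- -a
  set.seed(derive_seed(seed, "trait"))
  g_env <- stats::rnorm(length(strains), 0, arch$strain_env_sd)
  strain_values <- base_phi_norm + a * (dos - 0.5) + g_env
  names(strain_values) <- strains
  qtl_part <- a * (dos - 0.5)
  realized <- if (stats::var(strain_values) > 0)
    stats::var(qtl_part) / stats::var(strain_values) else 0
  eyes <- do.call(rbind, lapply(seq_along(strains), function(i) {
    k <- seq_len(n_eyes_per_strain)
    animal <- sprintf("%s_a%02d", strains[i], ceiling(k / 2))
    lat <- ifelse(k %% 2 == 1L, "OD", "OS")
    data.frame(
      eye_id = paste0(animal, "_", lat),
      animal_id = animal,
      strain = strains[i],
      eye = lat,
      phi_norm_true = strain_values[i] +
        stats::rnorm(n_eyes_per_strain, 0, arch$eye_env_sd),
      stringsAsFactors = FALSE
    )
  }))
  rownames(eyes) <- NULL
  list(eyes = eyes, strain_values = strain_values, qtl_dosage = dos,
       allelic_effect = a, realized_fraction = realized)
}
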