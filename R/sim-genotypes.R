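# Synthetic recombinant inbred (RI) genotypes on a marker map.
#
# The panel emulates BXD-style lines: every strain is a fixed homozygous
# mosaic of the two parental genomes (B = C57BL/6J-like, D = DBA/2J-like).
# Along a chromosome the genotype sequence is a two-state Markov chain whose
# adjacent-marker switching probability is the RI-expanded recombination
# fraction R = 4r/(1+6r) appropriate for sib-mated lines, with r obtained
# from the Haldane map function of the cM gap.

#' Haldane map function: map distance (cM) to recombination fraction
#'
#' @param d_cM genetic distance in centimorgans (vectorised, >= 0)
#' @return recombination fraction in [0, 0.5)
#' @export
haldane_r <- function(d_cM) {
  if (any(d_cM < 0)) stop("map distances must be non-negative", call. = FALSE)
  0.5 * (1 - exp(-2 * d_cM / 100))
}

#' RI expansion of a recombination fraction for sib-mated lines
#'
#' @param r single-meiosis recombination fraction
#' @return expected discordance fraction R = 4r/(1+6r) between adjacent
#'   markers across a sib-mated RI panel
#' @export
ri_expand <- function(r) {
  if (any(r < 0 | r > 0.5)) stop("r must lie in [0, 0.5]", call. = FALSE)
  4 * r / (1 + 6 * r)
}

#' Build a regular marker map
#'
#' Convenience scaffold for simulations: equally spaced markers per
#' chromosome with a linear cM-to-Mb relation (2 Mb per cM by default,
#' a mouse-like average).
#'
#' @param n_chr number of chromosomes
#' @param length_cM chromosome length in cM (recycled)
#' @param spacing_cM marker spacing in cM
#' @param mb_per_cM physical-to-genetic scale used to fill Mb positions
#' @return data frame with columns `marker`, `chr`, `cM`, `Mb`
#' @export
sim_marker_map <- function(n_chr = 19, length_cM = 75, spacing_cM = 2.5,
                           mb_per_cM = 2) {
  length_cM <- rep_len(length_cM, n_chr)
  maps <- lapply(seq_len(n_chr), function(ch) {
    pos <- seq(0, length_cM[ch], by = spacing_cM)
    data.frame(
      marker = sprintf("c%02d.m%03d", ch, seq_along(pos)),
      chr = as.character(ch),
      cM = pos,
      Mb = 3 + pos * mb_per_cM,
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  validate_marker_map(map)
  map
}

validate_marker_map <- function(map) {
  need <- c("marker", "chr", "cM", "Mb")
  if (!all(need %in% names(map))) {
    stop("marker map needs columns marker, chr, cM, Mb", call. = FALSE)
  }
  if (anyDuplicated(map$marker)) stop("duplicate marker names", call. = FALSE)
  for (ch in unique(map$chr)) {
    i <- map$chr == ch
    if (is.unsorted(map$cM[i]) || is.unsorted(map$Mb[i])) {
      stop(sprintf("non-monotone map positions on chromosome %s", ch),
           call. = FALSE)
    }
  }
  invisible(map)
}

#' Simulate RI-panel genotypes
#'
#' @param map marker map (see [sim_marker_map()])
#' @param n_strains number of RI strains (>= 2)
#' @param seed integer seed
#' @return a `genotype_matrix`: list with `calls` (strain x marker integer
#'   matrix, 0 = B, 1 = D, NA = missing), `map`, and `strains`
#' @export
sim_ri_genotypes <- function(map, n_strains, seed = 1L) {
  validate_marker_map(map)
  if (n_strains < 2) stop("need at least 2 strains", call. = FALSE)
  if (nrow(map) == 0) stop("empty marker map", call. = FALSE)
  set.seed(seed)
  strains <- sprintf("RIX%03d", seq_len(n_strains))
  calls <- matrix(NA_integer_, n_strains, nrow(map),
                  dimnames = list(strains, map$marker))
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    gaps <- diff(map$cM[idx])
    R <- ri_expand(haldane_r(gaps))
    for (s in seq_len(n_strains)) {
      g <- integer(length(idx))
      g[1] <- stats::rbinom(1L, 1L, 0.5)
      if (length(idx) > 1L) {
        flip <- stats::rbinom(length(R), 1L, R)
        for (j in seq_along(R)) g[j + 1L] <- if (flip[j]) 1L - g[j] else g[j]
      }
      calls[s, idx] <- g
    }
  }
  new_genotype_matrix(calls, map, strains)
}

new_genotype_matrix <- function(calls, map, strains) {
  structure(list(calls = calls, map = map, strains = strains),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("RI genotype matrix: %d strains x %d markers on %d chromosomes\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chr))))
  nmiss <- sum(is.na(x$calls))
  if (nmiss > 0) cat(sprintf("  missing calls: %d\n", nmiss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)
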