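# Haley-Knott interval mapping on an RI panel: expected-dosage imputation on
# a cM grid, single-QTL regression scan, permutation thresholds, and peak
# calling with candidate windows.

# Transition probability of the RI chain between two loci separated by d cM:
# P(genotype differs) = 4r/(1+6r) with Haldane r(d).
ri_switch_prob <- function(d_cM) ri_expand(haldane_r(d_cM))

#' Evaluation grid for interval mapping
#'
#' Union of the typed marker positions and a regular pseudomarker grid.
#' Physical positions (Mb) at pseudomarkers are interpolated piecewise
#' linearly through the marker map.
#'
#' @param map marker map
#' @param step_cM pseudomarker spacing in cM
#' @return data frame `chr`, `cM`, `Mb`, `marker` (NA at pseudomarkers)
#' @export
scan_grid <- function(map, step_cM = 1) {
  validate_marker_map(map)
  out <- lapply(unique(map$chr), function(ch) {
    m <- map[map$chr == ch, , drop = FALSE]
    grid <- unique(c(seq(min(m$cM), max(m$cM), by = step_cM), m$cM))
    grid <- sort(grid)
    mk <- m$marker[match(grid, m$cM)]
    if (nrow(m) >= 2) {
      mb <- stats::approx(m$cM, m$Mb, xout = grid, rule = 2, ties = "ordered")$y
    } else {
      mb <- rep(m$Mb, length(grid))
    }
    data.frame(chr = ch, cM = grid, Mb = mb, marker = mk,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Expected D-allele dosage at grid positions
#'
#' At a typed marker the dosage equals the call (0 for B, 1 for D). Between
#' markers the dosage is the conditional probability of the D allele given
#' the nearest typed flanking markers, under the two-state RI Markov chain
#' with per-interval switching probability 4r/(1+6r) (Haldane r from the cM
#' gap). A strain with no typed markers on a chromosome gets dosage 0.5
#' everywhere there, with a warning.
#'
#' @param genotypes a `genotype_matrix`
#' @param grid evaluation grid from [scan_grid()]; defaults to a 1 cM grid
#' @param step_cM pseudomarker spacing used when `grid` is NULL
#' @return list with `dosage` (strain x position matrix in [0,1]) and `grid`
#' @export
impute_dosage <- function(genotypes, grid = NULL, step_cM = 1) {
  map <- genotypes$map
  if (is.null(grid)) grid <- scan_grid(map, step_cM)
  calls <- genotypes$calls
  n <- nrow(calls)
  dosage <- matrix(NA_real_, n, nrow(grid),
                   dimnames = list(rownames(calls), NULL))
  for (ch in unique(grid$chr)) {
    gi <- which(grid$chr == ch)
    mi <- which(map$chr == ch)
    mpos <- map$cM[mi]
    for (s in seq_len(n)) {
      g <- calls[s, mi]
      typed <- which(!is.na(g))
      if (length(typed) == 0L) {
        warning(sprintf("strain %s has no typed markers on chromosome %s; dosage 0.5",
                        rownames(calls)[s], ch), call. = FALSE)
        dosage[s, gi] <- 0.5
        next
      }
      tp <- mpos[typed]
      tg <- g[typed]
      for (k in seq_along(gi)) {
        p <- grid$cM[gi[k]]
        li <- findInterval(p, tp)              # index of left typed flank
        if (li >= 1L && tp[li] == p) {         # exactly at a typed marker
          dosage[s, gi[k]] <- tg[li]
        } else if (li == 0L) {                 # before first typed marker
          R <- ri_switch_prob(tp[1L] - p)
          dosage[s, gi[k]] <- if (tg[1L] == 1L) 1 - R else R
        } else if (li == length(tp)) {         # past last typed marker
          R <- ri_switch_prob(p - tp[li])
          dosage[s, gi[k]] <- if (tg[li] == 1L) 1 - R else R
        } else {                               # interior: condition on flanks
          RL <- ri_switch_prob(p - tp[li])
          RR <- ri_switch_prob(tp[li + 1L] - p)
          tl <- function(a, b, R) if (a == b) 1 - R else R
          numD <- tl(tg[li], 1L, RL) * tl(1L, tg[li + 1L], RR)
          numB <- tl(tg[li], 0L, RL) * tl(0L, tg[li + 1L], RR)
          dosage[s, gi[k]] <- numD / (numD + numB)
        }
      }
    }
  }
  list(dosage = dosage, grid = grid)
}

#' Genome scan by Haley-Knott regression
#'
#' Regresses strain-mean phenotypes on expected D-allele dosage at each grid
#' position. The linkage statistic is LRS = n * ln(RSS0/RSS1) where RSS0 is
#' the residual sum of squares of the mean-only model; LOD = LRS/(2 ln 10).
#' The additive effect is the regression slope (trait change for a full B->D
#' substitution; sign positive when the D allele increases the trait), with
#' the half-difference between predicted parental values alongside.
#'
#' @param phenotype named numeric vector of strain means (names = strains)
#' @param genotypes a `genotype_matrix`
#' @param step_cM pseudomarker spacing (ignored when `dosages` supplied)
#' @param dosages optional precomputed result of [impute_dosage()]
#' @return object of class `qtl_scan`: the per-position scan table plus
#'   metadata; see `print`, `summary`, `plot` methods
#' @export
scan_qtl <- function(phenotype, genotypes, step_cM = 1, dosages = NULL) {
  if (is.null(names(phenotype))) stop("phenotype must be named by strain",
                                      call. = FALSE)
  if (is.null(dosages)) dosages <- impute_dosage(genotypes, step_cM = step_cM)
  common <- intersect(names(phenotype), rownames(dosages$dosage))
  if (length(common) < 3) stop("need >= 3 strains shared between phenotype and genotypes",
                               call. = FALSE)
  D <- dosages$dosage[common, , drop = FALSE]
  y <- phenotype[common]
  st <- hk_stats(y, D)
  tab <- data.frame(
    chr = dosages$grid$chr,
    cM = dosages$grid$cM,
    Mb = dosages$grid$Mb,
    marker = dosages$grid$marker,
    lrs = st$lrs,
    lod = st$lrs / (2 * log(10)),
    additive_effect = st$slope,
    half_effect = st$slope / 2,
    variance_explained = st$ve,
    monomorphic = st$mono,
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, n = length(y), strains = common,
                 phenotype = y, grid = dosages$grid),
            class = "qtl_scan")
}

# Core regression statistics, vectorised over positions. y: length-n vector,
# D: n x P dosage matrix. Returns lrs, slope, variance explained, and a
# monomorphic flag (zero dosage variance -> LRS recorded as 0).
hk_stats <- function(y, D) {
  n <- length(y)
  yc <- y - mean(y)
  rss0 <- sum(yc^2)
  Dc <- sweep(D, 2L, colMeans(D))
  sxx <- colSums(Dc^2)
  sxy <- as.numeric(crossprod(Dc, yc))
  mono <- sxx < .Machine$double.eps * n
  slope <- ifelse(mono, NA_real_, sxy / sxx)
  rss1 <- pmax(rss0 - ifelse(mono, 0, sxy^2 / sxx), .Machine$double.xmin)
  lrs <- ifelse(mono, 0, n * log(rss0 / rss1))
  list(lrs = lrs, slope = slope, ve = ifelse(mono, 0, 1 - rss1 / rss0),
       mono = mono)
}

#' Permutation thresholds for genome-wide significance
#'
#' Shuffles the strain means across strains, rescans, and records the
#' genome-wide maximum LRS per permutation. Thresholds are the empirical
#' quantiles of that sample at genome-wide p = 0.05 ("significant") and
#' p = 0.63 ("suggestive").
#'
#' @param phenotype named strain means
#' @param genotypes a `genotype_matrix`
#' @param n_perm number of permutations (>= 100)
#' @param seed integer seed
#' @param step_cM pseudomarker spacing (ignored when `dosages` supplied)
#' @param dosages optional precomputed [impute_dosage()] result
#' @return object of class `perm_thresholds` with the max-LRS sample
#' @export
permutation_thresholds <- function(phenotype, genotypes, n_perm = 2000,
                                   seed = 1L, step_cM = 1, dosages = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  if (is.null(dosages)) dosages <- impute_dosage(genotypes, step_cM = step_cM)
  common <- intersect(names(phenotype), rownames(dosages$dosage))
  D <- dosages$dosage[common, , drop = FALSE]
  y <- phenotype[common]
  n <- length(y)
  set.seed(seed)
  Y <- t(vapply(seq_len(n_perm), function(i) sample(y), numeric(n)))
  Yc <- Y - rowMeans(Y)
  rss0 <- sum((y - mean(y))^2)
  Dc <- sweep(D, 2L, colMeans(D))
  sxx <- colSums(Dc^2)
  keep <- sxx > .Machine$double.eps * n
  SXY <- Yc %*% Dc[, keep, drop = FALSE]
  RSS1 <- pmax(rss0 - sweep(SXY^2, 2L, sxx[keep], "/"), .Machine$double.xmin)
  maxlrs <- apply(n * log(rss0 / RSS1), 1L, max)
  structure(list(
    n_perm = n_perm, seed = seed, max_lrs = maxlrs,
    significant = quantile_li(maxlrs, 0.95),
    suggestive = quantile_li(maxlrs, 1 - 0.63)
  ), class = "perm_thresholds")
}

#' @export
print.perm_thresholds <- function(x, ...) {
  cat(sprintf("Permutation thresholds (%d permutations):\n", x$n_perm))
  cat(sprintf("  significant (p < 0.05): LRS %.2f\n", x$significant))
  cat(sprintf("  suggestive  (p < 0.63): LRS %.2f\n", x$suggestive))
  invisible(x)
}

#' Call QTL peaks and candidate windows
#'
#' Local maxima of the LRS profile above the suggestive threshold. Each peak
#' is bounded by the nearest flanking typed markers beyond the positions
#' where the profile has dropped by `drop_lod` LOD-equivalents from the
#' peak; the candidate window extends those marker bounds by +-1 Mb,
#' reflecting the mapping precision of an RI panel.
#'
#' @param scan a `qtl_scan`
#' @param thresholds a `perm_thresholds`
#' @param map marker map used for the typed-marker bounds
#' @param drop_lod support-interval drop criterion in LOD units
#' @param window_Mb candidate-window expansion beyond the marker bounds
#' @return data frame of peaks (empty if nothing reaches suggestive)
#' @export
find_peaks <- function(scan, thresholds, map = NULL, drop_lod = 1.5,
                       window_Mb = 1) {
  tab <- scan$table
  drop_lrs <- drop_lod * 2 * log(10)
  peaks <- list()
  for (ch in unique(tab$chr)) {
    d <- tab[tab$chr == ch, , drop = FALSE]
    active <- d$lrs >= thresholds$suggestive
    while (any(active)) {
      pk <- which(active)[which.max(d$lrs[which(active)])]
      lim <- d$lrs[pk] - drop_lrs
      lo <- pk
      while (lo > 1L && d$lrs[lo] > lim) lo <- lo - 1L
      hi <- pk
      while (hi < nrow(d) && d$lrs[hi] > lim) hi <- hi + 1L
      # nearest typed markers at or beyond the support edges
      typed <- which(!is.na(d$marker))
      ml <- typed[typed <= lo]
      mh <- typed[typed >= hi]
      ml <- if (length(ml)) max(ml) else if (length(typed)) min(typed) else lo
      mh <- if (length(mh)) min(mh) else if (length(typed)) max(typed) else hi
      peaks[[length(peaks) + 1L]] <- data.frame(
        chr = ch,
        peak_cM = d$cM[pk],
        peak_Mb = d$Mb[pk],
        peak_lrs = d$lrs[pk],
        peak_lod = d$lod[pk],
        variance_explained = d$variance_explained[pk],
        additive_effect = d$additive_effect[pk],
        marker_lo = d$marker[ml],
        marker_hi = d$marker[mh],
        bound_lo_Mb = d$Mb[ml],
        bound_hi_Mb = d$Mb[mh],
        window_lo_Mb = d$Mb[ml] - window_Mb,
        window_hi_Mb = d$Mb[mh] + window_Mb,
        classification = if (d$lrs[pk] >= thresholds$significant)
          "significant" else "suggestive",
        stringsAsFactors = FALSE
      )
      active[lo:hi] <- FALSE
    }
  }
  if (length(peaks) == 0L) {
    return(data.frame(
      chr = character(), peak_cM = numeric(), peak_Mb = numeric(),
      peak_lrs = numeric(), peak_lod = numeric(),
      variance_explained = numeric(), additive_effect = numeric(),
      marker_lo = character(), marker_hi = character(),
      bound_lo_Mb = numeric(), bound_hi_Mb = numeric(),
      window_lo_Mb = numeric(), window_hi_Mb = numeric(),
      classification = character(), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, peaks)
  out[order(-out$peak_lrs), , drop = FALSE]
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat(sprintf("Haley-Knott genome scan: %d strains, %d positions on %d chromosomes\n",
              x$n, nrow(x$table), length(unique(x$table$chr))))
  top <- x$table[which.max(x$table$lrs), ]
  cat(sprintf("  max LRS %.2f (LOD %.2f) at chr %s, %.1f cM (%.2f Mb)\n",
              top$lrs, top$lod, top$chr, top$cM, top$Mb))
  invisible(x)
}

#' @export
summary.qtl_scan <- function(object, ...) {
  tab <- object$table
  by_chr <- do.call(rbind, lapply(split(tab, tab$chr), function(d) {
    d[which.max(d$lrs), c("chr", "cM", "Mb", "lrs", "lod",
                          "additive_effect", "variance_explained")]
  }))
  by_chr <- by_chr[order(-by_chr$lrs), ]
  rownames(by_chr) <- NULL
  structure(list(n = object$n, by_chr = by_chr), class = "summary.qtl_scan")
}

#' @export
print.summary.qtl_scan <- function(x, ...) {
  cat(sprintf("Per-chromosome LRS maxima (%d strains):\n", x$n))
  print(x$by_chr, digits = 4)
  invisible(x)
}

#' @export
plot.qtl_scan <- function(x, thresholds = NULL, ...) {
  tab <- x$table
  chrs <- unique(tab$chr)
  off <- 0
  xs <- numeric(nrow(tab))
  mids <- numeric(length(chrs))
  for (i in seq_along(chrs)) {
    sel <- tab$chr == chrs[i]
    xs[sel] <- tab$cM[sel] - min(tab$cM[sel]) + off
    mids[i] <- off + (max(tab$cM[sel]) - min(tab$cM[sel])) / 2
    off <- max(xs[sel]) + 5
  }
  graphics::plot(xs, tab$lrs, type = "n", xaxt = "n",
                 xlab = "chromosome", ylab = "LRS", ...)
  for (ch in chrs) {
    sel <- tab$chr == ch
    graphics::lines(xs[sel], tab$lrs[sel], col = "steelblue")
  }
  graphics::axis(1, at = mids, labels = chrs)
  if (!is.null(thresholds)) {
    graphics::abline(h = thresholds$significant, col = "deeppink", lty = 2)
    graphics::abline(h = thresholds$suggestive, col = "grey50", lty = 2)
  }
  invisible(x)
}
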