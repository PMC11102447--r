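#' Genome-wide scan of one trait against all markers
#'
#' Simple linear regression of the trait on the allele code at each marker
#' (`trait ~ locus`), with a two-sided t-test on the slope. Monomorphic
#' markers get p = 1. Missing trait values are dropped. p-values are
#' floored at 1e-300 before the -log10 transform.
#'
#' @param trait named numeric vector (names = segregant ids).
#' @param genotypes 0/1 segregant x marker matrix.
#' @param map marker map matching the genotype columns.
#' @param trait_id label stored with the scan.
#' @return object of class `linkage_scan`: data.frame with `marker`,
#'   `chrom`, `pos`, `neglog10p`, `slope`, `r2`.
#' @export
scan_trait <- function(trait, genotypes, map, trait_id = "trait") {
  trait <- trait[!is.na(trait)]
  if (length(trait) == 0) stop("all trait values missing")
  ids <- intersect(names(trait), rownames(genotypes))
  y <- trait[ids]
  G <- genotypes[ids, map$marker, drop = FALSE]
  n <- length(y)
  sc <- .scan_core(y, G)
  p <- sc$p; slope <- sc$slope; r2 <- sc$r2
  structure(data.frame(marker = map$marker, chrom = map$chrom,
                       pos = map$pos, neglog10p = -log10(p),
                       slope = slope, r2 = r2, stringsAsFactors = FALSE),
            trait_id = trait_id, n = n,
            class = c("linkage_scan", "data.frame"))
}

.scan_core <- function(y, G) {
  n <- length(y)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  sx <- colSums(G)
  sxx <- sx - sx^2 / n                 # centred sum of squares (0/1 codes)
  sxy <- as.numeric(crossprod(G, yc))
  mono <- sxx <= 0
  slope <- ifelse(mono, NA_real_, sxy / sxx)
  r2 <- ifelse(mono | syy == 0, 0, sxy^2 / (sxx * syy))
  r2 <- pmin(r2, 1)
  tt <- sqrt(pmax(r2, 0) * (n - 2) / pmax(1 - r2, 1e-300))
  p <- ifelse(mono, 1, 2 * stats::pt(-abs(tt), df = n - 2))
  list(p = pmax(p, 1e-300), slope = slope, r2 = r2)
}

#' Permutation-based genome-wide significance threshold
#'
#' Each permutation picks a random trait from the deviation matrix,
#' shuffles its values across segregants (genotype rows intact, preserving
#' LD), scans the genome, and records the minimum p-value. The cutoff is
#' the 5th percentile of the permuted minima, reported as -log10 p.
#'
#' @param deviations segregant x trait matrix (NAs allowed).
#' @param genotypes,map as in [scan_trait()].
#' @param n_perm number of permutations.
#' @param quantile_level percentile of the null minima used as the cutoff.
#' @param seed integer seed.
#' @return list of class `permutation_threshold` with `cutoff` (-log10 p),
#'   `min_p` (the permuted minima) and `n_perm`.
#' @export
permutation_threshold <- function(deviations, genotypes, map,
                                  n_perm = 1000, quantile_level = 0.05,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  deviations <- as.matrix(deviations)
  Gm <- genotypes[rownames(deviations), map$marker, drop = FALSE]
  min_p <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    j <- sample.int(ncol(deviations), 1)
    y <- deviations[, j]
    keep <- !is.na(y)
    y[keep] <- sample(y[keep])
    min_p[i] <- min(.scan_core(y[keep], Gm[keep, , drop = FALSE])$p)
  }
  cutoff <- -log10(stats::quantile(min_p, quantile_level, names = FALSE))
  structure(list(cutoff = cutoff, min_p = min_p, n_perm = n_perm),
            class = "permutation_threshold")
}

#' @export
print.permutation_threshold <- function(x, ...) {
  cat(sprintf(
    "Permutation threshold: -log10 p >= %.3f (%d permutations)\n",
    x$cutoff, x$n_perm))
  invisible(x)
}

.drop_interval <- function(scan, peak_idx, drop = 2) {
  chr <- scan$chrom[peak_idx]
  lim <- scan$neglog10p[peak_idx] - drop
  i <- peak_idx
  while (i > 1 && scan$chrom[i - 1] == chr && scan$neglog10p[i - 1] >= lim) {
    i <- i - 1
  }
  j <- peak_idx
  nr <- nrow(scan)
  while (j < nr && scan$chrom[j + 1] == chr && scan$neglog10p[j + 1] >= lim) {
    j <- j + 1
  }
  c(i, j)
}

#' Call peaks from a linkage scan
#'
#' Markers above the cutoff are selected greedily in decreasing
#' significance. Each accepted peak is reported with its 2-unit
#' -log10 p drop interval (the run of markers within 2 units of the peak);
#' candidates whose interval comes within `min_separation` of an accepted
#' interval on the same chromosome are suppressed. Peaks whose marker lies
#' within `cis_exclusion` of the trait guide's binding site are flagged
#' `cis_excluded` (binding-site artefacts rather than trans interactions).
#'
#' @param scan a `linkage_scan`.
#' @param cutoff -log10 p significance cutoff (> 0).
#' @param drop interval drop in -log10 p units.
#' @param min_separation minimum distance in bp between distinct peak
#'   intervals on one chromosome.
#' @param cis_exclusion distance in bp defining a cis peak.
#' @param guide_chrom,guide_pos binding site of the trait's guide (optional).
#' @param H2 optional broad-sense heritability of the trait; when given,
#'   `prop_H2 = r2 / H2` (capped at 1) is reported per peak.
#' @return data.frame of class `linkage_peaks` with one row per peak:
#'   `trait`, `marker`, `chrom`, `pos`, `neglog10p`, `start`, `end`,
#'   `effect` (slope, 3S - BY), `r2`, `prop_H2`, `cis_excluded`.
#' @export
call_peaks <- function(scan, cutoff, drop = 2, min_separation = 1e5,
                       cis_exclusion = 1e4, guide_chrom = NULL,
                       guide_pos = NULL, H2 = NULL) {
  stopifnot(cutoff > 0)
  trait <- attr(scan, "trait_id")
  empty <- data.frame(trait = character(0), marker = character(0),
                      chrom = character(0), pos = integer(0),
                      neglog10p = numeric(0), start = integer(0),
                      end = integer(0), effect = numeric(0), r2 = numeric(0),
                      prop_H2 = numeric(0), cis_excluded = logical(0),
                      stringsAsFactors = FALSE)
  cand <- which(scan$neglog10p >= cutoff)
  if (length(cand) == 0) {
    return(structure(empty, class = c("linkage_peaks", "data.frame")))
  }
  cand <- cand[order(-scan$neglog10p[cand])]
  acc <- list()
  for (k in cand) {
    iv <- .drop_interval(scan, k, drop)
    ok <- TRUE
    for (a in acc) {
      if (scan$chrom[k] != a$chrom) next
      gap <- max(scan$pos[iv[1]], a$start) - min(scan$pos[iv[2]], a$end)
      if (gap < min_separation) { ok <- FALSE; break }
    }
    if (!ok) next
    acc[[length(acc) + 1]] <- list(
      idx = k, chrom = scan$chrom[k], start = scan$pos[iv[1]],
      end = scan$pos[iv[2]])
  }
  rows <- lapply(acc, function(a) {
    k <- a$idx
    cis <- FALSE
    if (!is.null(guide_chrom) && !is.null(guide_pos)) {
      cis <- scan$chrom[k] == guide_chrom &&
        abs(scan$pos[k] - guide_pos) < cis_exclusion
    }
    prop <- NA_real_
    if (!is.null(H2) && !is.na(H2) && H2 > 0) {
      prop <- min(scan$r2[k] / H2, 1)
    }
    data.frame(trait = trait, marker = scan$marker[k], chrom = scan$chrom[k],
               pos = scan$pos[k], neglog10p = scan$neglog10p[k],
               start = a$start, end = a$end, effect = scan$slope[k],
               r2 = scan$r2[k], prop_H2 = prop, cis_excluded = cis,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  structure(out, class = c("linkage_peaks", "data.frame"))
}

#' Allele effect and variance explained at one marker
#'
#' @param trait named numeric trait vector.
#' @param genotypes genotype matrix.
#' @param marker marker id.
#' @param H2 optional broad-sense heritability for `prop_H2`.
#' @return list with `effect` (mean trait of 3S carriers minus BY
#'   carriers), `r2`, `prop_H2` (capped at 1, with `capped` flag).
#' @export
locus_effect <- function(trait, genotypes, marker, H2 = NULL) {
  trait <- trait[!is.na(trait)]
  x <- genotypes[names(trait), marker]
  if (length(unique(x)) < 2) stop("monomorphic marker ", marker)
  eff <- mean(trait[x == 1]) - mean(trait[x == 0])
  r2 <- stats::cor(trait, x)^2
  prop <- NA_real_; capped <- FALSE
  if (!is.null(H2) && !is.na(H2) && H2 > 0) {
    prop <- r2 / H2
    capped <- prop > 1
    prop <- min(prop, 1)
  }
  list(effect = eff, r2 = r2, prop_H2 = prop, capped = capped)
}

#' Map loci for every background-effect guide and for baseline fitness
#'
#' Runs [scan_trait()]/[call_peaks()] on each column of the deviation
#' matrix, using a shared permutation threshold, and the same machinery on
#' segregant mean control fitness (baseline fitness loci).
#'
#' @param effects a `guide_effects` object.
#' @param genotypes,map as in [scan_trait()].
#' @param guide_library guide library (for binding sites / cis exclusion).
#' @param threshold a `permutation_threshold` (computed if NULL).
#' @param H2 optional named vector of per-guide broad-sense heritability.
#' @param n_perm permutations when computing the threshold.
#' @param seed seed for the permutation threshold.
#' @return list of class `linkage_result`: `peaks` (all trait peaks,
#'   trans-only rows flagged), `threshold`, `scans` omitted for size.
#' @export
map_deviations <- function(effects, genotypes, map, guide_library = NULL,
                           threshold = NULL, H2 = NULL, n_perm = 1000,
                           seed = NULL) {
  D <- effects$deviations
  if (ncol(D) == 0) stop("no background-effect guides to map")
  if (is.null(threshold)) {
    threshold <- permutation_threshold(D, genotypes, map, n_perm = n_perm,
                                       seed = seed)
  }
  pk <- lapply(colnames(D), function(g) {
    y <- D[, g]; y <- y[!is.na(y)]
    sc <- scan_trait(y, genotypes, map, trait_id = g)
    gc <- gp <- NULL
    if (!is.null(guide_library)) {
      gi <- match(g, guide_library$guides$guide)
      if (!is.na(gi)) {
        gc <- guide_library$guides$chrom[gi]
        gp <- guide_library$guides$pos[gi]
      }
    }
    h2g <- if (!is.null(H2)) unname(H2[g]) else NULL
    call_peaks(sc, threshold$cutoff, guide_chrom = gc, guide_pos = gp,
               H2 = h2g)
  })
  peaks <- do.call(rbind, pk)
  structure(list(peaks = peaks, threshold = threshold),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  p <- x$peaks
  cat("Linkage mapping:", nrow(p), "peaks for",
      length(unique(p$trait)), "traits at -log10 p >=",
      round(x$threshold$cutoff, 3), "\n")
  cat("  cis-excluded:", sum(p$cis_excluded), "\n")
  invisible(x)
}
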