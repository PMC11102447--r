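#' Build an evenly spaced marker map
#'
#' Lays out biallelic markers along a configurable number of chromosomes,
#' mimicking the marker density of a genotyped yeast cross. Coordinates are
#' 1-based and chromosome labels follow the yeast convention
#' (\code{chrI} ... \code{chrXVI}).
#'
#' @param n_chrom number of chromosomes.
#' @param markers_per_chrom markers per chromosome (recycled to `n_chrom`).
#' @param spacing distance in bp between adjacent markers.
#' @param first position of the first marker on each chromosome.
#' @return data.frame with columns `marker`, `chrom`, `pos`; positions are
#'   strictly increasing within each chromosome and marker ids are unique.
#' @examples
#' map <- marker_map(n_chrom = 2, markers_per_chrom = 5)
#' genome_length(map)
#' @export
marker_map <- function(n_chrom = 16, markers_per_chrom = 40,
                       spacing = 18000, first = 10000) {
  stopifnot(n_chrom >= 1, all(markers_per_chrom >= 2), spacing > 0, first >= 1)
  mpc <- rep_len(markers_per_chrom, n_chrom)
  chrom_labels <- paste0("chr", .roman(seq_len(n_chrom)))
  chrom <- rep(chrom_labels, mpc)
  pos <- unlist(lapply(mpc, function(m) first + spacing * (seq_len(m) - 1L)))
  marker <- sprintf("%s_%07d", chrom, pos)
  data.frame(marker = marker, chrom = chrom, pos = as.integer(pos),
             stringsAsFactors = FALSE)
}

.roman <- function(i) as.character(utils::as.roman(i))

#' Total genome length implied by a marker map
#'
#' Defined as the sum over chromosomes of the maximal marker position.
#'
#' @param map a marker map from [marker_map()].
#' @return genome length in bp.
#' @export
genome_length <- function(map) {
  sum(tapply(map$pos, map$chrom, max))
}

#' Simulate genotypes of a haploid cross panel
#'
#' Each chromosome is an independent two-state Markov chain over its markers:
#' the allele at the first marker is a fair coin and the allele switches
#' between adjacent markers with probability `recomb_fraction`. This gives
#' realistic linkage-disequilibrium decay without modelling interference or
#' genetic map units. Alleles are coded 0 (BY, lab parent) and 1 (3S,
#' clinical parent).
#'
#' @param n_segregants number of haploid progeny to simulate (>= 2).
#' @param map marker map from [marker_map()].
#' @param recomb_fraction per-interval switch probability in [0, 0.5].
#' @param seed integer seed; the output is deterministic given the seed.
#' @return integer matrix of 0/1 alleles, segregants in rows (named
#'   `seg001`, ...), markers in columns (named as in `map$marker`).
#' @examples
#' G <- simulate_cross(20, marker_map(2, 10), recomb_fraction = 0.1, seed = 1)
#' @export
simulate_cross <- function(n_segregants, map, recomb_fraction = 0.08,
                           seed = NULL) {
  if (!is.numeric(recomb_fraction) || recomb_fraction < 0 ||
      recomb_fraction > 0.5) {
    stop("recomb_fraction must lie in [0, 0.5]")
  }
  stopifnot(n_segregants >= 2)
  if (!is.null(seed)) set.seed(seed)
  chroms <- unique(map$chrom)
  cols <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    m <- sum(map$chrom == chroms[ci])
    start <- stats::rbinom(n_segregants, 1L, 0.5)
    if (m > 1) {
      sw <- matrix(stats::rbinom(n_segregants * (m - 1L), 1L, recomb_fraction),
                   nrow = n_segregants)
      cum <- t(apply(sw, 1L, cumsum)) %% 2L
      cols[[ci]] <- cbind(start, (start + cum) %% 2L)
    } else {
      cols[[ci]] <- matrix(start, ncol = 1L)
    }
  }
  G <- do.call(cbind, cols)
  storage.mode(G) <- "integer"
  dimnames(G) <- list(sprintf("seg%03d", seq_len(n_segregants)), map$marker)
  G
}

#' Random barcode sequences
#'
#' @param n number of distinct barcodes.
#' @param width barcode length in nt (default 20, the library design).
#' @return character vector of unique barcodes.
#' @keywords internal
random_barcodes <- function(n, width = 20L) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    bc <- vapply(seq_len(need + ceiling(need / 10) + 4L), function(i) {
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
            collapse = "")
    }, character(1))
    out <- unique(c(out, bc))
  }
  out[seq_len(n)]
}

#' Simulate a CRISPRi guide library
#'
#' Builds a guide table (target gene, binding coordinate, control and
#' polymorphic-binding-site flags) together with guide and segregant barcode
#' tables. Control guides target intergenic/noncoding positions and have no
#' target gene. A configurable fraction of non-control guides binds across a
#' BY/3S polymorphism (their 20-nt window overlaps a marker position), which
#' downstream analysis must flag and exclude.
#'
#' @param n_guides total number of guides including controls.
#' @param map marker map (binding positions are placed inside the genome).
#' @param n_controls number of control guides.
#' @param frac_polymorphic fraction of non-control guides placed so their
#'   binding window overlaps a marker (a known variant site).
#' @param barcodes_per_guide integer vector sampled from for the number of
#'   barcodes per guide.
#' @param seed integer seed.
#' @return list with `guides` (data.frame: `guide`, `gene`, `chrom`, `pos`,
#'   `control`, `polymorphic`) and `guide_barcodes` (data.frame: `guide_bc`,
#'   `guide`). Binding `pos` is the 1-based start of the 20-nt window.
#' @export
simulate_guide_library <- function(n_guides = 200, map, n_controls = 20,
                                   frac_polymorphic = 0.05,
                                   barcodes_per_guide = 1:3, seed = NULL) {
  stopifnot(n_guides > n_controls, n_controls >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_target <- n_guides - n_controls
  guide <- sprintf("g%04d", seq_len(n_guides))
  control <- c(rep(FALSE, n_target), rep(TRUE, n_controls))
  gene <- c(sprintf("gene%04d", seq_len(n_target)), rep(NA_character_,
                                                        n_controls))
  chrom_len <- tapply(map$pos, map$chrom, max)
  chrom <- sample(names(chrom_len), n_guides, replace = TRUE)
  pos <- vapply(chrom, function(cc) sample.int(chrom_len[[cc]] - 19L, 1L),
                integer(1))
  # plant polymorphic binding sites: window [pos, pos+19] covers a marker
  n_poly <- round(frac_polymorphic * n_target)
  polymorphic <- rep(FALSE, n_guides)
  if (n_poly > 0) {
    idx <- sample.int(n_target, n_poly)
    hit <- map[sample.int(nrow(map), n_poly, replace = TRUE), ]
    chrom[idx] <- hit$chrom
    pos[idx] <- pmax(1L, hit$pos - sample(0:19, n_poly, replace = TRUE))
    polymorphic[idx] <- TRUE
  }
  nbc <- sample(barcodes_per_guide, n_guides, replace = TRUE)
  bcs <- random_barcodes(sum(nbc))
  guide_barcodes <- data.frame(
    guide_bc = bcs,
    guide = rep(guide, nbc),
    stringsAsFactors = FALSE)
  list(
    guides = data.frame(guide = guide, gene = gene, chrom = chrom,
                        pos = as.integer(pos), control = control,
                        polymorphic = polymorphic, stringsAsFactors = FALSE),
    guide_barcodes = guide_barcodes)
}

#' Assign barcodes to segregants
#'
#' Most segregants carry a single barcode; a configurable fraction carries
#' 2-3 distinct barcodes, enabling replicate-based heritability estimates.
#'
#' @param segregants character vector of segregant ids.
#' @param frac_multi fraction of segregants given 2-3 barcodes.
#' @param seed integer seed.
#' @return data.frame with columns `seg_bc`, `segregant`.
#' @export
simulate_segregant_barcodes <- function(segregants, frac_multi = 0.18,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(segregants)
  nbc <- rep(1L, n)
  n_multi <- round(frac_multi * n)
  if (n_multi > 0) {
    nbc[sample.int(n, n_multi)] <- sample(2:3, n_multi, replace = TRUE)
  }
  data.frame(seg_bc = random_barcodes(sum(nbc)),
             segregant = rep(segregants, nbc), stringsAsFactors = FALSE)
}
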