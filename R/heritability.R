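#' Broad-sense heritability from replicated guide effects
#'
#' One-way ANOVA of per-lineage guide effects with segregant as the group:
#' H^2 = SS_between / SS_total. The per-lineage guide effect is the induced
#' lineage fitness minus the segregant's control-assay baseline.
#'
#' @param effect numeric per-lineage guide effects.
#' @param segregant group label per value.
#' @return list with `H2`, `ss_between`, `ss_total`, `defined`.
#' @examples
#' broad_sense(c(0, 2, 3, 5), c("a", "a", "b", "b"))$H2  # 9/13
#' @export
broad_sense <- function(effect, segregant) {
  keep <- !is.na(effect)
  effect <- effect[keep]; segregant <- as.character(segregant)[keep]
  gm <- tapply(effect, segregant, mean)
  n <- tapply(effect, segregant, length)
  ss_total <- sum((effect - mean(effect))^2)
  ss_between <- sum(n * (gm - mean(effect))^2)
  if (ss_total == 0) {
    return(list(H2 = NA_real_, ss_between = ss_between, ss_total = 0,
                defined = FALSE))
  }
  list(H2 = ss_between / ss_total, ss_between = ss_between,
       ss_total = ss_total, defined = TRUE)
}

#' Additive (genomic) relationship matrix for a haploid panel
#'
#' Marker genotypes (0/1) are centred by their allele frequency and scaled
#' by sqrt(p (1 - p)); the relationship matrix is the average over markers
#' of the products of standardised genotypes, so its diagonal averages ~1.
#' Monomorphic markers are dropped.
#'
#' @param genotypes 0/1 segregant x marker matrix.
#' @return symmetric segregant x segregant matrix.
#' @export
relationship_matrix <- function(genotypes) {
  p <- colMeans(genotypes)
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all markers monomorphic")
  G <- genotypes[, keep, drop = FALSE]
  p <- p[keep]
  W <- sweep(sweep(G, 2, p, "-"), 2, sqrt(p * (1 - p)), "/")
  tcrossprod(W) / ncol(W)
}

#' Narrow-sense heritability by relationship-matrix REML
#'
#' Fits the variance-component model y = mu + g + e with
#' g ~ N(0, sigma_A^2 A) on the additive relationship matrix A, maximising
#' the restricted likelihood exactly on the eigendecomposition of A (the
#' profile likelihood in the heritability parameter is optimised in one
#' dimension). Returns h^2 = V_A / (V_A + V_E), clipped to [0, 1].
#'
#' @param trait named numeric vector (names = segregant ids); NAs dropped.
#' @param genotypes 0/1 genotype matrix with matching rownames, or a
#'   precomputed relationship matrix via `A`.
#' @param A optional relationship matrix (overrides `genotypes`).
#' @param min_segregants minimum number of phenotyped segregants.
#' @return list with `h2`, `V_A`, `V_E`, `logLik`, `n`.
#' @export
narrow_sense <- function(trait, genotypes = NULL, A = NULL,
                         min_segregants = 30) {
  trait <- trait[!is.na(trait)]
  if (stats::var(trait) == 0) stop("zero-variance trait")
  if (is.null(A)) A <- relationship_matrix(genotypes)
  ids <- intersect(names(trait), rownames(A))
  if (length(ids) < min_segregants) {
    stop("need >= ", min_segregants, " segregants with trait values")
  }
  y <- trait[ids]
  A <- A[ids, ids]
  e <- eigen(A, symmetric = TRUE)
  if (min(e$values) < -1e-6) {
    # jitter a slightly indefinite matrix
    e <- eigen(A + diag(1e-6, nrow(A)), symmetric = TRUE)
    if (min(e$values) < -1e-6) stop("relationship matrix not PSD")
  }
  d <- pmax(e$values, 0)
  ys <- crossprod(e$vectors, y)[, 1]
  xs <- crossprod(e$vectors, rep(1, length(y)))[, 1]
  n <- length(y)
  restricted_ll <- function(theta) {
    v <- theta * d + (1 - theta)
    xvx <- sum(xs^2 / v)
    beta <- sum(xs * ys / v) / xvx
    r <- ys - xs * beta
    rss <- sum(r^2 / v)
    -0.5 * (sum(log(v)) + log(xvx) + (n - 1) * log(rss / (n - 1)))
  }
  opt <- stats::optimize(restricted_ll, c(1e-6, 1 - 1e-6), maximum = TRUE)
  theta <- opt$maximum
  # back out the variance components at the optimum
  v <- theta * d + (1 - theta)
  xvx <- sum(xs^2 / v)
  beta <- sum(xs * ys / v) / xvx
  s2 <- sum((ys - xs * beta)^2 / v) / (n - 1)
  h2 <- min(max(theta, 0), 1)
  list(h2 = h2, V_A = s2 * theta, V_E = s2 * (1 - theta),
       logLik = opt$objective, n = n)
}

#' Higher-order epistasis fraction
#'
#' The share of a trait's genetic basis not captured additively:
#' 1 - h^2 / H^2. Negative values (sampling noise pushing h^2 above H^2)
#' are floored at 0 with a flag.
#'
#' @param h2 narrow-sense heritability.
#' @param H2 broad-sense heritability (> 0).
#' @return list with `fraction` and `floored`.
#' @examples
#' epistasis_fraction(0.358, 0.737)$fraction  # 0.514
#' @export
epistasis_fraction <- function(h2, H2) {
  if (is.na(H2) || H2 <= 0) {
    return(list(fraction = NA_real_, floored = FALSE))
  }
  f <- 1 - h2 / H2
  list(fraction = max(f, 0), floored = f < 0)
}

#' Heritability decomposition for every background-effect guide
#'
#' For each guide with deviations: H^2 from replicate lineage guide effects
#' (induced fitness minus the segregant's control baseline), h^2 from
#' relationship-matrix REML on the deviation values, and the higher-order
#' epistasis fraction 1 - h^2/H^2.
#'
#' @param effects a `guide_effects` object.
#' @param fitness_list normalised fitness list (needs `"CON"` and the
#'   effects' assay).
#' @param genotypes 0/1 genotype matrix.
#' @param control_guides control guide ids used for segregant baselines.
#' @param baseline `"controls"` (CON lineages with control guides; default)
#'   or `"all"` (all CON lineages of the segregant).
#' @return data.frame with `guide`, `H2`, `h2`, `epistasis_fraction`.
#' @export
heritability_decomposition <- function(effects, fitness_list, genotypes,
                                       control_guides,
                                       baseline = c("controls", "all")) {
  baseline <- match.arg(baseline)
  con <- fitness_list$CON$fitness
  con <- con[con$flag == "" & !is.na(con$fitness), ]
  atc <- fitness_list[[effects$assay]]$fitness
  atc <- atc[atc$flag == "" & !is.na(atc$fitness), ]
  base_pool <- if (baseline == "controls") {
    con[con$guide %in% control_guides, ]
  } else {
    con
  }
  seg_base <- tapply(base_pool$fitness, base_pool$segregant, mean)
  A <- relationship_matrix(genotypes)
  guides <- colnames(effects$deviations)
  out <- lapply(guides, function(g) {
    da <- atc[atc$guide == g & atc$segregant %in% names(seg_base), ]
    eff <- da$fitness - seg_base[da$segregant]
    H2 <- broad_sense(eff, da$segregant)$H2
    d <- effects$deviations[, g]
    h2 <- tryCatch(narrow_sense(d[!is.na(d)], A = A)$h2,
                   error = function(e) NA_real_)
    data.frame(guide = g, H2 = H2, h2 = h2,
               epistasis_fraction = epistasis_fraction(h2, H2)$fraction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
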