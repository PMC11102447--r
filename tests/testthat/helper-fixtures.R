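# Shared fixtures, all generated in code.

small_panel <- function(n_seg = 40, n_chrom = 3, mpc = 12, n_guides = 24,
                        n_controls = 6, seed = 42) {
  map <- marker_map(n_chrom, mpc)
  G <- simulate_cross(n_seg, map, recomb_fraction = 0.1, seed = seed)
  lib <- simulate_guide_library(n_guides, map, n_controls = n_controls,
                                frac_polymorphic = 0, seed = seed + 1)
  sb <- simulate_segregant_barcodes(rownames(G), seed = seed + 2)
  list(map = map, G = G, lib = lib, sb = sb)
}

# hand-built two-lineage count table following the logistic closed form
two_lineage_counts <- function(s = c(0, 0.2), f0 = c(0.5, 0.5),
                               tp = c(0, 2, 4, 6, 10), depth = 1e6) {
  cm <- t(sapply(seq_along(s), function(i) {
    sapply(tp, function(t) {
      w <- f0 * exp(s * t)
      depth * (w / sum(w))[i]
    })
  }))
  d <- data.frame(lineage_id = paste0("lin", seq_along(s)),
                  seg_bc = "SB", guide_bc = paste0("GB", seq_along(s)),
                  segregant = "seg1", guide = paste0("g", seq_along(s)),
                  assay = "ATC1", valid = TRUE, stringsAsFactors = FALSE)
  d <- cbind(d, stats::setNames(as.data.frame(cm),
                                paste0("n_t", seq_along(tp) - 1)))
  attr(d, "timepoints") <- tp
  attr(d, "depth") <- depth
  class(d) <- c("lineage_counts", "data.frame")
  d
}

# build a minimal effect_architecture by hand for formula-level checks
manual_arch <- function(b, m, interactions, genotypes, kappa = 0,
                        tau = 0, sigma_lin = 0) {
  structure(list(
    b = b, m = m,
    qtl = data.frame(marker = character(0), effect = numeric(0)),
    interactions = interactions,
    hubs = data.frame(hub = character(0), marker = character(0),
                      style = character(0)),
    kappa = kappa, tau = tau, sigma_lin = sigma_lin,
    leaky = character(0), genotypes = genotypes),
    class = "effect_architecture")
}

# fitness data for one guide across segregants: control + induced lineages
guide_fitness_data <- function(effect_per_seg, n_seg = length(effect_per_seg),
                               n_bc = 3, noise_sd = 0.01, baseline_sd = 0.05,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  segs <- sprintf("s%03d", seq_len(n_seg))
  b <- stats::rnorm(n_seg, 0, baseline_sd)
  seg <- rep(segs, each = n_bc)
  bl <- rep(b, each = n_bc)
  con <- bl + stats::rnorm(length(seg), 0, noise_sd)
  atc <- bl + rep(effect_per_seg, each = n_bc) +
    stats::rnorm(length(seg), 0, noise_sd)
  list(fitness = c(con, atc), segregant = c(seg, seg),
       induced = rep(0:1, each = length(seg)), segs = segs, b = b)
}

# wrap per-assay fitness values in a minimal lineage_fitness list for
# normalize_assays()/guide_effects()
as_fitness_obj <- function(df) {
  structure(list(fitness = df,
                 trajectory = list(), deviance = numeric(0),
                 iterations = 0L),
            class = "lineage_fitness")
}
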