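#' Effect-level simulation of fitness tables and deviations
#'
#' Generates per-lineage fitness values directly from an effect
#' architecture (baseline + guide + interaction effects + lineage noise +
#' measurement noise), skipping the sequencing layer. This is the fast path
#' used for calibration studies that need many replicates of the
#' deviation/linkage/hub machinery; the sequencing layer is exercised
#' separately by [simulate_assay()] + [estimate_fitness()].
#'
#' @param arch an `effect_architecture`.
#' @param panel list with `G` (genotypes) and `lib` (guide library), as
#'   returned by the test fixtures or assembled by the caller.
#' @param n_bc replicate barcode lineages per segregant-guide combination.
#' @param meas_sd measurement noise SD added per lineage.
#' @param min_segregants minimum deviations per guide (as in
#'   [compute_deviations()]).
#' @param seed integer seed.
#' @return list with `fits` (named list of `lineage_fitness`-shaped
#'   objects for CON and ATC1) and `effects` (a `guide_effects` object
#'   whose `results` carry the fixed-mode mean effects and whose
#'   `deviations` are the centred per-segregant contrasts for every
#'   efficacious guide).
#' @export
simulate_effect_tables <- function(arch, panel, n_bc = 3, meas_sd = 0.01,
                                   min_segregants = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- panel$G
  guides <- panel$lib$guides$guide
  segs <- rownames(G)
  combo <- expand.grid(segregant = segs, guide = guides,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(combo)
  mk_tab <- function(induced, assay) {
    seg <- rep(combo$segregant, each = n_bc)
    gui <- rep(combo$guide, each = n_bc)
    eps <- stats::rnorm(n * n_bc, 0, arch$sigma_lin)
    f <- true_fitness_vec(arch, seg, gui, induced, eps) +
      stats::rnorm(n * n_bc, 0, meas_sd)
    structure(list(fitness = data.frame(
      lineage_id = paste0(assay, ":", seg, ":", gui, ":",
                          rep(seq_len(n_bc), n)),
      segregant = seg, guide = gui, assay = assay, fitness = f,
      score = 0, t0 = 100, flag = "", stringsAsFactors = FALSE),
      trajectory = list(), deviance = numeric(0), iterations = 0L),
      class = "lineage_fitness")
  }
  fits <- list(CON = mk_tab(FALSE, "CON"), ATC1 = mk_tab(TRUE, "ATC1"))

  eff_guides <- guides[arch$m[guides] != 0 |
                         guides %in% arch$interactions$guide]
  # combo-level contrasts: mean over barcode replicates, ATC minus CON;
  # combos are in expand.grid order (segregant varies fastest)
  grp <- rep(seq_len(n), each = n_bc)
  con_mean <- rowsum(fits$CON$fitness$fitness, grp) / n_bc
  atc_mean <- rowsum(fits$ATC1$fitness$fitness, grp) / n_bc
  eff_mat <- matrix(atc_mean - con_mean, nrow = length(segs),
                    dimnames = list(segs, guides))
  m_hat <- colMeans(eff_mat)
  keep <- guides %in% eff_guides & colSums(!is.na(eff_mat)) >= min_segregants
  dev_mat <- sweep(eff_mat[, keep, drop = FALSE], 2,
                   colMeans(eff_mat[, keep, drop = FALSE]), "-")
  results <- data.frame(guide = guides, m_hat = unname(m_hat),
                        p_mean = NA_real_, p_interaction = NA_real_,
                        model = "fixed", n_segregants = length(segs),
                        singular = FALSE, q_mean = NA_real_,
                        efficacious = unname(guides %in% eff_guides),
                        q_interaction = NA_real_,
                        background = unname(guides %in% colnames(dev_mat)),
                        n_deviations = length(segs),
                        stringsAsFactors = FALSE)
  effects <- structure(list(results = results, deviations = dev_mat,
                            null = NULL, assay = "ATC1", fdr = 0.05),
                       class = "guide_effects")
  list(fits = fits, effects = effects)
}

#' Replicated hub-recovery study
#'
#' Runs the deviation -> permutation-threshold -> linkage -> hub-calling ->
#' classification chain on freshly simulated panels, each carrying one
#' amplifying and one masking hub, and records whether each planted hub is
#' called at its marker (within one marker spacing) and classified
#' correctly. Also supports null panels (no hubs, no baseline coupling)
#' for false-positive calibration.
#'
#' @param n_rep number of replicates.
#' @param seed master seed.
#' @param n_segregants,n_guides panel size per replicate.
#' @param guides_per_hub interacting guides per hub.
#' @param n_perm permutations for the significance threshold.
#' @param null_run if TRUE, simulate architectures with no hubs and no
#'   baseline coupling and count hubs called (false positives).
#' @return data.frame with one row per replicate: `amp_ok`, `mask_ok`
#'   (planted run) or `n_false_hubs` (null run).
#' @export
hub_recovery_study <- function(n_rep = 100, seed = 1,
                               n_segregants = 169, n_guides = 200,
                               guides_per_hub = 18, n_perm = 1000,
                               null_run = FALSE) {
  set.seed(seed)
  seeds <- sample.int(1e8, 4 * n_rep)
  mp <- marker_map(16, 40)
  spacing <- 18000
  out <- vector("list", n_rep)
  for (i in seq_len(n_rep)) {
    s4 <- seeds[(4 * i - 3):(4 * i)]
    G <- simulate_cross(n_segregants, mp, 0.08, seed = s4[1])
    lib <- simulate_guide_library(n_guides, mp, n_controls = 20,
                                  frac_polymorphic = 0, seed = s4[2])
    cfg <- if (null_run) {
      arch_config(hub_styles = character(0), kappa = 0)
    } else {
      arch_config(guides_per_hub = guides_per_hub)
    }
    arch <- simulate_architecture(G, lib, cfg, seed = s4[3])
    sims <- simulate_effect_tables(arch, list(G = G, lib = lib),
                                   seed = s4[4])
    eff <- sims$effects
    if (ncol(eff$deviations) == 0) {
      out[[i]] <- data.frame(amp_ok = NA, mask_ok = NA, n_false_hubs = 0L)
      next
    }
    th <- permutation_threshold(eff$deviations, G, mp, n_perm = n_perm,
                                seed = s4[4] + 1L)
    pks <- lapply(colnames(eff$deviations), function(g) {
      y <- eff$deviations[, g]
      call_peaks(scan_trait(y[!is.na(y)], G, mp, trait_id = g),
                 th$cutoff)
    })
    peaks <- do.call(rbind, pks)
    par <- hub_count_threshold(peaks, genome_length(mp))
    hubs <- call_hubs(overlap_profile(peaks, mp), par, peaks)
    if (null_run) {
      out[[i]] <- data.frame(amp_ok = NA, mask_ok = NA,
                             n_false_hubs = nrow(hubs))
      next
    }
    bsc <- scan_trait(arch$b, G, mp, trait_id = "baseline_fitness")
    bpk <- call_peaks(bsc, th$cutoff)
    cls <- vapply(seq_len(nrow(hubs)), function(h) {
      if (hubs$n_members[h] < 3) return("small")
      hub_allele_summary(hubs[h, ], eff, sims$fits, G,
                         baseline_peaks = bpk)$classification
    }, character(1))
    found <- vapply(seq_len(nrow(arch$hubs)), function(h) {
      tm <- arch$hubs$marker[h]
      tchr <- sub("_[0-9]+$", "", tm)
      tpos <- as.integer(sub("^.*_", "", tm))
      hit <- which(hubs$chrom == tchr & abs(hubs$pos - tpos) <= spacing)
      if (length(hit)) cls[hit[1]] else "missed"
    }, character(1))
    out[[i]] <- data.frame(
      amp_ok = found[arch$hubs$style == "amplifying"][1] == "amplifying",
      mask_ok = found[arch$hubs$style == "masking"][1] == "masking",
      n_false_hubs = NA_integer_)
  }
  do.call(rbind, out)
}
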