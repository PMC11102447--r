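#' Pipeline configuration
#'
#' Collects every stage parameter with defaults matching the analysis as a
#' whole: BH FDR 0.05, 3-SD efficacy cutoff, minimum 5 T0 reads, 35-segregant
#' minimum for deviations, 1000 permutations, 100 kb peak separation, 10 kb
#' cis exclusion, 20 kb hub bins.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param n_segregants,n_guides,n_controls panel dimensions.
#' @param n_chrom,markers_per_chrom,recomb_fraction cross structure.
#' @param arch an [arch_config()].
#' @param sim a [sim_config()].
#' @param chimera_coefficients c(intercept, a_seg, a_guide) injected into
#'   the simulated counts (and re-estimated by the correction stage); NULL
#'   disables chimera injection/correction.
#' @param depth_scale depth-normalisation constant; `NA` (default) uses
#'   each assay's own T0 depth, appropriate for desk-scale simulations.
#' @param fdr FDR level for guide-effect families.
#' @param min_t0,min_guides_per_segregant,min_segregants_per_guide QC.
#' @param min_segregants_deviations minimum segregants with deviations.
#' @param n_perm linkage permutations.
#' @param min_separation,cis_exclusion,hub_bin,hub_alpha mapping/hub params.
#' @param deviation_method `"blup"` or `"fixed"`.
#' @param out_dir optional directory for artifacts (TSV/JSON).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_segregants = 169, n_guides = 200,
                            n_controls = 20, n_chrom = 16,
                            markers_per_chrom = 40, recomb_fraction = 0.08,
                            arch = arch_config(), sim = sim_config(),
                            chimera_coefficients = NULL,
                            depth_scale = NA, fdr = 0.05, min_t0 = 5,
                            min_guides_per_segregant = 100,
                            min_segregants_per_guide = 2,
                            min_segregants_deviations = 35, n_perm = 1000,
                            min_separation = 1e5, cis_exclusion = 1e4,
                            hub_bin = 2e4, hub_alpha = 0.05,
                            deviation_method = "blup", out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic-screen pipeline
#'
#' simulate -> count -> (chimera-correct) -> normalise -> fitness -> QC ->
#' assay normalisation -> guide effects -> heritability -> linkage -> hubs,
#' entirely in memory, with ground truth retained for recovery checks.
#' Artifacts (TSV/JSON) are written when `config$out_dir` is set.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_run` with elements `map`, `genotypes`,
#'   `library`, `seg_barcodes`, `arch`, `counts` (per assay), `fitness`
#'   (normalised list), `effects`, `heritability`, `linkage`,
#'   `baseline_peaks`, `hubs`, `hub_summaries`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  seed <- config$seed
  mp <- marker_map(config$n_chrom, config$markers_per_chrom)
  G <- simulate_cross(config$n_segregants, mp, config$recomb_fraction,
                      seed = seed)
  lib <- simulate_guide_library(config$n_guides, mp,
                                n_controls = config$n_controls,
                                seed = seed + 1L)
  sb <- simulate_segregant_barcodes(rownames(G), seed = seed + 2L)
  arch <- simulate_architecture(G, lib, config$arch, seed = seed + 3L)

  assays <- c(ATC1 = TRUE, ATC2 = TRUE, CON = FALSE)
  combos <- NULL
  counts <- list()
  for (i in seq_along(assays)) {
    a <- names(assays)[i]
    cn <- simulate_assay(arch, lib, sb, config$sim, induced = assays[[i]],
                         assay = a, seed = seed + 10L + i, combos = combos)
    if (is.null(combos)) combos <- attr(cn, "lineage_frame")
    if (!is.null(config$chimera_coefficients)) {
      cn <- inject_chimeras(cn, config$chimera_coefficients,
                            seed = seed + 20L + i)
      model <- fit_chimera_model(cn)
      cn <- correct_chimeras(cn, model)
    }
    counts[[a]] <- cn
  }

  fits <- list()
  for (a in names(counts)) {
    cn <- counts[[a]]
    raw_t0 <- stats::setNames(count_matrix(cn)[, 1], cn$lineage_id)
    norm <- normalize_depth(cn, config$depth_scale)
    norm <- norm[norm$valid, ]
    fit <- estimate_fitness(norm)
    fit <- qc_filter(fit, raw_t0 = raw_t0, min_t0 = config$min_t0,
                     min_guides_per_segregant =
                       config$min_guides_per_segregant,
                     min_segregants_per_guide =
                       config$min_segregants_per_guide)
    fits[[a]] <- fit
  }
  control_guides <- lib$guides$guide[lib$guides$control]
  fits <- normalize_assays(fits, control_guides)

  poly <- lib$guides$guide[lib$guides$polymorphic]
  eff <- guide_effects(fits, assay = "ATC1",
                       exclude = poly, fdr = config$fdr,
                       min_segregants = config$min_segregants_deviations,
                       deviation_method = config$deviation_method)

  herit <- if (ncol(eff$deviations) > 0) {
    heritability_decomposition(eff, fits, G, control_guides)
  } else NULL

  linkage <- baseline_peaks <- hubs <- NULL
  hub_summaries <- list()
  if (ncol(eff$deviations) > 0) {
    H2 <- if (!is.null(herit)) {
      stats::setNames(herit$H2, herit$guide)
    } else NULL
    linkage <- map_deviations(eff, G, mp, guide_library = lib,
                              H2 = H2, n_perm = config$n_perm,
                              seed = seed + 40L)
    # baseline fitness loci: segregant mean CON fitness, same machinery
    con <- fits$CON$fitness
    con <- con[con$flag == "", ]
    base_trait <- tapply(con$fitness, con$segregant, mean)
    bsc <- scan_trait(base_trait, G, mp, trait_id = "baseline_fitness")
    baseline_peaks <- call_peaks(bsc, linkage$threshold$cutoff)
    trans <- linkage$peaks[!linkage$peaks$cis_excluded, , drop = FALSE]
    params <- hub_count_threshold(trans, genome_length(mp),
                                  bin_size = config$hub_bin,
                                  alpha = config$hub_alpha)
    prof <- overlap_profile(trans, mp)
    hubs <- call_hubs(prof, params, trans)
    for (h in seq_len(nrow(hubs))) {
      if (hubs$n_members[h] >= 3) {
        hub_summaries[[hubs$hub[h]]] <- hub_allele_summary(
          hubs[h, ], eff, fits, G, baseline_peaks = baseline_peaks)
      }
    }
  }
  run <- structure(list(map = mp, genotypes = G, library = lib,
                        seg_barcodes = sb, arch = arch, counts = counts,
                        fitness = fits, effects = eff,
                        heritability = herit, linkage = linkage,
                        baseline_peaks = baseline_peaks, hubs = hubs,
                        hub_summaries = hub_summaries, config = config),
                   class = "pipeline_run")
  if (!is.null(config$out_dir)) write_artifacts(run, config$out_dir)
  run
}

#' Write pipeline artifacts to a directory
#'
#' Plain-text TSV/JSON only: genotypes, marker map, guide table, counts,
#' fitness, guide-effect results, deviations, heritability, peaks, hubs,
#' and the serialized configuration.
#'
#' @param run a `pipeline_run`.
#' @param dir output directory (created if needed).
#' @param force overwrite an existing completed directory.
#' @return invisibly, the directory.
#' @export
write_artifacts <- function(run, dir, force = FALSE) {
  done <- file.path(dir, "DONE")
  if (file.exists(done) && !force) {
    message("run directory already complete; use force = TRUE to rewrite")
    return(invisible(dir))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(run$map, "marker_map.tsv")
  gt <- data.frame(segregant = rownames(run$genotypes), run$genotypes,
                   check.names = FALSE)
  wt(gt, "genotypes.tsv")
  wt(run$library$guides, "guides.tsv")
  wt(run$library$guide_barcodes, "guide_barcodes.tsv")
  wt(run$seg_barcodes, "segregant_barcodes.tsv")
  for (a in names(run$counts)) {
    wt(as.data.frame(run$counts[[a]]), paste0("counts_", a, ".tsv"))
  }
  for (a in names(run$fitness)) {
    wt(run$fitness[[a]]$fitness, paste0("fitness_", a, ".tsv"))
  }
  wt(run$effects$results, "guide_effects.tsv")
  dv <- data.frame(segregant = rownames(run$effects$deviations),
                   run$effects$deviations, check.names = FALSE)
  wt(dv, "deviations.tsv")
  if (!is.null(run$heritability)) wt(run$heritability, "heritability.tsv")
  if (!is.null(run$linkage)) {
    wt(run$linkage$peaks, "peaks.tsv")
  }
  if (!is.null(run$hubs) && nrow(run$hubs)) {
    hb <- run$hubs
    hb$members <- vapply(hb$members, paste, character(1), collapse = ",")
    wt(hb, "hubs.tsv")
    bed <- data.frame(chrom = run$hubs$chrom, start = run$hubs$start - 1L,
                      end = run$hubs$end, name = run$hubs$hub)
    utils::write.table(bed, file.path(dir, "hubs.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  cfg <- run$config
  cfg$arch <- unclass(cfg$arch); cfg$sim <- unclass(cfg$sim)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(format(Sys.time()), done)
  invisible(dir)
}

#' Summary report of a pipeline run
#'
#' Counts of efficacious and background-effect guides, detected loci and
#' hubs, the heritability decomposition, and between-assay fitness
#' correlations (lineage-level and per-guide).
#'
#' @param run a `pipeline_run`.
#' @return list of class `pipeline_report` (also printed nicely).
#' @export
write_report <- function(run) {
  r <- run$effects$results
  fits <- run$fitness
  lin_cor <- function(a, b, method = "spearman") {
    fa <- fits[[a]]$fitness; fb <- fits[[b]]$fitness
    ok_a <- fa$flag == ""; ok_b <- fb$flag == ""
    ids <- intersect(fa$lineage_id[ok_a], fb$lineage_id[ok_b])
    stats::cor(fa$fitness[match(ids, fa$lineage_id)],
               fb$fitness[match(ids, fb$lineage_id)], method = method)
  }
  guide_cor <- function(a, b, guides, method = "spearman") {
    gm <- function(f) {
      d <- f$fitness[f$fitness$flag == "" & f$fitness$guide %in% guides, ]
      seg <- tapply(d$fitness, list(d$guide, d$segregant), mean)
      rowMeans(seg, na.rm = TRUE)
    }
    ga <- gm(fits[[a]]); gb <- gm(fits[[b]])
    ids <- intersect(names(ga), names(gb))
    stats::cor(ga[ids], gb[ids], method = method)
  }
  eff_guides <- r$guide[r$efficacious]
  rep <- list(
    n_guides_tested = nrow(r),
    n_efficacious = sum(r$efficacious, na.rm = TRUE),
    n_background = sum(r$background, na.rm = TRUE),
    n_loci = if (!is.null(run$linkage)) {
      sum(!run$linkage$peaks$cis_excluded)
    } else 0L,
    n_hubs = if (!is.null(run$hubs)) nrow(run$hubs) else 0L,
    hub_members = if (!is.null(run$hubs)) run$hubs$n_members else integer(0),
    mean_H2 = if (!is.null(run$heritability)) {
      mean(run$heritability$H2, na.rm = TRUE)
    } else NA_real_,
    mean_h2 = if (!is.null(run$heritability)) {
      mean(run$heritability$h2, na.rm = TRUE)
    } else NA_real_,
    mean_epistasis_fraction = if (!is.null(run$heritability)) {
      mean(run$heritability$epistasis_fraction, na.rm = TRUE)
    } else NA_real_,
    cor_ATC1_ATC2 = lin_cor("ATC1", "ATC2"),
    cor_ATC1_CON = lin_cor("ATC1", "CON"),
    cor_guide_ATC1_ATC2 = if (length(eff_guides) >= 3) {
      guide_cor("ATC1", "ATC2", eff_guides)
    } else NA_real_,
    cor_guide_ATC1_CON = if (length(eff_guides) >= 3) {
      guide_cor("ATC1", "CON", eff_guides)
    } else NA_real_)
  structure(rep, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat("  guides tested:      ", x$n_guides_tested, "\n")
  cat("  efficacious:        ", x$n_efficacious, "\n")
  cat("  background effects: ", x$n_background, "\n")
  cat("  trans loci:         ", x$n_loci, "\n")
  cat("  hubs:               ", x$n_hubs,
      if (length(x$hub_members)) {
        paste0("(members: ", paste(x$hub_members, collapse = ", "), ")")
      } else "", "\n")
  cat(sprintf("  mean H2 %.3f  mean h2 %.3f  mean 1 - h2/H2 %.3f\n",
              x$mean_H2, x$mean_h2, x$mean_epistasis_fraction))
  cat(sprintf("  lineage fitness cor (Spearman): ATC1~ATC2 %.3f, ATC1~CON %.3f\n",
              x$cor_ATC1_ATC2, x$cor_ATC1_CON))
  cat(sprintf("  efficacious-guide cor: ATC1~ATC2 %.3f, ATC1~CON %.3f\n",
              x$cor_guide_ATC1_ATC2, x$cor_guide_ATC1_CON))
  invisible(x)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run:", length(x$arch$b), "segregants x",
      nrow(x$library$guides), "guides, seed", x$config$seed, "\n")
  print(write_report(x))
  invisible(x)
}
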