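#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH over one family of tests.
#'
#' @param p numeric p-values in [0, 1].
#' @return q-values of the same length.
#' @export
adjust_fdr <- function(p) stats::p.adjust(p, method = "BH")

#' Test one guide for mean and background-dependent effects
#'
#' Compares the fitness of all lineages carrying one guide between the
#' control assay (guide indicator 0) and one induced assay (indicator 1)
#' with mixed models: the base model `fitness ~ guide + (1 | segregant)`
#' (random segregant intercept, fixed guide effect) and the interaction
#' model adding a per-segregant guide term as a random slope,
#' `fitness ~ guide + (1 + guide | segregant)`. The background-effect
#' p-value is the likelihood-ratio test of interaction vs base; the mean
#' effect and its p-value come from whichever model the LRT (at
#' `lrt_alpha`) selects.
#'
#' @param fitness numeric lineage fitness values (CON and ATC pooled).
#' @param segregant segregant id per lineage.
#' @param induced 0/1 indicator per lineage (1 = induced assay).
#' @return list with `m_hat`, `p_mean`, `p_interaction`, `model`
#'   (`"base"` or `"interaction"`), `n_segregants`, `singular`, and the
#'   fitted interaction model (or NULL) for deviation extraction.
#' @export
test_guide <- function(fitness, segregant, induced, lrt_alpha = 0.05) {
  stopifnot(length(fitness) == length(segregant),
            length(fitness) == length(induced))
  d <- data.frame(fitness = fitness, segregant = factor(segregant),
                  guide = as.numeric(induced))
  if (nlevels(d$segregant) < 2) stop("need >= 2 segregants")
  res <- list(m_hat = NA_real_, p_mean = NA_real_,
              p_interaction = NA_real_, model = NA_character_,
              n_segregants = nlevels(d$segregant), singular = FALSE,
              fit_interaction = NULL)
  base <- tryCatch(suppressMessages(suppressWarnings(
    lmerTest::lmer(fitness ~ guide + (1 | segregant), data = d))),
    error = function(e) NULL)
  inter <- tryCatch(suppressMessages(suppressWarnings(
    lmerTest::lmer(fitness ~ guide + (1 + guide | segregant), data = d))),
    error = function(e) NULL)
  if (is.null(base)) {
    res$singular <- TRUE
    return(res)
  }
  if (!is.null(inter)) {
    lrt <- suppressMessages(suppressWarnings(anova(base, inter)))
    res$p_interaction <- lrt[2, "Pr(>Chisq)"]
  }
  use_inter <- !is.null(inter) && !is.na(res$p_interaction) &&
    res$p_interaction < lrt_alpha
  chosen <- if (use_inter) inter else base
  co <- tryCatch(summary(chosen)$coefficients,
                 error = function(e) NULL)
  if (is.null(co) || !"guide" %in% rownames(co)) {
    res$singular <- TRUE
    return(res)
  }
  res$m_hat <- co["guide", "Estimate"]
  res$p_mean <- co["guide", "Pr(>|t|)"]
  res$model <- if (use_inter) "interaction" else "base"
  res$fit_interaction <- inter
  res
}

#' Per-segregant deviation values for one guide
#'
#' The deviation of segregant s is its predicted guide effect minus the mean
#' guide effect, re-centred to average exactly zero over the segregants with
#' estimates. In `method = "blup"` the per-segregant effects are the random
#' slopes of the interaction model (shrinkage estimates); in
#' `method = "fixed"` they are the unshrunk contrasts
#' mean(induced fitness of s) - mean(control fitness of s).
#'
#' @param fitness,segregant,induced as in [test_guide()].
#' @param fit_interaction fitted interaction model (required for
#'   `method = "blup"`).
#' @param method `"blup"` or `"fixed"`.
#' @param min_segregants guides with deviations for fewer segregants than
#'   this are dropped (returns NULL).
#' @return named numeric vector of deviations (mean 0), or NULL.
#' @export
compute_deviations <- function(fitness, segregant, induced,
                               fit_interaction = NULL, method = "blup",
                               min_segregants = 35) {
  segregant <- as.character(segregant)
  obs <- sort(unique(segregant[induced == 1]))
  if (method == "blup") {
    if (is.null(fit_interaction)) stop("interaction fit required for BLUPs")
    re <- lme4::ranef(fit_interaction)$segregant
    if (!"guide" %in% colnames(re)) return(NULL)
    d <- re[obs[obs %in% rownames(re)], "guide"]
    names(d) <- obs[obs %in% rownames(re)]
  } else {
    eff <- vapply(obs, function(s) {
      a <- fitness[segregant == s & induced == 1]
      c0 <- fitness[segregant == s & induced == 0]
      if (!length(a) || !length(c0)) return(NA_real_)
      mean(a) - mean(c0)
    }, numeric(1))
    d <- eff[!is.na(eff)]
  }
  if (length(d) < min_segregants) return(NULL)
  d - mean(d)
}

#' Efficacy threshold from a fitted null distribution
#'
#' Because every targeted gene is essential, guides are not expected to show
#' positive effects; the subset of mean effects at or above the centre of
#' the distribution is treated as the upper half of the null. That subset is
#' reflected about the centre to a symmetric sample whose SD estimates the
#' null SD, and the efficacy cutoff is `center - 3 * SD`.
#'
#' @param m_hat numeric vector of mean guide effects (>= 50 values).
#' @param center `"median"` (default) or `"mean"` of the effects, used as
#'   the null centre.
#' @return object of class `efficacy_null`: list with `center`, `sd`,
#'   `cutoff`.
#' @export
efficacy_threshold <- function(m_hat, center = c("median", "mean")) {
  center <- match.arg(center)
  m_hat <- m_hat[!is.na(m_hat)]
  if (length(m_hat) < 50) stop("need >= 50 mean effects")
  c0 <- if (center == "median") stats::median(m_hat) else mean(m_hat)
  upper <- m_hat[m_hat >= c0]
  if (length(upper) == 0) stop("no effects at or above the null centre")
  reflected <- c(upper, 2 * c0 - upper)
  s <- stats::sd(reflected)
  structure(list(center = c0, sd = s, cutoff = c0 - 3 * s),
            class = "efficacy_null")
}

#' @export
print.efficacy_null <- function(x, ...) {
  cat(sprintf(
    "Null distribution of mean effects: center %.4g, sd %.4g\n", x$center,
    x$sd))
  cat(sprintf("Efficacy cutoff (center - 3 sd): %.4g\n", x$cutoff))
  invisible(x)
}

#' Flag guides whose binding window overlaps a variant
#'
#' Guides designed against the reference allele bind imperfectly over a
#' polymorphic site, so apparent background effects at such sites reflect
#' binding-site disruption rather than biology; they are excluded from
#' effect modelling.
#'
#' @param guide_library list from [simulate_guide_library()] (or any list
#'   with a `guides` data.frame carrying `guide`, `chrom`, `pos`).
#' @param variants data.frame with `chrom`, `pos` of known variant sites.
#' @param window_size guide binding window width in nt.
#' @return character vector of excluded guide ids.
#' @export
flag_polymorphic_guides <- function(guide_library, variants,
                                    window_size = 20) {
  g <- guide_library$guides
  hit <- vapply(seq_len(nrow(g)), function(i) {
    v <- variants[variants$chrom == g$chrom[i], "pos"]
    any(v >= g$pos[i] & v <= g$pos[i] + window_size - 1L)
  }, logical(1))
  g$guide[hit]
}

#' Test all guides for mean and background effects
#'
#' Runs [test_guide()] per guide on the CON-vs-induced contrast, applies BH
#' correction separately to the mean-effect family (all tested guides) and
#' the interaction family (guides with significant mean effects), derives
#' the efficacy threshold from the fitted null, and extracts per-segregant
#' deviation values for guides with significant background effects.
#'
#' @param fitness_list named list of `lineage_fitness` objects normalised by
#'   [normalize_assays()]; must contain `"CON"` and `assay`.
#' @param assay induced assay to contrast against CON (default `"ATC1"`).
#' @param exclude guide ids to skip (e.g. polymorphic-site guides).
#' @param fdr FDR level for both families.
#' @param min_segregants minimum segregants with deviations per guide.
#' @param deviation_method `"blup"` or `"fixed"` (see
#'   [compute_deviations()]).
#' @param null_center passed to [efficacy_threshold()].
#' @return object of class `guide_effects`: list with `results` (per-guide
#'   data.frame), `deviations` (segregant x guide matrix, NA for missing),
#'   `null` (`efficacy_null`), `assay`.
#' @export
guide_effects <- function(fitness_list, assay = "ATC1", exclude = character(0),
                          fdr = 0.05, min_segregants = 35,
                          deviation_method = "blup",
                          null_center = "median") {
  stopifnot("CON" %in% names(fitness_list), assay %in% names(fitness_list))
  con <- fitness_list$CON$fitness
  atc <- fitness_list[[assay]]$fitness
  con <- con[con$flag == "" & !is.na(con$fitness), ]
  atc <- atc[atc$flag == "" & !is.na(atc$fitness), ]
  guides <- sort(setdiff(intersect(unique(con$guide), unique(atc$guide)),
                         exclude))
  rows <- vector("list", length(guides))
  devs <- vector("list", length(guides))
  for (i in seq_along(guides)) {
    g <- guides[i]
    dc <- con[con$guide == g, ]
    da <- atc[atc$guide == g, ]
    fitv <- c(dc$fitness, da$fitness)
    segv <- c(dc$segregant, da$segregant)
    indv <- c(rep(0, nrow(dc)), rep(1, nrow(da)))
    tg <- tryCatch(test_guide(fitv, segv, indv), error = function(e) NULL)
    if (is.null(tg)) {
      rows[[i]] <- data.frame(guide = g, m_hat = NA_real_, p_mean = NA_real_,
                              p_interaction = NA_real_, model = NA,
                              n_segregants = NA_integer_, singular = TRUE,
                              stringsAsFactors = FALSE)
      next
    }
    rows[[i]] <- data.frame(guide = g, m_hat = tg$m_hat, p_mean = tg$p_mean,
                            p_interaction = tg$p_interaction,
                            model = tg$model,
                            n_segregants = tg$n_segregants,
                            singular = tg$singular, stringsAsFactors = FALSE)
    devs[[i]] <- list(fit = tg$fit_interaction, fitness = fitv,
                      segregant = segv, induced = indv)
  }
  res <- do.call(rbind, rows)
  res$q_mean <- adjust_fdr(res$p_mean)
  null <- efficacy_threshold(res$m_hat, center = null_center)
  res$efficacious <- !is.na(res$q_mean) & res$q_mean < fdr &
    !is.na(res$m_hat) & res$m_hat < null$cutoff
  res$q_interaction <- NA_real_
  fam <- which(res$efficacious & !is.na(res$p_interaction))
  res$q_interaction[fam] <- adjust_fdr(res$p_interaction[fam])
  res$background <- !is.na(res$q_interaction) & res$q_interaction < fdr

  segs <- sort(unique(c(con$segregant, atc$segregant)))
  dev_mat <- matrix(NA_real_, length(segs), length(guides),
                    dimnames = list(segs, guides))
  for (i in which(res$background)) {
    di <- devs[[i]]
    d <- compute_deviations(di$fitness, di$segregant, di$induced,
                            fit_interaction = di$fit,
                            method = deviation_method,
                            min_segregants = min_segregants)
    if (is.null(d)) {
      res$background[i] <- FALSE
      res$model[i] <- paste0(res$model[i], ";few_deviations")
      next
    }
    dev_mat[names(d), i] <- d
  }
  dev_mat <- dev_mat[, res$background, drop = FALSE]
  res$n_deviations <- NA_integer_
  res$n_deviations[match(colnames(dev_mat), res$guide)] <-
    colSums(!is.na(dev_mat))
  structure(list(results = res, deviations = dev_mat, null = null,
                 assay = assay, fdr = fdr),
            class = "guide_effects")
}

#' @export
print.guide_effects <- function(x, ...) {
  r <- x$results
  cat("Guide effect tests (", x$assay, " vs CON):", nrow(r), "guides\n")
  cat(sprintf("  efficacious: %d (q < %.2g and m < %.3g)\n",
              sum(r$efficacious, na.rm = TRUE), x$fdr, x$null$cutoff))
  cat("  background effects:", sum(r$background, na.rm = TRUE),
      "guides with deviations for", nrow(x$deviations), "segregants\n")
  invisible(x)
}

#' Structure of deviation values: baseline coupling and dispersion
#'
#' Two regressions summarising what shapes background effects: (1) pooled
#' deviation values against the baseline fitness of the segregant (a
#' negative slope means the same perturbation is more detrimental in fitter
#' backgrounds); (2) the per-guide standard deviation of deviations against
#' |mean effect| (a positive slope means more severe perturbations have
#' more variable effects across backgrounds).
#'
#' @param deviations segregant x guide deviation matrix.
#' @param baseline named per-segregant baseline fitness.
#' @param m_hat named per-guide mean effects.
#' @return list with `baseline_slope`, `baseline_r2`, `dispersion_slope`,
#'   `dispersion_r2`.
#' @export
deviation_structure <- function(deviations, baseline, m_hat) {
  segs <- intersect(rownames(deviations), names(baseline))
  D <- deviations[segs, , drop = FALSE]
  b <- baseline[segs]
  long_d <- as.numeric(D)
  long_b <- rep(b, times = ncol(D))
  ok <- !is.na(long_d)
  f1 <- stats::lm(long_d[ok] ~ long_b[ok])
  sd_g <- apply(D, 2, stats::sd, na.rm = TRUE)
  am <- abs(m_hat[colnames(D)])
  f2 <- stats::lm(sd_g ~ am)
  list(baseline_slope = unname(stats::coef(f1)[2]),
       baseline_r2 = summary(f1)$r.squared,
       dispersion_slope = unname(stats::coef(f2)[2]),
       dispersion_r2 = summary(f2)$r.squared)
}

#' Select one guide per targeted gene
#'
#' Keeps, per gene, the guide with the most significant background effect
#' (smallest interaction q); ties are broken by the presence of mapped loci,
#' then by guide id.
#'
#' @param effects a `guide_effects` object.
#' @param guide_library guide library (for the gene map).
#' @param mapped_guides optional character vector of guides with at least
#'   one mapped locus (tie-break preference).
#' @return character vector of selected guide ids (one per gene).
#' @export
select_guide_per_gene <- function(effects, guide_library,
                                  mapped_guides = character(0)) {
  r <- effects$results[effects$results$background, , drop = FALSE]
  if (nrow(r) == 0) return(character(0))
  g <- guide_library$guides
  r$gene <- g$gene[match(r$guide, g$guide)]
  r <- r[!is.na(r$gene), , drop = FALSE]
  r$mapped <- r$guide %in% mapped_guides
  r <- r[order(r$gene, r$q_interaction, !r$mapped, r$guide), ]
  r$guide[!duplicated(r$gene)]
}
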