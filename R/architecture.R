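#' Configuration for a simulated effect architecture
#'
#' Collects the generative parameters of the fitness model used by the
#' simulator. Fitness is on a per-generation natural-log scale throughout.
#'
#' The generative trait for a lineage of segregant s carrying guide g is
#' \deqn{fitness = b_s + induced (m_g + \kappa b_s + \sum_l \beta_{g,l} x_{s,l}
#'   + \epsilon),\quad \epsilon \sim N(0, (\tau |m_g| + \sigma_{lin})^2)}
#' where \eqn{b_s} is the baseline fitness of the segregant, \eqn{m_g} the
#' mean guide effect, \eqn{\kappa} couples the induced deviation to baseline
#' fitness (more detrimental in fitter backgrounds when negative), and
#' \eqn{\tau} makes the deviation spread grow with the magnitude of the mean
#' effect.
#'
#' @param n_qtl number of baseline-fitness QTL.
#' @param qtl_effect_range range of additive QTL effects (3S allele adds a
#'   draw from this range, per generation).
#' @param sigma_b SD of the non-QTL residual of baseline fitness.
#' @param frac_efficacious fraction of non-control guides with a mean effect.
#' @param m_range range of |mean effect| for efficacious guides (effects are
#'   negative: all targets are essential genes).
#' @param hub_styles character vector, one entry per hub, each
#'   `"amplifying"` or `"masking"`.
#' @param guides_per_hub interacting guides per hub (disjoint sets);
#'   default 18, the smallest hub membership the assay design is meant to
#'   resolve.
#' @param amp_slope for amplifying hubs, |beta| = amp_slope * |m_g| (3S
#'   allele beneficial under induction).
#' @param mask_rate for masking hubs, the induced allele effect is
#'   a * max(0, 1 - mask_rate * |m_g|) where a is the hub's baseline QTL
#'   effect. The default of 3 attenuates the locus fully at the severe end
#'   of the mean-effect range (|m| = 1/3).
#' @param mask_qtl_effect baseline allele effect of the QTL a masking hub
#'   sits on. Masking hubs are major fitness loci (detectable in a baseline
#'   scan and explaining a sizeable share of baseline fitness variance), so
#'   their anchor QTL takes this fixed effect rather than a draw from
#'   `qtl_effect_range`.
#' @param kappa baseline-coupling slope (deviation per unit baseline fitness).
#' @param tau dispersion slope (deviation SD per unit |m_g|). This is a
#'   combination-level dispersion: each segregant-guide pair draws one
#'   repeatable residual interaction effect with SD `tau * |m_g|`, shared
#'   by its replicate barcode lineages and by replicate induced assays (it
#'   stands in for unmodelled higher-order epistasis).
#' @param sigma_lin per-lineage noise SD (independent across barcodes).
#' @param frac_leaky fraction of efficacious guides whose effect is also
#'   expressed without induction (off by default).
#' @return list of class `arch_config`.
#' @export
arch_config <- function(n_qtl = 3, qtl_effect_range = c(0.02, 0.05),
                        sigma_b = 0.02, frac_efficacious = 0.33,
                        m_range = c(0.05, 0.35),
                        hub_styles = c("amplifying", "masking"),
                        guides_per_hub = 18, amp_slope = 0.4,
                        mask_rate = 3, mask_qtl_effect = 0.065,
                        kappa = -0.3, tau = 0.25,
                        sigma_lin = 0.01, frac_leaky = 0) {
  structure(list(n_qtl = n_qtl, qtl_effect_range = qtl_effect_range,
                 sigma_b = sigma_b, frac_efficacious = frac_efficacious,
                 m_range = m_range, hub_styles = hub_styles,
                 guides_per_hub = guides_per_hub, amp_slope = amp_slope,
                 mask_rate = mask_rate, mask_qtl_effect = mask_qtl_effect,
                 kappa = kappa, tau = tau,
                 sigma_lin = sigma_lin, frac_leaky = frac_leaky),
            class = "arch_config")
}

#' Simulate an effect architecture with retained ground truth
#'
#' Draws baseline fitness QTL, mean guide effects, and hub interaction
#' effects over a genotype matrix and guide library. Amplifying hubs carry no
#' additive fitness effect; their interaction effect on induced fitness of
#' the 3S allele grows with |m_g|. Masking hubs are themselves baseline
#' fitness QTL whose allele effect is attenuated proportionally to |m_g|
#' under induction, i.e. the induced allele effect is
#' `a * max(0, 1 - mask_rate * |m_g|)`.
#'
#' @param genotypes 0/1 matrix from [simulate_cross()].
#' @param guide_library list from [simulate_guide_library()].
#' @param config an [arch_config()].
#' @param seed integer seed.
#' @return object of class `effect_architecture`: list with `b` (named
#'   baseline fitness per segregant), `qtl` (marker, effect), `m` (named mean
#'   effect per guide), `interactions` (guide, marker, beta), `hubs` (hub,
#'   marker, style), `kappa`, `tau`, `sigma_lin`, `leaky` (guide ids), and
#'   the genotype matrix used.
#' @export
simulate_architecture <- function(genotypes, guide_library,
                                  config = arch_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  markers <- colnames(genotypes)
  n_hub <- length(config$hub_styles)
  if (config$n_qtl + n_hub > length(markers)) {
    stop("more hubs/QTL than markers")
  }
  guides <- guide_library$guides

  # masking hubs must sit on a fitness QTL; draw QTL markers first and
  # reserve one per masking hub
  n_mask <- sum(config$hub_styles == "masking")
  n_qtl <- max(config$n_qtl, n_mask)
  qtl_markers <- if (n_qtl > 0) sample(markers, n_qtl) else character(0)
  qtl_effects <- stats::runif(n_qtl, config$qtl_effect_range[1],
                              config$qtl_effect_range[2])
  # masking hubs are major fitness loci: their anchor QTL (the first
  # n_mask markers) take the fixed major-locus effect
  if (n_mask > 0) qtl_effects[seq_len(n_mask)] <- config$mask_qtl_effect
  b <- as.numeric(genotypes[, qtl_markers, drop = FALSE] %*% qtl_effects) +
    stats::rnorm(nrow(genotypes), 0, config$sigma_b)
  b <- b - mean(b)
  names(b) <- rownames(genotypes)

  # mean guide effects: controls 0, a fraction of targets efficacious
  m <- stats::setNames(numeric(nrow(guides)), guides$guide)
  targets <- guides$guide[!guides$control]
  n_eff <- round(config$frac_efficacious * length(targets))
  efficacious <- if (n_eff > 0) sample(targets, n_eff) else character(0)
  m[efficacious] <- -stats::runif(n_eff, config$m_range[1],
                                  config$m_range[2])

  # hubs and interaction effects (disjoint guide sets, efficacious only).
  # amplifying hubs are not fitness loci; keep them off QTL-bearing
  # chromosomes so baseline-coupling signal cannot shadow them
  qtl_chrom <- sub("_[0-9]+$", "", qtl_markers)
  hub_pool <- markers[!(sub("_[0-9]+$", "", markers) %in% qtl_chrom)]
  if (length(hub_pool) == 0) hub_pool <- setdiff(markers, qtl_markers)
  mask_markers <- if (n_mask > 0) qtl_markers[seq_len(n_mask)] else character(0)
  n_amp <- n_hub - n_mask
  amp_markers <- if (n_amp > 0) sample(hub_pool, n_amp) else character(0)
  hub_marker <- character(n_hub); i_a <- 0L; i_m <- 0L
  for (h in seq_len(n_hub)) {
    if (config$hub_styles[h] == "masking") {
      i_m <- i_m + 1L; hub_marker[h] <- mask_markers[i_m]
    } else {
      i_a <- i_a + 1L; hub_marker[h] <- amp_markers[i_a]
    }
  }
  hubs <- data.frame(hub = sprintf("hub%d", seq_len(n_hub)),
                     marker = hub_marker, style = config$hub_styles,
                     stringsAsFactors = FALSE)
  inter <- list()
  avail <- efficacious
  for (h in seq_len(n_hub)) {
    k <- min(config$guides_per_hub, length(avail))
    if (k == 0) break
    gset <- sample(avail, k)
    avail <- setdiff(avail, gset)
    if (config$hub_styles[h] == "amplifying") {
      beta <- config$amp_slope * abs(m[gset])
    } else {
      # the realized allele contrast under induction is
      # (1 + kappa) a + beta; choose beta so that it equals
      # a * max(0, 1 - mask_rate |m|), the attenuated locus effect
      a <- qtl_effects[match(hub_marker[h], qtl_markers)]
      beta <- a * pmax(0, 1 - config$mask_rate * abs(m[gset])) -
        (1 + config$kappa) * a
    }
    inter[[h]] <- data.frame(guide = gset, marker = hub_marker[h],
                             beta = as.numeric(beta),
                             hub = hubs$hub[h], stringsAsFactors = FALSE)
  }
  interactions <- if (length(inter)) do.call(rbind, inter) else
    data.frame(guide = character(0), marker = character(0),
               beta = numeric(0), hub = character(0))
  rownames(interactions) <- NULL

  leaky <- character(0)
  if (config$frac_leaky > 0 && length(efficacious) > 0) {
    leaky <- sample(efficacious,
                    round(config$frac_leaky * length(efficacious)))
  }
  # repeatable combination-level residual interaction (tau dispersion)
  eps_combo <- matrix(
    stats::rnorm(nrow(genotypes) * nrow(guides), 0,
                 rep(config$tau * abs(m), each = nrow(genotypes))),
    nrow(genotypes), nrow(guides),
    dimnames = list(rownames(genotypes), guides$guide))
  structure(list(b = b,
                 qtl = data.frame(marker = qtl_markers, effect = qtl_effects,
                                  stringsAsFactors = FALSE),
                 m = m, interactions = interactions, hubs = hubs,
                 kappa = config$kappa, tau = config$tau,
                 sigma_lin = config$sigma_lin, leaky = leaky,
                 eps_combo = eps_combo,
                 genotypes = genotypes, config = config),
            class = "effect_architecture")
}

#' @export
print.effect_architecture <- function(x, ...) {
  cat("Effect architecture:", length(x$b), "segregants,",
      length(x$m), "guides\n")
  cat("  baseline QTL:", nrow(x$qtl),
      " efficacious guides:", sum(x$m < 0), "\n")
  if (nrow(x$hubs)) {
    cat("  hubs:\n")
    for (h in seq_len(nrow(x$hubs))) {
      cat("   ", x$hubs$hub[h], x$hubs$style[h], "at", x$hubs$marker[h],
          "with", sum(x$interactions$hub == x$hubs$hub[h]), "guides\n")
    }
  }
  cat("  kappa =", x$kappa, " tau =", x$tau,
      " sigma_lin =", x$sigma_lin, "\n")
  invisible(x)
}

#' Expected fitness of a segregant-guide combination
#'
#' Evaluates the generative model (see [arch_config()]) at a given lineage
#' noise value. Without induction the fitness equals the segregant's
#' baseline fitness exactly (unless the guide is marked leaky).
#'
#' @param arch an `effect_architecture`.
#' @param segregant,guide ids present in the architecture.
#' @param induced logical; is the guide expressed?
#' @param eps lineage noise value (default 0 gives the expectation).
#' @return fitness per generation (natural log scale).
#' @export
true_fitness <- function(arch, segregant, guide, induced, eps = 0) {
  if (!segregant %in% names(arch$b)) stop("unknown segregant: ", segregant)
  if (!guide %in% names(arch$m)) stop("unknown guide: ", guide)
  b <- arch$b[[segregant]]
  on <- induced || guide %in% arch$leaky
  if (!on) return(b)
  ints <- arch$interactions[arch$interactions$guide == guide, , drop = FALSE]
  bx <- if (nrow(ints)) {
    sum(ints$beta * arch$genotypes[segregant, ints$marker])
  } else 0
  g_on <- arch$m[[guide]] != 0 || nrow(ints) > 0
  ec <- if (is.null(arch$eps_combo)) 0 else arch$eps_combo[segregant, guide]
  # controls with kappa: coupling applies only to guides that do something
  b + arch$m[[guide]] + (if (g_on) arch$kappa * b else 0) + bx + ec + eps
}

#' Per-lineage induced/uninduced fitness for a whole panel (vectorised)
#'
#' @param arch an `effect_architecture`.
#' @param segregant,guide equal-length id vectors (one entry per lineage).
#' @param induced logical scalar.
#' @param eps numeric vector of lineage noise values (default all 0).
#' @return numeric vector of fitnesses.
#' @keywords internal
true_fitness_vec <- function(arch, segregant, guide, induced, eps = 0) {
  b <- arch$b[segregant]
  if (!induced) {
    on <- guide %in% arch$leaky
    if (!any(on)) return(unname(b))
  } else {
    on <- rep(TRUE, length(guide))
  }
  m <- arch$m[guide]
  bx <- numeric(length(guide))
  if (nrow(arch$interactions)) {
    key <- split(seq_len(nrow(arch$interactions)), arch$interactions$guide)
    for (g in names(key)) {
      rows <- arch$interactions[key[[g]], , drop = FALSE]
      sel <- which(guide == g)
      if (length(sel)) {
        x <- arch$genotypes[segregant[sel], rows$marker, drop = FALSE]
        bx[sel] <- as.numeric(x %*% rows$beta)
      }
    }
  }
  active <- m != 0 | bx != 0
  ec <- if (is.null(arch$eps_combo)) 0 else
    arch$eps_combo[cbind(segregant, guide)]
  eps <- rep_len(eps, length(guide))
  unname(b + on * (m + ifelse(active, arch$kappa * b, 0) + bx + ec + eps))
}
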