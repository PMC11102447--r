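#' Estimate per-lineage relative fitness from count trajectories
#'
#' Implements an iterative lineage-trajectory model in the FitSeq family:
#' each lineage has a constant fitness \eqn{s_i} (per generation, natural
#' log) while the mean population fitness \eqn{\bar s(t)} varies over time
#' with lineage frequencies. Whole trajectories are projected,
#' \eqn{\hat n_i(t+\Delta) = \hat n_i(t) e^{(s_i - \bar s(t)) \Delta}},
#' anchored at a fitted starting abundance \eqn{\hat n_i(0)} (a per-lineage
#' nuisance parameter: conditioning on the observed T0 count would treat a
#' noisy draw as exact), and \eqn{(\hat n_i(0), s_i)} are updated jointly
#' to minimise the Poisson deviance between the projected and observed
#' trajectory, T0 included. Initialisation is the observed T0 count and
#' the least-squares slope of log frequency against generations
#' (pseudocount 0.5 on zero counts). Reported fitness is centred so the
#' T0-frequency-weighted mean is zero.
#'
#' @param counts a `lineage_counts` object (typically depth-normalised).
#' @param generations time points in generations; defaults to the table's
#'   `timepoints` attribute.
#' @param max_iter maximum outer iterations.
#' @param tol convergence tolerance on max |change in s|.
#' @return object of class `lineage_fitness`: list with `fitness`
#'   (data.frame: `lineage_id`, `segregant`, `guide`, `assay`, `fitness`,
#'   `score`, `t0`, `flag`), `trajectory` (mean fitness per time point and
#'   fitted frequencies), `deviance` trace and `iterations`.
#' @examples
#' \donttest{
#' map <- marker_map(2, 8); G <- simulate_cross(20, map, seed = 1)
#' lib <- simulate_guide_library(12, map, n_controls = 3, seed = 1)
#' sb <- simulate_segregant_barcodes(rownames(G), seed = 1)
#' arch <- simulate_architecture(G, lib, seed = 1)
#' cfg <- sim_config(depth = 1e5, seed = 1)
#' cn <- simulate_assay(arch, lib, sb, cfg, induced = TRUE)
#' fit <- estimate_fitness(cn)
#' summary(fit)
#' }
#' @export
estimate_fitness <- function(counts, generations = NULL, max_iter = 200,
                             tol = 1e-6) {
  N <- count_matrix(counts)
  if (is.null(generations)) generations <- attr(counts, "timepoints")
  stopifnot(length(generations) == ncol(N))
  L <- nrow(N); TT <- ncol(N)
  dt <- diff(generations)
  alive <- rowSums(N) > 0

  # initial slope of log frequency (pseudocount 0.5 on zeros)
  Np <- N; Np[Np == 0] <- 0.5
  lf <- log(sweep(Np, 2, colSums(N), "/"))
  tc <- generations - mean(generations)
  s <- as.numeric((lf %*% tc) / sum(tc^2))
  s[!alive] <- NA_real_

  f_obs <- sweep(N, 2, colSums(N), "/")
  s <- s - sum(f_obs[, 1] * ifelse(is.na(s), 0, s)) /
    sum(f_obs[!is.na(s), 1])

  trel <- generations - generations[1]
  Tm <- matrix(trel, L, TT, byrow = TRUE)
  a <- log(pmax(N[, 1], 0.5))   # log anchor; pseudo half-count at T0 = 0
  okrow <- alive

  dev_of <- function(s, a) {
    sa <- ifelse(is.na(s), 0, s)
    sbar <- as.numeric(crossprod(f_obs, sa))
    cum <- c(0, cumsum(sbar[-TT] * dt))
    mu <- exp(a + outer(sa, trel) - rep(cum, each = L))
    d <- 2 * (mu - N + ifelse(N > 0 & mu > 0, N * log(N / mu), 0))
    list(dev = sum(d[okrow, , drop = FALSE]), mu = mu, sbar = sbar)
  }

  # a lineage whose expected reads fall below half a read by the end of
  # the assay is at the assay's resolution limit: its deviance is flat in
  # s below that point (the MLE for a crashed trajectory is -Inf), so s is
  # floored at the least-extreme value consistent with extinction
  tot_gen <- generations[TT] - generations[1]
  s_cap <- 2
  cur <- dev_of(s, a)
  dev_trace <- cur$dev
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    sbar <- cur$sbar
    cum <- c(0, cumsum(sbar[-TT] * dt))
    # joint (anchor, fitness) Newton on the Poisson deviance per lineage,
    # all lineages at once
    s_new <- ifelse(is.na(s), NA_real_, s)
    a_new <- a
    for (nw in 1:50) {
      s_floor <- (log(0.5) - a_new + cum[TT]) / tot_gen
      mu <- exp(a_new + outer(ifelse(is.na(s_new), 0, s_new), trel) -
                  rep(cum, each = L))
      ga <- rowSums(mu - N)
      gs <- rowSums((mu - N) * Tm)
      haa <- rowSums(mu)
      has <- rowSums(mu * Tm)
      hss <- rowSums(mu * Tm^2)
      det <- pmax(haa * hss - has^2, 1e-12)
      d_a <- pmax(pmin((hss * ga - has * gs) / det, 1), -1)
      d_s <- pmax(pmin((haa * gs - has * ga) / det, 0.3), -0.3)
      s_prev_in <- s_new
      a_new <- a_new - d_a
      s_new <- pmin(pmax(s_new - d_s, s_floor), s_cap)
      if (max(abs(s_new - s_prev_in), na.rm = TRUE) < 1e-10) break
    }
    # damped acceptance: the mean-fitness profile moves with s, so guard
    # against overshoot by halving toward the previous iterate
    cand <- s_new; cand_a <- a_new
    improved <- FALSE
    for (half in 0:20) {
      nxt <- dev_of(cand, cand_a)
      if (nxt$dev <= cur$dev + 1e-9 * max(1, abs(cur$dev))) {
        improved <- TRUE
        break
      }
      cand <- (cand + s) / 2
      cand_a <- (cand_a + a) / 2
    }
    if (!improved) break  # stalled: keep the previous iterate
    # pin the gauge: the model only identifies fitness differences, so
    # re-centre to T0-frequency-weighted mean 0 every iteration
    w0 <- f_obs[, 1]
    cand <- cand - sum(w0 * ifelse(is.na(cand), 0, cand)) /
      sum(w0[!is.na(cand)])
    delta <- max(abs(cand - s), na.rm = TRUE)
    s <- cand; a <- cand_a
    cur <- dev_of(s, a)
    dev_trace <- c(dev_trace, cur$dev)
    if (delta < tol) break
  }

  # centre: T0-frequency-weighted mean fitness is 0
  w0 <- f_obs[, 1]
  s <- s - sum(w0 * ifelse(is.na(s), 0, s)) / sum(w0[!is.na(s)])

  # per-lineage fit score: total Poisson log-likelihood of the trajectory
  sc <- dev_of(s, a)
  mu <- sc$mu
  ll <- ifelse(mu > 0, N * log(mu) - mu - lgamma(N + 1), 0)
  score <- rowSums(ll)
  score[!alive] <- NA_real_

  fitness <- data.frame(
    lineage_id = counts$lineage_id, segregant = counts$segregant,
    guide = counts$guide, assay = counts$assay,
    fitness = s, score = score, t0 = N[, 1],
    flag = ifelse(alive, "", "all_zero"), stringsAsFactors = FALSE)
  f_hat <- sweep(sc$mu, 2, colSums(sc$mu), "/")
  structure(list(fitness = fitness,
                 trajectory = list(generations = generations,
                                   mean_fitness = sc$sbar,
                                   fitted_freq = f_hat),
                 deviance = dev_trace, iterations = iters),
            class = "lineage_fitness")
}

#' @export
print.lineage_fitness <- function(x, ...) {
  cat("Lineage fitness estimates:", nrow(x$fitness), "lineages,",
      x$iterations, "iterations\n")
  cat("  mean population fitness by time point:",
      paste(signif(x$trajectory$mean_fitness, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.lineage_fitness <- function(object, ...) {
  s <- object$fitness$fitness
  cat("Fitness (per generation):\n")
  print(summary(s))
  cat("Flagged lineages:", sum(object$fitness$flag != ""), "\n")
  invisible(object)
}

#' Quality-control filtering of lineage fitness estimates
#'
#' Applies, in order: removal of lineages whose fit score falls below
#' Q1 - 1 IQR of all fit scores; removal of lineages with a T0 count below
#' `min_t0`; then iterated removal of all lineages of segregants with fewer
#' than `min_guides_per_segregant` distinct guides and of guides with fewer
#' than `min_segregants_per_guide` distinct segregants, to a fixed point.
#' Removal is by flag only; no rows are dropped silently.
#'
#' @param fit a `lineage_fitness` object.
#' @param raw_t0 optional vector of raw (pre-normalisation) T0 counts named
#'   by lineage id; defaults to the `t0` column of the fit.
#' @param min_t0 minimum T0 reads.
#' @param min_guides_per_segregant,min_segregants_per_guide breadth filters.
#' @return the `lineage_fitness` object with updated `flag` column and a
#'   `removals` element counting each removal class.
#' @export
qc_filter <- function(fit, raw_t0 = NULL, min_t0 = 5,
                      min_guides_per_segregant = 100,
                      min_segregants_per_guide = 2) {
  d <- fit$fitness
  if (is.null(raw_t0)) {
    t0 <- d$t0
  } else {
    t0 <- raw_t0[d$lineage_id]
  }
  flag <- ifelse(d$flag == "", "", d$flag)
  q <- stats::quantile(d$score, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  thr <- q[1] - (q[2] - q[1])
  poor <- !is.na(d$score) & d$score < thr
  flag[poor & flag == ""] <- "poor_fit"
  low <- !is.na(t0) & t0 < min_t0
  flag[low & flag == ""] <- "low_t0"
  repeat {
    keep <- flag == ""
    gps <- tapply(d$guide[keep], d$segregant[keep],
                  function(g) length(unique(g)))
    bad_seg <- names(gps)[gps < min_guides_per_segregant]
    spg <- tapply(d$segregant[keep], d$guide[keep],
                  function(s) length(unique(s)))
    bad_gui <- names(spg)[spg < min_segregants_per_guide]
    hit_s <- keep & d$segregant %in% bad_seg
    hit_g <- keep & d$guide %in% bad_gui
    if (!any(hit_s) && !any(hit_g)) break
    flag[hit_s] <- "removed_segregant"
    flag[hit_g & flag == ""] <- "removed_guide"
  }
  if (all(flag != "")) {
    stop("qc_filter removed every lineage (",
         paste(names(table(flag)), table(flag), collapse = ", "), ")")
  }
  fit$fitness$flag <- flag
  fit$removals <- table(flag[flag != ""])
  fit
}

#' Normalise fitness across assays via control guides
#'
#' Fitness estimates are relative to each assay's own population mean, so
#' assays are put on a common scale using control guides (targeting
#' intergenic and noncoding DNA). Per control guide and assay, the mean
#' fitness of its lineages is taken; control guides whose average fitness is
#' below zero and inconsistent between induced and control assays (absolute
#' CON-vs-ATC difference beyond `sd_rule` SDs of all control differences)
#' are dropped; each induced assay is shifted by the difference of retained
#' control medians against CON; finally all assays are shifted together so
#' the mean CON lineage fitness is exactly zero.
#'
#' @param fitness_list named list of `lineage_fitness` objects; must contain
#'   `"CON"` plus at least one induced assay.
#' @param control_guides character vector of control guide ids.
#' @param sd_rule SD multiple defining "inconsistent" control guides.
#' @param use_flagged include QC-flagged lineages (default FALSE).
#' @return the list with adjusted fitness values; attribute `normalization`
#'   records shifts and retained controls.
#' @export
normalize_assays <- function(fitness_list, control_guides, sd_rule = 2,
                             use_flagged = FALSE) {
  stopifnot("CON" %in% names(fitness_list))
  ctrl_mean <- function(fit) {
    d <- fit$fitness
    if (!use_flagged) d <- d[d$flag == "", , drop = FALSE]
    d <- d[d$guide %in% control_guides, , drop = FALSE]
    tapply(d$fitness, d$guide, mean, na.rm = TRUE)
  }
  means <- lapply(fitness_list, ctrl_mean)
  common <- Reduce(intersect, lapply(means, names))
  if (length(common) == 0) stop("no control guides shared across assays")
  atc <- setdiff(names(fitness_list), "CON")
  diffs <- sapply(atc, function(a) means[[a]][common] - means$CON[common])
  diffs <- matrix(diffs, nrow = length(common))
  overall <- rowMeans(sapply(names(fitness_list),
                             function(a) means[[a]][common]))
  sd_all <- stats::sd(as.numeric(diffs))
  incons <- apply(abs(diffs), 1, max) > sd_rule * sd_all
  drop <- overall < 0 & incons
  retained <- common[!drop]
  if (length(retained) == 0) stop("no control guides retained")
  if (length(retained) < 10) {
    warning("fewer than 10 control guides retained")
  }
  shifts <- stats::setNames(numeric(length(atc)), atc)
  for (a in atc) {
    shifts[a] <- stats::median(means[[a]][retained]) -
      stats::median(means$CON[retained])
    fitness_list[[a]]$fitness$fitness <-
      fitness_list[[a]]$fitness$fitness - shifts[a]
  }
  con <- fitness_list$CON$fitness
  keep <- if (use_flagged) rep(TRUE, nrow(con)) else con$flag == ""
  global <- mean(con$fitness[keep], na.rm = TRUE)
  for (a in names(fitness_list)) {
    fitness_list[[a]]$fitness$fitness <-
      fitness_list[[a]]$fitness$fitness - global
  }
  attr(fitness_list, "normalization") <-
    list(shifts = shifts, global = global, retained_controls = retained,
         dropped_controls = common[drop])
  fitness_list
}
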