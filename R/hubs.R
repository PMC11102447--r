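#' Interval overlap counts at marker positions
#'
#' For each marker, the number of peak intervals (closed, in bp) covering
#' its position.
#'
#' @param peaks a `linkage_peaks` data.frame (needs `chrom`, `start`,
#'   `end`); cis-excluded rows should be removed by the caller.
#' @param map marker map.
#' @return data.frame `marker`, `chrom`, `pos`, `count`.
#' @export
overlap_profile <- function(peaks, map) {
  if (nrow(peaks)) {
    gl <- tapply(map$pos, map$chrom, max)
    if (any(peaks$start > peaks$end) || any(peaks$start < 1) ||
        any(peaks$end > gl[peaks$chrom])) {
      stop("interval outside genome")
    }
  }
  count <- integer(nrow(map))
  for (i in seq_len(nrow(peaks))) {
    hit <- map$chrom == peaks$chrom[i] & map$pos >= peaks$start[i] &
      map$pos <= peaks$end[i]
    count[hit] <- count[hit] + 1L
  }
  data.frame(marker = map$marker, chrom = map$chrom, pos = map$pos,
             count = count, stringsAsFactors = FALSE)
}

#' Poisson threshold for hub calling
#'
#' The genome is split into bins and a per-bin significance level of
#' `alpha / n_bins` is applied to a Poisson model of interval overlaps with
#' rate lambda = (total interval length) / (genome length). The minimum
#' significant overlap count k is the smallest integer with
#' P(X >= k) < alpha / n_bins.
#'
#' @param peaks `linkage_peaks` rows whose intervals enter the profile.
#' @param genome_len genome length in bp.
#' @param bin_size bin width in bp.
#' @param alpha family-wise significance level.
#' @return list of class `hub_params`: `lambda`, `n_bins`, `threshold`
#'   (per-bin p cutoff), `k`, `bin_size`, `alpha`.
#' @export
hub_count_threshold <- function(peaks, genome_len, bin_size = 2e4,
                                alpha = 0.05) {
  stopifnot(genome_len > 0)
  total <- if (nrow(peaks)) sum(peaks$end - peaks$start + 1) else 0
  lambda <- total / genome_len
  if (nrow(peaks) > 0 && lambda <= 0) stop("lambda <= 0 with intervals")
  n_bins <- ceiling(genome_len / bin_size)
  thr <- alpha / n_bins
  k <- 1L
  while (stats::ppois(k - 1, lambda, lower.tail = FALSE) >= thr) {
    k <- k + 1L
  }
  structure(list(lambda = lambda, n_bins = n_bins, threshold = thr, k = k,
                 bin_size = bin_size, alpha = alpha), class = "hub_params")
}

#' @export
print.hub_params <- function(x, ...) {
  cat(sprintf(
    "Hub threshold: lambda = %.4g over %d bins (p < %.3g) -> k = %d\n",
    x$lambda, x$n_bins, x$threshold, x$k))
  invisible(x)
}

#' Call hub loci from an overlap profile
#'
#' Maximal runs of adjacent markers (consecutive on one chromosome) with
#' overlap count >= k become hubs. The hub marker is the position with the
#' highest count; ties are resolved to the tied marker closest to the mean
#' of the tied positions. Members are the traits whose intervals overlap
#' the hub marker.
#'
#' @param profile from [overlap_profile()].
#' @param params from [hub_count_threshold()].
#' @param peaks the `linkage_peaks` the profile was built from.
#' @return data.frame of class `hub_set`: one row per hub with `hub`,
#'   `chrom`, `start`, `end`, `marker`, `pos`, `count`, `n_members`, and a
#'   `members` list-column of trait ids.
#' @export
call_hubs <- function(profile, params, peaks) {
  hot <- profile$count >= params$k
  runs <- list()
  i <- 1L
  n <- nrow(profile)
  while (i <= n) {
    if (hot[i]) {
      j <- i
      while (j < n && hot[j + 1] && profile$chrom[j + 1] == profile$chrom[i]) {
        j <- j + 1L
      }
      runs[[length(runs) + 1]] <- i:j
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(runs) == 0) {
    out <- data.frame(hub = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      marker = character(0), pos = integer(0),
                      count = integer(0), n_members = integer(0))
    out$members <- list()
    return(structure(out, class = c("hub_set", "data.frame")))
  }
  rows <- lapply(seq_along(runs), function(h) {
    r <- runs[[h]]
    cmax <- max(profile$count[r])
    tied <- r[profile$count[r] == cmax]
    if (length(tied) > 1) {
      ctr <- mean(profile$pos[tied])
      tied <- tied[which.min(abs(profile$pos[tied] - ctr))]
    }
    k <- tied[1]
    mem <- unique(peaks$trait[peaks$chrom == profile$chrom[k] &
                                peaks$start <= profile$pos[k] &
                                peaks$end >= profile$pos[k]])
    out <- data.frame(hub = sprintf("hub%02d", h), chrom = profile$chrom[k],
                      start = profile$pos[min(r)], end = profile$pos[max(r)],
                      marker = profile$marker[k], pos = profile$pos[k],
                      count = profile$count[k], n_members = length(mem),
                      stringsAsFactors = FALSE)
    out$members <- list(mem)
    out
  })
  structure(do.call(rbind, rows), class = c("hub_set", "data.frame"))
}

#' Allele-stratified summaries and epistasis classification of a hub
#'
#' For each member guide: mean induced fitness of segregants carrying the
#' 3S vs the BY allele at the hub marker (fitnesses of replicate barcode
#' lineages are averaged within a segregant first) with standard errors,
#' and the deviation contrast mean(d | 3S) - mean(d | BY). At the hub
#' level, |allele fitness difference| is regressed on |mean guide effect|:
#' a positive slope classifies the hub as amplifying (its effect grows with
#' perturbation severity), a negative slope together with the marker lying
#' in a baseline-fitness locus classifies it as masking (the locus's own
#' fitness effect is attenuated by severe perturbations). A sign-epistasis
#' flag is raised when the allele-effect sign under some member's induction
#' differs from the sign in the control condition.
#'
#' @param hub one row of a `hub_set`.
#' @param effects a `guide_effects` object (for deviations and m_hat).
#' @param fitness_list normalised fitness list.
#' @param genotypes genotype matrix.
#' @param baseline_peaks optional `linkage_peaks` for baseline fitness; the
#'   hub marker is a baseline locus if it falls inside any interval.
#' @param alpha significance level on the classification slope.
#' @return list of class `hub_summary`: `members` data.frame
#'   (`guide`, `m_hat`, `mean_3S`, `mean_BY`, `se_3S`, `se_BY`,
#'   `delta_fitness`, `delta_deviation`), `slope`, `slope_p`,
#'   `classification`, `sign_epistasis`, `baseline_locus`.
#' @export
hub_allele_summary <- function(hub, effects, fitness_list, genotypes,
                               baseline_peaks = NULL, alpha = 0.05) {
  members <- hub$members[[1]]
  if (length(members) < 3) stop("hub has fewer than 3 members")
  marker <- hub$marker
  x <- genotypes[, marker]
  atc <- fitness_list[[effects$assay]]$fitness
  atc <- atc[atc$flag == "" & !is.na(atc$fitness), ]
  con <- fitness_list$CON$fitness
  con <- con[con$flag == "" & !is.na(con$fitness), ]
  res <- effects$results

  seg_means <- function(d, g) {
    dg <- d[d$guide == g, ]
    tapply(dg$fitness, dg$segregant, mean)
  }
  rows <- lapply(members, function(g) {
    sm <- seg_means(atc, g)
    allele <- x[names(sm)]
    if (length(unique(allele)) < 2) return(NULL)
    m3 <- sm[allele == 1]; m0 <- sm[allele == 0]
    d <- effects$deviations[, g]
    dev <- d[!is.na(d)]
    a <- x[names(dev)]
    data.frame(guide = g,
               m_hat = res$m_hat[match(g, res$guide)],
               mean_3S = mean(m3), mean_BY = mean(m0),
               se_3S = stats::sd(m3) / sqrt(length(m3)),
               se_BY = stats::sd(m0) / sqrt(length(m0)),
               delta_fitness = mean(m3) - mean(m0),
               delta_deviation = mean(dev[a == 1]) - mean(dev[a == 0]),
               stringsAsFactors = FALSE)
  })
  omitted <- members[vapply(rows, is.null, logical(1))]
  mem <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  fit <- stats::lm(abs(delta_fitness) ~ abs(m_hat), data = mem)
  sl <- summary(fit)$coefficients
  slope <- sl[2, "Estimate"]; slope_p <- sl[2, "Pr(>|t|)"]

  baseline_locus <- FALSE
  if (!is.null(baseline_peaks) && nrow(baseline_peaks)) {
    baseline_locus <- any(baseline_peaks$chrom == hub$chrom &
                            baseline_peaks$start <= hub$pos &
                            baseline_peaks$end >= hub$pos)
  }
  classification <- "unclassified"
  if (!is.na(slope_p) && slope_p < alpha) {
    if (slope > 0) classification <- "amplifying"
    if (slope < 0 && baseline_locus) classification <- "masking"
  }
  # control-condition allele effect at the marker, from all CON lineages
  con_seg <- tapply(con$fitness, con$segregant, mean)
  ca <- x[names(con_seg)]
  con_diff <- mean(con_seg[ca == 1]) - mean(con_seg[ca == 0])
  sign_epistasis <- any(sign(mem$delta_fitness) != sign(con_diff))
  structure(list(hub = hub$hub, marker = marker, members = mem,
                 omitted = omitted, slope = slope, slope_p = slope_p,
                 classification = classification,
                 sign_epistasis = sign_epistasis,
                 baseline_locus = baseline_locus,
                 control_allele_diff = con_diff),
            class = "hub_summary")
}

#' @export
print.hub_summary <- function(x, ...) {
  cat("Hub", x$hub, "at", x$marker, "-", x$classification, "\n")
  cat(sprintf("  |allele fitness difference| ~ |m|: slope %.3g (p %.3g)\n",
              x$slope, x$slope_p))
  cat("  members:", nrow(x$members),
      if (x$sign_epistasis) " sign epistasis\n" else "\n")
  invisible(x)
}
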