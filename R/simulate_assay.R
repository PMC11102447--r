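#' Configuration for a simulated pooled fitness assay
#'
#' @param timepoints sequenced time points in generations; must start at 0
#'   and be strictly increasing. Default matches a 10-generation serial
#'   batch assay sequenced at 0, 2, 4, 6 and 10 generations.
#' @param depth reads sampled per time point.
#' @param dilution serial-transfer dilution factor (1:4 roughly every two
#'   generations); used only when `bottleneck` is finite.
#' @param bottleneck cells kept at each transfer; `Inf` (default) disables
#'   drift between time points so that sequencing is the only noise source.
#' @param t0_cv coefficient of variation of log-normal T0 lineage abundances
#'   (the spread left by the pooled transformation).
#' @param frac_present probability that a given segregant-guide combination
#'   is present in the pool at T0 (combinations can be lost during library
#'   integration; absent combinations are what chimera detection keys on).
#' @param lineages_per_combo mean number of distinct barcode-pair lineages
#'   per present combination (1-2 drawn per combo; ~1.4 barcodes per guide
#'   per strain is what pooled integration typically recovers).
#' @param noiseless logical; if TRUE counts are exact expectations (no
#'   multinomial sampling, no lineage noise).
#' @param seed integer seed recorded in all outputs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(timepoints = c(0, 2, 4, 6, 10), depth = 1e6,
                       dilution = 4, bottleneck = Inf, t0_cv = 0.5,
                       frac_present = 0.65, lineages_per_combo = 1.4,
                       noiseless = FALSE, seed = 1L) {
  stopifnot(timepoints[1] == 0, all(diff(timepoints) > 0), depth > 0,
            lineages_per_combo >= 1, lineages_per_combo <= 2)
  structure(list(timepoints = timepoints, depth = depth, dilution = dilution,
                 bottleneck = bottleneck, t0_cv = t0_cv,
                 frac_present = frac_present,
                 lineages_per_combo = lineages_per_combo,
                 noiseless = noiseless,
                 seed = seed), class = "sim_config")
}

#' Simulate one pooled fitness assay to a lineage count table
#'
#' Every present segregant-guide combination contributes one lineage per
#' (segregant barcode, guide barcode) pair. Expected lineage frequencies
#' follow \eqn{f_i(t) \propto f_i(0) e^{s_i t}} (renormalised each transfer,
#' equivalent to growth at \eqn{s_i - \bar s(t)}), and observed counts at
#' each sequenced time point are multinomial draws of the configured depth.
#'
#' @param arch `effect_architecture` from [simulate_architecture()].
#' @param guide_library list from [simulate_guide_library()].
#' @param seg_barcodes data.frame from [simulate_segregant_barcodes()].
#' @param config a [sim_config()].
#' @param induced logical; gRNAs active (ATC assay) or not (CON).
#' @param assay label stored in the table, e.g. `"ATC1"`.
#' @param seed integer seed; defaults to `config$seed`.
#' @param combos optional: a data.frame (`segregant`, `guide`) fixing
#'   which combinations are present, or a full lineage frame (with
#'   `seg_bc`, `guide_bc` columns, e.g. the `lineage_frame` attribute of a
#'   previous assay) so replicate assays share the exact same lineages.
#'   Default: all combinations, thinned at `config$frac_present`.
#' @return object of class `lineage_counts`: data.frame with columns
#'   `lineage_id`, `seg_bc`, `guide_bc`, `segregant`, `guide`, `assay`,
#'   `valid`, and `n_t0` ... one per time point. Attributes: `timepoints`,
#'   `depth`, `truth` (per-lineage true fitness and noise), `combos`.
#' @export
simulate_assay <- function(arch, guide_library, seg_barcodes, config,
                           induced, assay = if (induced) "ATC1" else "CON",
                           seed = config$seed, combos = NULL) {
  if (!is.null(seed)) set.seed(seed)
  segs <- names(arch$b)
  guides <- guide_library$guides$guide
  if (is.null(combos)) {
    combos <- expand.grid(segregant = segs, guide = guides,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    if (config$frac_present < 1) {
      keep <- stats::runif(nrow(combos)) < config$frac_present
      # every segregant-guide must be joinable downstream; make sure each
      # guide keeps >= 2 segregants and each segregant >= 1 guide
      combos <- combos[keep, , drop = FALSE]
    }
  }
  if (!is.null(combos$seg_bc)) {
    # a lineage frame from a previous assay: reuse it verbatim so that
    # replicate assays share the same lineages
    lin <- combos
    combos <- unique(combos[c("segregant", "guide")])
  } else {
    sb <- split(seg_barcodes$seg_bc, seg_barcodes$segregant)
    gb <- split(guide_library$guide_barcodes$guide_bc,
                guide_library$guide_barcodes$guide)
    n_sb <- lengths(sb)[combos$segregant]
    n_gb <- lengths(gb)[combos$guide]
    avail <- n_sb * n_gb
    # 1-2 distinct barcode-pair lineages per combination; the extra
    # lineage appears with probability lineages_per_combo - 1
    reps <- pmin(1L + stats::rbinom(nrow(combos), 1L,
                                    config$lineages_per_combo - 1), avail)
    pair_idx <- mapply(function(a, k) sample.int(a, k), avail, reps,
                       SIMPLIFY = FALSE)
    lin <- data.frame(
      segregant = rep(combos$segregant, reps),
      guide = rep(combos$guide, reps),
      stringsAsFactors = FALSE)
    lin$seg_bc <- unlist(mapply(function(s, ii) {
      sb[[s]][(ii - 1L) %% length(sb[[s]]) + 1L]
    }, combos$segregant, pair_idx, SIMPLIFY = FALSE), use.names = FALSE)
    lin$guide_bc <- unlist(mapply(function(s, g, ii) {
      gb[[g]][(ii - 1L) %/% length(sb[[s]]) + 1L]
    }, combos$segregant, combos$guide, pair_idx, SIMPLIFY = FALSE),
    use.names = FALSE)
  }
  L <- nrow(lin)
  lin$lineage_id <- paste(lin$seg_bc, lin$guide_bc, sep = ":")

  # per-lineage noise (combination-level dispersion lives in the
  # architecture and is shared across replicates and assays)
  if (config$noiseless) {
    eps <- numeric(L)
  } else {
    eps <- stats::rnorm(L, 0, arch$sigma_lin)
  }
  s_true <- true_fitness_vec(arch, lin$segregant, lin$guide, induced, eps)

  # T0 abundances (log-normal with configured CV), then growth + sampling
  if (config$noiseless) {
    ab0 <- rep(1, L)
  } else {
    sdlog <- sqrt(log(1 + config$t0_cv^2))
    ab0 <- stats::rlnorm(L, -sdlog^2 / 2, sdlog)
  }
  tp <- config$timepoints
  counts <- matrix(0, L, length(tp))
  f <- ab0 / sum(ab0)
  prev_t <- 0
  for (k in seq_along(tp)) {
    if (tp[k] > prev_t) {
      w <- f * exp(s_true * (tp[k] - prev_t))
      f <- w / sum(w)
      prev_t <- tp[k]
    }
    if (is.finite(config$bottleneck) && k > 1 && !config$noiseless) {
      nb <- stats::rmultinom(1, config$bottleneck, f)[, 1]
      f <- nb / sum(nb)
    }
    if (config$noiseless) {
      counts[, k] <- config$depth * f
    } else {
      counts[, k] <- stats::rmultinom(1, config$depth, f)[, 1]
    }
    if (sum(f) <= 0) stop("zero total abundance at time point ", tp[k])
  }
  colnames(counts) <- paste0("n_t", seq_along(tp) - 1L)
  out <- data.frame(lineage_id = lin$lineage_id, seg_bc = lin$seg_bc,
                    guide_bc = lin$guide_bc, segregant = lin$segregant,
                    guide = lin$guide, assay = assay, valid = TRUE,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(counts))
  truth <- data.frame(lineage_id = lin$lineage_id, segregant = lin$segregant,
                      guide = lin$guide, fitness_true = s_true, eps = eps,
                      stringsAsFactors = FALSE)
  structure(out, timepoints = tp, depth = config$depth, truth = truth,
            combos = combos,
            lineage_frame = lin[c("segregant", "guide", "seg_bc",
                                  "guide_bc")],
            seed = seed,
            class = c("lineage_counts", "data.frame"))
}

#' Count columns of a lineage count table
#' @param counts a `lineage_counts` object.
#' @return numeric matrix, lineages x time points.
#' @export
count_matrix <- function(counts) {
  cols <- grep("^n_t[0-9]+$", names(counts), value = TRUE)
  m <- as.matrix(counts[cols])
  rownames(m) <- counts$lineage_id
  m
}

#' Inject PCR chimeras into a count table
#'
#' Template switching during PCR pairs barcodes that never co-occurred in a
#' cell. The expected chimera frequency of a (segregant barcode, guide
#' barcode) pair is linear in the marginal frequencies of the two barcodes:
#' counts with mean `depth * (intercept + a_seg * F_seg + a_guide * F_guide)`
#' are added to every pair -- including invalid pairings absent from the
#' library, which appear as new rows flagged `valid = FALSE`.
#'
#' @param counts a `lineage_counts` object.
#' @param coefficients numeric c(intercept, a_seg, a_guide), all >= 0.
#' @param seed integer seed.
#' @return the count table with chimeric counts added; attribute
#'   `chimera_truth` holds the injected counts per pair and time point.
#' @export
inject_chimeras <- function(counts, coefficients = c(0, 0.02, 0.02),
                            seed = NULL) {
  if (any(coefficients < 0) || length(coefficients) != 3) {
    stop("coefficients must be three non-negative numbers")
  }
  if (!is.null(seed)) set.seed(seed)
  tp <- attr(counts, "timepoints")
  cm <- count_matrix(counts)
  seg_bcs <- sort(unique(counts$seg_bc))
  guide_bcs <- sort(unique(counts$guide_bc))
  pairs <- expand.grid(seg_bc = seg_bcs, guide_bc = guide_bcs,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pair_id <- paste(pairs$seg_bc, pairs$guide_bc, sep = ":")
  add <- matrix(0, nrow(pairs), length(tp),
                dimnames = list(pair_id, colnames(cm)))
  for (k in seq_along(tp)) {
    tot <- sum(cm[, k])
    f_seg <- tapply(cm[, k], counts$seg_bc, sum)[pairs$seg_bc] / tot
    f_gui <- tapply(cm[, k], counts$guide_bc, sum)[pairs$guide_bc] / tot
    mu <- tot * (coefficients[1] + coefficients[2] * f_seg +
                   coefficients[3] * f_gui)
    add[, k] <- stats::rpois(nrow(pairs), mu)
  }
  # merge: existing rows get their additions; new invalid rows appended
  idx <- match(counts$lineage_id, pair_id)
  ccols <- colnames(cm)
  counts[ccols] <- cm + add[idx, , drop = FALSE]
  new <- setdiff(which(rowSums(add) > 0), idx)
  if (length(new)) {
    seg_of <- counts$segregant[match(pairs$seg_bc[new], counts$seg_bc)]
    gui_of <- counts$guide[match(pairs$guide_bc[new], counts$guide_bc)]
    newrows <- data.frame(lineage_id = pair_id[new],
                          seg_bc = pairs$seg_bc[new],
                          guide_bc = pairs$guide_bc[new],
                          segregant = seg_of, guide = gui_of,
                          assay = counts$assay[1], valid = FALSE,
                          stringsAsFactors = FALSE)
    newrows <- cbind(newrows, as.data.frame(add[new, , drop = FALSE]))
    at <- attributes(counts)
    counts <- rbind(as.data.frame(counts), newrows)
    attr(counts, "timepoints") <- at$timepoints
    attr(counts, "depth") <- at$depth
    attr(counts, "truth") <- at$truth
    attr(counts, "combos") <- at$combos
    class(counts) <- c("lineage_counts", "data.frame")
  }
  attr(counts, "chimera_truth") <- list(coefficients = coefficients,
                                        added = add)
  counts
}

#' @export
`[.lineage_counts` <- function(x, i, j, ...) {
  at <- attributes(x)
  out <- NextMethod()
  if (is.data.frame(out)) {
    for (a in c("timepoints", "depth", "truth", "combos", "lineage_frame",
                "seed", "chimera_truth")) {
      if (!is.null(at[[a]])) attr(out, a) <- at[[a]]
    }
    class(out) <- c("lineage_counts", "data.frame")
  }
  out
}

#' @export
print.lineage_counts <- function(x, ...) {
  tp <- attr(x, "timepoints")
  cat("Lineage counts:", nrow(x), "lineages (",
      sum(!x$valid), "invalid pairs ),", length(tp),
      "time points at generations", paste(tp, collapse = ", "), "\n")
  cat("  assay:", unique(x$assay), " total reads/tp:",
      paste(signif(colSums(count_matrix(x)), 3), collapse = ", "), "\n")
  invisible(x)
}
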