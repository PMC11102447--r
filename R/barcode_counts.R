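#' Extract the barcode pair from one read pair
#'
#' The forward read carries the 20-nt guide barcode immediately upstream of
#' the anchor `CCCGAGTCGCGATAA`; the reverse read carries the segregant
#' barcode immediately upstream of `TACCGTTCGTATAGG`. A read pair is
#' rejected when an anchor is not found immediately downstream of the
#' expected barcode window, or when the mean Illumina quality of the first
#' `quality_window` bases of either read is below `min_quality`.
#'
#' @param fwd,rev read sequences.
#' @param fwd_qual,rev_qual per-base quality strings (phred+33).
#' @param barcode_length barcode length (20).
#' @param min_quality mean-quality threshold (reject strictly below).
#' @param quality_window number of leading bases averaged.
#' @param max_anchor_mismatch allowed anchor mismatches (0 = exact).
#' @return list with `guide_bc`, `seg_bc`, `accepted`, `reason`.
#' @export
extract_barcode_pair <- function(fwd, rev, fwd_qual, rev_qual,
                                 barcode_length = 20, min_quality = 30,
                                 quality_window = 35,
                                 max_anchor_mismatch = 0) {
  res <- extract_barcodes(fwd, rev, fwd_qual, rev_qual, barcode_length,
                          min_quality, quality_window, max_anchor_mismatch)
  list(guide_bc = res$guide_bc[1], seg_bc = res$seg_bc[1],
       accepted = res$accepted[1], reason = res$reason[1])
}

.mean_head_quality <- function(qual, window) {
  vapply(qual, function(q) {
    v <- utf8ToInt(substr(q, 1, window)) - 33L
    mean(v)
  }, numeric(1), USE.NAMES = FALSE)
}

.anchor_mismatches <- function(seqs, from, anchor) {
  obs <- substr(seqs, from, from + nchar(anchor) - 1L)
  mm <- integer(length(obs))
  for (i in seq_len(nchar(anchor))) {
    mm <- mm + (substr(obs, i, i) != substr(anchor, i, i))
  }
  mm + (nchar(obs) < nchar(anchor)) * nchar(anchor)
}

#' Vectorised barcode-pair extraction
#'
#' @inheritParams extract_barcode_pair
#' @return data.frame with columns `guide_bc`, `seg_bc`, `accepted`,
#'   `reason` (one of `"ok"`, `"short_read"`, `"low_quality"`,
#'   `"anchor_mismatch"`).
#' @export
extract_barcodes <- function(fwd, rev, fwd_qual, rev_qual,
                             barcode_length = 20, min_quality = 30,
                             quality_window = 35, max_anchor_mismatch = 0) {
  need <- barcode_length + nchar(ANCHOR_GUIDE)
  n <- length(fwd)
  reason <- rep("ok", n)
  short <- nchar(fwd) < need | nchar(rev) < need
  reason[short] <- "short_read"
  qok <- .mean_head_quality(fwd_qual, quality_window) >= min_quality &
    .mean_head_quality(rev_qual, quality_window) >= min_quality
  reason[!short & !qok] <- "low_quality"
  mm_f <- .anchor_mismatches(fwd, barcode_length + 1L, ANCHOR_GUIDE)
  mm_r <- .anchor_mismatches(rev, barcode_length + 1L, ANCHOR_SEG)
  bad_anchor <- mm_f > max_anchor_mismatch | mm_r > max_anchor_mismatch
  reason[reason == "ok" & bad_anchor] <- "anchor_mismatch"
  acc <- reason == "ok"
  data.frame(
    guide_bc = ifelse(acc, substr(fwd, 1, barcode_length), NA_character_),
    seg_bc = ifelse(acc, substr(rev, 1, barcode_length), NA_character_),
    accepted = acc, reason = reason, stringsAsFactors = FALSE)
}

#' Match observed barcodes against a reference list
#'
#' The similarity score between an observed sequence and a reference is
#' `100 * (1 - edit_distance / max(length_obs, length_ref))`; for 20-mers a
#' score of 90 is roughly a 1-2 nucleotide difference. The best-scoring
#' reference is reported when its score reaches `threshold`; ties are broken
#' by the lexicographically smallest reference sequence.
#'
#' @param observed character vector of observed barcode sequences.
#' @param references character vector of reference barcodes (unique).
#' @param threshold minimum similarity score for a match.
#' @return data.frame with `observed`, `ref`, `score`, `matched` (one row
#'   per element of `observed`).
#' @export
match_barcode <- function(observed, references, threshold = 90) {
  if (length(references) == 0) stop("empty reference list")
  if (anyDuplicated(references)) stop("references must be unique")
  references <- sort(references)
  uo <- unique(observed)
  exact <- match(uo, references)
  ref <- references[exact]
  score <- ifelse(is.na(exact), NA_real_, 100)
  todo <- which(is.na(exact))
  if (length(todo)) {
    d <- utils::adist(uo[todo], references)
    len <- outer(nchar(uo[todo]), nchar(references), pmax)
    sc <- 100 * (1 - d / len)
    best <- max.col(sc, ties.method = "first")  # references sorted: ties ->
    bi <- cbind(seq_along(todo), best)          # smallest sequence wins
    ref[todo] <- references[best]
    score[todo] <- sc[bi]
  }
  i <- match(observed, uo)
  out <- data.frame(observed = observed, ref = ref[i], score = score[i],
                    matched = score[i] >= threshold, stringsAsFactors = FALSE)
  out$ref[!out$matched] <- NA_character_
  out
}

#' Tally matched barcode pairs into a lineage count table
#'
#' Pairs whose (segregant, guide) combination is absent from the valid
#' library are tallied as chimera candidates (`valid = FALSE`).
#'
#' @param pairs data.frame with columns `seg_bc`, `guide_bc`, `timepoint`
#'   (1-based index) for every matched read pair.
#' @param seg_barcodes data.frame (`seg_bc`, `segregant`).
#' @param guide_barcodes data.frame (`guide_bc`, `guide`).
#' @param valid_combos data.frame (`segregant`, `guide`) of combinations
#'   present in the library.
#' @param timepoints generations of the sequenced time points.
#' @param assay assay label.
#' @return a `lineage_counts` object.
#' @export
tally_counts <- function(pairs, seg_barcodes, guide_barcodes, valid_combos,
                         timepoints = c(0, 2, 4, 6, 10), assay = "ATC1") {
  ntp <- length(timepoints)
  key <- paste(pairs$seg_bc, pairs$guide_bc, sep = ":")
  tab <- table(key, factor(pairs$timepoint, levels = seq_len(ntp)))
  ids <- rownames(tab)
  seg_bc <- sub(":.*$", "", ids)
  guide_bc <- sub("^.*:", "", ids)
  segregant <- seg_barcodes$segregant[match(seg_bc, seg_barcodes$seg_bc)]
  guide <- guide_barcodes$guide[match(guide_bc, guide_barcodes$guide_bc)]
  combo_key <- paste(segregant, guide, sep = ":")
  lib_key <- paste(valid_combos$segregant, valid_combos$guide, sep = ":")
  valid <- combo_key %in% lib_key
  cm <- matrix(as.numeric(tab), nrow = nrow(tab), ncol = ntp)
  colnames(cm) <- paste0("n_t", seq_len(ntp) - 1L)
  out <- data.frame(lineage_id = ids, seg_bc = seg_bc, guide_bc = guide_bc,
                    segregant = segregant, guide = guide,
                    assay = rep(assay, length(ids)),
                    valid = valid, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(cm))
  structure(out, timepoints = timepoints, depth = sum(cm[, 1]),
            class = c("lineage_counts", "data.frame"))
}

#' Fit the linear PCR-chimera model
#'
#' For each of the first `n_fit` time points, ordinary least squares of the
#' frequency of each known-invalid (chimera-candidate) pair on the total
#' frequencies of its segregant barcode and its guide barcode:
#' `frequency ~ F_seg + F_guide`. Coefficients are averaged over the fits.
#'
#' @param counts a `lineage_counts` table that includes chimera-candidate
#'   rows (`valid = FALSE`).
#' @param n_fit number of early time points fitted (default 4).
#' @return object of class `chimera_model`: list with `intercept`, `a_seg`,
#'   `a_guide` (averaged) and the per-time-point fits.
#' @export
fit_chimera_model <- function(counts, n_fit = 4) {
  cand <- which(!counts$valid)
  if (length(cand) < 10) {
    stop("need >= 10 known-invalid combinations to fit the chimera model")
  }
  cm <- count_matrix(counts)
  n_fit <- min(n_fit, ncol(cm))
  fits <- matrix(NA_real_, n_fit, 3,
                 dimnames = list(NULL, c("intercept", "a_seg", "a_guide")))
  for (k in seq_len(n_fit)) {
    tot <- sum(cm[, k])
    f_seg_tab <- tapply(cm[, k], counts$seg_bc, sum) / tot
    f_gui_tab <- tapply(cm[, k], counts$guide_bc, sum) / tot
    y <- cm[cand, k] / tot
    xs <- f_seg_tab[counts$seg_bc[cand]]
    xg <- f_gui_tab[counts$guide_bc[cand]]
    fit <- stats::lm(y ~ xs + xg)
    if (any(is.na(stats::coef(fit)))) stop("rank-deficient chimera design")
    fits[k, ] <- stats::coef(fit)
  }
  avg <- colMeans(fits)
  structure(list(intercept = avg[["intercept"]], a_seg = avg[["a_seg"]],
                 a_guide = avg[["a_guide"]], per_timepoint = fits),
            class = "chimera_model")
}

#' @export
print.chimera_model <- function(x, ...) {
  cat("PCR chimera model (averaged over", nrow(x$per_timepoint),
      "time points):\n")
  cat(sprintf("  frequency ~ %.3g + %.3g * F_seg + %.3g * F_guide\n",
              x$intercept, x$a_seg, x$a_guide))
  invisible(x)
}

#' Subtract predicted chimera frequencies from a count table
#'
#' Each pair's frequency at each time point is reduced by its predicted
#' chimera frequency; corrected frequencies are floored at zero and counts
#' rescaled back at the original per-time-point depth.
#'
#' @param counts a `lineage_counts` object.
#' @param model a fitted [fit_chimera_model()].
#' @return corrected `lineage_counts` (counts may be non-integer).
#' @export
correct_chimeras <- function(counts, model) {
  cm <- count_matrix(counts)
  for (k in seq_len(ncol(cm))) {
    tot <- sum(cm[, k])
    if (tot == 0) next
    f_seg_tab <- tapply(cm[, k], counts$seg_bc, sum) / tot
    f_gui_tab <- tapply(cm[, k], counts$guide_bc, sum) / tot
    pred <- model$intercept + model$a_seg * f_seg_tab[counts$seg_bc] +
      model$a_guide * f_gui_tab[counts$guide_bc]
    f_corr <- pmax(0, cm[, k] / tot - pred)
    cm[, k] <- f_corr * tot
  }
  ccols <- colnames(cm)
  counts[ccols] <- cm
  counts
}

#' Depth-normalise a count table
#'
#' Divides each count by its time point's total and multiplies by a common
#' scale, so that all time points carry equal weight. The scale should be
#' close to the true per-time-point sequencing depth (450,000,000 —
#' roughly a full lane — for a production experiment): downstream fitness
#' estimation treats the normalised counts as Poisson observations, so a
#' scale far above the real depth would overstate their precision. For a
#' desk-scale simulation pass the simulated depth (`NA` uses the table's
#' own T0 total).
#'
#' @param counts a `lineage_counts` object.
#' @param scale common total per time point; `NA` for the T0 total.
#' @return normalised `lineage_counts` (non-integer counts).
#' @export
normalize_depth <- function(counts, scale = 450e6) {
  if (is.na(scale)) scale <- sum(count_matrix(counts)[, 1])
  cm <- count_matrix(counts)
  tot <- colSums(cm)
  if (any(tot <= 0)) stop("time point with zero total count")
  cm <- sweep(cm, 2, tot, "/") * scale
  counts[colnames(cm)] <- cm
  attr(counts, "depth") <- scale
  counts
}
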