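mk_read <- function(bc, anchor, len = 50) {
  core <- paste0(bc, anchor)
  paste0(core, strrep("A", len - nchar(core)))
}

test_that("barcode-pair extraction filters on anchors and quality", {
  gb <- strrep("ACGT", 5)
  sb <- strrep("TGCA", 5)
  fwd <- mk_read(gb, "CCCGAGTCGCGATAA")
  rev <- mk_read(sb, "TACCGTTCGTATAGG")
  q <- strrep("F", 50)
  r <- extract_barcode_pair(fwd, rev, q, q)
  expect_true(r$accepted)
  expect_equal(r$guide_bc, gb)
  expect_equal(r$seg_bc, sb)
  # one substitution in the anchor with strict matching: rejected
  bad <- sub("CCCGAGTCGCGATAA", "CCCGAGTCGCGATAC", fwd)
  r2 <- extract_barcode_pair(bad, rev, q, q)
  expect_false(r2$accepted)
  expect_equal(r2$reason, "anchor_mismatch")
  # ... but accepted when one mismatch is allowed
  r2b <- extract_barcode_pair(bad, rev, q, q, max_anchor_mismatch = 1)
  expect_true(r2b$accepted)
  # mean quality boundary over the first 35 bases: 29.9 out, 30.0 in
  q_at <- function(mean_q) {
    # 35 bases whose mean is mean_q, rest high
    v <- rep(round(mean_q), 35)
    v[1] <- v[1] + round((mean_q - round(mean_q)) * 35)
    intToUtf8(c(v + 33, rep(70, 15)))
  }
  stopifnot(abs(mean(utf8ToInt(substr(q_at(29.9), 1, 35)) - 33) - 29.9)
            < 0.02)
  r3 <- extract_barcode_pair(fwd, rev, q_at(29.9), q)
  expect_false(r3$accepted)
  expect_equal(r3$reason, "low_quality")
  r4 <- extract_barcode_pair(fwd, rev, q_at(30), q)
  expect_true(r4$accepted)
  # short reads are rejected with a reason
  r5 <- extract_barcode_pair("ACGT", rev, "FFFF", q)
  expect_equal(r5$reason, "short_read")
})

test_that("similarity matching scores edit distance out of 100", {
  refs <- c(strrep("A", 20), strrep("C", 20), strrep("G", 20))
  # exact match scores 100 regardless of list order
  for (rf in list(refs, rev(refs))) {
    m <- match_barcode(strrep("C", 20), rf)
    expect_equal(m$score, 100)
    expect_equal(m$ref, strrep("C", 20))
  }
  # 1 substitution: score 95, matched at threshold 90
  obs1 <- paste0(strrep("A", 19), "T")
  m1 <- match_barcode(obs1, refs)
  expect_equal(m1$score, 95)
  expect_true(m1$matched)
  # 3 substitutions: score 85, unmatched
  obs3 <- paste0(strrep("A", 17), "TTT")
  m3 <- match_barcode(obs3, refs)
  expect_equal(m3$score, 85)
  expect_false(m3$matched)
  # equidistant tie resolves to the lexicographically smallest reference
  tie <- match_barcode(paste0(strrep("A", 10), strrep("C", 10)),
                       refs, threshold = 40)
  expect_equal(tie$ref, strrep("A", 20))
  expect_error(match_barcode("ACGT", character(0)), "empty")
  expect_error(match_barcode("ACGT", c("AA", "AA")), "unique")
})

test_that("tallying separates valid pairs from chimera candidates", {
  sb <- data.frame(seg_bc = c("S1", "S2"), segregant = c("segA", "segB"))
  gb <- data.frame(guide_bc = c("G1", "G2"), guide = c("g1", "g2"))
  combos <- data.frame(segregant = c("segA", "segB"),
                       guide = c("g1", "g2"))
  pairs <- data.frame(
    seg_bc = c(rep("S1", 5), "S1"),
    guide_bc = c(rep("G1", 5), "G2"),  # S1+G2 is an invalid combination
    timepoint = 1)
  tl <- tally_counts(pairs, sb, gb, combos, timepoints = 0)
  expect_equal(unname(count_matrix(tl)["S1:G1", 1]), 5)
  expect_false(tl$valid[tl$lineage_id == "S1:G2"])
  expect_true(tl$valid[tl$lineage_id == "S1:G1"])
  empty <- tally_counts(pairs[0, ], sb, gb, combos, timepoints = 0)
  expect_equal(nrow(empty), 0)
})

test_that("chimera model matches the normal-equation oracle and nulls", {
  # toy: 12 candidate pairs with known frequencies at one time point,
  # compare lm-based fit to hand-solved least squares
  set.seed(3)
  n <- 12
  base <- data.frame(
    lineage_id = paste0("L", 1:n),
    seg_bc = rep(paste0("S", 1:4), 3),
    guide_bc = rep(paste0("G", 1:3), each = 4),
    segregant = rep(paste0("seg", 1:4), 3),
    guide = rep(paste0("g", 1:3), each = 4),
    assay = "CON", valid = rep(c(TRUE, FALSE), c(2, 10)),
    stringsAsFactors = FALSE)
  cm <- matrix(rpois(n * 4, 200), n, 4,
               dimnames = list(NULL, paste0("n_t", 0:3)))
  counts <- cbind(base, as.data.frame(cm))
  attr(counts, "timepoints") <- c(0, 2, 4, 6)
  class(counts) <- c("lineage_counts", "data.frame")
  fit <- fit_chimera_model(counts, n_fit = 4)
  # oracle: normal equations per time point, coefficients averaged
  ora <- rowMeans(sapply(1:4, function(k) {
    tot <- sum(cm[, k])
    fs <- tapply(cm[, k], counts$seg_bc, sum)[counts$seg_bc] / tot
    fg <- tapply(cm[, k], counts$guide_bc, sum)[counts$guide_bc] / tot
    cand <- !counts$valid
    X <- cbind(1, fs[cand], fg[cand])
    drop(solve(crossprod(X), crossprod(X, cm[cand, k] / tot)))
  }))
  expect_equal(c(fit$intercept, fit$a_seg, fit$a_guide), unname(ora),
               tolerance = 1e-10)
  expect_error(fit_chimera_model(counts[counts$valid, ]), ">= 10")
})

test_that("chimera correction recovers coefficients and reduces error", {
  p <- small_panel(n_seg = 30, n_guides = 20, n_controls = 4)
  arch <- simulate_architecture(p$G, p$lib, arch_config(guides_per_hub = 3),
                                seed = 5)
  cfg <- sim_config(depth = 1e6, seed = 13, frac_present = 0.6)
  cn <- simulate_assay(arch, p$lib, p$sb, cfg, induced = FALSE,
                       assay = "CON")
  truth_cm <- count_matrix(cn)
  coefs <- c(0, 3e-4, 3e-4)  # chimeric fraction in the <10% regime
  cc <- inject_chimeras(cn, coefs, seed = 14)
  fit <- fit_chimera_model(cc)
  expect_lt(abs(fit$a_seg - coefs[2]) / coefs[2], 0.10)
  expect_lt(abs(fit$a_guide - coefs[3]) / coefs[3], 0.10)
  corr <- correct_chimeras(cc, fit)
  # valid-lineage frequency MAE strictly smaller after correction
  idx <- match(rownames(truth_cm), cc$lineage_id)
  f_true <- sweep(truth_cm, 2, colSums(truth_cm), "/")
  mae <- function(m) {
    f <- sweep(m, 2, colSums(m), "/")
    mean(abs(f[idx, ] - f_true))
  }
  expect_lt(mae(count_matrix(corr)), mae(count_matrix(cc)))
  # zero-coefficient model leaves counts unchanged; floor at zero holds
  zero <- structure(list(intercept = 0, a_seg = 0, a_guide = 0,
                         per_timepoint = matrix(0, 4, 3)),
                    class = "chimera_model")
  expect_equal(count_matrix(correct_chimeras(cc, zero)), count_matrix(cc))
  big <- structure(list(intercept = 1, a_seg = 0, a_guide = 0,
                        per_timepoint = matrix(0, 4, 3)),
                   class = "chimera_model")
  expect_true(all(count_matrix(correct_chimeras(cc, big)) == 0))
})

test_that("depth normalisation scales each time point to a common total", {
  d <- two_lineage_counts(s = c(0, 0), f0 = c(0.1, 0.9), depth = 100)
  n <- normalize_depth(d, scale = 1000)
  expect_equal(unname(count_matrix(n)[, 1]), c(100, 900))
  expect_true(all(abs(colSums(count_matrix(n)) - 1000) < 1e-9))
  d0 <- d
  d0$n_t2 <- 0
  expect_error(normalize_depth(d0, 1000), "zero total")
})
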