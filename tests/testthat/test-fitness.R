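test_that("a neutral pool estimates zero fitness everywhere", {
  cn <- two_lineage_counts(s = c(0, 0, 0), f0 = c(0.2, 0.3, 0.5))
  fit <- estimate_fitness(cn)
  expect_true(all(abs(fit$fitness$fitness) < 1e-6))
})

test_that("the noiseless two-lineage case inverts the logistic exactly", {
  cn <- two_lineage_counts(s = c(0, 0.2))
  fit <- estimate_fitness(cn)
  expect_lt(max(abs(fit$fitness$fitness - c(-0.1, 0.1))), 1e-3)
  # two time points: matches the closed form s = d log(f_i/f_j) / dt
  cn2 <- two_lineage_counts(s = c(0, 0.15), tp = c(0, 4))
  f2 <- estimate_fitness(cn2)
  expect_equal(diff(f2$fitness$fitness), 0.15, tolerance = 1e-9)
})

test_that("estimator is shift invariant and rank preserving (noiseless)", {
  s <- c(-0.15, -0.05, 0, 0.08, 0.2)
  f0 <- rep(0.2, 5)
  a <- estimate_fitness(two_lineage_counts(s = s, f0 = f0))
  b <- estimate_fitness(two_lineage_counts(s = s + 0.07, f0 = f0))
  expect_equal(a$fitness$fitness, b$fitness$fitness, tolerance = 1e-6)
  expect_equal(order(a$fitness$fitness), order(s))
  # deviance never increases over accepted iterations
  expect_true(all(diff(a$deviance) <= 1e-9 * max(1, abs(a$deviance[1]))))
})

test_that("fitness recovery on a stochastic simulation is accurate", {
  p <- small_panel(n_seg = 50, n_guides = 40, n_controls = 8, seed = 21)
  arch <- simulate_architecture(p$G, p$lib, arch_config(guides_per_hub = 6),
                                seed = 22)
  cfg <- sim_config(depth = 1e6, seed = 23)
  cn <- simulate_assay(arch, p$lib, p$sb, cfg, induced = TRUE)
  fit <- estimate_fitness(normalize_depth(cn, NA))
  tr <- attr(cn, "truth")
  est <- fit$fitness$fitness
  keep <- count_matrix(cn)[, 1] >= 5 & !is.na(est)
  r <- cor(est[keep], tr$fitness_true[match(fit$fitness$lineage_id,
                                            tr$lineage_id)][keep])
  expect_gte(r, 0.95)
})

test_that("QC filtering applies score, T0 and breadth rules", {
  mkfit <- function(score, t0, seg, gui) {
    as_fitness_obj(data.frame(
      lineage_id = paste0("L", seq_along(score)), segregant = seg,
      guide = gui, assay = "ATC1", fitness = 0, score = score, t0 = t0,
      flag = "", stringsAsFactors = FALSE))
  }
  # equal scores: IQR 0, nothing removed on score
  f <- mkfit(rep(-5, 8), rep(10, 8), rep(c("a", "b"), 4),
             rep(c("g1", "g2"), each = 4))
  q <- qc_filter(f, min_t0 = 5, min_guides_per_segregant = 1,
                 min_segregants_per_guide = 1)
  expect_true(all(q$fitness$flag == ""))
  # T0 boundary: 4 removed, 5 kept
  f2 <- mkfit(rep(0, 4), c(4, 5, 10, 10), rep("a", 4), paste0("g", 1:4))
  q2 <- qc_filter(f2, min_t0 = 5, min_guides_per_segregant = 1,
                  min_segregants_per_guide = 1)
  expect_equal(q2$fitness$flag, c("low_t0", "", "", ""))
  # hand-computed Q1 - IQR: scores {0 x99, -100} -> only the outlier out
  f3 <- mkfit(c(rep(0, 99), -100), rep(10, 100),
              rep(c("a", "b"), 50), rep(paste0("g", 1:10), 10))
  q3 <- qc_filter(f3, min_t0 = 5, min_guides_per_segregant = 1,
                  min_segregants_per_guide = 1)
  expect_equal(sum(q3$fitness$flag == "poor_fit"), 1)
  expect_equal(which(q3$fitness$flag == "poor_fit"), 100L)
  # breadth filters iterate to a fixed point
  f4 <- mkfit(rep(0, 5), rep(10, 5),
              c("a", "a", "b", "b", "c"),
              c("g1", "g2", "g1", "g2", "g1"))
  # segregant c has 1 guide (< 2): drop it; then g1 still has 2 segregants
  q4 <- qc_filter(f4, min_t0 = 5, min_guides_per_segregant = 2,
                  min_segregants_per_guide = 2)
  expect_equal(q4$fitness$flag, c("", "", "", "", "removed_segregant"))
  expect_error(qc_filter(f4, min_t0 = 100), "every lineage")
})

test_that("assay normalisation removes offsets via control guides", {
  set.seed(31)
  n <- 400
  segs <- sprintf("s%02d", rep(1:20, 20))
  guides <- rep(sprintf("g%02d", 1:20), each = 20)
  ctrl <- sprintf("g%02d", 1:12)
  base <- rnorm(n, 0, 0.05)
  mk <- function(f, assay) as_fitness_obj(data.frame(
    lineage_id = paste0(assay, seq_len(n)), segregant = segs,
    guide = guides, assay = assay, fitness = f, score = 0, t0 = 10,
    flag = "", stringsAsFactors = FALSE))
  # pure offset: ATC = CON + delta is removed exactly
  fl <- list(CON = mk(base, "CON"), ATC1 = mk(base + 0.3, "ATC1"))
  out <- normalize_assays(fl, ctrl)
  expect_equal(out$ATC1$fitness$fitness, out$CON$fitness$fitness,
               tolerance = 1e-12)
  expect_equal(mean(out$CON$fitness$fitness), 0, tolerance = 1e-12)
  # identical assays: zero shift
  fl2 <- list(CON = mk(base, "CON"), ATC1 = mk(base, "ATC1"))
  out2 <- normalize_assays(fl2, ctrl)
  expect_equal(unname(attr(out2, "normalization")$shifts), 0,
               tolerance = 1e-12)
  # noisy controls with true effect 0: residual median difference small
  fl3 <- list(CON = mk(base + rnorm(n, 0, 0.005), "CON"),
              ATC1 = mk(base + 0.1 + rnorm(n, 0, 0.005), "ATC1"))
  out3 <- normalize_assays(fl3, ctrl)
  cm <- function(x, g) tapply(x$fitness$fitness[x$fitness$guide %in% g],
                              x$fitness$guide[x$fitness$guide %in% g],
                              mean)
  expect_lt(abs(median(cm(out3$ATC1, ctrl)) - median(cm(out3$CON, ctrl))),
            1e-3)
})
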