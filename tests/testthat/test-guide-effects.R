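test_that("BH adjustment matches hand computation", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_fdr(0.2), 0.2)
})

test_that("test_guide finds no effect when ATC equals CON", {
  d <- guide_fitness_data(rep(0, 30), noise_sd = 0.01, seed = 1)
  r <- test_guide(d$fitness, d$segregant, d$induced)
  expect_lt(abs(r$m_hat), 0.01)
  expect_gt(r$p_mean, 0.05)
})

test_that("test_guide recovers planted uniform and variable effects", {
  n_rep <- 40
  uni_hit <- uni_int <- het_int <- logical(n_rep)
  m_in_range <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    d <- guide_fitness_data(rep(-0.1, 50), noise_sd = 0.01, seed = 100 + i)
    r <- test_guide(d$fitness, d$segregant, d$induced)
    m_in_range[i] <- r$m_hat > -0.12 && r$m_hat < -0.08
    uni_int[i] <- !is.na(r$p_interaction) && r$p_interaction < 0.05
    set.seed(200 + i)
    d2 <- guide_fitness_data(rnorm(50, -0.1, 0.05), noise_sd = 0.01,
                             seed = 300 + i)
    r2 <- test_guide(d2$fitness, d2$segregant, d2$induced)
    het_int[i] <- !is.na(r2$p_interaction) && r2$p_interaction < 0.05
  }
  expect_true(all(m_in_range))
  # uniform effect: interaction should rarely fire
  expect_gte(mean(!uni_int), 0.9)
  # segregant-specific effects: interaction detected nearly always
  expect_gte(mean(het_int), 0.9)
})

test_that("efficacy threshold reflects the null and is equivariant", {
  set.seed(7)
  m_null <- rnorm(2000, 0, 0.01)
  nm <- efficacy_threshold(m_null)
  # symmetric null: cutoff ~ -3 sd
  expect_lt(abs(nm$cutoff - (-3 * 0.01)), 0.004)
  expect_lt(mean(m_null < nm$cutoff), 0.005)
  # location equivariance
  nm2 <- efficacy_threshold(m_null + 0.05)
  expect_equal(nm2$cutoff, nm$cutoff + 0.05, tolerance = 1e-12)
  # planted cluster passes, null does not
  m <- c(m_null, rnorm(300, -0.2, 0.02))
  nm3 <- efficacy_threshold(m)
  expect_true(all(m[2001:2300] < nm3$cutoff))
  expect_lt(mean(m_null < nm3$cutoff), 0.005)
  expect_error(efficacy_threshold(rnorm(10)), ">= 50")
})

test_that("polymorphic-site guides are flagged on window overlap", {
  lib <- list(guides = data.frame(
    guide = c("g1", "g2", "g3"), chrom = "chrI",
    pos = c(100, 100, 100), control = FALSE, polymorphic = FALSE,
    stringsAsFactors = FALSE))
  # variant inside [100, 119], at boundary, and 1 bp outside
  v_in <- data.frame(chrom = "chrI", pos = 119)
  v_out <- data.frame(chrom = "chrI", pos = 120)
  expect_equal(flag_polymorphic_guides(lib, v_in), c("g1", "g2", "g3"))
  expect_equal(flag_polymorphic_guides(lib, v_out), character(0))
  # simulator-planted polymorphic guides are exactly recovered
  p <- small_panel()
  lib2 <- simulate_guide_library(40, p$map, n_controls = 5,
                                 frac_polymorphic = 0.2, seed = 9)
  flagged <- flag_polymorphic_guides(lib2, p$map)
  planted <- lib2$guides$guide[lib2$guides$polymorphic]
  expect_true(all(planted %in% flagged))
})

test_that("deviation values are centred contrasts of per-segregant effects", {
  # hand-checkable fixed-effects mode: effects {-0.2, -0.1, -0.3}
  segs <- c("a", "b", "c")
  eff <- c(-0.2, -0.1, -0.3)
  fit <- c(rep(0, 3), eff)          # CON baselines 0, ATC = effect
  seg <- c(segs, segs)
  ind <- rep(0:1, each = 3)
  d <- compute_deviations(fit, seg, ind, method = "fixed",
                          min_segregants = 3)
  expect_equal(unname(d[segs]), c(0, 0.1, -0.1))
  expect_equal(mean(d), 0, tolerance = 1e-9)
  # segregant-count boundary: 34 dropped, 35 retained
  mk <- function(n) {
    s <- sprintf("s%02d", 1:n)
    list(f = c(rep(0, n), rnorm(n, -0.1, 0.01)), s = c(s, s),
         i = rep(0:1, each = n))
  }
  set.seed(5)
  d34 <- mk(34); d35 <- mk(35)
  expect_null(compute_deviations(d34$f, d34$s, d34$i, method = "fixed"))
  expect_length(compute_deviations(d35$f, d35$s, d35$i, method = "fixed"),
                35)
  # BLUP deviations are centred too
  dd <- guide_fitness_data(rnorm(40, -0.1, 0.05), seed = 11)
  r <- test_guide(dd$fitness, dd$segregant, dd$induced)
  db <- compute_deviations(dd$fitness, dd$segregant, dd$induced,
                           fit_interaction = r$fit_interaction,
                           min_segregants = 35)
  expect_equal(mean(db), 0, tolerance = 1e-9)
})

test_that("deviations track the planted interaction structure", {
  # planted kappa/beta structure recovered by the estimated deviations
  set.seed(13)
  n_seg <- 60
  b <- rnorm(n_seg, 0, 0.05)
  x <- rbinom(n_seg, 1, 0.5)
  beta <- 0.08
  kappa <- -0.4
  m <- -0.15
  eff <- m + kappa * b + beta * x + rnorm(n_seg, 0, 0.02)
  segs <- sprintf("s%03d", 1:n_seg)
  n_bc <- 3
  seg <- rep(segs, each = n_bc)
  bl <- rep(b, each = n_bc)
  con <- bl + rnorm(length(seg), 0, 0.01)
  atc <- bl + rep(eff, each = n_bc) + rnorm(length(seg), 0, 0.01)
  dv <- compute_deviations(c(con, atc), c(seg, seg),
                           rep(0:1, each = length(seg)), method = "fixed")
  planted <- beta * x + kappa * b
  planted <- planted - mean(planted)
  expect_gt(cor(dv[segs], planted), 0.8)
})

test_that("guide_effects controls the FDR on an all-null screen", {
  # no planted effects at all: background calls at q < 0.05 stay near zero
  p <- small_panel(n_seg = 50, n_guides = 60, n_controls = 10, seed = 61)
  arch <- simulate_architecture(
    p$G, p$lib, arch_config(frac_efficacious = 0,
                            hub_styles = character(0)), seed = 62)
  cfg <- sim_config(depth = 3e5, seed = 63)
  fits <- list()
  for (a in c("ATC1", "CON")) {
    cn <- simulate_assay(arch, p$lib, p$sb, cfg, induced = a != "CON",
                         assay = a, seed = 63 + (a == "CON"))
    fit <- estimate_fitness(normalize_depth(cn, NA))
    fit <- qc_filter(fit, min_t0 = 0, min_guides_per_segregant = 1,
                     min_segregants_per_guide = 2)
    fits[[a]] <- fit
  }
  fits <- normalize_assays(fits, p$lib$guides$guide[p$lib$guides$control])
  eff <- guide_effects(fits, min_segregants = 30)
  r <- eff$results
  expect_lte(sum(r$q_mean < 0.05 & !is.na(r$q_mean)) / nrow(r), 0.10)
  expect_lte(sum(r$background, na.rm = TRUE), 2)
})
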