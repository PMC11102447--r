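test_that("marker map is ordered with unique ids and a derivable length", {
  map <- marker_map(3, c(5, 8, 4), spacing = 10000, first = 5000)
  expect_equal(nrow(map), 17)
  expect_false(anyDuplicated(map$marker) > 0)
  for (cc in unique(map$chrom)) {
    expect_true(all(diff(map$pos[map$chrom == cc]) > 0))
  }
  expect_equal(genome_length(map),
               sum(tapply(map$pos, map$chrom, max)))
})

test_that("cross simulation respects the recombination fraction", {
  map <- marker_map(2, 20)
  # no recombination: one parental block per chromosome
  G0 <- simulate_cross(30, map, recomb_fraction = 0, seed = 1)
  for (cc in unique(map$chrom)) {
    blk <- G0[, map$chrom == cc]
    expect_true(all(apply(blk, 1, function(r) length(unique(r)) == 1)))
  }
  # free recombination: adjacent markers uncorrelated
  G5 <- simulate_cross(10000, marker_map(1, 10), 0.5, seed = 2)
  r <- sapply(1:9, function(j) cor(G5[, j], G5[, j + 1]))
  expect_true(all(abs(r) < 0.05))
  # switch rate matches the configured fraction (binomial expectation)
  G1 <- simulate_cross(10000, marker_map(1, 10), 0.1, seed = 3)
  sw <- mean(G1[, -1] != G1[, -10])
  expect_lt(abs(sw - 0.1), 0.01)
  # determinism
  expect_identical(simulate_cross(50, map, 0.1, seed = 9),
                   simulate_cross(50, map, 0.1, seed = 9))
  expect_error(simulate_cross(10, map, 0.7), "recomb_fraction")
})

test_that("architecture obeys its construction rules", {
  p <- small_panel()
  # degenerate: no hubs, no QTL -> baseline is pure residual, no betas
  cfg0 <- arch_config(n_qtl = 0, hub_styles = character(0))
  a0 <- simulate_architecture(p$G, p$lib, cfg0, seed = 1)
  expect_equal(nrow(a0$interactions), 0)
  expect_lt(sd(a0$b), 3 * cfg0$sigma_b)
  # controls are silent; efficacious effects are negative
  a <- simulate_architecture(p$G, p$lib, arch_config(guides_per_hub = 4),
                             seed = 2)
  ctrl <- p$lib$guides$guide[p$lib$guides$control]
  expect_true(all(a$m[ctrl] == 0))
  expect_false(any(a$interactions$guide %in% ctrl))
  expect_true(all(a$m[a$m != 0] < 0))
  # amplifying hubs: |beta| increases with |m|
  amp <- a$interactions[a$interactions$hub ==
                          a$hubs$hub[a$hubs$style == "amplifying"][1], ]
  o <- order(abs(a$m[amp$guide]))
  expect_true(all(diff(abs(amp$beta)[o]) >= 0))
  # masking hub: realized induced allele effect is a * max(0, 1 - r |m|),
  # verified by direct evaluation of the fitness contrast at the marker
  mh <- a$hubs[a$hubs$style == "masking", ][1, ]
  qa <- a$qtl$effect[a$qtl$marker == mh$marker]
  msk <- a$interactions[a$interactions$hub == mh$hub, ]
  r <- a$config$mask_rate
  g1 <- msk$guide[1]
  # direct evaluation on a two-segregant world where the only genetic
  # signal is the hub QTL: the induced contrast must equal the closed form
  G2 <- matrix(c(1L, 0L), 2, 1,
               dimnames = list(c("s3S", "sBY"), mh$marker))
  a2 <- manual_arch(b = c(s3S = qa, sBY = 0),
                    m = a$m[g1],
                    interactions = msk[msk$guide == g1, ],
                    genotypes = G2, kappa = a$kappa)
  contrast <- true_fitness(a2, "s3S", g1, TRUE) -
    true_fitness(a2, "sBY", g1, TRUE)
  expect_equal(contrast, qa * max(0, 1 - r * abs(a$m[g1])),
               tolerance = 1e-12)
  # equivalent identity on the stored coefficients
  expect_equal((1 + a$config$kappa) * qa + msk$beta,
               qa * pmax(0, 1 - r * abs(a$m[msk$guide])),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(
    simulate_architecture(p$G, p$lib,
                          arch_config(hub_styles = rep("amplifying", 1e4))),
    "hubs")
})

test_that("true_fitness evaluates the generative formula", {
  G <- matrix(c(1L, 0L), 2, 1, dimnames = list(c("sA", "sB"), "mk1"))
  arch <- manual_arch(
    b = c(sA = 0.05, sB = -0.02), m = c(gC = 0, gE = -0.2),
    interactions = data.frame(guide = "gE", marker = "mk1", beta = 0.08,
                              hub = "hub1"),
    genotypes = G, kappa = -0.5)
  # uninduced: baseline only
  expect_equal(true_fitness(arch, "sA", "gE", induced = FALSE), 0.05)
  # induced control with no effect: baseline only
  expect_equal(true_fitness(arch, "sA", "gC", induced = TRUE), 0.05)
  # hand evaluation: b + m + kappa b + beta x = .05 - .2 - .025 + .08
  expect_equal(true_fitness(arch, "sA", "gE", induced = TRUE), -0.095)
  expect_equal(true_fitness(arch, "sB", "gE", induced = TRUE),
               -0.02 - 0.2 + 0.01 + 0)
  expect_error(true_fitness(arch, "nope", "gE", TRUE), "unknown")
})

test_that("assay simulation conserves frequency, depth and determinism", {
  p <- small_panel()
  arch <- simulate_architecture(p$G, p$lib, arch_config(guides_per_hub = 4),
                                seed = 3)
  cfg <- sim_config(depth = 5e4, seed = 7)
  cn <- simulate_assay(arch, p$lib, p$sb, cfg, induced = TRUE)
  cm <- count_matrix(cn)
  expect_true(all(abs(colSums(cm) - cfg$depth) <= 1))
  cn2 <- simulate_assay(arch, p$lib, p$sb, cfg, induced = TRUE)
  expect_identical(as.data.frame(cn), as.data.frame(cn2))
  # neutral pool: expected frequencies constant over time (noiseless)
  arch0 <- simulate_architecture(p$G, p$lib,
                                 arch_config(n_qtl = 0, sigma_b = 0,
                                             frac_efficacious = 0,
                                             hub_styles = character(0)),
                                 seed = 4)
  ncfg <- sim_config(depth = 1e5, noiseless = TRUE, frac_present = 1,
                     seed = 8)
  nn <- count_matrix(simulate_assay(arch0, p$lib, p$sb, ncfg, TRUE))
  expect_lt(max(abs(nn - nn[, 1])), 1e-8)
})

test_that("noiseless growth follows the closed-form logistic", {
  # two lineages s = {0, 0.2}: f_2(10) = e^2 / (1 + e^2)
  cn <- two_lineage_counts()
  cm <- count_matrix(cn)
  f2 <- cm[2, 5] / sum(cm[, 5])
  expect_equal(f2, exp(2) / (1 + exp(2)), tolerance = 1e-12)
  # log frequency ratio exactly linear in t with slope s_i - s_j
  lr <- log(cm[2, ] / cm[1, ])
  tp <- attr(cn, "timepoints")
  expect_equal(unname(diff(lr) / diff(tp)), rep(0.2, 4), tolerance = 1e-10)
})

test_that("chimera injection follows the frequency-linear Poisson model", {
  p <- small_panel(n_seg = 15, n_guides = 10, n_controls = 2)
  arch <- simulate_architecture(p$G, p$lib, arch_config(guides_per_hub = 2),
                                seed = 5)
  cfg <- sim_config(depth = 2e5, seed = 9, frac_present = 0.6)
  cn <- simulate_assay(arch, p$lib, p$sb, cfg, induced = FALSE,
                       assay = "CON")
  # zero coefficients: unchanged
  cn0 <- inject_chimeras(cn, c(0, 0, 0), seed = 1)
  expect_equal(count_matrix(cn0)[cn$lineage_id, ], count_matrix(cn))
  # intercept-only: every pair gains Poisson(depth * c)
  c0 <- 2e-6
  cni <- inject_chimeras(cn, c(c0, 0, 0), seed = 2)
  added <- attr(cni, "chimera_truth")$added
  mu <- 2e5 * c0
  expect_lt(abs(mean(added) - mu), 3 * sqrt(mu / length(added)))
  expect_error(inject_chimeras(cn, c(-1, 0, 0)), "non-negative")
  # realistic coefficients keep the per-segregant chimeric fraction < 10%
  cc <- inject_chimeras(cn, c(0, 5e-4, 5e-4), seed = 3)
  tot_by_seg <- tapply(count_matrix(cc)[, 1], cc$segregant, sum)
  chi_by_seg <- tapply(count_matrix(cc)[, 1] * !cc$valid, cc$segregant, sum)
  expect_true(all(chi_by_seg / tot_by_seg < 0.10))
})

test_that("read emission round-trips and has the right error rate", {
  p <- small_panel(n_seg = 8, n_guides = 6, n_controls = 1)
  arch <- simulate_architecture(p$G, p$lib,
                                arch_config(hub_styles = character(0)),
                                seed = 6)
  cfg <- sim_config(depth = 2000, seed = 10)
  cn <- simulate_assay(arch, p$lib, p$sb, cfg, induced = TRUE)
  r <- emit_reads(cn, read_layout(), timepoint = 1)
  expect_equal(length(r$fwd), sum(round(count_matrix(cn)[, 1])))
  ex <- extract_barcodes(r$fwd, r$rev, r$fwd_qual, r$rev_qual)
  expect_true(all(ex$accepted))
  tl <- tally_counts(
    data.frame(seg_bc = ex$seg_bc, guide_bc = ex$guide_bc, timepoint = 1),
    p$sb, p$lib$guide_barcodes, attr(cn, "combos"),
    timepoints = 0, assay = "ATC1")
  m1 <- count_matrix(cn)[, 1]
  m1 <- m1[m1 > 0]
  m2 <- count_matrix(tl)[names(m1), 1]
  expect_equal(m2, m1)
  # a single lineage with count 5 emits exactly 5 pairs
  one <- cn[which(count_matrix(cn)[, 1] > 0)[1], ]
  one$n_t0 <- 5
  r5 <- emit_reads(one, read_layout(), timepoint = 1)
  expect_equal(length(r5$fwd), 5)
  # substitution rate 0.01: P(barcode hit) = 1 - 0.99^20
  rl <- read_layout(error_rate = 0.01)
  set.seed(11)
  rm <- emit_reads(cn, rl, timepoint = 1)
  frac <- mean(substr(rm$fwd, 1, 20) != cn$guide_bc[
    rep(seq_len(nrow(cn)), round(count_matrix(cn)[, 1]))])
  pexp <- 1 - 0.99^20
  n <- length(rm$fwd)
  expect_lt(abs(frac - pexp), 3 * sqrt(pexp * (1 - pexp) / n))
})

test_that("fastq writing and reading round-trip", {
  reads <- list(fwd = c("ACGTACGTAA", "TTTTCCCCGG"),
                rev = c("GGGGAAAATT", "CACACACACA"),
                fwd_qual = c("FFFFFFFFFF", "FFFFFFFFFF"),
                rev_qual = c("FFFFFFFFFF", "FFFFFFFFFF"))
  pre <- file.path(tempdir(), "rt")
  paths <- write_fastq_pair(reads, pre)
  fq <- read_fastq(paths[1])
  expect_equal(unname(fq$seq), reads$fwd)
  expect_equal(unname(fq$qual), reads$fwd_qual)
  unlink(paths)
})
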