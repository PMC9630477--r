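test_that("significance selection keeps p < threshold with order preserved", {
  stats <- tiny_sumstats(p = c(9e-6, 2e-5, 1e-5, 1e-7),
                         pos = c(1, 2, 3, 4) * 1e6)
  kept <- select_significant(stats, 1e-5)
  expect_identical(kept$SNP, stats$SNP[c(1, 4)])
  # The boundary is exclusive: p = 2e-5 and p = 1e-5 are both dropped.
  expect_false("rs000002" %in% kept$SNP)
  expect_false("rs000003" %in% kept$SNP)
  expect_equal(nrow(select_significant(stats[0, ], 1e-5)), 0)
})

test_that("clumping keeps the more significant variant of a linked pair", {
  # Hand-built haplotypes: columns 1-2 strongly correlated, r^2 > 0.1.
  set.seed(1)
  base <- rbinom(400, 1, 0.3)
  noisy <- ifelse(runif(400) < 0.9, base, 1 - base)
  hap <- cbind(base, noisy)
  expect_gt(cor(base, noisy)^2, 0.1)

  panel <- panel_from_matrix(hap, chr = c(1, 1), pos = c(1e6, 1.1e6))
  subset <- tiny_sumstats(p = c(1e-6, 1e-8), pos = c(1e6, 1.1e6))
  kept <- ld_clump(subset, panel, r2_threshold = 0.1, window_kb = 500)
  expect_identical(kept$SNP, "rs000002")  # the p = 1e-8 index survives

  # Beyond the window the same LD is ignored.
  panel_far <- panel_from_matrix(hap, chr = c(1, 1), pos = c(1e6, 1.6e6))
  subset_far <- tiny_sumstats(p = c(1e-6, 1e-8), pos = c(1e6, 1.6e6))
  kept_far <- ld_clump(subset_far, panel_far, r2_threshold = 0.1,
                       window_kb = 500)
  expect_setequal(kept_far$SNP, subset_far$SNP)
})

test_that("clumping matches the exhaustive pairwise oracle on random panels", {
  for (seed in 1:5) {
    panel <- simulate_ld_panel(n_blocks = 10, block_size = 5, rho = 0.7,
                               n_haplotypes = 400, pos_step = 100e3,
                               seed = seed)
    sim <- simulate_gwas(sim_config(n_snps = 50, causal_beta = 0.2,
                                    seed = seed + 100),
                         variants = panel$variants)
    kept <- ld_clump(sim$exposure, panel, r2_threshold = 0.1, window_kb = 500)
    expect_true(clump_is_valid(sim$exposure, kept, panel, 0.1, 500))
    expect_true(nrow(kept) < 50)  # rho = 0.7 blocks must lose variants
  }
})

test_that("clumping is invariant to input row order", {
  panel <- simulate_ld_panel(n_blocks = 6, block_size = 5, rho = 0.8,
                             n_haplotypes = 500, seed = 9)
  sim <- simulate_gwas(sim_config(n_snps = 30, seed = 10),
                       variants = panel$variants)
  kept1 <- ld_clump(sim$exposure, panel, 0.1, 500)
  set.seed(1)
  shuffled <- sim$exposure[sample.int(30), ]
  kept2 <- ld_clump(shuffled, panel, 0.1, 500)
  expect_identical(kept1$SNP, kept2$SNP)
})

test_that("clumping respects LD extremes and names missing variants", {
  pan0 <- simulate_ld_panel(n_blocks = 3, block_size = 10, rho = 0,
                            n_haplotypes = 10000, seed = 11)
  sim0 <- simulate_gwas(sim_config(n_snps = 30, seed = 12),
                        variants = pan0$variants)
  expect_equal(nrow(ld_clump(sim0$exposure, pan0, 0.1, 500)), 30)

  pan95 <- simulate_ld_panel(n_blocks = 3, block_size = 10, rho = 0.95,
                             n_haplotypes = 10000, seed = 13)
  sim95 <- simulate_gwas(sim_config(n_snps = 30, seed = 14),
                         variants = pan95$variants)
  kept <- ld_clump(sim95$exposure, pan95, 0.1, 500)
  # Neighbours of every retained index within a near-duplicate block go.
  expect_true(clump_is_valid(sim95$exposure, kept, pan95, 0.1, 500))
  expect_lt(nrow(kept), 15)

  stray <- sim0$exposure
  stray$SNP[1] <- "rs_not_in_panel"
  expect_error(ld_clump(stray, pan0, 0.1, 500), "rs_not_in_panel")
})

test_that("harmonization aligns, flips, and drops variants as specified", {
  exposure <- tiny_sumstats(p = rep(1e-8, 5), pos = (1:5) * 1e6,
                            ea = c("A", "A", "A", "A", "A"),
                            oa = c("G", "G", "T", "T", "C"),
                            eaf = c(0.3, 0.3, 0.10, 0.50, 0.3),
                            beta = c(0.1, 0.1, 0.1, 0.1, 0.1))
  outcome <- tiny_sumstats(p = rep(0.5, 5), pos = (1:5) * 1e6,
                           ea = c("A", "G", "A", "A", "A"),
                           oa = c("G", "A", "T", "T", "C"),
                           eaf = c(0.3, 0.7, 0.12, 0.50, 0.3),
                           beta = c(0.2, -0.2, 0.05, 0.05, 0.05))
  h <- harmonize(exposure, outcome)
  # Variant 1: same orientation, untouched.
  expect_equal(h$beta_out[h$SNP == "rs000001"], 0.2)
  # Variant 2: swapped alleles, sign flipped and EAF complemented.
  expect_equal(h$beta_out[h$SNP == "rs000002"], 0.2)
  expect_equal(h$eaf_out[h$SNP == "rs000002"], 0.3)
  expect_true(h$flipped[h$SNP == "rs000002"])
  # Variant 3: palindromic with concordant informative frequencies, kept.
  expect_true("rs000003" %in% h$SNP)
  expect_false(h$flipped[h$SNP == "rs000003"])
  # Variant 4: palindromic at EAF 0.5, ambiguous, dropped.
  expect_false("rs000004" %in% h$SNP)
  expect_equal(attr(h, "log")$n_palindromic_dropped, 1)
})

test_that("incompatible allele pairs and missing variants are dropped, not fatal", {
  exposure <- tiny_sumstats(p = rep(1e-8, 3), pos = (1:3) * 1e6,
                            ea = c("A", "A", "A"), oa = c("G", "G", "G"))
  outcome <- tiny_sumstats(p = rep(0.5, 2), pos = (1:2) * 1e6,
                           snp = c("rs000001", "rs000002"),
                           ea = c("A", "A"), oa = c("G", "C"))
  h <- harmonize(exposure, outcome)
  expect_identical(h$SNP, "rs000001")
  log <- attr(h, "log")
  expect_equal(log$n_incompatible, 1)   # A/G vs A/C
  expect_equal(log$n_missing_outcome, 1)
})

test_that("strand-complement alleles are recognised", {
  exposure <- tiny_sumstats(p = 1e-8, pos = 1e6, ea = "A", oa = "G")
  outcome <- tiny_sumstats(p = 0.5, pos = 1e6, ea = "C", oa = "T",
                           beta = -0.3)  # T/C is the complement of A/G, swapped
  h <- harmonize(exposure, outcome)
  expect_equal(nrow(h), 1)
  expect_true(h$flipped)
  expect_equal(h$beta_out, 0.3)
})

test_that("PVE and F statistics follow the stated formulas and threshold", {
  n <- 3757L
  # With se = 1/sqrt(n), PVE = b^2 / (b^2 + 1) and F = (n-2) * b^2.
  b <- sqrt(c(9.9, 10.0, 37) / (n - 2))
  x <- tiny_sumstats(p = rep(1e-8, 3), pos = (1:3) * 1e6, beta = b,
                     se = rep(1 / sqrt(n), 3), eaf = rep(0.25, 3), n = n)
  strength <- compute_strength(x, n = n, min_f = 10)
  expect_equal(x$BETA^2 / (x$BETA^2 + 1),
               (2 * x$EAF * (1 - x$EAF) * x$BETA^2) /
                 (2 * x$EAF * (1 - x$EAF) * x$BETA^2 +
                    2 * x$EAF * (1 - x$EAF) * x$SE^2 * n))
  # Weak instruments (F < 10) are removed; F at or above 10 retained.
  expect_false("rs000001" %in% strength$SNP)   # F ~ 9.9
  expect_true("rs000003" %in% strength$SNP)    # F ~ 37
  expect_true(all(strength$f_stat >= 10))
  dropped <- attr(strength, "dropped")
  expect_true(all(dropped$f_stat < 10))
  # The threshold is inclusive: a variant whose F equals it exactly stays.
  f_mid <- compute_strength(x, n = n, min_f = 0)$f_stat[2]
  at_boundary <- compute_strength(x, n = n, min_f = f_mid)
  expect_true("rs000002" %in% at_boundary$SNP)
})

test_that("a zero effect has zero PVE and is removed as weak", {
  x <- tiny_sumstats(p = c(1e-8, 1e-8), pos = c(1, 2) * 1e6,
                     beta = c(0, 0.2))
  strength <- compute_strength(x, n = 3757L)
  expect_identical(strength$SNP, "rs000002")
  expect_equal(attr(strength, "dropped")$pve, 0)
  expect_equal(attr(strength, "dropped")$f_stat, 0)
})

test_that("set-level F matches the k-instrument formula", {
  # Construct a single instrument with R^2 = 0.01 at n = 3757:
  # F = ((n - 2) / 1) * 0.01 / 0.99 ~ 37.93.
  n <- 3757L
  b <- sqrt(0.01 / 0.99)   # PVE = b^2/(b^2+1) = 0.01
  x <- tiny_sumstats(p = 1e-8, pos = 1e6, beta = b, se = 1 / sqrt(n), n = n)
  strength <- compute_strength(x, n = n)
  expect_equal(attr(strength, "r2_set"), 0.01, tolerance = 1e-12)
  expect_equal(attr(strength, "f_set"), (n - 1 - 1) * 0.01 / 0.99,
               tolerance = 1e-9)
  expect_equal(attr(strength, "f_set"), 37.93, tolerance = 0.01)
  expect_error(compute_strength(x, n = 2L), "n must be")
})

test_that("the selection pipeline only ever shrinks the variant set", {
  panel <- simulate_ld_panel(n_blocks = 8, block_size = 6, rho = 0.6,
                             n_haplotypes = 500, seed = 41)
  sim <- simulate_gwas(sim_config(n_snps = 48, causal_beta = 0.3,
                                  flip_frac = 0.3, seed = 42),
                       variants = panel$variants)
  sig <- select_significant(sim$exposure, 1e-3)
  clumped <- ld_clump(sig, panel, 0.1, 500)
  h <- harmonize(sim$exposure, sim$outcome, ids = clumped$SNP)
  strength <- compute_strength(h, min_f = 10)
  counts <- c(nrow(sim$exposure), nrow(sig), nrow(clumped), nrow(h),
              nrow(strength))
  expect_true(all(diff(counts) <= 0))

  sel <- select_instruments(sim$exposure, sim$outcome, panel,
                            p_threshold = 1e-3)
  expect_identical(sort(sel$harmonized$SNP), sort(strength$SNP))
  expect_true(all(sel$fate$fate %in%
                    c("kept", "clumped", "not_harmonized", "weak_instrument")))
  expect_setequal(sel$fate$SNP[sel$fate$fate == "kept"], strength$SNP)
})
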