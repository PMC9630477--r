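test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_snps = 0), "n_snps")
  expect_error(sim_config(n_exp = 1), "sample sizes")
  expect_error(sim_config(invalid_frac = 1.2), "invalid_frac")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("reported SEs match the analytic binomial-variance formula and p-values match z", {
  sim <- simulate_gwas(sim_config(n_snps = 200, seed = 42))
  for (tab in list(sim$exposure, sim$outcome)) {
    expect_equal(tab$SE, 1 / sqrt(2 * tab$N * tab$EAF * (1 - tab$EAF)))
    expect_equal(tab$P, 2 * pnorm(-abs(tab$BETA / tab$SE)), tolerance = 1e-6)
    expect_true(all(tab$P > 0 & tab$P <= 1))
    expect_false(anyDuplicated(tab$SNP) > 0)
  }
})

test_that("a fixed seed reproduces byte-identical tables", {
  cfg <- sim_config(n_snps = 50, causal_beta = 0.3, invalid_frac = 0.3,
                    flip_frac = 0.5, seed = 99)
  expect_identical(simulate_gwas(cfg), simulate_gwas(cfg))
  pan_a <- simulate_ld_panel(n_blocks = 3, block_size = 4, seed = 7)
  pan_b <- simulate_ld_panel(n_blocks = 3, block_size = 4, seed = 7)
  expect_identical(pan_a, pan_b)
  med_cfg <- sim_config(n_snps = 30, seed = 5)
  expect_identical(simulate_mediation_gwas(med_cfg),
                   simulate_mediation_gwas(med_cfg))
})

test_that("null model gives centred Wald z-scores and N(0,1) calibration", {
  sim <- simulate_gwas(sim_config(n_snps = 100, causal_beta = 0, seed = 1))
  z <- (sim$outcome$BETA / sim$exposure$BETA) /
    (sim$outcome$SE / abs(sim$exposure$BETA))
  expect_lt(abs(mean(z)), 3 / sqrt(100))

  # Calibration across replicates: per-SNP Wald z-scores should be
  # indistinguishable from standard normal in almost every null data set.
  set.seed(2024)
  n_rep <- 2000
  pass <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    s <- simulate_gwas(sim_config(n_snps = 100, causal_beta = 0))
    z <- (s$outcome$BETA / s$exposure$BETA) /
      (s$outcome$SE / abs(s$exposure$BETA))
    pass[i] <- stats::ks.test(z, "pnorm")$p.value > 0.01
  }
  expect_gte(mean(pass), 0.98)
})

test_that("noiseless limit recovers the causal slope exactly", {
  sim <- simulate_gwas(sim_config(n_snps = 50, causal_beta = 0.5,
                                  n_exp = 1e18, n_out = 1e18, seed = 3))
  ratio <- sim$outcome$BETA / sim$exposure$BETA
  expect_equal(ratio, rep(0.5, 50), tolerance = 1e-4)
})

test_that("planted pleiotropy has the configured directional mean", {
  sim <- simulate_gwas(sim_config(n_snps = 10000, causal_beta = 0.5,
                                  invalid_frac = 1, pleio_mean = 0.1,
                                  pleio_sd = 0.05, n_exp = 1e8, n_out = 1e8,
                                  seed = 4))
  # With negligible sampling noise, Gamma_j - 0.5 * gamma_j recovers alpha_j.
  alpha_hat <- sim$outcome$BETA - 0.5 * sim$exposure$BETA
  se_mean <- sd(alpha_hat) / sqrt(length(alpha_hat))
  expect_lt(abs(mean(alpha_hat) - 0.1), 3 * se_mean)
  expect_equal(sim$truth$valid, rep(FALSE, 10000))
})

test_that("InSIDE violation couples pleiotropy to instrument strength", {
  sim <- simulate_gwas(sim_config(n_snps = 5000, invalid_frac = 1,
                                  inside_kappa = 0.5, pleio_sd = 0.01,
                                  seed = 8))
  expect_gt(cor(sim$truth$alpha, sim$truth$gamma), 0.9)
})

test_that("allele-label flipping preserves the underlying association", {
  cfg <- sim_config(n_snps = 200, causal_beta = 0.4, flip_frac = 0.5, seed = 11)
  sim <- simulate_gwas(cfg)
  flipped <- sim$outcome$EA != sim$exposure$EA
  expect_gt(sum(flipped), 50)
  # Undoing the flip restores the original orientation.
  restored <- ifelse(flipped, -sim$outcome$BETA, sim$outcome$BETA)
  expect_equal(unname(coef(lm(restored ~ 0 + sim$exposure$BETA))), 0.4,
               tolerance = 0.05)
})

test_that("LD panel reproduces the AR(1) correlation structure", {
  # Independence: rho = 0 leaves all pairs essentially uncorrelated.
  pan0 <- simulate_ld_panel(n_blocks = 2, block_size = 5, rho = 0,
                            n_haplotypes = 1000, seed = 21)
  r2 <- ld_r2(pan0)
  expect_lt(max(r2[upper.tri(r2)]), 0.05)

  # Adjacent-pair r^2 matches rho^2 of the generating process.  Binary
  # allele counts at low frequency make the per-pair sample r^2 noticeably
  # noisier than a Gaussian bound would suggest, so the sharp comparison is
  # on the mean over adjacent pairs.
  pan9 <- simulate_ld_panel(n_blocks = 5, block_size = 6, rho = 0.9,
                            n_haplotypes = 10000, seed = 22)
  r2 <- ld_r2(pan9)
  adj <- vapply(seq_len(5), function(b) {
    cols <- (b - 1) * 6 + seq_len(6)
    diag(r2[cols[-6], cols[-1]])
  }, numeric(5))
  expect_lt(abs(mean(adj) - 0.81), 0.02)
  expect_lt(max(abs(adj - 0.81)), 0.08)

  # Variants in different blocks stay independent.
  cross <- r2[1:6, 7:30]
  expect_lt(max(cross), 0.05)

  # Lag-2 correlation decays as rho^2 (AR(1), not constant-within-block).
  lag2 <- vapply(seq_len(5), function(b) {
    cols <- (b - 1) * 6 + seq_len(6)
    diag(r2[cols[1:4], cols[3:6]])
  }, numeric(4))
  expect_lt(max(abs(lag2 - 0.9^4)), 0.03)
})

test_that("panel rejects degenerate configurations", {
  expect_error(simulate_ld_panel(rho = 1), "rho")
  expect_error(simulate_ld_panel(n_haplotypes = 1), "n_haplotypes")
  expect_error(simulate_ld_panel(n_blocks = 0), "positive integer")
})

test_that("mediation generator records coherent ground truth", {
  cfg <- sim_config(n_snps = 40, seed = 31)
  med <- simulate_mediation_gwas(cfg, a = 0.8, b = 0.5, c_direct = 0.1)
  expect_equal(med$truth$total, 0.5)
  expect_equal(med$truth$indirect, 0.4)
  expect_equal(med$truth$proportion, 0.8)
  expect_equal(med$truth$total, med$truth$c + med$truth$a * med$truth$b)
  expect_equal(nrow(med$exposure), 80)

  # A zeroed path means a zero indirect effect.
  med0 <- simulate_mediation_gwas(sim_config(n_snps = 20, seed = 32), a = 0)
  expect_equal(med0$truth$indirect, 0)
})

test_that("noiseless mediation data reproduce the total effect via Wald ratios", {
  cfg <- sim_config(n_snps = 30, n_exp = 1e18, n_out = 1e18, seed = 33)
  med <- simulate_mediation_gwas(cfg, a = 0.8, b = 0.5, c_direct = 0.1,
                                 n_med = 1e18, med_direct_sd = 0)
  exp_snps <- med$truth$exposure_snps
  i <- match(exp_snps, med$exposure$SNP)
  ratios <- med$outcome$BETA[i] / med$exposure$BETA[i]
  expect_equal(ratios, rep(0.5, length(i)), tolerance = 1e-3)
})
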