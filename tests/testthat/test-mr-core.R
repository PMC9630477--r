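test_that("Wald ratio follows the delta method and guards its domain", {
  est <- wald_ratio(0.1, 0.02, 0.2, 0.05)
  expect_equal(est$beta, 2.0)
  expect_equal(est$se, 0.05 / abs(0.1))  # first-order: out_se / |exp_beta|
  est2 <- wald_ratio(0.1, 0.02, 0.2, 0.05, second_order = TRUE)
  expect_equal(est2$se, sqrt(0.05^2 / 0.1^2 + 0.2^2 * 0.02^2 / 0.1^4))
  expect_gt(est2$se, est$se)
  expect_error(wald_ratio(0, 0.02, 0.2, 0.05), "zero")
})

test_that("IVW degenerates to the Wald ratio for a single instrument", {
  h <- make_h(1, seed = 1)
  expect_equal(mr_ivw(h)$beta,
               wald_ratio(h$beta_exp, h$se_exp, h$beta_out, h$se_out)$beta)
  expect_equal(mr_ivw(h)$se, h$se_out / abs(h$beta_exp))
})

test_that("equal-weight symmetric ratios average exactly", {
  h <- data.frame(SNP = c("a", "b", "c"),
                  beta_exp = c(1, 1, 1), se_exp = 0.01,
                  beta_out = c(0.4, 0.5, 0.6), se_out = 0.1)
  expect_equal(mr_ivw(h, "fixed")$beta, 0.5)
  expect_equal(mr_weighted_median(h, n_boot = 100, seed = 1)$beta, 0.5)
})

test_that("IVW, Egger and the weighted median match their brute-force oracles", {
  for (seed in 1:25) {
    h <- random_h(J = sample(3:20, 1), seed = seed)
    ivw <- mr_ivw(h, "fixed")
    orc <- oracle_ivw_fixed(h)
    expect_equal(ivw$beta, orc$beta, tolerance = 1e-10)
    expect_equal(ivw$se, orc$se, tolerance = 1e-10)

    rnd <- mr_ivw(h, "random")
    orc_r <- oracle_ivw_random(h)
    expect_equal(rnd$se, orc_r$se, tolerance = 1e-10)

    egger <- mr_egger(h)
    orc_e <- oracle_egger(h)
    expect_equal(egger$slope$beta, orc_e$slope, tolerance = 1e-10)
    expect_equal(egger$intercept$beta, orc_e$intercept, tolerance = 1e-10)
    expect_equal(egger$slope$se, orc_e$slope_se, tolerance = 1e-9)
    expect_equal(egger$intercept$se, orc_e$intercept_se, tolerance = 1e-9)

    wm <- mr_weighted_median(h, n_boot = 100, seed = seed)
    r <- h$beta_out / h$beta_exp
    w <- h$beta_exp^2 / h$se_out^2
    expect_equal(wm$beta, oracle_weighted_median(r, w), tolerance = 1e-10)

    q <- cochran_q(h)
    expect_equal(q$Q, oracle_cochran_q(h), tolerance = 1e-10)
    expect_equal(q$df, nrow(h) - 1)
  }
})

test_that("the auto rule switches to random effects only under heterogeneity", {
  hom <- make_h(20, seed = 2, sy = 0.01, sx = 0)
  est <- mr_ivw(hom, "auto")
  expect_identical(est$method,
                   if (attr(est, "Q_pval") < 0.05) "ivw_random" else "ivw_fixed")
  # Strong planted heterogeneity forces the random-effect variant.
  het <- make_h(20, seed = 3, sy = 0.01, sx = 0,
                alpha = rnorm(20, 0, 0.2))
  est_het <- mr_ivw(het, "auto")
  expect_identical(est_het$method, "ivw_random")
  expect_gt(est_het$se, mr_ivw(het, "fixed")$se)
})

test_that("an exact linear relation is reproduced by MR-Egger with zero residual", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  h <- data.frame(SNP = letters[1:5], beta_exp = x, se_exp = 0.01,
                  beta_out = 0.1 + 0.3 * x, se_out = c(1, 2, 1, 2, 1) * 0.01)
  egger <- mr_egger(h)
  expect_equal(egger$intercept$beta, 0.1, tolerance = 1e-10)
  expect_equal(egger$slope$beta, 0.3, tolerance = 1e-10)
  expect_equal(egger$sigma, 0, tolerance = 1e-6)
  expect_error(mr_egger(h[1:2, ]), "at least 3")
})

test_that("weighted median interpolates cumulative weights correctly", {
  h <- data.frame(SNP = c("a", "b", "c"), beta_exp = 1, se_exp = 0.01,
                  beta_out = c(0.2, 0.5, 0.9), se_out = 0.1)
  expect_equal(mr_weighted_median(h, n_boot = 100, seed = 1)$beta, 0.5)

  # One ratio carrying 60% of the weight is the median.
  w_target <- c(0.2, 0.6, 0.2)
  h2 <- data.frame(SNP = c("a", "b", "c"),
                   beta_exp = 1, se_exp = 0.01,
                   beta_out = c(0.1, 0.7, 1.5),
                   se_out = 1 / sqrt(w_target))
  expect_equal(mr_weighted_median(h2, n_boot = 100, seed = 1)$beta, 0.7)

  # Unequal-weight 4-ratio instance against the interpolation oracle.
  h4 <- random_h(4, seed = 77)
  r <- h4$beta_out / h4$beta_exp
  w <- h4$beta_exp^2 / h4$se_out^2
  expect_equal(mr_weighted_median(h4, n_boot = 100, seed = 2)$beta,
               oracle_weighted_median(r, w), tolerance = 1e-12)
  expect_error(mr_weighted_median(h4[1:2, ], n_boot = 100), "at least 3")

  # The bootstrap SE is reproducible under a fixed seed.
  a <- mr_weighted_median(h4, n_boot = 200, seed = 5)
  b <- mr_weighted_median(h4, n_boot = 200, seed = 5)
  expect_identical(a, b)
})

test_that("Cochran's Q is zero for identical ratios and chi-square on average", {
  h <- data.frame(SNP = c("a", "b"), beta_exp = c(0.1, 0.2), se_exp = 0.01,
                  beta_out = c(0.05, 0.10), se_out = c(0.01, 0.02))
  q <- cochran_q(h)
  expect_lt(q$Q, 1e-15)
  expect_equal(q$pval, 1)
  expect_equal(q$df, 1)
  expect_error(cochran_q(h[1, ]), "at least 2")

  # Homogeneous replicates: E[Q] = J - 1 (chi-square moment).
  set.seed(6)
  J <- 10
  qs <- replicate(2000, {
    hh <- data.frame(SNP = as.character(seq_len(J)), beta_exp = 1,
                     se_exp = 0, beta_out = rnorm(J, 0.3, 0.05),
                     se_out = 0.05)
    cochran_q(hh)$Q
  })
  expect_lt(abs(mean(qs) - (J - 1)), 3 * sqrt(2 * (J - 1) / 2000))
})

test_that("estimates are invariant to allele orientation", {
  # Flipping the reported effect allele of any variant (negating both
  # betas) leaves every estimator unchanged.
  h <- random_h(8, seed = 90)
  flip <- c(2, 5, 7)
  h2 <- h
  h2$beta_exp[flip] <- -h2$beta_exp[flip]
  h2$beta_out[flip] <- -h2$beta_out[flip]
  expect_equal(mr_ivw(h, "fixed")$beta, mr_ivw(h2, "fixed")$beta)
  expect_equal(mr_egger(h)$slope$beta, mr_egger(h2)$slope$beta)
  expect_equal(mr_egger(h)$intercept$beta, mr_egger(h2)$intercept$beta)
  expect_equal(mr_weighted_median(h, n_boot = 100, seed = 1)$beta,
               mr_weighted_median(h2, n_boot = 100, seed = 1)$beta)
})

test_that("mr_fit bundles the estimator suite with a primary tag", {
  sim <- simulate_gwas(sim_config(n_snps = 40, causal_beta = 0.3, seed = 17))
  h <- harmonize(sim$exposure, sim$outcome)
  fit <- mr_fit(h, n_boot = 200, seed = 1)
  expect_s3_class(fit, "mr_fit")
  expect_setequal(fit$estimates$method,
                  c("ivw_fixed", "ivw_random", "egger_slope",
                    "egger_intercept", "weighted_median"))
  expect_true(fit$primary %in% c("ivw_fixed", "ivw_random"))
  expect_equal(unname(coef(fit)["ivw_fixed"]),
               mr_ivw(h, "fixed")$beta)
  ci <- confint(fit)
  expect_true(all(ci[, 1] < ci[, 2]))
  expect_equal(length(residuals(fit)), nrow(h))
  expect_output(print(summary(fit)), "Cochran")
})
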