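# Leave-one-out IVW slopes for weighted regression through the origin.
.loo_slopes <- function(x, y, w) {
  sxy <- sum(w * x * y)
  sxx <- sum(w * x^2)
  (sxy - w * x * y) / (sxx - w * x^2)
}

#' MR-PRESSO residual-sum, outlier and distortion tests
#'
#' Simulation-based pleiotropy diagnostics.  The global test compares the
#' observed weighted residual sum of squares of leave-one-out-predicted
#' outcome effects against its null distribution obtained by redrawing, in
#' each of `n_sim` simulations, exposure effects from
#' `N(beta_exp, se_exp^2)` and outcome effects from their leave-one-out
#' model predictions `N(b_loo * beta_exp, se_out^2)`.  The outlier test
#' compares each variant's observed weighted squared residual against its
#' simulated distribution, declaring outliers at the Bonferroni level
#' `outlier_alpha / J`.  The distortion test compares the relative change
#' in the fixed-effect IVW estimate after removing the flagged outliers
#' against removals of random subsets of the same size.  Empirical p-values
#' use the `(1 + exceedances) / (1 + n_sim)` convention.
#'
#' @param h a harmonized data frame with at least 4 instruments.
#' @param n_sim simulations for the null distributions (default 1000).
#' @param seed integer seed.
#' @param outlier_alpha family-wise level for the outlier test (default
#'   0.05, Bonferroni-corrected over instruments).
#' @return A list of class `mr_presso` with `global_rss`, `global_pval`,
#'   `outlier_pvals`, `outliers` (integer indices into `h`),
#'   `distortion`, `distortion_pval`, and the IVW estimates with
#'   (`beta_all`) and without (`beta_outlier_free`) the flagged variants.
#' @export
mr_presso <- function(h, n_sim = 1000, seed = NULL, outlier_alpha = 0.05) {
  .check_harmonized(h)
  J <- nrow(h)
  .assert(J >= 4, "MR-PRESSO requires at least 4 instruments (got %d)", J)
  .assert(.is_count(n_sim, 10), "n_sim must be an integer >= 10")
  .assert(.is_number(outlier_alpha) && outlier_alpha > 0 && outlier_alpha <= 1,
          "outlier_alpha must lie in (0, 1]")
  .maybe_seed(seed)

  x <- h$beta_exp; y <- h$beta_out
  sx <- h$se_exp; sy <- h$se_out
  w <- 1 / sy^2
  b_loo <- .loo_slopes(x, y, w)
  resid_obs <- y - b_loo * x
  d_obs <- w * resid_obs^2          # per-variant weighted squared residual
  rss_obs <- sum(d_obs)

  # Null simulations, vectorized across replicates (rows).
  xs <- matrix(rnorm(n_sim * J, mean = rep(x, each = n_sim),
                     sd = rep(sx, each = n_sim)), n_sim, J)
  ys <- matrix(rnorm(n_sim * J, mean = rep(b_loo * x, each = n_sim),
                     sd = rep(sy, each = n_sim)), n_sim, J)
  wm <- matrix(rep(w, each = n_sim), n_sim, J)
  sxy <- drop((xs * ys) %*% w)
  sxx <- drop((xs * xs) %*% w)
  b_loo_sim <- (sxy - wm * xs * ys) / (sxx - wm * xs * xs)
  d_sim <- wm * (ys - b_loo_sim * xs)^2
  rss_sim <- rowSums(d_sim)

  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (1 + n_sim)
  outlier_pvals <- (1 + colSums(d_sim >= rep(d_obs, each = n_sim))) / (1 + n_sim)
  outliers <- which(outlier_pvals < outlier_alpha / J)

  beta_all <- sum(w * x * y) / sum(w * x^2)
  distortion <- NA_real_
  distortion_pval <- NA_real_
  beta_free <- NA_real_
  if (length(outliers) > 0 && J - length(outliers) >= 2) {
    keep <- setdiff(seq_len(J), outliers)
    beta_free <- sum(w[keep] * x[keep] * y[keep]) / sum(w[keep] * x[keep]^2)
    distortion <- (beta_free - beta_all) / abs(beta_all)
    d_null <- vapply(seq_len(n_sim), function(i) {
      drop_i <- sample.int(J, length(outliers))
      ki <- setdiff(seq_len(J), drop_i)
      bi <- sum(w[ki] * x[ki] * y[ki]) / sum(w[ki] * x[ki]^2)
      (bi - beta_all) / abs(beta_all)
    }, numeric(1))
    distortion_pval <- (1 + sum(abs(d_null) >= abs(distortion))) / (1 + n_sim)
  }
  structure(list(global_rss = rss_obs, global_pval = global_pval,
                 outlier_pvals = outlier_pvals, outliers = outliers,
                 outlier_snps = h$SNP[outliers],
                 distortion = distortion, distortion_pval = distortion_pval,
                 beta_all = beta_all, beta_outlier_free = beta_free,
                 n_sim = n_sim, outlier_alpha = outlier_alpha),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO (%d simulations)\n", x$n_sim))
  cat(sprintf("  global RSS = %.4g, p = %.4g\n", x$global_rss, x$global_pval))
  if (length(x$outliers) > 0) {
    cat(sprintf("  outliers (Bonferroni %g): %s\n", x$outlier_alpha,
                paste(x$outlier_snps, collapse = ", ")))
    cat(sprintf("  distortion = %.3g (p = %.4g)\n", x$distortion,
                x$distortion_pval))
  } else {
    cat("  no outliers detected\n")
  }
  invisible(x)
}

#' Cook's-distance exclusion of influential instruments
#'
#' Cook's distances from the weighted IVW regression of outcome on exposure
#' effects through the origin (weights `1 / se_out^2`); instruments with
#' distance above `4 / J` are flagged for exclusion.  When all points lie
#' exactly on the fitted line (zero residual variance) no instrument is
#' excluded.
#'
#' @param h a harmonized data frame with at least 3 instruments.
#' @param threshold exclusion threshold; defaults to `4 / J`.
#' @return A list with `distances`, `threshold` and `excluded` (integer
#'   indices into `h`).
#' @export
cooks_exclusion <- function(h, threshold = NULL) {
  .check_harmonized(h)
  J <- nrow(h)
  .assert(J >= 3, "Cook's-distance exclusion requires at least 3 instruments (got %d)", J)
  threshold <- threshold %||% (4 / J)
  .assert(.is_number(threshold) && threshold > 0, "threshold must be > 0")
  w <- 1 / h$se_out^2
  fit <- lm(beta_out ~ 0 + beta_exp, data = h, weights = w)
  if (sum(w * fit$residuals^2) < 1e-12) {
    d <- setNames(rep(0, J), h$SNP)
  } else {
    d <- setNames(as.numeric(cooks.distance(fit)), h$SNP)
  }
  list(distances = d, threshold = threshold,
       excluded = which(unname(d) > threshold))
}

#' Re-estimate after removing pleiotropic instruments
#'
#' Repeats the full univariable estimator suite on the instrument set with
#' the given indices removed, pairing the pre- and post-removal fits.
#'
#' @param h a harmonized data frame.
#' @param excluded integer indices (into the rows of `h`) to remove; an
#'   empty set returns the original fit on both sides.
#' @param ... passed to [mr_fit()].
#' @return A list with `pre` and `post` (`mr_fit` objects) and `excluded`.
#' @export
rerun_after_removal <- function(h, excluded, ...) {
  .check_harmonized(h)
  excluded <- as.integer(excluded)
  .assert(all(excluded >= 1 & excluded <= nrow(h)),
          "excluded indices must address rows of the harmonized set")
  pre <- mr_fit(h, ...)
  if (length(excluded) == 0L) {
    return(list(pre = pre, post = pre, excluded = excluded))
  }
  remaining <- h[-excluded, , drop = FALSE]
  .assert(nrow(remaining) >= 2,
          "fewer than 2 instruments remain after removal")
  list(pre = pre, post = mr_fit(remaining, ...), excluded = excluded)
}

#' Full sensitivity suite for one instrument set
#'
#' Bundles Cochran's Q, the MR-Egger intercept, MR-PRESSO and
#' Cook's-distance exclusion, then re-runs the estimators with the union of
#' flagged instruments removed.  All diagnostics are reported side by side;
#' no precedence is imposed among them.
#'
#' @param h a harmonized data frame with at least 4 instruments.
#' @param n_sim MR-PRESSO simulations.
#' @param seed integer seed.
#' @param outlier_alpha MR-PRESSO outlier-test level.
#' @param ... passed to [mr_fit()] for the re-run.
#' @return An object of class `mr_sensitivity` with components `q`,
#'   `egger_intercept`, `presso`, `cooks`, `excluded` (union of flagged
#'   indices) and `rerun`.
#' @export
mr_sensitivity <- function(h, n_sim = 1000, seed = NULL,
                           outlier_alpha = 0.05, ...) {
  .check_harmonized(h)
  .maybe_seed(seed)
  q <- cochran_q(h)
  egger <- mr_egger(h)
  presso <- mr_presso(h, n_sim = n_sim, outlier_alpha = outlier_alpha)
  cooks <- cooks_exclusion(h)
  excluded <- sort(union(presso$outliers, cooks$excluded))
  rerun <- if (length(excluded) > 0 && nrow(h) - length(excluded) >= 2) {
    rerun_after_removal(h, excluded, ...)
  } else {
    NULL
  }
  structure(list(q = q, egger_intercept = egger$intercept, presso = presso,
                 cooks = cooks, excluded = excluded, rerun = rerun),
            class = "mr_sensitivity")
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  cat("MR sensitivity report\n")
  cat(sprintf("  Cochran's Q = %.4g on %d df (p = %.3g)\n", x$q$Q, x$q$df,
              x$q$pval))
  cat(sprintf("  Egger intercept = %.4g (p = %.3g)\n",
              x$egger_intercept$beta, x$egger_intercept$pval))
  cat(sprintf("  MR-PRESSO global p = %.4g; %d outlier(s)\n",
              x$presso$global_pval, length(x$presso$outliers)))
  cat(sprintf("  Cook's distance > %.3g: %d instrument(s)\n",
              x$cooks$threshold, length(x$cooks$excluded)))
  if (!is.null(x$rerun)) {
    cat(sprintf("  re-run without %d flagged instrument(s): primary beta %.4g -> %.4g\n",
                length(x$excluded),
                x$rerun$pre$estimates$beta[match(x$rerun$pre$primary,
                                                 x$rerun$pre$estimates$method)],
                x$rerun$post$estimates$beta[match(x$rerun$post$primary,
                                                  x$rerun$post$estimates$method)]))
  }
  invisible(x)
}

#' Reverse-direction MR with stricter instrument selection
#'
#' Runs the estimator suite with trait roles swapped: instruments are
#' selected from the original outcome's GWAS at the genome-wide threshold
#' `p < 5e-8` with clumping at `r^2 = 0.01` (window 500 kb), strength
#' filtered, and used to estimate the effect of the outcome trait on the
#' original exposure trait.
#'
#' @param outcome_stats summary statistics of the trait now acting as
#'   exposure (the original outcome).
#' @param exposure_stats summary statistics of the trait now acting as
#'   outcome (the original exposure).
#' @param panel optional `ld_panel` for clumping.
#' @param p_threshold,r2_threshold,window_kb,min_f selection parameters
#'   (defaults 5e-8, 0.01, 500, 10).
#' @param ... passed to [mr_fit()].
#' @return An `mr_fit` with an `"selection"` attribute recording the
#'   instrument-selection log.
#' @export
reverse_mr <- function(outcome_stats, exposure_stats, panel = NULL,
                       p_threshold = 5e-8, r2_threshold = 0.01,
                       window_kb = 500, min_f = 10, ...) {
  sel <- select_significant(outcome_stats, p_threshold)
  .assert(nrow(sel) > 0,
          "no reverse-direction instruments at p < %g", p_threshold)
  selection <- select_instruments(outcome_stats, exposure_stats, panel,
                                  p_threshold = p_threshold,
                                  r2_threshold = r2_threshold,
                                  window_kb = window_kb, min_f = min_f)
  h <- selection$harmonized
  .assert(nrow(h) > 0,
          "no reverse-direction instruments survive harmonization and strength filtering")
  fit <- mr_fit(h, ...)
  attr(fit, "selection") <- selection
  fit
}
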