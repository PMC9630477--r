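#' Wald ratio estimate for a single instrument
#'
#' The per-variant causal-effect estimate `out_beta / exp_beta`.  The
#' default standard error is the first-order delta-method value
#' `out_se / |exp_beta|` (exposure-side noise ignored, consistent with IVW
#' weighting by outcome standard errors); `second_order = TRUE` adds the
#' exposure-noise term `out_beta^2 exp_se^2 / exp_beta^4`.
#'
#' @param exp_beta,exp_se exposure effect and standard error.
#' @param out_beta,out_se outcome effect and standard error.
#' @param second_order use the second-order delta-method standard error.
#' @return A one-row MR estimate data frame (`method`, `n_snps`, `beta`,
#'   `se`, `ci_lower`, `ci_upper`, `pval`).
#' @export
wald_ratio <- function(exp_beta, exp_se, out_beta, out_se,
                       second_order = FALSE) {
  .assert(.is_number(exp_beta) && .is_number(out_beta) &&
            .is_number(exp_se) && .is_number(out_se),
          "wald_ratio expects scalar effects and standard errors")
  .assert(exp_beta != 0, "Wald ratio undefined: exposure effect is zero")
  .assert(out_se > 0, "out_se must be > 0")
  beta <- out_beta / exp_beta
  se <- if (second_order) {
    sqrt(out_se^2 / exp_beta^2 + out_beta^2 * exp_se^2 / exp_beta^4)
  } else {
    out_se / abs(exp_beta)
  }
  .mr_row("wald", beta, se, .p_from_z(beta / se), 1L)
}

# Wald ratios and their first-order weights for a harmonized set.
.ratios <- function(h) {
  .assert(all(h$beta_exp != 0),
          "Wald ratio undefined: zero exposure effect for variant(s) %s",
          paste(h$SNP[h$beta_exp == 0], collapse = ", "))
  list(r = h$beta_out / h$beta_exp,
       w = h$beta_exp^2 / h$se_out^2)  # = 1 / se(ratio)^2
}

#' Inverse-variance-weighted estimate
#'
#' Meta-analysis of the per-variant Wald ratios with weights
#' `1 / se(ratio)^2`, equivalent to weighted least squares of outcome on
#' exposure effects through the origin with weights `1 / se_out^2`.
#' `"fixed"` uses `SE = 1 / sqrt(sum w_j)`; `"random"` applies
#' multiplicative over-dispersion, multiplying the SE by
#' `max(1, sqrt(Q / (J - 1)))`; `"auto"` follows the heterogeneity rule:
#' fixed effects unless Cochran's Q has p < 0.05, in which case random
#' effects are used.  A single instrument degrades to the Wald ratio.
#'
#' @param h a harmonized data frame (see [harmonize()]).
#' @param effects `"auto"`, `"fixed"` or `"random"`.
#' @return A one-row MR estimate data frame; the method tag records which
#'   variant was used (`ivw_fixed` / `ivw_random`, or `wald` when J = 1).
#' @export
mr_ivw <- function(h, effects = c("auto", "fixed", "random")) {
  .check_harmonized(h)
  effects <- match.arg(effects)
  J <- nrow(h)
  .assert(J >= 1, "IVW requires at least one instrument")
  if (J == 1L) {
    return(wald_ratio(h$beta_exp, h$se_exp, h$beta_out, h$se_out))
  }
  fit <- .wls_origin(h$beta_exp, h$beta_out, 1 / h$se_out^2)
  q <- sum((1 / h$se_out^2) * fit$resid^2)  # Cochran's Q on the ratio scale
  q_pval <- pchisq(q, df = J - 1, lower.tail = FALSE)
  scale <- max(1, fit$sigma)                # sigma = sqrt(Q / (J - 1))
  use_random <- switch(effects, fixed = FALSE, random = TRUE,
                       auto = q_pval < 0.05)
  se <- if (use_random) fit$se_unscaled * scale else fit$se_unscaled
  row <- .mr_row(if (use_random) "ivw_random" else "ivw_fixed",
                 fit$beta, se, .p_from_z(fit$beta / se), J)
  attr(row, "Q") <- q
  attr(row, "Q_df") <- J - 1L
  attr(row, "Q_pval") <- q_pval
  row
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with an
#' intercept and weights `1 / se_out^2`, after orienting all exposure
#' effects positive.  The intercept estimates the average directional
#' pleiotropy; its two-sided p-value uses the t distribution with J - 2
#' degrees of freedom.  Standard errors carry the usual multiplicative
#' over-dispersion scale floored at 1.
#'
#' @param h a harmonized data frame with at least 3 instruments.
#' @return A list with elements `slope` and `intercept`, each a one-row MR
#'   estimate data frame (method tags `egger_slope`, `egger_intercept`).
#' @export
mr_egger <- function(h) {
  .check_harmonized(h)
  J <- nrow(h)
  .assert(J >= 3, "MR-Egger requires at least 3 instruments (got %d)", J)
  s <- ifelse(h$beta_exp < 0, -1, 1)
  x <- s * h$beta_exp
  y <- s * h$beta_out
  w <- 1 / h$se_out^2
  fit <- .wls_origin(cbind(intercept = 1, slope = x), y, w)
  scale <- max(1, fit$sigma)
  se <- fit$se_unscaled * scale
  pvals <- pmax(2 * pt(-abs(fit$beta / se), df = J - 2), .Machine$double.xmin)
  slope <- .mr_row("egger_slope", fit$beta[["slope"]], se[["slope"]],
                   pvals[["slope"]], J)
  intercept <- .mr_row("egger_intercept", fit$beta[["intercept"]],
                       se[["intercept"]], pvals[["intercept"]], J)
  list(slope = slope, intercept = intercept, sigma = fit$sigma)
}

# Weighted-median point estimate: order the ratios, form the standardized
# mid-cumulative weights s_j = (cumsum(w) - w/2) / sum(w), and interpolate
# linearly to s = 0.5.
.weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o]
  s <- (cumsum(w) - 0.5 * w) / sum(w)
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] < 0.5) return(r[length(r)])
  below <- max(which(s < 0.5))
  r[below] + (r[below + 1] - r[below]) * (0.5 - s[below]) / (s[below + 1] - s[below])
}

#' Weighted-median estimate
#'
#' The weighted median of the per-variant Wald ratios with weights
#' `1 / se(ratio)^2`, consistent when at least half the weight comes from
#' valid instruments.  The standard error is obtained by parametric
#' bootstrap: per-variant exposure and outcome effects are redrawn from
#' normal distributions centred on their estimates and the median is
#' recomputed.
#'
#' @param h a harmonized data frame with at least 3 instruments.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return A one-row MR estimate data frame (method tag `weighted_median`).
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  .check_harmonized(h)
  J <- nrow(h)
  .assert(J >= 3, "weighted median requires at least 3 instruments (got %d)", J)
  .assert(.is_count(n_boot, 1), "n_boot must be a positive integer")
  .maybe_seed(seed)
  rw <- .ratios(h)
  est <- .weighted_median_point(rw$r, rw$w)
  boots <- vapply(seq_len(n_boot), function(i) {
    bx <- rnorm(J, h$beta_exp, h$se_exp)
    by <- rnorm(J, h$beta_out, h$se_out)
    ok <- bx != 0
    .weighted_median_point(by[ok] / bx[ok], bx[ok]^2 / h$se_out[ok]^2)
  }, numeric(1))
  se <- sd(boots)
  .mr_row("weighted_median", est, se, .p_from_z(est / se), J)
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_j (r_j - beta_IVW_fixed)^2` over the per-variant Wald ratios,
#' with `J - 1` degrees of freedom and an upper-tail chi-square p-value.
#' p < 0.05 is conventionally read as significant heterogeneity, triggering
#' the random-effect IVW variant.
#'
#' @param h a harmonized data frame with at least 2 instruments.
#' @return A list with `Q`, `df` and `pval`.
#' @export
cochran_q <- function(h) {
  .check_harmonized(h)
  J <- nrow(h)
  .assert(J >= 2, "Cochran's Q requires at least 2 instruments (got %d)", J)
  rw <- .ratios(h)
  beta <- sum(rw$w * rw$r) / sum(rw$w)
  q <- sum(rw$w * (rw$r - beta)^2)
  list(Q = q, df = J - 1L, pval = pchisq(q, df = J - 1, lower.tail = FALSE))
}

#' Fit the univariable two-sample MR estimator suite
#'
#' Runs, on one harmonized instrument set: fixed- and random-effect IVW,
#' the heterogeneity-driven automatic choice between them (the primary
#' estimate), MR-Egger (slope and pleiotropy intercept; J >= 3), and the
#' weighted median (J >= 3), together with Cochran's Q.
#'
#' @param h a harmonized data frame (see [harmonize()]).
#' @param n_boot bootstrap replicates for the weighted-median SE.
#' @param seed integer seed for the bootstrap.
#' @param level confidence level for intervals.
#' @return An object of class `mr_fit` with components `estimates` (one row
#'   per method), `primary` (the method tag selected by the heterogeneity
#'   rule), `heterogeneity` (Cochran's Q), and `data`.
#' @examples
#' sim <- simulate_gwas(sim_config(n_snps = 30, causal_beta = 0.3, seed = 7))
#' h <- harmonize(sim$exposure, sim$outcome)
#' fit <- mr_fit(h, seed = 1)
#' summary(fit)
#' @export
mr_fit <- function(h, n_boot = 1000, seed = NULL, level = 0.95) {
  .check_harmonized(h)
  J <- nrow(h)
  .assert(J >= 1, "mr_fit requires at least one instrument")
  .maybe_seed(seed)

  rows <- list()
  het <- NULL
  if (J == 1L) {
    rows$wald <- wald_ratio(h$beta_exp, h$se_exp, h$beta_out, h$se_out)
    primary <- "wald"
  } else {
    rows$ivw_fixed <- mr_ivw(h, "fixed")
    rows$ivw_random <- mr_ivw(h, "random")
    auto <- mr_ivw(h, "auto")
    primary <- auto$method
    het <- cochran_q(h)
  }
  if (J >= 3) {
    egger <- mr_egger(h)
    rows$egger_slope <- egger$slope
    rows$egger_intercept <- egger$intercept
    rows$weighted_median <- mr_weighted_median(h, n_boot = n_boot)
  }
  estimates <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (level != 0.95) {
    zq <- qnorm(1 - (1 - level) / 2)
    estimates$ci_lower <- estimates$beta - zq * estimates$se
    estimates$ci_upper <- estimates$beta + zq * estimates$se
  }
  structure(list(estimates = estimates, primary = primary,
                 heterogeneity = het, level = level, data = h),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR fit: %d instrument(s); primary method: %s\n",
              nrow(x$data), x$primary))
  est <- x$estimates
  est[c("beta", "se", "ci_lower", "ci_upper")] <-
    lapply(est[c("beta", "se", "ci_lower", "ci_upper")], signif, digits)
  est$pval <- format.pval(est$pval, digits = 3)
  print.data.frame(est, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  fit <- x$fit
  print(fit)
  if (!is.null(fit$heterogeneity)) {
    het <- fit$heterogeneity
    cat(sprintf("Cochran's Q = %.4g on %d df (p = %.3g)%s\n", het$Q, het$df,
                het$pval,
                if (het$pval < 0.05) " -- significant heterogeneity" else ""))
  }
  egger_i <- fit$estimates[fit$estimates$method == "egger_intercept", ]
  if (nrow(egger_i) == 1) {
    cat(sprintf("MR-Egger intercept = %.4g (p = %.3g)%s\n", egger_i$beta,
                egger_i$pval,
                if (egger_i$pval < 0.05) " -- directional pleiotropy indicated" else ""))
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  setNames(object$estimates$beta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  est <- object$estimates
  zq <- qnorm(1 - (1 - level) / 2)
  ci <- cbind(est$beta - zq * est$se, est$beta + zq * est$se)
  dimnames(ci) <- list(est$method,
                       sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                  1 - (1 - level) / 2)))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
residuals.mr_fit <- function(object, ...) {
  h <- object$data
  est <- object$estimates
  beta <- est$beta[match(object$primary, est$method)]
  setNames(h$beta_out - beta * h$beta_exp, h$SNP)
}

#' Diagnostic scatter of instrument effects
#'
#' Outcome versus exposure per-variant effects with the fitted IVW (through
#' the origin) and MR-Egger lines.
#'
#' @param x an `mr_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  h <- x$data
  est <- x$estimates
  graphics::plot(h$beta_exp, h$beta_out,
                 xlab = "exposure effect", ylab = "outcome effect",
                 pch = 19, ...)
  graphics::segments(h$beta_exp, h$beta_out - 1.96 * h$se_out,
                     h$beta_exp, h$beta_out + 1.96 * h$se_out,
                     col = "grey70")
  b_ivw <- est$beta[match(x$primary, est$method)]
  graphics::abline(0, b_ivw, col = "steelblue", lwd = 2)
  if ("egger_slope" %in% est$method) {
    graphics::abline(est$beta[est$method == "egger_intercept"],
                     est$beta[est$method == "egger_slope"],
                     col = "firebrick", lty = 2, lwd = 2)
    graphics::legend("topleft", legend = c("IVW", "MR-Egger"),
                     col = c("steelblue", "firebrick"), lty = c(1, 2),
                     bty = "n")
  }
  invisible(x)
}
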