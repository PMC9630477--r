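#' Multivariable MR by weighted least squares
#'
#' Regresses per-instrument outcome effects on the matrix of exposure
#' effects without intercept, with weights `1 / se_out^2`:
#' `lambda_out = sum_i lambda_trait_i * beta_trait_i + e, e ~ N(0, sigma^2)`.
#' Each coefficient is the direct effect of its exposure conditional on the
#' others.  Standard errors come from the weighted normal equations scaled
#' by `max(1, sigma_hat)` — the same multiplicative over-dispersion as the
#' random-effect IVW, to which this reduces for a single exposure column.
#'
#' @param beta_exp numeric matrix (instruments x exposures) of exposure
#'   effects, or a vector for a single exposure.
#' @param beta_out per-instrument outcome effects.
#' @param se_out per-instrument outcome standard errors.
#' @param exposure_names optional coefficient names.
#' @return An object of class `mvmr_fit` with `coefficients`, `se`, `pval`,
#'   `sigma`, `J`, `k`, and `condition` (condition number of the weighted
#'   design).
#' @export
mvmr_fit <- function(beta_exp, beta_out, se_out, exposure_names = NULL) {
  X <- as.matrix(beta_exp)
  J <- nrow(X)
  k <- ncol(X)
  .assert(length(beta_out) == J && length(se_out) == J,
          "beta_out and se_out must match the instrument rows of beta_exp")
  .assert(all(is.finite(X)) && all(is.finite(beta_out)),
          "effect estimates must be complete and finite")
  .assert(all(se_out > 0), "se_out must be > 0")
  .assert(J >= k + 1,
          "multivariable MR needs at least %d instruments for %d exposure(s), got %d",
          k + 1, k, J)
  nm <- exposure_names %||% colnames(X) %||% paste0("exposure", seq_len(k))
  colnames(X) <- nm

  w <- 1 / se_out^2
  Xw <- X * sqrt(w)
  qr_x <- qr(Xw)
  if (qr_x$rank < k) {
    bad <- nm[qr_x$pivot[(qr_x$rank + 1):k]]
    stop(sprintf("collinear exposure effect column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  fit <- .wls_origin(X, beta_out, w)
  scale <- max(1, fit$sigma)
  se <- fit$se_unscaled * scale
  structure(list(coefficients = setNames(fit$beta, nm),
                 se = setNames(se, nm),
                 pval = setNames(.p_from_z(fit$beta / se), nm),
                 sigma = fit$sigma, J = J, k = k,
                 condition = kappa(Xw, exact = TRUE),
                 residuals = fit$resid, weights = w),
            class = "mvmr_fit")
}

#' @export
print.mvmr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Multivariable MR: %d instrument(s), %d exposure(s)\n", x$J, x$k))
  tab <- data.frame(beta = signif(x$coefficients, digits),
                    se = signif(x$se, digits),
                    pval = signif(x$pval, 3))
  print(tab)
  cat(sprintf("residual scale sigma = %.4g; weighted-design condition number = %.3g\n",
              x$sigma, x$condition))
  invisible(x)
}

#' @export
summary.mvmr_fit <- function(object, ...) object

#' @export
coef.mvmr_fit <- function(object, ...) object$coefficients

#' @export
confint.mvmr_fit <- function(object, parm, level = 0.95, ...) {
  zq <- qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - zq * object$se,
              object$coefficients + zq * object$se)
  dimnames(ci) <- list(names(object$coefficients),
                       sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                  1 - (1 - level) / 2)))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
residuals.mvmr_fit <- function(object, ...) object$residuals

#' Parametric bootstrap confidence intervals at the summary-statistic level
#'
#' Re-draws every `beta*` column of `data` from a normal distribution
#' centred on its value with the matching `se*` column as standard
#' deviation (`beta_exp`/`se_exp`, `beta_out`/`se_out`, `BETA`/`SE`, ...),
#' recomputes `statistic` on each replicate, and returns percentile
#' intervals.  With all standard errors zero the interval collapses to the
#' point estimate.
#'
#' @param data a data frame of per-instrument effects.
#' @param statistic function mapping such a data frame to a named numeric
#'   vector.
#' @param n_reps bootstrap replicates (default 1000, minimum 100).
#' @param level confidence level.
#' @param seed integer seed.
#' @param max_undefined maximal tolerated fraction of replicates in which a
#'   statistic component is undefined (NA/NaN) before an error is raised.
#' @return A list with `estimate`, `ci` (matrix with `lower`/`upper`
#'   columns), `replicates` and `n_undefined`.
#' @export
parametric_bootstrap <- function(data, statistic, n_reps = 1000,
                                 level = 0.95, seed = NULL,
                                 max_undefined = 0.1) {
  .assert(is.data.frame(data), "data must be a data.frame")
  .assert(is.function(statistic), "statistic must be a function")
  .assert(.is_count(n_reps, 100), "n_reps must be an integer >= 100")
  .assert(.is_number(level) && level > 0 && level < 1,
          "level must lie in (0, 1)")
  .maybe_seed(seed)

  beta_cols <- grep("^(beta|BETA)", names(data), value = TRUE)
  se_for <- function(b) {
    cand <- sub("^beta", "se", sub("^BETA", "SE", b))
    .assert(cand %in% names(data),
            "no standard-error column %s matching %s", cand, b)
    cand
  }
  se_cols <- vapply(beta_cols, se_for, character(1))
  .assert(length(beta_cols) > 0, "data has no beta columns to resample")

  estimate <- statistic(data)
  J <- nrow(data)
  reps <- matrix(NA_real_, n_reps, length(estimate),
                 dimnames = list(NULL, names(estimate)))
  for (i in seq_len(n_reps)) {
    d <- data
    for (j in seq_along(beta_cols)) {
      d[[beta_cols[j]]] <- rnorm(J, data[[beta_cols[j]]], data[[se_cols[j]]])
    }
    reps[i, ] <- statistic(d)
  }
  n_undef <- colSums(!is.finite(reps))
  .assert(all(n_undef <= max_undefined * n_reps),
          "statistic undefined in more than %g%% of bootstrap replicates (%s)",
          100 * max_undefined,
          paste(sprintf("%s: %d", colnames(reps), n_undef), collapse = ", "))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- t(apply(reps, 2, quantile, probs = probs, na.rm = TRUE))
  colnames(ci) <- c("lower", "upper")
  list(estimate = estimate, ci = ci, replicates = reps,
       n_undefined = n_undef)
}

# Point decomposition given merged per-instrument effects:
# total from univariable IVW, direct from the joint exposure+mediator WLS.
.mediation_point <- function(d, tol = 1e-10) {
  w <- 1 / d$se_out^2
  total <- sum(w * d$beta_exp * d$beta_out) / sum(w * d$beta_exp^2)
  X <- cbind(exposure = d$beta_exp, mediator = d$beta_med)
  xtwx <- crossprod(X * w, X)
  bb <- tryCatch(drop(solve(xtwx, crossprod(X * w, d$beta_out))),
                 error = function(e) c(NA_real_, NA_real_))
  direct <- unname(bb[1])
  b_med <- unname(bb[2])
  a_hat <- sum((1 / d$se_med^2) * d$beta_exp * d$beta_med) /
    sum((1 / d$se_med^2) * d$beta_exp^2)
  indirect <- total - direct
  c(total = total, direct = direct, indirect = indirect,
    proportion = if (is.finite(total) && abs(total) > tol)
      indirect / total else NA_real_,
    indirect_product = a_hat * b_med,
    b_mediator = b_med, a_exposure_mediator = a_hat)
}

#' Mediation decomposition by network MR
#'
#' Decomposes the causal effect of an exposure on an outcome into the
#' component transmitted through a mediator and the remainder.  Following
#' the network-MR convention, only instruments for the exposure are used:
#' the total effect is the univariable IVW estimate of exposure on outcome;
#' the direct effect is the exposure coefficient of the multivariable
#' weighted least squares of outcome effects on exposure and mediator
#' effects jointly ([mvmr_fit()]); the indirect effect is
#' `total - direct` (difference method; the product `a * b` of the
#' exposure-to-mediator IVW estimate and the mediator's joint coefficient is
#' also reported for cross-checking).  The proportion mediated is
#' `indirect / total`, undefined (NA) when the total is numerically zero.
#' Confidence intervals are percentile intervals from a parametric
#' bootstrap redrawing all per-instrument effects from their estimated
#' normal distributions.
#'
#' @param exposure,mediator,outcome summary-statistics data frames.
#' @param panel optional `ld_panel` for clumping.
#' @param instruments optional explicit instrument ids; otherwise selected
#'   from the exposure GWAS.
#' @param p_threshold,r2_threshold,window_kb,min_f instrument-selection
#'   parameters (defaults 1e-5, 0.1, 500, 10).
#' @param n_boot bootstrap replicates (default 1000).
#' @param level confidence level for the percentile intervals.
#' @param seed integer seed.
#' @param method primary indirect-effect estimator: `"difference"`
#'   (default) or `"product"`.
#' @return An object of class `mr_mediation`: a table of `total`, `direct`,
#'   `indirect` and `proportion` with bootstrap intervals, plus the
#'   instrument count, replicate count, and the full point decomposition.
#' @export
mr_mediation <- function(exposure, mediator, outcome, panel = NULL,
                         instruments = NULL, p_threshold = 1e-5,
                         r2_threshold = 0.1, window_kb = 500, min_f = 10,
                         n_boot = 1000, level = 0.95, seed = NULL,
                         method = c("difference", "product")) {
  method <- match.arg(method)
  .maybe_seed(seed)
  if (is.null(instruments)) {
    sel <- select_significant(exposure, p_threshold)
    .assert(nrow(sel) > 0, "no exposure instruments at p < %g", p_threshold)
    if (!is.null(panel)) sel <- ld_clump(sel, panel, r2_threshold, window_kb)
    instruments <- sel$SNP
  }
  h_out <- harmonize(exposure, outcome, ids = instruments)
  h_med <- harmonize(exposure, mediator, ids = instruments)
  common <- intersect(h_out$SNP, h_med$SNP)
  .assert(length(common) >= 3,
          "mediation requires at least 3 instruments present in all three GWAS (got %d)",
          length(common))
  h_out <- h_out[match(common, h_out$SNP), , drop = FALSE]
  h_med <- h_med[match(common, h_med$SNP), , drop = FALSE]
  strength <- compute_strength(h_out, min_f = min_f)
  ids <- strength$SNP
  .assert(length(ids) >= 3,
          "fewer than 3 instruments survive the strength filter")
  keep <- match(ids, h_out$SNP)
  d <- data.frame(SNP = ids,
                  beta_exp = h_out$beta_exp[keep],
                  se_exp = h_out$se_exp[keep],
                  beta_med = h_med$beta_out[keep],
                  se_med = h_med$se_out[keep],
                  beta_out = h_out$beta_out[keep],
                  se_out = h_out$se_out[keep],
                  stringsAsFactors = FALSE)

  point <- .mediation_point(d)
  pick <- function(p) {
    if (method == "difference") {
      c(total = unname(p["total"]), direct = unname(p["direct"]),
        indirect = unname(p["indirect"]),
        proportion = unname(p["proportion"]))
    } else {
      ind <- unname(p["indirect_product"])
      tot <- unname(p["total"])
      c(total = tot, direct = tot - ind, indirect = ind,
        proportion = if (is.finite(tot) && abs(tot) > 1e-10)
          ind / tot else NA_real_)
    }
  }
  boot <- parametric_bootstrap(d, function(dd) pick(.mediation_point(dd)),
                               n_reps = n_boot, level = level)
  est <- pick(point)
  table <- data.frame(quantity = names(est), estimate = unname(est),
                      ci_lower = boot$ci[names(est), "lower"],
                      ci_upper = boot$ci[names(est), "upper"],
                      stringsAsFactors = FALSE)
  rownames(table) <- NULL
  structure(list(estimates = table, point = point, method = method,
                 n_snps = length(ids), n_boot = n_boot, level = level,
                 instruments = ids, data = d, boot = boot),
            class = "mr_mediation")
}

#' @export
print.mr_mediation <- function(x, digits = 4, ...) {
  cat(sprintf("Mediation MR (%s method): %d instrument(s), %d bootstrap replicates\n",
              x$method, x$n_snps, x$n_boot))
  tab <- x$estimates
  tab[-1] <- lapply(tab[-1], signif, digits)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}
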