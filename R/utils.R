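`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

.is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Required header of a summary-statistics table (one row per variant).
.sumstats_cols <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")

.check_sumstats <- function(x, name = "summary statistics") {
  .assert(is.data.frame(x), "%s must be a data.frame", name)
  missing <- setdiff(.sumstats_cols, names(x))
  .assert(length(missing) == 0L, "%s is missing column(s): %s",
          name, paste(missing, collapse = ", "))
  invisible(x)
}

.check_harmonized <- function(h) {
  .assert(is.data.frame(h), "harmonized set must be a data.frame")
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  missing <- setdiff(need, names(h))
  .assert(length(missing) == 0L, "harmonized set is missing column(s): %s",
          paste(missing, collapse = ", "))
  .assert(all(h$se_out > 0) && all(h$se_exp >= 0),
          "harmonized set contains non-positive standard errors")
  invisible(h)
}

# Two-sided normal p-value, kept strictly inside (0, 1].
.p_from_z <- function(z) pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)

.maybe_seed <- function(seed) {
  if (!is.null(seed)) {
    .assert(.is_count(seed, min = -.Machine$integer.max),
            "seed must be a single integer")
    set.seed(seed)
  }
  invisible(NULL)
}

# One row of an MR estimate table.
.mr_row <- function(method, beta, se, pval, n_snps, level = 0.95) {
  zq <- qnorm(1 - (1 - level) / 2)
  data.frame(method = method, n_snps = n_snps, beta = beta, se = se,
             ci_lower = beta - zq * se, ci_upper = beta + zq * se,
             pval = pval, stringsAsFactors = FALSE)
}

# Weighted least squares through the origin: y ~ X (no intercept), weights w.
# Shared backbone of IVW and multivariable MR.  Returns unscaled SEs plus the
# multiplicative over-dispersion scale sqrt(RSS_w / (J - k)).
.wls_origin <- function(X, y, w) {
  X <- as.matrix(X)
  J <- nrow(X)
  k <- ncol(X)
  .assert(length(y) == J && length(w) == J, "incompatible dimensions in WLS")
  .assert(J > k, "weighted least squares needs more instruments (%d) than coefficients (%d)", J, k)
  xtwx <- crossprod(X * w, X)
  beta <- drop(solve(xtwx, crossprod(X * w, y)))
  cov_unscaled <- solve(xtwx)
  resid <- y - drop(X %*% beta)
  sigma2 <- sum(w * resid^2) / (J - k)
  list(beta = beta, se_unscaled = sqrt(diag(cov_unscaled)),
       sigma = sqrt(sigma2), resid = resid, J = J, k = k,
       cov_unscaled = cov_unscaled)
}
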