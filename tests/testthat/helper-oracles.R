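# Shared fixtures and independent brute-force oracles used across the suite.
# Oracles deliberately use a different computational route (stats::lm QR
# fits, explicit loops over definitions) than the package internals.

make_h <- function(J, seed = NULL, beta = 0.5, x_sd = 0.25, sy = 0.01,
                   sx = 0.02, alpha = rep(0, J)) {
  if (!is.null(seed)) set.seed(seed)
  x <- abs(rnorm(J, 0, x_sd))
  sy <- rep(sy, length.out = J)
  sx <- rep(sx, length.out = J)
  data.frame(SNP = sprintf("rs%03d", seq_len(J)),
             beta_exp = x + rnorm(J, 0, sx), se_exp = sx,
             beta_out = beta * x + alpha + rnorm(J, 0, sy), se_out = sy,
             eaf_exp = runif(J, 0.1, 0.5), n_exp = 10000L,
             stringsAsFactors = FALSE)
}

random_h <- function(J, seed) {
  set.seed(seed)
  data.frame(SNP = sprintf("rs%03d", seq_len(J)),
             beta_exp = rnorm(J, 0, 0.3) + 0.05, se_exp = runif(J, 0.01, 0.05),
             beta_out = rnorm(J, 0, 0.2), se_out = runif(J, 0.005, 0.05),
             eaf_exp = runif(J, 0.1, 0.5), n_exp = 10000L,
             stringsAsFactors = FALSE)
}

# Weighted regression of outcome on exposure effects through the origin.
oracle_ivw_fixed <- function(h) {
  fit <- lm(beta_out ~ 0 + beta_exp, data = h, weights = 1 / h$se_out^2)
  s <- summary(fit)
  list(beta = unname(coef(fit)), se = unname(s$coefficients[, 2] / s$sigma))
}

oracle_ivw_random <- function(h) {
  fx <- oracle_ivw_fixed(h)
  r <- h$beta_out / h$beta_exp
  w <- h$beta_exp^2 / h$se_out^2
  q <- sum(w * (r - fx$beta)^2)
  list(beta = fx$beta, se = fx$se * max(1, sqrt(q / (nrow(h) - 1))), Q = q)
}

# Weighted regression with intercept after orienting exposure effects
# positive; SEs carry the over-dispersion scale floored at 1.
oracle_egger <- function(h) {
  s <- ifelse(h$beta_exp < 0, -1, 1)
  d <- data.frame(x = s * h$beta_exp, y = s * h$beta_out)
  fit <- lm(y ~ x, data = d, weights = 1 / h$se_out^2)
  sm <- summary(fit)
  se_unscaled <- sm$coefficients[, 2] / sm$sigma
  se <- se_unscaled * max(1, sm$sigma)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       intercept_se = unname(se[1]), slope_se = unname(se[2]),
       sigma = sm$sigma)
}

# Direct evaluation of the weighted-median interpolation definition with an
# explicit scan over the order statistics.
oracle_weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o] / sum(w)
  cum <- 0
  s <- numeric(length(r))
  for (j in seq_along(r)) {
    s[j] <- cum + w[j] / 2
    cum <- cum + w[j]
  }
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] < 0.5) return(r[length(r)])
  j <- max(which(s < 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

oracle_cochran_q <- function(h) {
  r <- h$beta_out / h$beta_exp
  w <- h$beta_exp^2 / h$se_out^2
  b <- sum(w * r) / sum(w)
  sum(w * (r - b)^2)
}

# Cook's distance from the influence formulas of the weighted
# through-origin regression, written out longhand.
oracle_cooks <- function(h) {
  w <- 1 / h$se_out^2
  x <- h$beta_exp
  y <- h$beta_out
  b <- sum(w * x * y) / sum(w * x^2)
  e <- y - b * x
  hat <- w * x^2 / sum(w * x^2)
  s2 <- sum(w * e^2) / (length(x) - 1)
  (w * e^2 / s2) * hat / (1 - hat)^2
}

# Step-up BH applied by hand to the sorted p-values.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * sorted[i] / i)
    adj[i] <- min(running, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

oracle_mvmr <- function(X, y, sy) {
  d <- as.data.frame(X)
  names(d) <- paste0("x", seq_len(ncol(X)))
  d$y <- y
  fml <- stats::as.formula(paste("y ~ 0 +", paste(names(d)[-ncol(d)], collapse = " + ")))
  fit <- lm(fml, data = d, weights = 1 / sy^2)
  sm <- summary(fit)
  se_unscaled <- sm$coefficients[, 2] / sm$sigma
  list(beta = unname(coef(fit)), se = unname(se_unscaled * max(1, sm$sigma)))
}

# Exhaustive pairwise verification of a clumping result: every retained
# pair must violate neither the LD nor the window rule, and every removed
# variant must conflict with a retained index of smaller (or tied-earlier)
# p-value.
clump_is_valid <- function(subset, kept, panel, r2_threshold, window_kb) {
  r2 <- ld_r2(panel, subset$SNP)
  in_conflict <- function(a, b) {
    subset$CHR[a] == subset$CHR[b] &&
      abs(subset$POS[a] - subset$POS[b]) <= window_kb * 1000 &&
      r2[subset$SNP[a], subset$SNP[b]] > r2_threshold
  }
  ranks <- order(order(subset$P, subset$POS, subset$SNP))
  kept_idx <- match(kept$SNP, subset$SNP)
  for (i in kept_idx) {
    for (j in kept_idx) {
      if (i < j && in_conflict(i, j)) return(FALSE)
    }
  }
  removed <- setdiff(seq_len(nrow(subset)), kept_idx)
  for (i in removed) {
    conflicts <- vapply(kept_idx, function(j) {
      in_conflict(i, j) && ranks[j] < ranks[i]
    }, logical(1))
    if (!any(conflicts)) return(FALSE)
  }
  TRUE
}

# Minimal valid summary-statistics table built by hand.
tiny_sumstats <- function(p = c(1e-8, 1e-6), pos = c(1e6, 1.1e6),
                          chr = rep(1, length(p)),
                          snp = sprintf("rs%06d", seq_along(p)),
                          ea = rep("A", length(p)), oa = rep("G", length(p)),
                          eaf = rep(0.3, length(p)), beta = rep(0.1, length(p)),
                          se = rep(0.02, length(p)), n = 3757L) {
  data.frame(SNP = snp, CHR = chr, POS = pos, EA = ea, OA = oa, EAF = eaf,
             BETA = beta, SE = se, P = p, N = n, stringsAsFactors = FALSE)
}

# Panel with hand-set haplotypes for exact LD control.
panel_from_matrix <- function(hap, chr, pos, ids = sprintf("rs%06d", seq_len(ncol(hap)))) {
  colnames(hap) <- ids
  structure(list(haplotypes = hap,
                 variants = data.frame(SNP = ids, CHR = chr, POS = pos,
                                       stringsAsFactors = FALSE),
                 rho = NA_real_, n_blocks = NA_integer_,
                 block_size = NA_integer_),
            class = "ld_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
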