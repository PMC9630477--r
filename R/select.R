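#' Select variants passing a significance threshold
#'
#' Retains exactly the variants with `P < p_threshold`, preserving the input
#' row order.  The default reproduces the loose exposure-side instrument
#' threshold of 1e-5; reverse-direction instruments use the genome-wide
#' 5e-8.
#'
#' @param stats a summary-statistics data frame.
#' @param p_threshold significance level (exclusive).
#' @return The subset of rows of `stats`; possibly empty.
#' @export
select_significant <- function(stats, p_threshold = 1e-5) {
  .check_sumstats(stats)
  .assert(.is_number(p_threshold) && p_threshold > 0 && p_threshold <= 1,
          "p_threshold must lie in (0, 1]")
  stats[stats$P < p_threshold, , drop = FALSE]
}

#' Greedy LD clumping of a variant subset
#'
#' p-value-ranked greedy clumping: repeatedly take the remaining variant with
#' the smallest p-value as the index, and remove every other remaining
#' variant on the same chromosome within `window_kb` whose sample r-squared
#' with the index (computed from the reference panel) exceeds
#' `r2_threshold`.  Ties on p are broken by position and then id, so the
#' result does not depend on input row order.
#'
#' @param subset a summary-statistics data frame (e.g. from
#'   [select_significant()]).
#' @param panel an `ld_panel` containing every variant in `subset`.
#' @param r2_threshold LD r-squared above which a variant is removed
#'   (default 0.1; reverse-direction instruments use 0.01).
#' @param window_kb physical window in kilobases (default 500).
#' @return The retained index variants, ordered by ascending p-value.
#' @export
ld_clump <- function(subset, panel, r2_threshold = 0.1, window_kb = 500) {
  .check_sumstats(subset)
  .assert(inherits(panel, "ld_panel"), "panel must be an ld_panel")
  .assert(.is_number(r2_threshold) && r2_threshold >= 0 && r2_threshold <= 1,
          "r2_threshold must lie in [0, 1]")
  .assert(.is_number(window_kb) && window_kb > 0, "window_kb must be > 0")
  if (nrow(subset) == 0L) return(subset)
  miss <- setdiff(subset$SNP, panel$variants$SNP)
  .assert(length(miss) == 0L,
          "variant(s) not present in reference panel: %s",
          paste(miss, collapse = ", "))

  ord <- order(subset$P, subset$POS, subset$SNP)
  window_bp <- window_kb * 1000
  hap <- panel$haplotypes
  remaining <- rep(TRUE, nrow(subset))
  keep <- integer(0)
  for (i in ord) {
    if (!remaining[i]) next
    keep <- c(keep, i)
    remaining[i] <- FALSE
    cand <- which(remaining & subset$CHR == subset$CHR[i] &
                    abs(subset$POS - subset$POS[i]) <= window_bp)
    if (length(cand) > 0) {
      r2 <- drop(stats::cor(hap[, subset$SNP[i]],
                            hap[, subset$SNP[cand], drop = FALSE]))^2
      remaining[cand[r2 > r2_threshold]] <- FALSE
    }
  }
  subset[keep, , drop = FALSE]
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effects to the exposure's effect allele for a set of
#' instruments.  Where the outcome's effect allele matches the exposure's
#' other allele (directly or on the complementary strand), the outcome beta
#' is sign-flipped and its allele frequency complemented.  Palindromic
#' variants (A/T or C/G), whose strand is not decidable from allele labels,
#' are aligned by allele frequency: they are retained as-is when both
#' frequencies fall on the same side of 0.5 and outside the ambiguity band
#' (0.42 to 0.58), and dropped otherwise.  Variants missing from the outcome
#' or with incompatible allele pairs are dropped and counted in the log.
#'
#' @param exposure,outcome summary-statistics data frames.
#' @param ids optional variant ids restricting the instrument set (e.g. the
#'   output of [ld_clump()]); defaults to all exposure variants.
#' @param ambiguity_band frequency band within which a palindromic variant
#'   is considered unalignable.
#' @return A harmonized data frame with columns `SNP, CHR, POS, EA, OA`,
#'   `beta_exp, se_exp, pval_exp, eaf_exp, n_exp`,
#'   `beta_out, se_out, pval_out, eaf_out, n_out`, `flipped`, `palindromic`,
#'   carrying a `"log"` attribute with per-reason drop counts.
#' @export
harmonize <- function(exposure, outcome, ids = NULL,
                      ambiguity_band = c(0.42, 0.58)) {
  .check_sumstats(exposure, "exposure")
  .check_sumstats(outcome, "outcome")
  if (!is.null(ids)) {
    exposure <- exposure[exposure$SNP %in% ids, , drop = FALSE]
  }
  n_input <- nrow(exposure)
  idx_out <- match(exposure$SNP, outcome$SNP)
  missing <- is.na(idx_out)
  exp_t <- exposure[!missing, , drop = FALSE]
  out_t <- outcome[idx_out[!missing], , drop = FALSE]

  ea_x <- toupper(exp_t$EA); oa_x <- toupper(exp_t$OA)
  ea_y <- toupper(out_t$EA); oa_y <- toupper(out_t$OA)
  comp <- .allele_comp
  palindromic <- ea_x == unname(comp[oa_x])

  same <- ea_y == ea_x & oa_y == oa_x
  swap <- ea_y == oa_x & oa_y == ea_x
  strand <- unname(comp[ea_y]) == ea_x & unname(comp[oa_y]) == oa_x
  strand_swap <- unname(comp[ea_y]) == oa_x & unname(comp[oa_y]) == ea_x

  lo <- ambiguity_band[1]; hi <- ambiguity_band[2]
  fx <- exp_t$EAF; fy <- out_t$EAF
  freq_informative <- (fx < lo | fx > hi) & (fy < lo | fy > hi)
  freq_concordant <- (fx < 0.5) == (fy < 0.5)

  action <- character(nrow(exp_t))  # "keep", "flip", or a drop reason
  # Palindromic: allele labels are strand-ambiguous; decide on frequency only.
  pal_pair_ok <- palindromic & (same | swap | strand | strand_swap)
  action[palindromic & !pal_pair_ok] <- "incompatible"
  action[pal_pair_ok & !freq_informative] <- "palindromic_ambiguous"
  action[pal_pair_ok & freq_informative & !freq_concordant] <- "palindromic_discordant"
  action[pal_pair_ok & freq_informative & freq_concordant] <- "keep"
  # Non-palindromic: allele labels decide.
  action[!palindromic & (same | strand)] <- "keep"
  action[!palindromic & (swap | strand_swap)] <- "flip"
  action[!palindromic & !(same | swap | strand | strand_swap)] <- "incompatible"

  kept <- action %in% c("keep", "flip")
  flip <- action == "flip"
  beta_out <- ifelse(flip, -out_t$BETA, out_t$BETA)
  eaf_out <- ifelse(flip, 1 - out_t$EAF, out_t$EAF)

  h <- data.frame(SNP = exp_t$SNP, CHR = exp_t$CHR, POS = exp_t$POS,
                  EA = ea_x, OA = oa_x,
                  beta_exp = exp_t$BETA, se_exp = exp_t$SE,
                  pval_exp = exp_t$P, eaf_exp = exp_t$EAF, n_exp = exp_t$N,
                  beta_out = beta_out, se_out = out_t$SE,
                  pval_out = out_t$P, eaf_out = eaf_out, n_out = out_t$N,
                  flipped = flip, palindromic = palindromic,
                  stringsAsFactors = FALSE)[kept, , drop = FALSE]
  rownames(h) <- NULL
  attr(h, "log") <- list(
    n_input = n_input,
    n_missing_outcome = sum(missing),
    n_incompatible = sum(action == "incompatible"),
    n_palindromic_dropped = sum(action %in% c("palindromic_ambiguous",
                                              "palindromic_discordant")),
    n_flipped = sum(flip),
    n_kept = nrow(h))
  h
}

#' Instrument strength: proportion of variance explained and F statistics
#'
#' Computes, per variant, the proportion of exposure variance explained
#' `PVE_j = 2 f (1-f) b^2 / (2 f (1-f) b^2 + 2 f (1-f) se^2 n)` and the
#' strength statistic `F_j = (n - 2) PVE_j / (1 - PVE_j)`; variants with
#' `F_j < min_f` (weak instruments) are removed.  The retained set's
#' `R^2 = sum(PVE_j)` yields the set-level
#' `F = ((n - k - 1) / k) R^2 / (1 - R^2)` with `k` retained instruments.
#'
#' @param x a harmonized data frame (columns `beta_exp`, `se_exp`,
#'   `eaf_exp`) or a raw summary-statistics table (columns `BETA`, `SE`,
#'   `EAF`).
#' @param n exposure GWAS sample size; taken from the table's `n_exp` / `N`
#'   column when omitted.
#' @param min_f weak-instrument threshold (default 10; variants with
#'   `F_j >= min_f` are retained).
#' @return An object of class `instrument_set`: the retained rows of `x`
#'   with `pve` and `f_stat` columns, plus attributes `dropped` (removed
#'   rows), `n`, `k`, `r2_set`, `f_set` and `min_f`.
#' @export
compute_strength <- function(x, n = NULL, min_f = 10) {
  .assert(is.data.frame(x), "x must be a data.frame")
  if (all(c("beta_exp", "se_exp", "eaf_exp") %in% names(x))) {
    beta <- x$beta_exp; se <- x$se_exp; eaf <- x$eaf_exp
    if (is.null(n) && "n_exp" %in% names(x)) n <- max(x$n_exp)
  } else {
    .check_sumstats(x)
    beta <- x$BETA; se <- x$SE; eaf <- x$EAF
    if (is.null(n)) n <- max(x$N)
  }
  .assert(!is.null(n) && .is_count(n, 3), "n must be an integer sample size >= 3")
  .assert(.is_number(min_f) && min_f >= 0, "min_f must be >= 0")

  v <- 2 * eaf * (1 - eaf)
  pve <- (v * beta^2) / (v * beta^2 + v * se^2 * n)
  f_stat <- (n - 2) * pve / (1 - pve)
  x$pve <- pve
  x$f_stat <- f_stat
  keep <- is.finite(f_stat) & f_stat >= min_f

  out <- x[keep, , drop = FALSE]
  k <- nrow(out)
  .assert(n > k + 1, "sample size n = %d too small for k = %d instruments", n, k)
  r2_set <- sum(out$pve)
  # The sum of marginal PVEs approximates the joint R^2 only when well
  # below 1; beyond that the set-level F is not interpretable.
  f_set <- if (k > 0 && r2_set < 1) {
    ((n - k - 1) / k) * r2_set / (1 - r2_set)
  } else {
    NA_real_
  }
  structure(out, dropped = x[!keep, , drop = FALSE], n = n, k = k,
            r2_set = r2_set, f_set = f_set, min_f = min_f,
            class = c("instrument_set", "data.frame"))
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: %d variant(s) with F >= %g (%d removed as weak)\n",
              attr(x, "k"), attr(x, "min_f"), nrow(attr(x, "dropped"))))
  cat(sprintf("  set R^2 = %.4g, set F = %.4g (n = %d)\n",
              attr(x, "r2_set"), attr(x, "f_set"), attr(x, "n")))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("  ... %d more row(s)\n", nrow(x) - 10))
  invisible(x)
}

#' Full instrument-selection pipeline for one exposure
#'
#' Applies, in order: significance thresholding, greedy LD clumping (when a
#' panel is supplied), allele harmonization against the outcome, and
#' F-statistic strength filtering.  Each step can only shrink the variant
#' set; every initially significant variant's fate is recorded.
#'
#' @param exposure,outcome summary-statistics data frames.
#' @param panel optional `ld_panel` for clumping.
#' @param p_threshold exposure significance threshold (default 1e-5).
#' @param r2_threshold,window_kb clumping parameters (defaults 0.1, 500).
#' @param min_f weak-instrument threshold (default 10).
#' @return A list of class `instrument_selection` with elements `harmonized`
#'   (the final harmonized instrument data frame, with `pve`/`f_stat`),
#'   `strength` (the `instrument_set`), `fate` (per-variant filter fate) and
#'   `log` (per-step counts).
#' @export
select_instruments <- function(exposure, outcome, panel = NULL,
                               p_threshold = 1e-5, r2_threshold = 0.1,
                               window_kb = 500, min_f = 10) {
  sig <- select_significant(exposure, p_threshold)
  fate <- data.frame(SNP = sig$SNP, fate = "kept", stringsAsFactors = FALSE)
  log <- c(sprintf("significance p < %g: %d variant(s)", p_threshold, nrow(sig)))

  clumped <- sig
  if (!is.null(panel) && nrow(sig) > 0) {
    clumped <- ld_clump(sig, panel, r2_threshold, window_kb)
    fate$fate[!(fate$SNP %in% clumped$SNP)] <- "clumped"
    log <- c(log, sprintf("LD clumping r2 > %g within %g kb: %d retained",
                          r2_threshold, window_kb, nrow(clumped)))
  }

  h <- harmonize(exposure, outcome, ids = clumped$SNP)
  hlog <- attr(h, "log")
  dropped_h <- setdiff(clumped$SNP, h$SNP)
  fate$fate[fate$SNP %in% dropped_h & fate$fate == "kept"] <- "not_harmonized"
  log <- c(log, sprintf(
    "harmonization: %d retained (%d missing from outcome, %d incompatible, %d palindromic dropped, %d flipped)",
    hlog$n_kept, hlog$n_missing_outcome, hlog$n_incompatible,
    hlog$n_palindromic_dropped, hlog$n_flipped))

  strength <- NULL
  final <- h
  if (nrow(h) > 0) {
    strength <- compute_strength(h, min_f = min_f)
    weak <- attr(strength, "dropped")$SNP
    fate$fate[fate$SNP %in% weak] <- "weak_instrument"
    final <- as.data.frame(strength)
    log <- c(log, sprintf("strength filter F >= %g: %d retained (set F = %.3g)",
                          min_f, attr(strength, "k"), attr(strength, "f_set")))
  }
  structure(list(harmonized = final, strength = strength, fate = fate,
                 log = log),
            class = "instrument_selection")
}

#' @export
print.instrument_selection <- function(x, ...) {
  cat("Instrument selection\n")
  for (line in x$log) cat("  -", line, "\n")
  invisible(x)
}
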