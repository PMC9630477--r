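#' Configuration for the synthetic GWAS generator
#'
#' Collects the generative parameters of a paired exposure/outcome GWAS
#' simulation with known causal structure.  Per-variant true exposure effects
#' `gamma_j` are drawn with spread `gamma_sd`; the true outcome effect is
#' `causal_beta * gamma_j + alpha_j`, where `alpha_j` is a horizontal
#' (direct-on-outcome) pleiotropic effect carried by a fraction
#' `invalid_frac` of variants.  Observed marginal effects add sampling noise
#' with the analytic standard error `1 / sqrt(2 * n * eaf * (1 - eaf))` of a
#' standardized-trait GWAS.
#'
#' @param n_snps number of variants.
#' @param n_exp,n_out exposure and outcome GWAS sample sizes.  Defaults mirror
#'   a 3,757-sample immunophenotype GWAS and a 66,628-sample total-body
#'   bone-mineral-density GWAS.
#' @param causal_beta true causal effect of the exposure on the outcome.
#' @param gamma_sd scale of the true per-variant exposure effects.
#' @param invalid_frac fraction of variants with horizontal pleiotropy.
#' @param pleio_mean,pleio_sd mean and SD of the pleiotropic effects
#'   `alpha_j` on invalid variants; a nonzero mean gives directional
#'   pleiotropy.
#' @param inside_kappa coupling `alpha_j = inside_kappa * gamma_j + noise`;
#'   `0` (the default) satisfies the InSIDE assumption, nonzero values
#'   violate it (the regime where MR-Egger fails).
#' @param maf_range range of effect-allele frequencies, drawn uniformly.
#' @param oriented if `TRUE` (default) instrument effects are oriented to the
#'   exposure-increasing allele (half-normal `|N(0, gamma_sd^2)|`), the
#'   convention under which directional pleiotropy is a detectable,
#'   sign-coherent phenomenon; `FALSE` draws them from the signed normal.
#' @param flip_frac fraction of outcome rows emitted with swapped allele
#'   labels, complemented EAF and sign-flipped beta, to exercise
#'   harmonization.
#' @param seed integer seed; fixing it makes the output byte-identical.
#'
#' @return An object of class `sim_config`.
#' @seealso [simulate_gwas()], [simulate_mediation_gwas()], [simulate_ld_panel()]
#' @export
sim_config <- function(n_snps = 100L, n_exp = 3757L, n_out = 66628L,
                       causal_beta = 0, gamma_sd = 0.25,
                       invalid_frac = 0, pleio_mean = 0, pleio_sd = 0.05,
                       inside_kappa = 0, maf_range = c(0.05, 0.5),
                       oriented = TRUE, flip_frac = 0, seed = NULL) {
  .assert(.is_count(n_snps, 1), "n_snps must be a positive integer")
  # Sample sizes may be arbitrarily large (even beyond integer range) so
  # that the noiseless limit can be expressed directly.
  .assert(.is_number(n_exp) && n_exp >= 2 && .is_number(n_out) && n_out >= 2,
          "sample sizes n_exp and n_out must be >= 2")
  .assert(.is_number(causal_beta), "causal_beta must be a single number")
  .assert(.is_number(gamma_sd) && gamma_sd >= 0, "gamma_sd must be >= 0")
  .assert(.is_number(invalid_frac) && invalid_frac >= 0 && invalid_frac <= 1,
          "invalid_frac must lie in [0, 1]")
  .assert(.is_number(pleio_mean), "pleio_mean must be a single number")
  .assert(.is_number(pleio_sd) && pleio_sd >= 0, "pleio_sd must be >= 0")
  .assert(.is_number(inside_kappa), "inside_kappa must be a single number")
  .assert(is.numeric(maf_range) && length(maf_range) == 2 &&
            all(maf_range > 0) && all(maf_range <= 0.5) &&
            maf_range[1] <= maf_range[2],
          "maf_range must be two increasing values in (0, 0.5]")
  .assert(.is_number(flip_frac) && flip_frac >= 0 && flip_frac <= 1,
          "flip_frac must lie in [0, 1]")
  structure(list(n_snps = as.integer(n_snps), n_exp = n_exp,
                 n_out = n_out, causal_beta = causal_beta,
                 gamma_sd = gamma_sd, invalid_frac = invalid_frac,
                 pleio_mean = pleio_mean, pleio_sd = pleio_sd,
                 inside_kappa = inside_kappa, maf_range = maf_range,
                 oriented = isTRUE(oriented), flip_frac = flip_frac,
                 seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic GWAS configuration\n")
  cat(sprintf("  %d SNPs; n_exp = %d, n_out = %d\n", x$n_snps, x$n_exp, x$n_out))
  cat(sprintf("  causal beta = %g; gamma_sd = %g (%s)\n", x$causal_beta,
              x$gamma_sd, if (x$oriented) "oriented" else "signed"))
  cat(sprintf("  pleiotropy: %g%% invalid, alpha ~ N(%g, %g^2), kappa = %g\n",
              100 * x$invalid_frac, x$pleio_mean, x$pleio_sd, x$inside_kappa))
  invisible(x)
}

# Default variant map: variants round-robin across 22 chromosomes, spaced
# 1 Mb within a chromosome so they fall outside any 500 kb clumping window.
.default_variants <- function(m) {
  idx <- seq_len(m)
  chrom <- ((idx - 1L) %% 22L) + 1L
  ordinal <- ((idx - 1L) %/% 22L) + 1L
  data.frame(SNP = sprintf("rs%06d", idx), CHR = chrom,
             POS = ordinal * 1000000L, stringsAsFactors = FALSE)
}

.allele_comp <- c(A = "T", C = "G", G = "C", T = "A")

.random_alleles <- function(m) {
  nt <- c("A", "C", "G", "T")
  ea <- nt[sample.int(4L, m, replace = TRUE)]
  shift <- sample.int(3L, m, replace = TRUE)
  oa <- nt[((match(ea, nt) - 1L + shift) %% 4L) + 1L]
  list(ea = ea, oa = oa)
}

.sumstats_table <- function(variants, ea, oa, eaf, beta, se, n) {
  data.frame(SNP = variants$SNP, CHR = variants$CHR, POS = variants$POS,
             EA = ea, OA = oa, EAF = eaf, BETA = beta, SE = se,
             P = .p_from_z(beta / se), N = n,
             stringsAsFactors = FALSE)
}

.flip_rows <- function(stats, rows) {
  if (length(rows) == 0L) return(stats)
  ea <- stats$EA[rows]
  stats$EA[rows] <- stats$OA[rows]
  stats$OA[rows] <- ea
  stats$EAF[rows] <- 1 - stats$EAF[rows]
  stats$BETA[rows] <- -stats$BETA[rows]
  stats
}

#' Simulate paired exposure/outcome GWAS summary statistics
#'
#' Generates marginal per-variant association tables for an exposure and an
#' outcome trait under a known causal model, together with the ground truth
#' needed for recovery tests.  Effects are simulated directly at the summary
#' level; linkage disequilibrium lives only in the reference panel (see
#' [simulate_ld_panel()]).
#'
#' @param config a [sim_config()] object.
#' @param variants optional variant map (`SNP`, `CHR`, `POS`) to align the
#'   tables with an LD reference panel; defaults to unlinked positions.
#'
#' @return A list with elements `exposure` and `outcome` (summary-statistics
#'   data frames with columns `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N`)
#'   and `truth` (per-variant `gamma`, `alpha`, `valid`, plus `causal_beta`).
#' @examples
#' sim <- simulate_gwas(sim_config(n_snps = 50, causal_beta = 0.5, seed = 1))
#' head(sim$exposure)
#' @export
simulate_gwas <- function(config, variants = NULL) {
  .assert(inherits(config, "sim_config"), "config must come from sim_config()")
  .maybe_seed(config$seed)
  m <- config$n_snps
  if (is.null(variants)) {
    variants <- .default_variants(m)
  } else {
    .assert(is.data.frame(variants) && nrow(variants) == m &&
              all(c("SNP", "CHR", "POS") %in% names(variants)),
            "variants must have %d rows and columns SNP, CHR, POS", m)
  }

  eaf <- runif(m, config$maf_range[1], config$maf_range[2])
  gamma <- rnorm(m, 0, config$gamma_sd)
  if (config$oriented) gamma <- abs(gamma)

  n_invalid <- round(config$invalid_frac * m)
  invalid <- if (n_invalid > 0) sample.int(m, n_invalid) else integer(0)
  alpha <- numeric(m)
  if (n_invalid > 0) {
    alpha[invalid] <- config$inside_kappa * gamma[invalid] +
      rnorm(n_invalid, config$pleio_mean, config$pleio_sd)
  }
  gamma_out <- config$causal_beta * gamma + alpha

  se_exp <- 1 / sqrt(2 * config$n_exp * eaf * (1 - eaf))
  se_out <- 1 / sqrt(2 * config$n_out * eaf * (1 - eaf))
  beta_exp <- gamma + rnorm(m, 0, se_exp)
  beta_out <- gamma_out + rnorm(m, 0, se_out)

  alleles <- .random_alleles(m)
  exposure <- .sumstats_table(variants, alleles$ea, alleles$oa, eaf,
                              beta_exp, se_exp, config$n_exp)
  outcome <- .sumstats_table(variants, alleles$ea, alleles$oa, eaf,
                             beta_out, se_out, config$n_out)
  if (config$flip_frac > 0) {
    rows <- which(runif(m) < config$flip_frac)
    outcome <- .flip_rows(outcome, rows)
  }

  truth <- list(gamma = gamma, alpha = alpha,
                valid = !(seq_len(m) %in% invalid),
                causal_beta = config$causal_beta, config = config)
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Simulate a haplotype reference panel with block-wise AR(1) LD
#'
#' Builds a stand-in for an external LD reference (such as a 1000 Genomes
#' panel): haplotypes organised in independent blocks, with the allele
#' correlation between variants at lag `k` inside a block equal to `rho^k`
#' (a two-state Markov chain whose second eigenvalue is `rho`).  The
#' effect-allele frequency is constant within a block, which keeps the AR(1)
#' allele correlation exact.
#'
#' @param n_blocks number of independent LD blocks.
#' @param block_size variants per block.
#' @param rho within-block adjacent-variant allele correlation, `|rho| < 1`.
#' @param n_haplotypes number of haplotypes (rows).
#' @param maf_range per-block allele frequency range.
#' @param pos_step base-pair spacing between adjacent variants in a block.
#' @param seed integer seed.
#'
#' @return An object of class `ld_panel`: a list with `haplotypes` (a
#'   `n_haplotypes x n_variants` 0/1 matrix with variant ids as column
#'   names) and `variants` (`SNP`, `CHR`, `POS`).  Blocks sharing a
#'   chromosome are separated by a 2 Mb gap.
#' @export
simulate_ld_panel <- function(n_blocks = 10L, block_size = 10L, rho = 0.8,
                              n_haplotypes = 1000L,
                              maf_range = c(0.05, 0.5), pos_step = 100000L,
                              seed = NULL) {
  .assert(.is_count(n_blocks, 1) && .is_count(block_size, 1),
          "n_blocks and block_size must be positive integers")
  .assert(.is_count(n_haplotypes, 2), "n_haplotypes must be an integer >= 2")
  .assert(.is_number(rho) && abs(rho) < 1, "rho must satisfy |rho| < 1")
  .assert(.is_count(pos_step, 1), "pos_step must be a positive integer")
  .assert(is.numeric(maf_range) && length(maf_range) == 2 &&
            all(maf_range > 0) && all(maf_range <= 0.5),
          "maf_range must lie in (0, 0.5]")
  if (rho < 0) {
    .assert(maf_range[1] * (1 - rho) <= 1 &&
              maf_range[1] + rho * (1 - maf_range[1]) >= 0,
            "rho = %g is too negative for allele frequencies in [%g, %g]",
            rho, maf_range[1], maf_range[2])
  }
  .maybe_seed(seed)

  m <- n_blocks * block_size
  H <- as.integer(n_haplotypes)
  hap <- matrix(0L, nrow = H, ncol = m)
  for (b in seq_len(n_blocks)) {
    f <- runif(1, maf_range[1], maf_range[2])
    cols <- (b - 1L) * block_size + seq_len(block_size)
    x <- rbinom(H, 1L, f)
    hap[, cols[1]] <- x
    if (block_size > 1L) {
      p_stay <- f + rho * (1 - f)   # P(X_{j+1} = 1 | X_j = 1)
      p_gain <- f * (1 - rho)       # P(X_{j+1} = 1 | X_j = 0)
      for (j in 2:block_size) {
        x <- rbinom(H, 1L, ifelse(x == 1L, p_stay, p_gain))
        hap[, cols[j]] <- x
      }
    }
  }

  block <- rep(seq_len(n_blocks), each = block_size)
  within <- rep(seq_len(block_size), times = n_blocks)
  chrom <- ((block - 1L) %% 22L) + 1L
  block_ordinal <- (block - 1L) %/% 22L
  pos <- block_ordinal * (block_size * pos_step + 2000000L) +
    within * pos_step
  variants <- data.frame(SNP = sprintf("rs%06d", seq_len(m)),
                         CHR = chrom, POS = as.integer(pos),
                         stringsAsFactors = FALSE)
  colnames(hap) <- variants$SNP
  structure(list(haplotypes = hap, variants = variants, rho = rho,
                 n_blocks = as.integer(n_blocks),
                 block_size = as.integer(block_size)),
            class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("LD reference panel: %d haplotypes x %d variants (%d block(s) of %d, rho = %g)\n",
              nrow(x$haplotypes), ncol(x$haplotypes), x$n_blocks,
              x$block_size, x$rho))
  invisible(x)
}

#' Pairwise LD between panel variants
#'
#' Squared Pearson correlation of allele counts between panel columns, the
#' r-squared used by [ld_clump()].
#'
#' @param panel an `ld_panel`.
#' @param ids variant ids; defaults to all panel variants.
#' @return A symmetric matrix of r-squared values.
#' @export
ld_r2 <- function(panel, ids = NULL) {
  .assert(inherits(panel, "ld_panel"), "panel must be an ld_panel")
  ids <- ids %||% panel$variants$SNP
  miss <- setdiff(ids, panel$variants$SNP)
  .assert(length(miss) == 0L, "variant(s) not present in reference panel: %s",
          paste(miss, collapse = ", "))
  stats::cor(panel$haplotypes[, ids, drop = FALSE])^2
}

#' Simulate exposure/mediator/outcome GWAS summary statistics
#'
#' Extends [simulate_gwas()] with a mediator on the causal path: the exposure
#' affects the mediator with effect `a`, the mediator affects the outcome
#' with effect `b`, and the exposure retains a direct effect `c_direct`, so
#' the total exposure effect is `c_direct + a * b` and the proportion
#' mediated is `a * b / (c_direct + a * b)`.  The mediator has its own
#' instruments (effects drawn like the exposure's), and exposure instruments
#' may carry variant-specific direct effects on the mediator
#' (`med_direct_sd`), the pathway heterogeneity that makes the joint
#' exposure+mediator regression identifiable from exposure instruments alone.
#'
#' @param config a [sim_config()]; `causal_beta` is ignored in favour of the
#'   path coefficients.
#' @param a exposure-to-mediator effect.
#' @param b mediator-to-outcome effect.
#' @param c_direct direct exposure-to-outcome effect.
#' @param n_snps_med number of mediator-specific instruments.
#' @param n_med mediator GWAS sample size.
#' @param med_direct_sd SD of variant-specific direct effects of exposure
#'   instruments on the mediator (0 gives a perfectly proportional, hence
#'   collinear, exposure/mediator effect pattern).
#'
#' @return A list with `exposure`, `mediator`, `outcome` summary-statistics
#'   tables over the union of both instrument sets, and `truth` recording
#'   `a`, `b`, `c`, `total = c + a*b`, `indirect = a*b`, `proportion`,
#'   per-variant true effects, and which variants are exposure instruments.
#' @export
simulate_mediation_gwas <- function(config, a = 0.8, b = 0.5, c_direct = 0.1,
                                    n_snps_med = config$n_snps,
                                    n_med = config$n_exp,
                                    med_direct_sd = 0.05) {
  .assert(inherits(config, "sim_config"), "config must come from sim_config()")
  .assert(.is_number(a) && .is_number(b) && .is_number(c_direct),
          "a, b and c_direct must be single numbers")
  .assert(.is_count(n_snps_med, 1), "n_snps_med must be a positive integer")
  .assert(.is_number(n_med) && n_med >= 2, "n_med must be >= 2")
  .assert(.is_number(med_direct_sd) && med_direct_sd >= 0,
          "med_direct_sd must be >= 0")
  .maybe_seed(config$seed)

  m_e <- config$n_snps
  m_m <- as.integer(n_snps_med)
  m <- m_e + m_m
  variants <- .default_variants(m)

  gamma <- rnorm(m_e, 0, config$gamma_sd)
  delta <- rnorm(m_m, 0, config$gamma_sd)
  if (config$oriented) {
    gamma <- abs(gamma)
    delta <- abs(delta)
  }
  eta <- rnorm(m_e, 0, med_direct_sd)

  n_invalid <- round(config$invalid_frac * m_e)
  invalid <- if (n_invalid > 0) sample.int(m_e, n_invalid) else integer(0)
  alpha <- numeric(m_e)
  if (n_invalid > 0) {
    alpha[invalid] <- config$inside_kappa * gamma[invalid] +
      rnorm(n_invalid, config$pleio_mean, config$pleio_sd)
  }

  true_exp <- c(gamma, numeric(m_m))
  true_med <- c(a * gamma + eta, delta)
  true_out <- c(c_direct * gamma + b * (a * gamma + eta) + alpha, b * delta)

  eaf <- runif(m, config$maf_range[1], config$maf_range[2])
  se_e <- 1 / sqrt(2 * config$n_exp * eaf * (1 - eaf))
  se_m <- 1 / sqrt(2 * n_med * eaf * (1 - eaf))
  se_o <- 1 / sqrt(2 * config$n_out * eaf * (1 - eaf))
  alleles <- .random_alleles(m)

  exposure <- .sumstats_table(variants, alleles$ea, alleles$oa, eaf,
                              true_exp + rnorm(m, 0, se_e), se_e, config$n_exp)
  mediator <- .sumstats_table(variants, alleles$ea, alleles$oa, eaf,
                              true_med + rnorm(m, 0, se_m), se_m, n_med)
  outcome <- .sumstats_table(variants, alleles$ea, alleles$oa, eaf,
                             true_out + rnorm(m, 0, se_o), se_o, config$n_out)

  total <- c_direct + a * b
  truth <- list(a = a, b = b, c = c_direct, total = total,
                indirect = a * b,
                proportion = if (abs(total) > 0) a * b / total else NA_real_,
                gamma = gamma, delta = delta, eta = eta, alpha = alpha,
                exposure_snps = variants$SNP[seq_len(m_e)],
                mediator_snps = variants$SNP[m_e + seq_len(m_m)],
                config = config)
  list(exposure = exposure, mediator = mediator, outcome = outcome,
       truth = truth)
}
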