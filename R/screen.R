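#' Run the MR screen over exposure-outcome pairs in memory
#'
#' For every exposure-outcome pair: selects instruments (significance
#' threshold, LD clumping, harmonization, strength filter), fits the
#' univariable estimator suite, optionally runs the sensitivity suite, and
#' finally applies group-wise FDR correction to the primary (IVW) p-values
#' when trait-type/panel metadata are supplied (a single pooled BH
#' correction otherwise).  A pair whose pipeline fails at any stage is
#' recorded in the error log instead of aborting the screen.
#'
#' @param exposures named list of exposure summary-statistics data frames.
#' @param outcomes named list of outcome summary-statistics data frames.
#' @param panel optional `ld_panel` for clumping.
#' @param metadata optional data frame with columns `exposure`,
#'   `trait_type`, `panel` used for group-wise FDR.
#' @param p_threshold,r2_threshold,window_kb,min_f instrument-selection
#'   parameters (defaults 1e-5, 0.1, 500, 10).
#' @param n_boot weighted-median bootstrap replicates.
#' @param n_sim MR-PRESSO simulations.
#' @param sensitivity run the sensitivity suite per pair (default TRUE).
#' @param fdr_level significance level for the FDR flag.
#' @param seed integer seed making the whole screen reproducible.
#' @return An object of class `mr_screen`: `results` (one row per pair and
#'   method, FDR-annotated for the primary method), `sensitivity`,
#'   `instruments` (per-variant filter fates), and `errors`.
#' @export
mr_screen <- function(exposures, outcomes, panel = NULL, metadata = NULL,
                      p_threshold = 1e-5, r2_threshold = 0.1,
                      window_kb = 500, min_f = 10, n_boot = 1000,
                      n_sim = 1000, sensitivity = TRUE, fdr_level = 0.05,
                      seed = NULL) {
  .assert(is.list(exposures) && length(exposures) > 0 &&
            !is.null(names(exposures)),
          "exposures must be a named list of summary-statistics tables")
  .assert(is.list(outcomes) && length(outcomes) > 0 &&
            !is.null(names(outcomes)),
          "outcomes must be a named list of summary-statistics tables")
  .maybe_seed(seed)

  results <- list()
  sens_rows <- list()
  fates <- list()
  errors <- list()
  for (en in names(exposures)) {
    for (on in names(outcomes)) {
      pair <- sprintf("%s ~ %s", on, en)
      out <- tryCatch({
        sel <- select_instruments(exposures[[en]], outcomes[[on]], panel,
                                  p_threshold = p_threshold,
                                  r2_threshold = r2_threshold,
                                  window_kb = window_kb, min_f = min_f)
        h <- sel$harmonized
        .assert(nrow(h) >= 1, "no instruments retained")
        fit <- mr_fit(h, n_boot = n_boot)
        est <- fit$estimates
        est$exposure <- en
        est$outcome <- on
        est$primary <- est$method == fit$primary |
          (fit$primary %in% c("ivw_fixed", "ivw_random") &
             est$method == fit$primary)
        fates[[pair]] <- transform(sel$fate, exposure = en, outcome = on)
        srow <- NULL
        if (sensitivity && nrow(h) >= 4) {
          sr <- mr_sensitivity(h, n_sim = n_sim)
          post_beta <- NA_real_
          post_pval <- NA_real_
          if (!is.null(sr$rerun)) {
            post <- sr$rerun$post$estimates
            post_beta <- post$beta[match(sr$rerun$post$primary, post$method)]
            post_pval <- post$pval[match(sr$rerun$post$primary, post$method)]
          }
          srow <- data.frame(exposure = en, outcome = on, n_snps = nrow(h),
                             Q = sr$q$Q, Q_df = sr$q$df, Q_pval = sr$q$pval,
                             egger_intercept = sr$egger_intercept$beta,
                             egger_intercept_se = sr$egger_intercept$se,
                             egger_intercept_pval = sr$egger_intercept$pval,
                             presso_global_pval = sr$presso$global_pval,
                             presso_n_outliers = length(sr$presso$outliers),
                             presso_distortion_pval = sr$presso$distortion_pval,
                             cooks_n_excluded = length(sr$cooks$excluded),
                             n_excluded = length(sr$excluded),
                             beta_after_removal = post_beta,
                             pval_after_removal = post_pval,
                             stringsAsFactors = FALSE)
        }
        list(est = est, srow = srow)
      }, error = function(e) e)
      if (inherits(out, "error")) {
        errors[[pair]] <- data.frame(exposure = en, outcome = on,
                                     error = conditionMessage(out),
                                     stringsAsFactors = FALSE)
      } else {
        results[[pair]] <- out$est
        if (!is.null(out$srow)) sens_rows[[pair]] <- out$srow
      }
    }
  }

  results <- if (length(results)) do.call(rbind, c(results, make.row.names = FALSE)) else NULL
  if (!is.null(results)) {
    front <- c("exposure", "outcome", "method", "primary")
    results <- results[c(front, setdiff(names(results), front))]
    primary <- results[results$primary, , drop = FALSE]
    if (!is.null(metadata)) {
      .assert(all(c("exposure", "trait_type", "panel") %in% names(metadata)),
              "metadata needs columns exposure, trait_type, panel")
      idx <- match(primary$exposure, metadata$exposure)
      .assert(!anyNA(idx), "metadata missing for exposure(s): %s",
              paste(unique(primary$exposure[is.na(idx)]), collapse = ", "))
      primary$trait_type <- metadata$trait_type[idx]
      primary$panel <- metadata$panel[idx]
      primary <- groupwise_fdr(primary, p_col = "pval", level = fdr_level)
    } else {
      primary$p_fdr <- bh_adjust(primary$pval)
      primary$significant <- primary$p_fdr < fdr_level
    }
    key_res <- paste(results$exposure, results$outcome, results$method)
    key_pri <- paste(primary$exposure, primary$outcome, primary$method)
    results$p_fdr <- primary$p_fdr[match(key_res, key_pri)]
    results$significant <- primary$significant[match(key_res, key_pri)]
    if (!is.null(metadata)) {
      results$trait_type <- metadata$trait_type[match(results$exposure,
                                                      metadata$exposure)]
      results$panel <- metadata$panel[match(results$exposure,
                                            metadata$exposure)]
    }
  }
  structure(list(
    results = results,
    sensitivity = if (length(sens_rows))
      do.call(rbind, c(sens_rows, make.row.names = FALSE)) else NULL,
    instruments = if (length(fates))
      do.call(rbind, c(fates, make.row.names = FALSE)) else NULL,
    errors = if (length(errors))
      do.call(rbind, c(errors, make.row.names = FALSE)) else NULL),
    class = "mr_screen")
}

#' @export
print.mr_screen <- function(x, ...) {
  n_pairs <- if (is.null(x$results)) 0L else
    nrow(unique(x$results[c("exposure", "outcome")]))
  cat(sprintf("MR screen: %d exposure-outcome pair(s) estimated", n_pairs))
  if (!is.null(x$errors)) cat(sprintf(", %d failed", nrow(x$errors)))
  cat("\n")
  if (!is.null(x$results)) {
    prim <- x$results[x$results$primary, , drop = FALSE]
    cat(sprintf("  %d pair(s) significant after FDR\n",
                sum(prim$significant, na.rm = TRUE)))
  }
  invisible(x)
}

.default_screen_config <- function() {
  list(thresholds = list(exposure_p = 1e-5, outcome_p = 5e-8,
                         clump_r2 = 0.1, reverse_clump_r2 = 0.01,
                         window_kb = 500, min_f = 10, fdr_level = 0.05),
       methods = list(n_boot = 1000, n_sim = 1000, sensitivity = TRUE))
}

.merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(defaults[[nm]])) {
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

# Simulated screen inputs: one independent exposure/outcome simulation per
# exposure, variant ids prefixed per exposure, outcomes stacked into one
# table per configured outcome name.
.simulate_screen_inputs <- function(sim, seed) {
  n_exposures <- sim$n_exposures %||% 2L
  sim$n_exposures <- NULL
  outcome_name <- sim$outcome_name %||% "outcome"
  sim$outcome_name <- NULL
  exposures <- list()
  outcome_parts <- list()
  metadata <- list()
  types <- trait_types()
  panels <- immune_panels()
  for (i in seq_len(n_exposures)) {
    args <- sim
    args$seed <- (seed %||% 0) + i
    cfg <- do.call(sim_config, args)
    s <- simulate_gwas(cfg)
    prefix <- sprintf("exp%02d", i)
    s$exposure$SNP <- paste0(prefix, "_", s$exposure$SNP)
    s$outcome$SNP <- paste0(prefix, "_", s$outcome$SNP)
    exposures[[prefix]] <- s$exposure
    outcome_parts[[prefix]] <- s$outcome
    metadata[[prefix]] <- data.frame(
      exposure = prefix,
      trait_type = types[((i - 1) %% length(types)) + 1],
      panel = panels[((i - 1) %% length(panels)) + 1],
      stringsAsFactors = FALSE)
  }
  outcome <- do.call(rbind, c(outcome_parts, make.row.names = FALSE))
  list(exposures = exposures,
       outcomes = setNames(list(outcome), outcome_name),
       metadata = do.call(rbind, c(metadata, make.row.names = FALSE)))
}

#' Run the full screen from a configuration and write result files
#'
#' Executes the complete pipeline — simulate or ingest, select, estimate,
#' sensitivity, group-wise FDR, and optional mediation — and writes
#' tab-delimited result tables plus a JSON run manifest to `out_dir`.
#' Re-running with an identical configuration and seed reproduces
#' byte-identical result files.
#'
#' @param config a list, or the path of a YAML file, with blocks:
#'   `inputs` (`exposures`/`outcomes` as named path maps, optional `panel`
#'   prefix, optional `metadata` path) or `simulate` ([sim_config()]
#'   arguments plus `n_exposures`); optional `thresholds`
#'   (`exposure_p`, `clump_r2`, `window_kb`, `min_f`, `fdr_level`);
#'   optional `methods` (`n_boot`, `n_sim`, `sensitivity`); optional
#'   `mediation` (`exposure`, `mediator`, `outcome` paths); `seed`; and
#'   `out_dir` (overridable by the argument).
#' @param out_dir output directory; created if needed.
#' @return Invisibly, the named vector of files written.
#' @export
run_screen <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    .assert(file.exists(config), "config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  .assert(is.list(config), "config must be a list or a YAML file path")
  cfg <- .merge_config(.default_screen_config(), config)
  out_dir <- out_dir %||% cfg$out_dir
  .assert(!is.null(out_dir), "an output directory is required (out_dir)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  input_files <- character(0)

  if (!is.null(cfg$simulate)) {
    sim_in <- .simulate_screen_inputs(cfg$simulate, seed)
    exposures <- sim_in$exposures
    outcomes <- sim_in$outcomes
    metadata <- sim_in$metadata
    panel <- NULL
  } else {
    .assert(!is.null(cfg$inputs),
            "config needs either a simulate or an inputs block")
    read_map <- function(paths, what) {
      .assert(is.list(paths) || is.character(paths),
              "inputs$%s must map names to file paths", what)
      paths <- unlist(paths)
      if (is.null(names(paths)) || any(names(paths) == "")) {
        names(paths) <- tools::file_path_sans_ext(basename(paths))
      }
      for (p in paths) .assert(file.exists(p), "%s file not found: %s", what, p)
      input_files <<- c(input_files, unname(paths))
      lapply(as.list(paths), read_sumstats)
    }
    exposures <- read_map(cfg$inputs$exposures, "exposure")
    outcomes <- read_map(cfg$inputs$outcomes, "outcome")
    panel <- NULL
    if (!is.null(cfg$inputs$panel)) {
      panel <- read_panel(cfg$inputs$panel)
      input_files <- c(input_files, paste0(cfg$inputs$panel, ".haplotypes.tsv"),
                       paste0(cfg$inputs$panel, ".variants.tsv"))
    }
    metadata <- NULL
    if (!is.null(cfg$inputs$metadata)) {
      .assert(file.exists(cfg$inputs$metadata), "metadata file not found: %s",
              cfg$inputs$metadata)
      metadata <- read.delim(cfg$inputs$metadata, stringsAsFactors = FALSE)
      input_files <- c(input_files, cfg$inputs$metadata)
    }
  }

  screen <- mr_screen(exposures, outcomes, panel = panel,
                      metadata = metadata,
                      p_threshold = cfg$thresholds$exposure_p,
                      r2_threshold = cfg$thresholds$clump_r2,
                      window_kb = cfg$thresholds$window_kb,
                      min_f = cfg$thresholds$min_f,
                      n_boot = cfg$methods$n_boot,
                      n_sim = cfg$methods$n_sim,
                      sensitivity = isTRUE(cfg$methods$sensitivity),
                      fdr_level = cfg$thresholds$fdr_level,
                      seed = seed)

  mediation_tab <- NULL
  if (!is.null(cfg$mediation)) {
    med <- cfg$mediation
    for (p in c(med$exposure, med$mediator, med$outcome)) {
      .assert(file.exists(p), "mediation file not found: %s", p)
    }
    input_files <- c(input_files, med$exposure, med$mediator, med$outcome)
    mm <- mr_mediation(read_sumstats(med$exposure),
                       read_sumstats(med$mediator),
                       read_sumstats(med$outcome),
                       p_threshold = cfg$thresholds$exposure_p,
                       min_f = cfg$thresholds$min_f,
                       n_boot = cfg$methods$n_boot)
    mediation_tab <- transform(mm$estimates,
                               exposure = basename(med$exposure),
                               mediator = basename(med$mediator),
                               outcome = basename(med$outcome),
                               n_snps = mm$n_snps, n_boot = mm$n_boot)
  }

  written <- character(0)
  emit <- function(tab, name) {
    if (is.null(tab)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, setNames(path, name))
  }
  emit(screen$results, "results.tsv")
  emit(screen$sensitivity, "sensitivity.tsv")
  emit(screen$instruments, "instruments.tsv")
  emit(screen$errors, "errors.tsv")
  emit(mediation_tab, "mediation.tsv")

  manifest <- list(
    package = "mrscreen",
    version = as.character(packageVersion("mrscreen")),
    seed = seed,
    config = cfg,
    input_md5 = if (length(input_files))
      as.list(tools::md5sum(input_files)) else list(),
    row_counts = list(
      results = if (is.null(screen$results)) 0L else nrow(screen$results),
      sensitivity = if (is.null(screen$sensitivity)) 0L else
        nrow(screen$sensitivity),
      instruments = if (is.null(screen$instruments)) 0L else
        nrow(screen$instruments),
      errors = if (is.null(screen$errors)) 0L else nrow(screen$errors),
      mediation = if (is.null(mediation_tab)) 0L else nrow(mediation_tab)))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  written <- c(written, setNames(manifest_path, "manifest.json"))

  if (!is.null(screen$errors)) {
    warning(sprintf("%d exposure-outcome pair(s) failed; see errors.tsv",
                    nrow(screen$errors)), call. = FALSE)
  }
  invisible(written)
}
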