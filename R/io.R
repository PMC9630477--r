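#' Read and write GWAS summary-statistics tables
#'
#' Tab-delimited files with header columns
#' `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N`, one row per variant.
#'
#' @param path file path.
#' @param x a summary-statistics data frame.
#' @return `read_sumstats()` returns the data frame; `write_sumstats()`
#'   returns `path` invisibly.
#' @export
read_sumstats <- function(path) {
  .assert(file.exists(path), "summary-statistics file not found: %s", path)
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .check_sumstats(x, name = path)
  x
}

#' @rdname read_sumstats
#' @export
write_sumstats <- function(x, path) {
  .check_sumstats(x)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write LD reference panels
#'
#' A panel is stored as two plain-text files: `<prefix>.haplotypes.tsv`
#' (tab-delimited 0/1 matrix, one haplotype per row, variant ids as header)
#' and `<prefix>.variants.tsv` (columns `SNP`, `CHR`, `POS`).
#'
#' @param panel an `ld_panel` object.
#' @param prefix path prefix for the two files.
#' @return `read_panel()` returns an `ld_panel`; `write_panel()` returns
#'   `prefix` invisibly.
#' @export
write_panel <- function(panel, prefix) {
  .assert(inherits(panel, "ld_panel"), "panel must be an ld_panel")
  write.table(panel$haplotypes, paste0(prefix, ".haplotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(panel$variants, paste0(prefix, ".variants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_panel
#' @export
read_panel <- function(prefix) {
  hap_path <- paste0(prefix, ".haplotypes.tsv")
  var_path <- paste0(prefix, ".variants.tsv")
  .assert(file.exists(hap_path), "panel haplotype file not found: %s", hap_path)
  .assert(file.exists(var_path), "panel variant file not found: %s", var_path)
  hap <- as.matrix(read.delim(hap_path, check.names = FALSE))
  variants <- read.delim(var_path, stringsAsFactors = FALSE)
  .assert(ncol(hap) == nrow(variants),
          "panel haplotype column count does not match the variant map")
  colnames(hap) <- variants$SNP
  structure(list(haplotypes = hap, variants = variants, rho = NA_real_,
                 n_blocks = NA_integer_, block_size = NA_integer_),
            class = "ld_panel")
}

#' Validate a summary-statistics table
#'
#' Checks the structural contract of a GWAS summary-statistics table:
#' required header columns (fatal), allele letters in A/C/G/T (fatal),
#' positive standard errors (fatal), p-values in (0, 1] (fatal), unique
#' variant ids (fatal), and allele frequencies in (0, 1) (warning).
#'
#' @param x a data frame, or a file path.
#' @param name label used in messages.
#' @return A data frame with columns `level` (`"fatal"` or `"warning"`),
#'   `row` and `message`; zero rows when the table is clean.
#' @export
validate_sumstats <- function(x, name = "sumstats") {
  if (is.character(x) && length(x) == 1L) {
    name <- x
    .assert(file.exists(x), "file not found: %s", x)
    x <- read.delim(x, stringsAsFactors = FALSE, check.names = FALSE)
  }
  report <- data.frame(level = character(0), row = integer(0),
                       message = character(0), stringsAsFactors = FALSE)
  note <- function(level, row, msg) {
    rbind(report, data.frame(level = level, row = row, message = msg,
                             stringsAsFactors = FALSE))
  }
  missing <- setdiff(.sumstats_cols, names(x))
  if (length(missing) > 0) {
    return(note("fatal", NA_integer_,
                sprintf("%s: malformed header, missing column(s) %s",
                        name, paste(missing, collapse = ", "))))
  }
  bad <- which(!(toupper(x$EA) %in% names(.allele_comp)) |
                 !(toupper(x$OA) %in% names(.allele_comp)))
  for (i in bad) {
    report <- note("fatal", i, sprintf("%s row %d: allele outside A/C/G/T (%s/%s)",
                                       name, i, x$EA[i], x$OA[i]))
  }
  bad <- which(!is.finite(x$SE) | x$SE <= 0)
  for (i in bad) {
    report <- note("fatal", i, sprintf("%s row %d: SE must be > 0 (got %s)",
                                       name, i, format(x$SE[i])))
  }
  bad <- which(!is.finite(x$P) | x$P <= 0 | x$P > 1)
  for (i in bad) {
    report <- note("fatal", i, sprintf("%s row %d: P must lie in (0, 1] (got %s)",
                                       name, i, format(x$P[i])))
  }
  dup <- unique(x$SNP[duplicated(x$SNP)])
  for (id in dup) {
    report <- note("fatal", NA_integer_,
                   sprintf("%s: duplicated variant id %s", name, id))
  }
  bad <- which(!is.finite(x$EAF) | x$EAF <= 0 | x$EAF >= 1)
  for (i in bad) {
    report <- note("warning", i, sprintf("%s row %d: EAF outside (0, 1) (got %s)",
                                         name, i, format(x$EAF[i])))
  }
  report
}

#' Validate a set of input files
#'
#' Runs [validate_sumstats()] over each path; a missing file is reported as
#' fatal rather than raising an error, so the full report is always
#' produced.
#'
#' @param paths character vector of summary-statistics file paths.
#' @return The combined validation report (see [validate_sumstats()]), with
#'   an extra `file` column.
#' @export
validate_inputs <- function(paths) {
  reports <- lapply(paths, function(p) {
    if (!file.exists(p)) {
      rep <- data.frame(level = "fatal", row = NA_integer_,
                        message = sprintf("file not found: %s", p),
                        stringsAsFactors = FALSE)
    } else {
      rep <- validate_sumstats(p)
    }
    if (nrow(rep) > 0) rep$file <- p else rep$file <- character(0)
    rep
  })
  do.call(rbind, reports)
}
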