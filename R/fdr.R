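#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: with the p-values sorted
#' ascending, `adjusted_(i) = min over j >= i of m * p_(j) / j`, capped at
#' 1 and returned in input order (delegates to [stats::p.adjust()]).
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  .assert(is.numeric(pvals), "pvals must be numeric")
  if (length(pvals) == 0L) return(numeric(0))
  .assert(all(is.finite(pvals)) && all(pvals > 0) && all(pvals <= 1),
          "all p-values must lie in (0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Immune-trait grouping labels
#'
#' The default grouping key used by [groupwise_fdr()]: four immune-trait
#' measurement types (median fluorescence intensity, absolute count,
#' relative count, morphological parameter) crossed with seven
#' immune-cell panels, giving 28 subgroups.
#'
#' @return A character vector of labels.
#' @export
trait_types <- function() c("MFI", "AC", "RC", "MP")

#' @rdname trait_types
#' @export
immune_panels <- function() {
  c("maturation stages of T cell", "TBNK", "Treg", "B cell",
    "Myeloid cell", "cDC", "Monocyte")
}

#' Group-wise FDR correction of MR results
#'
#' Applies [bh_adjust()] independently within each subgroup defined by the
#' grouping key (default: trait type x immune panel, 4 x 7 = 28 possible
#' subgroups; groups absent from the data are simply absent).  Intended for
#' the primary (IVW) p-values; sensitivity-method p-values are reported
#' unadjusted.
#'
#' @param results data frame of MR results.
#' @param by character vector of grouping columns (default
#'   `c("trait_type", "panel")`).
#' @param p_col name of the raw p-value column.
#' @param level significance level for the `significant` flag.
#' @param labels named list of admissible labels per grouping column; set a
#'   component to `NULL` to skip validation.  Defaults validate
#'   `trait_type` against [trait_types()] and `panel` against
#'   [immune_panels()].
#' @return `results` with columns `p_fdr` and `significant` added, and an
#'   `"n_groups"` attribute counting the non-empty subgroups.
#' @export
groupwise_fdr <- function(results, by = c("trait_type", "panel"),
                          p_col = "pval", level = 0.05,
                          labels = list(trait_type = trait_types(),
                                        panel = immune_panels())) {
  .assert(is.data.frame(results), "results must be a data.frame")
  missing <- setdiff(c(by, p_col), names(results))
  .assert(length(missing) == 0L, "results is missing column(s): %s",
          paste(missing, collapse = ", "))
  for (col in by) {
    admissible <- labels[[col]]
    if (!is.null(admissible)) {
      bad <- setdiff(unique(results[[col]]), admissible)
      .assert(length(bad) == 0L, "unknown %s label(s): %s", col,
              paste(bad, collapse = ", "))
    }
  }
  if (nrow(results) == 0L) {
    results$p_fdr <- numeric(0)
    results$significant <- logical(0)
    attr(results, "n_groups") <- 0L
    return(results)
  }
  key <- interaction(results[by], drop = TRUE, sep = " / ")
  p_fdr <- numeric(nrow(results))
  for (g in levels(key)) {
    idx <- which(key == g)
    p_fdr[idx] <- bh_adjust(results[[p_col]][idx])
  }
  results$p_fdr <- p_fdr
  results$significant <- p_fdr < level
  attr(results, "n_groups") <- nlevels(key)
  results
}
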