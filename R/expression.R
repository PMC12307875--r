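#' Volcano filter: call differentially expressed genes
#'
#' Applies the two-dimensional cutoff used for volcano-plot screening: a
#' gene is `up` when `log2fc >= lfc_cut` and `pvalue <= p_cut`, `down` when
#' `log2fc <= -lfc_cut` and `pvalue <= p_cut`, otherwise `unchanged`. Both
#' cutoffs are inclusive. The calls partition the table (one direction per
#' gene) and negating every log2 fold change swaps up and down exactly.
#'
#' @param table Data frame with columns `gene`, `log2fc`, `pvalue` (extra
#'   columns are carried through). Whether `pvalue` holds raw or adjusted
#'   values is the caller's choice and is simply recorded.
#' @param lfc_cut Log2 fold-change cutoff (> 0), default 2.
#' @param p_cut P-value cutoff (> 0), default 0.01.
#' @return `table` with a `direction` factor (`up`, `down`, `unchanged`).
#' @export
#' @examples
#' tbl <- data.frame(gene = c("PDK4", "X"), log2fc = c(2.5, 0.1),
#'                   pvalue = c(0.005, 0.4))
#' volcano_filter(tbl)
volcano_filter <- function(table, lfc_cut = 2.0, p_cut = 0.01) {
  need <- c("gene", "log2fc", "pvalue")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop_param("gene table lacks column(s): ", paste(miss, collapse = ", "))
  if (lfc_cut <= 0 || p_cut <= 0) stop_param("cutoffs must be > 0")
  dir <- rep("unchanged", nrow(table))
  sig <- table$pvalue <= p_cut
  dir[sig & table$log2fc >= lfc_cut] <- "up"
  dir[sig & table$log2fc <= -lfc_cut] <- "down"
  table$direction <- factor(dir, levels = c("up", "down", "unchanged"))
  table
}

#' Flag mitochondrial genes among DEG calls
#'
#' Case-insensitive membership of each gene symbol in a user-supplied
#' mitochondrial gene list (e.g. a MitoCarta-style inventory), plus a
#' direction-by-membership summary.
#'
#' @param calls [volcano_filter()] output.
#' @param mito_genes Non-empty character vector of mitochondrial gene
#'   symbols.
#' @return A list with `calls` (input plus logical `is_mitochondrial`) and
#'   `summary` (counts per direction x membership).
#' @export
map_mitochondrial <- function(calls, mito_genes) {
  if (length(mito_genes) == 0)
    stop_param("mito_genes must be non-empty")
  if (!"direction" %in% names(calls))
    stop_param("calls must come from volcano_filter()")
  calls$is_mitochondrial <- toupper(calls$gene) %in% toupper(mito_genes)
  summary <- as.data.frame(table(direction = calls$direction,
                                 is_mitochondrial = calls$is_mitochondrial))
  names(summary)[3] <- "n"
  list(calls = calls, summary = summary)
}

#' Relative expression by the 2^-ddCt method
#'
#' Quantifies qPCR expression of a target gene relative to a reference gene
#' (e.g. beta-actin) and a control condition:
#' `dCt = Ct_target - Ct_reference` per condition (replicate means),
#' `ddCt = dCt_treated - dCt_control`, fold change `= 2^(-ddCt)`. The result
#' is invariant to any constant offset applied to all Ct values of one
#' condition.
#'
#' @param ct Data frame with columns `gene_role` (`target` or `reference`),
#'   `condition` (`treated` or `control`) and `ct` (cycle-threshold values,
#'   finite and > 0; replicates allowed).
#' @return A list: `fold_change` (2^-ddCt), `ddct`, and the per-condition
#'   `dct` values.
#' @export
#' @examples
#' ct <- data.frame(
#'   gene_role = rep(c("target", "reference"), each = 2),
#'   condition = rep(c("control", "treated"), 2),
#'   ct = c(25, 24, 20, 20))
#' ddct(ct)$fold_change
ddct <- function(ct) {
  need <- c("gene_role", "condition", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stop_param("ct table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop_param("Ct values must be finite and > 0")
  cell_mean <- function(role, cond) {
    v <- ct$ct[ct$gene_role == role & ct$condition == cond]
    if (length(v) == 0)
      stop_param("missing Ct values for ", role, " / ", cond)
    mean(v)
  }
  dct_control <- cell_mean("target", "control") -
    cell_mean("reference", "control")
  dct_treated <- cell_mean("target", "treated") -
    cell_mean("reference", "treated")
  dd <- dct_treated - dct_control
  list(fold_change = 2^(-dd), ddct = dd,
       dct = c(control = dct_control, treated = dct_treated))
}
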