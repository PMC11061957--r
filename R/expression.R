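#' Is a gene expressed in at least one tissue?
#'
#' The annotation summaries count a gene as transcribed if it is expressed
#' in at least one of the examined tissues. What "expressed" means
#' numerically is configurable: by default any strictly positive value
#' counts; with a numeric `threshold`, the maximum over tissues must reach
#' it (inclusive).
#'
#' @param x Numeric vector of expression values across tissues (one gene).
#' @param threshold `NULL` (default; any value > 0) or a numeric detection
#'   threshold compared with `>=`.
#' @return Logical scalar.
#' @export
expressed_anywhere <- function(x, threshold = NULL) {
  stopifnot(all(x >= 0))
  if (is.null(threshold)) return(max(x) > 0)
  stopifnot(threshold >= 0)
  max(x) >= threshold
}

#' Tissue-specificity index tau
#'
#' tau = sum_i(1 - x_i / x_max) / (n - 1); 0 for uniform expression across
#' tissues, 1 for expression confined to a single tissue. Invariant to
#' positive scaling of the row. Undefined (NA) for an all-zero row.
#'
#' @param x Non-negative expression vector across n >= 2 tissues.
#' @return Value in `[0, 1]`, or `NA_real_` for an all-zero row.
#' @export
tissue_specificity_tau <- function(x) {
  stopifnot(all(x >= 0), length(x) >= 2L)
  if (max(x) == 0) {
    warning("all-zero expression row: tau undefined")
    return(NA_real_)
  }
  sum(1 - x / max(x)) / (length(x) - 1L)
}

#' Relative abundance by the 2^-dCt method
#'
#' 2^-(Ct_target - Ct_reference), the RT-qPCR relative abundance of a
#' target gene versus a reference gene (beta-actin).
#'
#' @param ct_target,ct_reference Finite Ct values (vectorised).
#' @return Relative abundance(s).
#' @export
delta_ct <- function(ct_target, ct_reference) {
  stopifnot(all(is.finite(ct_target)), all(is.finite(ct_reference)))
  2^(-(ct_target - ct_reference))
}

#' Summarise an RT-qPCR Ct table
#'
#' Computes 2^-dCt per well, averages technical replicates within each
#' biological replicate, then reports the mean and standard deviation over
#' biological replicates per (gene, tissue) — mirroring a design of three
#' biological replicates with five technical replicates each.
#'
#' @param ct_table data.frame with columns `gene`, `tissue`, `biorep`,
#'   `techrep`, `ct_target`, `ct_reference`.
#' @return data.frame: `gene`, `tissue`, `mean`, `sd`, `n_bioreps`.
#' @export
qpcr_summary <- function(ct_table) {
  need <- c("gene", "tissue", "biorep", "techrep", "ct_target", "ct_reference")
  miss <- setdiff(need, names(ct_table))
  if (length(miss)) stop("Ct table missing column(s): ", paste(miss, collapse = ", "))
  stopifnot(all(ct_table$ct_target > 0), all(ct_table$ct_reference > 0))
  ct_table$abund <- delta_ct(ct_table$ct_target, ct_table$ct_reference)
  bio <- stats::aggregate(abund ~ gene + tissue + biorep, data = ct_table, FUN = mean)
  agg_m <- stats::aggregate(abund ~ gene + tissue, data = bio, FUN = mean)
  agg_s <- stats::aggregate(abund ~ gene + tissue, data = bio, FUN = stats::sd)
  agg_n <- stats::aggregate(abund ~ gene + tissue, data = bio, FUN = length)
  out <- merge(merge(agg_m, agg_s, by = c("gene", "tissue"),
                     suffixes = c("_mean", "_sd")),
               agg_n, by = c("gene", "tissue"))
  names(out) <- c("gene", "tissue", "mean", "sd", "n_bioreps")
  out[order(out$gene, out$tissue), , drop = FALSE]
}

#' Expression-presence and specificity report for a matrix
#'
#' @param mat Genes x tissues matrix of non-negative expression values.
#' @param threshold Passed to [expressed_anywhere()].
#' @return data.frame: `gene`, `expressed`, `tau`.
#' @export
expression_report <- function(mat, threshold = NULL) {
  stopifnot(!is.null(rownames(mat)), !anyDuplicated(colnames(mat)))
  data.frame(gene = rownames(mat),
             expressed = apply(mat, 1L, expressed_anywhere, threshold = threshold),
             tau = suppressWarnings(apply(mat, 1L, function(r)
               if (max(r) == 0) NA_real_ else tissue_specificity_tau(r))))
}
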