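#' Gene-list over-representation by summed hypergeometric densities
#'
#' Probability of observing an intersection at least as large as `QT` when
#' `Q` differentially regulated genes are drawn from a universe of `Auniv`
#' genes containing a target list of `Tt` genes:
#' `p = sum_{i = QT}^{min(Q, Tt)} dhyper(i, Tt, Auniv - Tt, Q)`.
#'
#' @param QT observed intersection between the DE genes and the target list.
#' @param Q number of differentially regulated genes.
#' @param Tt size of the target gene list.
#' @param Auniv total number of genes in the universe (a required input: it
#'   depends on the annotation in use and is never hard-coded).
#' @return upper-tail probability in (0, 1].
#' @examples
#' list_enrichment(QT = 2, Q = 5, Tt = 4, Auniv = 20)  # 3856/15504
#' @export
list_enrichment <- function(QT, Q, Tt, Auniv) {
  if (any(c(QT, Q, Tt, Auniv) < 0) || Q > Auniv || Tt > Auniv ||
      QT > min(Q, Tt)) {
    stop("invalid enrichment counts: need QT <= min(Q, Tt) and Q, Tt <= Auniv",
         call. = FALSE)
  }
  sum(dhyper(QT:min(Q, Tt), Tt, Auniv - Tt, Q))
}

#' Cross-validate a DE gene set against published target lists
#'
#' Runs [list_enrichment()] for each named target list against one set of
#' differentially expressed genes, reporting the counts alongside the raw
#' p-value and a Benjamini-Hochberg column across the lists.
#'
#' @param de_genes character vector of DE gene identifiers.
#' @param target_lists named list of character vectors (one per published
#'   list); identifiers must share the namespace of `de_genes`.
#' @param Auniv universe size (total genes).
#' @return data frame `list_name`, `Q`, `T`, `QT`, `p`, `p_adj` in input
#'   list order.
#' @export
cross_validate <- function(de_genes, target_lists, Auniv) {
  if (Auniv <= 0) stop("empty universe", call. = FALSE)
  if (is.null(names(target_lists)) || any(names(target_lists) == "")) {
    stop("target_lists must be named", call. = FALSE)
  }
  de <- unique(de_genes)
  rows <- lapply(names(target_lists), function(nm) {
    tl <- unique(target_lists[[nm]])
    qt <- length(intersect(de, tl))
    data.frame(list_name = nm, Q = length(de), T = length(tl), QT = qt,
               p = list_enrichment(qt, length(de), length(tl), Auniv),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Read a gene list from a plain-text file
#'
#' One identifier per line; blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return character vector of identifiers.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Delta-delta-Ct relative fold change
#'
#' Relative quantification of qPCR measurements against a reference gene and
#' a control condition, assuming amplification efficiency exactly 2:
#' `fold = 2 ^ -((Ct_target_exp - Ct_ref_exp) - (Ct_target_ctrl - Ct_ref_ctrl))`.
#'
#' @param ct_target_exp,ct_ref_exp cycle thresholds of target and reference
#'   gene in the experimental condition.
#' @param ct_target_ctrl,ct_ref_ctrl the same in the control condition.
#' @return fold change (> 0, unitless); vectorized.
#' @examples
#' ddct_fold_change(20, 18, 22, 18)  # delta-delta-Ct = -2, fold = 4
#' @export
ddct_fold_change <- function(ct_target_exp, ct_ref_exp,
                             ct_target_ctrl, ct_ref_ctrl) {
  cts <- c(ct_target_exp, ct_ref_exp, ct_target_ctrl, ct_ref_ctrl)
  if (anyNA(cts) || any(!is.finite(cts))) {
    stop("non-finite Ct value", call. = FALSE)
  }
  ddct <- (ct_target_exp - ct_ref_exp) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
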