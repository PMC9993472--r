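#' Call condition-specific genes from a two-state expression table
#'
#' Threshold-based specificity calls on mean abundance per state:
#' `log2fc = log2((mean_a + pseudocount) / (mean_b + pseudocount))`.
#' A gene is `a_specific` when `log2fc >= log2fcMin` and `mean_a >=
#' minLevel`; `b_specific` symmetrically; `low_expressed` when both means
#' fall below `minLevel`; otherwise `shared`.  The default
#' `log2fcMin = 2` encodes a 4-fold change.
#'
#' @param expr numeric matrix, genes x samples (one shared gene universe —
#'   a gene quantified in only one state cannot be represented and tables
#'   from separate files must be joined first; a mismatch is an error in
#'   [joinStateTables()]).
#' @param states factor/character of length `ncol(expr)` with exactly two
#'   levels assigning each sample to a state.
#' @param stateA,stateB which level is the "A" (e.g. disease) and "B"
#'   (e.g. normal) state; default the first and second level.
#' @param log2fcMin minimum |log2 fold change| for a specific call.
#' @param minLevel minimum mean abundance (TPM/RPKM) for an expressed gene.
#' @param pseudocount added to both means before the ratio.
#' @return data.frame with `gene_id`, `mean_a`, `mean_b`, `log2fc`, `call`.
#' @export
callSpecificGenes <- function(expr, states, stateA = NULL, stateB = NULL,
                              log2fcMin = 2, minLevel = 1, pseudocount = 0.1) {
  states <- as.character(states)
  lv <- unique(states)
  if (length(lv) != 2) stop("need exactly two states, got: ",
                            paste(lv, collapse = ", "))
  if (is.null(stateA)) stateA <- lv[1]
  if (is.null(stateB)) stateB <- lv[2]
  stopifnot(stateA %in% lv, stateB %in% lv, length(states) == ncol(expr))
  meanA <- rowMeans(expr[, states == stateA, drop = FALSE])
  meanB <- rowMeans(expr[, states == stateB, drop = FALSE])
  lfc <- log2((meanA + pseudocount) / (meanB + pseudocount))
  call <- ifelse(meanA < minLevel & meanB < minLevel, "low_expressed",
          ifelse(lfc >= log2fcMin & meanA >= minLevel, "a_specific",
          ifelse(-lfc >= log2fcMin & meanB >= minLevel, "b_specific",
                 "shared")))
  data.frame(gene_id = rownames(expr), mean_a = meanA, mean_b = meanB,
             log2fc = lfc, call = call, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Join per-state expression tables on a shared gene universe
#'
#' @param exprA,exprB genes x samples matrices from the two states.
#' @return list with the joined matrix `expr` and the `states` vector.
#'   Gene sets must be identical (any gene present in one state only is an
#'   error).
#' @export
joinStateTables <- function(exprA, exprB) {
  if (!setequal(rownames(exprA), rownames(exprB)))
    stop("expression tables must share one gene universe; ",
         length(union(setdiff(rownames(exprA), rownames(exprB)),
                      setdiff(rownames(exprB), rownames(exprA)))),
         " gene(s) present in one state only")
  exprB <- exprB[rownames(exprA), , drop = FALSE]
  list(expr = cbind(exprA, exprB),
       states = rep(c("A", "B"), c(ncol(exprA), ncol(exprB))))
}

#' Expression breadth across a multi-cell panel
#'
#' For each gene, the number and fraction of panel cells in which it is
#' expressed (abundance at or above `threshold`); genes with breadth at or
#' below `breadthMax` are labelled cell-specific.
#'
#' @param panel genes x cells abundance matrix (>= 1 gene; intended for
#'   panels of >= 3 cells).
#' @param threshold expressed-call cutoff (abundance units).
#' @param breadthMax maximum breadth for the cell-specific label.
#' @return data.frame `gene_id`, `n_expressed`, `breadth`, `cell_specific`.
#' @export
expressionBreadth <- function(panel, threshold = 1, breadthMax = 0.2) {
  stopifnot(nrow(panel) >= 1)
  nExpr <- rowSums(panel >= threshold)
  breadth <- nExpr / ncol(panel)
  data.frame(gene_id = rownames(panel), n_expressed = nExpr,
             breadth = breadth, cell_specific = breadth <= breadthMax,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of genes with a factor peak at the promoter
#'
#' A gene is bound when at least one peak overlaps its TSS window
#' ([tssWindow()], default +/- 2 kb) — the computation behind "fraction of
#' specific genes with RNAPII at the promoter".
#'
#' @param genes stranded gene `GRanges` (non-empty).
#' @param peaks peak `GRanges` of a single factor.
#' @param flank promoter half-width in bp.
#' @return list with `bound` (named logical per gene) and `fraction`.
#' @export
promoterBindingFraction <- function(genes, peaks, flank = 2000L) {
  if (length(genes) == 0) stop("empty gene list")
  fac <- unique(mcols(peaks)$factor)
  if (length(fac) > 1)
    stop("peaks must be of a single factor, got: ", paste(fac, collapse = ", "))
  bound <- countOverlaps(tssWindow(genes, flank), peaks) > 0
  names(bound) <- mcols(genes)$gene_id
  list(bound = bound, fraction = mean(bound))
}
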