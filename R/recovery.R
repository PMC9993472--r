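#' Enhancer-gene links of a network
#'
#' Edges joining one distal enhancer node (`E`) and one gene promoter node
#' (`P` or `Ep`) — the realised enhancer-promoter interactions.
#'
#' @param network an [EPNetwork-class].
#' @return data.frame `element_id`, `gene_id`, `type`.
#' @export
extractEPEdges <- function(network) {
  nodes <- as.data.frame(networkNodes(network))
  edges <- as.data.frame(networkEdges(network)[, c("node_a", "node_b",
                                                   "type")])
  kindOf <- setNames(nodes$kind, nodes$node)
  geneOf <- setNames(nodes$gene_id, nodes$node)
  isE <- function(n) kindOf[n] == "E"
  keep <- xor(isE(edges$node_a), isE(edges$node_b))
  if (!any(keep))
    return(data.frame(element_id = character(), gene_id = character(),
                      type = character(), stringsAsFactors = FALSE))
  ed <- edges[keep, , drop = FALSE]
  eNode <- ifelse(isE(ed$node_a), ed$node_a, ed$node_b)
  gNode <- ifelse(isE(ed$node_a), ed$node_b, ed$node_a)
  data.frame(element_id = sub("^E:", "", eNode),
             gene_id = unname(geneOf[gNode]), type = ed$type,
             stringsAsFactors = FALSE)
}

#' Precision and recall of recovered enhancer-gene links
#'
#' Compares the enhancer-gene links of a network against a planted truth
#' table, matching enhancers by their genomic footprint (an element
#' counts as matching a planted enhancer when their ranges overlap).
#'
#' @param network an [EPNetwork-class] built for one state.
#' @param enhancers the enhancer `GRanges` the network was annotated with.
#' @param truthEp truth table with columns `gene_id`, `chrom`, `start`,
#'   `end` (BED coordinates of the planted enhancer), e.g. one state's
#'   rows of `truth$epEdges` from [generateDataset()].
#' @return list `precision`, `recall`, `nPredicted`, `nTruth`.
#' @export
epRecovery <- function(network, enhancers, truthEp) {
  pred <- extractEPEdges(network)
  truthGR <- bedToGRanges(truthEp$chrom, truthEp$start, truthEp$end)
  predGR <- enhancers[match(pred$element_id,
                            mcols(enhancers)$element_id)]
  hit <- findOverlaps(predGR, truthGR, select = "first")
  matched <- !is.na(hit) & pred$gene_id == truthEp$gene_id[hit]
  tp <- sum(matched)
  truthKey <- paste(truthEp$gene_id, truthEp$chrom, truthEp$start)
  recovered <- unique(paste(truthEp$gene_id[hit[matched]],
                            truthEp$chrom[hit[matched]],
                            truthEp$start[hit[matched]]))
  list(precision = if (nrow(pred)) tp / nrow(pred) else NA_real_,
       recall = if (nrow(truthEp)) length(recovered) / length(truthKey)
                else NA_real_,
       nPredicted = nrow(pred), nTruth = nrow(truthEp))
}

#' Per-bin gene density on one chromosome
#'
#' Number of gene TSSs falling in each fixed-width bin — the orientation
#' input for [callCompartments()].
#'
#' @param genes stranded gene `GRanges`.
#' @param chrom chromosome to bin.
#' @param binsize bin width in bp.
#' @param nBins number of bins.
#' @return integer vector of length `nBins`.
#' @export
geneDensityPerBin <- function(genes, chrom, binsize, nBins) {
  tss <- tssSites(genes[as.character(seqnames(genes)) == chrom])
  bin <- ((start(tss) - 1) %/% binsize) + 1
  as.integer(table(factor(bin, levels = seq_len(nBins))))
}
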