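#' Classify enhancer chromatin state from histone marks
#'
#' H3K4me1 with H3K27ac is `active`; H3K4me1 alone is `intermediate`;
#' H3K4me1 with H3K27me3 is `poised`; anything without H3K4me1 is
#' `unclassified`.  H3K4me1 + both K27 marks is resolved as `poised`
#' (repression dominates), keeping the rule total and mutually exclusive.
#'
#' @param marks character vector, or list of character vectors, of histone
#'   factors overlapping an element.
#' @return character state(s), one per input element.
#' @export
classifyEnhancerState <- function(marks) {
  if (!is.list(marks)) marks <- list(marks)
  vapply(marks, function(m) {
    if (!"H3K4me1" %in% m) return("unclassified")
    if ("H3K27me3" %in% m) return("poised")
    if ("H3K27ac" %in% m) return("active")
    "intermediate"
  }, character(1))
}

#' Score promoters as strong vs enhancer-like
#'
#' Mean H3K4me3 and H3K4me1 signal over each gene's TSS window; the
#' log2 ratio `log2((me3 + eps)/(me1 + eps))` classifies the promoter as
#' `enhancer_like` when negative and `strong` otherwise (the tie at
#' exactly 0 is strong).
#'
#' @param genes stranded gene `GRanges` with `gene_id`.
#' @param me3Track,me1Track bedGraph-style `GRanges` with `score`
#'   (H3K4me3 and H3K4me1 signal).
#' @param flank promoter half-width in bp.
#' @param eps pseudo-signal keeping the ratio defined on empty windows.
#' @return data.frame `gene_id`, `me3_signal`, `me1_signal`, `log2_ratio`,
#'   `klass`.
#' @export
promoterStrength <- function(genes, me3Track, me1Track,
                             flank = 2000L, eps = 0.1) {
  win <- tssWindow(genes, flank)
  me3 <- signalInWindow(me3Track, win)
  me1 <- signalInWindow(me1Track, win)
  ratio <- log2((me3 + eps) / (me1 + eps))
  data.frame(gene_id = mcols(genes)$gene_id,
             me3_signal = me3, me1_signal = me1, log2_ratio = ratio,
             klass = ifelse(ratio < 0, "enhancer_like", "strong"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Define the distal enhancer universe
#'
#' Enhancers are H3K4me1 peaks lying outside every TSS window and
#' overlapping at least one RNAPII loop anchor (restricting to enhancers
#' engaged in RNAPII-mediated interactions); their chromatin state comes
#' from [classifyEnhancerState()] on overlapping K27 marks.  Setting
#' `requireAnchor = FALSE` relaxes the loop-anchor requirement to overlap
#' with any peak in `rnapiiPeaks`.
#'
#' @param me1Peaks,k27acPeaks,k27me3Peaks peak `GRanges` for H3K4me1,
#'   H3K27ac, H3K27me3.
#' @param genes stranded gene `GRanges`.
#' @param loops RNAPII [LoopSet-class].
#' @param flank TSS-window half-width in bp.
#' @param requireAnchor require overlap with a loop anchor (default) or,
#'   when `FALSE`, with `rnapiiPeaks`.
#' @param rnapiiPeaks RNAPII peak `GRanges`, used when
#'   `requireAnchor = FALSE`.
#' @return enhancer `GRanges` with metadata `element_id` and `state`.
#' @export
defineEnhancers <- function(me1Peaks, k27acPeaks, k27me3Peaks, genes, loops,
                            flank = 2000L, requireAnchor = TRUE,
                            rnapiiPeaks = NULL) {
  win <- tssWindow(genes, flank)
  distal <- me1Peaks[countOverlaps(me1Peaks, win) == 0]
  if (requireAnchor) {
    keep <- countOverlaps(distal, anchorOne(loops)) +
            countOverlaps(distal, anchorTwo(loops)) > 0
  } else {
    if (is.null(rnapiiPeaks))
      stop("rnapiiPeaks required when requireAnchor = FALSE")
    keep <- countOverlaps(distal, rnapiiPeaks) > 0
  }
  enh <- distal[keep]
  marks <- lapply(seq_along(enh), function(i) {
    m <- "H3K4me1"
    if (length(k27acPeaks) && countOverlaps(enh[i], k27acPeaks) > 0)
      m <- c(m, "H3K27ac")
    if (length(k27me3Peaks) && countOverlaps(enh[i], k27me3Peaks) > 0)
      m <- c(m, "H3K27me3")
    m
  })
  mcols(enh) <- DataFrame(
    element_id = sprintf("ENH_%04d", seq_along(enh)),
    state = classifyEnhancerState(marks))
  enh
}

#' Annotate loop anchors as promoter, enhancer-like promoter, or enhancer
#'
#' An anchor overlapping any TSS window is annotated with that gene:
#' `P` for a strong promoter, `Ep` for an enhancer-like promoter
#' (promoter identity takes precedence over enhancer overlap).  An anchor
#' overlapping several TSS windows takes the gene with the nearest TSS
#' (ambiguity is reported via a message).  Otherwise an anchor overlapping
#' an enhancer element is `E`; anything else is `none`.
#'
#' @param anchors `GRanges` of loop anchors.
#' @param genes stranded gene `GRanges` with `gene_id`.
#' @param strengths promoter strength table from [promoterStrength()].
#' @param enhancers enhancer `GRanges` from [defineEnhancers()].
#' @param flank TSS-window half-width in bp.
#' @return data.frame `type` (`P`/`Ep`/`E`/`none`), `gene_id`,
#'   `element_id`, one row per anchor.
#' @export
annotateAnchors <- function(anchors, genes, strengths, enhancers,
                            flank = 2000L) {
  win <- tssWindow(genes, flank)
  tss <- tssSites(genes); strand(tss) <- "*"
  klass <- setNames(strengths$klass, strengths$gene_id)
  type <- rep("none", length(anchors))
  geneId <- rep(NA_character_, length(anchors))
  elementId <- rep(NA_character_, length(anchors))
  hits <- findOverlaps(anchors, win)
  if (length(hits)) {
    nAmb <- 0L
    byAnchor <- split(subjectHits(hits), queryHits(hits))
    for (a in names(byAnchor)) {
      gi <- byAnchor[[a]]
      ai <- as.integer(a)
      if (length(gi) > 1) {
        nAmb <- nAmb + 1L
        d <- GenomicRanges::distance(anchors[ai], tss[gi])
        gi <- gi[which.min(d)]
      }
      g <- mcols(genes)$gene_id[gi]
      geneId[ai] <- g
      type[ai] <- if (identical(unname(klass[g]), "enhancer_like")) "Ep" else "P"
    }
    if (nAmb > 0)
      message("annotateAnchors: ", nAmb,
              " anchor(s) overlapped multiple TSS windows; nearest TSS used")
  }
  ehits <- findOverlaps(anchors, enhancers, select = "first")
  isE <- type == "none" & !is.na(ehits)
  type[isE] <- "E"
  elementId[isE] <- mcols(enhancers)$element_id[ehits[isE]]
  data.frame(type = type, gene_id = geneId, element_id = elementId,
             stringsAsFactors = FALSE)
}

#' Build the enhancer-promoter interaction network
#'
#' One node per annotated element (promoters keyed by gene, enhancers by
#' element id), one edge per distinct node pair, typed by the sorted pair
#' of anchor annotations (`E-P`, `Ep-P`, `P-P`, `E-E`, `E-Ep`, `Ep-Ep`).
#' Loops with a `none` anchor contribute no edge; multiple loops joining
#' one pair collapse into a single edge whose `n_loops` counts the
#' support.  A gene's connected-enhancer count is its number of distinct
#' `E` or `Ep` partners (enhancer-like promoters count as enhancers).
#'
#' @param loops [LoopSet-class] the annotations were computed on.
#' @param annoOne,annoTwo anchor annotation data.frames from
#'   [annotateAnchors()] for `anchorOne(loops)` and `anchorTwo(loops)`.
#' @return an [EPNetwork-class].
#' @export
buildEPNetwork <- function(loops, annoOne, annoTwo) {
  stopifnot(nrow(annoOne) == length(loops), nrow(annoTwo) == length(loops))
  nodeKey <- function(anno) {
    ifelse(anno$type %in% c("P", "Ep"), paste0("G:", anno$gene_id),
    ifelse(anno$type == "E", paste0("E:", anno$element_id), NA))
  }
  kA <- nodeKey(annoOne); kB <- nodeKey(annoTwo)
  keep <- which(!is.na(kA) & !is.na(kB))
  nodes <- unique(data.frame(
    node = c(kA[keep], kB[keep]),
    kind = c(annoOne$type[keep], annoTwo$type[keep]),
    gene_id = c(annoOne$gene_id[keep], annoTwo$gene_id[keep]),
    stringsAsFactors = FALSE))
  edgeKey <- ifelse(kA[keep] < kB[keep],
                    paste(kA[keep], kB[keep], sep = "|"),
                    paste(kB[keep], kA[keep], sep = "|"))
  typeOf <- function(tA, tB) paste(sort(c(tA, tB)), collapse = "-")
  edgeRows <- lapply(split(seq_along(keep), edgeKey), function(ii) {
    li <- keep[ii]
    i <- li[1]
    a <- kA[i]; b <- kB[i]
    if (a > b) { tmp <- a; a <- b; b <- tmp
                 tt <- typeOf(annoTwo$type[i], annoOne$type[i])
    } else tt <- typeOf(annoOne$type[i], annoTwo$type[i])
    data.frame(node_a = a, node_b = b, type = tt,
               n_loops = length(li), stringsAsFactors = FALSE)
  })
  edges <- if (length(edgeRows)) do.call(rbind, edgeRows) else
    data.frame(node_a = character(), node_b = character(),
               type = character(), n_loops = integer(),
               stringsAsFactors = FALSE)
  loopIdx <- lapply(split(keep, edgeKey), as.integer)
  edgesDF <- DataFrame(edges, row.names = NULL)
  edgesDF$loops <- IRanges::IntegerList(
    if (nrow(edges)) loopIdx else list())
  new("EPNetwork",
      nodes = DataFrame(unique(nodes), row.names = NULL),
      edges = edgesDF)
}

#' Per-gene connected-enhancer counts
#'
#' Number of distinct `E` elements plus `Ep` (enhancer-like promoter)
#' partners connected to each gene's promoter node.
#'
#' @param network an [EPNetwork-class].
#' @return named integer vector over genes present in the network.
#' @export
geneEnhancerCounts <- function(network) {
  nodes <- as.data.frame(networkNodes(network))
  edges <- as.data.frame(networkEdges(network)[, c("node_a", "node_b")])
  kindOf <- setNames(nodes$kind, nodes$node)
  geneOf <- setNames(nodes$gene_id, nodes$node)
  geneNodes <- nodes$node[nodes$kind %in% c("P", "Ep")]
  counts <- vapply(geneNodes, function(gn) {
    nb <- unique(c(edges$node_b[edges$node_a == gn],
                   edges$node_a[edges$node_b == gn]))
    nb <- setdiff(nb, gn)
    sum(kindOf[nb] %in% c("E", "Ep"))
  }, integer(1))
  setNames(as.integer(counts), geneOf[geneNodes])
}

#' Expression effect of connected-enhancer count
#'
#' Genes are stratified by connected-enhancer count (1, 2, >= 3 by
#' default); per-stratum expression values are compared pairwise with
#' [wilcoxonRankSum()].  Strata with fewer than 2 genes yield NA
#' p-values for their comparisons.
#'
#' @param enhancerCounts named integer vector from [geneEnhancerCounts()].
#' @param expression named numeric vector of per-gene abundance.
#' @param breaks stratum definition: counts >= `max(breaks)` share the top
#'   stratum.
#' @return list with `strata` (named list of expression vectors) and
#'   `p.values` (data.frame of pairwise comparisons).
#' @export
enhancerCountEffect <- function(enhancerCounts, expression,
                                breaks = c(1L, 2L, 3L)) {
  common <- intersect(names(enhancerCounts), names(expression))
  ec <- enhancerCounts[common]; ex <- expression[common]
  labs <- c(as.character(breaks[-length(breaks)]),
            paste0(">=", breaks[length(breaks)]))
  stratumOf <- function(k) {
    if (k < breaks[1]) return(NA_character_)
    i <- findInterval(k, breaks)
    labs[i]
  }
  st <- vapply(ec, stratumOf, character(1))
  strata <- lapply(labs, function(l) unname(ex[which(st == l)]))
  names(strata) <- labs
  cmb <- combn(labs, 2)
  pv <- apply(cmb, 2, function(pair) {
    a <- strata[[pair[1]]]; b <- strata[[pair[2]]]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    wilcoxonRankSum(a, b)$p.value
  })
  list(strata = strata,
       p.values = data.frame(stratum_a = cmb[1, ], stratum_b = cmb[2, ],
                             p.value = pv, stringsAsFactors = FALSE))
}
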