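#' @importFrom igraph graph_from_edgelist components make_empty_graph
NULL

#' Cluster loops into interaction domains (RAID/CCD)
#'
#' A domain is a connected component of the graph whose nodes are loops and
#' whose edges join loops with any anchor pair closer than `mergeGap` bp
#' (strict overlap when `mergeGap = 0`).  RNAPII loops yield RAIDs
#' (RNAPII-associated interaction domains), CTCF loops yield CCDs
#' (CTCF-mediated chromatin contact domains).  The result is a partition:
#' every loop belongs to exactly one domain.
#'
#' @param loops a [LoopSet-class] of a single factor.
#' @param mergeGap maximum separation in bp for two anchors to connect
#'   their loops; 0 requires genuine overlap.
#' @return list with `domains` (a `GRanges` of domain spans, metadata
#'   `domain_id`, `factor`, `n_loops`) and `membership` (integer vector
#'   mapping each loop to its domain index).
#' @export
clusterDomains <- function(loops, mergeGap = 0L) {
  fac <- unique(loopFactor(loops))
  if (length(fac) > 1)
    stop("loops must be of a single factor, got: ", paste(fac, collapse = ", "))
  n <- length(loops)
  if (n == 0)
    return(list(domains = GRanges(), membership = integer()))
  anchors <- c(anchorOne(loops), anchorTwo(loops))
  loopOf <- rep(seq_len(n), 2L)
  maxgap <- if (mergeGap > 0) as.integer(mergeGap) - 1L else -1L
  hits <- findOverlaps(anchors, anchors, maxgap = maxgap)
  edges <- cbind(loopOf[queryHits(hits)], loopOf[subjectHits(hits)])
  edges <- edges[edges[, 1] < edges[, 2], , drop = FALSE]
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, t(edges))
  membership <- igraph::components(g)$membership
  # relabel components by left-most anchor for order-invariant output
  spanStart <- tapply(start(anchorOne(loops)), membership, min)
  chromOf <- tapply(as.character(seqnames(anchorOne(loops))), membership,
                    function(x) x[1])
  ord <- order(chromOf, spanStart)
  relabel <- integer(length(ord)); relabel[as.integer(names(spanStart))[ord]] <-
    seq_along(ord)
  membership <- relabel[membership]
  chromA <- as.character(seqnames(anchorOne(loops)))
  sMin <- tapply(start(anchorOne(loops)), membership, min)
  eMax <- tapply(pmax(end(anchorOne(loops)), end(anchorTwo(loops))),
                 membership, max)
  dIdx <- as.integer(names(sMin))
  domains <- GRanges(chromA[match(dIdx, membership)],
                     IRanges(as.integer(sMin), as.integer(eMax)))
  domains <- domains[order(dIdx)]
  mcols(domains) <- DataFrame(
    domain_id = sprintf("%s_%03d", ifelse(fac == "RNAPII", "RAID",
                                          ifelse(fac == "CTCF", "CCD", "DOM")),
                        seq_along(domains)),
    factor = fac,
    n_loops = as.integer(table(factor(membership, seq_along(domains)))))
  list(domains = domains, membership = membership)
}

#' Assign genes to interaction domains
#'
#' A gene is inside a domain iff its TSS lies within the domain span;
#' domains are classified SG (single gene) with exactly one TSS and MG
#' (multi-gene) with two or more.  When `geneSubset` is given (e.g. the
#' condition-specific genes), the fraction of that subset inside any
#' domain is reported.
#'
#' @param domains domain `GRanges` from [clusterDomains()].
#' @param genes stranded gene `GRanges` with `gene_id`.
#' @param geneSubset optional character vector of gene_ids.
#' @return list: `geneDomain` (named character, domain_id or NA per gene),
#'   `geneClass` (per-domain `SG`/`MG`/`none`), `fractionInside` (for the
#'   subset, or all genes when no subset given).
#' @export
assignGenesToDomains <- function(domains, genes, geneSubset = NULL) {
  tss <- tssSites(genes)
  strand(tss) <- "*"
  hits <- findOverlaps(tss, domains, select = "first")
  geneDomain <- setNames(
    ifelse(is.na(hits), NA_character_, mcols(domains)$domain_id[hits]),
    mcols(genes)$gene_id)
  counts <- as.integer(table(factor(hits, levels = seq_along(domains))))
  geneClass <- setNames(
    ifelse(counts == 0, "none", ifelse(counts == 1, "SG", "MG")),
    mcols(domains)$domain_id)
  subset <- if (is.null(geneSubset)) names(geneDomain) else geneSubset
  inside <- !is.na(geneDomain[subset])
  list(geneDomain = geneDomain, geneClass = geneClass,
       fractionInside = mean(inside))
}

#' Genes with a loop anchor proximal to the TSS
#'
#' A gene is included when any loop anchor overlaps its TSS window; each
#' gene is counted once but its number of overlapping anchors is reported
#' (both anchors of one loop can count separately).
#'
#' @param loops a [LoopSet-class].
#' @param genes stranded gene `GRanges` with `gene_id`.
#' @param flank promoter half-width in bp.
#' @return named integer vector of anchor counts over all genes (0 for
#'   genes with no proximal anchor).
#' @export
genesWithAnchorAtTss <- function(loops, genes, flank = 2000L) {
  win <- tssWindow(genes, flank)
  counts <- countOverlaps(win, anchorOne(loops)) +
            countOverlaps(win, anchorTwo(loops))
  setNames(counts, mcols(genes)$gene_id)
}

#' Call A/B compartments from a binned contact matrix
#'
#' Standard leading-eigenvector compartment calling: the matrix is
#' distance-normalised (each diagonal divided by its mean, the
#' observed/expected transform), converted to a bin-bin Pearson
#' correlation matrix, and the sign of its first principal component
#' labels the bins.  The sign is oriented so that the `A` compartment has
#' the higher mean gene density.  Bins with a zero contact marginal are
#' `NA` and excluded from the eigendecomposition.
#'
#' @param mat square symmetric non-negative contact matrix (one
#'   chromosome).
#' @param binsize bin width in bp.
#' @param geneDensity numeric per-bin gene count used for orientation.
#' @param chrom chromosome label carried into the track.
#' @return a [CompartmentTrack-class].  A structureless (near-constant)
#'   matrix yields `eigenvalueFraction` near 0 and a warning.
#' @export
callCompartments <- function(mat, binsize, geneDensity,
                             chrom = "chr1") {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat),
            length(geneDensity) == nrow(mat))
  if (any(mat < 0)) stop("contact matrix must be non-negative")
  if (!isTRUE(all.equal(mat, t(mat), tolerance = 1e-8)))
    stop("contact matrix must be symmetric")
  if (all(mat == 0)) stop("all-zero contact matrix")
  nb <- nrow(mat)
  covered <- rowSums(mat) > 0
  sub <- mat[covered, covered, drop = FALSE]
  m <- nrow(sub)
  # observed/expected by diagonal mean
  d <- abs(row(sub) - col(sub))
  expd <- tapply(sub, d, mean)
  oe <- sub / matrix(as.numeric(expd[as.character(d)]), m, m)
  oe[!is.finite(oe)] <- 0
  cc <- suppressWarnings(cor(oe))
  cc[!is.finite(cc)] <- 0
  eg <- eigen(cc, symmetric = TRUE)
  evFrac <- abs(eg$values[1]) / sum(abs(eg$values))
  if (!is.finite(evFrac)) evFrac <- 0
  pc1sub <- eg$vectors[, 1]
  pc1 <- rep(NA_real_, nb)
  pc1[covered] <- pc1sub
  if (sd(pc1sub) < 1e-10 || evFrac < 2 / m)
    warning("contact matrix has little compartment structure ",
            "(eigenvalue fraction ", sprintf("%.3f", evFrac), ")")
  lab <- rep(NA_character_, nb)
  lab[covered] <- ifelse(pc1sub >= 0, "A", "B")
  # orientation: the gene-dense class is A
  dA <- mean(geneDensity[which(lab == "A")])
  dB <- mean(geneDensity[which(lab == "B")])
  if (!is.na(dA) && !is.na(dB) && dB > dA) {
    lab[covered] <- ifelse(lab[covered] == "A", "B", "A")
    pc1 <- -pc1
  }
  new("CompartmentTrack", chrom = chrom, binSize = as.numeric(binsize),
      labels = factor(lab, levels = c("A", "B")), pc1 = pc1,
      eigenvalueFraction = evFrac)
}

#' Per-gene compartment switch between two states
#'
#' Each gene is assigned the bin containing its TSS; the switch class is
#' `B->A`, `A->B`, `stable`, or `NA` when either track is `NA` at that
#' bin (or the TSS falls outside the binned region).
#'
#' @param trackA,trackB [CompartmentTrack-class] objects with identical
#'   bin size and bin count (state A and state B).
#' @param genes stranded gene `GRanges` with `gene_id` (on the tracks'
#'   chromosome).
#' @param geneSubset optional gene_ids over which to report the `B->A`
#'   fraction.
#' @return list: `switchClass` (named character per gene) and
#'   `fractionBtoA` over the subset (NA-class genes excluded from the
#'   denominator).
#' @export
compartmentSwitch <- function(trackA, trackB, genes, geneSubset = NULL) {
  if (trackA@binSize != trackB@binSize ||
      length(trackA@labels) != length(trackB@labels))
    stop("compartment tracks must share bin size and bin count")
  tss <- start(tssSites(genes))
  bin <- ((tss - 1L) %/% as.integer(trackA@binSize)) + 1L
  onChrom <- as.character(seqnames(genes)) == trackA@chrom &
    bin >= 1L & bin <= length(trackA@labels)
  la <- rep(NA_character_, length(genes))
  lb <- la
  la[onChrom] <- as.character(trackA@labels[bin[onChrom]])
  lb[onChrom] <- as.character(trackB@labels[bin[onChrom]])
  cls <- ifelse(is.na(la) | is.na(lb), NA_character_,
         ifelse(la == lb, "stable",
         ifelse(la == "B", "B->A", "A->B")))
  names(cls) <- mcols(genes)$gene_id
  subset <- if (is.null(geneSubset)) names(cls) else geneSubset
  sub <- cls[subset]
  list(switchClass = cls,
       fractionBtoA = mean(sub[!is.na(sub)] == "B->A"))
}

#' Synthesize a binned contact matrix from loops
#'
#' Desk-scale stand-in for a Hi-C map: each loop adds its PET count to the
#' cell joining its two anchor bins (symmetrically), plus its count on each
#' anchor's diagonal.
#'
#' @param loops a [LoopSet-class] on one chromosome.
#' @param binsize bin width in bp.
#' @param nBins number of bins (chromosome length / binsize).
#' @return symmetric numeric matrix `nBins x nBins`.
#' @export
contactMatrixFromLoops <- function(loops, binsize, nBins) {
  mat <- matrix(0, nBins, nBins)
  if (length(loops) == 0) return(mat)
  mid <- function(gr) (start(gr) + end(gr)) / 2
  b1 <- pmin(nBins, pmax(1, ceiling(mid(anchorOne(loops)) / binsize)))
  b2 <- pmin(nBins, pmax(1, ceiling(mid(anchorTwo(loops)) / binsize)))
  for (i in seq_along(b1)) {
    pc <- petCount(loops)[i]
    mat[b1[i], b2[i]] <- mat[b1[i], b2[i]] + pc
    if (b1[i] != b2[i]) mat[b2[i], b1[i]] <- mat[b2[i], b1[i]] + pc
    mat[b1[i], b1[i]] <- mat[b1[i], b1[i]] + pc
    mat[b2[i], b2[i]] <- mat[b2[i], b2[i]] + pc
  }
  mat
}
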