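#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- queryHits subjectHits metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   strand<- findOverlaps countOverlaps reduce resize
NULL

#' LoopSet: paired-anchor chromatin contacts
#'
#' A `LoopSet` holds intra-chromosomal chromatin loops as two parallel
#' [GenomicRanges::GRanges] of anchors, one PET (paired-end tag) count and
#' one mediating factor (`"RNAPII"` or `"CTCF"`) per loop.  Loops are stored
#' in canonical orientation: on each row, `anchorOne` starts at or before
#' `anchorTwo`.
#'
#' @slot anchorOne,anchorTwo parallel `GRanges` of loop anchors.
#' @slot petCount integer vector, one count (>= 1) per loop.
#' @slot loopFactor character vector, mediating protein factor per loop.
#'
#' @seealso [LoopSet()] for construction, [readBedpe()] for file input,
#'   [clusterDomains()] for interaction-domain calling.
#' @export
setClass("LoopSet",
  representation(
    anchorOne  = "GRanges",
    anchorTwo  = "GRanges",
    petCount   = "integer",
    loopFactor = "character"
  )
)

setValidity("LoopSet", function(object) {
  msg <- character()
  n <- length(object@anchorOne)
  if (length(object@anchorTwo) != n)
    msg <- c(msg, "anchorOne and anchorTwo must have equal length")
  if (length(object@petCount) != n || length(object@loopFactor) != n)
    msg <- c(msg, "petCount and loopFactor must parallel the anchors")
  if (n > 0 && length(object@anchorTwo) == n) {
    if (!all(as.character(seqnames(object@anchorOne)) ==
             as.character(seqnames(object@anchorTwo))))
      msg <- c(msg, "loops must be intra-chromosomal")
    if (any(start(object@anchorOne) > start(object@anchorTwo)))
      msg <- c(msg, "anchors not in canonical order (anchorOne must start first)")
    if (any(object@petCount < 1L))
      msg <- c(msg, "petCount must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LoopSet
#'
#' Anchors are canonically ordered per loop (left-most anchor first) before
#' validation, so the constructor is idempotent: constructing from an already
#' canonical set returns the identical object.
#'
#' @param anchorOne,anchorTwo `GRanges` of equal length; each row is one loop.
#' @param petCount integer PET support per loop (recycled if length 1).
#' @param loopFactor mediating factor per loop, e.g. `"RNAPII"` (recycled).
#' @return A [LoopSet-class] object.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9001, 9500))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 2000))
#' LoopSet(a, b, petCount = 4L)   # anchors swapped into canonical order
#' @export
LoopSet <- function(anchorOne, anchorTwo,
                    petCount = 1L, loopFactor = "RNAPII") {
  n <- length(anchorOne)
  petCount   <- rep(as.integer(petCount), length.out = n)
  loopFactor <- rep(as.character(loopFactor), length.out = n)
  if (n > 0) {
    flip <- start(anchorTwo) < start(anchorOne)
    if (any(flip)) {
      tmp <- anchorOne[flip]
      anchorOne[flip] <- anchorTwo[flip]
      anchorTwo[flip] <- tmp
    }
  }
  new("LoopSet", anchorOne = anchorOne, anchorTwo = anchorTwo,
      petCount = petCount, loopFactor = loopFactor)
}

#' Enhancer-promoter interaction network
#'
#' Nodes are regulatory elements (distal enhancers `E`, strong promoters `P`,
#' enhancer-like promoters `Ep`); edges are loop-backed interactions typed by
#' the annotations of their two anchors (`E-P`, `P-P`, `Ep-P`, `E-E`, ...).
#'
#' @slot nodes `DataFrame` with columns `node`, `kind` (`E`/`P`/`Ep`),
#'   `gene_id` (NA for distal enhancers).
#' @slot edges `DataFrame` with columns `node_a`, `node_b`, `type`,
#'   `n_loops`, and a `loops` IntegerList of supporting loop indices.
#' @export
setClass("EPNetwork",
  representation(nodes = "DataFrame", edges = "DataFrame")
)

setValidity("EPNetwork", function(object) {
  msg <- character()
  if (!all(c("node", "kind", "gene_id") %in% colnames(object@nodes)))
    msg <- c(msg, "nodes must have columns node, kind, gene_id")
  if (!all(c("node_a", "node_b", "type", "n_loops") %in% colnames(object@edges)))
    msg <- c(msg, "edges must have columns node_a, node_b, type, n_loops")
  if (nrow(object@edges) > 0 && any(object@edges$n_loops < 1L))
    msg <- c(msg, "every edge must be backed by at least one loop")
  if (length(msg)) msg else TRUE
})

#' A/B compartment track
#'
#' Per-bin compartment labels on one chromosome, derived from the leading
#' eigenvector of the observed/expected correlation matrix of a binned
#' contact map.  Orientation is fixed so that the `A` label has the higher
#' mean gene density.
#'
#' @slot chrom chromosome name.
#' @slot binSize bin width in base pairs.
#' @slot labels factor of per-bin labels, levels `A`, `B` (NA for bins with
#'   zero contact marginal).
#' @slot pc1 numeric leading-eigenvector loading per bin.
#' @slot eigenvalueFraction fraction of total variance carried by the
#'   leading eigenvalue (a structure-strength diagnostic).
#' @export
setClass("CompartmentTrack",
  representation(
    chrom              = "character",
    binSize            = "numeric",
    labels             = "factor",
    pc1                = "numeric",
    eigenvalueFraction = "numeric"
  )
)

setValidity("CompartmentTrack", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@pc1))
    msg <- c(msg, "labels and pc1 must have one entry per bin")
  if (!all(levels(object@labels) == c("A", "B")))
    msg <- c(msg, "label levels must be exactly A, B")
  if (object@binSize <= 0)
    msg <- c(msg, "binSize must be positive")
  if (length(msg)) msg else TRUE
})
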