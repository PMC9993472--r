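#' Interval overlap in BED (0-based, half-open) coordinates
#'
#' The whole package stores ranges internally as `GRanges` (1-based, closed)
#' and converts at file boundaries; this helper exposes the raw half-open
#' overlap test on BED-style coordinates for callers working outside
#' `GRanges`.  Two records overlap iff they share a chromosome and
#' `startA < endB && startB < endA`.
#'
#' @param chromA,startA,endA,chromB,startB,endB vectorised BED coordinates.
#' @return logical vector.
#' @examples
#' bedOverlaps("chr1", 0, 10, "chr1", 5, 15)    # TRUE
#' bedOverlaps("chr1", 0, 10, "chr1", 10, 20)   # FALSE: half-open adjacency
#' bedOverlaps("chr1", 0, 10, "chr2", 0, 10)    # FALSE: different chromosome
#' @export
bedOverlaps <- function(chromA, startA, endA, chromB, startB, endB) {
  chromA == chromB & startA < endB & startB < endA
}

#' Convert between BED coordinates and GRanges
#'
#' `bedToGRanges()` maps 0-based half-open records to 1-based closed
#' `GRanges`; `grangesToBed()` is its inverse.  Both are exact round trips.
#'
#' @param chrom,start,end BED-style coordinate vectors.
#' @param strand optional strand vector (`+`, `-`, `*`).
#' @return `bedToGRanges()`: a `GRanges`; `grangesToBed()`: a data.frame
#'   with columns `chrom`, `start`, `end`.
#' @export
bedToGRanges <- function(chrom, start, end, strand = "*") {
  n <- max(length(chrom), length(start))
  if (n == 0) return(GRanges())
  if (any(start < 0) || any(end <= start))
    stop("invalid BED coordinates: need 0 <= start < end")
  GRanges(rep(chrom, length.out = n), IRanges(start + 1L, end),
          strand = rep(strand, length.out = n))
}

#' @rdname bedToGRanges
#' @param gr a `GRanges`
#' @export
grangesToBed <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)),
             start = start(gr) - 1L, end = end(gr),
             stringsAsFactors = FALSE)
}

#' TSS of gene models
#'
#' Returns width-1 ranges at each gene's transcription start site: the
#' left-most base for `+` genes and the right-most base for `-` genes
#' (the BED `end - 1` convention).
#'
#' @param genes a stranded `GRanges` of gene bodies with `mcols(genes)$gene_id`.
#' @return a `GRanges` of width-1 TSS positions (strand preserved).
#' @export
tssSites <- function(genes) {
  if (any(!as.character(strand(genes)) %in% c("+", "-")))
    stop("gene models must be stranded (+/-)")
  resize(genes, width = 1L, fix = "start")
}

#' Promoter window around the TSS
#'
#' The symmetric window of `flank` bp on each side of the TSS (width
#' `2*flank + 1`), clamped at the chromosome origin.  This is the anchor
#' region for all promoter-centred logic (RNAPII occupancy, promoter
#' strength, differential CTCF binding), with the conventional default of
#' +/- 2 kb.
#'
#' @param genes stranded gene-body `GRanges` (see [tssSites()]).
#' @param flank half-width in bp, > 0.
#' @return `GRanges` of promoter windows, parallel to `genes`, strand
#'   dropped, metadata columns preserved.
#' @export
tssWindow <- function(genes, flank = 2000L) {
  stopifnot(flank > 0)
  tss <- start(tssSites(genes))
  win <- GRanges(seqnames(genes),
                 IRanges(pmax(1L, as.integer(tss - flank)),
                         as.integer(tss + flank)))
  mcols(win) <- mcols(genes)
  win
}

#' Mean signal over windows from a piecewise-constant track
#'
#' Length-weighted mean of a bedGraph-style track over each query window.
#' Bases not covered by the track contribute 0 (the bedGraph sparsity
#' convention), so a window entirely outside the covered region scores 0.
#'
#' @param track `GRanges` with a numeric `score` column (non-overlapping
#'   intervals, as read by [readBedGraph()]).
#' @param windows query `GRanges`.
#' @return numeric vector of mean signal, one value per window.
#' @examples
#' trk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100), score = 2)
#' win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))
#' signalInWindow(trk, win)  # half covered at 2.0 -> 1.0
#' @export
signalInWindow <- function(track, windows) {
  if (!"score" %in% colnames(mcols(track)))
    stop("track must carry a 'score' metadata column")
  # chromosomes absent from the track legitimately score 0 (zero-fill)
  hits <- suppressWarnings(findOverlaps(windows, track))
  if (length(hits) == 0) return(numeric(length(windows)))
  q <- queryHits(hits); s <- subjectHits(hits)
  ovl <- pmin(end(windows)[q], end(track)[s]) -
         pmax(start(windows)[q], start(track)[s]) + 1L
  contrib <- ovl * mcols(track)$score[s]
  num <- tapply(contrib, q, sum)
  out <- numeric(length(windows))
  out[as.integer(names(num))] <- as.numeric(num)
  out / width(windows)
}
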