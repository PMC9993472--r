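#' @describeIn LoopSet-class number of loops
#' @param x a `LoopSet`
#' @export
setMethod("length", "LoopSet", function(x) length(x@anchorOne))

#' Accessors for LoopSet slots
#'
#' `anchorOne()`/`anchorTwo()` return the left and right anchor `GRanges`,
#' `petCount()` the PET support, `loopFactor()` the mediating factor.
#'
#' @param x a [LoopSet-class]
#' @return the corresponding slot.
#' @name LoopSet-accessors
NULL

#' @rdname LoopSet-accessors
#' @export
anchorOne <- function(x) x@anchorOne

#' @rdname LoopSet-accessors
#' @export
anchorTwo <- function(x) x@anchorTwo

#' @rdname LoopSet-accessors
#' @export
petCount <- function(x) x@petCount

#' @rdname LoopSet-accessors
#' @export
loopFactor <- function(x) x@loopFactor

#' @describeIn LoopSet-class subset loops
#' @param i index vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "LoopSet", function(x, i, j, ..., drop = TRUE) {
  new("LoopSet",
      anchorOne = x@anchorOne[i], anchorTwo = x@anchorTwo[i],
      petCount = x@petCount[i], loopFactor = x@loopFactor[i])
})

#' @describeIn LoopSet-class display a summary
#' @param object a `LoopSet`
#' @export
setMethod("show", "LoopSet", function(object) {
  n <- length(object)
  facs <- paste(unique(object@loopFactor), collapse = ",")
  cat("LoopSet with", n, "loops",
      if (n) paste0("(factor: ", facs, ")") else "", "\n")
  if (n) {
    k <- min(n, 5L)
    df <- data.frame(
      chrom = as.character(seqnames(object@anchorOne))[seq_len(k)],
      anchor1 = sprintf("[%d,%d]", start(object@anchorOne)[seq_len(k)],
                        end(object@anchorOne)[seq_len(k)]),
      anchor2 = sprintf("[%d,%d]", start(object@anchorTwo)[seq_len(k)],
                        end(object@anchorTwo)[seq_len(k)]),
      pet = object@petCount[seq_len(k)])
    print(df)
    if (n > k) cat("...", n - k, "more\n")
  }
  invisible(object)
})

#' Concatenate LoopSets
#'
#' @param ... `LoopSet` objects with compatible anchors.
#' @return a single `LoopSet`.
#' @export
concatLoops <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, length, 1L) > 0]
  if (!length(parts)) return(LoopSet(GRanges(), GRanges()))
  new("LoopSet",
      anchorOne  = do.call(c, lapply(parts, anchorOne)),
      anchorTwo  = do.call(c, lapply(parts, anchorTwo)),
      petCount   = unlist(lapply(parts, petCount), use.names = FALSE),
      loopFactor = unlist(lapply(parts, loopFactor), use.names = FALSE))
}

#' @describeIn EPNetwork-class display a summary
#' @param object an `EPNetwork`
#' @export
setMethod("show", "EPNetwork", function(object) {
  tt <- table(object@edges$type)
  cat("EPNetwork:", nrow(object@nodes), "nodes,", nrow(object@edges),
      "edges\n")
  if (length(tt))
    cat("  edge types:",
        paste(sprintf("%s=%d", names(tt), as.integer(tt)), collapse = " "),
        "\n")
  invisible(object)
})

#' Accessors for EPNetwork
#' @param x an [EPNetwork-class]
#' @return `networkNodes()`/`networkEdges()` return the node and edge tables.
#' @name EPNetwork-accessors
NULL

#' @rdname EPNetwork-accessors
#' @export
networkNodes <- function(x) x@nodes

#' @rdname EPNetwork-accessors
#' @export
networkEdges <- function(x) x@edges

#' @describeIn CompartmentTrack-class display a summary
#' @param object a `CompartmentTrack`
#' @export
setMethod("show", "CompartmentTrack", function(object) {
  tt <- table(object@labels, useNA = "ifany")
  cat("CompartmentTrack on", object@chrom, "|", length(object@labels),
      "bins of", object@binSize, "bp | eigenvalue fraction",
      sprintf("%.3f", object@eigenvalueFraction), "\n")
  print(tt)
  invisible(object)
})

#' Accessors for CompartmentTrack
#' @param x a [CompartmentTrack-class]
#' @name CompartmentTrack-accessors
#' @return `compartmentLabels()` the per-bin factor; `binSize()` the bin
#'   width; `eigenvalueFraction()` the leading-eigenvalue variance fraction.
NULL

#' @rdname CompartmentTrack-accessors
#' @export
compartmentLabels <- function(x) x@labels

#' @rdname CompartmentTrack-accessors
#' @export
binSize <- function(x) x@binSize

#' @rdname CompartmentTrack-accessors
#' @export
eigenvalueFraction <- function(x) x@eigenvalueFraction
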