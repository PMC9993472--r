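suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# gene models from BED-style coordinate triplets
mkGenes <- function(chrom, start, end, strand, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("g%d", seq_along(start))
  gr <- bedToGRanges(chrom, start, end, strand = strand)
  mcols(gr) <- DataFrame(gene_id = ids)
  names(gr) <- ids
  gr
}

mkPeakSet <- function(chrom, start, end, intensity = 1, factorName = "RNAPII") {
  gr <- bedToGRanges(chrom, start, end)
  mcols(gr) <- DataFrame(name = sprintf("pk%d", seq_along(gr)),
                         intensity = rep(intensity, length.out = length(gr)),
                         factor = rep(factorName, length(gr)))
  gr
}

mkLoops <- function(chrom, s1, e1, s2, e2, pet = 1L, factorName = "RNAPII") {
  LoopSet(bedToGRanges(chrom, s1, e1), bedToGRanges(chrom, s2, e2),
          petCount = pet, loopFactor = factorName)
}

mkTrack <- function(chrom, start, end, score) {
  gr <- bedToGRanges(chrom, start, end)
  mcols(gr) <- DataFrame(score = score)
  gr
}

mkCpgs <- function(chrom, pos, meth, total) {
  gr <- bedToGRanges(chrom, pos, pos + 1)
  mcols(gr) <- DataFrame(count_meth = as.integer(meth),
                         count_total = as.integer(total),
                         beta = meth / total)
  gr
}

# memoised synthetic datasets so several test files can share one
.dsCache <- new.env(parent = emptyenv())
cachedDataset <- function(tag, config) {
  if (is.null(.dsCache[[tag]]))
    .dsCache[[tag]] <- generateDataset(config)
  .dsCache[[tag]]
}

zeroNoiseConfig <- function(seed = 11L)
  synthConfig(seed = seed, loopNoiseRate = 0, exprNoiseSd = 0,
              methylNoise = FALSE)

# checkerboard contact-matrix fixture with planted compartment classes
blockMatrix <- function(classes, within = 8, between = 2, noiseSd = 0,
                        seed = 1) {
  set.seed(seed)
  n <- length(classes)
  m <- ifelse(outer(classes, classes, `==`), within, between)
  nz <- matrix(rnorm(n * n, 0, noiseSd), n)
  m <- pmax(m + (nz + t(nz)) / 2, 0)
  diag(m) <- diag(m) + within
  m
}

# state-specific E-P network built from a bundle, as the pipeline would
buildStateNetwork <- function(bundle, state) {
  loops <- bundle$loops[[state]]$RNAPII
  enh <- defineEnhancers(bundle$peaks[[state]]$H3K4me1,
                         bundle$peaks[[state]]$H3K27ac,
                         bundle$peaks[[state]]$H3K27me3,
                         bundle$genes, loops)
  strengths <- promoterStrength(bundle$genes,
                                bundle$signal[[state]]$H3K4me3,
                                bundle$signal[[state]]$H3K4me1)
  a1 <- annotateAnchors(anchorOne(loops), bundle$genes, strengths, enh)
  a2 <- annotateAnchors(anchorTwo(loops), bundle$genes, strengths, enh)
  list(network = buildEPNetwork(loops, a1, a2), enhancers = enh,
       strengths = strengths, loops = loops)
}
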