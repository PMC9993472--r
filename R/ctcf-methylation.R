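#' Differential CTCF binding near TSSs (MA classification)
#'
#' Sites are the merged footprints of the two states' CTCF peaks restricted
#' to the TSS windows of the supplied genes.  Per site and state, the
#' intensity is the maximum overlapping peak intensity (0 when the state
#' has no peak).  With `M = log2((a + eps)/(b + eps))` and
#' `A = 0.5 * log2((a + eps)(b + eps))`, a site is `up_a` when
#' `M >= mMin`, `up_b` when `M <= -mMin`, else `common`.
#'
#' @param peaksA,peaksB CTCF peak `GRanges` for states A and B, with
#'   `intensity` on a comparable (pre-normalised) scale.
#' @param genes stranded gene `GRanges` restricting the analysis to
#'   promoter-proximal sites.
#' @param flank TSS-window half-width in bp.
#' @param mMin minimum |M| for a differential call (1 = 2-fold).
#' @param eps pseudo-intensity.
#' @param aggregate how to summarise several overlapping peaks: `"max"`
#'   (default), `"sum"`, or `"mean"`.
#' @return `GRanges` of sites with metadata `intensity_a`, `intensity_b`,
#'   `M`, `A`, `call`, `nearest_gene`.  Empty merged set returns an empty
#'   `GRanges` with a warning.
#' @export
differentialBinding <- function(peaksA, peaksB, genes, flank = 2000L,
                                mMin = 1, eps = 0.1,
                                aggregate = c("max", "sum", "mean")) {
  aggregate <- match.arg(aggregate)
  win <- tssWindow(genes, flank)
  merged <- reduce(c(GenomicRanges::granges(peaksA),
                     GenomicRanges::granges(peaksB)))
  sites <- merged[countOverlaps(merged, win) > 0]
  if (length(sites) == 0) {
    warning("no CTCF sites near the supplied TSSs")
    mcols(sites) <- DataFrame(intensity_a = numeric(), intensity_b = numeric(),
                              M = numeric(), A = numeric(), call = character(),
                              nearest_gene = character())
    return(sites)
  }
  agg <- switch(aggregate, max = max, sum = sum, mean = mean)
  siteIntensity <- function(peaks) {
    hits <- findOverlaps(sites, peaks)
    v <- numeric(length(sites))
    if (length(hits)) {
      byPk <- tapply(mcols(peaks)$intensity[subjectHits(hits)],
                     queryHits(hits), agg)
      v[as.integer(names(byPk))] <- as.numeric(byPk)
    }
    v
  }
  ia <- siteIntensity(peaksA); ib <- siteIntensity(peaksB)
  M <- log2((ia + eps) / (ib + eps))
  A <- 0.5 * log2((ia + eps) * (ib + eps))
  call <- ifelse(M >= mMin, "up_a", ifelse(M <= -mMin, "up_b", "common"))
  tss <- tssSites(genes); strand(tss) <- "*"
  nearest <- GenomicRanges::nearest(sites, tss)
  mcols(sites) <- DataFrame(intensity_a = ia, intensity_b = ib, M = M, A = A,
                            call = call,
                            nearest_gene = mcols(genes)$gene_id[nearest])
  sites
}

#' CTCF binding breadth across a cell panel
#'
#' Per site, the number of panel cells whose peak set overlaps it.  When
#' two site groups are given, their breadth distributions are compared
#' with [ksTwoSample()].
#'
#' @param sites site `GRanges`.
#' @param panel named list of peak `GRanges`, one per panel cell (>= 2).
#' @param groups optional factor/character over `sites` with exactly two
#'   levels defining the groups to compare.
#' @return list: `breadth` (integer per site) and, with `groups`, `ks`
#'   (list with `D`, `p.value`).
#' @export
bindingBreadth <- function(sites, panel, groups = NULL) {
  stopifnot(length(panel) >= 2)
  breadth <- Reduce(`+`, lapply(panel, function(pk)
    as.integer(countOverlaps(sites, pk) > 0)))
  out <- list(breadth = breadth)
  if (!is.null(groups)) {
    groups <- as.character(groups)
    lv <- unique(groups)
    if (length(lv) != 2) stop("groups must have exactly two levels")
    out$ks <- ksTwoSample(breadth[groups == lv[1]], breadth[groups == lv[2]])
  }
  out
}

#' Coverage-weighted region methylation
#'
#' Per region, the coverage-weighted mean beta over CpGs passing the
#' coverage filter inside it: `sum(count_meth) / sum(count_total)`.
#' Regions with fewer than `minCpgs` surviving CpGs are `NA`.  Intended
#' for CTCF peak footprints (~500 bp) and motif windows (219 bp).
#'
#' @param cpgs width-1 methylation `GRanges` (see
#'   [readMethylationTable()]).
#' @param regions query `GRanges`.
#' @param levelKind free-text label stored with the result (e.g.
#'   `"peak_500bp"`, `"motif_219bp"`).
#' @param minCov minimum per-CpG `count_total`.
#' @param minCpgs minimum surviving CpGs per region.
#' @return data.frame `region` (chrom:start-end), `level_kind`, `n_cpgs`,
#'   `beta_mean`.
#' @export
methylationInRegions <- function(cpgs, regions, levelKind = "region",
                                 minCov = 5L, minCpgs = 1L) {
  cov <- cpgs[mcols(cpgs)$count_total >= minCov]
  hits <- findOverlaps(regions, cov)
  nC <- integer(length(regions)); meth <- numeric(length(regions))
  tot <- numeric(length(regions))
  if (length(hits)) {
    q <- queryHits(hits); s <- subjectHits(hits)
    nC <- as.integer(table(factor(q, seq_along(regions))))
    mm <- tapply(mcols(cov)$count_meth[s], q, sum)
    tt <- tapply(mcols(cov)$count_total[s], q, sum)
    meth[as.integer(names(mm))] <- mm
    tot[as.integer(names(tt))] <- tt
  }
  beta <- ifelse(nC >= minCpgs & tot > 0, meth / tot, NA_real_)
  data.frame(
    region = sprintf("%s:%d-%d", as.character(seqnames(regions)),
                     start(regions) - 1L, end(regions)),
    level_kind = levelKind, n_cpgs = nC, beta_mean = beta,
    stringsAsFactors = FALSE)
}

#' Compare methylation between two region groups
#'
#' Rank-sum test on the non-NA `beta_mean` values of two
#' [methylationInRegions()] tables (e.g. bound-state vs unbound-state
#' motif windows).
#'
#' @param groupA,groupB region-methylation data.frames.
#' @return list `median_a`, `median_b`, `p.value` (NA with a message if
#'   either group has < 2 usable values).
#' @export
compareRegionMethylation <- function(groupA, groupB) {
  a <- groupA$beta_mean[!is.na(groupA$beta_mean)]
  b <- groupB$beta_mean[!is.na(groupB$beta_mean)]
  if (length(a) < 2 || length(b) < 2) {
    message("compareRegionMethylation: insufficient non-NA values")
    return(list(median_a = median(a), median_b = median(b),
                p.value = NA_real_))
  }
  list(median_a = median(a), median_b = median(b),
       p.value = wilcoxonRankSum(a, b)$p.value)
}

#' Call differentially methylated cytosines (DMCs)
#'
#' Positions covered at `minCov` in both states are tested with Fisher's
#' exact test on the `[[meth_a, unmeth_a], [meth_b, unmeth_b]]` count
#' table; Benjamini-Hochberg correction is applied across all tested
#' positions.  A DMC requires `q <= qMax` and `|beta_a - beta_b| >=
#' deltaMin`.
#'
#' @param cpgsA,cpgsB methylation `GRanges` for the two states, matched by
#'   (chrom, pos).
#' @param minCov minimum coverage in each state.
#' @param deltaMin minimum |beta difference|.
#' @param qMax maximum BH-adjusted p.
#' @return data.frame of tested positions: `chrom`, `pos` (0-based),
#'   `beta_a`, `beta_b`, `delta`, `p.value`, `q.value`, `is_dmc`.  No
#'   shared covered position returns an empty frame with a warning.
#' @export
callDmc <- function(cpgsA, cpgsB, minCov = 5L, deltaMin = 0.25,
                    qMax = 0.05) {
  keyA <- paste(seqnames(cpgsA), start(cpgsA))
  keyB <- paste(seqnames(cpgsB), start(cpgsB))
  idx <- match(keyA, keyB)
  shared <- which(!is.na(idx))
  a <- cpgsA[shared]; b <- cpgsB[idx[shared]]
  covOK <- mcols(a)$count_total >= minCov & mcols(b)$count_total >= minCov
  a <- a[covOK]; b <- b[covOK]
  if (length(a) == 0) {
    warning("no shared positions at the required coverage")
    return(data.frame(chrom = character(), pos = integer(),
                      beta_a = numeric(), beta_b = numeric(),
                      delta = numeric(), p.value = numeric(),
                      q.value = numeric(), is_dmc = logical()))
  }
  ma <- mcols(a)$count_meth; ta <- mcols(a)$count_total
  mb <- mcols(b)$count_meth; tb <- mcols(b)$count_total
  p <- vapply(seq_along(a), function(i)
    fisherExact2x2(ma[i], ta[i] - ma[i], mb[i], tb[i] - mb[i]),
    numeric(1))
  q <- p.adjust(p, method = "BH")
  betaA <- ma / ta; betaB <- mb / tb
  delta <- betaA - betaB
  data.frame(chrom = as.character(seqnames(a)), pos = start(a) - 1L,
             beta_a = betaA, beta_b = betaB, delta = delta,
             p.value = p, q.value = q,
             is_dmc = q <= qMax & abs(delta) >= deltaMin,
             stringsAsFactors = FALSE)
}
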