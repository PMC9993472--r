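#' Configuration for the synthetic two-state dataset
#'
#' Builds the parameter set for [generateDataset()].  The defaults define
#' the package's reference study conditions: 200 genes on 2 chromosomes,
#' 50 genes specific to each state with a 16-fold planted expression
#' ratio, 1-3 enhancers per specific gene wired by RNAPII loops,
#' promoter-promoter loops between planted co-expressed gene pairs,
#' state-specific CTCF sites whose 219-bp motif windows are hypomethylated
#' when bound (beta 0.1) and hypermethylated when not (beta 0.9), GWAS-style
#' lead SNPs inside enhancers with LD satellites decaying in r-squared,
#' a 20-cell expression panel and a 29-cell CTCF occupancy panel.
#'
#' @param seed master RNG seed; every file type draws from its own
#'   sub-stream so adding one never perturbs the others.
#' @param nChroms,chromLength genome shape; each chromosome hosts
#'   `nGenes/nChroms` gene territories in its first ~62\% and a gene-free
#'   tail (the planted B compartment).
#' @param nGenes,nSpecificA,nSpecificB gene counts.
#' @param foldSpecific planted expression ratio (> 1) of specific genes
#'   between their bound and unbound state, before noise.
#' @param enhancerCountProbs probabilities for 1, 2 and 3 enhancers per
#'   specific gene.
#' @param loopNoiseRate fraction (of planted loops) of spurious random
#'   loops added per state.
#' @param exprNoiseSd multiplicative log-normal expression noise, sd in
#'   log2 units (0 = noiseless).
#' @param methylNoise draw methylation counts binomially around the
#'   planted beta (FALSE = deterministic rounded counts).
#' @param nPanelCells expression-panel size (cells/tissues).
#' @param nCtcfPanelCells CTCF occupancy panel size.
#' @param nPPPairsPerState planted co-expressed promoter-promoter pairs
#'   per state.
#' @param epFraction fraction of specific genes given an enhancer-like
#'   promoter (H3K4me3/H3K4me1 ratio < 1) in their bound state.
#' @param methylInverseCoupling couple CTCF binding to motif
#'   hypomethylation.
#' @param ldBlockSize LD block extent in bp around each lead SNP.
#' @param r2Decay per-kb exponential decay rate of satellite r-squared.
#' @param dmcDelta planted beta difference at differential CTCF motifs.
#' @return a `SynthConfig` list (class `"SynthConfig"`).
#' @export
synthConfig <- function(seed = 1L, nChroms = 2L, chromLength = 2.4e7,
                        nGenes = 200L, nSpecificA = 50L, nSpecificB = 50L,
                        foldSpecific = 16,
                        enhancerCountProbs = c(0.35, 0.35, 0.30),
                        loopNoiseRate = 0.1, exprNoiseSd = 0.25,
                        methylNoise = TRUE,
                        nPanelCells = 20L, nCtcfPanelCells = 29L,
                        nPPPairsPerState = 10L, epFraction = 0.2,
                        methylInverseCoupling = TRUE,
                        ldBlockSize = 50000L, r2Decay = 0.1,
                        dmcDelta = 0.8) {
  cfg <- list(seed = as.integer(seed), nChroms = as.integer(nChroms),
              chromLength = chromLength, nGenes = as.integer(nGenes),
              nSpecificA = as.integer(nSpecificA),
              nSpecificB = as.integer(nSpecificB),
              foldSpecific = foldSpecific,
              enhancerCountProbs = enhancerCountProbs,
              loopNoiseRate = loopNoiseRate, exprNoiseSd = exprNoiseSd,
              methylNoise = methylNoise,
              nPanelCells = as.integer(nPanelCells),
              nCtcfPanelCells = as.integer(nCtcfPanelCells),
              nPPPairsPerState = as.integer(nPPPairsPerState),
              epFraction = epFraction,
              methylInverseCoupling = methylInverseCoupling,
              ldBlockSize = as.integer(ldBlockSize), r2Decay = r2Decay,
              dmcDelta = dmcDelta)
  stopifnot(cfg$nGenes >= cfg$nSpecificA + cfg$nSpecificB,
            cfg$foldSpecific > 1,
            cfg$loopNoiseRate >= 0, cfg$loopNoiseRate <= 1,
            cfg$exprNoiseSd >= 0, cfg$dmcDelta >= 0, cfg$dmcDelta <= 1,
            cfg$epFraction >= 0, cfg$epFraction <= 1,
            abs(sum(cfg$enhancerCountProbs) - 1) < 1e-8)
  class(cfg) <- "SynthConfig"
  cfg
}

# Independent RNG sub-stream per file type, derived from the master seed.
subSeed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + k * 9973) %% 2147483647)
}

withStream <- function(seed, k, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(subSeed(seed, k))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

#' Generate the synthetic two-state dataset with planted ground truth
#'
#' Deterministic given `config$seed`: two calls with one config return
#' identical bundles.  See [synthConfig()] for what is planted.  The
#' returned truth tables list every planted entity; every planted entity
#' is realised in the bundle.
#'
#' @param config a [synthConfig()] object.
#' @return list with elements `bundle` (in-memory data: `genes`, `expr` +
#'   `states`, `panel`, per-state `peaks`/`signal`/`loops`/`methylation`,
#'   `snps`, `ctcfPanel`, `contact`) and `truth` (planted specific genes,
#'   enhancer-gene links, PP pairs, domain groups, promoter classes,
#'   differential CTCF sites with motif windows, DMCs, compartment
#'   labels, trait SNPs).
#' @export
generateDataset <- function(config = synthConfig()) {
  stopifnot(inherits(config, "SynthConfig"))
  cf <- config
  genesPerChrom <- ceiling(cf$nGenes / cf$nChroms)
  territory <- floor(cf$chromLength * 0.625 / genesPerChrom)
  if (territory < 70000)
    stop("planted entities exceed chromosome capacity; increase chromLength ",
         "(need >= ", ceiling(70000 * genesPerChrom / 0.625), " bp)")
  chroms <- paste0("chr", seq_len(cf$nChroms))
  geneRegionEnd <- genesPerChrom * territory
  # all generated ranges share one seqlevel set so they combine cleanly
  GR <- function(ch, r, ...) GRanges(factor(ch, levels = chroms), r, ...)

  ## ---- layout stream: genes, roles, enhancers, element structure ----
  lay <- withStream(cf$seed, 1L, {
    i <- seq_len(cf$nGenes)
    chromIdx <- (i - 1L) %/% genesPerChrom + 1L
    slot <- (i - 1L) %% genesPerChrom + 1L
    tss <- (slot - 1L) * territory + 50001L + sample(0:2000, cf$nGenes,
                                                     replace = TRUE)
    role <- rep("shared", cf$nGenes)
    role[seq_len(cf$nSpecificA)] <- "a_specific"
    if (cf$nSpecificB > 0)
      role[cf$nSpecificA + seq_len(cf$nSpecificB)] <- "b_specific"
    nonspec <- which(role == "shared")
    role[nonspec[seq_along(nonspec) %% 4L == 0L]] <- "low"
    spec <- role %in% c("a_specific", "b_specific")
    ep <- rep(FALSE, cf$nGenes)
    si <- which(spec)
    ep[si[seq_along(si) %% round(1 / max(cf$epFraction, 1e-9)) == 0L]] <-
      cf$epFraction > 0
    nEnh <- integer(cf$nGenes)
    nEnh[spec] <- sample(1:3, sum(spec), replace = TRUE,
                         prob = cf$enhancerCountProbs)
    enhJit <- sample(0:1000, 3 * cf$nGenes, replace = TRUE)
    enhState <- sample(c("active", "intermediate", "poised"),
                       3 * cf$nGenes, replace = TRUE,
                       prob = c(0.7, 0.2, 0.1))
    sharedLevel <- 2^runif(cf$nGenes, 1, 5)
    list(chromIdx = chromIdx, tss = tss, role = role, ep = ep, nEnh = nEnh,
         enhJit = enhJit, enhState = enhState, sharedLevel = sharedLevel)
  })
  gi <- data.frame(
    gene_id = sprintf("G%04d", seq_len(cf$nGenes)),
    chrom = chroms[lay$chromIdx], tss = lay$tss,
    strand = ifelse(seq_len(cf$nGenes) %% 2L == 1L, "+", "-"),
    role = lay$role, ep = lay$ep, nEnh = lay$nEnh,
    sharedLevel = lay$sharedLevel, stringsAsFactors = FALSE)
  gi$boundState <- ifelse(gi$role == "a_specific", "A",
                   ifelse(gi$role == "b_specific", "B", NA))

  genes <- GR(gi$chrom,
                   IRanges(ifelse(gi$strand == "+", gi$tss, gi$tss - 9999L),
                           ifelse(gi$strand == "+", gi$tss + 9999L, gi$tss)),
                   strand = gi$strand)
  mcols(genes) <- DataFrame(gene_id = gi$gene_id)
  names(genes) <- gi$gene_id

  # enhancers of specific genes: 1 kb elements 15-52 kb downstream of TSS
  enhRows <- do.call(rbind, lapply(which(!is.na(gi$boundState)), function(g) {
    k <- gi$nEnh[g]
    if (k == 0) return(NULL)
    j <- seq_len(k)
    center <- gi$tss[g] + 15000L + (j - 1L) * 18000L +
      lay$enhJit[(g - 1L) * 3L + j]
    data.frame(gene = g, gene_id = gi$gene_id[g], state = gi$boundState[g],
               chrom = gi$chrom[g], start = center - 500L,
               end = center + 499L,
               enh_state = lay$enhState[(g - 1L) * 3L + j],
               stringsAsFactors = FALSE)
  }))
  enhRows$element <- sprintf("PE%04d", seq_len(nrow(enhRows)))

  # planted P-P pairs: consecutive same-state specific genes
  mkPairs <- function(idx, state) {
    idx <- idx[seq_len(min(2L * cf$nPPPairsPerState, length(idx)))]
    if (length(idx) < 2) return(NULL)
    a <- idx[seq(1, length(idx) - 1, 2)]; b <- idx[seq(2, length(idx), 2)]
    ok <- gi$chrom[a] == gi$chrom[b]
    data.frame(state = state, gene_a = gi$gene_id[a[ok]],
               gene_b = gi$gene_id[b[ok]], ia = a[ok], ib = b[ok],
               stringsAsFactors = FALSE)
  }
  ppPairs <- rbind(mkPairs(which(gi$role == "a_specific"), "A"),
                   mkPairs(which(gi$role == "b_specific"), "B"))

  ## ---- loops stream ----
  loops <- withStream(cf$seed, 3L, {
    mkState <- function(state) {
      er <- enhRows[enhRows$state == state, , drop = FALSE]
      w1 <- sample(1000:3000, nrow(er), replace = TRUE)
      w2 <- sample(1000:3000, nrow(er), replace = TRUE)
      tssOf <- gi$tss[er$gene]
      a1 <- GR(er$chrom,
                    IRanges(pmax(1L, as.integer((er$start + er$end) %/% 2 - w1 %/% 2)),
                            width = w1))
      a2 <- GR(er$chrom,
                    IRanges(pmax(1L, as.integer(tssOf - w2 %/% 2)), width = w2))
      pet <- 1L + stats::rpois(nrow(er), 2)
      ep <- LoopSet(a1, a2, petCount = pet, loopFactor = "RNAPII")
      pp <- ppPairs[!is.null(ppPairs) & ppPairs$state == state, , drop = FALSE]
      ppLoops <- if (nrow(pp)) {
        LoopSet(GR(gi$chrom[pp$ia], IRanges(gi$tss[pp$ia] - 1000L,
                                                 gi$tss[pp$ia] + 999L)),
                GR(gi$chrom[pp$ib], IRanges(gi$tss[pp$ib] - 1000L,
                                                 gi$tss[pp$ib] + 999L)),
                petCount = 3L, loopFactor = "RNAPII")
      } else LoopSet(GRanges(), GRanges())
      planted <- concatLoops(ep, ppLoops)
      nNoise <- round(cf$loopNoiseRate * length(planted))
      noise <- if (nNoise > 0) {
        nc <- sample(chroms, nNoise, replace = TRUE)
        p1 <- sample.int(as.integer(cf$chromLength - 120000), nNoise)
        gap <- sample(10000:100000, nNoise, replace = TRUE)
        wA <- sample(1000:3000, nNoise, replace = TRUE)
        wB <- sample(1000:3000, nNoise, replace = TRUE)
        LoopSet(GR(nc, IRanges(p1, width = wA)),
                GR(nc, IRanges(p1 + gap, width = wB)),
                petCount = 1L + stats::rpois(nNoise, 1),
                loopFactor = "RNAPII")
      } else LoopSet(GRanges(), GRanges())
      rnapii <- concatLoops(planted, noise)
      # CTCF loops: TSS-proximal CTCF anchor to a distal CTCF site
      bound <- which(gi$boundState %in% state)
      ctcf <- if (length(bound)) {
        LoopSet(GR(gi$chrom[bound], IRanges(gi$tss[bound] - 1000L,
                                                 gi$tss[bound] + 999L)),
                GR(gi$chrom[bound], IRanges(gi$tss[bound] + 79000L,
                                                 gi$tss[bound] + 80999L)),
                petCount = 4L, loopFactor = "CTCF")
      } else LoopSet(GRanges(), GRanges())
      list(RNAPII = rnapii, CTCF = ctcf, nPlanted = length(planted))
    }
    list(A = mkState("A"), B = mkState("B"))
  })

  ## ---- peaks and signal tracks per state ----
  expressedIn <- function(state)
    gi$role == "shared" | gi$boundState %in% state
  rnapiiSkip <- function(state) {
    # 5% of specific genes lack a promoter RNAPII peak in their bound state
    si <- which(gi$boundState %in% state)
    si[seq_along(si) %% 20L == 0L]
  }
  mkPeaks <- function(state) {
    expr <- which(expressedIn(state))
    er <- enhRows[enhRows$state == state, , drop = FALSE]
    enhGR <- GR(er$chrom, IRanges(er$start, er$end))
    peak <- function(gr, intensity, factorName, prefix) {
      mcols(gr) <- DataFrame(
        name = sprintf("%s_%s_%04d", prefix, state, seq_along(gr)),
        intensity = rep(intensity, length.out = length(gr)),
        factor = rep(factorName, length(gr)))
      gr
    }
    rnapiiGenes <- setdiff(expr, rnapiiSkip(state))
    rnapii <- c(
      peak(GR(gi$chrom[rnapiiGenes],
                   IRanges(gi$tss[rnapiiGenes] - 500L,
                           gi$tss[rnapiiGenes] + 499L)),
           5, "RNAPII", "rpP"),
      peak(enhGR, 3, "RNAPII", "rpE"))
    me1 <- c(peak(enhGR, 6, "H3K4me1", "m1E"),
             { epg <- which(gi$ep & gi$boundState %in% state)
               peak(GR(gi$chrom[epg], IRanges(gi$tss[epg] - 1000L,
                                                   gi$tss[epg] + 999L)),
                    6, "H3K4me1", "m1P") })
    k27ac <- peak(enhGR[er$enh_state == "active"], 4, "H3K27ac", "acE")
    k27me3 <- peak(enhGR[er$enh_state == "poised"], 3, "H3K27me3", "pzE")
    strongP <- intersect(expr, which(!gi$ep | !(gi$boundState %in% state)))
    me3 <- peak(GR(gi$chrom[strongP], IRanges(gi$tss[strongP] - 1000L,
                                                   gi$tss[strongP] + 999L)),
                8, "H3K4me3", "m3P")
    # CTCF: promoter-proximal sites (~500 bp) + distal loop anchors
    specHere <- which(gi$boundState %in% state)
    sharedG <- which(gi$role == "shared")
    ctcf <- c(
      peak(GR(gi$chrom[specHere], IRanges(gi$tss[specHere] - 250L,
                                               gi$tss[specHere] + 249L)),
           8, "CTCF", "ctS"),
      peak(GR(gi$chrom[sharedG], IRanges(gi$tss[sharedG] - 250L,
                                              gi$tss[sharedG] + 249L)),
           5, "CTCF", "ctC"),
      peak(GR(gi$chrom[specHere], IRanges(gi$tss[specHere] + 79500L,
                                               gi$tss[specHere] + 80499L)),
           6, "CTCF", "ctD"))
    list(RNAPII = rnapii, H3K4me1 = me1, H3K27ac = k27ac,
         H3K27me3 = k27me3, H3K4me3 = me3, CTCF = ctcf)
  }
  mkSignal <- function(state) {
    expr <- expressedIn(state)
    isEp <- gi$ep & gi$boundState %in% state
    win <- data.frame(chrom = gi$chrom, start = gi$tss - 2000L,
                      end = gi$tss + 2000L)
    me3v <- ifelse(!expr, 0.5, ifelse(isEp, 2, 8))
    me1v <- ifelse(!expr, 0.5, ifelse(isEp, 8, 2))
    er <- enhRows[enhRows$state == state, , drop = FALSE]
    ord <- order(win$chrom, win$start)
    me3 <- GR(win$chrom[ord], IRanges(win$start[ord], win$end[ord]))
    mcols(me3) <- DataFrame(score = me3v[ord])
    me1gr <- c(GR(win$chrom, IRanges(win$start, win$end),
                       score = me1v),
               GR(er$chrom, IRanges(er$start, er$end), score = 6))
    me1gr <- GenomicRanges::sort(me1gr)
    list(H3K4me3 = me3, H3K4me1 = me1gr)
  }
  peaks <- list(A = mkPeaks("A"), B = mkPeaks("B"))
  signal <- list(A = mkSignal("A"), B = mkSignal("B"))

  ## ---- expression stream: two-state table ----
  stateMean <- function(state) {
    ifelse(gi$role == "low", 0.3,
    ifelse(gi$role == "shared", gi$sharedLevel,
    ifelse(gi$boundState == state, 0.5 * gi$nEnh * cf$foldSpecific,
           0.5 * gi$nEnh)))
  }
  muA <- stateMean("A"); muB <- stateMean("B")
  expr <- withStream(cf$seed, 2L, {
    noise <- function(n) 2^stats::rnorm(n, 0, cf$exprNoiseSd)
    m <- cbind(A_1 = muA * noise(cf$nGenes), A_2 = muA * noise(cf$nGenes),
               B_1 = muB * noise(cf$nGenes), B_2 = muB * noise(cf$nGenes))
    rownames(m) <- gi$gene_id
    m
  })
  states <- c("A", "A", "B", "B")

  ## ---- panel stream: multi-cell expression panel ----
  panel <- withStream(cf$seed, 6L, {
    m <- matrix(0.05, cf$nGenes, cf$nPanelCells,
                dimnames = list(gi$gene_id,
                                sprintf("cell%02d", seq_len(cf$nPanelCells))))
    for (g in seq_len(cf$nGenes)) {
      if (gi$role[g] == "shared")
        m[g, ] <- gi$sharedLevel[g] * 2^stats::rnorm(cf$nPanelCells, 0, 0.5)
      else if (gi$role[g] == "low")
        m[g, ] <- 0.2
    }
    # specific genes: on in 3 cells; planted pairs share cells + profile
    onCells <- vector("list", cf$nGenes)
    for (p in seq_len(if (is.null(ppPairs)) 0L else nrow(ppPairs))) {
      cells <- sample.int(cf$nPanelCells, 3)
      z <- stats::rnorm(3, 0, 1)
      for (g in c(ppPairs$ia[p], ppPairs$ib[p])) {
        onCells[[g]] <- cells
        m[g, cells] <- 0.5 * gi$nEnh[g] * cf$foldSpecific *
          2^(z + stats::rnorm(3, 0, 0.3))
      }
    }
    for (g in which(!is.na(gi$boundState))) {
      if (!is.null(onCells[[g]])) next
      cells <- sample.int(cf$nPanelCells, 3)
      m[g, cells] <- 0.5 * gi$nEnh[g] * cf$foldSpecific *
        2^stats::rnorm(3, 0, 0.5)
    }
    m
  })

  ## ---- methylation stream ----
  motifHalf <- 109L   # 219-bp motif window
  specIdx <- which(!is.na(gi$boundState))
  sharedIdx <- which(gi$role == "shared")
  methPos <- function(g) gi$tss[g] + seq(-100L, 100L, by = 20L)
  meth <- withStream(cf$seed, 4L, {
    rows <- list()
    for (g in c(specIdx, sharedIdx)) {
      base <- if (is.na(gi$boundState[g]) || !cf$methylInverseCoupling)
        c(A = 0.5, B = 0.5)
      else if (gi$boundState[g] == "A")
        c(A = 0.5 - cf$dmcDelta / 2, B = 0.5 + cf$dmcDelta / 2)
      else c(A = 0.5 + cf$dmcDelta / 2, B = 0.5 - cf$dmcDelta / 2)
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = gi$chrom[g], pos = methPos(g) - 1L,
                   betaA = unname(base["A"]), betaB = unname(base["B"]),
                   stringsAsFactors = FALSE)
    }
    # background CpGs in the gene-free tail, identical in both states
    for (ch in chroms) {
      pos <- sort(sample((geneRegionEnd + 10000L):(cf$chromLength - 1000L),
                         150L))
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = ch, pos = pos, betaA = 0.5, betaB = 0.5,
                   stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    cov <- 30L
    draw <- function(beta) {
      if (cf$methylNoise) stats::rbinom(nrow(df), cov, beta)
      else as.integer(round(beta * cov))
    }
    df$methA <- draw(df$betaA); df$methB <- draw(df$betaB)
    df$cov <- cov
    df
  })
  mkCpgs <- function(methCol) {
    gr <- bedToGRanges(meth$chrom, meth$pos, meth$pos + 1)
    mcols(gr) <- DataFrame(count_meth = meth[[methCol]],
                           count_total = meth$cov,
                           beta = meth[[methCol]] / meth$cov)
    gr
  }
  methylation <- list(A = mkCpgs("methA"), B = mkCpgs("methB"))

  ## ---- SNP stream ----
  snps <- withStream(cf$seed, 5L, {
    rows <- list()
    firstEnh <- enhRows[!duplicated(enhRows$gene), , drop = FALSE]
    for (r in seq_len(nrow(firstEnh))) {
      e <- firstEnh[r, ]
      cls <- if (e$state == "A") "cancer_related" else "normal_function"
      leadPos <- (e$start + e$end) %/% 2
      lead <- sprintf("rs%s%04d", tolower(e$state), r)
      rows[[length(rows) + 1L]] <- data.frame(
        rsid = lead, chrom = e$chrom, pos = leadPos, trait_class = cls,
        lead_rsid = NA_character_, r2 = NA_real_, stringsAsFactors = FALSE)
      d <- c(500L, 1500L, 2800L)
      d <- d[d <= cf$ldBlockSize / 2]
      if (length(d))
        rows[[length(rows) + 1L]] <- data.frame(
          rsid = sprintf("%s_s%d", lead, seq_along(d)), chrom = e$chrom,
          pos = leadPos + d, trait_class = cls, lead_rsid = lead,
          r2 = exp(-cf$r2Decay * d / 1000), stringsAsFactors = FALSE)
    }
    bg <- data.frame(
      rsid = sprintf("rsbg%03d", 1:50),
      chrom = sample(chroms, 50, replace = TRUE),
      pos = sample((geneRegionEnd + 10000L):(cf$chromLength - 1000L), 50),
      trait_class = "other", lead_rsid = NA_character_, r2 = NA_real_,
      stringsAsFactors = FALSE)
    rbind(do.call(rbind, rows), bg)
  })

  ## ---- contact stream: planted A/B block matrices ----
  nBins <- 32L
  binsizeC <- ceiling(cf$chromLength / nBins)
  contact <- withStream(cf$seed, 7L, {
    lapply(chroms, function(ch) {
      binStart <- (seq_len(nBins) - 1L) * binsizeC
      labels <- ifelse(binStart < geneRegionEnd, "A", "B")
      same <- outer(labels, labels, `==`)
      m <- 2 + 6 * same
      nz <- matrix(stats::runif(nBins * nBins, 0, 1), nBins)
      m <- m + (nz + t(nz)) / 2
      diag(m) <- diag(m) + 4
      list(chrom = ch, mat = m, binsize = binsizeC, labels = labels)
    })
  })
  names(contact) <- chroms

  ## ---- CTCF occupancy panel ----
  constitutive <- GR(gi$chrom[sharedIdx],
                          IRanges(gi$tss[sharedIdx] - 250L,
                                  gi$tss[sharedIdx] + 249L))
  specificSites <- GR(gi$chrom[specIdx],
                           IRanges(gi$tss[specIdx] - 250L,
                                   gi$tss[specIdx] + 249L))
  ctcfPanel <- lapply(seq_len(cf$nCtcfPanelCells), function(j) {
    gr <- if (j == 1L) c(constitutive, specificSites) else constitutive
    mcols(gr) <- DataFrame(name = sprintf("c%02d_%04d", j, seq_along(gr)),
                           intensity = 5, factor = "CTCF")
    gr
  })
  names(ctcfPanel) <- sprintf("cell%02d", seq_len(cf$nCtcfPanelCells))

  ## ---- truth tables ----
  domainGroup <- seq_len(cf$nGenes)
  if (!is.null(ppPairs))
    for (p in seq_len(nrow(ppPairs)))
      domainGroup[ppPairs$ib[p]] <- domainGroup[ppPairs$ia[p]]
  hasLoops <- !is.na(gi$boundState)
  grpSize <- table(domainGroup[hasLoops])
  truth <- list(
    specificGenes = data.frame(
      gene_id = gi$gene_id[hasLoops],
      state = gi$boundState[hasLoops], stringsAsFactors = FALSE),
    epEdges = data.frame(
      state = enhRows$state, gene_id = enhRows$gene_id,
      chrom = enhRows$chrom, start = enhRows$start - 1L,
      end = enhRows$end, enh_state = enhRows$enh_state,
      stringsAsFactors = FALSE),
    enhancerCounts = data.frame(
      gene_id = gi$gene_id[hasLoops], state = gi$boundState[hasLoops],
      n_enhancers = gi$nEnh[hasLoops], stringsAsFactors = FALSE),
    ppPairs = if (is.null(ppPairs))
      data.frame(state = character(), gene_a = character(),
                 gene_b = character()) else
      ppPairs[, c("state", "gene_a", "gene_b")],
    domains = data.frame(
      state = gi$boundState[hasLoops], gene_id = gi$gene_id[hasLoops],
      group = domainGroup[hasLoops],
      gene_class = ifelse(grpSize[as.character(domainGroup[hasLoops])] > 1,
                          "MG", "SG"),
      stringsAsFactors = FALSE),
    promoterClass = data.frame(
      gene_id = gi$gene_id[hasLoops], state = gi$boundState[hasLoops],
      klass = ifelse(gi$ep[hasLoops], "enhancer_like", "strong"),
      stringsAsFactors = FALSE),
    ctcfSites = data.frame(
      gene_id = gi$gene_id[specIdx], chrom = gi$chrom[specIdx],
      start = gi$tss[specIdx] - 251L, end = gi$tss[specIdx] + 249L,
      call = ifelse(gi$boundState[specIdx] == "A", "up_a", "up_b"),
      motif_start = gi$tss[specIdx] - motifHalf - 1L,
      motif_end = gi$tss[specIdx] + motifHalf,
      stringsAsFactors = FALSE),
    dmcs = if (cf$methylInverseCoupling) {
      do.call(rbind, lapply(specIdx, function(g)
        data.frame(chrom = gi$chrom[g], pos = methPos(g) - 1L,
                   stringsAsFactors = FALSE)))
    } else data.frame(chrom = character(), pos = integer()),
    compartments = do.call(rbind, lapply(contact, function(x)
      data.frame(chrom = x$chrom, bin = seq_along(x$labels),
                 label = x$labels, stringsAsFactors = FALSE))),
    traitSnps = data.frame(
      rsid = snps$rsid[is.na(snps$lead_rsid) & snps$trait_class != "other"],
      trait_class = snps$trait_class[is.na(snps$lead_rsid) &
                                     snps$trait_class != "other"],
      stringsAsFactors = FALSE))
  rownames(truth$domains) <- NULL

  bundle <- list(genes = genes, expr = expr, states = states, panel = panel,
                 peaks = peaks, signal = signal,
                 loops = list(A = loops$A[c("RNAPII", "CTCF")],
                              B = loops$B[c("RNAPII", "CTCF")]),
                 methylation = methylation, snps = snps,
                 ctcfPanel = ctcfPanel, contact = contact,
                 chroms = chroms, chromLength = cf$chromLength)
  list(bundle = bundle, truth = truth, config = cf)
}

#' Write a synthetic bundle to disk
#'
#' Emits every bundle component in the package's text formats (BED,
#' BEDPE, bedGraph, TSV) plus the truth tables, and writes
#' `manifest.tsv` listing each emitted path with its record count.
#' Re-writing the same bundle to the same directory reproduces identical
#' files and manifest.
#'
#' @param dataset result of [generateDataset()].
#' @param dir output directory (created if absent).
#' @return the manifest data.frame, invisibly.
#' @export
writeBundle <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- dataset$bundle
  manifest <- list()
  emit <- function(fname, writer, obj, n) {
    writer(obj, file.path(dir, fname))
    manifest[[length(manifest) + 1L]] <<- data.frame(
      path = fname, n_records = n, stringsAsFactors = FALSE)
  }
  emit("genes.bed", writeGeneTable, b$genes, length(b$genes))
  emit("expression_states.tsv", writeExpressionTable, b$expr, nrow(b$expr))
  emit("expression_panel.tsv", writeExpressionTable, b$panel, nrow(b$panel))
  for (st in c("A", "B")) {
    for (fac in names(b$peaks[[st]]))
      emit(sprintf("peaks_%s_%s.bed", fac, st), writeBed,
           b$peaks[[st]][[fac]], length(b$peaks[[st]][[fac]]))
    for (fac in names(b$signal[[st]]))
      emit(sprintf("signal_%s_%s.bedgraph", fac, st), writeBedGraph,
           b$signal[[st]][[fac]], length(b$signal[[st]][[fac]]))
    for (fac in names(b$loops[[st]]))
      emit(sprintf("loops_%s_%s.bedpe", fac, st), writeBedpe,
           b$loops[[st]][[fac]], length(b$loops[[st]][[fac]]))
    emit(sprintf("methylation_%s.tsv", st), writeMethylationTable,
         b$methylation[[st]], length(b$methylation[[st]]))
  }
  emit("snps.tsv", writeSnpTable, b$snps, nrow(b$snps))
  for (cell in names(b$ctcfPanel))
    emit(sprintf("ctcf_panel_%s.bed", cell), writeBed,
         b$ctcfPanel[[cell]], length(b$ctcfPanel[[cell]]))
  for (ch in names(b$contact))
    emit(sprintf("contact_%s.tsv", ch),
         function(x, p) writeTsv(as.data.frame(x), p),
         b$contact[[ch]]$mat, nrow(b$contact[[ch]]$mat))
  for (tn in names(dataset$truth)) {
    tt <- dataset$truth[[tn]]
    emit(sprintf("truth_%s.tsv", tn),
         function(x, p) writeTsv(x, p, col.names = TRUE), tt, nrow(tt))
  }
  mf <- do.call(rbind, manifest)
  mf <- mf[order(mf$path), , drop = FALSE]
  writeTsv(mf, file.path(dir, "manifest.tsv"), col.names = TRUE)
  invisible(mf)
}
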