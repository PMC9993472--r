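test_that("differential binding computes M/A from per-site intensities", {
  genes <- mkGenes("chr1", c(10000, 50000, 90000), c(14000, 54000, 94000),
                   c("+", "+", "+"), ids = c("up", "eq", "aonly"))
  pkA <- mkPeakSet("chr1", c(9800, 49800, 89800), c(10200, 50200, 90200),
                   intensity = c(8, 5, 8), factorName = "CTCF")
  pkB <- mkPeakSet("chr1", c(9800, 49800), c(10200, 50200),
                   intensity = c(2, 5), factorName = "CTCF")
  res <- differentialBinding(pkA, pkB, genes, eps = 0)
  m <- mcols(res)
  expect_equal(m$M[1], 2)                      # log2(8/2)
  expect_equal(m$A[1], 2)                      # 0.5*log2(16)
  expect_equal(m$call[1], "up_a")
  expect_equal(m$M[2], 0)
  expect_equal(m$call[2], "common")
  expect_equal(m$nearest_gene, c("up", "eq", "aonly"))
  # state-absent peak takes the pseudo-intensity
  res2 <- differentialBinding(pkA, pkB, genes, eps = 0.1)
  expect_equal(mcols(res2)$M[3], log2(8.1 / 0.1), tolerance = 1e-12)
  expect_equal(mcols(res2)$call[3], "up_a")
  # peaks far from every TSS are dropped
  far <- mkPeakSet("chr1", 5e6, 5e6 + 400, intensity = 9,
                   factorName = "CTCF")
  expect_warning(empty <- differentialBinding(far, far, genes), "no CTCF")
  expect_length(empty, 0)
})

test_that("differential binding is antisymmetric under state swap", {
  set.seed(12)
  starts <- sort(sample.int(1e6, 30)) * 10
  genes <- mkGenes("chr1", starts, starts + 4000,
                   sample(c("+", "-"), 30, replace = TRUE))
  mkPk <- function() {
    keep <- runif(30) < 0.8
    mkPeakSet("chr1", starts[keep] - 200, starts[keep] + 200,
              intensity = round(rexp(sum(keep), 0.2), 2),
              factorName = "CTCF")
  }
  pkA <- mkPk(); pkB <- mkPk()
  fwd <- differentialBinding(pkA, pkB, genes)
  rev <- differentialBinding(pkB, pkA, genes)
  expect_equal(mcols(fwd)$M, -mcols(rev)$M)
  swap <- c(up_a = "up_b", up_b = "up_a", common = "common")
  expect_equal(unname(swap[mcols(fwd)$call]), mcols(rev)$call)
})

test_that("binding breadth counts panel cells and feeds the KS comparison", {
  sites <- bedToGRanges("chr1", c(100, 1000), c(400, 1300))
  panel <- list(
    c1 = mkPeakSet("chr1", c(150, 1100), c(250, 1200), factorName = "CTCF"),
    c2 = mkPeakSet("chr1", 1100, 1200, factorName = "CTCF"),
    c3 = mkPeakSet("chr1", 1050, 1250, factorName = "CTCF"))
  res <- bindingBreadth(sites, panel)
  expect_equal(res$breadth, c(1L, 3L))
  grouped <- bindingBreadth(sites, panel, groups = c("specific", "const"))
  expect_equal(grouped$ks$D, 1)
  same <- bindingBreadth(c(sites, sites), panel,
                         groups = c("g1", "g1", "g2", "g2"))
  expect_equal(same$ks$D, 0)
  expect_error(bindingBreadth(sites, panel, groups = c("a", "a")),
               "two levels")
})

test_that("region methylation is coverage-weighted and coverage-gated", {
  region <- bedToGRanges("chr1", 0, 1000)
  equal <- mkCpgs("chr1", c(10, 20), c(2, 4), c(10, 10))
  expect_equal(methylationInRegions(equal, region)$beta_mean, 0.3)
  weighted <- mkCpgs("chr1", c(10, 20), c(6, 6), c(30, 10))
  expect_equal(methylationInRegions(weighted, region)$beta_mean, 0.3)
  lowCov <- mkCpgs("chr1", 10, 2, 3)
  expect_true(is.na(methylationInRegions(lowCov, region)$beta_mean))
  expect_equal(methylationInRegions(lowCov, region)$n_cpgs, 0L)
  # input order invariance
  set.seed(6)
  pos <- sample.int(1000, 50)
  cpgs <- mkCpgs("chr1", pos, rbinom(50, 20, 0.4), 20)
  perm <- sample(50)
  expect_equal(methylationInRegions(cpgs, region)$beta_mean,
               methylationInRegions(cpgs[perm], region)$beta_mean)
})

test_that("group methylation comparison delegates to the rank-sum kernel", {
  a <- data.frame(beta_mean = c(0.1, 0.15, 0.12, NA))
  b <- data.frame(beta_mean = c(0.8, 0.9, 0.85))
  res <- compareRegionMethylation(a, b)
  expect_equal(res$median_a, 0.12)
  expect_equal(res$p.value, 0.1)   # fully separated 3-vs-3, exact 2/20
  same <- compareRegionMethylation(b, b)
  expect_equal(same$p.value, 1)
  expect_message(
    nas <- compareRegionMethylation(data.frame(beta_mean = NA_real_), b),
    "insufficient")
  expect_true(is.na(nas$p.value))
})

test_that("DMC calling gates on coverage, delta and BH-adjusted p", {
  a <- mkCpgs("chr1", c(100, 200, 300), c(9, 5, 8), c(10, 10, 10))
  b <- mkCpgs("chr1", c(100, 200, 400), c(1, 5, 1), c(10, 10, 10))
  res <- callDmc(a, b)
  expect_equal(nrow(res), 2)      # pos 300/400 unshared
  expect_equal(res$delta[1], 0.8)
  expect_equal(res$p.value[1],
               fisherExact2x2(9, 1, 1, 9), tolerance = 1e-12)
  expect_true(res$is_dmc[1])
  expect_equal(res$p.value[2], 1)
  expect_false(res$is_dmc[2])
  # strong delta at low coverage is excluded
  lowA <- mkCpgs("chr1", 100, 3, 3)
  lowB <- mkCpgs("chr1", 100, 0, 3)
  expect_warning(none <- callDmc(lowA, lowB), "no shared positions")
  expect_equal(nrow(none), 0)
})

test_that("noiseless synthetic data reproduce planted CTCF and DMC truth", {
  ds <- cachedDataset("zero11", zeroNoiseConfig())
  b <- ds$bundle
  spec <- ds$truth$specificGenes
  sg <- b$genes[spec$gene_id]
  diff <- differentialBinding(b$peaks$A$CTCF, b$peaks$B$CTCF, sg)
  truth <- ds$truth$ctcfSites
  hits <- findOverlaps(diff, bedToGRanges(truth$chrom, truth$start,
                                          truth$end), select = "first")
  expect_false(anyNA(hits))
  expect_equal(mcols(diff)$call, truth$call[hits])
  # DMCs: exactly the planted motif cytosines
  dmc <- callDmc(b$methylation$A, b$methylation$B)
  got <- dmc[dmc$is_dmc, c("chrom", "pos")]
  want <- ds$truth$dmcs[order(ds$truth$dmcs$chrom, ds$truth$dmcs$pos), ]
  got <- got[order(got$chrom, got$pos), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want[, c("chrom", "pos")])
})

test_that("bound motifs are hypomethylated relative to unbound motifs", {
  for (seed in c(7L, 19L)) {
    ds <- cachedDataset(paste0("default", seed), synthConfig(seed = seed))
    tru <- ds$truth$ctcfSites
    motifs <- bedToGRanges(tru$chrom, tru$motif_start, tru$motif_end)
    mA <- methylationInRegions(ds$bundle$methylation$A, motifs,
                               "motif_219bp")
    boundA <- tru$call == "up_a"
    res <- compareRegionMethylation(mA[boundA, ], mA[!boundA, ])
    expect_lt(res$median_a, res$median_b)
    expect_lt(res$p.value, 0.01)
  }
})
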