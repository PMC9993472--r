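# brute-force union-find over all anchor pairs, the independent oracle
# for loop clustering
bruteComponents <- function(loops, mergeGap = 0L) {
  n <- length(loops)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  bedA <- grangesToBed(anchorOne(loops)); bedB <- grangesToBed(anchorTwo(loops))
  anchorsOf <- function(i) rbind(bedA[i, ], bedB[i, ])
  near <- function(p, q)  # BED half-open intervals within mergeGap bp
    p$chrom == q$chrom & p$start < q$end + mergeGap & q$start < p$end + mergeGap
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    ai <- anchorsOf(i); aj <- anchorsOf(j)
    touching <- any(vapply(1:2, function(u) any(vapply(1:2, function(v)
      near(ai[u, ], aj[v, ]), TRUE)), TRUE))
    if (touching) parent[find(i)] <- find(j)
  }
  vapply(seq_len(n), find, 1L)
}

test_that("anchor-sharing loops chain into one domain", {
  loops <- mkLoops("chr1", c(0, 5500), c(1000, 6500), c(5000, 9000),
                   c(6000, 10000))
  res <- clusterDomains(loops)
  expect_equal(res$membership, c(1L, 1L))
  expect_equal(grangesToBed(res$domains),
               data.frame(chrom = "chr1", start = 0, end = 10000))
  expect_equal(mcols(res$domains)$domain_id, "RAID_001")
  far <- mkLoops("chr1", c(0, 2e6), c(1000, 2e6 + 1000), c(5000, 2.1e6),
                 c(6000, 2.1e6 + 1000))
  expect_equal(length(clusterDomains(far)$domains), 2L)
  mixed <- mkLoops("chr1", c(0, 0), c(10, 10), c(100, 100), c(200, 200),
                   factorName = c("RNAPII", "CTCF"))
  expect_error(clusterDomains(mixed), "single factor")
})

test_that("clustering matches brute-force union-find and partitions loops", {
  set.seed(77)
  for (rep in 1:4) {
    n <- 50
    s1 <- sample.int(2e5, n)
    gapAB <- sample(2000:50000, n, replace = TRUE)
    loops <- mkLoops(sample(c("chr1", "chr2"), n, replace = TRUE),
                     s1, s1 + sample(500:3000, n, replace = TRUE),
                     s1 + gapAB, s1 + gapAB + sample(500:3000, n,
                                                     replace = TRUE))
    for (gap in c(0L, 1000L)) {
      res <- clusterDomains(loops, mergeGap = gap)
      brute <- bruteComponents(loops, gap)
      # same partition up to labelling
      expect_equal(length(unique(res$membership)), length(unique(brute)))
      expect_true(all(tapply(brute, res$membership,
                             function(x) length(unique(x))) == 1))
      # partition: every loop in exactly one domain, counts consistent
      expect_equal(length(res$membership), n)
      expect_equal(sum(mcols(res$domains)$n_loops), n)
    }
  }
})

test_that("clustering is invariant under loop input order", {
  set.seed(17)
  n <- 40
  s1 <- sample.int(1e5, n)
  loops <- mkLoops("chr1", s1, s1 + 1500, s1 + 20000, s1 + 21500)
  ref <- clusterDomains(loops)
  refSpan <- grangesToBed(ref$domains)
  for (i in 1:20) {
    perm <- sample(n)
    res <- clusterDomains(loops[perm])
    expect_equal(grangesToBed(res$domains), refSpan)
    # permuted membership names the same grouping
    expect_equal(res$membership, ref$membership[perm])
  }
})

test_that("gene-domain assignment is TSS-based with half-open boundaries", {
  loops <- mkLoops("chr1", 1000, 2000, 9000, 10000)
  dom <- clusterDomains(loops)$domains     # span [1000,10000) in BED terms
  genes <- mkGenes("chr1", c(5000, 10000, 400, 8000, 9600),
                   c(6000, 11000, 1400, 8800, 10600),
                   c("+", "+", "+", "+", "+"),
                   ids = c("mid", "pastEnd", "before", "in2", "in3"))
  asg <- assignGenesToDomains(dom, genes)
  expect_equal(unname(asg$geneDomain[c("mid", "pastEnd", "before")]),
               c("RAID_001", NA, NA))
  expect_equal(unname(asg$geneClass["RAID_001"]), "MG")  # 3 TSSs inside
  one <- assignGenesToDomains(dom, genes[1])
  expect_equal(unname(one$geneClass["RAID_001"]), "SG")
  none <- assignGenesToDomains(dom, genes[3])
  expect_equal(unname(none$geneClass["RAID_001"]), "none")
  expect_equal(none$fractionInside, 0)
  sub <- assignGenesToDomains(dom, genes, geneSubset = c("mid", "before"))
  expect_equal(sub$fractionInside, 0.5)
})

test_that("genes with loop anchors at the TSS are found and deduplicated", {
  genes <- mkGenes("chr1", c(5000, 90000), c(9000, 95000), c("+", "+"),
                   ids = c("hit", "miss"))
  loops <- mkLoops("chr1", 4500, 5200, 40000, 41000)
  counts <- genesWithAnchorAtTss(loops, genes)
  expect_equal(unname(counts), c(1L, 0L))
  # both anchors of one loop at one TSS: anchor count 2, gene counted once
  both <- mkLoops("chr1", 4000, 5000, 5200, 6200)
  counts <- genesWithAnchorAtTss(both, genes)
  expect_equal(unname(counts["hit"]), 2L)
  empty <- mkLoops(character(), numeric(), numeric(), numeric(), numeric())
  expect_equal(sum(genesWithAnchorAtTss(empty, genes)), 0L)
})

test_that("compartment calling recovers planted classes, oriented by gene density", {
  classes <- rep(rep(c("A", "B"), each = 5), 2)   # 20 bins, interleaved blocks
  density <- ifelse(classes == "A", 5L, 0L)
  m <- blockMatrix(classes)
  trk <- callCompartments(m, binsize = 1e5, geneDensity = density)
  expect_equal(as.character(compartmentLabels(trk)), classes)
  expect_true(eigenvalueFraction(trk) > 0.2)
  # flipping the density flips the orientation: gene-dense class is A
  flipped <- callCompartments(m, 1e5, ifelse(classes == "A", 0L, 5L))
  expect_equal(as.character(compartmentLabels(flipped)),
               ifelse(classes == "A", "B", "A"))
  # structureless matrix is flagged
  expect_warning(callCompartments(matrix(3, 10, 10), 1e5, rep(1L, 10)),
                 "little compartment structure")
  expect_error(callCompartments(matrix(0, 5, 5), 1e5, rep(1L, 5)),
               "all-zero")
  # zero-marginal bins are NA
  m2 <- blockMatrix(classes)
  m2[3, ] <- 0; m2[, 3] <- 0
  trk2 <- callCompartments(m2, 1e5, density)
  expect_true(is.na(compartmentLabels(trk2)[3]))
})

test_that("per-gene compartment switches classify by TSS bin", {
  classes <- rep(c("B", "A"), each = 5)
  density <- c(rep(0L, 5), rep(4L, 5))
  tA <- callCompartments(blockMatrix(classes), 1000, density)
  genes <- mkGenes("chr1", c(1500, 7500), c(2500, 8500), c("+", "+"))
  sw <- compartmentSwitch(tA, tA, genes)
  expect_equal(unname(sw$switchClass), c("stable", "stable"))
  expect_equal(sw$fractionBtoA, 0)
  # a track with inverted orientation flips every gene's class
  tInv <- callCompartments(blockMatrix(classes), 1000,
                           ifelse(classes == "B", 4L, 0L))
  sw2 <- compartmentSwitch(tA, tInv, genes)
  expect_equal(unname(sw2$switchClass), c("B->A", "A->B"))
  expect_equal(sw2$fractionBtoA, 0.5)
  # track with differing bin size is rejected
  tC <- callCompartments(blockMatrix(classes), 2000, density)
  expect_error(compartmentSwitch(tA, tC, genes), "share bin size")
  # genes beyond the binned region are NA
  far <- mkGenes("chr1", 1e6, 1e6 + 100, "+")
  expect_true(is.na(compartmentSwitch(tA, tA, far)$switchClass))
})

test_that("loop-derived contact matrices are symmetric with loop-weighted cells", {
  loops <- mkLoops("chr1", c(100, 5100), c(600, 5600), c(5100, 10100),
                   c(5600, 10600), pet = c(3L, 2L))
  m <- contactMatrixFromLoops(loops, binsize = 5000, nBins = 3)
  expect_true(isSymmetric(m))
  expect_equal(m[1, 2], 3)
  expect_equal(m[2, 3], 2)
  expect_equal(contactMatrixFromLoops(loops[0], 5000, 3), matrix(0, 3, 3))
})
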