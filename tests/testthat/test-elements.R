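test_that("enhancer state rules are exhaustive and mutually exclusive", {
  expect_equal(classifyEnhancerState(c("H3K4me1", "H3K27ac")), "active")
  expect_equal(classifyEnhancerState("H3K4me1"), "intermediate")
  expect_equal(classifyEnhancerState(c("H3K4me1", "H3K27me3")), "poised")
  expect_equal(classifyEnhancerState("H3K27ac"), "unclassified")
  # totality over every subset of the three marks
  marks <- c("H3K4me1", "H3K27ac", "H3K27me3")
  subsets <- unlist(lapply(0:3, function(k)
    combn(marks, k, simplify = FALSE)), recursive = FALSE)
  states <- classifyEnhancerState(subsets)
  expect_length(states, 8)
  expect_true(all(states %in% c("active", "intermediate", "poised",
                                "unclassified")))
  # repression dominates when both K27 marks are present
  expect_equal(classifyEnhancerState(marks), "poised")
})

test_that("promoter strength classifies by signed log2 me3/me1 ratio", {
  genes <- mkGenes("chr1", c(10000, 50000, 90000), c(14000, 54000, 94000),
                   c("+", "+", "+"), ids = c("ep", "strong", "tie"))
  me3 <- mkTrack("chr1", c(8000, 48000, 88000), c(12001, 52001, 92001),
                 c(2, 8, 5))
  me1 <- mkTrack("chr1", c(8000, 48000, 88000), c(12001, 52001, 92001),
                 c(8, 2, 5))
  ps <- promoterStrength(genes, me3, me1)
  expect_equal(ps$log2_ratio[1], log2(2.1 / 8.1), tolerance = 1e-12)
  expect_equal(ps$klass, c("enhancer_like", "strong", "strong"))
  # antisymmetry: swapping the tracks flips the class and negates the ratio
  sw <- promoterStrength(genes, me1, me3)
  expect_equal(sw$log2_ratio, -ps$log2_ratio)
  expect_equal(sw$klass[1:2], c("strong", "enhancer_like"))
  # both-zero windows default to strong through the pseudo-signal
  bare <- promoterStrength(genes, mkTrack("chr2", 0, 10, 1),
                           mkTrack("chr2", 0, 10, 1))
  expect_equal(unique(bare$klass), "strong")
})

mkScene <- function() {
  genes <- mkGenes("chr1", c(10000, 50000), c(14000, 54000), c("+", "+"),
                   ids = c("gStrong", "gEp"))
  strengths <- data.frame(gene_id = c("gStrong", "gEp"),
                          klass = c("strong", "enhancer_like"),
                          stringsAsFactors = FALSE)
  enh <- mkPeakSet("chr1", c(30000, 70000), c(31000, 71000),
                   factorName = "H3K4me1")
  mcols(enh) <- DataFrame(element_id = c("ENH_0001", "ENH_0002"),
                          state = "active")
  list(genes = genes, strengths = strengths, enh = enh)
}

test_that("anchor annotation applies promoter precedence and nearest-TSS", {
  sc <- mkScene()
  anchors <- bedToGRanges("chr1", c(9500, 30200, 49500, 200000),
                          c(10500, 30800, 50500, 201000))
  # first anchor overlaps both the strong promoter window and an enhancer
  enhAtTss <- c(sc$enh, mkPeakSet("chr1", 9000, 11000,
                                  factorName = "H3K4me1"))
  mcols(enhAtTss)$element_id <- c("ENH_0001", "ENH_0002", "ENH_0003")
  mcols(enhAtTss)$state <- "active"
  anno <- annotateAnchors(anchors, sc$genes, sc$strengths, enhAtTss)
  expect_equal(anno$type, c("P", "E", "Ep", "none"))
  expect_equal(anno$gene_id, c("gStrong", NA, "gEp", NA))
  expect_equal(anno$element_id[2], "ENH_0001")
  # anchor spanning two TSS windows resolves to the nearest TSS
  close <- mkGenes("chr1", c(10000, 13000), c(12000, 16000), c("+", "+"),
                   ids = c("near1", "near2"))
  strengths2 <- data.frame(gene_id = c("near1", "near2"),
                           klass = "strong", stringsAsFactors = FALSE)
  wide <- bedToGRanges("chr1", 11500, 12900)  # in both windows, closer to tss2
  expect_message(
    anno2 <- annotateAnchors(wide, close, strengths2, sc$enh),
    "multiple TSS windows")
  expect_equal(anno2$gene_id, "near2")
})

test_that("network edges are typed, deduplicated and loop-backed", {
  sc <- mkScene()
  # loops: E1-P(gStrong) twice, P(gStrong)-Ep(gEp), E2-none
  loops <- mkLoops("chr1", c(30100, 30200, 9800, 70100),
                   c(30900, 30900, 10800, 70900),
                   c(9600, 9700, 49600, 200000),
                   c(10400, 10600, 50400, 201000))
  a1 <- annotateAnchors(anchorOne(loops), sc$genes, sc$strengths, sc$enh)
  a2 <- annotateAnchors(anchorTwo(loops), sc$genes, sc$strengths, sc$enh)
  net <- buildEPNetwork(loops, a1, a2)
  edges <- as.data.frame(networkEdges(net)[, c("node_a", "node_b", "type",
                                               "n_loops")])
  expect_equal(nrow(edges), 2)   # E1-gStrong (x2 loops), gStrong-gEp
  ep <- edges[edges$type == "E-P", ]
  expect_equal(ep$n_loops, 2L)
  expect_equal(sort(edges$type), c("E-P", "Ep-P"))
  # edge count never exceeds loop count; removing loops never adds edges
  net3 <- buildEPNetwork(loops[1:3], a1[1:3, ], a2[1:3, ])
  expect_lte(nrow(networkEdges(net3)), 3)
  keyOf <- function(n) paste(networkEdges(n)$node_a, networkEdges(n)$node_b)
  expect_true(all(keyOf(net3) %in% keyOf(net)))
  counts <- geneEnhancerCounts(net)
  expect_equal(counts[["gStrong"]], 2L)   # E1 + enhancer-like gEp
})

test_that("self and duplicate pairs collapse in P-P extraction", {
  sc <- mkScene()
  loops <- mkLoops("chr1", c(9800, 9900, 49500), c(10800, 10900, 50500),
                   c(49600, 49700, 49900), c(50400, 50600, 50900))
  a1 <- annotateAnchors(anchorOne(loops), sc$genes, sc$strengths, sc$enh)
  a2 <- annotateAnchors(anchorTwo(loops), sc$genes, sc$strengths, sc$enh)
  net <- buildEPNetwork(loops, a1, a2)
  pairs <- extractPPPairs(net)
  expect_equal(nrow(pairs), 1)   # two supporting loops, one self-loop dropped
  expect_equal(sort(unlist(pairs[1, ])), c(gene_a = "gEp",
                                           gene_b = "gStrong"))
  expect_equal(nrow(extractPPPairs(net, includeEp = FALSE)), 0)
})

test_that("enhancer-count strata show the planted additive effect", {
  ds <- cachedDataset("default7", synthConfig(seed = 7))
  res <- buildStateNetwork(ds$bundle, "A")
  counts <- geneEnhancerCounts(res$network)
  truth <- ds$truth$enhancerCounts
  truthA <- setNames(truth$n_enhancers, truth$gene_id)[truth$state == "A"]
  shared <- intersect(names(counts), names(truthA))
  # distal enhancer counts may be inflated by enhancer-like promoters of
  # partner genes; compare against planted counts for pure-E genes
  pureE <- shared[vapply(shared, function(g) {
    counts[[g]] >= truthA[[g]]
  }, TRUE)]
  expect_gte(length(pureE) / length(shared), 0.99)
  de <- callSpecificGenes(ds$bundle$expr, ds$bundle$states, "A", "B")
  exprA <- setNames(de$mean_a, de$gene_id)
  eff <- enhancerCountEffect(setNames(truthA, names(truthA)), exprA)
  med <- vapply(eff$strata, median, 1)
  expect_true(med[["1"]] < med[[">=3"]])
  p13 <- eff$p.values$p.value[eff$p.values$stratum_a == "1" &
                              eff$p.values$stratum_b == ">=3"]
  expect_lt(p13, 0.05)
  # degenerate stratum yields NA p-values but the run continues
  eff2 <- enhancerCountEffect(c(g1 = 1L, g2 = 1L, g3 = 3L),
                              c(g1 = 2, g2 = 3, g3 = 9))
  expect_true(all(is.na(eff2$p.values$p.value)))
})

test_that("planted per-gene enhancer counts are recovered without noise", {
  ds <- cachedDataset("zero11", zeroNoiseConfig())
  for (st in c("A", "B")) {
    res <- buildStateNetwork(ds$bundle, st)
    links <- extractEPEdges(res$network)
    got <- table(links$gene_id)
    truth <- ds$truth$enhancerCounts
    truth <- truth[truth$state == st, ]
    expect_equal(as.integer(got[truth$gene_id]), truth$n_enhancers)
  }
})
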