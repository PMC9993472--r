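# independent enumeration oracle for the rank-sum U distribution:
# all C(n, nx) assignments of the observed values to the first sample
enumRankSumP <- function(x, y, alternative) {
  z <- c(x, y); nx <- length(x)
  r <- rank(z)
  uOf <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  U <- uOf(seq_len(nx))
  Us <- apply(utils::combn(length(z), nx), 2, uOf)
  pG <- mean(Us >= U); pL <- mean(Us <= U)
  switch(alternative, greater = pG, less = pL,
         two.sided = min(1, 2 * min(pG, pL)))
}

test_that("rank-sum test is exact for small samples, with and without ties", {
  res <- wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(res$p.value, 1 / 20)
  expect_equal(res$method, "exact")
  # identical multisets: U = |x||y|/2, p = 1
  res <- wilcoxonRankSum(c(2, 7, 7), c(2, 7, 7))
  expect_equal(res$U, 4.5)
  expect_equal(res$p.value, 1)
  # all values tied
  expect_equal(wilcoxonRankSum(rep(3, 4), rep(3, 5))$p.value, 1)
  # tie-free instances agree with the independent exact implementation
  set.seed(5)
  for (i in 1:20) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    v <- sample(100, nx + ny)
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    expect_equal(wilcoxonRankSum(x, y)$p.value,
                 wilcox.test(x, y, exact = TRUE)$p.value)
  }
  # tied instances agree with the enumeration oracle
  for (i in 1:20) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(4, nx, replace = TRUE); y <- sample(4, ny, replace = TRUE)
    for (alt in c("two.sided", "greater", "less"))
      expect_equal(wilcoxonRankSum(x, y, alternative = alt)$p.value,
                   enumRankSumP(x, y, alt))
  }
})

test_that("rank-sum normal approximation tracks the reference above the cutoff", {
  set.seed(9)
  x <- rnorm(15); y <- rnorm(18, 0.8)
  mine <- wilcoxonRankSum(x, y)
  expect_equal(mine$method, "normal")
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-8)
})

test_that("two-proportion z follows the pooled formula", {
  expect_equal(twoProportionZ(5, 10, 5, 10), list(z = 0, p.value = 1))
  res <- twoProportionZ(9, 10, 1, 10)
  expect_equal(res$z, 0.8 / sqrt(0.5 * 0.5 * 0.2), tolerance = 1e-10)
  # z^2 equals the uncorrected 2x2 chi-square statistic
  for (tab in list(c(9, 10, 1, 10), c(30, 50, 12, 40), c(5, 9, 7, 11))) {
    z <- twoProportionZ(tab[1], tab[2], tab[3], tab[4])$z
    chi <- suppressWarnings(chisq.test(
      matrix(c(tab[1], tab[2] - tab[1], tab[3], tab[4] - tab[3]), 2),
      correct = FALSE))$statistic
    expect_equal(z^2, unname(chi), tolerance = 1e-10)
  }
  expect_message(res <- twoProportionZ(0, 10, 0, 10), "degenerate")
  expect_equal(res$p.value, 1)
})

test_that("hypergeometric tail matches subset enumeration", {
  expect_equal(hypergeometricTail(10, 4, 5, 3), 66 / 252, tolerance = 1e-12)
  expect_equal(hypergeometricTail(10, 4, 5, 0), 1)
  expect_equal(hypergeometricTail(4, 2, 2, 2), 1 / 6, tolerance = 1e-12)
  # enumeration over all n-subsets of a labelled universe
  enumTail <- function(N, K, n, k) {
    subs <- utils::combn(N, n)
    mean(apply(subs, 2, function(s) sum(s <= K) >= k))
  }
  for (N in 5:9) for (K in 0:N) for (n in 1:N) for (k in 0:min(n, K))
    expect_equal(hypergeometricTail(N, K, n, k), enumTail(N, K, n, k),
                 tolerance = 1e-10)
  # monotone non-increasing in k
  p <- vapply(0:4, function(k) hypergeometricTail(10, 4, 5, k), 1)
  expect_true(all(diff(p) <= 0))
  expect_error(hypergeometricTail(10, 11, 5, 3), "impossible")
})

test_that("Fisher exact matches enumeration and the hypergeometric tail", {
  expect_equal(fisherExact2x2(1, 1, 1, 1), 1)
  expect_equal(fisherExact2x2(5, 0, 0, 5), 2 / 252, tolerance = 1e-10)
  # one-sided extreme tables: two-sided sum collapses to the upper tail
  expect_equal(fisher.test(matrix(c(5, 0, 0, 5), 2),
                           alternative = "greater")$p.value,
               hypergeometricTail(10, 5, 5, 5), tolerance = 1e-10)
  expect_equal(fisher.test(matrix(c(4, 1, 0, 5), 2),
                           alternative = "greater")$p.value,
               hypergeometricTail(10, 4, 5, 4), tolerance = 1e-10)
})

test_that("two-sample KS statistic and degenerate cases are exact", {
  expect_equal(ksTwoSample(1:4, 1:4), list(D = 0, p.value = 1))
  expect_equal(ksTwoSample(c(1, 2), c(3, 4))$D, 1)
  expect_equal(ksTwoSample(c(1, 3), c(2, 4))$D, 0.5)
  # D equals the brute-force ECDF supremum on random data
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(sample(5:30, 1), 0.5)
    grid <- sort(c(x, y))
    bruteD <- max(abs(ecdf(x)(grid) - ecdf(y)(grid)))
    expect_equal(ksTwoSample(x, y)$D, bruteD, tolerance = 1e-12)
  }
})

test_that("PWM scanning matches a naive per-position rescan on both strands", {
  pwm <- rbind(A = c(2, -1, -1), C = c(-1, 2, -1),
               G = c(-1, -1, 2), T = c(-2, -2, -2))
  hits <- pwmScan("ACG", pwm, threshold = 6)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$position, 1)
  expect_equal(hits$strand, "+")
  expect_equal(nrow(pwmScan("ACG", pwm, threshold = 7)), 0)
  # reverse strand: revcomp of ACG is CGT, present at forward position 2
  hits <- pwmScan("TCGT", pwm, threshold = 6)
  expect_true(any(hits$strand == "-" & hits$position == 2))
  # non-ACGT bases contribute zero
  expect_message(h <- pwmScan("ANG", pwm, threshold = 3), "non-ACGT")
  expect_equal(h$score, 4)   # A(2) + 0 + G(2)
  # random-sequence equivalence with an independent naive scanner
  set.seed(13)
  seq1 <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                collapse = "")
  w <- 5
  pwm2 <- matrix(rnorm(4 * w), 4, dimnames = list(c("A", "C", "G", "T")))
  naive <- function(s, mat, thr) {
    ch <- strsplit(s, "")[[1]]
    out <- NULL
    for (i in seq_len(length(ch) - w + 1)) {
      sc <- 0
      for (j in seq_len(w)) sc <- sc + mat[ch[i + j - 1], j]
      if (sc >= thr) out <- rbind(out, data.frame(position = i, score = sc))
    }
    out
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rcSeq <- paste(rev(comp[strsplit(seq1, "")[[1]]]), collapse = "")
  thr <- 2
  mine <- pwmScan(seq1, pwm2, thr)
  fwd <- naive(seq1, pwm2, thr)
  rev <- naive(rcSeq, pwm2, thr)
  expect_equal(mine$position[mine$strand == "+"], fwd$position)
  expect_equal(mine$score[mine$strand == "+"], fwd$score, tolerance = 1e-12)
  # reverse hits in forward coordinates: position i on revcomp maps to
  # nchar - (i + w - 1) + 1 on the forward strand
  expect_equal(sort(mine$position[mine$strand == "-"]),
               sort(500 - (rev$position + w - 1) + 1))
})

test_that("TF occupancy ranking orders by differential fraction", {
  setA <- bedToGRanges("chr1", c(0, 100, 200, 300), c(50, 150, 250, 350))
  setB <- bedToGRanges("chr1", c(1000, 1100, 1200, 1300),
                       c(1050, 1150, 1250, 1350))
  tfs <- list(
    biased = mkPeakSet("chr1", c(0, 100, 200, 1000), c(50, 150, 250, 1050),
                       factorName = "TF:biased"),
    flat = mkPeakSet("chr1", c(0, 100, 1000, 1100), c(50, 150, 1050, 1150),
                     factorName = "TF:flat"),
    empty = mkPeakSet(character(), numeric(), numeric())[0])
  rk <- tfOccupancyRanking(setA, setB, tfs)
  expect_equal(rk$tf[1], "biased")
  expect_equal(rk$frac_a[rk$tf == "biased"], 0.75)
  expect_equal(rk$frac_b[rk$tf == "biased"], 0.25)
  expect_equal(rk$note[rk$tf == "empty"], "empty peak set")
  # identical occupancy gives z = 0
  same <- tfOccupancyRanking(setA, setA, tfs["flat"])
  expect_equal(same$z, 0)
})

test_that("LD expansion thresholds satellites and inherits trait class", {
  snps <- data.frame(
    rsid = c("rs1", "rs2", "rs3"), chrom = "chr1", pos = c(100, 600, 5100),
    trait_class = c("cancer_related", "other", "other"),
    lead_rsid = c(NA, "rs1", "rs1"), r2 = c(NA, 0.9, 0.5),
    stringsAsFactors = FALSE)
  got <- expandLd(snps, r2Min = 0.8)
  expect_setequal(got$rsid, c("rs1", "rs2"))
  expect_equal(got$trait_class[got$rsid == "rs2"], "cancer_related")
  expect_setequal(expandLd(snps, r2Min = 0)$rsid, c("rs1", "rs2", "rs3"))
  expect_equal(expandLd(snps[1, ], r2Min = 0.8)$rsid, "rs1")
  # monotone set inclusion in r2Min
  sizes <- vapply(c(0, 0.4, 0.8, 0.95), function(t)
    nrow(expandLd(snps, r2Min = t)), 1L)
  expect_true(all(diff(sizes) <= 0))
  bad <- snps; bad$lead_rsid[2] <- "rs99"
  expect_error(expandLd(bad), "unknown lead")
  expect_message(ok <- expandLd(bad, strict = FALSE), "dropped 1")
})

test_that("SNP-element enrichment counts at element level", {
  universe <- bedToGRanges("chr1", (0:9) * 100, (0:9) * 100 + 50)
  target <- universe[1:5]
  # SNPs hitting elements 1,2,3 (in target) and 6 (outside)
  snps <- bedToGRanges("chr1", c(10, 110, 210, 510), c(11, 111, 211, 511))
  res <- snpElementEnrichment(snps, target, universe)
  expect_equal(res[c("k", "n", "K", "N")], list(k = 3, n = 5, K = 4, N = 10))
  expect_equal(res$p.value, 66 / 252, tolerance = 1e-12)
  none <- snpElementEnrichment(snps[0], target, universe)
  expect_equal(none$k, 0)
  expect_equal(none$p.value, 1)
  expect_error(
    snpElementEnrichment(snps, bedToGRanges("chr1", 5000, 5100), universe),
    "subset")
})
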