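#' @importFrom stats pnorm phyper fisher.test ks.test p.adjust cor sd
#'   rnorm rpois runif setNames median quantile
#' @importFrom utils combn
NULL

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact when the combined sample size is at most `exactMax` (default 12):
#' the U null distribution is built by enumerating every
#' `choose(n, |x|)`-labelling of the observed values, which remains exact
#' under ties.  Larger samples use the normal approximation with tie
#' correction and a 0.5 continuity correction.
#'
#' @param x,y numeric samples, each non-empty.
#' @param alternative `"two.sided"` (default), `"greater"` (x shifted above
#'   y) or `"less"`.
#' @param exactMax combined-size cutoff for exact enumeration.
#' @return list with `U` (Mann-Whitney statistic for `x`), `p.value`, and
#'   `method` (`"exact"` or `"normal"`).  If all values across both samples
#'   are tied the p-value is 1.
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6), alternative = "less")$p.value # 0.05
#' @export
wilcoxonRankSum <- function(x, y, alternative = c("two.sided", "greater", "less"),
                            exactMax = 12L) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 1, length(y) >= 1)
  nx <- length(x); ny <- length(y); n <- nx + ny
  z <- c(x, y)
  r <- rank(z)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (length(unique(z)) == 1L)
    return(list(U = U, p.value = 1, method = "degenerate"))
  if (n <= exactMax) {
    idx <- combn(n, nx)
    Us <- apply(idx, 2, function(i) sum(r[i])) - nx * (nx + 1) / 2
    pGreater <- mean(Us >= U)
    pLess <- mean(Us <= U)
    p <- switch(alternative,
                greater = pGreater,
                less = pLess,
                two.sided = min(1, 2 * min(pGreater, pLess)))
    return(list(U = U, p.value = p, method = "exact"))
  }
  mu <- nx * ny / 2
  ties <- table(z)
  sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  cc <- 0.5
  zGreater <- (U - mu - cc) / sqrt(sig2)
  zLess <- (U - mu + cc) / sqrt(sig2)
  p <- switch(alternative,
              greater = pnorm(zGreater, lower.tail = FALSE),
              less = pnorm(zLess),
              two.sided = min(1, 2 * min(pnorm(zGreater, lower.tail = FALSE),
                                         pnorm(zLess))))
  list(U = U, p.value = p, method = "normal")
}

#' Two-proportion z-test (pooled variance)
#'
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with the pooled estimate
#' `p = (k1 + k2)/(n1 + n2)`; the two-sided p-value is from the standard
#' normal.  No continuity correction (so `z^2` equals the 2x2 chi-square
#' statistic without Yates correction).  Degenerate pooled proportions 0 or
#' 1 return `z = 0`, `p = 1` with a message.
#'
#' @param k1,n1,k2,n2 successes and trials per group (`n1, n2 >= 1`).
#' @return list with `z` and `p.value`.
#' @export
twoProportionZ <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  pooled <- (k1 + k2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) {
    message("twoProportionZ: degenerate pooled proportion; returning z = 0")
    return(list(z = 0, p.value = 1))
  }
  z <- (k1 / n1 - k2 / n2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  list(z = z, p.value = 2 * pnorm(-abs(z)))
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for drawing `n` from a universe of `N` with `K` positives —
#' the enrichment p-value for "k of my n elements hit, against K of N
#' overall".
#'
#' @param N universe size; `K` universe positives; `n` draw size; `k`
#'   observed positives in the draw.
#' @return upper-tail probability in (0, 1]; `k = 0` gives exactly 1.
#' @examples
#' hypergeometricTail(10, 4, 5, 3)  # 66/252
#' @export
hypergeometricTail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > n || k > K)
    stop("impossible hypergeometric parameters")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided by summation of hypergeometric probabilities no larger than
#' the observed table's.
#'
#' @param a,b,c,d cell counts, row-wise: `[[a, b], [c, d]]`.
#' @return two-sided p-value.
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  fisher.test(matrix(c(a, c, b, d), 2))$p.value
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|`, p-value from the asymptotic Kolmogorov
#' distribution.
#'
#' @param x,y numeric samples.
#' @return list with `D` and `p.value`.
#' @export
ksTwoSample <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  res <- suppressWarnings(ks.test(x, y, exact = FALSE))
  list(D = unname(res$statistic), p.value = res$p.value)
}

#' Scan a sequence with a log-odds position weight matrix
#'
#' Both strands are scanned; a position is a hit when the summed log-odds
#' score reaches `threshold`.  Reverse-strand hits are reported in forward
#' coordinates (start of the occupied window).  Non-ACGT bases contribute 0
#' to the score (and trigger a single message).
#'
#' @param sequence character scalar over `ACGT` (case-insensitive).
#' @param pwm numeric matrix, 4 rows named `A`, `C`, `G`, `T`, one column
#'   per motif position, entries in log-odds units.
#' @param threshold minimum score for a hit.
#' @return data.frame with columns `position` (1-based start on the forward
#'   strand), `strand` (`+`/`-`) and `score`, ordered by position.
#' @export
pwmScan <- function(sequence, pwm, threshold) {
  stopifnot(is.character(sequence), length(sequence) == 1,
            nrow(pwm) == 4, !is.null(rownames(pwm)))
  pwm <- pwm[c("A", "C", "G", "T"), , drop = FALSE]
  w <- ncol(pwm)
  s <- strsplit(toupper(sequence), "")[[1]]
  if (length(s) < w) stop("pwm wider than sequence")
  code <- match(s, c("A", "C", "G", "T"))
  if (anyNA(code)) message("pwmScan: non-ACGT bases score 0")
  scoreStrand <- function(mat) {
    vapply(seq_len(length(s) - w + 1L), function(i) {
      idx <- code[i:(i + w - 1L)]
      sum(mat[cbind(idx, seq_len(w))], na.rm = TRUE)
    }, numeric(1))
  }
  fwd <- scoreStrand(pwm)
  # reverse complement: complement rows, reverse columns
  rcp <- pwm[c("T", "G", "C", "A"), rev(seq_len(w)), drop = FALSE]
  rownames(rcp) <- c("A", "C", "G", "T")
  rev <- scoreStrand(rcp)
  mkHits <- function(scores, strand) {
    i <- which(scores >= threshold)
    data.frame(position = i, strand = rep(strand, length(i)),
               score = scores[i])
  }
  hits <- rbind(mkHits(fwd, "+"), mkHits(rev, "-"))
  hits[order(hits$position, hits$strand), , drop = FALSE]
}

#' Rank transcription factors by differential enhancer occupancy
#'
#' For each TF peak set, the fraction of each element set overlapped by at
#' least one peak, ranked by `frac_a - frac_b` (descending), with the
#' pooled two-proportion z statistic attached.  Empty peak sets are
#' retained with zero fractions and flagged in `note`.
#'
#' @param setA,setB `GRanges` of regulatory elements (both non-empty).
#' @param tfPeaks named list of `GRanges`, one per TF.
#' @return data.frame `tf`, `frac_a`, `frac_b`, `z`, `p.value`, `note`,
#'   ordered by decreasing `frac_a - frac_b`.
#' @export
tfOccupancyRanking <- function(setA, setB, tfPeaks) {
  stopifnot(length(setA) > 0, length(setB) > 0, length(names(tfPeaks)) > 0)
  rows <- lapply(names(tfPeaks), function(tf) {
    pk <- tfPeaks[[tf]]
    if (length(pk) == 0)
      return(data.frame(tf = tf, frac_a = 0, frac_b = 0, z = 0,
                        p.value = 1, note = "empty peak set"))
    kA <- sum(countOverlaps(setA, pk) > 0)
    kB <- sum(countOverlaps(setB, pk) > 0)
    zt <- suppressMessages(
      twoProportionZ(kA, length(setA), kB, length(setB)))
    data.frame(tf = tf, frac_a = kA / length(setA), frac_b = kB / length(setB),
               z = zt$z, p.value = zt$p.value, note = "")
  })
  out <- do.call(rbind, rows)
  out[order(out$frac_a - out$frac_b, decreasing = TRUE), , drop = FALSE]
}

#' Expand lead SNPs with their LD satellites
#'
#' Returns lead SNPs plus satellites whose `r2` with a retained lead is at
#' least `r2Min`; satellites inherit the lead's `trait_class`.  A satellite
#' citing an unknown lead is an error in strict mode (dropped with a
#' message otherwise).
#'
#' @param snps SNP data.frame (see [readSnpTable()]): leads have
#'   `lead_rsid = NA`, satellites carry `lead_rsid` and `r2`.
#' @param r2Min linkage-disequilibrium threshold in `[0, 1]`.
#' @param strict error on unknown leads.
#' @return SNP data.frame subset with inherited `trait_class`.
#' @export
expandLd <- function(snps, r2Min = 0.8, strict = TRUE) {
  lead <- snps[is.na(snps$lead_rsid), , drop = FALSE]
  sat <- snps[!is.na(snps$lead_rsid), , drop = FALSE]
  unknown <- !sat$lead_rsid %in% lead$rsid
  if (any(unknown)) {
    if (strict)
      stop("satellite SNP(s) citing unknown lead: ",
           paste(head(sat$rsid[unknown], 5), collapse = ", "))
    message("expandLd: dropped ", sum(unknown), " satellite(s) with unknown lead")
    sat <- sat[!unknown, , drop = FALSE]
  }
  sat <- sat[sat$r2 >= r2Min, , drop = FALSE]
  sat$trait_class <- lead$trait_class[match(sat$lead_rsid, lead$rsid)]
  rbind(lead, sat)
}

#' Hypergeometric SNP enrichment in a set of regulatory elements
#'
#' Element-level counting: the universe is the full element set (`N`), the
#' universe positives are elements containing at least one SNP (`K`), and
#' the test asks whether the `n` target elements contain SNP-hit elements
#' (`k`) more often than chance.  The target must be a subset of the
#' universe.
#'
#' @param snps `GRanges` of SNP positions (see [snpsToGRanges()]).
#' @param target,universe element `GRanges`; every target element must
#'   occur (identical coordinates) in the universe.
#' @return list with `k`, `n`, `K`, `N` and `p.value` from
#'   [hypergeometricTail()].
#' @export
snpElementEnrichment <- function(snps, target, universe) {
  inUniverse <- countOverlaps(target, universe, type = "equal") > 0
  if (!all(inUniverse))
    stop("target elements must be a subset of the universe")
  hit <- function(el) sum(countOverlaps(el, snps) > 0)
  N <- length(universe); K <- hit(universe)
  n <- length(target); k <- hit(target)
  list(k = k, n = n, K = K, N = N,
       p.value = hypergeometricTail(N, K, n, k))
}

#' Benjamini-Hochberg adjustment helper
#'
#' Thin wrapper over [stats::p.adjust()] applied only when more than
#' `minTests` simultaneous tests are reported (raw p-values are returned
#' otherwise, matching single-test reporting).
#'
#' @param p numeric vector of p-values.
#' @param minTests apply BH only above this count.
#' @return adjusted (or raw) p-values.
#' @export
adjustBH <- function(p, minTests = 10L) {
  if (length(p) > minTests) p.adjust(p, method = "BH") else p
}
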