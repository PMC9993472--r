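#' Extract promoter-promoter gene pairs from the network
#'
#' Unordered pairs of distinct genes joined by promoter-promoter edges.
#' By default `Ep-P` and `Ep-Ep` edges count (an enhancer-like promoter is
#' still a promoter); set `includeEp = FALSE` to restrict to strong `P-P`
#' edges.
#'
#' @param network an [EPNetwork-class].
#' @param includeEp include edges involving enhancer-like promoters.
#' @return data.frame `gene_a`, `gene_b` (lexicographically ordered,
#'   deduplicated; self-pairs excluded).
#' @export
extractPPPairs <- function(network, includeEp = TRUE) {
  nodes <- as.data.frame(networkNodes(network))
  edges <- as.data.frame(networkEdges(network)[, c("node_a", "node_b", "type")])
  types <- if (includeEp) c("P-P", "Ep-P", "Ep-Ep") else "P-P"
  geneOf <- setNames(nodes$gene_id, nodes$node)
  pp <- edges[edges$type %in% types, , drop = FALSE]
  if (!nrow(pp))
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  ga <- unname(geneOf[pp$node_a]); gb <- unname(geneOf[pp$node_b])
  keep <- !is.na(ga) & !is.na(gb) & ga != gb
  ga <- ga[keep]; gb <- gb[keep]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  unique(data.frame(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE))
}

#' Pearson correlation of gene pairs across an expression panel
#'
#' Standard Pearson r per pair over panel samples, plus the fraction of
#' pairs exceeding `rMin` (the co-transcription call).  Pairs involving a
#' zero-variance gene have undefined r and are excluded from the fraction
#' denominator (with a message).
#'
#' @param pairs data.frame `gene_a`, `gene_b` (see [extractPPPairs()]).
#' @param panel genes x samples abundance matrix with >= 3 samples.
#' @param rMin correlation cutoff for calling a pair co-transcribed.
#' @return list: `correlations` (data.frame `gene_a`, `gene_b`, `r`,
#'   `n_samples`) and `fractionCorrelated`.
#' @export
pairPearson <- function(pairs, panel, rMin = 0.25) {
  stopifnot(ncol(panel) >= 3)
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), rownames(panel))
  if (length(missing))
    stop("pair gene(s) absent from panel: ", paste(head(missing, 5),
                                                   collapse = ", "))
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- panel[pairs$gene_a[i], ]; b <- panel[pairs$gene_b[i], ]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  if (anyNA(r))
    message("pairPearson: ", sum(is.na(r)),
            " pair(s) with a zero-variance gene excluded from the fraction")
  list(correlations = data.frame(pairs, r = r, n_samples = ncol(panel)),
       fractionCorrelated = mean(r[!is.na(r)] > rMin))
}

#' Degree-preserving rewired null for pair co-expression
#'
#' Each permutation draws a random perfect rematching of the multiset of
#' genes appearing in the observed pairs (every gene keeps its pairing
#' multiplicity), rejecting matchings that contain a self-pair or an
#' observed pair.  The empirical p-value for the observed mean Pearson r
#' uses the permutation-inclusive estimator
#' `(1 + #\{null >= observed\}) / (nPerm + 1)`.  With `mode = "free"` the
#' degree constraint is dropped: pairs are drawn uniformly from distinct
#' genes of the paired set.
#'
#' @param pairs observed gene pairs (>= 2 rows).
#' @param panel genes x samples abundance matrix.
#' @param nPerm number of permutations (> 0).
#' @param seed integer RNG seed; identical seeds give identical null
#'   distributions.
#' @param mode `"degree"` (default) or `"free"`.
#' @param maxTries rejection-sampling cap per permutation before erroring
#'   as infeasible.
#' @param returnMatchings also return every permuted pairing (for
#'   auditing the degree constraint; memory-proportional to `nPerm`).
#' @return list: `observedMean`, `null` (numeric vector of permuted mean
#'   r), `p.value`, and optionally `matchings`.
#' @export
rewiredNull <- function(pairs, panel, nPerm = 1000L, seed = 1L,
                        mode = c("degree", "free"), maxTries = 1000L,
                        returnMatchings = FALSE) {
  mode <- match.arg(mode)
  if (nPerm < 1) stop("nPerm must be >= 1 (null undefined)")
  if (nrow(pairs) < 2) stop("need >= 2 pairs for a rewired null")
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  if (length(genes) < 3)
    stop("rematching impossible: fewer than 3 distinct genes")
  sub <- panel[genes, , drop = FALSE]
  ok <- apply(sub, 1, sd) > 0
  cm <- matrix(NA_real_, length(genes), length(genes),
               dimnames = list(genes, genes))
  if (sum(ok) >= 2)
    cm[ok, ok] <- suppressWarnings(cor(t(sub[ok, , drop = FALSE])))
  pairR <- function(a, b) cm[cbind(a, b)]
  obs <- pairR(pairs$gene_a, pairs$gene_b)
  observedMean <- mean(obs, na.rm = TRUE)
  obsKey <- paste(pmin(pairs$gene_a, pairs$gene_b),
                  pmax(pairs$gene_a, pairs$gene_b))
  multiset <- c(rbind(pairs$gene_a, pairs$gene_b))
  nP <- nrow(pairs)
  set.seed(as.integer(seed))
  matchings <- if (returnMatchings) vector("list", nPerm) else NULL
  null <- numeric(nPerm)
  for (p in seq_len(nPerm)) {
    done <- FALSE
    for (t in seq_len(maxTries)) {
      if (mode == "free") {
        a <- sample(genes, nP, replace = TRUE)
        b <- sample(genes, nP, replace = TRUE)
      } else {
        perm <- sample(multiset)
        a <- perm[seq(1, 2 * nP, 2)]; b <- perm[seq(2, 2 * nP, 2)]
      }
      key <- paste(pmin(a, b), pmax(a, b))
      if (any(a == b) || any(key %in% obsKey)) next
      null[p] <- mean(pairR(a, b), na.rm = TRUE)
      if (returnMatchings)
        matchings[[p]] <- data.frame(gene_a = a, gene_b = b,
                                     stringsAsFactors = FALSE)
      done <- TRUE
      break
    }
    if (!done)
      stop("rewiredNull: no valid rematching found in ", maxTries, " tries")
  }
  out <- list(observedMean = observedMean, null = null,
              p.value = (1 + sum(null >= observedMean)) / (nPerm + 1))
  if (returnMatchings) out$matchings <- matchings
  out
}
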