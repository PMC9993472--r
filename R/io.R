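#' @importFrom utils read.table write.table head tail
NULL

# Split a tab-separated text file into a character matrix, keeping the
# original 1-based line number of every record.  '#' comment lines and
# blank lines are ignored.
readRecords <- function(path, nFieldsMin) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lineNo <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]; lineNo <- lineNo[keep]
  if (!length(lines))
    return(list(fields = list(), lineNo = integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < nFieldsMin
  if (any(short))
    stop(sprintf("%s:%d: expected >= %d tab-separated fields",
                 path, lineNo[which(short)[1]], nFieldsMin))
  list(fields = fields, lineNo = lineNo)
}

# Apply per-record problems in strict (error at first offending line) or
# lenient (drop with a message counting skips) mode.  `problems` is a
# character vector with NA for valid records.
applyStrictness <- function(problems, path, lineNo, strict) {
  bad <- !is.na(problems)
  if (!any(bad)) return(!bad)
  if (strict) {
    i <- which(bad)[1]
    stop(sprintf("%s:%d: %s", path, lineNo[i], problems[i]))
  }
  message(sprintf("%s: skipped %d malformed record(s)", path, sum(bad)))
  !bad
}

num <- function(x) suppressWarnings(as.numeric(x))
int <- function(x) suppressWarnings(as.integer(x))

#' Read and write peak files (BED4+score)
#'
#' Columns: chrom, start, end, name, score; 0-based half-open coordinates,
#' tab-separated, `#` comments ignored.  `score` is the peak intensity
#' (non-negative signal units).
#'
#' @param path file path.
#' @param factorName the protein/histone factor the peaks belong to (e.g.
#'   `"H3K4me1"`, `"CTCF"`); stored in `mcols()$factor`.
#' @param strict if `TRUE` (default) any record violating an invariant is an
#'   error naming file and line; if `FALSE` offending records are skipped
#'   with a message.
#' @return `readBed()`: a `GRanges` with metadata columns `name`,
#'   `intensity`, `factor`.  `writeBed()` returns `path` invisibly;
#'   `writeBed()` then `readBed()` is the identity on canonical records.
#' @export
readBed <- function(path, factorName = NA_character_, strict = TRUE) {
  rec <- readRecords(path, 5L)
  if (!length(rec$fields)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(name = character(), intensity = numeric(),
                           factor = character())
    return(gr)
  }
  m <- do.call(rbind, lapply(rec$fields, `[`, 1:5))
  chrom <- m[, 1]; s <- num(m[, 2]); e <- num(m[, 3])
  name <- m[, 4]; score <- num(m[, 5])
  problems <- rep(NA_character_, nrow(m))
  problems[is.na(s) | is.na(e) | is.na(score)] <- "non-numeric coordinate or score"
  ok <- is.na(problems)
  problems[ok & (s < 0 | e <= s)] <- "invalid interval (need 0 <= start < end)"
  ok <- is.na(problems)
  problems[ok & score < 0] <- "negative intensity"
  problems[chrom == ""] <- "empty chromosome name"
  keep <- applyStrictness(problems, path, rec$lineNo, strict)
  gr <- bedToGRanges(chrom[keep], s[keep], e[keep])
  mcols(gr) <- DataFrame(name = name[keep], intensity = score[keep],
                         factor = rep(factorName, sum(keep)))
  gr
}

#' @rdname readBed
#' @param peaks a `GRanges` with `name` and `intensity` metadata columns
#'   (missing columns are filled with defaults).
#' @export
writeBed <- function(peaks, path) {
  bed <- grangesToBed(peaks)
  bed$name <- if ("name" %in% colnames(mcols(peaks))) mcols(peaks)$name
              else sprintf("pk%d", seq_along(peaks))
  bed$score <- if ("intensity" %in% colnames(mcols(peaks)))
                 mcols(peaks)$intensity else 0
  writeTsv(bed, path)
}

#' Read a gene table (BED6, gene_id in the name column)
#'
#' Columns: chrom, start, end, gene_id, score, strand.  Strand must be
#' `+` or `-`; the TSS is derived from strand by [tssSites()].
#'
#' @inheritParams readBed
#' @return stranded `GRanges` with metadata column `gene_id`.
#' @export
readGeneTable <- function(path, strict = TRUE) {
  rec <- readRecords(path, 6L)
  if (!length(rec$fields)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(gene_id = character())
    return(gr)
  }
  m <- do.call(rbind, lapply(rec$fields, `[`, 1:6))
  s <- num(m[, 2]); e <- num(m[, 3])
  problems <- rep(NA_character_, nrow(m))
  problems[is.na(s) | is.na(e)] <- "non-numeric coordinate"
  ok <- is.na(problems)
  problems[ok & (s < 0 | e <= s)] <- "invalid interval (need 0 <= start < end)"
  problems[!m[, 6] %in% c("+", "-")] <- "gene strand must be + or -"
  problems[duplicated(m[, 4])] <- "duplicate gene_id"
  keep <- applyStrictness(problems, path, rec$lineNo, strict)
  gr <- bedToGRanges(m[keep, 1], s[keep], e[keep], strand = m[keep, 6])
  mcols(gr) <- DataFrame(gene_id = m[keep, 4])
  names(gr) <- m[keep, 4]
  gr
}

#' @rdname readGeneTable
#' @param genes stranded `GRanges` with `gene_id`.
#' @export
writeGeneTable <- function(genes, path) {
  bed <- grangesToBed(genes)
  bed$name <- mcols(genes)$gene_id
  bed$score <- 0
  bed$strand <- as.character(strand(genes))
  writeTsv(bed, path)
}

#' Read and write loop files (BEDPE)
#'
#' Seven mandatory columns (chromA, startA, endA, chromB, startB, endB,
#' pet_count) plus an optional eighth factor column.  Coordinates are BED
#' 0-based half-open.  Inter-chromosomal records violate the intra-
#' chromosomal loop invariant: they are an error in strict mode and skipped
#' (with a count message) in lenient mode.  Anchors are put in canonical
#' order on read.
#'
#' @inheritParams readBed
#' @param factorName default factor when the file has no 8th column.
#' @return `readBedpe()`: a [LoopSet-class].
#' @export
readBedpe <- function(path, factorName = "RNAPII", strict = TRUE) {
  rec <- readRecords(path, 7L)
  if (!length(rec$fields))
    return(LoopSet(GRanges(), GRanges()))
  nf <- vapply(rec$fields, length, 1L)
  m <- do.call(rbind, lapply(rec$fields, function(f) f[1:7]))
  fac <- ifelse(nf >= 8L,
                vapply(rec$fields, function(f) f[min(8L, length(f))], ""),
                factorName)
  sA <- num(m[, 2]); eA <- num(m[, 3]); sB <- num(m[, 5]); eB <- num(m[, 6])
  pet <- int(m[, 7])
  problems <- rep(NA_character_, nrow(m))
  problems[is.na(sA) | is.na(eA) | is.na(sB) | is.na(eB) | is.na(pet)] <-
    "non-numeric field"
  ok <- is.na(problems)
  problems[ok & (sA < 0 | eA <= sA | sB < 0 | eB <= sB)] <-
    "invalid anchor interval"
  ok <- is.na(problems)
  problems[ok & pet < 1L] <- "pet_count must be >= 1"
  ok <- is.na(problems)
  problems[ok & m[, 1] != m[, 4]] <- "inter-chromosomal loop"
  keep <- applyStrictness(problems, path, rec$lineNo, strict)
  LoopSet(bedToGRanges(m[keep, 1], sA[keep], eA[keep]),
          bedToGRanges(m[keep, 4], sB[keep], eB[keep]),
          petCount = pet[keep], loopFactor = fac[keep])
}

#' @rdname readBedpe
#' @param loops a [LoopSet-class].
#' @export
writeBedpe <- function(loops, path) {
  a <- grangesToBed(anchorOne(loops)); b <- grangesToBed(anchorTwo(loops))
  df <- data.frame(a$chrom, a$start, a$end, b$chrom, b$start, b$end,
                   petCount(loops), loopFactor(loops))
  writeTsv(df, path)
}

#' Read a bedGraph signal track
#'
#' Four columns: chrom, start, end, value (BED coordinates).  Overlapping
#' intervals are rejected per chromosome in strict mode since the track must
#' be piecewise constant.
#'
#' @inheritParams readBed
#' @return `GRanges` with numeric `score` column.
#' @export
readBedGraph <- function(path, strict = TRUE) {
  rec <- readRecords(path, 4L)
  if (!length(rec$fields)) {
    gr <- GRanges(); mcols(gr) <- DataFrame(score = numeric()); return(gr)
  }
  m <- do.call(rbind, lapply(rec$fields, `[`, 1:4))
  s <- num(m[, 2]); e <- num(m[, 3]); v <- num(m[, 4])
  problems <- rep(NA_character_, nrow(m))
  problems[is.na(s) | is.na(e) | is.na(v)] <- "non-numeric field"
  ok <- is.na(problems)
  problems[ok & (s < 0 | e <= s)] <- "invalid interval"
  keep <- applyStrictness(problems, path, rec$lineNo, strict)
  gr <- bedToGRanges(m[keep, 1], s[keep], e[keep])
  mcols(gr) <- DataFrame(score = v[keep])
  gr
}

#' @rdname readBedGraph
#' @param track `GRanges` with a `score` column.
#' @export
writeBedGraph <- function(track, path) {
  bed <- grangesToBed(track)
  bed$value <- mcols(track)$score
  writeTsv(bed, path)
}

#' Read a per-CpG methylation table
#'
#' Columns: chrom, pos (0-based), count_meth, count_total.  Invariants:
#' `count_total >= 1` and `count_meth <= count_total`; the beta value
#' `count_meth / count_total` is computed on read.
#'
#' @inheritParams readBed
#' @return width-1 `GRanges` with metadata `count_meth`, `count_total`,
#'   `beta`.
#' @export
readMethylationTable <- function(path, strict = TRUE) {
  rec <- readRecords(path, 4L)
  if (!length(rec$fields)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(count_meth = integer(), count_total = integer(),
                           beta = numeric())
    return(gr)
  }
  m <- do.call(rbind, lapply(rec$fields, `[`, 1:4))
  pos <- num(m[, 2]); cm <- int(m[, 3]); ct <- int(m[, 4])
  problems <- rep(NA_character_, nrow(m))
  problems[is.na(pos) | is.na(cm) | is.na(ct)] <- "non-numeric field"
  ok <- is.na(problems)
  problems[ok & pos < 0] <- "negative position"
  ok <- is.na(problems)
  problems[ok & (ct < 1L | cm < 0L | cm > ct)] <-
    "need 0 <= count_meth <= count_total, count_total >= 1"
  keep <- applyStrictness(problems, path, rec$lineNo, strict)
  gr <- bedToGRanges(m[keep, 1], pos[keep], pos[keep] + 1)
  mcols(gr) <- DataFrame(count_meth = cm[keep], count_total = ct[keep],
                         beta = cm[keep] / ct[keep])
  gr
}

#' @rdname readMethylationTable
#' @param cpgs width-1 `GRanges` with `count_meth`, `count_total`.
#' @export
writeMethylationTable <- function(cpgs, path) {
  df <- data.frame(chrom = as.character(seqnames(cpgs)),
                   pos = start(cpgs) - 1L,
                   count_meth = mcols(cpgs)$count_meth,
                   count_total = mcols(cpgs)$count_total)
  writeTsv(df, path)
}

#' Read a SNP table with LD annotation
#'
#' Columns: rsid, chrom, pos (0-based), trait_class, lead_rsid, r2.  Lead
#' SNPs carry `.` (or empty) in `lead_rsid`/`r2`; LD satellites must carry
#' both (the r2-iff-lead invariant).  `trait_class` is one of
#' `cancer_related`, `normal_function`, `other`.
#'
#' @inheritParams readBed
#' @return data.frame with columns `rsid`, `chrom`, `pos`, `trait_class`,
#'   `lead_rsid` (NA for leads), `r2` (NA for leads).
#' @export
readSnpTable <- function(path, strict = TRUE) {
  rec <- readRecords(path, 6L)
  empty <- data.frame(rsid = character(), chrom = character(),
                      pos = numeric(), trait_class = character(),
                      lead_rsid = character(), r2 = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(rec$fields)) return(empty)
  m <- do.call(rbind, lapply(rec$fields, `[`, 1:6))
  pos <- num(m[, 2 + 1])
  lead <- m[, 5]; lead[lead %in% c(".", "")] <- NA
  r2 <- m[, 6]; r2[r2 %in% c(".", "")] <- NA
  r2 <- num(r2)
  problems <- rep(NA_character_, nrow(m))
  problems[is.na(pos) | pos < 0] <- "invalid position"
  problems[!m[, 4] %in% c("cancer_related", "normal_function", "other")] <-
    "unknown trait_class"
  problems[is.na(lead) != is.na(r2)] <- "r2 must be present iff lead_rsid is"
  ok <- is.na(problems)
  problems[ok & !is.na(r2) & (r2 < 0 | r2 > 1)] <- "r2 outside [0,1]"
  keep <- applyStrictness(problems, path, rec$lineNo, strict)
  data.frame(rsid = m[keep, 1], chrom = m[keep, 2], pos = pos[keep],
             trait_class = m[keep, 4], lead_rsid = lead[keep],
             r2 = r2[keep], stringsAsFactors = FALSE)
}

#' @rdname readSnpTable
#' @param snps SNP data.frame as returned by `readSnpTable()`.
#' @export
writeSnpTable <- function(snps, path) {
  df <- snps
  df$lead_rsid[is.na(df$lead_rsid)] <- "."
  df$r2 <- ifelse(is.na(df$r2), ".", format(df$r2, trim = TRUE))
  writeTsv(df, path)
}

#' SNPs as width-1 GRanges
#' @param snps SNP data.frame (see [readSnpTable()]).
#' @return `GRanges` with `rsid` and `trait_class` metadata.
#' @export
snpsToGRanges <- function(snps) {
  gr <- bedToGRanges(snps$chrom, snps$pos, snps$pos + 1)
  mcols(gr) <- DataFrame(rsid = snps$rsid, trait_class = snps$trait_class)
  gr
}

#' Read and write expression tables
#'
#' Tab-separated matrix: header row of sample labels, each following row a
#' gene_id and its non-negative abundances (TPM/RPKM).  Row labels must be
#' unique; negative values are invariant violations.
#'
#' @inheritParams readBed
#' @return numeric matrix, genes x samples, gene_ids as rownames.
#' @export
readExpressionTable <- function(path, strict = TRUE) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   row.names = NULL, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop(path, ": expression table needs gene_id + >=1 sample")
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  problems <- rep(NA_character_, nrow(mat))
  problems[apply(mat, 1, function(r) any(is.na(r) | r < 0))] <-
    "negative or missing abundance"
  problems[duplicated(ids)] <- "duplicate gene_id"
  keep <- applyStrictness(problems, path, seq_len(nrow(mat)) + 1L, strict)
  mat <- mat[keep, , drop = FALSE]
  rownames(mat) <- ids[keep]
  mat
}

#' @rdname readExpressionTable
#' @param expr genes x samples numeric matrix with rownames.
#' @export
writeExpressionTable <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  writeTsv(df, path, col.names = TRUE)
}

# Fixed-format TSV writer: no quoting, no scientific notation, '.' never
# localised -- guarantees byte-identical output for identical input.
writeTsv <- function(df, path, col.names = FALSE) {
  old <- options(scipen = 15); on.exit(options(old))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = col.names)
  invisible(path)
}
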