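#' @importFrom jsonlite write_json read_json
#' @importFrom yaml read_yaml
NULL

runConfigDefaults <- function() {
  list(
    flank = 2000, log2fcMin = 2, minLevel = 1, pseudocount = 0.1,
    breadthThreshold = 1, breadthMax = 0.2, mergeGap = 0, eps = 0.1,
    rMin = 0.25, nPerm = 1000, mMin = 1, minCov = 5, deltaMin = 0.25,
    qMax = 0.05, r2Min = 0.8, seed = 1, strict = TRUE)
}

runConfigPathKeys <- function() {
  c("genes", "expressionStates", "expressionPanel",
    "loopsRnapiiA", "loopsRnapiiB", "loopsCtcfA", "loopsCtcfB",
    "peaksRnapiiA", "peaksRnapiiB", "peaksMe1A", "peaksMe1B",
    "peaksK27acA", "peaksK27acB", "peaksK27me3A", "peaksK27me3B",
    "peaksCtcfA", "peaksCtcfB",
    "signalMe3A", "signalMe3B", "signalMe1A", "signalMe1B",
    "methylationA", "methylationB", "snps")
}

#' Validate a pipeline run configuration
#'
#' Checks the schema (unknown keys are problems), parameter domains, and
#' that every referenced input path exists.  Data contents are never
#' touched.  All problems are collected and returned together, not just
#' the first.
#'
#' @param config a named list, or the path of a YAML/JSON file holding
#'   one.  Recognised keys: `inputs` (named list of file paths, see the
#'   conventional names in [bundleRunConfig()]), `outDir`, and the stage
#'   parameters of [runConfigDefaults()].
#' @return character vector of problems; empty when valid.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) return(paste("config file not found:", config))
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
      else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  problems <- character()
  known <- c("inputs", "outDir", names(runConfigDefaults()))
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    problems <- c(problems, paste("unknown key:", unknown))
  if (is.null(config$outDir))
    problems <- c(problems, "missing key: outDir")
  pos <- c("flank", "minLevel", "nPerm", "minCov", "mMin", "log2fcMin")
  for (k in pos) {
    v <- config[[k]]
    if (!is.null(v) && (!is.numeric(v) || v <= 0))
      problems <- c(problems, paste0(k, " must be a positive number"))
  }
  frac <- c("breadthMax", "rMin", "deltaMin", "qMax", "r2Min")
  for (k in frac) {
    v <- config[[k]]
    if (!is.null(v) && (!is.numeric(v) || v < 0 || v > 1))
      problems <- c(problems, paste0(k, " must lie in [0, 1]"))
  }
  unknownIn <- setdiff(names(config$inputs), runConfigPathKeys())
  if (length(unknownIn))
    problems <- c(problems, paste("unknown input key:", unknownIn))
  for (k in names(config$inputs)) {
    p <- config$inputs[[k]]
    if (!file.exists(p))
      problems <- c(problems, paste0("input '", k, "' not found: ", p))
  }
  problems
}

#' Run configuration for a written synthetic bundle
#'
#' Maps the conventional file names emitted by [writeBundle()] to the
#' input keys of [runPipeline()].
#'
#' @param bundleDir directory written by [writeBundle()].
#' @param outDir output directory for pipeline results.
#' @param ... stage-parameter overrides (see [runConfigDefaults()]).
#' @return a config list accepted by [validateRunConfig()]/[runPipeline()].
#' @export
bundleRunConfig <- function(bundleDir, outDir, ...) {
  f <- function(x) file.path(bundleDir, x)
  inputs <- list(
    genes = f("genes.bed"),
    expressionStates = f("expression_states.tsv"),
    expressionPanel = f("expression_panel.tsv"),
    loopsRnapiiA = f("loops_RNAPII_A.bedpe"),
    loopsRnapiiB = f("loops_RNAPII_B.bedpe"),
    loopsCtcfA = f("loops_CTCF_A.bedpe"),
    loopsCtcfB = f("loops_CTCF_B.bedpe"),
    peaksRnapiiA = f("peaks_RNAPII_A.bed"),
    peaksRnapiiB = f("peaks_RNAPII_B.bed"),
    peaksMe1A = f("peaks_H3K4me1_A.bed"),
    peaksMe1B = f("peaks_H3K4me1_B.bed"),
    peaksK27acA = f("peaks_H3K27ac_A.bed"),
    peaksK27acB = f("peaks_H3K27ac_B.bed"),
    peaksK27me3A = f("peaks_H3K27me3_A.bed"),
    peaksK27me3B = f("peaks_H3K27me3_B.bed"),
    peaksCtcfA = f("peaks_CTCF_A.bed"),
    peaksCtcfB = f("peaks_CTCF_B.bed"),
    signalMe3A = f("signal_H3K4me3_A.bedgraph"),
    signalMe3B = f("signal_H3K4me3_B.bedgraph"),
    signalMe1A = f("signal_H3K4me1_A.bedgraph"),
    signalMe1B = f("signal_H3K4me1_B.bedgraph"),
    methylationA = f("methylation_A.tsv"),
    methylationB = f("methylation_B.tsv"),
    snps = f("snps.tsv"))
  c(list(inputs = inputs, outDir = outDir), list(...))
}

#' Run the integrative pipeline end to end
#'
#' Executes the stages in dependency order — input parsing, specificity
#' calls and breadth, loop clustering into domains, enhancer definition
#' and promoter strength, network construction, co-transcription and SNP
#' enrichment, differential CTCF binding, region methylation and DMC
#' calling — writing one TSV per stage plus a JSON run report.  Stages
#' whose inputs are absent from `config$inputs` are skipped and noted in
#' the report.  Identical config and seed give byte-identical stage
#' outputs.
#'
#' @param config a config list or YAML/JSON path (see
#'   [validateRunConfig()]); validation failure is an error listing every
#'   problem.
#' @return the run report (named list, also written to
#'   `<outDir>/report.json`), with per-stage record counts, parameters in
#'   force, output paths, wall time and warnings.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    path <- config
    config <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
      else jsonlite::read_json(path, simplifyVector = TRUE)
  }
  problems <- validateRunConfig(config)
  if (length(problems))
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "))
  prm <- utils::modifyList(runConfigDefaults(),
                           config[setdiff(names(config),
                                          c("inputs", "outDir"))])
  ins <- config$inputs
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = prm, stages = list())
  t0 <- proc.time()[["elapsed"]]
  note <- function(stage, n, path = NA_character_, warnings = character()) {
    report$stages[[stage]] <<- list(
      n_records = n, output = path,
      warnings = if (length(warnings)) warnings else character())
    message(sprintf("[%s] %d record(s)%s", stage, n,
                    if (!is.na(path)) paste0(" -> ", path) else ""))
  }
  outTsv <- function(df, fname) {
    p <- file.path(outDir, fname)
    if (is.null(df)) df <- data.frame(empty = character())
    writeTsv(df, p, col.names = TRUE)
    p
  }
  has <- function(...) all(c(...) %in% names(ins))
  strict <- isTRUE(prm$strict)

  ## io
  genes <- readGeneTable(ins$genes, strict = strict)
  note("io", length(genes))

  ## de + breadth
  expr <- readExpressionTable(ins$expressionStates, strict = strict)
  exprStates <- ifelse(grepl("^A", colnames(expr)), "A", "B")
  de <- callSpecificGenes(expr, exprStates, "A", "B",
                          log2fcMin = prm$log2fcMin,
                          minLevel = prm$minLevel,
                          pseudocount = prm$pseudocount)
  note("de", nrow(de), outTsv(de, "specific_genes.tsv"))
  panel <- readExpressionTable(ins$expressionPanel, strict = strict)
  breadth <- expressionBreadth(panel, prm$breadthThreshold, prm$breadthMax)
  note("breadth", nrow(breadth), outTsv(breadth, "expression_breadth.tsv"))
  specA <- de$gene_id[de$call == "a_specific"]
  specB <- de$gene_id[de$call == "b_specific"]

  ## domains per state and factor
  domainRows <- list()
  for (st in c("A", "B")) {
    specHere <- if (st == "A") specA else specB
    for (fac in c("Rnapii", "Ctcf")) {
      key <- paste0("loops", fac, st)
      if (!has(key)) next
      loops <- readBedpe(ins[[key]], factorName = toupper(fac),
                         strict = strict)
      dom <- clusterDomains(loops, mergeGap = prm$mergeGap)
      asg <- assignGenesToDomains(dom$domains, genes, specHere)
      df <- data.frame(state = st, grangesToBed(dom$domains),
                       domain_id = mcols(dom$domains)$domain_id,
                       factor = mcols(dom$domains)$factor,
                       n_loops = mcols(dom$domains)$n_loops,
                       gene_class = unname(
                         asg$geneClass[mcols(dom$domains)$domain_id]),
                       stringsAsFactors = FALSE)
      domainRows[[paste0(fac, st)]] <- df
    }
  }
  domainsAll <- do.call(rbind, domainRows)
  note("domains", if (is.null(domainsAll)) 0L else nrow(domainsAll),
       outTsv(domainsAll, "domains.tsv"))

  ## elements + epnet + cotx per state
  networkRows <- list(); cotx <- list(); elementRows <- list()
  for (st in c("A", "B")) {
    need <- paste0(c("loopsRnapii", "peaksMe1", "signalMe3", "signalMe1"), st)
    if (!has(need)) next
    loops <- readBedpe(ins[[paste0("loopsRnapii", st)]], "RNAPII",
                       strict = strict)
    me1 <- readBed(ins[[paste0("peaksMe1", st)]], "H3K4me1", strict = strict)
    k27ac <- if (has(paste0("peaksK27ac", st)))
      readBed(ins[[paste0("peaksK27ac", st)]], "H3K27ac", strict = strict)
      else GRanges()
    k27me3 <- if (has(paste0("peaksK27me3", st)))
      readBed(ins[[paste0("peaksK27me3", st)]], "H3K27me3", strict = strict)
      else GRanges()
    me3T <- readBedGraph(ins[[paste0("signalMe3", st)]], strict = strict)
    me1T <- readBedGraph(ins[[paste0("signalMe1", st)]], strict = strict)
    enh <- defineEnhancers(me1, k27ac, k27me3, genes, loops,
                           flank = prm$flank)
    strengths <- promoterStrength(genes, me3T, me1T, flank = prm$flank,
                                  eps = prm$eps)
    annoOne <- annotateAnchors(anchorOne(loops), genes, strengths, enh,
                               flank = prm$flank)
    annoTwo <- annotateAnchors(anchorTwo(loops), genes, strengths, enh,
                               flank = prm$flank)
    net <- buildEPNetwork(loops, annoOne, annoTwo)
    elementRows[[st]] <- data.frame(state = st, grangesToBed(enh),
                                    element_id = mcols(enh)$element_id,
                                    enh_state = mcols(enh)$state,
                                    stringsAsFactors = FALSE)
    ed <- as.data.frame(networkEdges(net)[, c("node_a", "node_b", "type",
                                              "n_loops")])
    networkRows[[st]] <- data.frame(state = st, ed, stringsAsFactors = FALSE)
    pairs <- extractPPPairs(net)
    if (nrow(pairs) >= 2) {
      pc <- pairPearson(pairs, panel, rMin = prm$rMin)
      rn <- rewiredNull(pairs, panel, nPerm = prm$nPerm, seed = prm$seed)
      cotx[[st]] <- data.frame(state = st, pc$correlations,
                               fraction_correlated = pc$fractionCorrelated,
                               rewired_p = rn$p.value,
                               stringsAsFactors = FALSE)
    }
  }
  elementsAll <- do.call(rbind, elementRows)
  note("elements", if (is.null(elementsAll)) 0L else nrow(elementsAll),
       outTsv(elementsAll, "elements.tsv"))
  netAll <- do.call(rbind, networkRows)
  note("epnet", if (is.null(netAll)) 0L else nrow(netAll),
       outTsv(netAll, "ep_network.tsv"))
  cotxAll <- do.call(rbind, cotx)
  note("cotx", if (is.null(cotxAll)) 0L else nrow(cotxAll),
       outTsv(cotxAll, "cotranscription.tsv"))

  ## SNP enrichment against the state-A enhancer set
  if (has("snps") && !is.null(elementsAll) && nrow(elementsAll)) {
    snps <- readSnpTable(ins$snps, strict = strict)
    expanded <- expandLd(snps, r2Min = prm$r2Min, strict = FALSE)
    expanded <- expanded[expanded$trait_class == "cancer_related", ,
                         drop = FALSE]
    uni <- bedToGRanges(elementsAll$chrom, elementsAll$start,
                        elementsAll$end)
    tgt <- uni[elementsAll$state == "A"]
    enr <- snpElementEnrichment(snpsToGRanges(expanded), tgt, uni)
    enrDf <- data.frame(set_label = "state_A_enhancers", k = enr$k,
                        n = enr$n, K = enr$K, N = enr$N,
                        p_value = enr$p.value)
    note("enrich-snp", 1L, outTsv(enrDf, "snp_enrichment.tsv"))
  } else note("enrich-snp", 0L, warnings = "skipped: no SNP input")

  ## differential CTCF binding + methylation + DMC
  if (has("peaksCtcfA", "peaksCtcfB")) {
    pkA <- readBed(ins$peaksCtcfA, "CTCF", strict = strict)
    pkB <- readBed(ins$peaksCtcfB, "CTCF", strict = strict)
    specGenes <- genes[mcols(genes)$gene_id %in% c(specA, specB)]
    diff <- differentialBinding(pkA, pkB, specGenes, flank = prm$flank,
                                mMin = prm$mMin, eps = prm$eps)
    diffDf <- data.frame(grangesToBed(diff), as.data.frame(mcols(diff)))
    note("ctcf-diff", nrow(diffDf), outTsv(diffDf, "ctcf_differential.tsv"))
    if (has("methylationA", "methylationB")) {
      cpgA <- readMethylationTable(ins$methylationA, strict = strict)
      cpgB <- readMethylationTable(ins$methylationB, strict = strict)
      mm <- rbind(
        data.frame(state = "A",
                   methylationInRegions(cpgA, diff, "peak_site",
                                        minCov = prm$minCov)),
        data.frame(state = "B",
                   methylationInRegions(cpgB, diff, "peak_site",
                                        minCov = prm$minCov)))
      note("methyl", nrow(mm), outTsv(mm, "region_methylation.tsv"))
      dmc <- callDmc(cpgA, cpgB, minCov = prm$minCov,
                     deltaMin = prm$deltaMin, qMax = prm$qMax)
      note("dmc", nrow(dmc), outTsv(dmc, "dmc.tsv"))
    } else {
      note("methyl", 0L, warnings = "skipped: no methylation input")
      note("dmc", 0L, warnings = "skipped: no methylation input")
    }
  } else {
    note("ctcf-diff", 0L, warnings = "skipped: no CTCF peak input")
  }

  report$wall_time_s <- round(proc.time()[["elapsed"]] - t0, 3)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
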