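#' False-positive rate of predicted genes
#'
#' Fraction of predicted ORFs without a match in the reference protein
#' set, as a percentage: `100 * (nPredicted - nMatching) / nPredicted`.
#' Tables round it to one decimal.
#'
#' @param nPredicted number of predicted ORFs (>= 1).
#' @param nMatching number of predicted ORFs matching the reference
#'   (0 <= nMatching <= nPredicted).
#' @return Percentage in \[0, 100\] (unrounded).
#' @export
falsePositiveRate <- function(nPredicted, nMatching) {
  if (any(nPredicted < 1))
    stop("FPR undefined: nPredicted must be >= 1")
  if (any(nMatching < 0) || any(nMatching > nPredicted))
    stop("nMatching must lie in [0, nPredicted]")
  100 * (nPredicted - nMatching) / nPredicted
}

#' Dataset composition table
#'
#' Per-label read counts with percentages of total and dataset sizes in
#' Mb (`count * readLength / 1e6`), plus a total row; percentages and
#' sizes are rounded to one decimal, matching the conventions of
#' sequencing-dataset summary tables.
#'
#' @param counts named numeric vector of per-label read counts.
#' @param readLength read length in bp.
#' @return A data.frame with columns `label`, `read_count`, `percent`,
#'   `read_length`, `size_mb`; the last row is the total.
#' @export
compositionTable <- function(counts, readLength) {
  if (!length(counts) || is.null(names(counts)))
    stop("counts must be a non-empty named vector")
  total <- sum(counts)
  df <- data.frame(
    label = c(names(counts), "Total"),
    read_count = c(as.numeric(counts), total),
    percent = c(round(100 * as.numeric(counts) / total, 1), 100),
    read_length = readLength,
    size_mb = round(c(as.numeric(counts), total) * readLength / 1e6, 1),
    stringsAsFactors = FALSE)
  df
}

.cfgGet <- function(cfg, section, key, default = NULL) {
  v <- cfg[[section]][[key]]
  if (is.null(v)) default else v
}

#' Run the full QC pipeline
#'
#' Executes the chained stages read-QC -> contamination screen ->
#' contaminant filter on an input read pair (or a simulated mixture),
#' writing per-stage outputs and reports into a run directory. Any
#' stage can be skipped by configuration; skipped stages pass their
#' input through unchanged and the run report notes the no-op. A rerun
#' with the same configuration and seeds produces identical reports.
#'
#' @param config a configuration list or the path of a YAML file with
#'   sections `input` (paths `r1`, `r2`) or `simulate` (arguments of
#'   [communityDesign()]/[simulateCommunity()]: `design`, `scale`,
#'   `seed`, `errorRate`, ...), and optional sections `readqc`, `screen`
#'   and `filter` mirroring the arguments of [qcParams()],
#'   [screenContamination()] and [filterContaminants()]; each section
#'   accepts `skip: true`.
#' @param outDir run directory (created; stage outputs in
#'   subdirectories).
#' @return Invisibly, a list with the per-stage results and the run
#'   summary (also written as `run_report.json`).
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  notes <- character()
  sim <- NULL
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    design <- communityDesign(sc$design %||% "genomic", scale = sc$scale)
    sim <- simulateCommunity(design,
                             errorRate = sc$errorRate %||% 0.01,
                             insertSize = sc$insertSize %||% 500L,
                             seed = sc$seed %||% 1L)
    writeSimulation(sim, file.path(outDir, "simulate"))
    r1 <- sim$r1; r2 <- sim$r2
    rrnaRefs <- sim$rrna
    genomeRefs <- sim$genomes
    target <- design$target
  } else if (!is.null(config$input)) {
    pr <- readFastqPair(config$input$r1, config$input$r2)
    r1 <- pr$r1; r2 <- pr$r2
    rrnaRefs <- .cfgGet(config, "screen", "rrna")
    genomeRefs <- .cfgGet(config, "screen", "genomes")
    target <- .cfgGet(config, "screen", "target")
  } else stop("config must provide an 'input' or 'simulate' section")

  nInput <- length(r1) + length(r2)
  summary <- list(input_reads = nInput)

  ## stage 1: read QC
  qcRes <- NULL
  if (isTRUE(.cfgGet(config, "readqc", "skip", FALSE))) {
    notes <- c(notes, "readqc: skipped (input passed through)")
  } else {
    rc <- config$readqc %||% list()
    tags <- NULL
    if (!is.null(rc$tags))
      tags <- TagSet(if (identical(rc$tags, "default")) NULL else rc$tags,
                     maxMismatches = rc$maxMismatches %||% 2L,
                     maxShift = rc$maxShift %||% 5L)
    params <- qcParams(
      targetLength = rc$targetLength %||% NA,
      endTrimQuality = rc$endTrimQuality %||% NA,
      filterQuality = rc$filterQuality %||% 20L,
      minQualityFraction = rc$minQualityFraction %||% 0,
      minLengthAfterTrim = rc$minLengthAfterTrim %||% 30L,
      removeDuplicates = rc$removeDuplicates %||% FALSE,
      tags = tags, keepPairs = rc$keepPairs %||% "both-pass",
      threads = rc$threads %||% 1L)
    qcRes <- tryCatch(processReadSet(r1, params, reads2 = r2),
                      error = function(e)
                        stop("stage 'readqc' failed: ",
                             conditionMessage(e), call. = FALSE))
    dir.create(file.path(outDir, "readqc"), showWarnings = FALSE)
    writeQCReport(qcRes$report, file.path(outDir, "readqc", "report"))
    writeFastq(qcRes$reads, file.path(outDir, "readqc", "R1.qc.fastq"))
    writeFastq(qcRes$reads2, file.path(outDir, "readqc", "R2.qc.fastq"))
    r1 <- qcRes$reads; r2 <- qcRes$reads2
    summary$readqc_removed <- as.list(removedCounts(qcRes$report))
  }
  summary$reads_after_readqc <- length(r1) + length(r2)

  ## stage 2: contamination screen
  screenRes <- NULL
  if (isTRUE(.cfgGet(config, "screen", "skip", FALSE)) ||
      (is.null(rrnaRefs) && is.null(config$screen))) {
    notes <- c(notes, "screen: skipped")
  } else {
    scn <- config$screen %||% list()
    screenRes <- tryCatch(
      screenContamination(c(r1, r2), rrnaRefs = rrnaRefs,
                          genomeRefs = genomeRefs, target = target,
                          sampleProportion = scn$sampleProportion %||% 0.001,
                          seed = scn$seed %||% 1L,
                          dominanceThreshold =
                            scn$dominanceThreshold %||% 0.02),
      error = function(e) stop("stage 'screen' failed: ",
                               conditionMessage(e), call. = FALSE))
    dir.create(file.path(outDir, "screen"), showWarnings = FALSE)
    writeScreeningTable(screenRes,
                        file.path(outDir, "screen", "profile.tsv"))
    summary$flagged_contaminants <- flaggedLabels(screenRes)
  }

  ## stage 3: contaminant filtering
  filterRes <- NULL
  if (isTRUE(.cfgGet(config, "filter", "skip", FALSE)) ||
      (is.null(config$filter) && is.null(screenRes))) {
    notes <- c(notes, "filter: skipped")
  } else {
    fl <- config$filter %||% list()
    contamRefs <- fl$contaminants
    if (is.null(contamRefs)) {
      flagged <- flaggedLabels(screenRes)
      if (!length(flagged)) {
        notes <- c(notes, "filter: no contaminants flagged; nothing removed")
      } else {
        contamRefs <- if (is.character(genomeRefs) &&
                          !is.null(names(genomeRefs)))
          genomeRefs[flagged]
        else readFastaSeqs(genomeRefs)[flagged]
      }
    } else if (is.character(contamRefs) && length(contamRefs) == 1L &&
               file.exists(contamRefs)) {
      contamRefs <- readFastaSeqs(contamRefs)
    }
    if (!is.null(contamRefs)) {
      filterRes <- tryCatch(
        filterContaminants(r1, contamRefs, reads2 = r2,
                           pairPolicy = fl$pairPolicy %||% "drop-if-either",
                           minMapFraction = fl$minMapFraction %||% 0.4),
        error = function(e) stop("stage 'filter' failed: ",
                                 conditionMessage(e), call. = FALSE))
      dir.create(file.path(outDir, "filter"), showWarnings = FALSE)
      writeFastq(filterRes$reads,
                 file.path(outDir, "filter", "R1.clean.fastq"))
      writeFastq(filterRes$reads2,
                 file.path(outDir, "filter", "R2.clean.fastq"))
      write.table(filterRes$report,
                  file.path(outDir, "filter", "removed.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      r1 <- filterRes$reads; r2 <- filterRes$reads2
      summary$contaminant_reads_removed <- sum(filterRes$report$removed)
    }
  }
  summary$clean_reads <- length(r1) + length(r2)

  if (is.null(qcRes) && is.null(filterRes)) {
    ## every stage skipped: copy the input through unchanged
    writeFastq(r1, file.path(outDir, "R1.passthrough.fastq"))
    if (!is.null(r2))
      writeFastq(r2, file.path(outDir, "R2.passthrough.fastq"))
    notes <- c(notes, "no stage ran: input copied to passthrough files")
  }

  ## clean-read composition against simulation truth, when available
  if (!is.null(sim)) {
    lab <- sim$truth$label[match(c(readIds(r1), readIds(r2)),
                                 sim$truth$read_id)]
    comp <- compositionTable(table(lab), sim$design$readLength)
    write.table(comp, file.path(outDir, "clean_composition.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summary$clean_composition <- setNames(
      as.list(comp$percent[-nrow(comp)]), comp$label[-nrow(comp)])
  }
  summary$notes <- notes
  jsonlite::write_json(summary, file.path(outDir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(readqc = qcRes, screen = screenRes, filter = filterRes,
                 reads = r1, reads2 = r2, summary = summary, sim = sim))
}
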