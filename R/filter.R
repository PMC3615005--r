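#' Map reads against a contaminant k-mer index
#'
#' Deterministic k-mer containment mapping: a read is called
#' `contaminant` when its best per-label shared-k-mer fraction reaches
#' `minMapFraction`; otherwise `clean`. Reads shorter than k map as
#' `clean` (counted in attribute `nTooShort`).
#'
#' @param reads a [ReadSet-class].
#' @param index a [KmerIndex-class] over contaminant genomes.
#' @param minMapFraction mapping threshold (default 0.4, tolerant of up
#'   to ~3 substitution errors in a 100 bp read at k = 16; see the
#'   methods vignette).
#' @param targetIndex optional [KmerIndex-class] over the target
#'   genome(s); reads reaching `minMapFraction` against both the target
#'   and a contaminant are still removed (conservative), with their
#'   count attached as attribute `nAmbiguous`.
#' @return A data.frame with one row per read: `read_id`, `verdict`
#'   ("clean"/"contaminant"), `matched_label` (`NA` when clean),
#'   `score`.
#' @export
mapReads <- function(reads, index, minMapFraction = 0.4,
                     targetIndex = NULL) {
  sm <- kmerScoreMatrix(reads, index)
  n <- nrow(sm$score)
  verdict <- rep("clean", n)
  label <- rep(NA_character_, n)
  score <- rep(0, n)
  if (n) {
    best <- max.col(sm$score, ties.method = "first")
    score <- sm$score[cbind(seq_len(n), best)]
    contam <- score >= minMapFraction & sm$nValid > 0
    verdict[contam] <- "contaminant"
    label[contam] <- colnames(sm$score)[best[contam]]
  }
  nAmb <- 0L
  if (!is.null(targetIndex) && n) {
    tm <- kmerScoreMatrix(reads, targetIndex)
    tBest <- if (ncol(tm$score)) do.call(pmax, c(as.data.frame(tm$score),
                                                 list(0))) else numeric(n)
    nAmb <- sum(verdict == "contaminant" & tBest >= minMapFraction)
  }
  structure(data.frame(read_id = if (is(reads, "ReadSet")) readIds(reads)
                                 else as.character(seq_len(n)),
                       verdict = verdict, matched_label = label,
                       score = score, stringsAsFactors = FALSE),
            nTooShort = sum(sm$nValid == 0), nAmbiguous = nAmb)
}

#' Remove reads assigned to contaminant genomes
#'
#' Maps every read (or both mates of every pair) against the contaminant
#' references and emits the clean reads in input order. For pairs, the
#' default policy `drop-if-either` removes the whole pair when either
#' mate maps to a contaminant; `drop-if-both` removes it only when both
#' do. Pair synchronization of the outputs is preserved.
#'
#' @param reads a [ReadSet-class] (mate 1 if `reads2` given).
#' @param contaminantRefs contaminant genome references: a
#'   [KmerIndex-class], a named character vector or a FASTA path.
#' @param reads2 optional mate-2 [ReadSet-class].
#' @param pairPolicy "drop-if-either" (default) or "drop-if-both".
#' @param minMapFraction mapping threshold (default 0.4).
#' @param k word length when references are given as sequences
#'   (default 16).
#' @param targetIndex optional target index passed to [mapReads()].
#' @return A list: `reads` (and `reads2`) with the clean output,
#'   `removedIds` (ids of removed reads), and `report` — a data.frame of
#'   per-label removed read counts plus a `retained` total; ambiguous
#'   and too-short counters are attached as attributes on `report`.
#' @export
filterContaminants <- function(reads, contaminantRefs, reads2 = NULL,
                               pairPolicy = "drop-if-either",
                               minMapFraction = 0.4, k = 16L,
                               targetIndex = NULL) {
  if (!pairPolicy %in% c("drop-if-either", "drop-if-both"))
    stop("pairPolicy must be 'drop-if-either' or 'drop-if-both'")
  if (is.character(contaminantRefs) && length(contaminantRefs) == 0L) {
    ## nothing to filter against: pass the input through
    report <- data.frame(label = character(), removed = numeric())
    attr(report, "retained") <- length(reads) +
      if (is.null(reads2)) 0L else length(reads2)
    attr(report, "nAmbiguous") <- 0L
    attr(report, "nTooShort") <- 0L
    return(list(reads = reads, reads2 = reads2,
                removedIds = character(), report = report,
                decisions = NULL))
  }
  index <- if (is(contaminantRefs, "KmerIndex")) contaminantRefs
           else buildKmerIndex(contaminantRefs, k)
  paired <- !is.null(reads2)
  d1 <- mapReads(reads, index, minMapFraction, targetIndex)
  if (paired) {
    if (length(reads) != length(reads2))
      stop("mate sets must have equal length")
    d2 <- mapReads(reads2, index, minMapFraction, targetIndex)
    dropPair <- if (pairPolicy == "drop-if-either")
      d1$verdict == "contaminant" | d2$verdict == "contaminant"
    else d1$verdict == "contaminant" & d2$verdict == "contaminant"
    keep <- !dropPair
    removedLabels <- c(d1$matched_label[dropPair], d2$matched_label[dropPair])
    removedIds <- c(d1$read_id[dropPair], d2$read_id[dropPair])
    out <- list(reads = reads[keep], reads2 = reads2[keep])
    retained <- 2L * sum(keep)
  } else {
    keep <- d1$verdict == "clean"
    removedLabels <- d1$matched_label[!keep]
    removedIds <- d1$read_id[!keep]
    out <- list(reads = reads[keep], reads2 = NULL)
    retained <- sum(keep)
  }
  removedLabels[is.na(removedLabels)] <- "partner_of_contaminant"
  perLabel <- table(factor(removedLabels,
                           levels = c(indexLabels(index),
                                      "partner_of_contaminant")))
  report <- data.frame(label = names(perLabel),
                       removed = as.numeric(perLabel))
  attr(report, "retained") <- retained
  attr(report, "nAmbiguous") <- attr(d1, "nAmbiguous") +
    if (paired) attr(d2, "nAmbiguous") else 0L
  attr(report, "nTooShort") <- attr(d1, "nTooShort") +
    if (paired) attr(d2, "nTooShort") else 0L
  c(out, list(removedIds = removedIds, report = report,
              decisions = d1))
}
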