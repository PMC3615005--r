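setClassUnion("TagSetOrNULL", c("TagSet", "NULL"))

#' QCParams: parameters of the read-QC stage
#'
#' See [qcParams()] for construction and defaults. Stages are applied in
#' a fixed order per read (or per pair): (1) trim to `targetLength`,
#' (2) trim low-quality bases from both ends at `endTrimQuality`,
#' (3) drop reads shorter than `minLengthAfterTrim`, (4) drop reads
#' matching a tag, (5) drop reads whose fraction of bases at or above
#' `filterQuality` is below `minQualityFraction`, (6) remove exact
#' duplicates (first occurrence kept). Each removed read is attributed
#' to its first failing stage.
#'
#' @export
setClass("QCParams",
  representation(targetLength = "integer", endTrimQuality = "integer",
                 filterQuality = "integer", minQualityFraction = "numeric",
                 minLengthAfterTrim = "integer", removeDuplicates = "logical",
                 tags = "TagSetOrNULL", keepPairs = "character",
                 threads = "integer", chunkSize = "integer"))

setValidity("QCParams", function(object) {
  inQ <- function(x) is.na(x) || (x >= 0L && x <= 93L)
  if (!inQ(object@endTrimQuality) || !inQ(object@filterQuality))
    return("quality thresholds must lie in [0, 93]")
  if (object@minQualityFraction < 0 || object@minQualityFraction > 1)
    return("minQualityFraction must lie in [0, 1]")
  if (object@minLengthAfterTrim < 1L)
    return("minLengthAfterTrim must be >= 1")
  if (!is.na(object@targetLength) &&
      object@minLengthAfterTrim > object@targetLength)
    return("configuration error: minLengthAfterTrim exceeds targetLength")
  if (!object@keepPairs %in% c("both-pass", "either-pass"))
    return("keepPairs must be 'both-pass' or 'either-pass'")
  if (object@threads < 1L) return("threads must be >= 1")
  if (object@chunkSize < 1L) return("chunkSize must be >= 1")
  TRUE
})

#' Construct read-QC parameters
#'
#' @param targetLength trim every read to its first `targetLength`
#'   bases, or `NA` (default) for no length trimming.
#' @param endTrimQuality Phred threshold for trimming maximal low-quality
#'   runs off both read ends, or `NA` (default) to skip.
#' @param filterQuality Phred threshold for the quality-fraction filter
#'   (default 20).
#' @param minQualityFraction minimum fraction of bases that must reach
#'   `filterQuality` for a read to pass (default 0; the filter is then
#'   vacuous).
#' @param minLengthAfterTrim reads shorter than this after trimming are
#'   dropped (default 30); an empty read counts as removed-by-length.
#' @param removeDuplicates drop exact duplicate reads/pairs, keeping the
#'   first occurrence (default FALSE).
#' @param tags a [TagSet-class] whose matches cause read removal, or
#'   `NULL` (default) for no tag filtering.
#' @param keepPairs pair policy: with "both-pass" (default) a pair is
#'   emitted only if both mates survive; the surviving mate of a dropped
#'   pair is accounted as removed for cause `pair_partner`. With
#'   "either-pass" a pair is emitted (both mates) if at least one mate
#'   survives.
#' @param threads number of worker processes for the chunked map over
#'   read blocks (default 1). Output is identical for any thread count.
#' @param chunkSize reads (or pairs) per processing block (default 10000).
#' @return A [QCParams-class].
#' @export
qcParams <- function(targetLength = NA, endTrimQuality = NA,
                     filterQuality = 20L, minQualityFraction = 0,
                     minLengthAfterTrim = 30L, removeDuplicates = FALSE,
                     tags = NULL, keepPairs = "both-pass", threads = 1L,
                     chunkSize = 10000L) {
  new("QCParams", targetLength = as.integer(targetLength),
      endTrimQuality = as.integer(endTrimQuality),
      filterQuality = as.integer(filterQuality),
      minQualityFraction = as.numeric(minQualityFraction),
      minLengthAfterTrim = as.integer(minLengthAfterTrim),
      removeDuplicates = isTRUE(removeDuplicates), tags = tags,
      keepPairs = keepPairs, threads = as.integer(threads),
      chunkSize = as.integer(chunkSize))
}

#' @export
setMethod("show", "QCParams", function(object) {
  cat("QCParams:\n")
  cat(sprintf("  targetLength=%s endTrimQuality=%s filterQuality=%s\n",
              object@targetLength, object@endTrimQuality,
              object@filterQuality))
  cat(sprintf("  minQualityFraction=%g minLengthAfterTrim=%d dedup=%s\n",
              object@minQualityFraction, object@minLengthAfterTrim,
              object@removeDuplicates))
  cat(sprintf("  tags=%s keepPairs=%s threads=%d\n",
              if (is.null(object@tags)) "none"
              else paste0(length(object@tags@tags), " tag(s)"),
              object@keepPairs, object@threads))
})

#' Trim reads to a fixed length
#'
#' Truncates sequence and qualities to the first `L` bases; reads
#' already at or below `L` are unchanged.
#'
#' @param reads a [ReadSet-class].
#' @param L positive target length.
#' @return The trimmed [ReadSet-class].
#' @export
trimToLength <- function(reads, L) {
  L <- as.integer(L)
  stopifnot(L >= 1L)
  s <- substr(reads@seq, 1L, L)
  q <- ifelse(is.na(reads@qual), reads@qual, substr(reads@qual, 1L, L))
  new("ReadSet", id = reads@id, seq = s, qual = q, mate = reads@mate)
}

## character-class regex matching quality chars strictly below minQ
.lowQualClass <- function(minQ)
  sprintf("[\\x21-\\x%02x]", min(0x20L + as.integer(minQ), 0x7eL))

#' Trim low-quality runs off both read ends
#'
#' Removes the maximal prefix and maximal suffix in which every base has
#' quality below `minQ`; interior bases are never removed. A read whose
#' bases are all below `minQ` becomes empty (and is then removed by the
#' minimum-length filter downstream).
#'
#' @param reads a [ReadSet-class] with qualities.
#' @param minQ Phred threshold; bases with quality < `minQ` are
#'   trimmable.
#' @return The trimmed [ReadSet-class].
#' @export
trimQualityEnds <- function(reads, minQ) {
  if (length(reads) && !hasQualities(reads))
    stop("trimQualityEnds requires per-base qualities (FASTQ input)")
  minQ <- as.integer(minQ)
  if (minQ <= 0L || length(reads) == 0L) return(reads)
  cls <- .lowQualClass(minQ)
  q <- reads@qual; s <- reads@seq
  m <- regexpr(paste0("^", cls, "+"), q, perl = TRUE)
  pref <- ifelse(m > 0L, attr(m, "match.length"), 0L)
  q <- substr(q, pref + 1L, nchar(q))
  s <- substr(s, pref + 1L, nchar(s))
  m <- regexpr(paste0(cls, "+$"), q, perl = TRUE)
  suff <- ifelse(m > 0L, attr(m, "match.length"), 0L)
  keepTo <- nchar(q) - suff
  q <- substr(q, 1L, keepTo)
  s <- substr(s, 1L, keepTo)
  new("ReadSet", id = reads@id, seq = s, qual = q, mate = reads@mate)
}

#' Quality-fraction filter verdicts
#'
#' A read passes when the fraction of its bases with quality at or above
#' `minQ` reaches `minFrac`. Zero-length reads cannot pass.
#'
#' @param reads a [ReadSet-class] with qualities.
#' @param minQ Phred threshold.
#' @param minFrac required fraction in \[0, 1\].
#' @return Logical vector of per-read verdicts.
#' @export
passesQualityFraction <- function(reads, minQ, minFrac) {
  if (length(reads) && !hasQualities(reads))
    stop("passesQualityFraction requires per-base qualities (FASTQ input)")
  len <- nchar(reads@qual)
  minQ <- as.integer(minQ)
  nLow <- if (minQ <= 0L) rep(0L, length(reads))
          else nchar(gsub(paste0("[^", substr(.lowQualClass(minQ), 2L, 99L)),
                          "", reads@qual, perl = TRUE))
  len > 0L & (len - nLow) / pmax(len, 1L) >= minFrac
}

#' Find tag/adapter matches near read ends
#'
#' For each tag and each enabled end, full-length tag placements are
#' tested at inward shifts 0..`maxShift` from that end (5': tag start at
#' offset s; 3': tag end s bases before the read's 3' end); a placement
#' matches when the tag fits entirely within the read and has at most
#' `maxMismatches` Hamming mismatches. The first match in scan order
#' (tags in declared order, 5' before 3', smaller shift first) is
#' reported. Tags longer than a read are skipped for that read.
#'
#' @param reads a [ReadSet-class].
#' @param tagset a [TagSet-class].
#' @return A data.frame with one row per read: `tag` (name, or `NA` for
#'   no match), `end` ("5prime"/"3prime"), `shift`, `mismatches`.
#' @export
findTagMatch <- function(reads, tagset) {
  n <- length(reads)
  out <- data.frame(tag = rep(NA_character_, n), end = NA_character_,
                    shift = NA_integer_, mismatches = NA_integer_,
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  seqs <- reads@seq
  len <- nchar(seqs)
  ends <- if (tagset@ends == "both") c("5prime", "3prime") else tagset@ends
  unmatched <- rep(TRUE, n)
  for (tname in names(tagset@tags)) {
    tag <- tagset@tags[[tname]]
    t <- nchar(tag)
    tagIv <- utf8ToInt(tag)
    for (end in ends) {
      for (s in 0:tagset@maxShift) {
        cand <- which(unmatched & len >= t + s)
        if (!length(cand)) next
        from <- if (end == "5prime") rep(s + 1L, length(cand))
                else len[cand] - s - t + 1L
        sub <- substr(seqs[cand], from, from + t - 1L)
        if (tagset@maxMismatches == 0L) {
          hit <- sub == tag
          mm <- rep(0L, length(cand))
        } else {
          ivm <- matrix(utf8ToInt(paste(sub, collapse = "")),
                        nrow = length(cand), ncol = t, byrow = TRUE)
          mm <- rowSums(ivm != matrix(tagIv, length(cand), t, byrow = TRUE))
          hit <- mm <= tagset@maxMismatches
        }
        if (any(hit)) {
          idx <- cand[hit]
          out$tag[idx] <- tname
          out$end[idx] <- end
          out$shift[idx] <- s
          out$mismatches[idx] <- mm[hit]
          unmatched[idx] <- FALSE
        }
      }
    }
  }
  out
}

#' Canonical duplicate keys for reads or pairs
#'
#' A single read's key is its (case-normalised) sequence; a pair's key
#' is `seq1 + "|" + seq2`, so the mate order matters. Keys are equal
#' exactly when the sequences are identical; qualities and identifiers
#' play no role.
#'
#' @param reads a [ReadSet-class] (mate 1 for pairs).
#' @param reads2 optional mate-2 [ReadSet-class].
#' @return Character vector of keys.
#' @export
duplicateKeys <- function(reads, reads2 = NULL) {
  if (is.null(reads2)) reads@seq
  else paste(reads@seq, reads2@seq, sep = "|")
}

## Stages 1-5 on one chunk (one mate). Returns trimmed reads + first
## failing cause (NA = pass) + bases trimmed.
.qcStages <- function(reads, params) {
  baseIn <- sum(nchar(reads@seq))
  if (!is.na(params@targetLength))
    reads <- trimToLength(reads, params@targetLength)
  if (!is.na(params@endTrimQuality))
    reads <- trimQualityEnds(reads, params@endTrimQuality)
  cause <- rep(NA_character_, length(reads))
  shortFail <- nchar(reads@seq) < params@minLengthAfterTrim
  cause[shortFail] <- "length"
  if (!is.null(params@tags)) {
    tm <- findTagMatch(reads, params@tags)
    cause[is.na(cause) & !is.na(tm$tag)] <- "tag"
  }
  if (params@minQualityFraction > 0 && !is.na(params@filterQuality)) {
    qf <- passesQualityFraction(reads, params@filterQuality,
                                params@minQualityFraction)
    cause[is.na(cause) & !qf] <- "quality_fraction"
  }
  list(reads = reads, cause = cause,
       basesTrimmed = baseIn - sum(nchar(reads@seq)))
}

#' Run the full read-QC stage
#'
#' Applies the fixed stage order (trim to length, end-quality trim,
#' minimum-length filter, tag filter, quality-fraction filter, duplicate
#' removal) to a read set or a pair of mate sets, with the configured
#' pair policy, over fixed-size read blocks. Blocks are processed
#' independently (optionally on several worker processes) and merged in
#' input order; duplicate removal runs on the ordered merge, so the
#' output is identical for any thread count.
#'
#' @param reads a [ReadSet-class] (mate 1 if `reads2` given).
#' @param params a [QCParams-class].
#' @param reads2 optional mate-2 [ReadSet-class] of the same length.
#' @return A list with `reads` (surviving mate-1/unpaired reads),
#'   `reads2` (surviving mate-2 reads or `NULL`) and `report`
#'   (a [QCReport-class] whose accounting identity always holds).
#' @export
processReadSet <- function(reads, params = qcParams(), reads2 = NULL) {
  paired <- !is.null(reads2)
  if (paired && length(reads) != length(reads2))
    stop("mate sets must have equal length")
  n <- length(reads)
  inputReads <- n * (1L + paired)
  inputBases <- sum(nchar(reads@seq)) + if (paired) sum(nchar(reads2@seq)) else 0
  chunks <- if (n) unname(split(seq_len(n),
                               ceiling(seq_len(n) / params@chunkSize)))
            else list()
  worker <- function(idx) {
    s1 <- .qcStages(reads[idx], params)
    s2 <- if (paired) .qcStages(reads2[idx], params) else NULL
    list(s1 = s1, s2 = s2)
  }
  res <- if (params@threads > 1L && length(chunks) > 1L &&
             .Platform$OS.type == "unix")
    parallel::mclapply(chunks, worker, mc.cores = params@threads,
                       mc.preschedule = TRUE)
  else lapply(chunks, worker)
  r1 <- do.call(c, c(list(new("ReadSet", id = character(),
                              seq = character(), qual = character(),
                              mate = integer())),
                     lapply(res, function(x) x$s1$reads)))
  c1 <- unlist(lapply(res, function(x) x$s1$cause), use.names = FALSE)
  basesTrimmed <- sum(vapply(res, function(x) x$s1$basesTrimmed, numeric(1)))
  removed <- setNames(numeric(length(.removalCauses)), .removalCauses)
  if (paired) {
    r2 <- do.call(c, c(list(r1[0]), lapply(res, function(x) x$s2$reads)))
    c2 <- unlist(lapply(res, function(x) x$s2$cause), use.names = FALSE)
    basesTrimmed <- basesTrimmed +
      sum(vapply(res, function(x) x$s2$basesTrimmed, numeric(1)))
    if (params@keepPairs == "both-pass") {
      keepPair <- is.na(c1) & is.na(c2)
      c1[is.na(c1) & !keepPair] <- "pair_partner"
      c2[is.na(c2) & !keepPair] <- "pair_partner"
    } else {
      keepPair <- is.na(c1) | is.na(c2)
      c1[!keepPair] <- ifelse(is.na(c1[!keepPair]), "pair_partner",
                              c1[!keepPair])
      c2[!keepPair] <- ifelse(is.na(c2[!keepPair]), "pair_partner",
                              c2[!keepPair])
      ## forgiven mates of kept pairs are emitted, not removed
      c1[keepPair] <- NA_character_
      c2[keepPair] <- NA_character_
    }
    for (cz in .removalCauses)
      removed[[cz]] <- sum(c1 == cz, na.rm = TRUE) +
                       sum(c2 == cz, na.rm = TRUE)
    out1 <- r1[keepPair]; out2 <- r2[keepPair]
    if (params@removeDuplicates && length(out1)) {
      dup <- duplicated(duplicateKeys(out1, out2))
      removed[["duplicate"]] <- 2 * sum(dup)
      out1 <- out1[!dup]; out2 <- out2[!dup]
    }
    outputReads <- 2L * length(out1)
    outputBases <- sum(nchar(out1@seq)) + sum(nchar(out2@seq))
  } else {
    keep <- is.na(c1)
    for (cz in .removalCauses)
      removed[[cz]] <- sum(c1 == cz, na.rm = TRUE)
    out1 <- r1[keep]; out2 <- NULL
    if (params@removeDuplicates && length(out1)) {
      dup <- duplicated(duplicateKeys(out1))
      removed[["duplicate"]] <- sum(dup)
      out1 <- out1[!dup]
    }
    outputReads <- length(out1)
    outputBases <- sum(nchar(out1@seq))
  }
  report <- new("QCReport", inputReads = as.numeric(inputReads),
                inputBases = as.numeric(inputBases),
                outputReads = as.numeric(outputReads),
                outputBases = as.numeric(outputBases), removed = removed,
                basesTrimmed = basesTrimmed,
                params = .paramsAsList(params))
  list(reads = out1, reads2 = out2, report = report)
}

.paramsAsList <- function(p) {
  list(targetLength = p@targetLength, endTrimQuality = p@endTrimQuality,
       filterQuality = p@filterQuality,
       minQualityFraction = p@minQualityFraction,
       minLengthAfterTrim = p@minLengthAfterTrim,
       removeDuplicates = p@removeDuplicates,
       tags = if (is.null(p@tags)) character() else names(p@tags@tags),
       maxMismatches = if (is.null(p@tags)) NA_integer_
                       else p@tags@maxMismatches,
       maxShift = if (is.null(p@tags)) NA_integer_ else p@tags@maxShift,
       keepPairs = p@keepPairs, threads = p@threads)
}

#' File-level read QC
#'
#' Reads one FASTQ file (or a mate pair), runs [processReadSet()] and
#' writes the surviving reads plus a human-readable and a
#' machine-readable (JSON) report into `outDir`.
#'
#' @param file1 FASTQ path (mate 1 if `file2` given).
#' @param params a [QCParams-class].
#' @param file2 optional mate-2 FASTQ path.
#' @param outDir output directory (created if needed).
#' @param qualityOffset as in [readFastq()].
#' @return Invisibly, a list with the [QCReport-class] and the output
#'   file paths.
#' @export
runReadQC <- function(file1, params = qcParams(), file2 = NULL,
                      outDir = ".", qualityOffset = "auto") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(file2)) {
    reads <- readFastq(file1, qualityOffset)
    res <- processReadSet(reads, params)
  } else {
    pr <- readFastqPair(file1, file2, qualityOffset)
    res <- processReadSet(pr$r1, params, reads2 = pr$r2)
  }
  stripExt <- function(f) sub("\\.(fastq|fq)(\\.gz)?$", "",
                              basename(f), ignore.case = TRUE)
  out1 <- file.path(outDir, paste0(stripExt(file1), ".qc.fastq"))
  writeFastq(res$reads, out1)
  paths <- out1
  if (!is.null(file2)) {
    out2 <- file.path(outDir, paste0(stripExt(file2), ".qc.fastq"))
    writeFastq(res$reads2, out2)
    paths <- c(paths, out2)
  }
  writeQCReport(res$report, file.path(outDir, "readqc_report"))
  invisible(list(report = res$report, files = paths))
}

#' Write a QC report as text and JSON
#'
#' @param report a [QCReport-class].
#' @param stem output path stem; `.txt` and `.json` files are written.
#' @return Invisibly, the two paths.
#' @export
writeQCReport <- function(report, stem) {
  txt <- paste0(stem, ".txt"); js <- paste0(stem, ".json")
  con <- file(txt, "w"); sink(con); show(report); sink(); close(con)
  jsonlite::write_json(
    list(input_reads = report@inputReads, input_bases = report@inputBases,
         removed = as.list(report@removed),
         bases_trimmed = report@basesTrimmed,
         output_reads = report@outputReads,
         output_bases = report@outputBases, parameters = report@params),
    js, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(c(txt, js))
}
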