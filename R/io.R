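#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
NULL

#' Detect the FASTQ quality-score encoding
#'
#' Heuristic over a sample of raw quality strings: any character below
#' ASCII 59 implies Phred+33; if every character is at ASCII 64 or above
#' and at least one exceeds ASCII 74, Phred+64 is inferred; ambiguous
#' samples fall back to the declared default of Phred+33.
#'
#' @param qualStrings character vector of raw (undecoded) quality strings.
#' @return 33 or 64.
#' @export
detectQualityEncoding <- function(qualStrings) {
  qualStrings <- qualStrings[!is.na(qualStrings) & nzchar(qualStrings)]
  if (!length(qualStrings))
    stop("no quality strings available; specify the quality offset explicitly")
  iv <- utf8ToInt(paste(qualStrings, collapse = ""))
  if (any(iv < 59L)) return(33L)
  if (all(iv >= 64L) && any(iv > 74L)) return(64L)
  33L
}

.stopParse <- function(path, what)
  stop(sprintf("malformed FASTQ in '%s': %s", path, what), call. = FALSE)

## Verify the 4-line record geometry on the raw lines: every quality
## line must be exactly as long as its sequence line. (The stringset
## parser silently pads short quality lines, so this cannot be checked
## on the parsed object.)
.auditFastqLengths <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  recno <- 0L
  repeat {
    lines <- readLines(con, n = 200000L)
    if (!length(lines)) break
    nfull <- (length(lines) %/% 4L) * 4L
    if (nfull < length(lines))
      .stopParse(path, sprintf("truncated record at end (%d stray line(s))",
                               length(lines) - nfull))
    if (!nfull) break
    sq <- lines[seq(2L, nfull, by = 4L)]
    ql <- lines[seq(4L, nfull, by = 4L)]
    bad <- which(nchar(ql) != nchar(sq))
    if (length(bad))
      .stopParse(path, sprintf(
        "record '%s' (#%d): quality length %d != sequence length %d",
        sub("^@", "", sub("\\s.*$", "", lines[4L * (bad[1] - 1L) + 1L])),
        recno + bad[1], nchar(ql[bad[1]]), nchar(sq[bad[1]])))
    recno <- recno + nfull %/% 4L
  }
  invisible(recno)
}

#' Read a FASTQ file into a ReadSet
#'
#' Parses 4-line FASTQ (plain or gzip) via Biostrings, validates that
#' every quality string matches its sequence length, decodes qualities
#' at the requested offset (or auto-detects it from the first 10,000
#' records) and normalises sequences (uppercase; characters outside
#' A/C/G/T/N become N, with the count attached as attribute
#' `nNonstandard`).
#'
#' @param path FASTQ file path.
#' @param qualityOffset 33, 64 or "auto" (default).
#' @param mate mate index to record on the reads (0, 1 or 2).
#' @return A [ReadSet-class]; qualities re-encoded internally at Phred+33.
#' @export
readFastq <- function(path, qualityOffset = "auto", mate = 0L) {
  if (!file.exists(path)) stop("file not found: ", path)
  .auditFastqLengths(path)
  x <- tryCatch(
    readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) .stopParse(path, conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(x))
  seqs <- as.character(x)
  qraw <- S4Vectors::mcols(x)$qualities
  quals <- tryCatch(as.character(qraw), error = function(e) {
    ## a short quality line is NUL-padded by the parser; locate it
    for (i in seq_along(qraw)) {
      bad <- tryCatch({ as.character(qraw[i]); FALSE },
                      error = function(e2) TRUE)
      if (bad)
        .stopParse(path, sprintf(
          "record '%s' (#%d): quality line shorter than its sequence",
          ids[i], i))
    }
    .stopParse(path, conditionMessage(e))
  })
  bad <- which(nchar(quals) != nchar(seqs))
  if (length(bad))
    .stopParse(path, sprintf(
      "record '%s' (#%d): quality length %d != sequence length %d",
      ids[bad[1]], bad[1], nchar(quals[bad[1]]), nchar(seqs[bad[1]])))
  offset <- qualityOffset
  if (identical(offset, "auto"))
    offset <- if (length(quals)) detectQualityEncoding(head(quals, 10000L))
              else 33L
  offset <- as.integer(offset)
  if (!offset %in% c(33L, 64L))
    stop("qualityOffset must be 33, 64 or 'auto'")
  if (length(quals)) {
    iv <- utf8ToInt(paste(quals, collapse = ""))
    sc <- iv - offset
    if (any(sc < 0L | sc > 93L))
      stop(sprintf(
        "quality encoding error in '%s': decoded score outside [0, 93] at offset %d",
        path, offset), call. = FALSE)
    if (offset != 33L) {
      ends <- cumsum(nchar(quals))
      starts <- c(1L, head(ends, -1L) + 1L)
      q33 <- intToUtf8(sc + 33L)
      quals <- substring(q33, starts, ends)
    }
  }
  ReadSet(ids, seqs, qual = quals, mate = mate)
}

#' Read a FASTA file into a ReadSet (no qualities)
#'
#' @param path FASTA file path (plain or gzip).
#' @param mate mate index to record (default 0).
#' @return A [ReadSet-class] with `hasQualities(x) == FALSE`.
#' @export
readFasta <- function(path, mate = 0L) {
  x <- readDNAStringSet(path, format = "fasta")
  ReadSet(sub("\\s.*$", "", names(x)), as.character(x), mate = mate)
}

## named character vector of sequences from a FASTA file; label = first
## whitespace-delimited header token
readFastaSeqs <- function(path) {
  x <- readDNAStringSet(path, format = "fasta")
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write a ReadSet as 4-line FASTQ
#'
#' Records are written in input order, qualities re-encoded at the given
#' offset. Reads lacking qualities cannot be written as FASTQ.
#'
#' @param reads a [ReadSet-class] with qualities.
#' @param path output path (".gz" suffix writes gzip).
#' @param qualityOffset 33 (default) or 64.
#' @return Invisibly, the number of records written.
#' @export
writeFastq <- function(reads, path, qualityOffset = 33L) {
  qualityOffset <- as.integer(qualityOffset)
  if (!qualityOffset %in% c(33L, 64L))
    stop("qualityOffset must be 33 or 64")
  n <- length(reads)
  if (n && !hasQualities(reads))
    stop("reads have no qualities; write FASTA instead (writeFasta)")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (n == 0L) {
    writeLines(character(), con)
    return(invisible(0L))
  }
  quals <- readQualStrings(reads)
  if (qualityOffset != 33L) {
    ends <- cumsum(nchar(quals))
    starts <- c(1L, head(ends, -1L) + 1L)
    iv <- utf8ToInt(paste(quals, collapse = "")) - 33L + qualityOffset
    quals <- substring(intToUtf8(iv), starts, ends)
  }
  lines <- character(4L * n)
  lines[seq(1L, by = 4L, length.out = n)] <- paste0("@", readIds(reads))
  lines[seq(2L, by = 4L, length.out = n)] <- readSeqs(reads)
  lines[seq(3L, by = 4L, length.out = n)] <- "+"
  lines[seq(4L, by = 4L, length.out = n)] <- quals
  writeLines(lines, con)
  invisible(n)
}

#' Write sequences as FASTA (wrapped at 70 columns)
#'
#' @param x a [ReadSet-class] or a named character vector of sequences.
#' @param path output path.
#' @return Invisibly, the number of records written.
#' @export
writeFasta <- function(x, path) {
  if (is(x, "ReadSet"))
    x <- setNames(readSeqs(x), readIds(x))
  ss <- DNAStringSet(x)
  writeXStringSet(ss, path, format = "fasta", width = 70L)
  invisible(length(ss))
}

#' Pair stem of read identifiers
#'
#' Strips a trailing "/1" or "/2" (and anything after the first
#' whitespace) so that the two mates of a pair share one stem.
#'
#' @param ids character vector of read identifiers.
#' @return character vector of stems.
#' @export
pairStem <- function(ids) sub("/[12]$", "", sub("\\s.*$", "", ids))

#' Read two FASTQ files as synchronized mate pairs
#'
#' Reads both files and verifies record-by-record that the pair stems
#' agree; a stem mismatch or unequal record counts is an error naming
#' the offending position.
#'
#' @param path1,path2 FASTQ paths for mate 1 and mate 2.
#' @param qualityOffset as in [readFastq()].
#' @return A list with elements `r1` and `r2` ([ReadSet-class]s of equal
#'   length, mates 1 and 2).
#' @export
readFastqPair <- function(path1, path2, qualityOffset = "auto") {
  r1 <- readFastq(path1, qualityOffset, mate = 1L)
  r2 <- readFastq(path2, qualityOffset, mate = 2L)
  if (length(r1) != length(r2))
    stop(sprintf("truncation error: %d records in '%s' vs %d in '%s'",
                 length(r1), path1, length(r2), path2), call. = FALSE)
  s1 <- pairStem(readIds(r1)); s2 <- pairStem(readIds(r2))
  bad <- which(s1 != s2)
  if (length(bad))
    stop(sprintf(
      "pair synchronization error at record %d: '%s' vs '%s'",
      bad[1], readIds(r1)[bad[1]], readIds(r2)[bad[1]]), call. = FALSE)
  list(r1 = r1, r2 = r2)
}
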