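#' @import methods
#' @importFrom stats rbinom runif setNames
#' @importFrom utils head write.table read.delim
NULL

## Internal quality-string convention: qualities are always stored as
## Phred+33-encoded ASCII strings, whatever the on-disk offset was.
## A ReadSet without qualities (FASTA input) has all-NA qual.

#' ReadSet: a set of sequencing reads
#'
#' An S4 container holding a vector of reads: identifiers, nucleotide
#' sequences over \{A,C,G,T,N\}, optional per-base Phred quality scores
#' (stored internally as Phred+33 ASCII strings) and a mate index
#' (0 = unpaired, 1/2 = first/second mate of a pair).
#'
#' @slot id character vector of read identifiers.
#' @slot seq character vector of sequences (uppercase A/C/G/T/N).
#' @slot qual character vector of Phred+33 quality strings, or all `NA`
#'   for quality-less (FASTA) input.
#' @slot mate integer vector, one of 0, 1, 2 per read.
#'
#' @examples
#' rs <- ReadSet("r1", "ACGT", qual = list(c(40L, 40L, 40L, 40L)))
#' readLengths(rs)
#' @export
setClass("ReadSet",
  representation(id = "character", seq = "character",
                 qual = "character", mate = "integer"))

setValidity("ReadSet", function(object) {
  n <- length(object@id)
  if (length(object@seq) != n || length(object@qual) != n ||
      length(object@mate) != n)
    return("id, seq, qual and mate must have equal length")
  if (any(grepl("[^ACGTN]", object@seq)))
    return("sequences must be over {A,C,G,T,N} (uppercase)")
  hasQ <- !is.na(object@qual)
  if (any(hasQ) && !all(hasQ))
    return("qualities must be present for all reads or for none")
  if (any(hasQ)) {
    if (any(nchar(object@qual[hasQ]) != nchar(object@seq[hasQ])))
      return("quality string length must equal sequence length")
    allq <- paste(object@qual[hasQ], collapse = "")
    if (nchar(allq) && {
      iv <- utf8ToInt(allq); any(iv < 33L | iv > 126L)
    })
      return("Phred scores must lie in [0, 93]")
  }
  if (!all(object@mate %in% c(0L, 1L, 2L)))
    return("mate must be 0 (unpaired), 1 or 2")
  TRUE
})

#' Construct a ReadSet
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of sequences; lowercase is uppercased and
#'   characters outside A/C/G/T/N are mapped to N (the count of such
#'   characters is attached as attribute `nNonstandard`).
#' @param qual per-base qualities: either a list of integer Phred score
#'   vectors, a character vector of Phred+33 strings, or `NULL` for
#'   quality-less reads.
#' @param mate integer scalar or vector: 0 (unpaired), 1 or 2.
#' @return A [ReadSet-class] object.
#' @export
ReadSet <- function(id = character(), seq = character(), qual = NULL,
                    mate = 0L) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  bad <- grepl("[^ACGTN]", seq)
  nNonstd <- 0L
  if (any(bad)) {
    nNonstd <- sum(nchar(gsub("[ACGTN]", "", seq[bad])))
    seq[bad] <- gsub("[^ACGTN]", "N", seq[bad])
  }
  if (is.null(qual)) {
    qual <- rep(NA_character_, length(seq))
  } else if (is.list(qual)) {
    qual <- vapply(qual, function(q) intToUtf8(as.integer(q) + 33L),
                   character(1))
  } else {
    qual <- as.character(qual)
  }
  mate <- rep(as.integer(mate), length.out = length(id))
  out <- new("ReadSet", id = id, seq = seq, qual = qual, mate = mate)
  attr(out, "nNonstandard") <- nNonstd
  out
}

#' @describeIn ReadSet number of reads
#' @param x a `ReadSet`
#' @export
setMethod("length", "ReadSet", function(x) length(x@id))

#' @export
setMethod("show", "ReadSet", function(object) {
  n <- length(object)
  cat("ReadSet with", n, "read(s)",
      if (n && !anyNA(object@qual)) "(with qualities)" else "(no qualities)",
      "\n")
  if (n) {
    k <- min(n, 3L)
    for (i in seq_len(k))
      cat(sprintf("  %s [%d bp] %s...\n", object@id[i],
                  nchar(object@seq[i]), substr(object@seq[i], 1, 24)))
    if (n > k) cat("  ...\n")
  }
})

#' @export
setMethod("[", "ReadSet", function(x, i, j, ..., drop = TRUE) {
  new("ReadSet", id = x@id[i], seq = x@seq[i], qual = x@qual[i],
      mate = x@mate[i])
})

#' @export
setMethod("c", "ReadSet", function(x, ...) {
  args <- c(list(x), list(...))
  new("ReadSet",
      id = unlist(lapply(args, slot, "id"), use.names = FALSE),
      seq = unlist(lapply(args, slot, "seq"), use.names = FALSE),
      qual = unlist(lapply(args, slot, "qual"), use.names = FALSE),
      mate = unlist(lapply(args, slot, "mate"), use.names = FALSE))
})

#' @rdname ReadSet-accessors
#' @export
readIds <- function(x) x@id

#' Accessors for ReadSet slots
#'
#' @param x a [ReadSet-class].
#' @return `readIds`, `readSeqs`: character vectors. `readQualStrings`:
#'   Phred+33 strings (`NA` if absent). `readQuals`: list of integer
#'   Phred score vectors. `readMates`: integer vector. `readLengths`:
#'   integer vector of sequence lengths. `hasQualities`: logical scalar.
#' @name ReadSet-accessors
#' @export
readSeqs <- function(x) x@seq

#' @rdname ReadSet-accessors
#' @export
readQualStrings <- function(x) x@qual

#' @rdname ReadSet-accessors
#' @export
readQuals <- function(x) {
  lapply(x@qual, function(q)
    if (is.na(q)) NULL else utf8ToInt(q) - 33L)
}

#' @rdname ReadSet-accessors
#' @export
readMates <- function(x) x@mate

#' @rdname ReadSet-accessors
#' @export
readLengths <- function(x) nchar(x@seq)

#' @rdname ReadSet-accessors
#' @export
hasQualities <- function(x) length(x) > 0L && !anyNA(x@qual)

#' TagSet: tag/adapter sequences with matching tolerances
#'
#' Named tag (adapter/barcode) sequences together with the tolerances
#' used when scanning read ends: tags may be shifted inward by up to
#' `maxShift` bases from either end and matched with up to
#' `maxMismatches` Hamming mismatches. A read matching any tag placement
#' is treated as an artifact.
#'
#' @slot tags named character vector of tag sequences over \{A,C,G,T\}.
#' @slot maxMismatches non-negative integer.
#' @slot maxShift non-negative integer.
#' @slot ends one of "5prime", "3prime", "both".
#' @export
setClass("TagSet",
  representation(tags = "character", maxMismatches = "integer",
                 maxShift = "integer", ends = "character"))

setValidity("TagSet", function(object) {
  if (length(object@tags) == 0L) return("at least one tag required")
  if (is.null(names(object@tags)) || any(!nzchar(names(object@tags))))
    return("tags must be named")
  if (any(!nzchar(object@tags)) || any(grepl("[^ACGT]", object@tags)))
    return("tag sequences must be non-empty and over {A,C,G,T}")
  if (object@maxMismatches < 0L || object@maxShift < 0L)
    return("maxMismatches and maxShift must be non-negative")
  if (!object@ends %in% c("5prime", "3prime", "both"))
    return("ends must be one of '5prime', '3prime', 'both'")
  TRUE
})

#' Construct a TagSet
#'
#' @param tags named character vector of tag sequences, or the path of a
#'   FASTA file of tags (names taken from headers). `NULL` loads the
#'   bundled default adapters (standard Illumina/454 library sequences).
#' @param maxMismatches maximum Hamming mismatches allowed (default 2).
#' @param maxShift maximum inward shift from a read end (default 5).
#' @param ends which read ends to scan: "5prime", "3prime" or "both".
#' @return A [TagSet-class].
#' @export
TagSet <- function(tags = NULL, maxMismatches = 2L, maxShift = 5L,
                   ends = "both") {
  if (is.null(tags))
    tags <- system.file("extdata", "adapters.fa", package = "seqscrub",
                        mustWork = TRUE)
  if (length(tags) == 1L && is.null(names(tags)) && file.exists(tags))
    tags <- readFastaSeqs(tags)
  new("TagSet", tags = toupper(tags),
      maxMismatches = as.integer(maxMismatches),
      maxShift = as.integer(maxShift), ends = ends)
}

#' @export
setMethod("show", "TagSet", function(object) {
  cat(sprintf("TagSet: %d tag(s), <=%d mismatch(es), shift <=%d, ends=%s\n",
              length(object@tags), object@maxMismatches, object@maxShift,
              object@ends))
})

#' KmerIndex: canonical k-mer index over labeled references
#'
#' Maps canonical k-mers (the lexicographically smaller of a k-mer and
#' its reverse complement, A<C<G<T) of a labeled reference collection to
#' their source labels. K-mers are stored as exact 2-bit numeric codes
#' (values below 4^k, exact in double precision for k <= 26); k-mers
#' containing N are skipped.
#'
#' @slot k integer word length (8..26).
#' @slot kmers named list: for each label, a numeric vector of distinct
#'   canonical k-mer codes.
#' @slot refLengths named numeric vector of reference lengths (bases).
#' @export
setClass("KmerIndex",
  representation(k = "integer", kmers = "list", refLengths = "numeric"))

setValidity("KmerIndex", function(object) {
  if (object@k < 8L || object@k > 26L)
    return("k must be in [8, 26]")
  if (length(object@kmers) &&
      (is.null(names(object@kmers)) || anyDuplicated(names(object@kmers))))
    return("k-mer sets must carry unique labels")
  TRUE
})

#' @export
setMethod("show", "KmerIndex", function(object) {
  cat(sprintf("KmerIndex: k=%d, %d reference label(s)\n", object@k,
              length(object@kmers)))
  for (lab in head(names(object@kmers), 6L))
    cat(sprintf("  %s: %d distinct k-mers (%g bp)\n", lab,
                length(object@kmers[[lab]]), object@refLengths[[lab]]))
  if (length(object@kmers) > 6L) cat("  ...\n")
})

#' @rdname KmerIndex-accessors
#' @export
indexK <- function(x) x@k

#' Accessors for KmerIndex
#' @param x a [KmerIndex-class].
#' @name KmerIndex-accessors
#' @export
indexLabels <- function(x) names(x@kmers)

#' AbundanceProfile: per-taxon read counts and proportions
#'
#' @slot counts named numeric vector of classified read counts per label.
#' @slot proportions named numeric vector; sums to 1 over classified
#'   labels (when any read is classified).
#' @slot nClassified number of classified reads.
#' @slot nUnassigned number of unassigned reads.
#' @export
setClass("AbundanceProfile",
  representation(counts = "numeric", proportions = "numeric",
                 nClassified = "numeric", nUnassigned = "numeric"))

setValidity("AbundanceProfile", function(object) {
  if (!identical(names(object@counts), names(object@proportions)))
    return("counts and proportions must share label names")
  if (object@nClassified != sum(object@counts))
    return("nClassified must equal sum(counts)")
  if (object@nClassified > 0 &&
      abs(sum(object@proportions) - 1) > 1e-9)
    return("proportions must sum to 1 over classified labels")
  TRUE
})

#' Construct an AbundanceProfile from per-read labels
#'
#' @param labels character vector of per-read assigned labels, with
#'   "unassigned" for reads no reference matched.
#' @param allLabels optional label universe for zero-count entries.
#' @return An [AbundanceProfile-class].
#' @export
AbundanceProfile <- function(labels, allLabels = NULL) {
  asg <- labels[labels != "unassigned"]
  lv <- sort(unique(c(allLabels, asg)))
  counts <- setNames(as.numeric(table(factor(asg, levels = lv))), lv)
  tot <- sum(counts)
  props <- if (tot > 0) counts / tot else counts
  new("AbundanceProfile", counts = counts, proportions = props,
      nClassified = tot, nUnassigned = sum(labels == "unassigned"))
}

#' @export
setMethod("show", "AbundanceProfile", function(object) {
  cat(sprintf("AbundanceProfile: %g classified, %g unassigned\n",
              object@nClassified, object@nUnassigned))
  if (length(object@counts)) {
    df <- data.frame(label = names(object@counts),
                     count = as.numeric(object@counts),
                     proportion = round(object@proportions, 4))
    print(df, row.names = FALSE)
  }
})

#' @rdname AbundanceProfile-accessors
#' @export
profileCounts <- function(x) x@counts

#' Accessors for AbundanceProfile
#' @param x an [AbundanceProfile-class].
#' @name AbundanceProfile-accessors
#' @export
profileProportions <- function(x) x@proportions

#' @rdname AbundanceProfile-accessors
#' @export
nClassified <- function(x) x@nClassified

#' @rdname AbundanceProfile-accessors
#' @export
nUnassigned <- function(x) x@nUnassigned

#' QCReport: read-QC accounting report
#'
#' Summarises a quality-control run: input/output read and base counts,
#' and per-cause removal counts. The accounting identity
#' `inputReads == outputReads + sum(removed)` holds on every run; each
#' removed read is attributed to exactly one primary cause (the first
#' failing stage in the fixed stage order).
#'
#' @slot inputReads,inputBases,outputReads,outputBases numeric counts.
#' @slot removed named numeric vector with causes `length`, `tag`,
#'   `quality_fraction`, `duplicate`, `pair_partner`.
#' @slot basesTrimmed numeric: bases removed by length/end trimming from
#'   surviving and removed reads alike.
#' @slot params list echoing the parameters used.
#' @export
setClass("QCReport",
  representation(inputReads = "numeric", inputBases = "numeric",
                 outputReads = "numeric", outputBases = "numeric",
                 removed = "numeric", basesTrimmed = "numeric",
                 params = "list"))

.removalCauses <- c("length", "tag", "quality_fraction", "duplicate",
                    "pair_partner")

setValidity("QCReport", function(object) {
  if (!identical(names(object@removed), .removalCauses))
    return(paste("removed must have causes:",
                 paste(.removalCauses, collapse = ", ")))
  if (object@inputReads != object@outputReads + sum(object@removed))
    return("accounting identity violated: input != output + sum(removed)")
  TRUE
})

#' @export
setMethod("show", "QCReport", function(object) {
  cat("Read QC report\n")
  cat(sprintf("  input:  %g reads, %g bases\n", object@inputReads,
              object@inputBases))
  for (cz in names(object@removed))
    cat(sprintf("  removed (%s): %g\n", cz, object@removed[[cz]]))
  cat(sprintf("  bases trimmed: %g\n", object@basesTrimmed))
  cat(sprintf("  output: %g reads, %g bases\n", object@outputReads,
              object@outputBases))
})

#' @rdname QCReport-accessors
#' @export
removedCounts <- function(x) x@removed

#' Accessors for QCReport
#' @param x a [QCReport-class].
#' @name QCReport-accessors
#' @export
inputReads <- function(x) x@inputReads

#' @rdname QCReport-accessors
#' @export
outputReads <- function(x) x@outputReads

#' @rdname QCReport-accessors
#' @export
reportParams <- function(x) x@params

#' ScreeningResult: combined contamination screen report
#'
#' Output of [screenContamination()]: the qualitative rRNA-read screen
#' (per-label rDNA read counts), the quantitative random-subsample
#' profile, and the flagged candidate contaminant labels (non-target
#' labels dominant in the rDNA screen and present in the quantitative
#' profile).
#'
#' @slot rdnaCounts named numeric vector of assigned rDNA read counts.
#' @slot nRdnaReads number of reads extracted as rDNA.
#' @slot profile an [AbundanceProfile-class] from the subsample screen.
#' @slot flagged character vector of flagged labels.
#' @slot target character vector of declared target labels (may be empty).
#' @slot params list of screening parameters used.
#' @export
setClass("ScreeningResult",
  representation(rdnaCounts = "numeric", nRdnaReads = "numeric",
                 profile = "AbundanceProfile", flagged = "character",
                 target = "character", params = "list"))

#' @export
setMethod("show", "ScreeningResult", function(object) {
  cat("Contamination screening result\n")
  cat(sprintf("  rDNA reads extracted: %g\n", object@nRdnaReads))
  if (length(object@rdnaCounts)) {
    tot <- sum(object@rdnaCounts)
    for (lab in names(sort(object@rdnaCounts, decreasing = TRUE)))
      cat(sprintf("    %s: %g rDNA reads (%.1f%%)\n", lab,
                  object@rdnaCounts[[lab]],
                  if (tot > 0) 100 * object@rdnaCounts[[lab]] / tot else 0))
  }
  cat("  subsample profile:\n")
  show(object@profile)
  cat(sprintf("  target: %s\n",
              if (length(object@target)) paste(object@target, collapse = ", ")
              else "(none declared)"))
  cat(sprintf("  flagged contaminants: %s\n",
              if (length(object@flagged)) paste(object@flagged, collapse = ", ")
              else "(none)"))
})

#' @rdname ScreeningResult-accessors
#' @export
flaggedLabels <- function(x) x@flagged

#' Accessors for ScreeningResult
#' @param x a [ScreeningResult-class].
#' @name ScreeningResult-accessors
#' @export
rdnaCounts <- function(x) x@rdnaCounts

#' @rdname ScreeningResult-accessors
#' @export
screenProfile <- function(x) x@profile
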