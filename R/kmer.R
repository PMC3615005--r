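## Canonical k-mer machinery.
##
## K-mers are encoded as base-4 numbers (A=0, C=1, G=2, T=3), so a
## k-mer code is < 4^k; for k <= 26 this is below 2^53 and exact in
## double precision. Numeric order of codes equals lexicographic order
## of the k-mer strings, so the canonical k-mer (lexicographic min of a
## k-mer and its reverse complement) is simply pmin(code, rcCode).
## Windows containing N are invalid and dropped. All window evaluation
## is vectorized over reads with a Horner scheme on a code matrix.

.baseCodeLookup <- local({
  lk <- rep(NA_integer_, 128L)
  lk[utf8ToInt("A")] <- 0L; lk[utf8ToInt("C")] <- 1L
  lk[utf8ToInt("G")] <- 2L; lk[utf8ToInt("T")] <- 3L
  lk
})

## Flat canonical k-mer codes for a character vector of sequences.
## Returns list(code = numeric (NA where the window contains N),
##              read = integer index into seqs,
##              nKmers = per-sequence window count (0 if too short)).
kmerCodes <- function(seqs, k, chunkCells = 4e6) {
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= 26L)
  n <- length(seqs)
  len <- nchar(seqs)
  nKmers <- pmax(len - k + 1L, 0L)
  codeParts <- list(); readParts <- list(); part <- 0L
  for (L in sort(unique(len[len >= k]))) {
    grp <- which(len == L)
    M <- L - k + 1L
    rowsPerChunk <- max(1L, floor(chunkCells / M))
    for (off in seq(1L, length(grp), by = rowsPerChunk)) {
      idx <- grp[off:min(off + rowsPerChunk - 1L, length(grp))]
      ns <- length(idx)
      iv <- utf8ToInt(paste(seqs[idx], collapse = ""))
      C <- matrix(.baseCodeLookup[iv], nrow = ns, ncol = L, byrow = TRUE)
      Cn <- is.na(C)
      if (any(Cn)) C[Cn] <- 0L
      Fw <- matrix(0, ns, M); Rv <- matrix(0, ns, M)
      V <- matrix(FALSE, ns, M)
      for (i in 0:(k - 1L)) {
        Fw <- Fw * 4 + C[, (1L + i):(M + i), drop = FALSE]
        Rv <- Rv * 4 + (3 - C[, (k - i):(M + k - 1L - i), drop = FALSE])
        if (any(Cn)) V <- V | Cn[, (1L + i):(M + i), drop = FALSE]
      }
      can <- pmin(Fw, Rv)
      if (any(V)) can[V] <- NA_real_
      part <- part + 1L
      codeParts[[part]] <- as.vector(t(can))
      readParts[[part]] <- rep(idx, each = M)
    }
  }
  list(code = unlist(codeParts, use.names = FALSE),
       read = unlist(readParts, use.names = FALSE),
       nKmers = nKmers)
}

## Decode a canonical code back to its k-mer string (diagnostics only).
decodeKmer <- function(code, k) {
  bases <- c("A", "C", "G", "T")
  vapply(code, function(v) {
    if (is.na(v)) return(NA_character_)
    b <- character(k)
    for (i in k:1) { b[i] <- bases[v %% 4 + 1]; v <- v %/% 4 }
    paste(b, collapse = "")
  }, character(1))
}

#' Build a canonical k-mer index from labeled references
#'
#' Indexes every canonical k-mer of every reference sequence under its
#' label. K-mers containing N are skipped; a reference shorter than k is
#' indexed with zero k-mers (with a warning).
#'
#' @param references named character vector of reference sequences, or
#'   the path of a (multi-)FASTA file whose headers' first
#'   whitespace-delimited tokens are the labels.
#' @param k word length, 8..26. Suggested defaults: 16 for genome
#'   references, 12 for rRNA references.
#' @return A [KmerIndex-class].
#' @export
buildKmerIndex <- function(references, k) {
  if (is.character(references) && length(references) == 1L &&
      is.null(names(references)) && file.exists(references))
    references <- readFastaSeqs(references)
  if (!length(references)) stop("no reference sequences supplied")
  if (is.null(names(references)) || any(!nzchar(names(references))))
    stop("reference sequences must be labeled")
  if (anyDuplicated(names(references)))
    stop("duplicate reference label(s): ",
         paste(unique(names(references)[duplicated(names(references))]),
               collapse = ", "))
  k <- as.integer(k)
  km <- lapply(names(references), function(lab) {
    s <- references[[lab]]
    if (nchar(s) < k) {
      warning("reference '", lab, "' is shorter than k; indexed with 0 k-mers")
      return(numeric())
    }
    fc <- kmerCodes(s, k)
    unique(fc$code[!is.na(fc$code)])
  })
  names(km) <- names(references)
  new("KmerIndex", k = k, kmers = km,
      refLengths = setNames(nchar(references), names(references)))
}

## Per-read fraction of valid k-mers found in each label's set.
## Returns list(score = n x labels matrix, nValid = per-read valid k-mer
## count). Reads shorter than k (or all-N windows) get nValid 0.
kmerScoreMatrix <- function(reads, index) {
  seqs <- if (is(reads, "ReadSet")) readSeqs(reads) else reads
  n <- length(seqs)
  labs <- sort(names(index@kmers))
  fc <- kmerCodes(seqs, index@k)
  ok <- !is.na(fc$code)
  code <- fc$code[ok]; rd <- fc$read[ok]
  nValid <- numeric(n)
  if (length(rd)) {
    tb <- tabulate(rd, nbins = n)
    nValid <- as.numeric(tb)
  }
  score <- matrix(0, n, length(labs), dimnames = list(NULL, labs))
  if (length(code)) {
    for (lab in labs) {
      hit <- code %in% index@kmers[[lab]]
      if (any(hit)) {
        hs <- tabulate(rd[hit], nbins = n)
        score[, lab] <- ifelse(nValid > 0, hs / nValid, 0)
      }
    }
  }
  list(score = score, nValid = nValid)
}

#' Fraction of read k-mers present in an index
#'
#' For each read, the fraction of its valid (N-free) canonical k-mers
#' that occur anywhere in the index (any label).
#'
#' @param reads a [ReadSet-class] or character vector of sequences.
#' @param index a [KmerIndex-class].
#' @return Numeric vector of hit fractions; `NA` for reads shorter than
#'   k (no valid k-mers).
#' @export
kmerHitFraction <- function(reads, index) {
  seqs <- if (is(reads, "ReadSet")) readSeqs(reads) else reads
  n <- length(seqs)
  allK <- unique(unlist(index@kmers, use.names = FALSE))
  fc <- kmerCodes(seqs, index@k)
  ok <- !is.na(fc$code)
  code <- fc$code[ok]; rd <- fc$read[ok]
  nValid <- as.numeric(tabulate(rd, nbins = n))
  hits <- numeric(n)
  if (length(code)) {
    hit <- code %in% allK
    hits <- as.numeric(tabulate(rd[hit], nbins = n))
  }
  out <- ifelse(nValid > 0, hits / nValid, NA_real_)
  out
}

#' Extract putative rRNA (rDNA) reads
#'
#' Emits, in input order, the reads whose fraction of canonical k-mers
#' present in the rRNA reference index is at least `minHitFraction`.
#' Reads shorter than k are skipped (counted in attribute `nSkipped`).
#'
#' @param reads a [ReadSet-class].
#' @param rrnaIndex a [KmerIndex-class] built from 16S/18S rRNA
#'   reference sequences (suggested k = 12).
#' @param minHitFraction minimum hit fraction (default 0.5).
#' @return The extracted [ReadSet-class], with attributes `nSkipped` and
#'   `hitFraction` (fractions of the extracted reads).
#' @export
extractRdnaReads <- function(reads, rrnaIndex, minHitFraction = 0.5) {
  hf <- kmerHitFraction(reads, rrnaIndex)
  keep <- which(!is.na(hf) & hf >= minHitFraction)
  out <- reads[keep]
  attr(out, "nSkipped") <- sum(is.na(hf))
  attr(out, "hitFraction") <- hf[keep]
  out
}

#' Assign reads to reference labels by best k-mer score
#'
#' Scores each read against every label as the fraction of its valid
#' canonical k-mers shared with that label's reference; the best label
#' wins if its score reaches `minScore`, with ties broken by the
#' lexicographically smallest label; otherwise the read is "unassigned".
#'
#' @param reads a [ReadSet-class] or character vector of sequences.
#' @param index a [KmerIndex-class] over candidate references.
#' @param minScore assignment threshold (default 0.4, calibrated so that
#'   a 100 bp read with up to 3 substitution errors at k = 16 is still
#'   assignable; see the methods vignette).
#' @return A data.frame with columns `read_id`, `label`, `score`; the
#'   number of best-score ties is attached as attribute `nTies`.
#' @export
assignTaxonomy <- function(reads, index, minScore = 0.4) {
  ids <- if (is(reads, "ReadSet")) readIds(reads)
         else as.character(seq_along(reads))
  sm <- kmerScoreMatrix(reads, index)
  n <- nrow(sm$score)
  if (n == 0L)
    return(structure(data.frame(read_id = character(),
                                label = character(), score = numeric()),
                     nTies = 0L))
  best <- max.col(sm$score, ties.method = "first")
  bestScore <- sm$score[cbind(seq_len(n), best)]
  label <- colnames(sm$score)[best]
  unas <- bestScore < minScore | sm$nValid == 0
  label[unas] <- "unassigned"
  nTies <- sum(rowSums(sm$score == bestScore & sm$score > 0) > 1L &
               !unas)
  structure(data.frame(read_id = ids, label = label, score = bestScore,
                       stringsAsFactors = FALSE),
            nTies = nTies)
}
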