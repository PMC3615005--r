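## Shared fixture builders. Everything is generated in code; seeds are
## fixed so fixtures are identical across runs and platforms.

## ReadSet from a list of integer quality vectors (sequences random)
readsWithQuals <- function(quals, seed = 100) {
  seqs <- withr_seed(seed, vapply(lengths(quals), function(L)
    paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""),
    character(1)))
  ReadSet(sprintf("q%03d", seq_along(quals)), seqs, qual = quals)
}

## run expr under a seed, restoring the RNG state afterwards
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

## random ReadSet of n reads, length L, random qualities in [qmin, qmax]
randomReads <- function(n, L = 50, qmin = 0, qmax = 40, seed = 101) {
  withr_seed(seed, {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""),
      character(1))
    quals <- lapply(seq_len(n), function(i)
      sample(qmin:qmax, L, replace = TRUE))
    ReadSet(sprintf("r%05d", seq_len(n)), seqs, qual = quals)
  })
}

## brute-force canonical k-mer enumeration (string-based oracle,
## independent of the package's numeric k-mer engine)
bruteCanonicalKmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character())
  kms <- substring(seq, 1:(L - k + 1), (1:(L - k + 1)) + k - 1)
  kms <- kms[!grepl("N", kms, fixed = TRUE)]
  rc <- vapply(strsplit(chartr("ACGT", "TGCA", kms), ""),
               function(x) paste(rev(x), collapse = ""), character(1))
  ifelse(kms < rc, kms, rc)
}

## single-component low-coverage unpaired read stream for artifact tests
artifactFixture <- function(seed = 2024, coverage = 0.5,
                            genomeLength = 100000) {
  g <- generateGenome(genomeLength, 0.5, seed)
  s <- simulateReads(g, "fix", coverage = coverage, seed = seed + 1)
  s$r1
}
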