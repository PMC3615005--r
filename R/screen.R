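## Run code under a seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' Randomly subsample a read set
#'
#' By default each read is kept independently with probability
#' `proportion` (Bernoulli sampling, so the sample size is binomial);
#' with `exactSize = TRUE` exactly `round(proportion * n)` reads are
#' drawn without replacement. Input order is preserved and the result is
#' deterministic for a fixed input order and seed.
#'
#' @param reads a [ReadSet-class].
#' @param proportion sampling proportion in (0, 1].
#' @param seed integer seed.
#' @param exactSize draw an exact-size sample instead (default FALSE).
#' @return The sampled [ReadSet-class]; selected indices are attached as
#'   attribute `indices`.
#' @export
randomSubsample <- function(reads, proportion, seed = 1L,
                            exactSize = FALSE) {
  if (!is.numeric(proportion) || proportion <= 0 || proportion > 1)
    stop("configuration error: proportion must lie in (0, 1]")
  n <- length(reads)
  idx <- withSeed(seed, {
    if (exactSize) sort(sample.int(n, round(proportion * n)))
    else which(runif(n) < proportion)
  })
  out <- reads[idx]
  attr(out, "indices") <- idx
  out
}

#' Classify a read subsample into an abundance profile
#'
#' Assigns each read to its best-scoring reference label via
#' [assignTaxonomy()] and aggregates the assignments into an
#' [AbundanceProfile-class] (counts and proportions over classified
#' reads, plus the unassigned count).
#'
#' @param sample a [ReadSet-class] (typically from [randomSubsample()]).
#' @param genomeIndex a [KmerIndex-class] over candidate source genomes.
#' @param minScore assignment threshold (default 0.4; see
#'   [assignTaxonomy()]).
#' @return An [AbundanceProfile-class]; the per-read assignment table is
#'   attached as attribute `assignments`.
#' @export
classifySubsample <- function(sample, genomeIndex, minScore = 0.4) {
  if (length(sample) == 0L) {
    warning("empty sample: returning an empty profile")
    return(AbundanceProfile(character(),
                            allLabels = indexLabels(genomeIndex)))
  }
  asg <- assignTaxonomy(sample, genomeIndex, minScore = minScore)
  prof <- AbundanceProfile(asg$label, allLabels = indexLabels(genomeIndex))
  attr(prof, "assignments") <- asg
  prof
}

#' Kullback-Leibler divergence between two composition profiles
#'
#' Computes `sum(p * ln(p / q))` after aligning the two profiles on the
#' union of their labels, replacing zero cells with the pseudocount and
#' renormalising. Non-negative, and zero exactly when the (renormalised)
#' profiles coincide.
#'
#' @param p observed proportions: an [AbundanceProfile-class] or a named
#'   numeric vector.
#' @param q reference proportions (named numeric vector or profile).
#' @param pseudocount value substituted for zero cells before
#'   renormalisation (default 1e-10).
#' @return Non-negative numeric scalar (natural-log units, nats).
#' @export
klDivergence <- function(p, q, pseudocount = 1e-10) {
  toVec <- function(x) {
    if (is(x, "AbundanceProfile")) profileProportions(x)
    else if (is.numeric(x) && !is.null(names(x))) x
    else stop("profiles must be AbundanceProfile or named numeric")
  }
  p <- toVec(p); q <- toVec(q)
  if (!length(intersect(names(p), names(q))))
    stop("disjoint label sets: p has {",
         paste(names(p), collapse = ", "), "}, q has {",
         paste(names(q), collapse = ", "), "}")
  labs <- sort(union(names(p), names(q)))
  align <- function(x) {
    v <- setNames(numeric(length(labs)), labs)
    v[names(x)] <- x
    v[v <= 0] <- pseudocount
    v / sum(v)
  }
  pv <- align(p); qv <- align(q)
  sum(pv * log(pv / qv))
}

#' De novo contamination screen
#'
#' Runs the two complementary screens over a read set: (1) the
#' qualitative rDNA screen — putative rRNA reads are extracted against
#' the rRNA reference index and taxonomically assigned, giving a ranked
#' per-label rDNA read count; (2) the quantitative random-subsample
#' screen — a seeded Bernoulli subsample is classified against the
#' candidate genome index into an abundance profile. A non-target label
#' is flagged as a candidate contaminant when its share of assigned rDNA
#' reads reaches `dominanceThreshold` (default 2%) and it also appears
#' (count > 0) in the quantitative profile, so the two screens mutually
#' verify each other. With no declared target, all labels are reported
#' and none is flagged.
#'
#' @param reads a [ReadSet-class] (combine both mates for paired data).
#' @param rrnaRefs rRNA (16S/18S) references: a [KmerIndex-class], a
#'   named character vector or a FASTA path. Which marker is screened is
#'   decided purely by the references supplied.
#' @param genomeRefs candidate source genome references (index, named
#'   vector or FASTA path).
#' @param target declared target label(s), or `NULL`.
#' @param sampleProportion subsample proportion (default 0.001).
#' @param seed integer seed for the subsample.
#' @param rrnaK,genomeK word lengths used when references are given as
#'   sequences (defaults 12 and 16).
#' @param minHitFraction rDNA extraction threshold (default 0.5).
#' @param minScore taxonomic assignment threshold (default 0.4).
#' @param dominanceThreshold rDNA dominance fraction for flagging
#'   (default 0.02).
#' @return A [ScreeningResult-class].
#' @export
screenContamination <- function(reads, rrnaRefs, genomeRefs,
                                target = NULL, sampleProportion = 0.001,
                                seed = 1L, rrnaK = 12L, genomeK = 16L,
                                minHitFraction = 0.5, minScore = 0.4,
                                dominanceThreshold = 0.02) {
  rrnaIndex <- if (is(rrnaRefs, "KmerIndex")) rrnaRefs
               else buildKmerIndex(rrnaRefs, rrnaK)
  genomeIndex <- if (is(genomeRefs, "KmerIndex")) genomeRefs
                 else buildKmerIndex(genomeRefs, genomeK)
  rdna <- extractRdnaReads(reads, rrnaIndex, minHitFraction)
  rdnaAsg <- assignTaxonomy(rdna, rrnaIndex, minScore = minScore)
  assigned <- rdnaAsg$label[rdnaAsg$label != "unassigned"]
  rdnaCounts <- setNames(as.numeric(table(factor(assigned,
                           levels = indexLabels(rrnaIndex)))),
                         indexLabels(rrnaIndex))
  sub <- randomSubsample(reads, sampleProportion, seed = seed)
  profile <- suppressWarnings(
    classifySubsample(sub, genomeIndex, minScore = minScore))
  flagged <- character()
  if (!is.null(target) && length(target)) {
    totR <- sum(rdnaCounts)
    dominant <- if (totR > 0)
      names(rdnaCounts)[rdnaCounts / totR >= dominanceThreshold]
      else character()
    inProfile <- names(profileCounts(profile))[profileCounts(profile) > 0]
    flagged <- sort(setdiff(intersect(dominant, inProfile), target))
  }
  new("ScreeningResult", rdnaCounts = rdnaCounts,
      nRdnaReads = length(rdna), profile = profile, flagged = flagged,
      target = as.character(target %||% character()),
      params = list(sampleProportion = sampleProportion, seed = seed,
                    rrnaK = indexK(rrnaIndex), genomeK = indexK(genomeIndex),
                    minHitFraction = minHitFraction, minScore = minScore,
                    dominanceThreshold = dominanceThreshold,
                    nSubsampled = length(sub)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a screening result as a machine-readable table
#'
#' One row per label: rDNA read count, subsample count, subsample
#' proportion and whether the label was flagged.
#'
#' @param x a [ScreeningResult-class].
#' @param path output TSV path.
#' @return Invisibly, the table (data.frame).
#' @export
writeScreeningTable <- function(x, path) {
  labs <- sort(union(names(x@rdnaCounts), names(profileCounts(x@profile))))
  df <- data.frame(
    label = labs,
    rdna_count = as.numeric(x@rdnaCounts[labs]),
    sample_count = as.numeric(profileCounts(x@profile)[labs]),
    proportion = as.numeric(profileProportions(x@profile)[labs]),
    flagged = labs %in% x@flagged)
  df$rdna_count[is.na(df$rdna_count)] <- 0
  df$sample_count[is.na(df$sample_count)] <- 0
  df$proportion[is.na(df$proportion)] <- 0
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
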