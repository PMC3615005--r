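#' @importFrom Biostrings reverseComplement
NULL

#' Generate a random genome sequence
#'
#' I.i.d. bases with the requested GC content split evenly between G
#' and C (and AT evenly between A and T); deterministic for a fixed
#' seed.
#'
#' @param length genome length in bp (>= 1000).
#' @param gc GC fraction in (0, 1) (default 0.5).
#' @param seed integer seed.
#' @return A single character string over A/C/G/T.
#' @export
generateGenome <- function(length, gc = 0.5, seed = 1L) {
  stopifnot(length >= 1000, gc > 0, gc < 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  withSeed(seed,
    paste(sample(names(p), length, replace = TRUE, prob = p),
          collapse = ""))
}

.revcompChar <- function(x) {
  if (!length(x)) return(character())
  as.character(reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate paired-end reads from a genome
#'
#' Fragments of `insertSize` bases (optionally Gaussian-jittered by
#' `insertSd`) start uniformly on the forward strand; mate 1 is read
#' forward from the fragment 5' end and mate 2 reverse-complemented from
#' the fragment 3' end. Each base is substituted independently with
#' probability `errorRate` to a uniformly chosen different base.
#' Qualities are a constant `baseQuality`. The number of pairs is
#' `round(coverage * genomeLength / (2 * readLength))`, so total
#' sequenced bases / genome length equals the requested fold coverage.
#'
#' @param genome a genome sequence (single character string).
#' @param label source label recorded in read ids and truth.
#' @param coverage fold coverage (> 0).
#' @param readLength read length in bp (default 100).
#' @param insertSize mean fragment length (default 500).
#' @param insertSd fragment length SD (default 0 = fixed).
#' @param errorRate per-base substitution probability (default 0.01).
#' @param baseQuality constant Phred score for all bases (default 35).
#' @param seed integer seed.
#' @return A list: `r1`, `r2` ([ReadSet-class]s, mates 1/2) and `truth`,
#'   a data.frame with one row per read (`read_id`, `label`, `pos` —
#'   1-based start of the read on the forward strand, `strand`,
#'   `n_errors`).
#' @export
simulateReads <- function(genome, label, coverage, readLength = 100L,
                          insertSize = 500L, insertSd = 0,
                          errorRate = 0.01, baseQuality = 35L,
                          seed = 1L) {
  G <- nchar(genome)
  readLength <- as.integer(readLength)
  stopifnot(coverage > 0, errorRate >= 0, errorRate < 0.5,
            readLength >= 1L, insertSize >= readLength)
  if (insertSize > G)
    stop("insert size exceeds genome length")
  nPairs <- round(coverage * G / (2 * readLength))
  withSeed(seed, {
    ins <- if (insertSd > 0)
      pmin(pmax(round(stats::rnorm(nPairs, insertSize, insertSd)),
                readLength), G)
    else rep(as.integer(insertSize), nPairs)
    start <- 1L + floor(runif(nPairs) * (G - ins + 1))
    r1seq <- substring(genome, start, start + readLength - 1L)
    r2start <- start + ins - readLength
    r2seq <- .revcompChar(substring(genome, r2start,
                                    r2start + readLength - 1L))
    seqs <- c(rbind(r1seq, r2seq))  # interleave r1/r2 per pair
    nReads <- 2L * nPairs
    nErr <- integer(nReads)
    if (errorRate > 0 && nReads > 0) {
      mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE),
                           use.names = FALSE),
                    nrow = nReads, ncol = readLength, byrow = TRUE)
      err <- matrix(runif(nReads * readLength) < errorRate,
                    nReads, readLength)
      idx <- which(err)
      if (length(idx)) {
        bases <- c("A", "C", "G", "T")
        code <- match(mat[idx], bases) - 1L
        shift <- sample.int(3L, length(idx), replace = TRUE)
        mat[idx] <- bases[((code + shift) %% 4L) + 1L]
      }
      nErr <- as.integer(rowSums(err))
      seqs <- do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
    }
    stems <- sprintf("%s_%07d", label, seq_len(nPairs))
    ids <- c(rbind(paste0(stems, "/1"), paste0(stems, "/2")))
    qual <- strrep(intToUtf8(33L + as.integer(baseQuality)), readLength)
    odd <- seq(1L, nReads, by = 2L); even <- odd + 1L
    r1 <- new("ReadSet", id = ids[odd], seq = seqs[odd],
              qual = rep(qual, nPairs), mate = rep(1L, nPairs))
    r2 <- new("ReadSet", id = ids[even], seq = seqs[even],
              qual = rep(qual, nPairs), mate = rep(2L, nPairs))
    truth <- data.frame(
      read_id = ids,
      label = label,
      pos = c(rbind(start, r2start)),
      strand = rep(c("+", "-"), nPairs),
      n_errors = nErr,
      stringsAsFactors = FALSE)
    list(r1 = r1, r2 = r2, truth = truth)
  })
}

#' Mix simulated read sets into one shuffled dataset
#'
#' Concatenates the components and applies one deterministic pair-level
#' shuffle; the truth table covers every emitted read exactly once and
#' per-component pair proportions are recorded.
#'
#' @param sims list of [simulateReads()] results.
#' @param seed integer shuffle seed.
#' @return A list: `r1`, `r2`, `truth`, and `proportions` (named vector
#'   of per-component read fractions).
#' @export
mixDatasets <- function(sims, seed = 1L) {
  stopifnot(length(sims) >= 1L)
  rl <- unique(unlist(lapply(sims, function(s)
    unique(c(readLengths(s$r1), readLengths(s$r2))))))
  if (length(rl) > 1L)
    stop("components must share one read length")
  r1 <- do.call(c, lapply(sims, `[[`, "r1"))
  r2 <- do.call(c, lapply(sims, `[[`, "r2"))
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  nPairs <- length(r1)
  perm <- withSeed(seed, sample.int(nPairs))
  r1 <- r1[perm]; r2 <- r2[perm]
  counts <- vapply(sims, function(s) length(s$r1), numeric(1))
  labs <- vapply(sims, function(s) s$truth$label[1], character(1))
  list(r1 = r1, r2 = r2, truth = truth,
       proportions = setNames(counts / sum(counts), labs))
}

#' Inject sequencing artifacts into a read set
#'
#' Emulates common library artifacts on disjoint, randomly selected
#' subsets of the reads: exact duplicates (the copy is re-emitted right
#' after its original, id suffixed "_dup"), tag contamination (a tag
#' sequence prepended at the 5' end or appended at the 3' end,
#' alternating), and 3'-decaying qualities (linear ramp from the read's
#' own first-base quality down to `decayMinQuality`). The truth lists
#' every injected artifact by read id.
#'
#' @param reads a [ReadSet-class].
#' @param duplicateRate,tagRate,decayRate per-read selection
#'   probabilities in \[0, 1) with sum < 1; selections are disjoint.
#' @param tagSeq tag sequence to inject (required if `tagRate` > 0).
#' @param decayMinQuality Phred floor of the decay ramp (default 2).
#' @param seed integer seed.
#' @return A list: `reads` (with artifacts) and `truth` (list with
#'   `duplicateIds`, `duplicateOf`, `taggedIds`, `tagEnd`, `decayedIds`).
#' @export
injectArtifacts <- function(reads, duplicateRate = 0, tagSeq = NULL,
                            tagRate = 0, decayRate = 0,
                            decayMinQuality = 2L, seed = 1L) {
  stopifnot(duplicateRate >= 0, duplicateRate < 1, tagRate >= 0,
            tagRate < 1, decayRate >= 0, decayRate < 1,
            duplicateRate + tagRate + decayRate < 1)
  if (tagRate > 0 && is.null(tagSeq))
    stop("tagSeq required when tagRate > 0")
  n <- length(reads)
  withSeed(seed, {
    u <- runif(n)
    dupSel <- which(u < duplicateRate)
    tagSel <- which(u >= duplicateRate & u < duplicateRate + tagRate)
    decaySel <- which(u >= duplicateRate + tagRate &
                      u < duplicateRate + tagRate + decayRate)
    id <- reads@id; seq <- reads@seq; qual <- reads@qual
    tagEnd <- character(length(tagSel))
    if (length(tagSel)) {
      tagSeq <- toupper(tagSeq)
      tq <- strrep(substr(qual[tagSel], 1L, 1L), nchar(tagSeq))
      five <- seq_along(tagSel) %% 2L == 1L
      s5 <- tagSel[five]; s3 <- tagSel[!five]
      seq[s5] <- paste0(tagSeq, seq[s5])
      qual[s5] <- paste0(tq[five], qual[s5])
      seq[s3] <- paste0(seq[s3], tagSeq)
      qual[s3] <- paste0(qual[s3], tq[!five])
      tagEnd[five] <- "5prime"; tagEnd[!five] <- "3prime"
    }
    if (length(decaySel)) {
      qual[decaySel] <- vapply(decaySel, function(i) {
        L <- nchar(qual[i])
        q0 <- utf8ToInt(substr(qual[i], 1L, 1L)) - 33L
        ramp <- round(q0 - (q0 - decayMinQuality) *
                      (seq_len(L) - 1L) / max(L - 1L, 1L))
        intToUtf8(pmax(ramp, 0L) + 33L)
      }, character(1))
    }
    ord <- sort(c(seq_len(n), dupSel + 0.5))
    src <- floor(ord)
    isDup <- ord != src
    outId <- ifelse(isDup, paste0(id[src], "_dup"), id[src])
    out <- new("ReadSet", id = outId, seq = seq[src], qual = qual[src],
               mate = reads@mate[src])
    list(reads = out,
         truth = list(duplicateIds = paste0(id[dupSel], "_dup"),
                      duplicateOf = id[dupSel],
                      taggedIds = id[tagSel], tagEnd = tagEnd,
                      decayedIds = id[decaySel]))
  })
}

#' Study mixture designs at desk scale
#'
#' Returns the component table of one of the two built-in species
#' mixtures, scaled down so the whole design simulates in minutes:
#' `"genomic"` — a eukaryotic target (yeast-like, 70x) plus two
#' bacterial contaminants (20x each), mixed 82.5/6.7/10.8% by reads,
#' 100 bp reads, at 1/100 scale by default; `"metagenomic"` — ten
#' oral-microbiome-like genomes (30x combined) with human-like (0.3x)
#' and alga-like (2x) eukaryotic contamination, 50.5/12.2/37.3% by
#' reads, 70 bp reads, at 1/500 scale by default. Full-scale genome
#' lengths are derived from the designs' read counts
#' (reads x readLength / coverage).
#'
#' @param type "genomic" or "metagenomic".
#' @param scale linear genome-length scale factor (default 0.01 genomic,
#'   0.002 metagenomic).
#' @return A list: `components` (data.frame with label, genomeLength,
#'   coverage, gc), `readLength`, `target` and `contaminants` labels.
#' @export
communityDesign <- function(type = c("genomic", "metagenomic"),
                            scale = NULL) {
  type <- match.arg(type)
  if (type == "genomic") {
    scale <- scale %||% 0.01
    comp <- data.frame(
      label = c("S_cerevisiae", "C_thermocellum", "E_coli"),
      genomeLength = round(c(8957552 * 100 / 70, 726328 * 100 / 20,
                             1173068 * 100 / 20) * scale),
      coverage = c(70, 20, 20),
      gc = c(0.38, 0.39, 0.51),
      stringsAsFactors = FALSE)
    list(components = comp, readLength = 100L,
         target = "S_cerevisiae",
         contaminants = c("C_thermocellum", "E_coli"))
  } else {
    scale <- scale %||% 0.002
    oral <- sprintf("oral_%02d", 1:10)
    comp <- data.frame(
      label = c("H_sapiens", "C_reinhardtii", oral),
      genomeLength = round(c(13965464 * 70 / 0.3, 3377606 * 70 / 2,
                             rep(10306092 * 70 / 30 / 10, 10)) * scale),
      coverage = c(0.3, 2, rep(30, 10)),
      gc = c(0.41, 0.64, round(seq(0.35, 0.60, length.out = 10), 2)),
      stringsAsFactors = FALSE)
    list(components = comp, readLength = 70L,
         target = oral,
         contaminants = c("H_sapiens", "C_reinhardtii"))
  }
}

#' Simulate a species mixture with embedded rRNA regions
#'
#' Generates one random genome per design component with a designated
#' rRNA-like region (a genome subsequence that is also emitted as the
#' component's rRNA reference, giving the rDNA screen ground truth at
#' desk scale), simulates paired reads per component at the design
#' coverages, and mixes them into one shuffled dataset.
#'
#' @param design a [communityDesign()] list (default: genomic design).
#' @param insertSize,insertSd,errorRate,baseQuality as in
#'   [simulateReads()].
#' @param rrnaLength length of the embedded rRNA region (default 1500).
#' @param seed master integer seed; all component seeds derive from it.
#' @return A list: `r1`, `r2`, `truth`, `proportions`, `genomes` (named
#'   character), `rrna` (named character, one entry per component),
#'   `rrnaRegions` (data.frame label/start/end), and the `design`.
#' @export
simulateCommunity <- function(design = communityDesign("genomic"),
                              insertSize = 500L, insertSd = 0,
                              errorRate = 0.01, baseQuality = 35L,
                              rrnaLength = 1500L, seed = 1L) {
  comp <- design$components
  nC <- nrow(comp)
  subseeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L,
                                        2L * nC + 1L))
  genomes <- character(nC); rrna <- character(nC)
  regions <- data.frame(label = comp$label, start = NA_integer_,
                        end = NA_integer_)
  sims <- vector("list", nC)
  for (i in seq_len(nC)) {
    g <- generateGenome(comp$genomeLength[i], comp$gc[i], subseeds[i])
    rs <- max(1L, floor(comp$genomeLength[i] / 3))
    re <- min(rs + rrnaLength - 1L, comp$genomeLength[i])
    genomes[i] <- g
    rrna[i] <- substr(g, rs, re)
    regions$start[i] <- rs; regions$end[i] <- re
    sims[[i]] <- simulateReads(g, comp$label[i], comp$coverage[i],
                               readLength = design$readLength,
                               insertSize = insertSize,
                               insertSd = insertSd,
                               errorRate = errorRate,
                               baseQuality = baseQuality,
                               seed = subseeds[nC + i])
  }
  names(genomes) <- comp$label
  names(rrna) <- comp$label
  mixed <- mixDatasets(sims, seed = subseeds[2L * nC + 1L])
  c(mixed, list(genomes = genomes, rrna = rrna, rrnaRegions = regions,
                design = design))
}

#' Which truth rows are rDNA reads?
#'
#' A read counts as an rDNA read when it lies entirely within its source
#' component's embedded rRNA region.
#'
#' @param truth a truth data.frame from [simulateCommunity()].
#' @param rrnaRegions the `rrnaRegions` table from the same simulation.
#' @param readLength read length in bp.
#' @return Logical vector over truth rows.
#' @export
isRdnaRead <- function(truth, rrnaRegions, readLength) {
  m <- match(truth$label, rrnaRegions$label)
  truth$pos >= rrnaRegions$start[m] &
    truth$pos + readLength - 1L <= rrnaRegions$end[m]
}

#' Write a simulation to disk
#'
#' Emits R1/R2 FASTQ (optionally gzipped), the genome and rRNA reference
#' FASTA files and the truth table as TSV.
#'
#' @param sim a [simulateCommunity()] result.
#' @param outDir output directory.
#' @param gzip gzip the FASTQ files (default TRUE).
#' @return Invisibly, the named vector of written paths.
#' @export
writeSimulation <- function(sim, outDir, gzip = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- c(
    r1 = file.path(outDir, paste0("reads_R1", ext)),
    r2 = file.path(outDir, paste0("reads_R2", ext)),
    genomes = file.path(outDir, "genomes.fa"),
    rrna = file.path(outDir, "rrna.fa"),
    truth = file.path(outDir, "truth.tsv"))
  writeFastq(sim$r1, paths[["r1"]])
  writeFastq(sim$r2, paths[["r2"]])
  writeFasta(sim$genomes, paths[["genomes"]])
  writeFasta(sim$rrna, paths[["rrna"]])
  write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
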