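test_that("generated genomes hit their GC target within binomial bounds", {
  for (gc in c(0.5, 0.9)) {
    g <- generateGenome(10000, gc, 111)
    obs <- mean(strsplit(g, "")[[1]] %in% c("G", "C"))
    expect_lt(abs(obs - gc), 3 * sqrt(gc * (1 - gc) / 10000))
  }
  expect_identical(generateGenome(2000, 0.5, 7),
                   generateGenome(2000, 0.5, 7))
  expect_error(generateGenome(500, 0.5, 1))
})

test_that("pair counts follow the coverage identity", {
  g <- generateGenome(12000, 0.5, 112)
  for (cov in c(2, 7.5, 30)) {
    s <- simulateReads(g, "g", coverage = cov, readLength = 100, seed = 113)
    expect_identical(length(s$r1), as.integer(round(cov * 12000 / 200)))
    ## emitted bases / genome length == coverage up to rounding
    expect_lt(abs(2 * length(s$r1) * 100 / 12000 - cov), 200 * 100 / 12000)
  }
  expect_error(simulateReads(g, "g", 1, insertSize = 20000), "insert")
})

test_that("error-free reads are exact genome substrings in both orientations", {
  g <- generateGenome(8000, 0.5, 114)
  s <- simulateReads(g, "g", 2, errorRate = 0, seed = 115)
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  expect_true(all(vapply(readSeqs(s$r1), grepl, logical(1), x = g,
                         fixed = TRUE)))
  expect_true(all(vapply(rc(readSeqs(s$r2)), grepl, logical(1), x = g,
                         fixed = TRUE)))
  ## truth records positions that reproduce the reads
  i <- 5L
  expect_identical(readSeqs(s$r1)[i],
                   substr(g, s$truth$pos[2 * i - 1],
                          s$truth$pos[2 * i - 1] + 99))
})

test_that("substitution errors match the configured rate and the truth", {
  g <- generateGenome(30000, 0.5, 116)
  s <- simulateReads(g, "g", 10, errorRate = 0.01, seed = 117)
  nReads <- 2 * length(s$r1)
  mu <- mean(s$truth$n_errors)
  expect_lt(abs(mu - 1), 3 * sqrt(1 * 0.99 / nReads) + 0.05)
  ## independent recomputation of mismatches for mate-1 reads
  mm <- vapply(seq_len(50), function(i) {
    ref <- substr(g, s$truth$pos[2 * i - 1], s$truth$pos[2 * i - 1] + 99)
    sum(strsplit(readSeqs(s$r1)[i], "")[[1]] != strsplit(ref, "")[[1]])
  }, numeric(1))
  expect_identical(mm, as.numeric(s$truth$n_errors[2 * (1:50) - 1]))
})

test_that("mixing preserves truth, proportions and pair integrity", {
  g1 <- generateGenome(4000, 0.5, 118); g2 <- generateGenome(4000, 0.5, 119)
  s1 <- simulateReads(g1, "a", 0.8, seed = 120)  # 16 pairs
  s2 <- simulateReads(g2, "b", 0.2, seed = 121)  # 4 pairs
  m <- mixDatasets(list(s1, s2), seed = 122)
  expect_identical(length(m$r1), 20L)
  expect_equal(unname(m$proportions), c(0.8, 0.2))
  ## truth covers every read exactly once
  ids <- c(readIds(m$r1), readIds(m$r2))
  expect_setequal(ids, m$truth$read_id)
  expect_identical(anyDuplicated(m$truth$read_id), 0L)
  expect_identical(pairStem(readIds(m$r1)), pairStem(readIds(m$r2)))
  ## shuffle is deterministic per seed
  m2 <- mixDatasets(list(s1, s2), seed = 122)
  expect_identical(readIds(m2$r1), readIds(m$r1))
  expect_error(mixDatasets(list(s1, simulateReads(g2, "c", 1,
                                                  readLength = 70,
                                                  seed = 123))),
               "read length")
})

test_that("artifact injection is truthful and rate-calibrated", {
  rs <- artifactFixture()
  n <- length(rs)
  inj <- injectArtifacts(rs, duplicateRate = 0.1, seed = 124)
  nDup <- length(inj$truth$duplicateIds)
  expect_lt(abs(nDup - 0.1 * n), 4 * sqrt(n * 0.1 * 0.9))
  expect_identical(length(inj$reads), n + nDup)
  ## each copy sits right after its original with identical sequence
  pos <- match(inj$truth$duplicateIds, readIds(inj$reads))
  expect_identical(readSeqs(inj$reads)[pos], readSeqs(inj$reads)[pos - 1])
  ## all-zero rates are the identity
  id0 <- injectArtifacts(rs, seed = 125)
  expect_identical(readSeqs(id0$reads), readSeqs(rs))
  expect_identical(readIds(id0$reads), readIds(rs))
})

test_that("tag and decay injection modify the selected reads only", {
  rs <- artifactFixture()
  tag <- "AGATCGGAAGAGC"
  inj <- injectArtifacts(rs, tagSeq = tag, tagRate = 0.05,
                         decayRate = 0.05, seed = 126)
  tr <- inj$truth
  expect_gt(length(tr$taggedIds), 0)
  expect_gt(length(tr$decayedIds), 0)
  expect_identical(intersect(tr$taggedIds, tr$decayedIds), character())
  tagged <- inj$reads[match(tr$taggedIds, readIds(inj$reads))]
  has5 <- startsWith(readSeqs(tagged), tag)
  has3 <- endsWith(readSeqs(tagged), tag)
  expect_true(all(has5 | has3))
  expect_identical(tr$tagEnd == "5prime", has5)
  decayed <- inj$reads[match(tr$decayedIds, readIds(inj$reads))]
  lastQ <- vapply(readQuals(decayed), function(q) q[length(q)], integer(1))
  expect_true(all(lastQ <= 2L))
  untouched <- setdiff(readIds(rs), c(tr$taggedIds, tr$decayedIds))
  expect_identical(
    readSeqs(inj$reads[match(untouched, readIds(inj$reads))]),
    readSeqs(rs[match(untouched, readIds(rs))]))
})

test_that("community simulation embeds rRNA regions inside the genomes", {
  sim <- simulateCommunity(communityDesign("genomic", scale = 0.002),
                           seed = 127)
  expect_identical(names(sim$rrna), names(sim$genomes))
  for (lab in names(sim$rrna)) {
    reg <- sim$rrnaRegions[sim$rrnaRegions$label == lab, ]
    expect_identical(sim$rrna[[lab]],
                     substr(sim$genomes[[lab]], reg$start, reg$end))
  }
  ## proportions near the design's read shares
  expect_equal(unname(sim$proportions),
               c(0.825, 0.067, 0.108), tolerance = 0.01)
})

test_that("metagenomic design mixes twelve components at 70 bp", {
  des <- communityDesign("metagenomic", scale = 0.0005)
  expect_identical(nrow(des$components), 12L)
  expect_identical(des$readLength, 70L)
  sim <- simulateCommunity(des, insertSize = 300, seed = 128)
  expect_identical(unique(readLengths(sim$r1)), 70L)
  ## human-like contaminant holds ~50.5% of reads
  expect_equal(unname(sim$proportions[["H_sapiens"]]), 0.505,
               tolerance = 0.01)
})

test_that("simulation output is identical across repeated runs", {
  s1 <- simulateCommunity(communityDesign("genomic", scale = 0.002),
                          seed = 129)
  s2 <- simulateCommunity(communityDesign("genomic", scale = 0.002),
                          seed = 129)
  expect_identical(readSeqs(s1$r1), readSeqs(s2$r1))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$genomes, s2$genomes)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSimulation(s1, d1, gzip = FALSE)
  writeSimulation(s2, d2, gzip = FALSE)
  for (f in c("reads_R1.fastq", "genomes.fa", "truth.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})
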