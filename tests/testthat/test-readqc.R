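test_that("length trimming truncates sequence and qualities together", {
  rs <- randomReads(5, L = 100, seed = 21)
  tr <- trimToLength(rs, 65)
  expect_identical(unique(readLengths(tr)), 65L)
  expect_identical(readSeqs(tr), substr(readSeqs(rs), 1, 65))
  expect_identical(readQuals(tr)[[1]], readQuals(rs)[[1]][1:65])
  ## no-op on short reads; boundary L = 1
  short <- randomReads(3, L = 50, seed = 22)
  expect_identical(readSeqs(trimToLength(short, 100)), readSeqs(short))
  expect_identical(unique(readLengths(trimToLength(short, 1))), 1L)
})

test_that("end trimming removes maximal low-quality runs only", {
  rs <- readsWithQuals(list(c(5, 10, 40, 40, 10, 5)))
  tr <- trimQualityEnds(rs, 20)
  expect_identical(readQuals(tr)[[1]], c(40L, 40L))
  expect_identical(readSeqs(tr), substr(readSeqs(rs), 3, 4))
  ## all high: unchanged; all low: empty; interior dips retained
  expect_identical(readQuals(trimQualityEnds(readsWithQuals(list(rep(30, 4))), 20))[[1]],
                   rep(30L, 4))
  expect_identical(readLengths(trimQualityEnds(readsWithQuals(list(rep(5, 6))), 20)), 0L)
  expect_identical(readQuals(trimQualityEnds(readsWithQuals(list(c(40, 5, 40))), 20))[[1]],
                   c(40L, 5L, 40L))
})

test_that("end trimming agrees with a brute-force scan oracle", {
  rs <- randomReads(300, L = 30, qmin = 0, qmax = 41, seed = 23)
  for (Q in c(10, 20, 35)) {
    tr <- trimQualityEnds(rs, Q)
    oracle <- vapply(readQuals(rs), function(q) {
      i <- 1L
      while (i <= length(q) && q[i] < Q) i <- i + 1L
      j <- length(q)
      while (j >= i && q[j] < Q) j <- j - 1L
      if (j < i) "" else paste(q[i:j], collapse = ",")
    }, character(1))
    got <- vapply(readQuals(tr), function(q) paste(q, collapse = ","),
                  character(1))
    expect_identical(got, oracle)
  }
})

test_that("quality-fraction verdicts match exhaustive counting", {
  rs <- readsWithQuals(list(c(20, 20, 20, 19)))
  expect_true(passesQualityFraction(rs, 20, 0.75))
  expect_false(passesQualityFraction(rs, 20, 0.8))
  ## f = 0 is vacuous for non-empty reads; empty reads never pass
  expect_true(passesQualityFraction(rs, 40, 0))
  empty <- trimQualityEnds(readsWithQuals(list(rep(1, 5))), 20)
  expect_false(passesQualityFraction(empty, 20, 0))
  rnd <- randomReads(500, L = 20, seed = 24)
  for (f in c(0.25, 0.5, 0.9)) {
    oracle <- vapply(readQuals(rnd), function(q) sum(q >= 20) / length(q) >= f,
                     logical(1))
    expect_identical(passesQualityFraction(rnd, 20, f), oracle)
  }
})

test_that("tag matching scans shifted placements at both ends", {
  rs <- ReadSet("r1", "AAACGTACGTTT")
  ts <- TagSet(c(t1 = "ACGT"), maxMismatches = 0, maxShift = 2)
  m <- findTagMatch(rs, ts)
  expect_identical(m$tag, "t1")
  expect_identical(m$end, "5prime")
  expect_identical(m$shift, 2L)
  ## no placement without mismatches
  expect_true(is.na(findTagMatch(rs, TagSet(c(t = "TTTT"), 0, 0))$tag))
  ## tag longer than read is skipped, not an error
  expect_true(is.na(findTagMatch(ReadSet("s", "ACG"),
                                 TagSet(c(t = "ACGTACGT"), 1, 2))$tag))
})

test_that("tag matching agrees with an exhaustive placement oracle", {
  set.seed(25)
  reads <- randomReads(200, L = 30, seed = 25)
  tags <- c(a = "ACGTTGCA", b = "GGGTTTCC")
  for (mm in c(0L, 2L)) {
    ts <- TagSet(tags, maxMismatches = mm, maxShift = 4)
    got <- findTagMatch(reads, ts)
    oracle <- vapply(readSeqs(reads), function(s) {
      L <- nchar(s)
      for (tg in tags) {
        t <- nchar(tg)
        for (end in c(5, 3)) for (sh in 0:4) {
          from <- if (end == 5) sh + 1 else L - sh - t + 1
          if (from < 1 || from + t - 1 > L) next
          sub <- substr(s, from, from + t - 1)
          d <- sum(strsplit(sub, "")[[1]] != strsplit(tg, "")[[1]])
          if (d <= mm) return(TRUE)
        }
      }
      FALSE
    }, logical(1), USE.NAMES = FALSE)
    expect_identical(!is.na(got$tag), oracle)
  }
})

test_that("duplicate keys depend only on sequences, order-sensitively", {
  a <- ReadSet(c("x", "y"), c("ACGT", "ACGT"),
               qual = list(c(1L, 2L, 3L, 4L), c(40L, 40L, 40L, 40L)))
  expect_identical(duplicateKeys(a)[1], duplicateKeys(a)[2])
  p1 <- ReadSet("p/1", "AAAA"); p2 <- ReadSet("p/2", "CCCC")
  expect_false(duplicateKeys(p1, p2) == duplicateKeys(p2, p1))
})

test_that("a fully permissive pipeline is the identity", {
  rs <- randomReads(100, L = 60, seed = 26)
  res <- processReadSet(rs, qcParams(minLengthAfterTrim = 1,
                                     minQualityFraction = 0))
  expect_identical(readSeqs(res$reads), readSeqs(rs))
  expect_identical(readQualStrings(res$reads), readQualStrings(rs))
  expect_identical(sum(removedCounts(res$report)), 0)
})

test_that("report accounting identity holds and causes partition removals", {
  rs <- randomReads(400, L = 40, qmin = 0, qmax = 40, seed = 27)
  params <- qcParams(endTrimQuality = 15, filterQuality = 20,
                     minQualityFraction = 0.6, minLengthAfterTrim = 25,
                     removeDuplicates = TRUE)
  res <- processReadSet(rs, params)
  rep <- res$report
  expect_identical(inputReads(rep),
                   outputReads(rep) + sum(removedCounts(rep)))
  expect_identical(outputReads(rep), as.numeric(length(res$reads)))
  ## idempotence: a second pass removes nothing
  res2 <- processReadSet(res$reads, params)
  expect_identical(readSeqs(res2$reads), readSeqs(res$reads))
  expect_identical(sum(removedCounts(res2$report)), 0)
})

test_that("raising quality thresholds never increases the output", {
  rs <- randomReads(300, L = 40, qmin = 0, qmax = 40, seed = 28)
  outs <- vapply(c(0, 0.3, 0.6, 0.9), function(f)
    outputReads(processReadSet(rs, qcParams(minQualityFraction = f,
                                            minLengthAfterTrim = 1))$report),
    numeric(1))
  expect_true(all(diff(outs) <= 0))
  outsQ <- vapply(c(5, 15, 25, 35), function(q)
    outputReads(processReadSet(rs, qcParams(filterQuality = q,
                                            minQualityFraction = 0.5,
                                            minLengthAfterTrim = 1))$report),
    numeric(1))
  expect_true(all(diff(outsQ) <= 0))
})

test_that("pair policies handle a failing mate as specified", {
  r1 <- ReadSet(c("a/1", "b/1"), c("ACGTACGTAC", "ACGTACGTAC"),
                qual = list(rep(40L, 10), rep(40L, 10)), mate = 1)
  r2 <- ReadSet(c("a/2", "b/2"), c("TTTTTTTTTT", "ACGTACGTAC"),
                qual = list(rep(2L, 10), rep(40L, 10)), mate = 2)
  params <- qcParams(filterQuality = 20, minQualityFraction = 0.9,
                     minLengthAfterTrim = 5, keepPairs = "both-pass")
  res <- processReadSet(r1, params, reads2 = r2)
  expect_identical(readIds(res$reads), "b/1")
  rc <- removedCounts(res$report)
  expect_identical(rc[["quality_fraction"]], 1)
  expect_identical(rc[["pair_partner"]], 1)

  params2 <- qcParams(filterQuality = 20, minQualityFraction = 0.9,
                      minLengthAfterTrim = 5, keepPairs = "either-pass")
  res2 <- processReadSet(r1, params2, reads2 = r2)
  expect_identical(readIds(res2$reads), c("a/1", "b/1"))
  expect_identical(sum(removedCounts(res2$report)), 0)
})

test_that("trimming plus threshold-20 filtering echoes its parameters", {
  rs <- randomReads(200, L = 75, qmin = 10, qmax = 40, seed = 29)
  params <- qcParams(targetLength = 65, filterQuality = 20,
                     minQualityFraction = 0.8, minLengthAfterTrim = 30)
  res <- processReadSet(rs, params)
  expect_identical(res$report@params$targetLength, 65L)
  expect_identical(res$report@params$filterQuality, 20L)
  expect_lte(outputReads(res$report), inputReads(res$report))
  expect_true(all(readLengths(res$reads) <= 65L))
})

test_that("contradictory configurations are rejected", {
  expect_error(qcParams(targetLength = 20, minLengthAfterTrim = 30),
               "configuration")
  expect_error(qcParams(filterQuality = 200), "\\[0, 93\\]")
  expect_error(qcParams(minQualityFraction = 1.2), "\\[0, 1\\]")
})

test_that("file-level QC writes outputs and both report formats", {
  d <- withr::local_tempdir()
  g <- generateGenome(20000, 0.5, 33)
  s <- simulateReads(g, "x", coverage = 5, seed = 34)
  writeFastq(s$r1, file.path(d, "R1.fq"))
  writeFastq(s$r2, file.path(d, "R2.fq"))
  res <- runReadQC(file.path(d, "R1.fq"), qcParams(removeDuplicates = TRUE),
                   file2 = file.path(d, "R2.fq"), outDir = file.path(d, "out"))
  expect_true(all(file.exists(res$files)))
  js <- jsonlite::read_json(file.path(d, "out", "readqc_report.json"))
  expect_equal(js$input_reads, 2 * length(s$r1))
  expect_true(file.exists(file.path(d, "out", "readqc_report.txt")))
})
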