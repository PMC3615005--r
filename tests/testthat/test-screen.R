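test_that("Bernoulli subsampling is seeded, ordered and sized binomially", {
  rs <- randomReads(1000, L = 30, seed = 61)
  expect_identical(length(randomSubsample(rs, 1.0, seed = 1)), 1000L)
  a <- randomSubsample(rs, 0.25, seed = 7)
  b <- randomSubsample(rs, 0.25, seed = 7)
  expect_identical(readIds(a), readIds(b))
  expect_false(identical(readIds(a),
                         readIds(randomSubsample(rs, 0.25, seed = 8))))
  ## order preserved
  expect_identical(readIds(a), readIds(rs)[sort(attr(a, "indices"))])
  expect_error(randomSubsample(rs, 0), "proportion")
  expect_error(randomSubsample(rs, 1.5), "proportion")
  ## exact-size mode
  expect_identical(length(randomSubsample(rs, 0.1, seed = 2,
                                          exactSize = TRUE)), 100L)
})

test_that("subsample size stays within 4 sigma of n*p at scale", {
  n <- 200000; p <- 0.001
  rs <- ReadSet(sprintf("r%d", 1:n), rep("ACGT", n))
  sz <- length(randomSubsample(rs, p, seed = 9))
  sigma <- sqrt(n * p * (1 - p))
  expect_lt(abs(sz - n * p), 4 * sigma)
})

test_that("subsample classification equals a per-read assignment loop", {
  refs <- c(X = generateGenome(5000, 0.45, 62),
            Y = generateGenome(5000, 0.55, 63))
  idx <- buildKmerIndex(refs, 16)
  s <- mixDatasets(list(simulateReads(refs[["X"]], "X", 2, seed = 64),
                        simulateReads(refs[["Y"]], "Y", 2, seed = 65)),
                   seed = 66)
  sample <- randomSubsample(s$r1, 0.5, seed = 67)
  prof <- classifySubsample(sample, idx)
  loop <- vapply(seq_len(length(sample)), function(i)
    assignTaxonomy(sample[i], idx)$label, character(1))
  expect_identical(unname(profileCounts(prof)),
                   as.numeric(table(factor(loop[loop != "unassigned"],
                                           levels = names(refs)))))
  expect_identical(nUnassigned(prof), sum(loop == "unassigned"))
  expect_equal(sum(profileProportions(prof)), 1)
})

test_that("single-source samples profile to proportion 1", {
  g <- c(only = generateGenome(5000, 0.5, 68))
  idx <- buildKmerIndex(g, 16)
  s <- simulateReads(g[[1]], "only", 1, errorRate = 0, seed = 69)
  prof <- classifySubsample(s$r1, idx)
  expect_identical(unname(profileProportions(prof)["only"]), 1)
  expect_warning(classifySubsample(s$r1[0], idx), "empty")
})

test_that("KL divergence matches its closed form and Gibbs' inequality", {
  p <- c(a = 0.5, b = 0.5); q <- c(a = 0.25, b = 0.75)
  expect_equal(klDivergence(p, p), 0)
  expect_equal(klDivergence(p, q), 0.5 * log(2) + 0.5 * log(2 / 3),
               tolerance = 1e-12)
  ## non-negativity on random simplex draws, zero handling included
  set.seed(70)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    pv <- rgamma(k, 1); pv <- setNames(pv / sum(pv), letters[1:k])
    qv <- rgamma(k, 1); qv <- setNames(qv / sum(qv), letters[1:k])
    if (i %% 5 == 0) qv[1] <- 0
    expect_gte(klDivergence(pv, qv), 0)
  }
  expect_error(klDivergence(c(a = 1), c(b = 1)), "disjoint")
})

test_that("screening flags dominant non-target labels verified by both methods", {
  sim <- simulateCommunity(communityDesign("genomic", scale = 0.002),
                           seed = 71)
  scr <- screenContamination(c(sim$r1, sim$r2), rrnaRefs = sim$rrna,
                             genomeRefs = sim$genomes,
                             target = "S_cerevisiae",
                             sampleProportion = 0.5, seed = 72)
  expect_setequal(flaggedLabels(scr),
                  c("C_thermocellum", "E_coli"))
  ## the two methods agree on dominant labels (mutual verification)
  rd <- rdnaCounts(scr)
  dominantRdna <- names(rd)[rd / sum(rd) >= 0.02]
  pr <- profileCounts(screenProfile(scr))
  dominantProfile <- names(pr)[pr / sum(pr) >= 0.02]
  expect_setequal(dominantRdna, dominantProfile)
})

test_that("contaminant-free input and undeclared targets produce no flags", {
  des <- communityDesign("genomic", scale = 0.002)
  des$components <- des$components[1, ]
  sim <- simulateCommunity(des, seed = 73)
  scr <- screenContamination(c(sim$r1, sim$r2), sim$rrna, sim$genomes,
                             target = "S_cerevisiae",
                             sampleProportion = 0.5, seed = 74)
  expect_identical(flaggedLabels(scr), character())
  ## no declared target: everything reported, nothing flagged
  sim2 <- simulateCommunity(communityDesign("genomic", scale = 0.002),
                            seed = 75)
  scr2 <- screenContamination(c(sim2$r1, sim2$r2), sim2$rrna, sim2$genomes,
                              target = NULL, sampleProportion = 0.5,
                              seed = 76)
  expect_identical(flaggedLabels(scr2), character())
  expect_identical(sort(names(rdnaCounts(scr2))),
                   sort(names(sim2$genomes)))
})

test_that("a sub-threshold contaminant appears in the profile unflagged", {
  des <- communityDesign("genomic", scale = 0.002)
  ## shrink one contaminant to ~0.5% of reads (coverage down 20x)
  des$components$coverage[2] <- 1
  des$components$genomeLength[3] <- 1000  # drop third component later
  des$components <- des$components[1:2, ]
  sim <- simulateCommunity(des, seed = 77)
  scr <- screenContamination(c(sim$r1, sim$r2), sim$rrna, sim$genomes,
                             target = "S_cerevisiae",
                             sampleProportion = 1.0, seed = 78,
                             dominanceThreshold = 0.02)
  expect_gt(profileCounts(screenProfile(scr))[["C_thermocellum"]], 0)
  expect_false("C_thermocellum" %in% flaggedLabels(scr))
})

test_that("estimated proportions approach truth as the sample grows", {
  sim <- simulateCommunity(communityDesign("genomic", scale = 0.005),
                           seed = 79)
  idx <- buildKmerIndex(sim$genomes, 16)
  reads <- c(sim$r1, sim$r2)
  err <- vapply(c(0.02, 0.1, 0.5), function(p) {
    prof <- classifySubsample(randomSubsample(reads, p, seed = 80), idx)
    sum(abs(profileProportions(prof)[names(sim$proportions)] -
            sim$proportions))
  }, numeric(1))
  expect_lt(err[3], err[1])
  expect_lt(klDivergence(
    classifySubsample(randomSubsample(reads, 0.5, seed = 81), idx),
    sim$proportions), 0.01)
})
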