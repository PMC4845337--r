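# small helper: one-locus matrix from explicit genotype pairs
gmFromPairs <- function(pairs) {
  GenotypeMatrix(matrix(pairs[, 1], ncol = 1),
                 matrix(pairs[, 2], ncol = 1), "fix")
}

test_that("tallyLocus counts alleles, genotypes and heterozygotes", {
  # {AA, AB, AB, AB, AB} with A=100, B=102
  gm <- gmFromPairs(cbind(c(100, 100, 100, 100, 100),
                          c(100, 102, 102, 102, 102)))
  cnt <- tallyLocus(gm, 1)
  expect_equal(cnt$n, 5L)
  expect_equal(cnt$h, 4L)
  expect_equal(unname(cnt$alleleCounts), c(6L, 4L))
  expect_equal(sum(cnt$alleleCounts), 2L * cnt$n)
  expect_equal(sum(cnt$genotypeCounts), cnt$n)
  expect_equal(observedHet(cnt), 0.8)
  # missing excluded from n
  gm2 <- gmFromPairs(cbind(c(100, NA, 102), c(102, NA, 102)))
  expect_equal(tallyLocus(gm2, 1)$n, 2L)
  expect_equal(tallyLocus(gm2, 1)$nMissing, 1L)
  # all-missing locus signals failure
  gm3 <- gmFromPairs(cbind(c(NA, NA), c(NA, NA)))
  expect_null(tallyLocus(gm3, 1))
})

test_that("heterozygosity estimators match closed forms", {
  allHet <- gmFromPairs(cbind(rep(100, 10), rep(102, 10)))
  expect_equal(observedHet(tallyLocus(allHet, 1)), 1.0)
  # n=10, two alleles at 0.5: unbiased He = (20/19) * 0.5
  expect_equal(expectedHet(tallyLocus(allHet, 1)), 20 / 19 * 0.5)
  mono <- gmFromPairs(cbind(rep(100, 6), rep(100, 6)))
  expect_equal(observedHet(tallyLocus(mono, 1)), 0)
  expect_equal(expectedHet(tallyLocus(mono, 1)), 0)
  # algebraic identity: unbiased form is plug-in times 2n/(2n-1)
  set.seed(12)
  for (i in 1:20) {
    gm <- randomGenotypeMatrix(sample(3:20, 1), 1, missingRate = 0)
    cnt <- tallyLocus(gm, 1)
    expect_equal(expectedHet(cnt),
                 expectedHet(cnt, unbiased = FALSE) *
                   2 * cnt$n / (2 * cnt$n - 1))
  }
})

test_that("HWE exact test: enumeration identity and extreme tables", {
  # complete heterozygote deficit: {AA:5, BB:5}
  def <- gmFromPairs(cbind(c(rep(100, 5), rep(102, 5)),
                           c(rep(100, 5), rep(102, 5))))
  res <- hweExactTest(tallyLocus(def, 1), method = "enumerate")
  expect_lt(res$p, 0.01)
  expect_equal(res$totalProb, 1, tolerance = 1e-9)
  # table at Hardy-Weinberg proportions is the conditional mode: p near 1
  hw <- gmFromPairs(cbind(c(rep(100, 25), rep(100, 50), rep(102, 25)),
                          c(rep(100, 25), rep(102, 50), rep(102, 25))))
  expect_gt(hweExactTest(tallyLocus(hw, 1), method = "enumerate")$p, 0.9)
  # probabilities over all tables sum to 1 for multiallelic tables too
  set.seed(13)
  for (k in 2:5) {
    gm <- simHWEMatrix(21, rep(1 / k, k))
    cnt <- tallyLocus(gm, 1)
    if (length(cnt$alleles) < 2) next
    e <- hweExactTest(cnt, method = "enumerate")
    expect_equal(e$totalProb, 1, tolerance = 1e-9)
    expect_gt(e$p, 0)
    expect_lte(e$p, 1)
  }
  # monomorphic locus is undefined
  mono <- gmFromPairs(cbind(rep(100, 5), rep(100, 5)))
  expect_true(is.na(hweExactTest(tallyLocus(mono, 1))$p))
})

test_that("Monte Carlo agrees with enumeration within 3 binomial SE", {
  set.seed(14)
  for (i in 1:3) {
    gm <- simHWEMatrix(21, c(0.45, 0.35, 0.2))
    cnt <- tallyLocus(gm, 1)
    if (length(cnt$alleles) < 2) next
    pe <- hweExactTest(cnt, method = "enumerate")$p
    reps <- 20000L
    pm <- hweExactTest(cnt, method = "monte_carlo", mcReps = reps,
                       seed = 100 + i)$p
    se <- sqrt(pe * (1 - pe) / reps)
    expect_lt(abs(pm - pe), max(3 * se, 2 / reps))
  }
  # Monte Carlo is reproducible under a fixed seed
  gm <- simHWEMatrix(21, c(0.5, 0.5))
  cnt <- tallyLocus(gm, 1)
  p1 <- hweExactTest(cnt, method = "monte_carlo", mcReps = 2000, seed = 7)$p
  p2 <- hweExactTest(cnt, method = "monte_carlo", mcReps = 2000, seed = 7)$p
  expect_identical(p1, p2)
})

test_that("auto method falls back to Monte Carlo above the table limit", {
  set.seed(15)
  gm <- simHWEMatrix(21, rep(0.1, 10))
  cnt <- tallyLocus(gm, 1)
  res <- hweExactTest(cnt, method = "auto", enumTableLimit = 50,
                      mcReps = 2000, seed = 3)
  expect_identical(res$method, "monte_carlo")
  expect_error(hweExactTest(cnt, method = "enumerate",
                            enumTableLimit = 50), "monte_carlo")
})

test_that("null-allele EM: boundary, recovery and oracle agreement", {
  # exact HWE proportions -> r at the boundary
  hw <- gmFromPairs(cbind(c(rep(100, 25), rep(100, 50), rep(102, 25)),
                          c(rep(100, 25), rep(102, 50), rep(102, 25))))
  em <- nullAlleleML(tallyLocus(hw, 1))
  expect_lt(em$r, 1e-4)
  expect_equal(sum(em$p) + em$r, 1, tolerance = 1e-8)
  # log-likelihood is non-decreasing on assorted fixtures
  set.seed(16)
  for (i in 1:10) {
    g <- simulateGenotypes(60, list(simLocus("L", c(0.5, 0.3, 0.2),
                                             nullFreq = runif(1, 0, 0.3))),
                           seed = i)
    cnt <- tallyLocus(g$matrix, 1)
    if (is.null(cnt) || length(cnt$alleles) < 2) next
    emi <- nullAlleleML(cnt)
    expect_true(all(diff(emi$loglik) >= -1e-9))
    expect_gte(emi$r, 0)
  }
  # parameter recovery at n = 1000 within +-0.05; noiseless sizes so the
  # check isolates the genotype model (binning recovery is tested in
  # test-genotype-io.R at realistic per-locus sample sizes)
  for (r in c(0, 0.1, 0.2)) {
    for (s in 1:3) {
      g <- simulateGenotypes(1000, list(simLocus("L", c(0.5, 0.3),
                                                 nullFreq = r)),
                             sizeNoiseSd = 0,
                             seed = 1000 * s + round(100 * r))
      rhat <- nullAlleleML(tallyLocus(g$matrix, 1))$r
      expect_lt(abs(rhat - r), 0.05)
    }
  }
  # EM equals a 1e-3 grid search within 2e-3 on two-allele tables
  set.seed(17)
  for (i in 1:8) {
    n <- sample(15:50, 1)
    g <- simulateGenotypes(n, list(simLocus("L", c(0.6, 0.4),
                                            nullFreq = runif(1, 0, 0.25))),
                           seed = 20 + i)
    cnt <- tallyLocus(g$matrix, 1)
    if (is.null(cnt) || length(cnt$alleles) != 2) next
    emr <- nullAlleleML(cnt)$r
    expect_lt(abs(emr - gridNullAllele(cnt)), 2e-3)
  }
})

test_that("treating missing calls as blanks raises the null estimate", {
  set.seed(18)
  g <- simulateGenotypes(300, list(simLocus("L", c(0.5, 0.5),
                                            nullFreq = 0.25)), seed = 5)
  cnt <- tallyLocus(g$matrix, 1)
  rCond <- nullAlleleML(cnt)$r
  rFull <- nullAlleleML(cnt, includeMissingAsBlanks = TRUE)$r
  expect_gt(rFull, 0)
  expect_gt(rCond, 0)
  # both fits see strong homozygote excess; with blanks as r^2 evidence
  # the full fit also recovers the simulated frequency
  expect_lt(abs(rFull - 0.25), 0.07)
  expect_lt(abs(rCond - 0.25), 0.07)
})

test_that("genotypic LD permutation test behaves at the extremes", {
  set.seed(19)
  x1 <- sample(1:2, 20, TRUE)
  x2 <- sample(1:2, 20, TRUE)
  a <- 100 + 2 * pmin(x1, x2)
  b <- 100 + 2 * pmax(x1, x2)
  gm <- GenotypeMatrix(cbind(a, a), cbind(b, b), "s",
                       lociNames = c("A", "B"))
  # locus B is an exact copy of locus A: minimum attainable p
  res <- genotypicLDTest(gm, "A", "B", permutations = 999, seed = 2)
  expect_equal(res$p, (1 + sum(res$G <= res$G)) / 1000, tolerance = 0.05)
  expect_lte(res$p, 0.05)
  # relabelling individuals leaves p unchanged under the same seed
  perm <- sample(20)
  gm2 <- GenotypeMatrix(cbind(a, a)[perm, ], cbind(b, b)[perm, ], "s",
                        lociNames = c("A", "B"))
  expect_equal(genotypicLDTest(gm2, "A", "B", permutations = 999,
                               seed = 2)$p, res$p)
  # undefined when a locus has fewer than two genotype classes
  mono <- GenotypeMatrix(cbind(a, rep(100, 20)),
                         cbind(b, rep(100, 20)), "s",
                         lociNames = c("A", "B"))
  expect_true(is.na(genotypicLDTest(mono, "A", "B",
                                    permutations = 99)$p))
})

test_that("bonferroni thresholds and flags", {
  bc <- bonferroni(runif(11), alpha = 0.05)
  expect_equal(bc$threshold, 0.05 / 11)
  expect_equal(bonferroni(0.04, 0.05)$threshold, 0.05)
  bc3 <- bonferroni(c(0.004, 0.02, 0.6), alpha = 0.05)
  expect_equal(unname(bc3$flags), c(TRUE, FALSE, FALSE))
  # undefined p-values are skipped but preserved in the flags
  bc4 <- bonferroni(c(0.004, NA, 0.6), alpha = 0.05)
  expect_equal(bc4$k, 2L)
  expect_true(is.na(bc4$flags[2]))
  expect_error(bonferroni(0.5, alpha = 1.2), "alpha")
})

test_that("locusStats assembles a consistent per-locus table", {
  set.seed(20)
  loci <- list(simLocus("poly", c(0.5, 0.3, 0.2)),
               simLocus("mono", 1),
               simLocus("withnull", c(0.6, 0.4), nullFreq = 0.2))
  g <- simulateGenotypes(40, loci, seed = 9)
  st <- locusStats(g$matrix, seed = 101)
  expect_equal(st$locus, c("poly", "mono", "withnull"))
  expect_equal(st$status[2], "M")
  expect_equal(st$na[2], 1L)
  expect_equal(st$he[2], 0)
  expect_true(is.na(st$pHWE[2]))
  expect_true(all(st$ho >= 0 & st$ho <= 1, na.rm = TRUE))
  expect_true(all(st$pHWE > 0 & st$pHWE <= 1, na.rm = TRUE))
  expect_true(all(st$sizeMin <= st$sizeMax, na.rm = TRUE))
  # deterministic under the same seed
  st2 <- locusStats(g$matrix, seed = 101)
  expect_identical(st, st2)
})
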