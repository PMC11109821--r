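test_that("Balding-Nichols drift has the right first two moments", {
  cfg <- simConfig(tree = data.frame(node = c("ROOT", "P"),
                                     parent = c(NA, "ROOT"),
                                     F = c(NA, 0.1)),
                   nSites = 1e5, seed = 81)
  set.seed(81)
  anc <- runif(1e5, 0.05, 0.95)           # the law the config specifies
  fr <- simulateFrequencies(cfg)
  # conditional moments: E[child] = parent, Var[child] = F p (1-p)
  delta <- fr[, "P"] - anc
  expect_lt(abs(mean(delta)), 3 * sd(delta) / sqrt(1e5))
  ratio <- var(delta) / mean(0.1 * anc * (1 - anc))
  expect_lt(abs(ratio - 1), 0.03)
})

test_that("zero drift copies frequencies exactly and seeds are
           deterministic", {
  tr <- data.frame(node = c("ROOT", "A", "B"), parent = c(NA, "ROOT",
                                                          "ROOT"),
                   F = c(NA, 0, 0))
  cfg <- simConfig(tree = tr, nSites = 1000, seed = 5)
  fr <- simulateFrequencies(cfg)
  expect_identical(fr[, "A"], fr[, "B"])
  fr2 <- simulateFrequencies(cfg)
  expect_identical(fr, fr2)
  fr3 <- simulateFrequencies(cfg, seed = 6)
  expect_false(identical(fr, fr3))
})

test_that("genotypes are binomial draws with Mendelian planted relatives", {
  tr <- data.frame(node = c("ROOT", "OUT", "P"),
                   parent = c(NA, "ROOT", "ROOT"), F = c(NA, 0.5, 0.05))
  cfg <- simConfig(tree = tr, nSites = 5000, samplesPerPop = 2, seed = 9,
                   relatives = data.frame(population = "P", degree = 1))
  fr <- simulateFrequencies(cfg)
  fr[, "P"] <- 1                             # force fixation
  sim <- simulateGenotypes(fr, cfg)
  expect_true(all(dosages(sim$gm)[, "P_1"] == 2L))
  # parent-offspring pairs can never be opposite homozygotes
  cfg2 <- simConfig(tree = tr, nSites = 20000, samplesPerPop = 2, seed = 10,
                    relatives = data.frame(population = "P", degree = 1))
  sim2 <- simulateGenotypes(simulateFrequencies(cfg2), cfg2)
  rel <- sim2$truth$relatives
  a <- dosages(sim2$gm)[, rel$sample1]
  b <- dosages(sim2$gm)[, rel$sample2]
  expect_equal(sum((a == 0 & b == 2) | (a == 2 & b == 0)), 0)
  expect_error(simulateGenotypes(simulateFrequencies(cfg),
                                 simConfig(tree = tr, relatives =
                                   data.frame(population = "Q",
                                              degree = 1), nSites = 5000)),
               "absent")
})

test_that("second-degree pairs sit between first-degree and unrelated in
           pseudo-haploid mismatch", {
  tr <- data.frame(node = c("ROOT", "OUT", "P"),
                   parent = c(NA, "ROOT", "ROOT"), F = c(NA, 0.5, 0.05))
  p0 <- matrix(NA_real_, 10, 3)
  for (i in 1:10) {
    cfg <- simConfig(tree = tr, nSites = 10000, samplesPerPop = 2,
                     seed = 200 + i,
                     relatives = data.frame(population = "P",
                                            degree = c(1, 2)))
    sim <- simulateGenotypes(simulateFrequencies(cfg), cfg)
    ph <- pseudoHaploidize(sim$gm, seed = i)
    rel <- sim$truth$relatives
    p0[i, 1] <- pairwiseMismatch(ph, c(rel$sample1[1], rel$sample2[1]))$p0
    p0[i, 2] <- pairwiseMismatch(ph, c(rel$sample1[2], rel$sample2[2]))$p0
    p0[i, 3] <- pairwiseMismatch(ph, c("P_1", "P_2"))$p0
  }
  m <- colMeans(p0)
  expect_lt(m[1], m[2])                       # 1st degree < 2nd degree
  expect_lt(m[2], m[3])                       # 2nd degree < unrelated
})

test_that("planted ROH intervals are fully homozygous inside and leave the
           rest untouched", {
  gm <- mkPopGeno(3000, 2, seed = 91, chroms = 1)
  spec <- data.frame(sample = "s1", chrom = "chr1", start = 2e6,
                     length = 2e6)
  res <- plantRoh(gm, spec, seed = 2)
  gr <- sites(gm)
  inside <- start(gr) >= 2e6 & start(gr) < 4e6
  expect_true(all(dosages(res$gm)[inside, "s1"] %in% c(0L, 2L)))
  expect_identical(dosages(res$gm)[!inside, "s1"],
                   dosages(gm)[!inside, "s1"])
  expect_identical(dosages(res$gm)[, "s2"], dosages(gm)[, "s2"])
  # empty spec returns the matrix bit-exact
  res0 <- plantRoh(gm, NULL)
  expect_identical(dosages(res0$gm), dosages(gm))
  overlap <- rbind(spec, data.frame(sample = "s1", chrom = "chr1",
                                    start = 3e6, length = 1e6))
  expect_error(plantRoh(gm, overlap, seed = 1), "overlapping")
})

test_that("simulated coverage yields the configured Rx by sex", {
  sexes <- c(f = "XX", m = "XY")
  lens <- setNames(rep(60e6, 10), paste0("chr", 1:10))
  cov <- simulateCoverage(sexes, lens, 50e6, depth = 5, seed = 3)
  rxF <- computeRx(cov[cov$sample == "f", ])
  rxM <- computeRx(cov[cov$sample == "m", ])
  expect_lt(abs(rxF$rx - 0.74), 0.01)
  expect_lt(abs(rxM$rx - 0.42), 0.01)
})

test_that("load placement weights shift RML upward and empty placements
           raise the N = 0 error", {
  pops <- list(A = paste0("A", 1:3), B = paste0("B", 1:3))
  wins <- 0
  for (seed in 1:10) {
    sl <- simulateLoad(pops, c(A = 0, B = 1), seed = seed)
    regs <- conservedRegions(sl$track, 4)
    vals <- sapply(unlist(pops), function(s)
      rml(sl$polarized, regs, s)$rml)
    if (mean(vals[4:6]) > mean(vals[1:3])) wins <- wins + 1
  }
  expect_gte(wins / 10, 0.9)
  empty <- simulateLoad(pops, c(A = 0, B = 1), derivedPerSample = 0,
                        seed = 1)
  expect_error(rml(empty$polarized, empty$regions, "A1"),
               "no derived alleles")
})

test_that("mtDNA simulation follows the infinite-sites star expectations", {
  mt0 <- simulateMtdna(nTips = 4, length = 500, mPerBranch = 0, seed = 2)
  expect_equal(mtdnaPi(mt0$aln)$value, 0)
  # 3-tip fixture: pi equals the hand count from the planted mutations
  mt3 <- simulateMtdna(nTips = 3, length = 1000, mPerBranch = 5, seed = 7)
  m <- mt3$truth$mutations
  # infinite sites: pairwise differences are sums of branch mutation counts
  expected <- (sum(combn(m, 2, sum)) / 3) / 1000
  expect_equal(mtdnaPi(mt3$aln)$value, expected)
  expect_error(simulateMtdna(nTips = 3, length = 10, mPerBranch = 100,
                             seed = 1), "exceed")
  # determinism
  a1 <- simulateMtdna(seed = 5)$aln
  a2 <- simulateMtdna(seed = 5)$aln
  expect_identical(as.character(a1), as.character(a2))
})
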