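mkProfile <- function(depths, chrXDepth, lens = NULL) {
  chroms <- paste0("chr", seq_along(depths))
  if (is.null(lens)) lens <- rep(50e6, length(depths))
  data.frame(chrom = c(chroms, "chrX"), length = c(lens, 40e6),
             alignedBases = c(depths * lens, chrXDepth * 40e6))
}

test_that("Rx is the mean per-autosome depth ratio with SE from autosome
           variance", {
  pr <- mkProfile(rep(2, 5), 2)
  r <- computeRx(pr)
  expect_equal(r$rx, 1)
  expect_equal(r$se, 0)
  r2 <- computeRx(mkProfile(rep(4, 5), 2))
  expect_equal(r2$rx, 0.5)
  pr3 <- mkProfile(c(2, 2.5, 2), 2)
  r3 <- computeRx(pr3)
  ratios <- 2 / c(2, 2.5, 2)
  expect_equal(r3$rx, mean(ratios))
  expect_equal(r3$se, sd(ratios) / sqrt(3))
  expect_warning(r4 <- computeRx(mkProfile(c(2, 0, 2), 2)), "zero-depth")
  expect_equal(r4$nAutosomes, 2)
})

test_that("sex assignment follows the 1.96 SE rule on the 0.65/0.5
           thresholds", {
  # the published female/male cluster means fall inside the assignment zones
  expect_equal(assignSex(list(rx = 0.74, se = 0.01))$assignment, "XX")
  expect_equal(assignSex(list(rx = 0.42, se = 0.01))$assignment, "XY")
  expect_equal(assignSex(list(rx = 0.60, se = 0.001))$assignment,
               "unassigned")
  # wide uncertainty blocks assignment even with an extreme point estimate
  expect_equal(assignSex(list(rx = 0.74, se = 0.1))$assignment,
               "unassigned")
})

test_that("k-means cluster means match the exhaustive 2-partition oracle", {
  vals <- c(0.4, 0.41, 0.42, 0.73, 0.74, 0.75)
  km <- kmeansThresholds(vals, seed = 3)
  # oracle: try every split of the sorted values into two contiguous groups
  sv <- sort(vals)
  best <- NULL
  for (cut in 1:(length(sv) - 1)) {
    g1 <- sv[1:cut]; g2 <- sv[(cut + 1):length(sv)]
    ss <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
    if (is.null(best) || ss < best$ss)
      best <- list(ss = ss, means = c(mean(g1), mean(g2)))
  }
  expect_equal(km$means, best$means, tolerance = 1e-12)
  expect_equal(km$suggestedCutoffs, mean(best$means))
  # permutation of input order gives identical means
  km2 <- kmeansThresholds(rev(vals), seed = 3)
  expect_equal(km2$means, km$means)
  # well-separated Gaussians are recovered closely
  set.seed(8)
  x <- c(rnorm(50, 0.45, 0.02), rnorm(50, 0.75, 0.02))
  km3 <- kmeansThresholds(x, seed = 1)
  expect_lt(max(abs(km3$means - c(0.45, 0.75))), 0.02)
  expect_error(kmeansThresholds(rep(0.5, 6)), "degenerate")
})

test_that("pairwise mismatch averages per-window P0 values", {
  # 3 windows of 10 sites with mismatch fractions 0.1, 0.2, 0.3
  mk <- function(mm) c(rep(2L, 10 - mm), rep(0L, mm))
  a <- rep(2L, 30)
  b <- c(mk(1), mk(2), mk(3))
  pos <- c(seq_len(10), 1e6 + seq_len(10), 2e6 + seq_len(10))
  gm <- mkGeno(cbind(a = a, b = b), pos = pos)
  ph <- new("GenoMatrix", sites = sites(gm), dosages = dosages(gm),
            ploidy = "pseudohaploid")
  pm <- pairwiseMismatch(ph, c("a", "b"), windowBp = 1e6)
  expect_equal(pm$perWindow$p0, c(0.1, 0.2, 0.3))
  expect_equal(pm$p0, 0.2)
  # identical and complementary genotypes hit the extremes
  phSame <- new("GenoMatrix", sites = sites(gm),
                dosages = cbind(a = a, b = a), ploidy = "pseudohaploid")
  expect_equal(pairwiseMismatch(phSame, c("a", "b"))$p0, 0)
  phOpp <- new("GenoMatrix", sites = sites(gm),
               dosages = cbind(a = a, b = 2L - a), ploidy = "pseudohaploid")
  expect_equal(pairwiseMismatch(phOpp, c("a", "b"))$p0, 1)
  expect_error(pairwiseMismatch(gm, c("a", "b")), "pseudo-haploid")
})

test_that("kinship classification normalizes by the population median and
           uses midpoint thresholds", {
  cfg <- kinshipConfig()
  expect_equal(unname(cfg$thresholds),
               c((0.5 + 0.25) / 2, (0.25 + 0.125) / 2, (0.125 + 0.0625) / 2,
                 (0.0625 + 0) / 2))
  mkRes <- function(p0, pair) list(pair = pair, p0 = p0, nWindows = 10)
  res <- list(mkRes(0.20, c("a", "b")), mkRes(0.21, c("a", "c")),
              mkRes(0.20, c("b", "c")), mkRes(0.10, c("a", "d")),
              mkRes(0.16, c("b", "d")), mkRes(0.205, c("c", "d")))
  kin <- classifyKinship(res, cfg)
  med <- median(sapply(res, `[[`, "p0"))
  expect_equal(kin$theta, 1 - kin$p0 / med)
  # P0 at the median -> theta 0 -> unrelated
  expect_equal(as.character(kin$degree[kin$p0 == med][1]), "unrelated")
  # normalized P0 = 0.5 -> theta 0.5 -> identical
  expect_equal(as.character(kin$degree[kin$p0 == 0.10]), "identical")
  # theta = 0.20 lies in [0.1875, 0.375) -> 1st degree
  k2 <- classifyKinship(list(mkRes(0.8, c("x", "y")),
                             mkRes(1.0, c("x", "z")),
                             mkRes(1.0, c("y", "z"))), cfg)
  expect_equal(as.character(k2$degree[1]), "1st")
  expect_equal(k2$theta[1], 0.2)
  clones <- list(mkRes(0, c("x", "y")), mkRes(0, c("x", "z")),
                 mkRes(0, c("y", "z")))
  expect_error(classifyKinship(clones, cfg), "median")
})

test_that("greedy pruning removes the minimum samples needed", {
  cfg <- kinshipConfig()
  mkKin <- function(s1, s2, deg) {
    data.frame(sample1 = s1, sample2 = s2, p0 = NA, normalizedP0 = NA,
               theta = NA,
               degree = factor(deg, levels = names(cfg$expectedTheta)),
               nWindows = 10)
  }
  one <- mkKin("a", "b", "identical")
  expect_equal(pruneRelatives(one), "a")       # lexicographic tie-break
  none <- mkKin("a", "b", "unrelated")
  expect_length(pruneRelatives(none), 0)
  # trio: child related 1st-degree to both parents; removing the child
  # resolves everything in one exclusion
  trio <- rbind(mkKin("mom", "kid", "1st"), mkKin("dad", "kid", "1st"),
                mkKin("mom", "dad", "unrelated"))
  ex <- pruneRelatives(trio)
  expect_equal(ex, "kid")
  left <- trio[!(trio$sample1 %in% ex | trio$sample2 %in% ex), ]
  expect_true(all(left$degree == "unrelated"))
  # coverage breaks ties toward the lower-coverage sample
  ex2 <- pruneRelatives(one, coverage = c(a = 10, b = 2))
  expect_equal(ex2, "b")
  # third-degree pairs are kept unless asked for
  third <- mkKin("a", "b", "3rd")
  expect_length(pruneRelatives(third, maxDegree = "2nd"), 0)
  expect_equal(pruneRelatives(third, maxDegree = "3rd"), "a")
})

test_that("theta ladder orders planted degrees as expected", {
  tr <- data.frame(node = c("ROOT", "OUT", "P"), parent = c(NA, "ROOT",
                                                            "ROOT"),
                   F = c(NA, 0.5, 0.05))
  thetas <- matrix(NA_real_, 5, 4)
  for (i in 1:5) {
    cfg <- simConfig(nSites = 20000, samplesPerPop = 8, seed = 100 + i,
                     tree = tr,
                     relatives = data.frame(population = "P", degree = 0:3))
    sim <- simulateGenotypes(simulateFrequencies(cfg), cfg)
    ph <- pseudoHaploidize(sim$gm, seed = i)
    ids <- sim$truth$samples$sample[sim$truth$samples$population == "P"]
    pairs <- combn(ids, 2)
    p0s <- lapply(seq_len(ncol(pairs)), function(k)
      pairwiseMismatch(ph, pairs[, k]))
    kin <- classifyKinship(p0s)
    rel <- sim$truth$relatives
    for (k in seq_len(nrow(rel))) {
      row <- kin[(kin$sample1 == rel$sample1[k] &
                    kin$sample2 == rel$sample2[k]) |
                 (kin$sample1 == rel$sample2[k] &
                    kin$sample2 == rel$sample1[k]), ]
      thetas[i, rel$degree[k] + 1] <- row$theta
    }
  }
  means <- colMeans(thetas)
  expect_true(all(diff(means) < 0))            # identical > 1st > 2nd > 3rd
})
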