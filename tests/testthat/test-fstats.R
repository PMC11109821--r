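test_that("allele frequencies and counts follow the diploid tally", {
  gm <- mkGeno(cbind(a = c(1L, 0L, NA), b = c(2L, 2L, 1L)))
  af <- alleleFrequencies(gm, c(a = "P", b = "Q"))
  expect_equal(af@freq[, "P"], c(0.5, 0, NA))
  expect_equal(af@count[, "P"], c(2, 2, 0))
  expect_equal(af@freq[, "Q"], c(1, 1, 0.5))
  # two diploids (0, 2) in one population -> freq 0.5, count 4
  af2 <- alleleFrequencies(gm, c(a = "P", b = "P"))
  expect_equal(unname(af2@freq[2, "P"]), (0 + 2) / 4)
  expect_equal(unname(af2@count[2, "P"]), 4)
  # brute-force per-site tally on a fixture with missing data
  gm3 <- mkPopGeno(200, 6, seed = 5)
  d <- dosages(gm3)
  d[sample(length(d), 50)] <- NA
  gm3 <- GenoMatrix(sites(gm3), d)
  grp <- setNames(rep(c("X", "Y"), 3), sampleIds(gm3))
  af3 <- alleleFrequencies(gm3, grp)
  for (p in c("X", "Y")) {
    cols <- names(grp)[grp == p]
    sub <- dosages(gm3)[, cols]
    expect_equal(af3@count[, p], 2 * rowSums(!is.na(sub)))
    expect_equal(af3@freq[, p],
                 ifelse(rowSums(!is.na(sub)) > 0,
                        rowSums(sub, na.rm = TRUE) /
                          (2 * rowSums(!is.na(sub))), NA))
  }
  # pseudo-haploid calls contribute one allele each
  ph <- pseudoHaploidize(gm3, 1)
  afp <- alleleFrequencies(ph, grp)
  expect_equal(afp@count[, "X"],
               rowSums(!is.na(dosages(ph)[, names(grp)[grp == "X"]])))
  expect_error(alleleFrequencies(gm, c(a = "P", zz = "Q")), "not in matrix")
})

test_that("f3 closed forms, symmetry and complete-case site use hold", {
  d <- cbind(o = rep(2L, 6), a = rep(0L, 6), b = rep(0L, 6))
  af <- alleleFrequencies(mkGeno(d), c(o = "O", a = "A", b = "B"))
  blocks <- rep(1:3, each = 2)
  f <- f3stat(af, "O", "A", "B", blocks)
  expect_equal(f@estimate, 1.0)
  dd <- cbind(o = c(0L, 1L, 2L), a = c(0L, 1L, 2L), b = c(0L, 1L, 2L))
  af2 <- alleleFrequencies(mkGeno(dd), c(o = "O", a = "A", b = "B"))
  expect_equal(f3stat(af2, "O", "A", "B", rep(1:3, 1))@estimate, 0)
  # symmetry in the two test populations is exact
  gm <- mkPopGeno(600, 9, seed = 11)
  grp <- setNames(rep(c("O", "A", "B"), each = 3), sampleIds(gm))
  af3 <- alleleFrequencies(gm, grp)
  blk <- makeBlocks(af3, "span", 3e6)
  fab <- f3stat(af3, "O", "A", "B", blk)
  fba <- f3stat(af3, "O", "B", "A", blk)
  expect_identical(fab@estimate, fba@estimate)
  expect_identical(fab@se, fba@se)
})

test_that("jackknife estimate and SE match the brute-force oracle", {
  set.seed(21)
  for (rep in 1:5) {
    nb <- sample(3:10, 1)
    terms <- rnorm(40 + rep * 17)
    blocks <- sort(sample(seq_len(nb), length(terms), replace = TRUE))
    blocks <- as.integer(factor(blocks))      # no empty blocks
    got <- ovipop:::.blockJackknife(terms, blocks)
    want <- oracleJackknife(terms, blocks)
    expect_equal(got$estimate, want$estimate, tolerance = 1e-13)
    expect_equal(got$se, want$se, tolerance = 1e-13)
  }
  # 6-site toy with 3 blocks of 2, end to end through f3stat
  d <- cbind(o = c(2L, 1L, 0L, 2L, 1L, 1L), a = c(0L, 1L, 0L, 2L, 2L, 0L),
             b = c(0L, 0L, 2L, 2L, 1L, 1L))
  af <- alleleFrequencies(mkGeno(d), c(o = "O", a = "A", b = "B"))
  blocks <- rep(1:3, each = 2)
  f <- f3stat(af, "O", "A", "B", blocks)
  p <- af@freq
  terms <- (p[, "O"] - p[, "A"]) * (p[, "O"] - p[, "B"])
  want <- oracleJackknife(terms, blocks)
  expect_equal(f@estimate, want$estimate, tolerance = 1e-13)
  expect_equal(f@se, want$se, tolerance = 1e-13)
})

test_that("corrected f3 subtracts the target sampling-noise term", {
  d <- cbind(o1 = c(1L, 2L), o2 = c(1L, 0L), a = c(0L, 2L), b = c(2L, 0L))
  af <- alleleFrequencies(mkGeno(d), c(o1 = "O", o2 = "O", a = "A", b = "B"))
  blocks <- c(1L, 2L)
  plain <- f3stat(af, "O", "A", "B", blocks)
  corr <- f3stat(af, "O", "A", "B", blocks, corrected = TRUE)
  p <- af@freq[, "O"]; nO <- af@count[, "O"]
  hO <- 2 * p * (1 - p) * nO / (nO - 1)
  expect_equal(corr@estimate, plain@estimate - mean(hO / nO))
  # pseudo-haploid target is refused in corrected mode
  ph <- pseudoHaploidize(mkGeno(d), 1)
  afp <- alleleFrequencies(ph, c(o1 = "O", a = "A", b = "B"))
  expect_error(f3stat(afp, "O", "A", "B", blocks, corrected = TRUE),
               "allele count >= 2")
})

test_that("f4 is zero when a = b and antisymmetric in its last pair", {
  gm <- mkPopGeno(600, 12, seed = 13)
  grp <- setNames(rep(c("A", "B", "C", "D"), each = 3), sampleIds(gm))
  af <- alleleFrequencies(gm, grp)
  blk <- makeBlocks(af, "span", 3e6)
  same <- setNames(grp, names(grp))
  same[grp == "B"] <- "A"                      # collapse B into A
  afSame <- alleleFrequencies(gm, same)
  expect_equal(f4stat(afSame, "A", "A", "C", "D", blk)@estimate, 0)
  fwd <- f4stat(af, "A", "B", "C", "D", blk)
  rev <- f4stat(af, "A", "B", "D", "C", blk)
  expect_equal(fwd@estimate, -rev@estimate)
  expect_equal(fwd@se, rev@se)
})

test_that("the 1-f3 distance matrix is symmetric with zero diagonal and
           respects clade structure under drift", {
  tr <- data.frame(node = c("ROOT", "OUT", "N1", "N2", "A", "B", "C", "D"),
                   parent = c(NA, "ROOT", "ROOT", "N1", "N2", "N2", "N1",
                              "ROOT"),
                   F = c(NA, 0.5, 0.03, 0.08, 0.05, 0.05, 0.05, 0.12))
  hits <- 0
  for (seed in 1:20) {
    cfg <- simConfig(tree = tr, nSites = 5000, samplesPerPop = 3,
                     seed = seed)
    sim <- simulateGenotypes(simulateFrequencies(cfg), cfg)
    grp <- setNames(sim$truth$samples$population, sim$truth$samples$sample)
    af <- alleleFrequencies(sim$gm, grp)
    blk <- makeBlocks(af, "span", 5e6)
    D <- distanceMatrix(af, outgroup = "OUT", blocks = blk)
    expect_identical(D, t(D))
    expect_true(all(diag(D) == 0))
    # within-clade (A,B) closer than across (A,C): shared drift monotonicity
    if (D["A", "B"] < D["A", "C"] && D["A", "B"] < D["B", "C"]) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.95)
})

test_that("chunked bootstrap is seed-deterministic and its identity draw
           reproduces the point estimate", {
  gm <- mkPopGeno(3000, 12, seed = 17)
  grp <- setNames(rep(c("O", "A", "B", "C"), each = 3), sampleIds(gm))
  af <- alleleFrequencies(gm, grp)
  blkAll <- rep(1L, nSites(gm))
  D <- distanceMatrix(af, outgroup = "O", blocks = blkAll)
  ident <- bootstrapDistanceMatrices(gm, grp, "O", chunkSize = 500,
                                     reps = 1, seed = 5, resample = FALSE)
  expect_equal(ident[[1]], D, tolerance = 1e-12)
  b1 <- bootstrapDistanceMatrices(gm, grp, "O", chunkSize = 500, reps = 10,
                                  seed = 42)
  b2 <- bootstrapDistanceMatrices(gm, grp, "O", chunkSize = 500, reps = 10,
                                  seed = 42)
  expect_identical(b1, b2)
  expect_false(identical(b1[[1]], b1[[2]]))
  expect_error(bootstrapDistanceMatrices(gm, grp, "O", chunkSize = 1e6),
               "chunkSize")
})
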