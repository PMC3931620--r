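test_that("sampling degenerate and two-state ensembles", {
  cfg <- modelConfig("nn")
  fa <- fillFoldArrays("AAAAA", "turner99", cfg, "sum-product")
  samp <- sampleStructures(fa, 20, seed = 1)
  expect_true(all(vapply(samp, function(s) nrow(basePairs(s)) == 0L, logical(1))))
  ## wrong semiring is a usage error
  mp <- fillFoldArrays("AAAAA", "turner99", cfg, "min-plus")
  expect_error(sampleStructures(mp, 5), "sum-product")
  ## two equiprobable states: zero energies on GAAAC
  zp <- makeZeroParams()
  fa2 <- fillFoldArrays("GAAAC", zp, cfg, "sum-product")
  samp2 <- sampleStructures(fa2, 4000, seed = 42)
  frac <- mean(vapply(samp2, function(s) nrow(basePairs(s)) == 1L, logical(1)))
  sigma <- sqrt(0.25 / 4000)
  expect_lt(abs(frac - 0.5), 4 * sigma)
  ## exact probabilities: closed form 1/2
  bpp <- basePairProbabilities("GAAAC", zp, cfg, method = "exact_small")
  expect_equal(bpp@prob$p, 0.5)
})

test_that("sampled pair probabilities converge to exact enumeration values", {
  set.seed(314)
  s <- randomRNA(16)
  cfg <- modelConfig("nn")
  exact <- bruteBPP(s, "turner99", cfg)
  m <- 8000
  emp <- basePairProbabilities(s, "turner99", cfg, method = "sample",
                               m = m, seed = 9)
  look <- function(bpp, i, j) {
    hit <- bpp@prob$i == i & bpp@prob$j == j
    if (any(hit)) bpp@prob$p[hit] else 0
  }
  for (r in seq_len(nrow(exact@prob))) {
    pex <- exact@prob$p[r]
    if (pex < 0.01) next
    pemp <- look(emp, exact@prob$i[r], exact@prob$j[r])
    sigma <- sqrt(pex * (1 - pex) / m)
    expect_lt(abs(pemp - pex), 4 * sigma + 1e-9)
  }
})

test_that("sampled structure frequencies follow the Boltzmann distribution", {
  set.seed(2718)
  s <- randomRNA(15)
  cfg <- modelConfig("enn")
  be <- brutePartition(s, "turner99", cfg)
  structs <- enumerateStructures(s)
  energies <- vapply(structs, function(p)
    evaluateEnergy(secondaryStructure(s, pairs = p), "turner99", cfg),
    numeric(1))
  RT <- cfg@gasConstant * cfg@temperature
  pr <- exp(-energies / RT); pr <- pr / sum(pr)
  keys <- vapply(structs, function(p) paste(pairKey(p), collapse = ";"),
                 character(1))
  m <- 20000
  fa <- fillFoldArrays(s, "turner99", cfg, "sum-product")
  samp <- sampleStructures(fa, m, seed = 6)
  skey <- vapply(samp, function(x) paste(pairKey(basePairs(x)), collapse = ";"),
                 character(1))
  obs <- as.numeric(table(factor(skey, levels = keys)))
  keep <- pr * m >= 5   # chi-square validity
  chi <- sum((obs[keep] - m * pr[keep])^2 / (m * pr[keep]))
  df <- sum(keep) - 1
  expect_gt(stats::pchisq(chi, df, lower.tail = FALSE), 0.001)
})

test_that("expected base pairs equals the ensemble average pair count", {
  s <- "GGGGAAAACCCC"
  cfg <- modelConfig("nn")
  bpp <- basePairProbabilities(s, "turner99", cfg, method = "exact_small")
  ## independent identity: sum over structures of N_bp * Boltzmann weight
  structs <- enumerateStructures(s)
  energies <- vapply(structs, function(p)
    evaluateEnergy(secondaryStructure(s, pairs = p), "turner99", cfg),
    numeric(1))
  RT <- cfg@gasConstant * cfg@temperature
  w <- exp(-energies / RT)
  expect_equal(expectedBasePairs(bpp),
               sum(vapply(structs, nrow, integer(1)) * w) / sum(w),
               tolerance = 1e-9)
  ## exterior consistency: per-base pairing probabilities sum to at most 1
  perBase <- tapply(c(bpp@prob$p, bpp@prob$p), c(bpp@prob$i, bpp@prob$j), sum)
  expect_true(all(perBase <= 1 + 1e-12))
})

test_that("melting curves are reproducible and melt at high temperature", {
  polyA <- strrep("A", 50)
  mc <- meltingCurve(polyA, "turner99", modelConfig("nn"),
                     tGrid = c(0, 60, 120), m = 50, seed = 3)
  expect_equal(mc$expected_bp, c(0, 0, 0))
  hp <- generateFixture(24, stem = 10, loop = 4)$seq
  for (mdl in c("nn", "enn")) {
    cfg <- modelConfig(mdl)
    mc2 <- meltingCurve(hp, "turner99", cfg, tGrid = seq(0, 120, by = 30),
                        m = 400, seed = 8)
    expect_gt(mc2$expected_bp[1], mc2$expected_bp[nrow(mc2)])
    expect_true(all(mc2$expected_bp_per_nt <= 0.5 + 1e-12))
    mc3 <- meltingCurve(hp, "turner99", cfg, tGrid = seq(0, 120, by = 30),
                        m = 400, seed = 8)
    expect_identical(mc2, mc3)
  }
  ## frozen-triplet mode runs and differs in general from re-inference
  cfgF <- modelConfig("enn", reinferTriplets = FALSE)
  mcF <- meltingCurve(hp, "turner99", cfgF, tGrid = c(80), m = 400, seed = 8)
  expect_true(is.finite(mcF$expected_bp))
})

test_that("identical seeds give identical samples", {
  fa <- fillFoldArrays("GGGGCAAAAGCCCC", "turner99", modelConfig("nn"))
  a <- sampleStructures(fa, 50, seed = 123)
  b <- sampleStructures(fa, 50, seed = 123)
  expect_identical(lapply(a, basePairs), lapply(b, basePairs))
})
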