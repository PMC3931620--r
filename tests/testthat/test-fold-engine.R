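test_that("degenerate sequences fold to the empty structure", {
  fr <- mfeFold("AAAAA", "turner99", modelConfig("nn"))
  expect_equal(foldEnergy(fr), 0)
  expect_identical(nrow(basePairs(fr)), 0L)
  expect_equal(partitionFunction("AAAAA", "turner99", modelConfig("nn"))$Z, 1)
  expect_equal(countStructures("AAAA"), 1)
  expect_equal(countStructures("GAAAC"), 2)
  expect_equal(countStructures("GGAAACC"), 6)
})

test_that("two-state closed forms hold on GAAAC", {
  zp <- makeZeroParams()
  expect_equal(partitionFunction("GAAAC", zp, modelConfig("nn"))$Z, 2)
  flat <- makeFlatParams(hairpinVal = -0.7)   # single-pair energy E1 = -0.7
  cfg <- modelConfig("nn")
  RT <- cfg@gasConstant * cfg@temperature
  expect_equal(partitionFunction("GAAAC", flat, cfg)$Z, 1 + exp(0.7 / RT),
               tolerance = 1e-12)
  expect_equal(foldEnergy(mfeFold("GAAAC", flat, cfg)), -0.7)
})

test_that("DP matches the enumeration oracle on a seeded random suite", {
  suite <- oracleSuite(40, 5, 16)
  for (mdl in c("nn", "enn")) {
    cfg <- modelConfig(mdl)
    for (s in suite) {
      dp <- mfeFold(s, "turner99", cfg)
      bf <- bruteMFE(s, "turner99", cfg)
      expect_equal(foldEnergy(dp), bf$energy, tolerance = 1e-9,
                   label = paste(mdl, s))
      ## the traced structure reproduces the reported energy through the
      ## independent evaluator
      expect_equal(evaluateEnergy(dp@structure, "turner99", cfg),
                   foldEnergy(dp), tolerance = 1e-6, label = paste(mdl, s))
      expect_equal(partitionFunction(s, "turner99", cfg)$logZ,
                   brutePartition(s, "turner99", cfg)$logZ,
                   tolerance = 1e-9, label = paste(mdl, s))
    }
  }
})

test_that("array invariants hold in both semirings", {
  ## subset weights only nest cleanly without the exterior closing penalty
  ## (an external helix in Z carries a terminal non-GC factor that the bare
  ## Zb cell does not), so the invariant is checked on the penalty-free model
  s <- "GGGCAAAGCCUAAGGC"
  for (mdl in c("nn", "enn")) {
    cfg <- modelConfig(mdl, useTerminalNonGC = FALSE)
    sp <- fillFoldArrays(s, "turner99", cfg, "sum-product")@arrays
    mp <- fillFoldArrays(s, "turner99", cfg, "min-plus")@arrays
    n <- nchar(s)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ## sum-product: log Z(i,j) >= log Zb >= log Zbb; min-plus reversed
      expect_gte(sp$Z[i, j], sp$Zb[i, j])
      expect_gte(sp$Zb[i, j], sp$Zbb[i, j])
      expect_lte(mp$Z[i, j], mp$Zb[i, j])
      expect_lte(mp$Zb[i, j], mp$Zbb[i, j])
      if (j - i <= cfg@theta) {
        expect_equal(sp$Z[i, j], 0)  # exactly the empty structure
        expect_equal(mp$Z[i, j], 0)
      }
    }
  }
})

test_that("a uniform stabilizing shift of hairpin energies never raises the MFE", {
  suite <- oracleSuite(10, 8, 14, seed = 77)
  base <- makeFlatParams()
  shifted <- base
  shifted@hairpinDG <- base@hairpinDG - 1
  for (s in suite) {
    e0 <- foldEnergy(mfeFold(s, base, modelConfig("nn")))
    e1 <- foldEnergy(mfeFold(s, shifted, modelConfig("nn")))
    expect_lte(e1, e0)
  }
})

test_that("nn-mode MFE structures are pinned on golden fixtures", {
  golden <- c(
    GGGGAAAACCCC = "((((....))))",
    GGCGCAAAAGCGCCAAAGGGC = "(((((....))))).......",
    GCGCUUCGGCGCAUAGCAUAGCUA = "((((....)))).((((...))))",
    CACUCAUAUAAUCGCGUGGAUAUGGCACGC = ".............(((((.......)))))"
  )
  for (s in names(golden)) {
    fr <- mfeFold(s, "turner99", modelConfig("nn"))
    expect_identical(dotBracket(fr), unname(golden[[s]]), label = s)
  }
})

test_that("the evaluator decomposes helices per the ENN helix contract", {
  ## empty structure: exterior bases carry no energy
  expect_equal(evaluateEnergy(secondaryStructure("ACGUACGU"),
                              "turner99", modelConfig("nn")), 0)
  p <- loadParameters("turner99")
  cfg <- modelConfig("enn")
  ## single hairpin
  expect_equal(evaluateEnergy(secondaryStructure("GAAAC", dotbracket = "(...)"),
                              p, cfg),
               hairpinEnergy("GAAAC", 1, 5, p, cfg))
  ## 3-pair helix closing a hairpin: one triplet window, one stem-end stack,
  ## one hairpin term (hand decomposition)
  s <- "GGGAAAACCC"
  st <- secondaryStructure(s, dotbracket = "(((....)))")
  tt <- inferTripletTable(p, cfg)
  expected <- tt@dG["GC", "GC", "GC"] +
    stackEnergy("GC", "GC", p, cfg) +
    hairpinEnergy(s, 3, 8, p, cfg)
  expect_equal(evaluateEnergy(st, p, cfg), unname(expected))
  ## under the NN model the same helix is two stacks plus the hairpin
  cfgN <- modelConfig("nn")
  expect_equal(evaluateEnergy(st, p, cfgN),
               unname(2 * stackEnergy("GC", "GC", p, cfgN) +
                        hairpinEnergy(s, 3, 8, p, cfgN)))
  ## size-1 bulge: bulge penalty + stack across, and it breaks the triplet
  ## chain (no triplet window spans the bulge)
  sb <- "GGAGAAAACCC"
  stb <- secondaryStructure(sb, dotbracket = "((.(....)))")
  ## pairs (1,11),(2,10),(4,9): bulge of size 1 between (2,10) and (4,9)
  expected_b <- stackEnergy("GC", "GC", p, cfgN) +        # (1,11)-(2,10) stem end
    p@bulgeDG[1] + stackEnergy("GC", "GC", p, cfgN) +     # bulge + stack across
    hairpinEnergy(sb, 4, 9, p, cfgN)
  expect_equal(evaluateEnergy(stb, p, cfg), unname(expected_b))
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(mfeFold("GGXAA", "turner99"), "invalid character")
  expect_error(secondaryStructure("GGGAAACCC", pairs = cbind(1, 3)), "theta")
  expect_error(secondaryStructure("AGGAAACCC", pairs = cbind(1, 9)),
               "non-canonical")
  expect_error(secondaryStructure("GGGAAAACCCC",
                                  pairs = rbind(c(1, 10), c(2, 11))),
               "pseudoknot|crosses")
  expect_error(secondaryStructure("GGGAAAACCCC",
                                  pairs = rbind(c(1, 11), c(1, 10))),
               "two pairs")
})
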