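test_that("shipped parameter sets load complete and symmetric tables", {
  p99 <- loadParameters("turner99")
  expect_s4_class(p99, "EnergyParams")
  expect_true(all(is.finite(p99@stackDG)))
  expect_identical(dim(p99@stackDG), c(6L, 6L))
  ## duplex-reversal symmetry: stack(x, y) == stack(rev(y), rev(x))
  rev <- c(AU = "UA", UA = "AU", GC = "CG", CG = "GC", GU = "UG", UG = "GU")
  for (x in pairTypes())
    for (y in pairTypes())
      expect_equal(p99@stackDG[x, y], p99@stackDG[rev[[y]], rev[[x]]])
  ## known published cells (kcal/mol at 37 C)
  expect_equal(p99@stackDG["GC", "CG"], -3.40)
  expect_equal(p99@stackDG["AU", "UA"], -1.10)
  expect_equal(unname(p99@multiloop[c("a", "b", "c")]), c(3.4, 0.4, 0.0))

  p04 <- loadParameters("turner04")
  differs <- sum(p99@hairpinDG != p04@hairpinDG, na.rm = TRUE) +
    sum(p99@stackDH != p04@stackDH) +
    sum(p99@multiloop != p04@multiloop)
  expect_gt(differs, 0)
})

test_that("parameter files round-trip and report schema errors by key", {
  p <- loadParameters("turner99")
  tmp <- tempfile(fileext = ".json")
  writeParameters(p, tmp)
  p2 <- loadParameters(tmp)
  for (sl in c("stackDG", "stackDH", "hairpinDG", "bulgeDG", "internalDG",
               "multiloop", "terminalNonGC"))
    expect_equal(unname(slot(p2, sl)), unname(slot(p, sl)), tolerance = 0,
                 label = sl)

  doc <- jsonlite::fromJSON(tmp, simplifyVector = FALSE)
  doc$stack$dG37[[2]][[3]] <- NULL
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, bad, auto_unbox = TRUE, digits = NA, null = "null")
  expect_error(loadParameters(bad), "stack")

  doc2 <- jsonlite::fromJSON(tmp, simplifyVector = FALSE)
  doc2$multiloop$b <- "not-a-number"
  bad2 <- tempfile(fileext = ".json")
  jsonlite::write_json(doc2, bad2, auto_unbox = TRUE, digits = NA, null = "null")
  expect_error(loadParameters(bad2), "multiloop.b")
})

test_that("temperature rescaling is exact at the reference and linear in T", {
  expect_equal(rescaleToTemperature(-2, -10, 310.15), -2)
  expect_equal(rescaleToTemperature(-2, -10, 620.30), 6)
  expect_equal(rescaleToTemperature(0, 0, 123.4), 0)
  ## linearity across every stack cell: midpoint value = mean of endpoints
  p <- loadParameters("turner99")
  e300 <- rescaleToTemperature(p@stackDG, p@stackDH, 300)
  e340 <- rescaleToTemperature(p@stackDG, p@stackDH, 340)
  e320 <- rescaleToTemperature(p@stackDG, p@stackDH, 320)
  expect_equal(e320, (e300 + e340) / 2, tolerance = 1e-12)
})

test_that("loop energy accessors follow the tables and reject invalid loops", {
  p <- loadParameters("turner99")
  cfg <- modelConfig()
  ## hairpin of size exactly theta: direct table lookup plus closing penalty
  expect_equal(hairpinEnergy("GAAAC", 1, 5, p, cfg), p@hairpinDG[3])  # GC closes
  expect_equal(hairpinEnergy("AAAAU", 1, 5, p, cfg),
               p@hairpinDG[3] + p@terminalNonGC[["dG37"]])            # AU closes
  expect_error(hairpinEnergy("GAAC", 1, 4, p, cfg), "theta")
  expect_error(hairpinEnergy("AAAAA", 1, 5, p, cfg), "canonical")
  ## bulge and internal loops: both-pair penalties for size >= 2
  expect_equal(bulgeEnergy("GGAAAACCAC", 1, 10, 2, 8, p, cfg),
               p@bulgeDG[1])                                # size-1, no penalty
  expect_equal(internalEnergy("GAGAAAACCC", 1, 10, 3, 8, p, cfg),
               p@internalDG[2])                             # 1x1 internal, GC+GC
  ## multiloop affine arithmetic
  expect_equal(multiloopEnergy(3, 4, p, cfg), 3.4 + 3 * 0.4)
  expect_equal(multiloopEnergy(4, 4, p, cfg) - multiloopEnergy(3, 4, p, cfg),
               unname(p@multiloop["b"]))
  expect_equal(multiloopEnergy(3, 5, p, cfg) - multiloopEnergy(3, 4, p, cfg),
               unname(p@multiloop["c"]))
})

test_that("loop sizes beyond 30 follow the log extrapolation", {
  p <- loadParameters("turner99")
  v <- TripletFold:::.loopVector(p@hairpinDG, p@hairpinDH, 310.15, 40L, p@lxc)
  expect_equal(v[35], p@hairpinDG[30] + p@lxc * log(35 / 30))
  expect_true(all(diff(v[30:40]) > 0))
})
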