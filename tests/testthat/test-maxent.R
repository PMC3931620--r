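RT37 <- 0.0019872 * 310.15

test_that("Boltzmann joint over triplet stacks is normalized and symmetric cases hold", {
  u <- boltzmannJointFromStacks(matrix(-2, 6, 6), RT37)
  expect_equal(sum(u), 1)
  expect_equal(max(abs(u - 1 / 216)), 0, tolerance = 1e-15)
  ## flattening toward uniform as RT grows
  p <- loadParameters("turner99")
  spread <- vapply(c(0.3, 0.6, 1.2, 5), function(rt)
    max(boltzmannJointFromStacks(p@stackDG, rt)) - 1 / 216, numeric(1))
  expect_true(all(diff(spread) < 0))
  ## modal cell corresponds to the most stabilizing pair of stacks
  j <- boltzmannJointFromStacks(p@stackDG, RT37)
  idx <- which(j == max(j), arr.ind = TRUE)[1, ]
  sums <- array(0, c(6, 6, 6))
  for (z3 in 1:6) sums[, , z3] <- p@stackDG + matrix(p@stackDG[, z3], 6, 6,
                                                     byrow = TRUE)
  expect_equal(unname(p@stackDG[idx[1], idx[2]] + p@stackDG[idx[2], idx[3]]),
               min(sums))
})

test_that("marginals match direct summation in every position", {
  p <- loadParameters("turner99")
  j <- boltzmannJointFromStacks(p@stackDG, RT37)
  m <- marginalsOf(j)
  expect_equal(sum(m$left), 1); expect_equal(sum(m$middle), 1)
  expect_equal(sum(m$right), 1)
  ## independent direct-summation oracle for a few cells
  direct <- function(kind, a, b) {
    tot <- 0; Zc <- 0
    for (x in 1:6) for (y in 1:6) for (z in 1:6) {
      wt <- exp(-(p@stackDG[x, y] + p@stackDG[y, z]) / RT37)
      Zc <- Zc + wt
      keep <- switch(kind, left = y == a && z == b,
                     middle = x == a && z == b, right = x == a && y == b)
      if (keep) tot <- tot + wt
    }
    tot / Zc
  }
  expect_equal(m$left[2, 5], direct("left", 2, 5))
  expect_equal(m$middle[3, 4], direct("middle", 3, 4))
  expect_equal(m$right[1, 6], direct("right", 1, 6))
  ## degenerate case: point mass propagates to point-mass marginals
  pm <- array(0, c(6, 6, 6)); pm[2, 3, 4] <- 1
  mm <- marginalsOf(pm)
  expect_equal(mm$left[3, 4], 1); expect_equal(mm$middle[2, 4], 1)
  expect_equal(mm$right[2, 3], 1)
})

test_that("IPF recovers the maximum-entropy joint with the target marginals", {
  expect_equal(max(abs(ipfMaxent(marginalsOf(array(1 / 216, c(6, 6, 6)))) -
                         1 / 216)), 0, tolerance = 1e-12)
  p <- loadParameters("turner99")
  j <- boltzmannJointFromStacks(p@stackDG, RT37)
  fit <- ipfMaxent(marginalsOf(j), epsilon = 1e-9)
  ## the Boltzmann joint lies in the pairwise exponential family, so it is
  ## the maxent fixed point itself
  expect_lt(max(abs(fit - j)), 1e-6)
  ## entropy of the fit is not below the entropy of the target-generating joint
  H <- function(q) -sum(q * log(q))
  expect_gte(H(fit), H(j) - 1e-9)
  ## invalid targets
  tg <- marginalsOf(j); tg$left <- tg$left * 2
  expect_error(ipfMaxent(tg), "sum to 1")
  ## iteration cap triggers a non-convergence error reporting the residual
  expect_error(ipfMaxent(marginalsOf(j), epsilon = 1e-15, maxCycles = 1L),
               "residual")
})

test_that("inverse-Boltzmann calibration behaves as specified", {
  u <- array(1 / 216, c(6, 6, 6))
  flat <- matrix(-2, 6, 6)
  expect_equal(max(abs(energiesFromDistribution(u, RT37, flat, "none") -
                         RT37 * log(216))), 0, tolerance = 1e-12)
  ## uniform joint from all-equal stacks recovers the stack value exactly,
  ## in both anchored modes
  for (cal in c("avg_stacks", "mean_avg_stacks"))
    expect_equal(max(abs(energiesFromDistribution(u, RT37, flat, cal) + 2)), 0,
                 tolerance = 1e-12, label = cal)
  ## zero cells are a domain error unless floored
  z <- u; z[1, 1, 1] <- 0; z <- z / sum(z)
  expect_error(energiesFromDistribution(z, RT37, flat), "zero cell")
  fl <- energiesFromDistribution(z, RT37, flat, floorProb = 1e-12)
  expect_true(all(is.finite(fl)))
  ## inverse-Boltzmann round trip: energies recovered up to one additive
  ## constant under the full-RT modes
  p <- loadParameters("turner99")
  j <- boltzmannJointFromStacks(p@stackDG, RT37)
  e <- energiesFromDistribution(j, RT37, p@stackDG, "mean_avg_stacks")
  sums <- array(0, c(6, 6, 6))
  for (z3 in 1:6) sums[, , z3] <- p@stackDG + matrix(p@stackDG[, z3], 6, 6,
                                                     byrow = TRUE)
  expect_lt(diff(range(e - sums)), 1e-9)
})

test_that("triplet inference composes the pipeline and responds to stacks", {
  cfgFlat <- modelConfig("enn")
  tt <- inferTripletTable(matrix(-1.5, 6, 6), cfgFlat)
  expect_s4_class(tt, "TripletTable")
  expect_equal(max(abs(tt@dG + 1.5)), 0, tolerance = 1e-9)
  ## fixed point: bypassing IPF gives the same table within 1e-6
  p <- loadParameters("turner99")
  cfg <- modelConfig("enn")
  tt99 <- inferTripletTable(p, cfg)
  direct <- energiesFromDistribution(
    boltzmannJointFromStacks(p@stackDG, RT37), RT37, p@stackDG, cfg@calibration)
  expect_lt(max(abs(tt99@dG - direct)), 1e-6)
  ## correlation with the average of constituent stacks
  sums <- array(0, c(6, 6, 6))
  for (z3 in 1:6) sums[, , z3] <- p@stackDG + matrix(p@stackDG[, z3], 6, 6,
                                                     byrow = TRUE)
  expect_gte(cor(as.vector(tt99@dG), as.vector(sums / 2)), 0.99)
  ## monotonicity: stabilizing one stack lowers every triplet containing it
  for (cal in c("avg_stacks", "mean_avg_stacks")) {
    cfg2 <- modelConfig("enn", calibration = cal)
    s2 <- p@stackDG; s2["GC", "CG"] <- s2["GC", "CG"] - 1
    t1 <- inferTripletTable(rescaleToTemperature(p@stackDG, p@stackDH, 310.15),
                            cfg2)@dG
    t2 <- inferTripletTable(rescaleToTemperature(s2, p@stackDH, 310.15), cfg2)@dG
    gi <- match("GC", pairTypes()); ci <- match("CG", pairTypes())
    contains <- array(FALSE, c(6, 6, 6))
    contains[gi, ci, ] <- TRUE; contains[, gi, ci] <- TRUE
    expect_true(all(t2[contains] < t1[contains]))
  }
})
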