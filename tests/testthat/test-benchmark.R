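test_that("pair-level comparison implements the exact-identity metrics", {
  s <- "GGGGGAAACCCAAGGGAAACCCAAAACC"
  ref <- secondaryStructure(s, dotbracket = "(((((...)))..(((...)))....))")
  ## identity
  cmp <- compareStructures(ref, ref)
  expect_equal(cmp, list(tp = nrow(ref@pairs), sensitivity = 1, ppv = 1))
  ## partial overlap with forced arithmetic
  s2 <- "GGGAAAACCCAA"
  a <- secondaryStructure(s2, pairs = rbind(c(1, 10), c(2, 9)))
  b <- secondaryStructure(s2, pairs = rbind(c(1, 10), c(3, 8)))
  cmp2 <- compareStructures(b, a)
  expect_equal(cmp2, list(tp = 1L, sensitivity = 0.5, ppv = 0.5))
  ## empty-prediction convention
  empty <- secondaryStructure(s2)
  cmp3 <- compareStructures(empty, a)
  expect_equal(cmp3, list(tp = 0L, sensitivity = 0, ppv = 1))
  ## symmetry: swapping prediction and reference exchanges the two metrics
  fwd <- compareStructures(b, a); rev <- compareStructures(a, b)
  expect_equal(fwd$sensitivity, rev$ppv)
  expect_equal(fwd$ppv, rev$sensitivity)
  ## length mismatch
  expect_error(compareStructures(a, secondaryStructure("GAAAC")), "length")
})

test_that("the benchmark harness folds CT items and tabulates averages", {
  ## two scaffold fixtures whose MFE equals the designed reference
  dirs <- tempfile(); dir.create(dirs)
  files <- character(0)
  for (k in 1:2) {
    fx <- generateFixture(10 + 4 * k, stem = 3 + 2 * k, loop = 4)
    path <- file.path(dirs, paste0("item", k, ".ct"))
    writeCT(fx$structure, path, id = paste0("item", k))
    files[paste0("item", k)] <- path
  }
  res <- runBenchmark(files, "turner99", modelConfig("nn"))
  expect_equal(unname(res$averages), c(1, 1))
  expect_identical(nrow(res$per_item), 2L)
  expect_length(res$errors, 0)
  ## empty item list is a validation error
  expect_error(runBenchmark(character(0)), "empty")
  ## corrupt items are skipped and recorded
  badf <- file.path(dirs, "bad.ct")
  writeLines("not a ct file at all", badf)
  files2 <- c(files, bad = badf)
  expect_warning(res2 <- runBenchmark(files2, "turner99", modelConfig("nn")),
                 "skipped")
  expect_identical(nrow(res2$per_item), 2L)
  expect_named(res2$errors, "bad")
})
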