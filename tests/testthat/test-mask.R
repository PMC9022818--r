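illusDesign <- function() taskDesign("0 1 0 1 0 1 0 1 0 1", 30, tr = 1)

test_that("boxcar expansion concatenates block indicators", {
  expect_identical(designBoxcar(taskDesign("0 1", "2 3")),
                   c(0L, 0L, 1L, 1L, 1L))
  box <- designBoxcar(illusDesign())
  expect_length(box, 300)
  taskTRs <- which(box == 1)
  expect_identical(taskTRs,
                   c(31:60, 91:120, 151:180, 211:240, 271:300))
  expect_identical(designBoxcar(taskDesign(c(0, 0), c(5, 5))), rep(0L, 10))
})

test_that("canonical HRF has the double-gamma shape", {
  expect_equal(canonicalHRF(0), 0)
  grid <- seq(0, 32, by = 0.1)
  h <- canonicalHRF(grid)
  expect_equal(grid[which.max(h)], 5, tolerance = 0.11)
  expect_lt(canonicalHRF(30), 0)   # undershoot
  expect_gt(canonicalHRF(5), 0)
})

test_that("activation curve follows convolution identities", {
  ## single-TR impulse: curve equals the HRF integrated over each TR bin
  ## (closed form via the gamma CDF), up to normalization
  imp <- taskDesign(c(1, 0), c(1, 99))
  cv <- values(activationCurve(imp, normalization = "single-event"))
  expect_equal(max(cv), 1, tolerance = 1e-12)
  tt <- seq_len(40)
  ref <- (pgamma(tt, 6) - pgamma(tt - 1, 6)) -
    (pgamma(tt, 16) - pgamma(tt - 1, 16)) / 6
  ## agreement up to the microtime discretization of the convolution
  expect_equal(cv[tt], ref / max(ref), tolerance = 0.02)
  expect_gt(cor(cv[tt], ref), 0.9999)

  ## all-rest design: identically zero
  expect_equal(values(activationCurve(taskDesign(c(0, 0), c(50, 50)))),
               rep(0, 100))

  ## global normalization peaks at exactly 1
  expect_equal(max(values(activationCurve(illusDesign()))), 1,
               tolerance = 1e-12)
})

test_that("activation mask respects threshold boundaries", {
  fc <- slidingWindowFC(simulateROITimeSeries(nROIs = 3, seed = 2), 17)
  curve <- activationCurve(illusDesign())
  all0 <- activationMask(curve, fc, threshold = 0)
  ## threshold 0 selects every window whose representative TR lies inside
  ## a task block (the response is positive there; between blocks the
  ## undershoot may dip below zero)
  sel <- selectedWindows(all0)
  box <- designBoxcar(illusDesign())
  repTR <- dynfc:::.windowRepTR(fc, "first")
  midBlock <- box[repTR] == 1 & box[pmax(repTR - 5, 1)] == 1
  expect_true(all(sel[midBlock]))
  ## threshold 1 under global normalization selects at most the peak windows
  top <- activationMask(curve, fc, threshold = 1)
  expect_lte(sum(selectedWindows(top)), 1)
  expect_error(activationMask(curve, fc, threshold = 1.2), "0, 1")

  ## threshold 0.8: selected windows form runs overlapping each task block
  m8 <- activationMask(curve, fc, threshold = 0.8)
  runs <- rle(selectedWindows(m8))
  expect_equal(sum(runs$values), 5)   # one run per task block
})

test_that("coverage over the FC window matches block arithmetic", {
  fc <- slidingWindowFC(simulateROITimeSeries(nROIs = 3, seed = 2), 17)
  design <- illusDesign()
  ## 100% coverage: windows fully inside a 30-TR block; 14 per block
  full <- coverageMask(design, fc, pct = 100, neighborhood = "window")
  expect_equal(sum(selectedWindows(full)), 5 * 14)
  ## 80% coverage (>= 14 of 17 task TRs): 20 per interior block, 17 for the
  ## final block that ends with the run
  cov80 <- coverageMask(design, fc, pct = 80, neighborhood = "window")
  expect_equal(sum(selectedWindows(cov80)), 4 * 20 + 17)
  ## rest coverage of an all-task design is empty
  allTask <- taskDesign(c(1, 1), c(150, 150))
  none <- coverageMask(allTask, fc, condition = 0, pct = 100,
                       neighborhood = "window")
  expect_equal(sum(selectedWindows(none)), 0)
})

test_that("mask combination is AND with identity and annihilator", {
  a <- manualMask(c(2, 5, 7), 10)
  allT <- manualMask(1:10, 10)
  allF <- manualMask(integer(0), 10)
  expect_identical(selectedWindows(combineMasks(a, allT)),
                   selectedWindows(a))
  expect_false(any(selectedWindows(combineMasks(a, allF))))
  b <- manualMask(c(5, 6, 7), 10)
  both <- combineMasks(a, b)
  expect_identical(which(selectedWindows(both)), c(5L, 7L))
  expect_true(all(selectedWindows(both) <= selectedWindows(a)))
  expect_identical(both@source, "both")
  expect_error(combineMasks(a, manualMask(1, 5)), "different window counts")
})

test_that("raising either threshold never adds windows", {
  fc <- slidingWindowFC(simulateROITimeSeries(nROIs = 3, seed = 2), 17)
  design <- illusDesign()
  curve <- activationCurve(design)
  prev <- rep(TRUE, nWindows(fc))
  for (th in seq(0, 1, by = 0.1)) {
    cur <- selectedWindows(activationMask(curve, fc, threshold = th))
    expect_true(all(cur <= prev))
    prev <- cur
  }
  prev <- rep(TRUE, nWindows(fc))
  for (pct in c(10, 30, 50, 70, 90, 100)) {
    cur <- selectedWindows(coverageMask(design, fc, pct = pct))
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("manual masks validate indices and round-trip through files", {
  expect_error(manualMask(c(1, 11), 10), "out of range")
  m <- manualMask(c(5, 7), 10)
  path <- tempfile(fileext = ".json")
  writeTemporalMask(m, path, design = illusDesign(),
                    settings = list(activationThreshold = 0.8))
  back <- readTemporalMask(path)
  expect_identical(selectedWindows(back), selectedWindows(m))
  expect_identical(back@source, "manual")
})

test_that("the calibrated convention reproduces the 79-window worked example", {
  ts <- simulateROITimeSeries(nROIs = 3, seed = 2)
  fc <- slidingWindowFC(ts, windowSize = 17, stepSize = 1)
  mask <- taskMask(illusDesign(), fc)
  expect_identical(sum(selectedWindows(mask)), 79L)
  ## per-block structure: 18 windows per interior task block, 7 in the
  ## final block truncated by the window count
  sel <- which(selectedWindows(mask))
  blocks <- tabulate(((sel - 1) %/% 60) + 1, 5)
  expect_identical(blocks, c(18L, 18L, 18L, 18L, 7L))
  ## the combined mask is contained in both components
  act <- activationMask(activationCurve(illusDesign()), fc, 0.8)
  cov <- coverageMask(illusDesign(), fc, pct = 80)
  expect_true(all(selectedWindows(mask) <= selectedWindows(act)))
  expect_true(all(selectedWindows(mask) <= selectedWindows(cov)))
})
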