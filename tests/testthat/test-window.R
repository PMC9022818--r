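test_that("window counting follows the floor formula", {
  expect_identical(countWindows(300, 17, 1), 284L)
  expect_identical(countWindows(100, 100, 1), 1L)
  ## enumerate start positions for T = 10, window 4, step 2
  starts <- seq(1, 10 - 4 + 1, by = 2)
  expect_identical(countWindows(10, 4, 2), length(starts))
  expect_error(countWindows(10, 11, 1), "larger than series")
  ## grid sweep against direct enumeration
  for (T in c(20, 37, 100)) for (w in c(5, 17)) for (s in c(1, 3, 5)) {
    expect_identical(countWindows(T, w, s),
                     length(seq(w, T, by = s)))
  }
})

test_that("weighted Pearson reduces to ordinary Pearson and matches the
           weighted-moment formula", {
  set.seed(31)
  x <- rnorm(17)
  expect_equal(weightedPearson(x, 2 * x + 1), 1.0)
  expect_equal(weightedPearson(x, -x, runif(17) + 0.1), -1.0)

  y <- rnorm(17)
  expect_equal(weightedPearson(x, y), cor(x, y), tolerance = 1e-14)

  ## independent evaluation of the weighted-moment formula
  w <- exp(-0.5 * ((1:17 - 9) / 2.8)^2)
  wn <- w / sum(w)
  mx <- sum(wn * x); my <- sum(wn * y)
  ref <- sum(wn * (x - mx) * (y - my)) /
    sqrt(sum(wn * (x - mx)^2) * sum(wn * (y - my)^2))
  expect_equal(weightedPearson(x, y, w), ref, tolerance = 1e-12)

  expect_warning(weightedPearson(rep(1, 10), rnorm(10)), "constant")
  expect_error(weightedPearson(1:2, 1:2), "at least 3")
})

test_that("full-length window reproduces the static correlation matrix", {
  set.seed(32)
  x <- matrix(rnorm(100 * 4), 100, 4)
  ts <- roiTimeSeries(x, tr = 1)
  fc <- slidingWindowFC(ts, windowSize = 100)
  expect_identical(nWindows(fc), 1L)
  expect_equal(unname(fcMatrices(fc, 1)), unname(cor(x)), tolerance = 1e-12)
})

test_that("windowed matrices equal the weighted-pearson oracle pairwise", {
  set.seed(33)
  x <- matrix(rnorm(60 * 4), 60, 4)
  ts <- roiTimeSeries(x, tr = 1)
  for (taper in c("rectangular", "gaussian")) {
    fc <- slidingWindowFC(ts, windowSize = 17, stepSize = 3, taper = taper)
    wts <- if (taper == "rectangular") rep(1, 17) else
      exp(-0.5 * ((1:17 - 9) / (17 / 6))^2)
    for (w in sample(nWindows(fc), 3)) {
      last <- windowLastTR(fc)[w]
      seg <- x[(last - 16):last, ]
      for (i in 1:3) for (j in (i + 1):4) {
        expect_equal(fcMatrices(fc, w)[i, j],
                     weightedPearson(seg[, i], seg[, j], wts),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("joint latent drive yields near-unit windowed correlations", {
  set.seed(34)
  z <- rnorm(120)
  x <- cbind(z + rnorm(120, sd = 1e-4), 2 * z + rnorm(120, sd = 1e-4))
  fc <- slidingWindowFC(roiTimeSeries(x, tr = 1), windowSize = 20)
  expect_true(all(fcMatrices(fc)[1, 2, ] > 0.99))
})

test_that("block-switched coupling raises within-block FC", {
  design <- taskDesign(c(0, 1, 0), c(100, 100, 100))
  ts <- simulateROITimeSeries(nROIs = 4, design = design, rhoTask = 0.8,
                              rhoRest = 0.1, noiseSD = 1,
                              hrfSmoothing = FALSE, seed = 5)
  fc <- slidingWindowFC(ts, windowSize = 17)
  last <- windowLastTR(fc)
  inTask <- last >= 117 & last <= 200   # windows fully inside TRs 101-200
  inRest <- last <= 100                 # fully inside TRs 1-100
  offDiag <- function(m) m[upper.tri(m)]
  meanFC <- function(sel) mean(apply(fcMatrices(fc)[, , sel], 3,
                                     function(m) mean(offDiag(m))))
  expect_gt(meanFC(inTask), meanFC(inRest))
})

test_that("FC is invariant to per-ROI affine rescaling", {
  set.seed(35)
  x <- matrix(rnorm(80 * 3), 80, 3)
  ts1 <- roiTimeSeries(x, tr = 1)
  ts2 <- roiTimeSeries(sweep(sweep(x, 2, c(2, -3, 0.5), `*`), 2,
                             c(10, -1, 4), `+`), tr = 1)
  f1 <- slidingWindowFC(ts1, 17, taper = "gaussian")
  f2 <- slidingWindowFC(ts2, 17, taper = "gaussian")
  ## sign flips where scale is negative: compare on magnitudes
  expect_equal(abs(fcMatrices(f1)), abs(fcMatrices(f2)), tolerance = 1e-10)
})

test_that("constant ROI within a window flags missing edges", {
  x <- matrix(rnorm(60 * 3), 60, 3)
  x[1:20, 2] <- 7
  ts <- roiTimeSeries(x, tr = 1)
  expect_warning(fc <- slidingWindowFC(ts, windowSize = 10), "constant")
  expect_true(anyNA(fcMatrices(fc, 1)))
  expect_equal(fcMatrices(fc, 1)[1, 3], cor(x[1:10, 1], x[1:10, 3]),
               tolerance = 1e-12)
  expect_equal(diag(fcMatrices(fc, 1)), rep(1, 3), ignore_attr = TRUE)
})

test_that("FC archives round-trip through JSON", {
  set.seed(36)
  ts <- roiTimeSeries(matrix(rnorm(40 * 3), 40, 3), tr = 2)
  fc <- slidingWindowFC(ts, windowSize = 12, stepSize = 4,
                        taper = "gaussian", gaussianSigma = 3)
  path <- tempfile(fileext = ".json")
  writeFCSeries(fc, path)
  back <- readFCSeries(path)
  expect_equal(fcMatrices(back), unname(fcMatrices(fc)), tolerance = 1e-15)
  expect_identical(windowLastTR(back), windowLastTR(fc))
  expect_identical(back@taper, "gaussian")
  expect_equal(back@gaussianSigma, 3)
  expect_identical(roiLabels(back), roiLabels(fc))
})
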