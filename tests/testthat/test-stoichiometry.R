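# Brightness histograms, calibration, expression and the mixture machinery.

cal <- CalibrationReference()   # 0.048 +/- 0.001, 0.355 fL

test_that("ROI histograms bin the masked brightness values", {
  vals <- rep(0.096, 500)
  h <- roiBrightnessHistogram(vals, binWidth = 0.004)
  expect_equal(sum(binCounts(h) > 0), 1)
  expect_lt(abs(binCenters(h)[which.max(binCounts(h))] - 0.096), 0.004)
  expect_equal(h@nPixels, 500L)

  withr::with_seed(8, {
    g <- rnorm(5000, 0.1, 0.03)
    hg <- roiBrightnessHistogram(g, binWidth = 0.004)
    wmean <- sum(binCenters(hg) * binCounts(hg)) / sum(binCounts(hg))
    expect_equal(wmean, mean(g), tolerance = 0.004)
  })

  expect_error(roiBrightnessHistogram(rep(0.1, 50)), "valid pixels")
})

test_that("the Gaussian peak fit recovers exact and noisy centres", {
  x <- seq(-0.1, 0.3, by = 0.004)
  y <- 100 * exp(-(x - 0.096)^2 / (2 * 0.03^2))
  h <- new("BrightnessHistogram",
           binEdges = c(x - 0.002, max(x) + 0.002), counts = y,
           density = FALSE, nPixels = 1000L, roiId = "exact",
           expression = NA_real_)
  fit <- fitGaussianPeak(h, cal)
  expect_true(fit@converged)
  expect_equal(peakBrightness(fit), 0.096, tolerance = 0.002)
  expect_equal(fit@subunits, 2, tolerance = 0.05)

  # skewed two-population histogram: the fit tracks the dominant mode
  y2 <- 100 * exp(-(x - 0.096)^2 / (2 * 0.03^2)) +
    20 * exp(-(x - 0.192)^2 / (2 * 0.05^2))
  h2 <- new("BrightnessHistogram",
            binEdges = c(x - 0.002, max(x) + 0.002), counts = y2,
            density = FALSE, nPixels = 1000L, roiId = "skew",
            expression = NA_real_)
  fit2 <- fitGaussianPeak(h2)
  grid <- seq(-0.1, 0.3, by = 1e-4)
  argmax <- grid[which.max(fit2@amplitude *
                             exp(-(grid - fit2@peakBrightness)^2 /
                                   (2 * fit2@width^2)))]
  expect_lt(abs(argmax - fit2@peakBrightness), 1e-4)
  expect_lt(abs(fit2@peakBrightness - 0.096), 0.02)
})

test_that("subunits per complex is the calibrated brightness ratio", {
  expect_equal(round(subunitsPerComplex(0.0798, cal), 2), 1.66)
  expect_equal(subunitsPerComplex(epsilon0(cal), cal), 1)
  expect_equal(subunitsPerComplex(0.096, cal), 2)
})

test_that("expression level is the median intensity over eps0", {
  m <- matrix(0.048, 10, 10)
  expect_equal(expressionLevel(m, calibration = cal), 1)
  m2 <- matrix(4.8, 10, 10)
  expect_equal(expressionLevel(m2, calibration = cal), 100)
  expect_error(expressionLevel(m, matrix(FALSE, 10, 10), cal), "empty")
})

test_that("expression regimes use closed-left, open-right windows", {
  expect_equal(classifyExpressionRegime(50), "low")
  expect_equal(classifyExpressionRegime(300), "physiological")
  expect_equal(classifyExpressionRegime(c(90, 599.9, 600)),
               c("physiological", "physiological", "high"))
})

test_that("accumulated histograms pool only cells inside the window", {
  cellA <- list(values = rep(c(0.09, 0.10), 300), expression = 150)
  cellB <- list(values = rep(c(0.19, 0.20), 300), expression = 700)
  one <- accumulateHistograms(list(cellA), binWidth = 0.004)
  both <- accumulateHistograms(list(cellA, cellB), binWidth = 0.004)
  expect_equal(one@counts, both@counts)     # B is outside [90, 600)
  expect_true(one@density)
  bw <- diff(one@binEdges[1:2])
  expect_equal(sum(one@counts) * bw, 1)     # unit area

  # two identical cells leave the shape unchanged
  two <- accumulateHistograms(list(cellA, cellA), binWidth = 0.004)
  expect_equal(two@counts, one@counts)
  expect_equal(two@nPixels, 2L * one@nPixels)

  expect_error(accumulateHistograms(list(cellB)), "window")
})

test_that("log-normal areas match numeric quadrature", {
  for (p in list(c(2, 0.096, 0.2), c(0.5, 0.3, 0.55))) {
    q <- stats::integrate(function(x)
      scanNB:::lognormalCurve(x, p[1], p[2], p[3]),
      lower = 0, upper = Inf, rel.tol = 1e-10)
    expect_equal(q$value, scanNB:::lognormalArea(p[1], p[3]),
                 tolerance = 1e-6)
  }
})

test_that("monomer reference fit recovers a known log-normal mode", {
  withr::with_seed(21, {
    m <- 0.048; sig <- 0.25
    vals <- rlnorm(2e5, meanlog = log(m) + sig^2, sdlog = sig)
    h <- roiBrightnessHistogram(vals, binWidth = 0.002)
    comp <- fitMonomerReference(h)
    expect_lt(abs(comp@mode - m), 0.02 * m)
    expect_lt(abs(comp@shape - sig), 0.03)
    expect_equal(comp@role, "monomer")
  })

  # near-symmetric narrow histogram: mode ~ mean
  withr::with_seed(22, {
    vals <- rlnorm(1e5, meanlog = log(0.05), sdlog = 0.08)
    comp <- fitMonomerReference(roiBrightnessHistogram(vals,
                                                       binWidth = 0.001))
    expect_lt(abs(comp@mode - mean(vals)), 0.001)
  })
})

test_that("pure-dimer histograms yield a dimer fraction of one", {
  m0 <- 0.048
  bw <- 0.004
  edges <- seq(0, 0.6, by = bw)
  xs <- (edges[-1] + edges[-length(edges)]) / 2
  dens <- scanNB:::lognormalCurve(xs, 1, 2 * m0, 0.25)
  dens <- dens / (sum(dens) * bw)
  h <- new("BrightnessHistogram", binEdges = edges, counts = dens,
           density = TRUE, nPixels = 10000L, roiId = "pureD",
           expression = NA_real_)
  fit <- fitLognormalMixture(h, m0)
  fr <- speciesFractions(fit)
  expect_gt(fr["dimer"], 0.95)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  # anchored modes are exact multiples of the monomer mode
  expect_identical(components(fit)[[1]]@mode, 2 * m0)
  expect_identical(components(fit)[[2]]@mode, 4 * m0)
})

test_that("refitting a fitted mixture reproduces its own fractions", {
  m0 <- 0.048
  bw <- 0.004
  edges <- seq(0, 0.8, by = bw)
  xs <- (edges[-1] + edges[-length(edges)]) / 2
  target <- scanNB:::lognormalCurve(xs, 1.0, 2 * m0, 0.25) +
    scanNB:::lognormalCurve(xs, 0.6, 4 * m0, 0.3) +
    scanNB:::lognormalCurve(xs, 0.2, 8 * m0, 0.3)
  target <- target / (sum(target) * bw)
  h <- new("BrightnessHistogram", binEdges = edges, counts = target,
           density = TRUE, nPixels = 10000L, roiId = "self",
           expression = NA_real_)
  fit1 <- fitLognormalMixture(h, m0)
  dens2 <- mixtureDensity(fit1, xs)
  h2 <- new("BrightnessHistogram", binEdges = edges,
            counts = dens2 / (sum(dens2) * bw), density = TRUE,
            nPixels = 10000L, roiId = "self2", expression = NA_real_)
  fit2 <- fitLognormalMixture(h2, m0)
  expect_lt(max(abs(speciesFractions(fit2) - speciesFractions(fit1))),
            0.02)
})

test_that("external intensity scaling preserves dispersion exactly", {
  expect_equal(expressionScaleExternal(c(10, 20), 450, 15), c(300, 600))
  withr::with_seed(3, {
    x <- rlnorm(100, 3, 0.6)
    y <- expressionScaleExternal(x, 450, mean(x))
    expect_equal(mean(y), 450)
    expect_equal(sd(y) / mean(y), sd(x) / mean(x))
  })
  expect_error(expressionScaleExternal(1:3, 450, 0), "positive")
})

test_that("fitted stoichiometry is linear in the true oligomer size", {
  # pure species s in {1, 2, 4, 8} at matched expression: recovered
  # subunits/complex within 10% of s
  for (s in c(1, 2, 4, 8)) {
    st <- quickStack(s, 240 / s, seed = 70 + s)
    nb <- computeNBMaps(st, divisor = "sample", smooth = 9)
    h <- roiBrightnessHistogram(nb, calibration = cal)
    fit <- fitGaussianPeak(h, cal)
    expect_lt(abs(fit@subunits - s) / s, 0.10)
  }
})

test_that("doubling the density doubles expression, not stoichiometry", {
  st1 <- quickStack(2, 50, seed = 81)
  st2 <- quickStack(2, 100, seed = 82)
  nb1 <- computeNBMaps(st1, divisor = "sample")
  nb2 <- computeNBMaps(st2, divisor = "sample")
  e1 <- expressionLevel(nb1, calibration = cal)
  e2 <- expressionLevel(nb2, calibration = cal)
  expect_equal(e2 / e1, 2, tolerance = 0.05)
  b1 <- roiBrightness(nb1); b2 <- roiBrightness(nb2)
  se <- roiBrightnessSE(nb1) + roiBrightnessSE(nb2)
  expect_lt(abs(b2 - b1), 3 * se)
})
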