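# Per-pixel estimators, QC and masking.

test_that("frame mean series handles constants, ramps and masks", {
  expect_equal(frameMeanSeries(constantFrameStack(rep(3, 5))), rep(3, 5))
  expect_equal(frameMeanSeries(constantFrameStack(10:1)), as.numeric(10:1))

  # hand computation on a 3-frame 2x2 stack with one pixel masked out
  arr <- array(0, c(3, 2, 2))
  arr[1, , ] <- matrix(c(1, 2, 3, 4), 2)
  arr[2, , ] <- matrix(c(5, 6, 7, 8), 2)
  arr[3, , ] <- matrix(c(9, 10, 11, 12), 2)
  mask <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2)
  st <- ImageStack(arr)
  expect_equal(frameMeanSeries(st, mask),
               c(mean(c(1, 2, 4)), mean(c(5, 6, 8)), mean(c(9, 10, 12))))
  expect_error(frameMeanSeries(st, matrix(TRUE, 3, 3)), "geometry")
})

test_that("photobleach fraction is the exact line-fit decline", {
  expect_equal(photobleachFraction(
    photobleachFraction(constantFrameStack(rep(7, 10)))), 0)
  expect_true(accepted(photobleachFraction(constantFrameStack(rep(7, 10)))))

  # exactly linear 100 -> 88: fraction 0.12, rejected by the 10% rule
  qc <- photobleachFraction(constantFrameStack(seq(100, 88, by = -1)))
  expect_equal(photobleachFraction(qc), 0.12)
  expect_false(accepted(qc))

  # 2% decline accepted
  qc2 <- photobleachFraction(constantFrameStack(c(100, 99, 98)))
  expect_equal(photobleachFraction(qc2), 0.02)
  expect_true(accepted(qc2))

  # increasing intensity: negative fraction, accepted
  expect_true(accepted(photobleachFraction(constantFrameStack(1:10))))
})

test_that("pixel moments follow the chosen divisor convention", {
  st <- ImageStack(array(c(2, 4, 3, 3), c(4, 1, 1)))
  mom <- pixelMoments(st)
  expect_equal(mom$mean[1, 1], 3)
  expect_equal(mom$variance[1, 1], 0.5)         # divisor T
  expect_equal(pixelMoments(st, "sample")$variance[1, 1], 2 / 3)
  expect_equal(pixelMoments(constantFrameStack(c(5, 5, 5)))$variance,
               matrix(0, 4, 4))
})

test_that("brightness and number maps implement the defining ratios", {
  st <- ImageStack(array(c(2, 4, 3, 3), c(4, 1, 1)))
  nb <- computeNBMaps(st)
  expect_equal(brightnessMap(nb)[1, 1], 0.5 / 3 - 1)  # -0.8333, retained
  expect_false(numberValidMask(nb)[1, 1])             # variance < mean
  expect_true(is.na(numberMap(nb)[1, 1]))

  # variance = mean exactly: brightness 0, number undefined
  nb0 <- computeNBMaps(ImageStack(array(c(0, 1, 2), c(3, 1, 1))),
                       divisor = "sample")
  expect_equal(brightnessMap(nb0)[1, 1], 0)
  expect_false(numberValidMask(nb0)[1, 1])
})

test_that("n x eps = F exactly on every number-valid pixel", {
  st <- quickStack(2, 10, seed = 31, height = 32, width = 32)
  for (div in c("population", "sample")) {
    nb <- computeNBMaps(st, divisor = div)
    ok <- numberValidMask(nb)
    expect_gt(sum(ok), 100)
    expect_equal(numberMap(nb)[ok] * brightnessMap(nb)[ok],
                 meanMap(nb)[ok], tolerance = 1e-12)
  }
})

test_that("moment pooling marks border pixels invalid, interior unchanged", {
  st <- quickStack(2, 10, seed = 32, frames = 30, height = 16, width = 16)
  nb <- computeNBMaps(st, smooth = 5)
  expect_false(any(validMask(nb)[1:2, ]))
  expect_equal(sum(validMask(nb)), 12^2)
  # pooled moments are the window averages of the raw moments
  raw <- pixelMoments(st)
  expect_equal(meanMap(nb)[8, 8], mean(raw$mean[6:10, 6:10]))
})

test_that("detrending removes a linear bleach from the variance", {
  beta <- 0.3
  st <- quickStack(2, 50, seed = 33, bleach = beta, height = 32, width = 32)
  rawEps <- roiBrightness(computeNBMaps(st, divisor = "sample"))
  detEps <- roiBrightness(computeNBMaps(st, divisor = "sample",
                                        detrend = TRUE))
  # after removing the ramp the expected brightness is eps <r^2>/<r>
  r <- 1 - beta * (0:99) / 99
  expect_lt(detEps, rawEps - 0.02)   # trend variance removed
  expect_lt(abs(detEps - 0.096 * mean(r^2) / mean(r)), 0.02)

  # without bleaching, detrending leaves the brightness unbiased
  st0 <- quickStack(2, 50, seed = 34, height = 32, width = 32)
  nbd <- computeNBMaps(st0, divisor = "sample", detrend = TRUE)
  expect_lt(abs(roiBrightness(nbd) - 0.096), 4 * roiBrightnessSE(nbd))
})

test_that("shot-noise null: mean brightness of background pixels is zero", {
  st <- quickStack(1, 0, seed = 41, B = 1.5)   # 4096 pixels
  nb <- computeNBMaps(st, divisor = "sample")
  eps <- brightnessMap(nb)[validMask(nb)]
  expect_gte(length(eps), 4096 * 0.99)
  expect_lt(abs(mean(eps)), 4 * sd(eps) / sqrt(length(eps)))
})

test_that("ROI-averaged brightness tracks the oracle over (s, p) settings", {
  for (case in list(list(s = 1, p = 1), list(s = 4, p = 0.5))) {
    cfg <- SimulationConfig(SpeciesSpec(case$s, 10),
                            labelingEfficiency = case$p,
                            height = 48, width = 48,
                            seed = 50 + case$s)
    nb <- computeNBMaps(simulateFrameCounts(cfg), divisor = "sample")
    expect_lt(abs(roiBrightness(nb) -
                    expectedMoments(cfg)@apparentBrightness),
              4 * roiBrightnessSE(nb))
  }
})

test_that("Otsu and absolute thresholds separate a bimodal intensity map", {
  m <- matrix(0.1, 20, 20)
  m[8:12, 8:12] <- 1.0
  otsuMask <- thresholdMask(m)
  expect_identical(otsuMask, m > 0.5)
  expect_identical(thresholdMask(m, "absolute", level = 0.5), otsuMask)
  expect_error(thresholdMask(m, "absolute"), "level")
  expect_warning(empty <- thresholdMask(matrix(0.1, 5, 5)), "contrast")
  expect_false(any(empty))
})

test_that("exclusion masks subtract from the selection", {
  mask <- matrix(TRUE, 4, 4)
  none <- matrix(FALSE, 4, 4)
  expect_identical(applyExclusions(mask, none), mask)
  expect_false(any(applyExclusions(mask, mask)))
  checker <- outer(1:4, 1:4, function(i, j) (i + j) %% 2 == 0)
  expect_identical(applyExclusions(mask, checker), !checker)
  expect_error(applyExclusions(mask, matrix(FALSE, 3, 3)), "differ")
})

test_that("shrinking the mask re-selects pixels without changing values", {
  st <- quickStack(2, 10, seed = 61, frames = 30, height = 16, width = 16)
  nb <- computeNBMaps(st)
  full <- matrix(TRUE, 16, 16)
  small <- full; small[1:8, ] <- FALSE
  h1 <- roiBrightnessHistogram(nb, full, minPixels = 10)
  vals1 <- brightnessMap(nb)[validMask(nb) & full]
  vals2 <- brightnessMap(nb)[validMask(nb) & small]
  expect_true(all(vals2 %in% vals1))
  expect_identical(brightnessMap(computeNBMaps(st)), brightnessMap(nb))
})
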