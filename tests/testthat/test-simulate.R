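# The moment oracle and the fast-tier simulator.

test_that("expectedMoments reproduces the closed forms for single species", {
  # monomer identity
  mono <- expectedMoments(SimulationConfig(SpeciesSpec(1, 10)))
  expect_equal(mono@apparentBrightness, 0.048)
  expect_equal(mono@meanF, 0.48)

  # dimer: twice the molecular brightness, the configured particle number
  dim2 <- expectedMoments(SimulationConfig(SpeciesSpec(2, 5)))
  expect_equal(dim2@apparentBrightness, 0.096)
  expect_equal(dim2@apparentNumber, 5)

  # partial labeling: eps0 (1 + (s-1) p)
  half <- expectedMoments(SimulationConfig(SpeciesSpec(2, 5),
                                           labelingEfficiency = 0.5))
  expect_equal(half@apparentBrightness, 0.048 * 1.5)

  # number x brightness = mean, the estimator identity at the oracle level
  for (mp in list(mono, dim2, half))
    expect_equal(mp@apparentNumber * mp@apparentBrightness, mp@meanF)
})

test_that("expectedMoments agrees with direct Monte-Carlo sampling", {
  # brute-force draws of F = Poisson(eps0 * Binomial(N s, p) + B)
  drawF <- function(s, nbar, p, eps0, B, n) {
    N <- rpois(n, nbar)
    K <- rbinom(n, N * s, p)
    rpois(n, eps0 * K + B)
  }
  withr::with_seed(42, {
    for (case in list(list(s = 2, nbar = 5, p = 1),
                      list(s = 2, nbar = 5, p = 0.5),
                      list(s = 4, nbar = 2, p = 0.8))) {
      n <- 1e6
      F <- drawF(case$s, case$nbar, case$p, 0.048, 0.1, n)
      mp <- expectedMoments(SimulationConfig(
        SpeciesSpec(case$s, case$nbar), labelingEfficiency = case$p,
        backgroundRate = 0.1))
      seMean <- sd(F) / sqrt(n)
      seVar <- sqrt((mean((F - mean(F))^4) - var(F)^2) / n)
      expect_lt(abs(mean(F) - mp@meanF), 4 * seMean)
      expect_lt(abs(var(F) - mp@varianceF), 4 * seVar)
    }
  })
})

test_that("degenerate configurations are rejected", {
  expect_error(SimulationConfig(SpeciesSpec(2, 5), labelingEfficiency = 1.2),
               "labelingEfficiency")
  expect_error(SpeciesSpec(0, 5), "subunits")
  expect_error(expectedMoments(SimulationConfig(list(), backgroundRate = 0)),
               "degenerate")
})

test_that("background-only stacks are pure shot noise", {
  st <- quickStack(1, 0, seed = 7, B = 2.0, height = 32, width = 32)
  nb <- computeNBMaps(st, divisor = "sample")
  # variance ~ mean per pixel: pooled brightness within 4 SE of zero
  expect_lt(abs(roiBrightness(nb)), 4 * roiBrightnessSE(nb))
})

test_that("simulated brightness matches the oracle within sampling error", {
  st <- quickStack(2, 5, seed = 13)
  nb <- computeNBMaps(st, divisor = "sample")
  expect_lt(abs(roiBrightness(nb) - 0.096), 4 * roiBrightnessSE(nb))
})

test_that("moment oracle agreement holds over many pixel-frames", {
  # >= 1e5 pixel-frames: 64 x 64 x 100
  cfg <- SimulationConfig(list(SpeciesSpec(2, 3), SpeciesSpec(4, 1)),
                          labelingEfficiency = 0.9, backgroundRate = 0.5,
                          seed = 99)
  st <- simulateFrameCounts(cfg)
  mp <- expectedMoments(cfg)
  F <- as.vector(frames(st))
  n <- length(F)
  expect_gte(n, 1e5)
  seMean <- sd(F) / sqrt(n)
  seVar <- sqrt((mean((F - mean(F))^4) - var(F)^2) / n)
  expect_lt(abs(mean(F) - mp@meanF), 4 * seMean)
  expect_lt(abs(var(F) - mp@varianceF), 4 * seVar)
})

test_that("a 12% linear bleach ramp is constructed and caught by QC", {
  st <- quickStack(2, 50, seed = 5, bleach = 0.12)
  qc <- photobleachFraction(st)
  expect_false(accepted(qc))
  expect_lt(abs(photobleachFraction(qc) - 0.12), 0.01)
})

test_that("identical config and seed give bit-identical stacks", {
  cfg <- SimulationConfig(SpeciesSpec(2, 5), frames = 20, height = 16,
                          width = 16, seed = 123)
  expect_identical(frames(simulateFrameCounts(cfg)),
                   frames(simulateFrameCounts(cfg)))
  cfg2 <- SimulationConfig(SpeciesSpec(2, 5), frames = 20, height = 16,
                           width = 16, seed = 124)
  expect_false(identical(frames(simulateFrameCounts(cfg)),
                         frames(simulateFrameCounts(cfg2))))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(1)
  a <- runif(1)
  set.seed(1)
  invisible(simulateFrameCounts(SimulationConfig(SpeciesSpec(1, 1),
                                                 frames = 5, height = 4,
                                                 width = 4, seed = 9)))
  expect_identical(runif(1), a)
})

test_that("apparent brightness is monotone in the brighter-species fraction", {
  total <- 10
  eps <- vapply(seq(0, 1, by = 0.1), function(f) {
    cfg <- SimulationConfig(list(SpeciesSpec(2, (1 - f) * total),
                                 SpeciesSpec(4, f * total)))
    expectedMoments(cfg)@apparentBrightness
  }, 0)
  expect_true(all(diff(eps) > 0))
  expect_equal(eps[1], 0.096)
  expect_equal(eps[11], 0.192)
})

test_that("vanishing labeling efficiency approaches the monomer brightness", {
  # fixed oligomer size, p -> 0: the few labeled complexes carry one dye each
  eps <- vapply(c(0.5, 0.1, 0.01, 1e-4), function(p)
    expectedMoments(SimulationConfig(SpeciesSpec(4, 10),
                                     labelingEfficiency = p)
    )@apparentBrightness, 0)
  expect_true(all(diff(eps) < 0))
  expect_equal(eps[4], 0.048, tolerance = 1e-3)
})
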