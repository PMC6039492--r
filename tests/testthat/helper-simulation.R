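# Shared fixtures: all synthetic, built in code at test time.

# One-species stack at the default acquisition geometry (overridable).
quickStack <- function(s, nbar, seed, p = 1, B = 0, frames = 100,
                       height = 64, width = 64, bleach = 0, eps0 = 0.048) {
  cfg <- SimulationConfig(SpeciesSpec(s, nbar), monomerBrightness = eps0,
                          labelingEfficiency = p, backgroundRate = B,
                          frames = frames, height = height, width = width,
                          bleachFraction = bleach, seed = seed)
  simulateFrameCounts(cfg)
}

# Deterministic stack whose every frame is constant: frame t has value vals[t].
constantFrameStack <- function(vals, height = 4, width = 4) {
  arr <- array(0, c(length(vals), height, width))
  for (t in seq_along(vals)) arr[t, , ] <- vals[t]
  ImageStack(arr)
}

# Standard-error of the ROI-pooled brightness (ratio-estimator delta method).
roiBrightnessSE <- function(maps, mask = NULL) {
  sel <- validMask(maps)
  if (!is.null(mask)) sel <- sel & mask
  v <- varianceMap(maps)[sel]
  m <- meanMap(maps)[sel]
  R <- mean(v) / mean(m)
  stats::sd(v - R * m) / (mean(m) * sqrt(length(m)))
}

# Independent per-pixel generator used as an oracle where the test must not
# rely on the package's own simulator: per-pixel species map (subunits s and
# occupancy nbar matrices), Poisson complexes, full labeling.
oracleStack <- function(sMap, nbarMap, eps0 = 0.048, frames = 100, seed = 1) {
  H <- nrow(sMap); W <- ncol(sMap); npx <- H * W
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  arr <- array(0, c(frames, H, W))
  for (t in seq_len(frames)) {
    N <- rpois(npx, as.vector(nbarMap))
    arr[t, , ] <- matrix(rpois(npx, eps0 * N * as.vector(sMap)), H, W)
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  ImageStack(arr)
}
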