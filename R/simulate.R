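#' Closed-form moments of a simulated sN&B acquisition
#'
#' Analytic expectation of the per-pixel photon-count mean and variance under
#' the independent-frame model: each species contributes a Poisson number of
#' complexes per observation volume, each complex carries a binomial number of
#' labeled subunits, and detection is Poisson. For species i with s_i subunits
#' at mean occupancy n_i, label probability p and monomer brightness eps0:
#' \deqn{\langle F\rangle = B + \sum_i n_i s_i p \epsilon_0}
#' \deqn{Var(F) = \langle F\rangle + \sum_i n_i E[k_i^2] \epsilon_0^2,\quad
#'       E[k_i^2] = s_i p(1-p) + (s_i p)^2}
#' The apparent brightness is the expectation of the map estimator,
#' \eqn{(Var(F) - \langle F\rangle)/\langle F\rangle}; for a single species
#' with no background it reduces to \eqn{\epsilon_0 (1 + (s-1)p)}. The
#' apparent number is \eqn{\langle F\rangle / \epsilon_{app}}, so that
#' number x brightness = mean exactly, mirroring the estimator identity.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{MomentPrediction}.
#' @examples
#' cfg <- SimulationConfig(SpeciesSpec(2, 5))
#' expectedMoments(cfg)  # brightness 0.096 = 2 x 0.048, number 5
#' @export
expectedMoments <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  p <- config@labelingEfficiency
  eps0 <- config@monomerBrightness
  B <- config@backgroundRate
  if (length(config@species) == 0L && B == 0)
    stop("degenerate configuration: no species and no background")
  s <- vapply(config@species, function(x) as.numeric(x@subunits), 0)
  nbar <- vapply(config@species, function(x) x@meanComplexes, 0)
  meanF <- B + sum(nbar * s * p * eps0)
  Ek2 <- s * p * (1 - p) + (s * p)^2
  varExcess <- sum(nbar * Ek2 * eps0^2)
  varF <- meanF + varExcess
  if (meanF > 0) {
    eps <- varExcess / meanF
    n <- if (eps > 0) meanF / eps else NA_real_
  } else {
    eps <- NA_real_
    n <- NA_real_
  }
  new("MomentPrediction", meanF = meanF, varianceF = varF,
      apparentBrightness = eps, apparentNumber = n)
}

#' Simulate a photon-count stack with independent frames (fast tier)
#'
#' Per pixel and frame, draws the complex count of each species from
#' Poisson(n_i), the labeled subunits of those complexes from a binomial with
#' the configured labeling efficiency, and the photon count from a Poisson
#' with rate eps0 x (labeled subunits) + background. Frames are statistically
#' independent, which is the correct limit when the interval between raster
#' scans is much longer than the residence time of a complex in the
#' observation volume. A non-zero \code{bleachFraction} beta scales the
#' expected signal of frame t (0-based) by \code{1 - beta * t/(T-1)}.
#'
#' Bit-reproducible given the config (the seed is applied locally; the
#' caller's RNG state is untouched).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return An \linkS4class{ImageStack} with the config echoed in
#'   \code{metadata}.
#' @examples
#' cfg <- SimulationConfig(SpeciesSpec(2, 5), frames = 50, height = 16,
#'                         width = 16, seed = 3)
#' st <- simulateFrameCounts(cfg)
#' @export
simulateFrameCounts <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  T <- config@frames; H <- config@height; W <- config@width
  npx <- H * W
  if (as.double(npx) * T > 2^31 - 1) stop("stack geometry overflows")
  p <- config@labelingEfficiency
  eps0 <- config@monomerBrightness
  ramp <- 1 - config@bleachFraction * (seq_len(T) - 1) / (T - 1)
  counts <- withLocalSeed(config@seed, {
    lambda <- matrix(0, npx, T)
    for (sp in config@species) {
      N <- matrix(stats::rpois(npx * T, sp@meanComplexes), npx, T)
      K <- if (p >= 1) {
        N * sp@subunits
      } else if (p <= 0) {
        N * 0L
      } else {
        matrix(stats::rbinom(npx * T, N * sp@subunits, p), npx, T)
      }
      lambda <- lambda + eps0 * K
    }
    lambda <- sweep(lambda, 2L, ramp, `*`) + config@backgroundRate
    matrix(stats::rpois(npx * T, lambda), npx, T)
  })
  arr <- aperm(array(counts, c(H, W, T)), c(3L, 1L, 2L))
  ImageStack(arr, dwellTime = config@dwellTime, pixelSize = config@pixelSize,
             metadata = list(seed = config@seed, tier = "independent-frame",
                             configDigest = configDigest(config)))
}

#' Simulate a raster-scanned stack of diffusing particles (validation tier)
#'
#' Brownian particles on a periodic 2-D plane are raster-scanned with a
#' Gaussian point-spread function: each pixel integrates
#' \eqn{\epsilon_0 k \exp(-2 d^2 / w_0^2)} over the particles (k = labeled
#' subunits of the particle, d = wrapped distance to the pixel centre, w_0 =
#' beam waist), and detection is Poisson. Particle positions advance once per
#' scan line (time step = width x dwell), an adequate granularity because
#' membrane diffusion over one line time is far below the beam waist; a
#' warning is issued if the RMS step exceeds half the waist (temporal
#' aliasing). The particle surface density is chosen so that the mean
#' occupancy of the PSF's effective area (\eqn{\pi w_0^2 / 2}) equals the
#' configured complexes per observation volume, making the mean intensity
#' match the fast tier.
#'
#' Downstream contracts are identical to \code{\link{simulateFrameCounts}};
#' this tier exists to validate the independent-frame approximation, not for
#' routine use (it is orders of magnitude slower).
#'
#' @param config a \linkS4class{SimulationConfig} with \code{psfWaist} and
#'   \code{diffusionCoefficient} set.
#' @return An \linkS4class{ImageStack}.
#' @export
simulateDiffusionStack <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  T <- config@frames; H <- config@height; W <- config@width
  px <- config@pixelSize
  w0 <- config@psfWaist
  D <- config@diffusionCoefficient     # um^2/s == nm^2/us
  p <- config@labelingEfficiency
  eps0 <- config@monomerBrightness
  dt <- W * config@dwellTime           # us per scan line
  stepSD <- sqrt(2 * D * dt)           # nm, per axis
  if (stepSD > w0 / 2)
    warning("diffusion step exceeds half the PSF waist; temporal aliasing")
  Ly <- H * px; Lx <- W * px
  aEff <- pi * w0^2 / 2                # effective PSF area, nm^2
  xc <- (seq_len(W) - 0.5) * px
  arr <- withLocalSeed(config@seed, {
    pos <- list(); klab <- list()
    for (sp in config@species) {
      dens <- sp@meanComplexes / aEff
      P <- stats::rpois(1L, dens * Lx * Ly)
      pos[[length(pos) + 1L]] <- cbind(stats::runif(P, 0, Lx),
                                       stats::runif(P, 0, Ly))
      klab[[length(klab) + 1L]] <-
        if (p >= 1) rep(sp@subunits, P) else stats::rbinom(P, sp@subunits, p)
    }
    out <- array(0L, c(T, H, W))
    for (t in seq_len(T)) {
      for (i in seq_len(H)) {
        yc <- (i - 0.5) * px
        lam <- rep(config@backgroundRate, W)
        for (g in seq_along(pos)) {
          P <- nrow(pos[[g]])
          if (P == 0L) next
          # advance this group's particles by one line time
          pos[[g]][, 1] <- (pos[[g]][, 1] +
                            stats::rnorm(P, 0, stepSD)) %% Lx
          pos[[g]][, 2] <- (pos[[g]][, 2] +
                            stats::rnorm(P, 0, stepSD)) %% Ly
          dy <- abs(pos[[g]][, 2] - yc); dy <- pmin(dy, Ly - dy)
          near <- dy < 4 * w0
          if (!any(near)) next
          dx <- abs(outer(pos[[g]][near, 1], xc, `-`))
          dx <- pmin(dx, Lx - dx)
          g2 <- exp(-2 * (dx^2 + dy[near]^2) / w0^2)
          lam <- lam + eps0 * colSums(klab[[g]][near] * g2)
        }
        out[t, i, ] <- stats::rpois(W, lam)
      }
    }
    out
  })
  ImageStack(arr, dwellTime = config@dwellTime, pixelSize = config@pixelSize,
             metadata = list(seed = config@seed, tier = "diffusion",
                             configDigest = configDigest(config)))
}

## Compact plain-text digest of a config, stored in stack metadata.
configDigest <- function(config) {
  s <- vapply(config@species,
              function(x) sprintf("%dx%g", x@subunits, x@meanComplexes), "")
  paste0("species=", paste(s, collapse = "+"),
         ";eps0=", config@monomerBrightness,
         ";p=", config@labelingEfficiency,
         ";B=", config@backgroundRate,
         ";T=", config@frames, ";h=", config@height, ";w=", config@width,
         ";beta=", config@bleachFraction, ";seed=", config@seed)
}
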