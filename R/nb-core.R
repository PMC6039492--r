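#' Per-frame mean intensity
#'
#' Arithmetic mean of each frame, optionally restricted to a mask. This is
#' the series the photobleaching QC line is fitted to.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param mask optional logical matrix (row x col); the whole frame is used
#'   when absent.
#' @return numeric vector, one value per frame.
#' @export
frameMeanSeries <- function(stack, mask = NULL) {
  stopifnot(is(stack, "ImageStack"))
  f <- stack@frames
  if (is.null(mask)) return(apply(f, 1L, mean))
  if (!identical(dim(mask), dim(f)[2:3]))
    stop("mask geometry does not match the stack")
  if (!any(mask)) stop("empty mask")
  apply(f, 1L, function(fr) mean(fr[mask]))
}

#' Photobleaching quality control
#'
#' Fits a straight line to the frame means by least squares and reports the
#' relative first-to-last decline, \code{(fit(0) - fit(T-1))/fit(0)} with
#' 0-based frame indices. Stacks whose photobleach fraction exceeds the
#' threshold (default 10\%) are rejected; a non-positive fitted starting
#' intensity makes the fraction undefined and also rejects the stack.
#'
#' @param x an \linkS4class{ImageStack} (method also exists for
#'   \linkS4class{QCReport}, where it is the accessor).
#' @param mask optional logical matrix restricting the frame means.
#' @param threshold rejection threshold on the fraction (default 0.10).
#' @param ... unused.
#' @return A \linkS4class{QCReport}.
#' @examples
#' cfg <- SimulationConfig(SpeciesSpec(2, 10), frames = 50, height = 16,
#'                         width = 16, bleachFraction = 0.12, seed = 2)
#' accepted(photobleachFraction(simulateFrameCounts(cfg)))  # FALSE
#' @rdname photobleachFraction
#' @export
setMethod("photobleachFraction", "ImageStack",
  function(x, mask = NULL, threshold = 0.10, ...) {
    fm <- frameMeanSeries(x, mask)
    T <- length(fm)
    if (T < 3L) stop("at least 3 frames are required for the bleaching fit")
    t0 <- seq_len(T) - 1
    fit <- stats::lm.fit(cbind(1, t0), fm)
    f0 <- fit$coefficients[1]
    fT <- f0 + fit$coefficients[2] * (T - 1)
    if (!is.finite(f0) || f0 <= 0) {
      return(new("QCReport", photobleachFraction = NA_real_,
                 accepted = FALSE, threshold = threshold, frameMeans = fm,
                 reason = "fitted initial intensity is not positive"))
    }
    frac <- (f0 - fT) / f0
    acc <- frac <= threshold
    new("QCReport", photobleachFraction = unname(frac), accepted = acc,
        threshold = threshold, frameMeans = fm,
        reason = if (acc) "" else
          sprintf("photobleaching %.1f%% exceeds %.0f%%",
                  100 * frac, 100 * threshold))
  })

#' @rdname photobleachFraction
#' @export
setMethod("photobleachFraction", "QCReport",
          function(x, ...) x@photobleachFraction)

#' Per-pixel time-mean and time-variance
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param divisor "population" (divisor T, matching the
#'   \eqn{\langle\delta F^2\rangle} convention; the default) or "sample"
#'   (divisor T - 1, unbiased). The two differ by O(1/T) in the brightness;
#'   see the package vignette for when each matters.
#' @param detrend subtract a per-pixel linear trend before computing the
#'   variance (default FALSE; stacks that bleach are normally rejected
#'   instead).
#' @return list with matrices \code{mean} and \code{variance}.
#' @examples
#' st <- ImageStack(array(c(2, 4, 3, 3), c(4, 1, 1)))
#' pixelMoments(st)  # mean 3, population variance 0.5
#' @export
pixelMoments <- function(stack, divisor = c("population", "sample"),
                         detrend = FALSE) {
  stopifnot(is(stack, "ImageStack"))
  divisor <- match.arg(divisor)
  f <- stack@frames
  d <- dim(f)
  T <- d[1]
  den <- if (divisor == "population") T else T - 1L
  fm <- matrix(f, T)                         # T x (H*W)
  mv <- colMeans(fm)
  if (detrend) {
    tc <- (seq_len(T) - 1) - (T - 1) / 2
    beta <- colSums(fm * tc) / sum(tc^2)     # per-pixel slope
    resid <- fm - outer(tc, beta)            # trend removed, mean kept
    ss <- colSums(resid^2) - T * colMeans(resid)^2
    den <- den - 1L                          # slope costs one more df
  } else {
    ss <- colSums(fm^2) - T * mv^2
  }
  list(mean = matrix(mv, d[2], d[3]),
       variance = matrix(pmax(ss, 0) / den, d[2], d[3]))
}

#' Compute number & brightness maps from a stack
#'
#' Per pixel, the molecular brightness \eqn{\epsilon = \sigma^2/F - 1} and
#' the particle number \eqn{n = F^2/(\sigma^2 - F)} from the time-mean F and
#' time-variance \eqn{\sigma^2}. On every pixel where both are defined,
#' \eqn{n \epsilon = F} exactly. Negative brightness values (variance below
#' shot noise) are retained in the brightness map; the number map is NA
#' where \eqn{\sigma^2 \le F} (flagged in \code{numberValidMask}).
#'
#' With \code{smooth} > 1 the moment maps are pooled over a w x w boxcar
#' before forming the ratios, trading spatial resolution for brightness
#' precision; single-pixel brightness at 100 frames has a sampling SD of
#' roughly \eqn{\sqrt{2/T}(1+\epsilon)} counts/dwell, which pooling divides
#' by w. Pixels whose window leaves the frame are invalid.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param divisor,detrend see \code{\link{pixelMoments}}.
#' @param smooth odd integer pooling window edge (default 1 = per-pixel).
#' @return An \linkS4class{NBMaps}.
#' @examples
#' cfg <- SimulationConfig(SpeciesSpec(2, 5), frames = 50, height = 16,
#'                         width = 16, seed = 3)
#' nb <- computeNBMaps(simulateFrameCounts(cfg))
#' mean(brightnessMap(nb), na.rm = TRUE)
#' @export
computeNBMaps <- function(stack, divisor = c("population", "sample"),
                          smooth = 1L, detrend = FALSE) {
  divisor <- match.arg(divisor)
  smooth <- as.integer(smooth)
  mom <- pixelMoments(stack, divisor, detrend)
  m <- boxcarPool(mom$mean, smooth)
  v <- boxcarPool(mom$variance, smooth)
  valid <- is.finite(m) & m > 0
  eps <- matrix(NA_real_, nrow(m), ncol(m))
  eps[valid] <- v[valid] / m[valid] - 1
  nvalid <- valid & is.finite(v) & (v - m) > 0
  n <- matrix(NA_real_, nrow(m), ncol(m))
  n[nvalid] <- m[nvalid]^2 / (v[nvalid] - m[nvalid])
  new("NBMaps", meanMap = m, varianceMap = v, numberMap = n,
      brightnessMap = eps, validMask = valid, numberValidMask = nvalid,
      divisor = divisor, smooth = smooth, dwellTime = stack@dwellTime)
}

#' @rdname brightnessMap
#' @export
setMethod("brightnessMap", "NBMaps", function(x, ...) x@brightnessMap)

#' @rdname brightnessMap
#' @export
setMethod("brightnessMap", "ImageStack",
          function(x, ...) computeNBMaps(x, ...)@brightnessMap)

#' @rdname numberMap
#' @export
setMethod("numberMap", "NBMaps", function(x, ...) x@numberMap)

#' @rdname numberMap
#' @export
setMethod("numberMap", "ImageStack",
          function(x, ...) computeNBMaps(x, ...)@numberMap)

#' ROI-pooled brightness and particle number
#'
#' Region-level estimates formed from moments pooled over all valid pixels of
#' a mask: brightness \code{mean(variance)/mean(F) - 1} and particle number
#' \code{mean(F)^2/(mean(variance) - mean(F))}. Pooling first makes the
#' region estimate robust at photon rates where single-pixel estimates are
#' noise-dominated (in particular the number denominator
#' \eqn{\sigma^2 - F}). \code{roiNumber} also offers the median of the
#' per-pixel number map for bright data.
#'
#' @param maps an \linkS4class{NBMaps}.
#' @param mask optional logical matrix; intersected with the validity mask.
#' @param method "pooled" (default) or "median" (per-pixel median).
#' @return a single numeric value.
#' @export
roiBrightness <- function(maps, mask = NULL) {
  stopifnot(is(maps, "NBMaps"))
  sel <- maps@validMask
  if (!is.null(mask)) sel <- sel & mask
  if (!any(sel)) stop("no valid pixels in the ROI")
  mean(maps@varianceMap[sel]) / mean(maps@meanMap[sel]) - 1
}

#' @rdname roiBrightness
#' @export
roiNumber <- function(maps, mask = NULL, method = c("pooled", "median")) {
  stopifnot(is(maps, "NBMaps"))
  method <- match.arg(method)
  if (method == "median") {
    sel <- maps@numberValidMask
    if (!is.null(mask)) sel <- sel & mask
    if (!any(sel)) stop("no number-valid pixels in the ROI")
    return(stats::median(maps@numberMap[sel]))
  }
  sel <- maps@validMask
  if (!is.null(mask)) sel <- sel & mask
  if (!any(sel)) stop("no valid pixels in the ROI")
  m <- mean(maps@meanMap[sel]); v <- mean(maps@varianceMap[sel])
  if (v <= m) return(NA_real_)
  m^2 / (v - m)
}

#' Threshold a mean-intensity map to remove background
#'
#' Pixels with mean intensity above the threshold are retained. The default
#' method picks the threshold by Otsu's criterion on the intensity
#' histogram; "absolute" uses a user-supplied level.
#'
#' @param meanMap numeric matrix of mean intensities.
#' @param method "otsu" (default) or "absolute".
#' @param level required threshold for \code{method = "absolute"}.
#' @return logical matrix. When the map has no contrast the mask is empty
#'   and a warning is raised.
#' @export
thresholdMask <- function(meanMap, method = c("otsu", "absolute"),
                          level = NULL) {
  method <- match.arg(method)
  m <- meanMap
  m[!is.finite(m)] <- min(m[is.finite(m)])
  if (method == "absolute") {
    if (is.null(level)) stop("'level' is required for method = \"absolute\"")
    return(meanMap > level & is.finite(meanMap))
  }
  rng <- range(m)
  if (diff(rng) <= 0) {
    warning("intensity map has no contrast; empty mask")
    return(matrix(FALSE, nrow(m), ncol(m)))
  }
  scaled <- (m - rng[1]) / diff(rng)
  th <- EBImage::otsu(scaled, range = c(0, 1))
  meanMap > (rng[1] + th * diff(rng)) & is.finite(meanMap)
}

#' Apply an exclusion mask
#'
#' Removes the excluded pixels from a selection mask (set difference), the
#' programmatic stand-in for manual removal of out-of-focus pixels, mobile
#' structures and internalized vesicles.
#'
#' @param mask logical selection matrix.
#' @param exclusionMask logical matrix of pixels to drop (same geometry).
#' @return logical matrix.
#' @export
applyExclusions <- function(mask, exclusionMask) {
  if (!identical(dim(mask), dim(exclusionMask)))
    stop("mask geometries differ")
  mask & !exclusionMask
}
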