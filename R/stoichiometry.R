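#' Histogram of molecular brightness over an ROI
#'
#' Bins the valid (optionally masked) brightness values of one cell into
#' fixed-width bins. Negative values are included; they carry real
#' information about the shot-noise-limited pixels and matter for the
#' Gaussian peak fit.
#'
#' @param x an \linkS4class{NBMaps} or a numeric vector of brightness values.
#' @param mask optional logical matrix (for maps input).
#' @param binWidth bin width in counts/dwell/molecule; default epsilon0/12
#'   of the calibration.
#' @param calibration \linkS4class{CalibrationReference} used for the default
#'   bin width and for recording expression (optional).
#' @param minPixels minimum number of values required (default 200).
#' @param roiId text identifier stored in the histogram.
#' @param expression expression level of the ROI in subunits per effective
#'   volume; computed from the maps when a calibration and mask are given.
#' @return A \linkS4class{BrightnessHistogram}.
#' @export
roiBrightnessHistogram <- function(x, mask = NULL, binWidth = NULL,
                                   calibration = CalibrationReference(),
                                   minPixels = 200, roiId = "",
                                   expression = NA_real_) {
  if (is(x, "NBMaps")) {
    sel <- x@validMask
    if (!is.null(mask)) sel <- sel & mask
    vals <- x@brightnessMap[sel]
    if (is.na(expression) && !is.null(calibration))
      expression <- tryCatch(expressionLevel(x, sel, calibration),
                             error = function(e) NA_real_)
  } else {
    vals <- as.numeric(x)
    vals <- vals[is.finite(vals)]
  }
  if (length(vals) < minPixels)
    stop(sprintf("only %d valid pixels (minimum %d)", length(vals),
                 minPixels))
  if (is.null(binWidth)) binWidth <- calibration@epsilon0 / 12
  edges <- seq(floor(min(vals) / binWidth) * binWidth,
               max(vals) + binWidth, by = binWidth)
  h <- graphics::hist(vals, breaks = edges, plot = FALSE)
  new("BrightnessHistogram", binEdges = h$breaks,
      counts = as.numeric(h$counts), density = FALSE,
      nPixels = length(vals), roiId = roiId,
      expression = as.numeric(expression))
}

#' @rdname accessors
#' @export
setMethod("binCenters", "BrightnessHistogram", function(x)
  (x@binEdges[-1] + x@binEdges[-length(x@binEdges)]) / 2)

#' @rdname accessors
#' @export
setMethod("binCounts", "BrightnessHistogram", function(x) x@counts)

#' Gaussian fit of a brightness histogram
#'
#' Nonlinear least squares of \eqn{A \exp(-(x-\mu)^2/2\sigma^2)} over the
#' full histogram, initialised at the modal bin (centre and height) with a
#' robust SD (IQR/1.349). The fitted centre \eqn{\mu} is the average
#' molecular brightness of the major receptor population in the ROI. On
#' optimiser failure the modal bin centre is returned with a warning and
#' \code{converged = FALSE}.
#'
#' @param hist a \linkS4class{BrightnessHistogram}.
#' @param calibration optional \linkS4class{CalibrationReference}; when
#'   given, the fit also records \code{peakBrightness/epsilon0} as subunits
#'   per complex.
#' @return A \linkS4class{GaussianPeakFit}.
#' @export
fitGaussianPeak <- function(hist, calibration = NULL) {
  stopifnot(is(hist, "BrightnessHistogram"))
  x <- binCenters(hist); y <- hist@counts
  i0 <- which.max(y)
  # weighted quantiles of the binned values for a robust spread estimate
  cw <- cumsum(y) / sum(y)
  qat <- function(p) x[which(cw >= p)[1]]
  sig0 <- max((qat(0.75) - qat(0.25)) / 1.349, diff(x[1:2]))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(A = y[i0], mu = x[i0], sigma = sig0),
      lower = c(0, min(x), diff(x[1:2]) / 10),
      upper = c(Inf, max(x), diff(range(x))),
      fn = function(p, x, y) y - p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)),
      x = x, y = y,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) {
    warning("Gaussian peak fit did not converge; reporting the modal bin")
    return(new("GaussianPeakFit", peakBrightness = x[i0], width = sig0,
               amplitude = y[i0],
               subunits = if (is.null(calibration)) NA_real_ else
                 x[i0] / calibration@epsilon0,
               fitRMSE = NA_real_, converged = FALSE))
  }
  p <- fit$par
  new("GaussianPeakFit", peakBrightness = unname(p[2]),
      width = unname(p[3]), amplitude = unname(p[1]),
      subunits = if (is.null(calibration)) NA_real_ else
        unname(p[2]) / calibration@epsilon0,
      fitRMSE = sqrt(fit$deviance / length(x)), converged = TRUE)
}

#' @rdname accessors
#' @export
setMethod("peakBrightness", "GaussianPeakFit", function(x) x@peakBrightness)

#' Subunits per complex
#'
#' Ratio of a measured molecular brightness to the monomer reference
#' brightness; the direct stoichiometry readout of sN&B. Summaries report it
#' to two decimals.
#'
#' @param peakBrightness measured brightness (counts/dwell/molecule), or a
#'   \linkS4class{GaussianPeakFit}.
#' @param calibration a \linkS4class{CalibrationReference}.
#' @return numeric: brightness / epsilon0.
#' @examples
#' subunitsPerComplex(0.0798, CalibrationReference())  # 1.66 subunits
#' @export
subunitsPerComplex <- function(peakBrightness,
                               calibration = CalibrationReference()) {
  stopifnot(is(calibration, "CalibrationReference"))
  if (is(peakBrightness, "GaussianPeakFit"))
    peakBrightness <- peakBrightness@peakBrightness
  peakBrightness / calibration@epsilon0
}

#' Expression level of an ROI
#'
#' Median mean-map intensity over the mask divided by the monomer
#' brightness: the number of labeled subunits per effective observation
#' volume.
#'
#' @param x an \linkS4class{NBMaps} or a mean-intensity matrix.
#' @param mask logical matrix (non-empty).
#' @param calibration a \linkS4class{CalibrationReference}.
#' @return numeric, subunits per effective volume.
#' @export
expressionLevel <- function(x, mask = NULL,
                            calibration = CalibrationReference()) {
  m <- if (is(x, "NBMaps")) x@meanMap else x
  if (is.null(mask)) mask <- is.finite(m)
  if (is(x, "NBMaps")) mask <- mask & x@validMask
  if (!any(mask)) stop("empty mask")
  stats::median(m[mask], na.rm = TRUE) / calibration@epsilon0
}

#' Classify an expression level into a regime
#'
#' Cells below the physiological window form sub-dimer complexes with
#' unlabeled endogenous receptors; above it, higher-order oligomers build up
#' with density. Bounds are closed on the left, open on the right:
#' low < bounds[1] <= physiological < bounds[2] <= high.
#'
#' @param expression subunits per effective volume (>= 0).
#' @param bounds numeric length 2, default c(90, 600).
#' @return character: "low", "physiological" or "high" (vectorised).
#' @export
classifyExpressionRegime <- function(expression, bounds = c(90, 600)) {
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2], all(expression >= 0))
  out <- rep("physiological", length(expression))
  out[expression < bounds[1]] <- "low"
  out[expression >= bounds[2]] <- "high"
  out
}

#' Accumulate brightness histograms over an expression window
#'
#' Pools all valid pixel brightness values from the cells whose expression
#' lies in [low, high) and bins them into a unit-area histogram, the input
#' of the oligomeric-species mixture fit.
#'
#' @param cells list of per-cell records; each element needs a numeric
#'   \code{values} vector (pixel brightness) and a scalar \code{expression}.
#'   Accepted-cell results of \code{\link{runCell}} qualify.
#' @param window numeric length 2: expression window, closed-left/open-right.
#' @param binWidth histogram bin width; default epsilon0/12.
#' @param calibration used for the default bin width.
#' @return A \linkS4class{BrightnessHistogram} with unit-area density counts.
#' @export
accumulateHistograms <- function(cells, window = c(90, 600),
                                 binWidth = NULL,
                                 calibration = CalibrationReference()) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  if (is.null(binWidth)) binWidth <- calibration@epsilon0 / 12
  expr <- vapply(cells, function(cl) as.numeric(cl$expression), 0)
  keep <- !is.na(expr) & expr >= window[1] & expr < window[2]
  if (!any(keep)) stop("no cells with expression inside the window")
  vals <- unlist(lapply(cells[keep], function(cl) cl$values),
                 use.names = FALSE)
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("no valid brightness values in the window")
  edges <- seq(floor(min(vals) / binWidth) * binWidth,
               max(vals) + binWidth, by = binWidth)
  h <- graphics::hist(vals, breaks = edges, plot = FALSE)
  dens <- h$counts / (sum(h$counts) * binWidth)
  new("BrightnessHistogram", binEdges = h$breaks, counts = dens,
      density = TRUE, nPixels = length(vals),
      roiId = sprintf("accumulated[%g,%g)", window[1], window[2]),
      expression = NA_real_)
}

#' Scale external intensities to sN&B expression units
#'
#' Rescales per-cell intensities from another modality (e.g. antibody
#' epifluorescence) by the ratio of a reference mean expression (from sN&B)
#' to the reference mean intensity of matched cells. A pure scale change:
#' the coefficient of variation of the input is preserved exactly.
#'
#' @param intensities numeric vector.
#' @param referenceMeanExpression mean expression of the reference cells,
#'   subunits per effective volume.
#' @param referenceMeanIntensity mean intensity of the reference cells in
#'   the external modality (> 0).
#' @return numeric vector in subunits per effective volume.
#' @examples
#' expressionScaleExternal(c(10, 20), 450, 15)  # 300, 600
#' @export
expressionScaleExternal <- function(intensities, referenceMeanExpression,
                                    referenceMeanIntensity) {
  if (!is.finite(referenceMeanIntensity) || referenceMeanIntensity <= 0)
    stop("'referenceMeanIntensity' must be positive")
  intensities * (referenceMeanExpression / referenceMeanIntensity)
}
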