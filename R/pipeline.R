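#' Configuration for an end-to-end sN&B run
#'
#' Bundles the parameters of the per-cell and cohort analyses. The defaults
#' are the quantitative-stoichiometry settings discussed in the vignette:
#' unbiased ("sample") variance divisor and 9 x 9 moment pooling, a
#' [90, 600) subunits/V_eff physiological expression window, 10\%
#' photobleaching ceiling, Otsu background thresholding and epsilon0/12
#' brightness bins.
#'
#' @param calibration a \linkS4class{CalibrationReference}.
#' @param window physiological expression window, subunits per effective
#'   volume, closed-left/open-right.
#' @param qcThreshold photobleach rejection threshold.
#' @param thresholdMethod "otsu" or "absolute".
#' @param thresholdLevel absolute threshold level, used only with
#'   \code{thresholdMethod = "absolute"}.
#' @param divisor variance divisor, "sample" or "population".
#' @param smooth moment pooling window (odd integer).
#' @param binWidth histogram bin width; NULL = epsilon0/12.
#' @param minPixels minimum valid pixels per cell histogram.
#' @param shapeRange,xModeMax mixture-fit bounds, see
#'   \code{\link{fitLognormalMixture}}.
#' @return A list of class "nbRunConfig".
#' @export
nbRunConfig <- function(calibration = CalibrationReference(),
                        window = c(90, 600), qcThreshold = 0.10,
                        thresholdMethod = "otsu", thresholdLevel = NULL,
                        divisor = "sample", smooth = 9, binWidth = NULL,
                        minPixels = 200, shapeRange = c(0.05, 0.6),
                        xModeMax = 1.0) {
  stopifnot(is(calibration, "CalibrationReference"),
            length(window) == 2L, window[1] < window[2])
  structure(list(calibration = calibration, window = window,
                 qcThreshold = qcThreshold,
                 thresholdMethod = thresholdMethod,
                 thresholdLevel = thresholdLevel, divisor = divisor,
                 smooth = smooth, binWidth = binWidth,
                 minPixels = minPixels, shapeRange = shapeRange,
                 xModeMax = xModeMax),
            class = "nbRunConfig")
}

#' Analyse one cell: QC, maps, histogram, stoichiometry
#'
#' Runs the per-cell pipeline in the standard order: photobleaching QC,
#' background thresholding of the mean map, optional file-supplied pixel
#' exclusions, number & brightness maps, brightness histogram, Gaussian
#' peak fit, expression level and subunits per complex. Rejected cells
#' carry the rejection reason and no stoichiometry fields; they are
#' excluded downstream.
#'
#' @param stack an \linkS4class{ImageStack} or a TIFF path.
#' @param exclusionMask optional logical matrix (or mask file path) of
#'   pixels to remove after thresholding; when absent the threshold mask
#'   alone is used.
#' @param config an \code{\link{nbRunConfig}}.
#' @param roiId identifier for the record.
#' @return list with \code{record} (one-row data.frame: roi_id, accepted,
#'   reason, photobleach_fraction, n_pixels, expression, regime,
#'   peak_brightness, subunits), plus (for accepted cells) \code{maps},
#'   \code{mask}, \code{histogram}, \code{peakFit}, \code{qc},
#'   \code{values} (pixel brightness, for accumulation) and
#'   \code{expression}.
#' @export
runCell <- function(stack, exclusionMask = NULL, config = nbRunConfig(),
                    roiId = "cell") {
  if (is.character(stack)) stack <- readStack(stack)
  if (is.character(exclusionMask)) exclusionMask <- readMask(exclusionMask)
  stopifnot(is(stack, "ImageStack"), inherits(config, "nbRunConfig"))
  qc <- photobleachFraction(stack, threshold = config$qcThreshold)
  rec <- data.frame(roi_id = roiId, accepted = qc@accepted,
                    reason = qc@reason,
                    photobleach_fraction = qc@photobleachFraction,
                    n_pixels = NA_integer_, expression = NA_real_,
                    regime = NA_character_, peak_brightness = NA_real_,
                    subunits = NA_real_, stringsAsFactors = FALSE)
  if (!qc@accepted)
    return(list(record = rec, qc = qc, expression = NA_real_))
  maps <- computeNBMaps(stack, divisor = config$divisor,
                        smooth = config$smooth)
  mask <- thresholdMask(maps@meanMap, config$thresholdMethod,
                        config$thresholdLevel)
  if (!is.null(exclusionMask)) mask <- applyExclusions(mask, exclusionMask)
  mask <- mask & maps@validMask
  if (!any(mask)) {
    rec$accepted <- FALSE
    rec$reason <- "no pixels left after thresholding/exclusion"
    return(list(record = rec, qc = qc, expression = NA_real_))
  }
  expr <- expressionLevel(maps, mask, config$calibration)
  hist <- roiBrightnessHistogram(maps, mask, binWidth = config$binWidth,
                                 calibration = config$calibration,
                                 minPixels = config$minPixels,
                                 roiId = roiId, expression = expr)
  fit <- fitGaussianPeak(hist, config$calibration)
  rec$n_pixels <- hist@nPixels
  rec$expression <- expr
  rec$regime <- classifyExpressionRegime(expr, config$window)
  rec$peak_brightness <- fit@peakBrightness
  rec$subunits <- fit@subunits
  list(record = rec, maps = maps, mask = mask, histogram = hist,
       peakFit = fit, qc = qc,
       values = maps@brightnessMap[mask & maps@validMask],
       expression = expr)
}

#' Analyse a cohort of cells: accumulated histogram and species fractions
#'
#' Pools the accepted cells whose expression falls in the configured
#' window, accumulates their brightness values into a unit-area histogram
#' and decomposes it into dimer/tetramer/larger fractions with the
#' constrained log-normal mixture. Results are deterministic given the
#' inputs and do not depend on the order of the cells.
#'
#' @param cells list of \code{\link{runCell}} results.
#' @param config an \code{\link{nbRunConfig}}.
#' @param monomer monomer anchor: a \linkS4class{LogNormalComponent} from
#'   \code{\link{fitMonomerReference}} on a calibration histogram, or NULL
#'   to anchor at the calibration's epsilon0.
#' @return list with \code{perCell} (data.frame over all cells),
#'   \code{histogram}, \code{mixture} (\linkS4class{MixtureFit}),
#'   \code{fractions} and \code{window}.
#' @export
runCohort <- function(cells, config = nbRunConfig(), monomer = NULL) {
  stopifnot(length(cells) >= 1L, inherits(config, "nbRunConfig"))
  perCell <- do.call(rbind, lapply(cells, function(cl) cl$record))
  perCell <- perCell[order(perCell$roi_id), , drop = FALSE]
  rownames(perCell) <- NULL
  acc <- Filter(function(cl) isTRUE(cl$record$accepted), cells)
  if (!length(acc)) stop("no accepted cells in the cohort")
  hist <- accumulateHistograms(acc, window = config$window,
                               binWidth = config$binWidth,
                               calibration = config$calibration)
  anchor <- if (is.null(monomer)) config$calibration@epsilon0 else monomer
  inWin <- sum(vapply(acc, function(cl)
    !is.na(cl$expression) && cl$expression >= config$window[1] &&
      cl$expression < config$window[2], TRUE))
  mix <- fitLognormalMixture(hist, anchor, shapeRange = config$shapeRange,
                             xModeMax = config$xModeMax,
                             expressionWindow = config$window,
                             nCells = inWin)
  list(perCell = perCell, histogram = hist, mixture = mix,
       fractions = speciesFractions(mix), window = config$window)
}

#' Write cohort results as CSV files
#'
#' Per-cell records and mixture component parameters, written as plain CSV
#' into a directory.
#'
#' @param cohort result of \code{\link{runCohort}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCohortResults <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "per_cell.csv")
  utils::write.csv(cohort$perCell, p1, row.names = FALSE)
  comps <- do.call(rbind, lapply(cohort$mixture@components, function(cc)
    data.frame(role = cc@role, mode = cc@mode, shape = cc@shape,
               amplitude = cc@amplitude, area = cc@area,
               mode_fixed = cc@modeFixed,
               fraction = unname(cohort$fractions[cc@role]))))
  p2 <- file.path(dir, "mixture_components.csv")
  utils::write.csv(comps, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
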