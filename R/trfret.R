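#' Shading (flat-field) correction of an epifluorescence image
#'
#' Divides the image by a smooth background estimate obtained by grayscale
#' morphological opening with a disc (the rolling-ball background), then
#' rescales so the image mean is preserved. A flat image is returned
#' unchanged; a ball radius much larger than the image makes the correction
#' a no-op.
#'
#' @param image numeric matrix.
#' @param ballRadius structuring disc radius in pixels (default 50).
#' @return corrected numeric matrix.
#' @export
shadingCorrect <- function(image, ballRadius = 50) {
  if (ballRadius < 1) stop("'ballRadius' must be >= 1")
  b <- 2 * floor(ballRadius) + 1
  if (b >= min(dim(image))) {
    bg <- matrix(min(image), nrow(image), ncol(image))
  } else {
    # grayscale morphology in EBImage operates on [0, 1]; rescale around it
    lo <- min(image, 0); hi <- max(image)
    if (hi <= lo) return(image)
    scaled <- (image - lo) / (hi - lo)
    bg <- EBImage::opening(scaled,
                           EBImage::makeBrush(b, shape = "disc"))
    bg <- bg * (hi - lo) + lo
  }
  if (any(bg <= 0)) {
    warning("non-positive background estimate; clamping")
    floorVal <- min(bg[bg > 0], max(image) * 1e-6)
    bg[bg <= 0] <- floorVal
  }
  image / bg * mean(bg)
}

#' Select labeled cells by thresholding the donor image
#'
#' Shares the thresholding contract of \code{\link{thresholdMask}} (Otsu by
#' default) and applies an optional exclusion mask for manual refinement.
#'
#' @param donorImage numeric matrix.
#' @param method,level see \code{\link{thresholdMask}}.
#' @param exclusionMask optional logical matrix of pixels to drop.
#' @return logical matrix.
#' @export
donorThresholdMask <- function(donorImage, method = c("otsu", "absolute"),
                               level = NULL, exclusionMask = NULL) {
  m <- thresholdMask(donorImage, method, level)
  if (!is.null(exclusionMask)) m <- applyExclusions(m, exclusionMask)
  m
}

#' Quantify a TR-FRET image set over a cell mask
#'
#' Background-subtracted mean donor intensity, and mean TR-FRET intensity
#' corrected for donor bleedthrough:
#' \deqn{\bar D = \langle donor\rangle_{mask} - B_D}
#' \deqn{TRFRET_{corr} = (\langle fret\rangle_{mask} - B_F) - b \bar D}
#' with b the bleedthrough fraction (default 6\%). The correction is affine
#' in each input mean; doubling all images and backgrounds doubles both
#' outputs. A negative corrected donor is flagged with a warning.
#'
#' @param set a \linkS4class{TRFRETImageSet}.
#' @param mask logical matrix (non-empty).
#' @return list with \code{meanDonor} and \code{meanTRFRETCorrected}.
#' @examples
#' s <- TRFRETImageSet(matrix(200, 8, 8), matrix(30, 8, 8))
#' fretQuantify(s, matrix(TRUE, 8, 8))$meanTRFRETCorrected  # 18
#' @export
fretQuantify <- function(set, mask) {
  stopifnot(is(set, "TRFRETImageSet"))
  validObject(set)
  if (!identical(dim(mask), dim(set@donor))) stop("mask geometry mismatch")
  if (!any(mask)) stop("empty mask")
  meanDonor <- mean(set@donor[mask]) - set@backgroundDonor
  if (meanDonor < 0) warning("negative background-corrected donor mean")
  corr <- (mean(set@fret[mask]) - set@backgroundFret) -
    set@bleedthrough * meanDonor
  list(meanDonor = meanDonor, meanTRFRETCorrected = corr)
}
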