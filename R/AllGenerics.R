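#' Accessors for sN&B data containers
#'
#' Standard accessor generics for the classes in this package: photon-count
#' frames and geometry of an \linkS4class{ImageStack}; the per-pixel maps and
#' masks of an \linkS4class{NBMaps}; calibration and fit parameters.
#'
#' @param x an object of the documented classes.
#' @return The slot value; matrices for maps and masks, scalars otherwise.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("dwellTime", function(x) standardGeneric("dwellTime"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("meanMap", function(x) standardGeneric("meanMap"))

#' @rdname accessors
#' @export
setGeneric("varianceMap", function(x) standardGeneric("varianceMap"))

#' Per-pixel molecular brightness
#'
#' For an \linkS4class{NBMaps} object, returns the stored brightness map
#' \eqn{\epsilon = \sigma^2/F - 1}. For an \linkS4class{ImageStack}, computes
#' the maps first (see \code{\link{computeNBMaps}}) and returns the brightness
#' map.
#'
#' @param x an NBMaps or ImageStack.
#' @param ... passed to \code{\link{computeNBMaps}} for stacks.
#' @return numeric matrix; NA on invalid pixels. Negative values are retained.
#' @export
setGeneric("brightnessMap", function(x, ...) standardGeneric("brightnessMap"))

#' Per-pixel particle number
#'
#' For an \linkS4class{NBMaps} object, returns the stored number map
#' \eqn{n = F^2/(\sigma^2 - F)}. For an \linkS4class{ImageStack}, computes the
#' maps first. Pixels whose variance does not exceed the mean have no defined
#' particle number and are NA (see \code{numberValidMask}).
#'
#' @param x an NBMaps or ImageStack.
#' @param ... passed to \code{\link{computeNBMaps}} for stacks.
#' @return numeric matrix; NA where undefined.
#' @export
setGeneric("numberMap", function(x, ...) standardGeneric("numberMap"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("numberValidMask", function(x) standardGeneric("numberValidMask"))

#' @rdname accessors
#' @export
setGeneric("epsilon0", function(x) standardGeneric("epsilon0"))

#' @rdname accessors
#' @export
setGeneric("effectiveVolume", function(x) standardGeneric("effectiveVolume"))

#' @rdname accessors
#' @export
setGeneric("accepted", function(x) standardGeneric("accepted"))

#' @rdname accessors
#' @export
setGeneric("photobleachFraction",
           function(x, ...) standardGeneric("photobleachFraction"))

#' @rdname accessors
#' @export
setGeneric("peakBrightness", function(x) standardGeneric("peakBrightness"))

#' @rdname accessors
#' @export
setGeneric("speciesFractions", function(x) standardGeneric("speciesFractions"))

#' @rdname accessors
#' @export
setGeneric("components", function(x) standardGeneric("components"))

#' @rdname accessors
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname accessors
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))
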