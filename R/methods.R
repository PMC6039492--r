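## Accessor and show methods.

#' @rdname accessors
#' @export
setMethod("frames", "ImageStack", function(x) x@frames)

#' @rdname accessors
#' @export
setMethod("nFrames", "ImageStack", function(x) dim(x@frames)[1])

#' @rdname accessors
#' @export
setMethod("dwellTime", "ImageStack", function(x) x@dwellTime)

#' @rdname accessors
#' @export
setMethod("dwellTime", "NBMaps", function(x) x@dwellTime)

#' @rdname accessors
#' @export
setMethod("pixelSize", "ImageStack", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setMethod("meanMap", "NBMaps", function(x) x@meanMap)

#' @rdname accessors
#' @export
setMethod("varianceMap", "NBMaps", function(x) x@varianceMap)

#' @rdname accessors
#' @export
setMethod("validMask", "NBMaps", function(x) x@validMask)

#' @rdname accessors
#' @export
setMethod("numberValidMask", "NBMaps", function(x) x@numberValidMask)

#' @rdname accessors
#' @export
setMethod("epsilon0", "CalibrationReference", function(x) x@epsilon0)

#' @rdname accessors
#' @export
setMethod("effectiveVolume", "CalibrationReference",
          function(x) x@effectiveVolume)

#' @rdname accessors
#' @export
setMethod("accepted", "QCReport", function(x) x@accepted)

setMethod("dim", "ImageStack", function(x) dim(x@frames))

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "ImageStack: %d frames of %d x %d px (dwell %g us, pixel %g nm)\n",
    d[1], d[2], d[3], object@dwellTime, object@pixelSize))
  cat(sprintf("  counts: mean %.3f, max %d\n", mean(object@frames),
              max(object@frames)))
})

setMethod("show", "NBMaps", function(object) {
  cat(sprintf("NBMaps: %d x %d px (%s divisor, pooling %d)\n",
              nrow(object@meanMap), ncol(object@meanMap), object@divisor,
              object@smooth))
  v <- object@validMask
  cat(sprintf("  %d valid px; ROI brightness %.4f counts/dwell/molecule\n",
              sum(v),
              mean(object@varianceMap[v]) / mean(object@meanMap[v]) - 1))
})

setMethod("show", "QCReport", function(object) {
  fr <- object@photobleachFraction
  cat(sprintf("QCReport: photobleach %s, %s\n",
              if (is.na(fr)) "undefined" else sprintf("%.1f%%", 100 * fr),
              if (object@accepted) "accepted" else
                paste0("REJECTED (", object@reason, ")")))
})

setMethod("show", "MomentPrediction", function(object) {
  cat(sprintf(paste0("MomentPrediction: <F> = %.4f, Var = %.4f, ",
                     "brightness = %.4f, number = %.3f\n"),
              object@meanF, object@varianceF, object@apparentBrightness,
              object@apparentNumber))
})

setMethod("show", "CalibrationReference", function(object) {
  cat(sprintf(
    "CalibrationReference: eps0 = %.4g +/- %.2g counts/%g us/molecule, V_eff = %.3g fL\n",
    object@epsilon0, object@epsilon0SEM, object@dwellTime,
    object@effectiveVolume))
})

setMethod("show", "BrightnessHistogram", function(object) {
  cat(sprintf("BrightnessHistogram '%s': %d px in %d bins [%.3f, %.3f]%s\n",
              object@roiId, object@nPixels, length(object@counts),
              min(object@binEdges), max(object@binEdges),
              if (object@density) " (unit area)" else ""))
})

setMethod("show", "GaussianPeakFit", function(object) {
  cat(sprintf("GaussianPeakFit: peak %.4f (sigma %.4f)%s%s\n",
              object@peakBrightness, object@width,
              if (is.na(object@subunits)) "" else
                sprintf(", %.2f subunits/complex", object@subunits),
              if (object@converged) "" else " [fallback: modal bin]"))
})

setMethod("show", "LogNormalComponent", function(object) {
  cat(sprintf("LogNormalComponent (%s): mode %.4f%s, shape %.3f, area %.4g\n",
              object@role, object@mode,
              if (object@modeFixed) " [fixed]" else "", object@shape,
              object@area))
})

setMethod("show", "MixtureFit", function(object) {
  fr <- object@fractions
  cat(sprintf("MixtureFit (%d cells, window [%g, %g)): D %.2f / T %.2f / X %.2f\n",
              object@nCells, object@expressionWindow[1],
              object@expressionWindow[2], fr["dimer"], fr["tetramer"],
              fr["larger"]))
})

setMethod("show", "ClusterReport", function(object) {
  cat(sprintf("ClusterReport: %d clusters over %d selected px (threshold %.3f)\n",
              object@nClusters, sum(object@selectedMask),
              object@thresholdIntensity))
  if (!is.na(object@inClusterBrightness))
    cat(sprintf("  brightness in %.4f vs matched out %.4f\n",
                object@inClusterBrightness, object@matchedOutBrightness))
})

setMethod("show", "TRFRETImageSet", function(object) {
  cat(sprintf("TRFRETImageSet: %d x %d px, bleedthrough %.1f%%\n",
              nrow(object@donor), ncol(object@donor),
              100 * object@bleedthrough))
})

setMethod("show", "SpeciesSpec", function(object) {
  cat(sprintf("SpeciesSpec '%s': %d subunits, %.3g complexes/volume\n",
              object@label, object@subunits, object@meanComplexes))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d species, %d frames of %d x %d px, seed %d\n",
              length(object@species), object@frames, object@height,
              object@width, object@seed))
  for (sp in object@species) show(sp)
})
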