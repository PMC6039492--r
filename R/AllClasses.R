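#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core data containers for scanning Number & Brightness (sN&B) analysis.
##
## An sN&B experiment repeatedly raster-scans the same field of view; each
## pixel then carries a short photon-count time series whose mean and variance
## report on the number n of diffusing complexes in the observation volume and
## on their molecular brightness epsilon (counts per dwell per complex).
## ---------------------------------------------------------------------------

#' ImageStack: a time-ordered stack of photon-count frames
#'
#' Holds the raw data of one sN&B acquisition: an integer photon-count array
#' with axes (time, row, col), the pixel dwell time and the pixel size.
#'
#' @slot frames numeric 3-D array (time x row x col) of non-negative integer
#'   photon counts per pixel dwell.
#' @slot dwellTime pixel dwell time in microseconds.
#' @slot pixelSize pixel edge length in nanometres.
#' @slot metadata named list of free-form acquisition metadata (seed, source
#'   file, simulation config digest, ...).
#' @exportClass ImageStack
setClass("ImageStack",
  representation(
    frames = "array",
    dwellTime = "numeric",
    pixelSize = "numeric",
    metadata = "list"
  )
)

setValidity("ImageStack", function(object) {
  f <- object@frames
  if (length(dim(f)) != 3L)
    return("'frames' must be a 3-D array (time, row, col)")
  if (dim(f)[1] < 2L)
    return("at least 2 frames are required")
  if (anyNA(f) || any(!is.finite(f)))
    return("photon counts must be finite")
  if (any(f < 0))
    return("photon counts must be non-negative")
  if (max(abs(f - round(f))) > 1e-9)
    return("photon counts must be integer-valued")
  if (length(object@dwellTime) != 1L || object@dwellTime <= 0)
    return("'dwellTime' must be a single positive number")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("'pixelSize' must be a single positive number")
  TRUE
})

#' Construct an ImageStack
#'
#' @param frames 3-D array of photon counts, axes (time, row, col).
#' @param dwellTime pixel dwell time in microseconds (default 40).
#' @param pixelSize pixel size in nanometres (default 156).
#' @param metadata named list of acquisition metadata.
#' @return An \linkS4class{ImageStack}.
#' @examples
#' st <- ImageStack(array(rpois(2 * 4 * 4, 5), c(2, 4, 4)))
#' nFrames(st)
#' @export
ImageStack <- function(frames, dwellTime = 40, pixelSize = 156,
                       metadata = list()) {
  storage.mode(frames) <- "double"
  new("ImageStack", frames = frames, dwellTime = dwellTime,
      pixelSize = pixelSize, metadata = metadata)
}

#' NBMaps: per-pixel number & brightness maps for one acquisition
#'
#' Per-pixel time-mean \eqn{F}, time-variance, particle number
#' \eqn{n = F^2/(\sigma^2 - F)} and molecular brightness
#' \eqn{\epsilon = \sigma^2/F - 1}, plus validity masks. On every pixel where
#' both estimators are defined the algebraic identity
#' \eqn{n \times \epsilon = F} holds exactly.
#'
#' @slot meanMap,varianceMap,numberMap,brightnessMap numeric matrices.
#' @slot validMask logical matrix: pixels where mean > 0 and, when moment
#'   pooling is used, the full pooling window lies inside the frame.
#' @slot numberValidMask logical matrix: subset of \code{validMask} where
#'   variance exceeds the mean so the number estimator is defined.
#' @slot divisor "population" (divisor T) or "sample" (divisor T - 1).
#' @slot smooth odd integer edge length of the boxcar window applied to the
#'   moment maps before forming epsilon and n (1 = per-pixel).
#' @slot dwellTime dwell time in microseconds, carried from the stack.
#' @exportClass NBMaps
setClass("NBMaps",
  representation(
    meanMap = "matrix",
    varianceMap = "matrix",
    numberMap = "matrix",
    brightnessMap = "matrix",
    validMask = "matrix",
    numberValidMask = "matrix",
    divisor = "character",
    smooth = "integer",
    dwellTime = "numeric"
  )
)

setValidity("NBMaps", function(object) {
  dm <- dim(object@meanMap)
  for (s in c("varianceMap", "numberMap", "brightnessMap", "validMask",
              "numberValidMask"))
    if (!identical(dim(slot(object, s)), dm))
      return(sprintf("'%s' does not match the mean map geometry", s))
  if (!object@divisor %in% c("population", "sample"))
    return("'divisor' must be \"population\" or \"sample\"")
  if (any(object@numberValidMask & !object@validMask))
    return("'numberValidMask' must be a subset of 'validMask'")
  TRUE
})

#' QCReport: photobleaching quality control for one stack
#'
#' A straight line is fitted to the frame means; the photobleach fraction is
#' the relative first-to-last decline of the fit. Stacks that bleach by more
#' than the threshold (default 10\%) are rejected from analysis.
#'
#' @slot photobleachFraction relative decline of the fitted frame-mean line,
#'   \code{(fit(0) - fit(T-1))/fit(0)}; NA when the fit is degenerate.
#' @slot accepted TRUE iff the fraction is defined and at most the threshold.
#' @slot threshold rejection threshold (default 0.10).
#' @slot frameMeans per-frame mean intensity used for the fit.
#' @slot reason human-readable reason when rejected.
#' @exportClass QCReport
setClass("QCReport",
  representation(
    photobleachFraction = "numeric",
    accepted = "logical",
    threshold = "numeric",
    frameMeans = "numeric",
    reason = "character"
  )
)

setValidity("QCReport", function(object) {
  fr <- object@photobleachFraction
  if (!is.na(fr) && object@accepted != (fr <= object@threshold))
    return("'accepted' must equal photobleachFraction <= threshold")
  if (is.na(fr) && object@accepted)
    return("a stack with undefined photobleach fraction cannot be accepted")
  TRUE
})

#' SpeciesSpec: one oligomeric species in a simulation
#'
#' @slot subunits integer number of receptor subunits per diffusing complex
#'   (1 = monomer, 2 = dimer, ...).
#' @slot meanComplexes mean number of complexes of this species per effective
#'   observation volume (the per-pixel Poisson mean in the fast tier).
#' @slot label short text tag.
#' @exportClass SpeciesSpec
setClass("SpeciesSpec",
  representation(subunits = "integer", meanComplexes = "numeric",
                 label = "character")
)

setValidity("SpeciesSpec", function(object) {
  if (object@subunits < 1L) return("'subunits' must be >= 1")
  if (object@meanComplexes < 0) return("'meanComplexes' must be >= 0")
  TRUE
})

#' Construct a SpeciesSpec
#'
#' @param subunits subunits per complex (positive integer).
#' @param meanComplexes mean complexes per effective volume (non-negative).
#' @param label text tag, defaults to e.g. "2-mer".
#' @return A \linkS4class{SpeciesSpec}.
#' @examples
#' SpeciesSpec(2, 10)  # dimers, 10 complexes per observation volume
#' @export
SpeciesSpec <- function(subunits, meanComplexes,
                        label = sprintf("%d-mer", as.integer(subunits))) {
  new("SpeciesSpec", subunits = as.integer(subunits),
      meanComplexes = as.numeric(meanComplexes), label = label)
}

#' SimulationConfig: ground truth and geometry for a synthetic acquisition
#'
#' Defaults mirror a two-photon sN&B acquisition: 40 us dwell, 156 nm pixels,
#' 100 frames, monomer brightness 0.048 counts/dwell/molecule, labeling
#' efficiency 1.
#'
#' @slot species list of \linkS4class{SpeciesSpec}.
#' @slot monomerBrightness counts per dwell per fluorophore (epsilon0).
#' @slot labelingEfficiency probability that a subunit carries a fluorophore.
#' @slot backgroundRate uniform background, counts per dwell per pixel.
#' @slot frames,height,width stack geometry.
#' @slot dwellTime microseconds; \code{pixelSize} nanometres.
#' @slot bleachFraction linear photobleaching ramp over the stack: frame t
#'   (0-based) signal is scaled by 1 - bleachFraction * t/(T-1).
#' @slot psfWaist 1/e^2 beam waist in nm (diffusion tier only).
#' @slot diffusionCoefficient um^2/s (diffusion tier only).
#' @slot seed RNG seed; simulations are bit-reproducible given the config.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    species = "list",
    monomerBrightness = "numeric",
    labelingEfficiency = "numeric",
    backgroundRate = "numeric",
    frames = "integer",
    height = "integer",
    width = "integer",
    dwellTime = "numeric",
    pixelSize = "numeric",
    bleachFraction = "numeric",
    psfWaist = "numeric",
    diffusionCoefficient = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  if (!all(vapply(object@species, is, TRUE, class2 = "SpeciesSpec")))
    return("'species' must be a list of SpeciesSpec")
  for (sp in object@species) {
    v <- validObject(sp, test = TRUE)
    if (is.character(v)) return(v)
  }
  if (object@monomerBrightness <= 0) return("'monomerBrightness' must be > 0")
  if (object@labelingEfficiency < 0 || object@labelingEfficiency > 1)
    return("'labelingEfficiency' must be in [0, 1]")
  if (object@backgroundRate < 0) return("'backgroundRate' must be >= 0")
  if (object@frames < 2L) return("at least 2 frames are required")
  if (object@height < 1L || object@width < 1L)
    return("geometry must be positive")
  if (object@dwellTime <= 0 || object@pixelSize <= 0)
    return("geometry must be positive")
  if (object@bleachFraction < 0 || object@bleachFraction >= 1)
    return("'bleachFraction' must be in [0, 1)")
  TRUE
})

#' Construct a SimulationConfig
#'
#' @param species list of \code{\link{SpeciesSpec}} (a single SpeciesSpec is
#'   accepted).
#' @param monomerBrightness epsilon0, counts/dwell/molecule (default 0.048).
#' @param labelingEfficiency label probability per subunit (default 1).
#' @param backgroundRate counts/dwell/pixel (default 0).
#' @param frames,height,width stack geometry (defaults 100, 64, 64).
#' @param dwellTime microseconds (default 40).
#' @param pixelSize nanometres (default 156).
#' @param bleachFraction linear bleach ramp over the stack (default 0).
#' @param psfWaist beam waist, nm (diffusion tier; default 300).
#' @param diffusionCoefficient um^2/s (diffusion tier; default 0.5, a typical
#'   membrane-protein mobility).
#' @param seed integer RNG seed.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- SimulationConfig(SpeciesSpec(2, 10), seed = 7)
#' expectedMoments(cfg)
#' @export
SimulationConfig <- function(species, monomerBrightness = 0.048,
                             labelingEfficiency = 1, backgroundRate = 0,
                             frames = 100, height = 64, width = 64,
                             dwellTime = 40, pixelSize = 156,
                             bleachFraction = 0, psfWaist = 300,
                             diffusionCoefficient = 0.5, seed = 1) {
  if (is(species, "SpeciesSpec")) species <- list(species)
  new("SimulationConfig", species = species,
      monomerBrightness = monomerBrightness,
      labelingEfficiency = labelingEfficiency,
      backgroundRate = backgroundRate,
      frames = as.integer(frames), height = as.integer(height),
      width = as.integer(width), dwellTime = dwellTime,
      pixelSize = pixelSize, bleachFraction = bleachFraction,
      psfWaist = psfWaist, diffusionCoefficient = diffusionCoefficient,
      seed = as.integer(seed))
}

#' MomentPrediction: closed-form moments for a simulated configuration
#'
#' Analytic expectation of the sN&B estimators under the independent-frame
#' model with Poisson complex numbers and binomial labeling (see
#' \code{\link{expectedMoments}}).
#'
#' @slot meanF expected counts/dwell; \code{varianceF} its variance.
#' @slot apparentBrightness expected brightness (variance/mean - 1).
#' @slot apparentNumber expected particle number (meanF/apparentBrightness),
#'   so apparentNumber * apparentBrightness = meanF exactly.
#' @exportClass MomentPrediction
setClass("MomentPrediction",
  representation(meanF = "numeric", varianceF = "numeric",
                 apparentBrightness = "numeric", apparentNumber = "numeric")
)

#' CalibrationReference: monomer brightness calibration
#'
#' Reference brightness of a monomeric fluorophore (e.g. free Alexa488 in
#' viscous solution) in counts per dwell per molecule, and the effective
#' two-photon observation volume. Receptor brightness divided by
#' \code{epsilon0} gives subunits per complex; median ROI intensity divided by
#' \code{epsilon0} gives the expression level in subunits per effective
#' volume.
#'
#' @slot epsilon0 counts/dwell/molecule (> 0).
#' @slot epsilon0SEM standard error of the calibration.
#' @slot effectiveVolume effective observation volume in femtolitres.
#' @slot dwellTime dwell time (us) the calibration refers to.
#' @exportClass CalibrationReference
setClass("CalibrationReference",
  representation(epsilon0 = "numeric", epsilon0SEM = "numeric",
                 effectiveVolume = "numeric", dwellTime = "numeric")
)

setValidity("CalibrationReference", function(object) {
  if (object@epsilon0 <= 0) return("'epsilon0' must be > 0")
  TRUE
})

#' Construct a CalibrationReference
#'
#' Defaults are the Alexa488 calibration used throughout the package
#' examples: 0.048 +/- 0.001 counts/40 us/molecule, 0.355 fL.
#'
#' @param epsilon0 monomer brightness, counts/dwell/molecule.
#' @param epsilon0SEM its standard error.
#' @param effectiveVolume effective volume, fL.
#' @param dwellTime dwell time, us.
#' @return A \linkS4class{CalibrationReference}.
#' @examples
#' cal <- CalibrationReference()
#' subunitsPerComplex(0.0798, cal)
#' @export
CalibrationReference <- function(epsilon0 = 0.048, epsilon0SEM = 0.001,
                                 effectiveVolume = 0.355, dwellTime = 40) {
  new("CalibrationReference", epsilon0 = epsilon0, epsilon0SEM = epsilon0SEM,
      effectiveVolume = effectiveVolume, dwellTime = dwellTime)
}

#' BrightnessHistogram: histogram of molecular brightness values
#'
#' @slot binEdges strictly increasing bin edges (counts/dwell/molecule).
#' @slot counts per-bin counts, or densities for accumulated (unit-area)
#'   histograms; length(binEdges) - 1.
#' @slot density TRUE when 'counts' is a unit-area density.
#' @slot nPixels number of pixel values binned.
#' @slot roiId text identifier.
#' @slot expression ROI expression level, subunits per effective volume
#'   (NA for pooled histograms).
#' @exportClass BrightnessHistogram
setClass("BrightnessHistogram",
  representation(binEdges = "numeric", counts = "numeric", density = "logical",
                 nPixels = "integer", roiId = "character",
                 expression = "numeric")
)

setValidity("BrightnessHistogram", function(object) {
  if (length(object@binEdges) != length(object@counts) + 1L)
    return("length(binEdges) must equal length(counts) + 1")
  if (any(diff(object@binEdges) <= 0))
    return("'binEdges' must be strictly increasing")
  if (any(object@counts < 0)) return("'counts' must be non-negative")
  TRUE
})

#' GaussianPeakFit: Gaussian fit of a brightness histogram
#'
#' The fitted centre is the average molecular brightness of the major
#' receptor population in the ROI; divided by the monomer reference it gives
#' subunits per complex.
#'
#' @slot peakBrightness fitted Gaussian centre (counts/dwell/molecule).
#' @slot width fitted Gaussian sigma; \code{amplitude} fitted height.
#' @slot subunits peakBrightness/epsilon0 when a calibration was supplied.
#' @slot fitRMSE root-mean-square residual of the fit.
#' @slot converged FALSE when the optimiser failed and the modal bin centre
#'   was reported instead.
#' @exportClass GaussianPeakFit
setClass("GaussianPeakFit",
  representation(peakBrightness = "numeric", width = "numeric",
                 amplitude = "numeric", subunits = "numeric",
                 fitRMSE = "numeric", converged = "logical")
)

setValidity("GaussianPeakFit", function(object) {
  if (!is.na(object@width) && object@width <= 0)
    return("'width' must be > 0")
  TRUE
})

#' LogNormalComponent: one constrained log-normal mixture component
#'
#' Parameterised by its mode m (peak position) and log-space SD sigma:
#' the component curve is
#' \eqn{A \exp(-(\ln x - (\ln m + \sigma^2))^2 / 2\sigma^2) / x} for x > 0,
#' whose total area is \eqn{A \sigma \sqrt{2\pi}} analytically.
#'
#' @slot mode peak position, counts/dwell/molecule.
#' @slot shape log-space SD (> 0); \code{amplitude} A (>= 0).
#' @slot area analytic area under the component.
#' @slot role one of "monomer", "dimer", "tetramer", "larger".
#' @slot modeFixed TRUE when the mode was anchored to a multiple of the
#'   monomer reference mode.
#' @exportClass LogNormalComponent
setClass("LogNormalComponent",
  representation(mode = "numeric", shape = "numeric", amplitude = "numeric",
                 area = "numeric", role = "character", modeFixed = "logical")
)

setValidity("LogNormalComponent", function(object) {
  if (object@shape <= 0) return("'shape' must be > 0")
  if (object@amplitude < 0) return("'amplitude' must be >= 0")
  if (object@area < 0) return("'area' must be >= 0")
  if (!object@role %in% c("monomer", "dimer", "tetramer", "larger"))
    return("unknown component role")
  TRUE
})

#' MixtureFit: constrained log-normal decomposition of a brightness histogram
#'
#' Sum of dimer (mode fixed at 2x the monomer anchor), tetramer (4x) and
#' larger-oligomer (free mode) log-normal components fitted by bounded least
#' squares; species fractions are the normalised component areas.
#'
#' @slot components list of \linkS4class{LogNormalComponent}.
#' @slot fractions named numeric (dimer/tetramer/larger), sums to 1.
#' @slot expressionWindow (low, high) expression window of the pooled cells.
#' @slot nCells number of cells pooled.
#' @slot goodness RMS residual of the fit on the density scale.
#' @slot converged optimiser convergence flag.
#' @exportClass MixtureFit
setClass("MixtureFit",
  representation(components = "list", fractions = "numeric",
                 expressionWindow = "numeric", nCells = "integer",
                 goodness = "numeric", converged = "logical")
)

setValidity("MixtureFit", function(object) {
  if (length(object@fractions) &&
      abs(sum(object@fractions) - 1) > 1e-9)
    return("'fractions' must sum to 1")
  if (length(object@expressionWindow) == 2L &&
      !any(is.na(object@expressionWindow)) &&
      object@expressionWindow[1] >= object@expressionWindow[2])
    return("expression window low must be < high")
  TRUE
})

#' ClusterReport: high-intensity pixel clusters of one cell
#'
#' @slot labelMap integer matrix, 0 outside clusters; components smaller than
#'   the minimum size are part of the selected set but unlabeled.
#' @slot selectedMask logical matrix of all selected top-fraction pixels.
#' @slot nClusters number of labeled clusters.
#' @slot inClusterBrightness,matchedOutBrightness mean brightness inside
#'   clusters and over expression-matched pixels outside (NA until compared).
#' @slot intensityDecileEdges decile edges of the masked mean intensities.
#' @slot thresholdIntensity intensity cutoff that defined the selection.
#' @exportClass ClusterReport
setClass("ClusterReport",
  representation(labelMap = "matrix", selectedMask = "matrix",
                 nClusters = "integer", inClusterBrightness = "numeric",
                 matchedOutBrightness = "numeric",
                 intensityDecileEdges = "numeric",
                 thresholdIntensity = "numeric")
)

setValidity("ClusterReport", function(object) {
  if (object@nClusters < 0L) return("'nClusters' must be >= 0")
  if (any((object@labelMap > 0) & !object@selectedMask))
    return("labeled pixels must lie inside the selected set")
  TRUE
})

#' TRFRETImageSet: one time-resolved FRET acquisition
#'
#' Donor, TR-FRET and (optional) acceptor epifluorescence images of the same
#' field, together with scalar background levels and the donor bleedthrough
#' fraction measured for the setup.
#'
#' @slot donor,fret,acceptor numeric matrices of identical geometry (the
#'   acceptor image may be a 0 x 0 matrix when absent).
#' @slot backgroundDonor,backgroundFret scalar background intensities.
#' @slot bleedthrough fraction of donor intensity leaking into the TR-FRET
#'   channel (default 0.06).
#' @exportClass TRFRETImageSet
setClass("TRFRETImageSet",
  representation(donor = "matrix", fret = "matrix", acceptor = "matrix",
                 backgroundDonor = "numeric", backgroundFret = "numeric",
                 bleedthrough = "numeric")
)

setValidity("TRFRETImageSet", function(object) {
  if (!identical(dim(object@donor), dim(object@fret)))
    return("donor and fret images must have the same geometry")
  if (length(object@acceptor) &&
      !identical(dim(object@acceptor), dim(object@donor)))
    return("acceptor image must match the donor geometry")
  if (object@bleedthrough < 0 || object@bleedthrough >= 1)
    return("'bleedthrough' must be in [0, 1)")
  TRUE
})

#' Construct a TRFRETImageSet
#'
#' @param donor,fret,acceptor images (matrices); acceptor optional.
#' @param backgroundDonor,backgroundFret scalar backgrounds (default 0).
#' @param bleedthrough donor bleedthrough fraction (default 0.06).
#' @return A \linkS4class{TRFRETImageSet}.
#' @examples
#' s <- TRFRETImageSet(matrix(200, 8, 8), matrix(30, 8, 8))
#' fretQuantify(s, matrix(TRUE, 8, 8))
#' @export
TRFRETImageSet <- function(donor, fret, acceptor = NULL,
                           backgroundDonor = 0, backgroundFret = 0,
                           bleedthrough = 0.06) {
  if (is.null(acceptor)) acceptor <- matrix(numeric(0), 0, 0)
  new("TRFRETImageSet", donor = donor, fret = fret, acceptor = acceptor,
      backgroundDonor = backgroundDonor, backgroundFret = backgroundFret,
      bleedthrough = bleedthrough)
}
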