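#' Identify top-intensity pixel clusters
#'
#' Selects the brightest fraction of the masked mean-intensity pixels
#' (default the top decile) using the smallest threshold whose selection
#' reaches the fraction; ties at the threshold are included, so the selected
#' set may slightly exceed the fraction. Connected components of the
#' selection are labeled (8-connectivity by default); components smaller
#' than \code{minSize} remain in the selected set but are not counted as
#' clusters.
#'
#' @param meanMap numeric matrix of mean intensities.
#' @param mask logical matrix of analysable pixels (non-empty).
#' @param fraction top intensity fraction to select, in (0, 1); default 0.10.
#' @param connectivity 4 or 8 (default 8).
#' @param minSize minimum pixels for a labeled cluster (default 4).
#' @return A \linkS4class{ClusterReport}.
#' @export
topIntensityClusters <- function(meanMap, mask, fraction = 0.10,
                                 connectivity = 8, minSize = 4) {
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must be in (0, 1)")
  if (!identical(dim(meanMap), dim(mask))) stop("mask geometry mismatch")
  mask <- mask & is.finite(meanMap)
  if (!any(mask)) stop("empty mask")
  ints <- meanMap[mask]
  n <- length(ints)
  if (diff(range(ints)) == 0) {
    warning("all masked intensities tie; selecting the whole mask")
    th <- ints[1]
  } else {
    k <- ceiling(fraction * n)
    th <- sort(ints, decreasing = TRUE)[k]
  }
  selected <- mask & meanMap >= th
  lab <- labelComponents(selected, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minSize)
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  labKept <- matrix(0L, nrow(lab), ncol(lab))
  labKept[lab > 0L] <- relabel[lab[lab > 0L]]
  new("ClusterReport", labelMap = labKept, selectedMask = selected,
      nClusters = length(keep), inClusterBrightness = NA_real_,
      matchedOutBrightness = NA_real_,
      intensityDecileEdges = unname(stats::quantile(ints, 0:10 / 10)),
      thresholdIntensity = unname(th))
}

#' Compare brightness inside and outside intensity clusters
#'
#' Mean molecular brightness over the cluster pixels versus over
#' expression-matched non-cluster pixels: out-of-cluster pixels are binned
#' by mean-intensity deciles and the comparison uses only the deciles that
#' cluster pixels occupy, so both groups sample similar expression levels.
#' Equal values indicate that clusters are density hot-spots of the same
#' oligomeric species rather than sites of higher-order assembly.
#'
#' @param brightnessMap numeric matrix (from \code{\link{computeNBMaps}}).
#' @param meanMap numeric matrix of mean intensities.
#' @param report a \linkS4class{ClusterReport}.
#' @param mask logical matrix of analysable pixels.
#' @return The report updated with \code{inClusterBrightness} and
#'   \code{matchedOutBrightness}.
#' @export
compareClusterBrightness <- function(brightnessMap, meanMap, report, mask) {
  stopifnot(is(report, "ClusterReport"))
  sel <- report@selectedMask & mask & is.finite(brightnessMap)
  if (!any(sel)) stop("no cluster pixels to compare")
  edges <- report@intensityDecileEdges
  decOf <- function(v) {
    d <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
    pmin(pmax(d, 1L), 10L)
  }
  occupied <- unique(decOf(meanMap[sel]))
  out <- mask & !report@selectedMask & is.finite(brightnessMap)
  out <- out & matrix(decOf(meanMap) %in% occupied, nrow(meanMap))
  if (!any(out)) stop("no expression-matched pixels outside the clusters")
  report@inClusterBrightness <- mean(brightnessMap[sel])
  report@matchedOutBrightness <- mean(brightnessMap[out])
  report
}
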