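#' Write an image stack to a multi-page TIFF
#'
#' Frames are stored as 16-bit unsigned counts, one TIFF page per frame, in
#' time order. The acquisition metadata (dwell time, pixel size, and any
#' entries of the stack's metadata list) is written to a plain-text JSON
#' sidecar at \code{<path>.json}, from which \code{\link{readStack}} restores
#' it; the round trip is lossless.
#'
#' @param stack an \linkS4class{ImageStack} with integer counts < 65536.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @examples
#' st <- ImageStack(array(rpois(2 * 4 * 4, 5), c(2, 4, 4)))
#' f <- tempfile(fileext = ".tif")
#' writeStack(st, f)
#' identical(frames(readStack(f)), frames(st))
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  validObject(stack)
  f <- stack@frames
  if (max(f) > 65535)
    stop("counts exceed the 16-bit range of the TIFF container")
  pages <- lapply(seq_len(dim(f)[1]), function(t) f[t, , , drop = TRUE] / 65535)
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                        compression = "none")
  if (!ok[1]) stop("could not write ", path)
  meta <- c(list(dwellTime = stack@dwellTime, pixelSize = stack@pixelSize),
            stack@metadata)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack from a multi-page TIFF
#'
#' Pages are interpreted as time-ordered frames of integer photon counts.
#' If a \code{<path>.json} metadata sidecar (as written by
#' \code{\link{writeStack}}) is present, dwell time, pixel size and free-form
#' metadata are restored from it; otherwise the defaults of
#' \code{\link{ImageStack}} apply.
#'
#' @param path TIFF path.
#' @param dwellTime,pixelSize used when no metadata sidecar exists.
#' @return An \linkS4class{ImageStack}.
#' @export
readStack <- function(path, dwellTime = 40, pixelSize = 156) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  arr <- array(0, c(length(pages), H, W))
  for (t in seq_along(pages)) arr[t, , ] <- pages[[t]]
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$dwellTime)) dwellTime <- meta$dwellTime
    if (!is.null(meta$pixelSize)) pixelSize <- meta$pixelSize
    meta$dwellTime <- NULL
    meta$pixelSize <- NULL
  }
  ImageStack(arr, dwellTime = dwellTime, pixelSize = pixelSize,
             metadata = meta)
}

#' Read a boolean exclusion mask from a single-page TIFF or PNG
#'
#' Non-zero pixels mark regions to exclude (out-of-focus areas, mobile
#' structures, internalized vesicles), the file-based surrogate for the
#' manual pixel exclusion step of the analysis.
#'
#' @param path TIFF or PNG path.
#' @return logical matrix.
#' @export
readMask <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0
}
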