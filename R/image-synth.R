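# Gaussian-PSF image synthesis and TIFF I/O.

#' Render a fluorescence image series from trajectories
#'
#' Pixel (i, j) of each frame receives
#' `I0 * sum_n exp(-(i - x_n)^2 / (2 sigma^2)) * exp(-(j - y_n)^2 / (2 sigma^2))`
#' with coordinates in pixel units, modeling a microscope PSF centered at the
#' exact sub-pixel particle coordinates. The user-facing `psfRadius` is the
#' e^-2 radius omega0 of the Gaussian PSF, so the Gaussian sigma is
#' omega0 / 2 (sigma in pixels: `omega0 / (2 * pixelSize)`). The PSF support
#' is truncated at 5 sigma (error < 1e-5 of the peak). Pixel (0, 0) samples
#' the PSF at the region origin; x maps to columns and y to rows.
#'
#' @param traj a [TrajectorySet-class].
#' @param psfRadius e^-2 PSF radius omega0 (um).
#' @param pixelSize um per pixel.
#' @param peakIntensity PSF peak intensity I0.
#' @return An [ImageSeries-class] of noiseless frames.
#' @export
renderSeries <- function(traj, psfRadius = 0.28, pixelSize = 0.1,
                         peakIntensity = 1) {
  stopifnot(psfRadius > 0, pixelSize > 0)
  d <- dim(traj@positions)
  nx <- as.integer(round(traj@regionExtent[1] / pixelSize))
  ny <- as.integer(round(traj@regionExtent[2] / pixelSize))
  sigmaPx <- psfRadius / (2 * pixelSize)
  fr <- cpp_render(traj@positions, d[1], d[3], nx, ny, pixelSize,
                   sigmaPx, peakIntensity, 5)
  new("ImageSeries", frames = fr, pixelSize = pixelSize,
      frameTime = traj@frameTime, psfRadius = psfRadius,
      peakIntensity = peakIntensity, noiseParam = 0)
}

#' Add white Gaussian background noise
#'
#' Adds i.i.d. zero-mean Gaussian noise of standard deviation
#' `noiseParam * peakIntensity` to every pixel. The implied signal-to-noise
#' ratio is `1 / noiseParam` (see [snRatio()]): the customary noise parameter
#' 0.2 corresponds to SN = 5.
#'
#' @param series an [ImageSeries-class].
#' @param noiseParam dimensionless noise level (>= 0).
#' @param seed optional integer seed; `NULL` continues the current stream.
#' @return The noisy [ImageSeries-class] (with `noiseParam` recorded).
#' @export
addBackgroundNoise <- function(series, noiseParam, seed = NULL) {
  stopifnot(noiseParam >= 0)
  if (noiseParam == 0) return(series)
  fr <- series@frames
  withSeed(seed, {
    fr <- fr + array(rnorm(length(fr), 0, noiseParam * series@peakIntensity),
                     dim = dim(fr))
  })
  initialize(series, frames = fr, noiseParam = noiseParam)
}

#' Signal-to-noise ratio implied by a noise parameter
#'
#' @param noiseParam background noise parameter (> 0 for a finite SN).
#' @return `1 / noiseParam` (Inf for 0).
#' @examples
#' snRatio(0.2)  # 5
#' @export
snRatio <- function(noiseParam) {
  stopifnot(noiseParam >= 0)
  ifelse(noiseParam == 0, Inf, 1 / noiseParam)
}

#' Crop the central square region
#'
#' Centered crop of `sizePx` pixels per side; for an odd margin the smaller
#' offset goes first (floor rule), e.g. 300 -> 257 leaves 21 pixels before
#' and 22 after. Calibration metadata is preserved.
#'
#' @param series an [ImageSeries-class].
#' @param sizePx crop size in pixels (<= frame dimension).
#' @return The cropped [ImageSeries-class].
#' @export
cropCenter <- function(series, sizePx) {
  d <- dim(series@frames)
  sizePx <- as.integer(sizePx)
  if (sizePx > min(d[1], d[2]) || sizePx < 1L)
    stop("crop size must be between 1 and the frame dimension")
  offR <- (d[1] - sizePx) %/% 2L
  offC <- (d[2] - sizePx) %/% 2L
  initialize(series,
             frames = series@frames[offR + seq_len(sizePx),
                                    offC + seq_len(sizePx), , drop = FALSE])
}

.tiffRangePath <- function(path) paste0(path, ".range")

#' Write / read multi-frame 32-bit float TIFF stacks
#'
#' `writeTiff` stores each frame as a 32-bit float grayscale TIFF page. The
#' installed TIFF writer clamps float samples to \[0, 1\], so intensities are
#' packed affinely into that range; the transform is recorded in a one-line
#' sidecar text file `<path>.range` that `readTiff` undoes when present. The
#' round trip is exact to 32-bit float precision (relative error ~1e-7).
#' TIFF tags are not relied on for calibration: supply `pixelSize` and
#' `frameTime` when reading.
#'
#' @param series an [ImageSeries-class].
#' @param path file path.
#' @return `writeTiff`: the path, invisibly. `readTiff`: an
#'   [ImageSeries-class].
#' @export
writeTiff <- function(series, path) {
  fr <- series@frames
  lo <- min(fr); hi <- max(fr)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(fr)[3]),
                  function(t) (fr[, , t] - lo) / scale)
  tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                    compression = "none", reduce = FALSE),
    error = function(e) ioError(sprintf("cannot write TIFF '%s': %s",
                                        path, conditionMessage(e))))
  writeLines(sprintf("lo=%.17g scale=%.17g", lo, scale),
             .tiffRangePath(path))
  invisible(path)
}

#' @rdname writeTiff
#' @param pixelSize um per pixel of the stored stack.
#' @param frameTime seconds per frame of the stored stack.
#' @param psfRadius optional e^-2 PSF radius metadata (um).
#' @param peakIntensity optional peak-intensity metadata.
#' @export
readTiff <- function(path, pixelSize, frameTime, psfRadius = 0.28,
                     peakIntensity = 1) {
  if (!file.exists(path))
    ioError(sprintf("TIFF file not found: '%s'", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      ioError(sprintf("cannot read TIFF '%s': %s",
                                      path, conditionMessage(e))))
  if (!length(pages)) ioError(sprintf("TIFF '%s' has no frames", path))
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L)
    ioError(sprintf("TIFF '%s' has frames of differing size", path))
  lo <- 0; scale <- 1
  rng <- .tiffRangePath(path)
  if (file.exists(rng)) {
    m <- regmatches(readLines(rng, n = 1L),
                    regexec("lo=([^ ]+) scale=([^ ]+)", readLines(rng, n = 1L)))[[1]]
    if (length(m) == 3L) {
      lo <- as.numeric(m[2]); scale <- as.numeric(m[3])
    }
  }
  fr <- array(0, dim = c(dims[[1]], length(pages)))
  for (t in seq_along(pages)) fr[, , t] <- pages[[t]] * scale + lo
  new("ImageSeries", frames = fr, pixelSize = pixelSize,
      frameTime = frameTime, psfRadius = psfRadius,
      peakIntensity = peakIntensity, noiseParam = 0)
}
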