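# k-space temporal correlation of an image time series.
#
# Wavenumber convention: angular, k = 2*pi*f, with f the standard discrete
# frequency in cycles/um. With this convention k^2 spans roughly 0-1000
# um^-2 for 0.1 um pixels and fits are customarily restricted to
# k^2 <= 200 um^-2.

# signed integer frequency indices for an N-point DFT (0, 1, ..., -1)
.fftIndex <- function(n) {
  i <- seq_len(n) - 1L
  ifelse(i <= n %/% 2, i, i - n)
}

#' Spatial Fourier transform of an image series
#'
#' Per-frame 2D discrete Fourier transform; by default the per-frame spatial
#' mean is removed first so the static uniform background does not dominate
#' the DC mode.
#'
#' @param series an [ImageSeries-class] with at least 2 frames.
#' @param subtractMean remove each frame's spatial mean before the FFT.
#' @return A list (class `kicsKSpace`) with the complex mode-by-frame matrix
#'   `kframes`, the frame dimension `dim`, per-mode `k2` values (um^-2),
#'   integer ring indices `ring`, and calibration.
#' @export
spatialTransform <- function(series, subtractMean = TRUE) {
  d <- dim(series@frames)
  if (d[3] < 2L) stop("need at least 2 frames")
  ny <- d[1]; nx <- d[2]
  K <- matrix(0i, nx * ny, d[3])
  for (t in seq_len(d[3])) {
    fr <- series@frames[, , t]
    if (subtractMean) fr <- fr - mean(fr)
    K[, t] <- as.vector(fft(fr))
  }
  fy <- .fftIndex(ny) / (ny * series@pixelSize)
  fx <- .fftIndex(nx) / (nx * series@pixelSize)
  k2 <- as.vector(outer((2 * pi * fy)^2, (2 * pi * fx)^2, `+`))
  ring <- as.vector(round(sqrt(outer(.fftIndex(ny)^2, .fftIndex(nx)^2, `+`))))
  structure(list(kframes = K, dim = c(ny, nx), k2 = k2, ring = ring,
                 pixelSize = series@pixelSize, frameTime = series@frameTime,
                 omega0 = series@psfRadius),
            class = "kicsKSpace")
}

#' Temporal correlation of k-space frames
#'
#' For each mode k and lag tau, averages `I(k, t) * Conj(I(k, t + tau))`
#' over all `nFrames - tau` frame pairs. The real part carries the transport
#' information; the imaginary part (zero in expectation for a statistically
#' stationary series) is kept as a diagnostic.
#'
#' @param kspace result of [spatialTransform()].
#' @param maxTau largest lag in frames (must be < number of frames).
#' @return A list (class `kicsRawCF`) with the complex mode-by-lag matrix
#'   `values`, `nPairs`, and the geometry carried over from `kspace`.
#' @export
temporalCorrelation <- function(kspace, maxTau = 100L) {
  K <- kspace$kframes
  nt <- ncol(K)
  maxTau <- as.integer(maxTau)
  if (maxTau >= nt) stop("maxTau must be smaller than the number of frames")
  nPairs <- nt - 0:maxTau
  # linear cross-correlation along time via zero-padded FFT, in mode chunks
  # to bound memory; equivalent to the direct sum over all frame pairs
  L <- stats::nextn(nt + maxTau, c(2, 3, 5))
  G <- matrix(0i, nrow(K), maxTau + 1L)
  chunk <- max(1L, floor(4e6 / L))
  starts <- seq(1L, nrow(K), by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, nrow(K))
    M <- matrix(0i, L, length(idx))
    M[seq_len(nt), ] <- t(K[idx, , drop = FALSE])
    FM <- stats::mvfft(M)
    A <- stats::mvfft(FM * Conj(FM), inverse = TRUE) / L
    # A[tau + 1, m] = sum_t M[t + tau] * Conj(M[t]); our CF is its conjugate
    G[idx, ] <- Conj(t(A[seq_len(maxTau + 1L), , drop = FALSE])) /
      rep(nPairs, each = length(idx))
  }
  structure(list(values = G, nPairs = nPairs, dim = kspace$dim,
                 k2 = kspace$k2, ring = kspace$ring,
                 pixelSize = kspace$pixelSize, frameTime = kspace$frameTime,
                 omega0 = kspace$omega0),
            class = "kicsRawCF")
}

#' Circularly average a raw k-space CF
#'
#' Modes are averaged over annuli one frequency step wide in |k|; the bin
#' center is the mean k^2 of the member modes (not the nominal ring radius),
#' which avoids a small-k bias. The DC mode is excluded, and rings beyond
#' the Nyquist radius are dropped, leaving `floor(N/2)` bins for an N-pixel
#' frame. If the imaginary residue exceeds 5% of the real part a warning is
#' emitted (non-stationarity indicator).
#'
#' @param rawCF result of [temporalCorrelation()].
#' @return A raw (unnormalized) [KICSCorrelation-class].
#' @export
circularAverage <- function(rawCF) {
  nyq <- min(rawCF$dim) %/% 2L
  keep <- rawCF$ring >= 1L & rawCF$ring <= nyq
  ring <- rawCF$ring[keep]
  re <- Re(rawCF$values[keep, , drop = FALSE])
  im <- Im(rawCF$values[keep, , drop = FALSE])
  idx <- factor(ring, levels = seq_len(nyq))
  nper <- as.vector(table(idx))
  vals <- apply(re, 2, function(col) tapply(col, idx, mean))
  imMax <- max(abs(apply(im, 2, function(col) tapply(col, idx, mean))))
  k2c <- as.vector(tapply(rawCF$k2[keep], idx, mean))
  imagRatio <- imMax / max(abs(vals))
  if (is.finite(imagRatio) && imagRatio > 0.05)
    warning(sprintf(
      "imaginary CF residue is %.1f%% of the real part; series may be non-stationary",
      100 * imagRatio))
  new("KICSCorrelation",
      k2Grid = k2c,
      tauGrid = (seq_len(ncol(vals)) - 1L) * rawCF$frameTime,
      values = unname(vals), nPairs = as.integer(rawCF$nPairs),
      normalized = FALSE, mask = rep(FALSE, length(k2c)),
      pixelSize = rawCF$pixelSize,
      omega0Hint = if (is.null(rawCF$omega0)) NA_real_ else rawCF$omega0,
      imagRatio = imagRatio)
}

#' Compute the circularly averaged kICS correlation function
#'
#' Convenience pipeline: [spatialTransform()], [temporalCorrelation()],
#' [circularAverage()]. The result is unnormalized; apply [normalizeCF()]
#' before two-component fitting.
#'
#' @param series an [ImageSeries-class].
#' @param maxTau largest lag in frames.
#' @param subtractMean remove per-frame spatial means before the FFT.
#' @return A raw [KICSCorrelation-class].
#' @export
kicsCorrelation <- function(series, maxTau = 100L, subtractMean = TRUE) {
  circularAverage(temporalCorrelation(spatialTransform(series, subtractMean),
                                      maxTau = maxTau))
}

#' Normalize a CF by its zero-lag row
#'
#' Divides each k^2 bin by its tau = 0 value, so that a single free species
#' decays as `exp(-k^2 D tau)` with the PSF factor cancelled. Bins whose
#' zero-lag power falls below `floorRel` times the maximum are masked rather
#' than divided (they would amplify noise).
#'
#' @param cf a raw [KICSCorrelation-class].
#' @param floorRel relative zero-lag power floor for masking.
#' @return The normalized [KICSCorrelation-class].
#' @export
normalizeCF <- function(cf, floorRel = 1e-8) {
  if (cf@normalized) return(cf)
  r0 <- cf@values[, 1]
  mask <- cf@mask | !(r0 > floorRel * max(r0, na.rm = TRUE))
  vals <- cf@values / r0
  vals[mask, ] <- NA_real_
  initialize(cf, values = vals, normalized = TRUE, mask = mask)
}

#' Tidy table of a correlation function
#'
#' @param cf a [KICSCorrelation-class].
#' @param path optional CSV output path.
#' @return data.frame with `k2`, `tau`, `value`, `n_pairs`, `masked`.
#' @export
cfTable <- function(cf, path = NULL) {
  df <- data.frame(
    k2 = rep(cf@k2Grid, times = length(cf@tauGrid)),
    tau = rep(cf@tauGrid, each = length(cf@k2Grid)),
    value = as.vector(cf@values),
    n_pairs = rep(cf@nPairs, each = length(cf@k2Grid)),
    masked = rep(cf@mask, times = length(cf@tauGrid)))
  if (!is.null(path)) {
    write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
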