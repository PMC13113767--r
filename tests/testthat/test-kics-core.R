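# Spatial FFT, temporal correlation, circular averaging, normalization.

flatSeries <- function(fr, pixelSize = 0.1, frameTime = 1) {
  new("ImageSeries", frames = fr, pixelSize = pixelSize,
      frameTime = frameTime, psfRadius = 0.28, peakIntensity = 1,
      noiseParam = 0)
}

test_that("spatial transform honors the angular-wavenumber convention", {
  # constant frames with mean subtraction -> all-zero transform
  s <- flatSeries(array(3.7, c(16, 16, 3)))
  ks <- spatialTransform(s, subtractMean = TRUE)
  expect_lt(max(Mod(ks$kframes)), 1e-9)

  # 256 px at 0.1 um: lowest nonzero k^2 = (2 pi / 25.6)^2
  s2 <- flatSeries(array(runif(256 * 256 * 2), c(256, 256, 2)))
  ks2 <- spatialTransform(s2)
  expect_equal(min(ks2$k2[ks2$k2 > 0]), (2 * pi / 25.6)^2, tolerance = 1e-12)

  # a centered Gaussian spot transforms to a Gaussian in |k|
  n <- 64
  xy <- seq_len(n) - 1 - n / 2
  spot <- exp(-outer(xy^2, xy^2, `+`) / (2 * 4))
  ks3 <- spatialTransform(flatSeries(array(spot, c(n, n, 2))),
                          subtractMean = FALSE)
  m <- Mod(ks3$kframes[, 1])
  # magnitude depends only on |k| and decays monotonically along the axis
  axis <- m[2:15 * n + 1]  # modes (0, j)
  expect_true(all(diff(axis) < 0))
})

test_that("Parseval holds between image and k space", {
  set.seed(8)
  fr <- array(rnorm(32 * 32 * 4), c(32, 32, 4))
  ks <- spatialTransform(flatSeries(fr), subtractMean = TRUE)
  for (t in 1:4) {
    x <- fr[, , t] - mean(fr[, , t])
    expect_equal(sum(Mod(ks$kframes[, t])^2), 32^2 * sum(x^2),
                 tolerance = 1e-9)
  }
})

test_that("temporal correlation matches the direct pair average", {
  set.seed(2)
  fr <- array(runif(16 * 16 * 12), c(16, 16, 12))
  ks <- spatialTransform(flatSeries(fr))
  tc <- temporalCorrelation(ks, maxTau = 5L)
  K <- ks$kframes
  nt <- ncol(K)
  direct <- sapply(0:5, function(tau)
    rowMeans(K[, 1:(nt - tau), drop = FALSE] *
             Conj(K[, tau + 1:(nt - tau), drop = FALSE])))
  expect_equal(tc$values, direct, tolerance = 1e-10)
  expect_identical(tc$nPairs, c(12:7))
  # power spectrum at tau = 0 is nonnegative
  expect_gte(min(Re(tc$values[, 1])), 0)
  expect_error(temporalCorrelation(ks, maxTau = 12L))
})

test_that("a static image gives a lag-independent correlation", {
  fr0 <- matrix(runif(24 * 24), 24, 24)
  fr <- array(fr0, c(24, 24, 8))
  cf <- kicsCorrelation(flatSeries(fr), maxTau = 4L, subtractMean = FALSE)
  for (j in 2:5) expect_equal(cf@values[, j], cf@values[, 1],
                              tolerance = 1e-10)
})

test_that("circular averaging uses Nyquist rings with mean-k^2 centers", {
  set.seed(3)
  fr <- array(runif(256 * 256 * 2), c(256, 256, 2))
  cf <- kicsCorrelation(flatSeries(fr), maxTau = 1L)
  expect_identical(length(cf@k2Grid), 128L)
  expect_true(all(diff(cf@k2Grid) > 0))
  # a radially symmetric k-space profile is reproduced exactly:
  # build a raw CF whose value is a function of the ring index
  s <- flatSeries(array(runif(32 * 32 * 3), c(32, 32, 3)))
  ks <- spatialTransform(s)
  tc <- temporalCorrelation(ks, maxTau = 1L)
  ring <- ks$ring
  tc$values[, 1] <- complex(real = exp(-0.1 * ring), imaginary = 0)
  tc$values[, 2] <- complex(real = 0.5 * exp(-0.1 * ring), imaginary = 0)
  cf2 <- circularAverage(tc)
  expect_equal(cf2@values[, 1], exp(-0.1 * seq_len(16)), tolerance = 1e-12)
  expect_equal(cf2@values[, 2], 0.5 * exp(-0.1 * seq_len(16)),
               tolerance = 1e-12)
})

test_that("an anisotropic cos^2-modulated CF averages to its isotropic part", {
  s <- flatSeries(array(runif(64 * 64 * 2), c(64, 64, 2)))
  ks <- spatialTransform(s)
  tc <- temporalCorrelation(ks, maxTau = 1L)
  fy <- ckics:::.fftIndex(64)
  fx <- ckics:::.fftIndex(64)
  ij <- expand.grid(fy = fy, fx = fx)
  theta <- atan2(ij$fy, ij$fx)
  base <- exp(-0.05 * ks$ring)
  # cos(2 theta) modulation has zero angular mean on every full ring
  tc$values[, 1] <- complex(real = base * (1 + 0.5 * cos(2 * theta)))
  cf <- circularAverage(tc)
  iso <- exp(-0.05 * seq_len(32))
  # rings are discrete so the angular cancellation is approximate at small m
  expect_lt(max(abs(cf@values[6:32, 1] - iso[6:32]) / iso[6:32]), 0.05)
})

test_that("normalization yields ones at zero lag and masks dead bins", {
  free <- freeRun()
  ncf <- normalizeCF(free$cf)
  expect_true(ncf@normalized)
  expect_true(all(ncf@values[!ncf@mask, 1] == 1))
  # single-species normalized CF decays like exp(-k^2 D tau)
  k2 <- ncf@k2Grid
  sel <- !ncf@mask & k2 < 60
  pred <- exp(-k2[sel] * 0.01 * 2 * 0.4)  # lag 2, D_out, 0.4 s frames
  expect_lt(median(abs(ncf@values[sel, 3] - pred)), 0.05)
  # masking: a bin with zero tau = 0 power is flagged, not divided
  cf2 <- free$cf
  cf2@values[5, ] <- 0
  ncf2 <- normalizeCF(cf2)
  expect_true(ncf2@mask[5])
  expect_true(all(is.na(ncf2@values[5, ])))
})

test_that("white noise adds a zero-lag pedestal but leaves tau > 0 unbiased", {
  free <- freeRun()
  noisy <- addBackgroundNoise(free$series, 0.2, seed = 99)
  cfN <- kicsCorrelation(noisy, maxTau = 5L)
  cf0 <- free$cf
  # tau = 0: noise raises the power spectrum
  expect_gt(mean(cfN@values[, 1] - cf0@values[, 1]), 0)
  # tau >= 1: agreement within sampling error (a few % of the tau = 0 power)
  for (j in 2:6) {
    rel <- abs(cfN@values[, j] - cf0@values[, j]) / cf0@values[, 1]
    expect_lt(median(rel), 0.05)
  }
})

test_that("correlation tables round-trip through CSV", {
  free <- freeRun()
  path <- withr::local_tempfile(fileext = ".csv")
  df <- cfTable(normalizeCF(free$cf), path)
  back <- read.csv(path)
  expect_equal(nrow(back), length(free$cf@k2Grid) * length(free$cf@tauGrid))
  expect_equal(back$value, df$value)
})
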