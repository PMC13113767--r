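# PSF rendering, background noise, cropping and TIFF round-trips.

makeTraj <- function(pos, nt = 1L, extent = c(6.4, 6.4), frameTime = 1) {
  np <- nrow(pos)
  arr <- array(0, c(np, 2, nt))
  for (t in seq_len(nt)) arr[, , t] <- pos
  new("TrajectorySet", positions = arr,
      insideFlags = matrix(FALSE, np, nt),
      frameTime = frameTime, regionExtent = extent)
}

test_that("rendering reproduces the Gaussian PSF model", {
  # no particles -> zero frames
  t0 <- makeTraj(matrix(numeric(0), 0, 2))
  s0 <- renderSeries(t0)
  expect_true(all(frames(s0) == 0))

  # one particle at a pixel center: peak I0 there, 90-degree symmetric
  t1 <- makeTraj(matrix(c(3.2, 3.2), 1, 2))
  s1 <- renderSeries(t1, psfRadius = 0.28, pixelSize = 0.1,
                     peakIntensity = 2.5)
  fr <- frames(s1)[, , 1]
  expect_equal(fr[33, 33], 2.5)
  expect_equal(max(fr), 2.5)
  patch <- fr[33 + (-5:5), 33 + (-5:5)]
  expect_equal(patch, t(patch))
  expect_equal(patch, patch[11:1, 11:1])

  # analytic total intensity: N * I0 * 2 pi sigma_px^2, particles off edges
  set.seed(4)
  pos <- cbind(runif(100, 1.5, 4.9), runif(100, 1.5, 4.9))
  s100 <- renderSeries(makeTraj(pos), psfRadius = 0.28, pixelSize = 0.1)
  sigmaPx <- 0.28 / (2 * 0.1)
  expect_lt(abs(sum(frames(s100)) / (100 * 2 * pi * sigmaPx^2) - 1), 0.01)
})

test_that("rendering is linear in the particle set", {
  set.seed(5)
  posA <- cbind(runif(20, 0, 6.4), runif(20, 0, 6.4))
  posB <- cbind(runif(30, 0, 6.4), runif(30, 0, 6.4))
  sA <- renderSeries(makeTraj(posA))
  sB <- renderSeries(makeTraj(posB))
  sAB <- renderSeries(makeTraj(rbind(posA, posB)))
  expect_equal(frames(sAB), frames(sA) + frames(sB), tolerance = 1e-12)
})

test_that("background noise has the set moments and is white", {
  t1 <- makeTraj(matrix(c(3.2, 3.2), 1, 2), nt = 50L)
  clean <- renderSeries(t1)
  expect_identical(addBackgroundNoise(clean, 0), clean)

  noisy <- addBackgroundNoise(clean, 0.1, seed = 7)
  resid <- frames(noisy) - frames(clean)
  expect_lt(abs(mean(resid)), 0.01)
  expect_lt(abs(sd(resid) / 0.1 - 1), 0.02)
  # spatial whiteness: lag-1 autocorrelation consistent with zero
  r <- as.vector(resid[, , 1])
  n <- length(r)
  lag1 <- cor(as.vector(resid[-1, , 1]), as.vector(resid[-64, , 1]))
  expect_lt(abs(lag1), 3 / sqrt(n))
  # reproducible by seed
  noisy2 <- addBackgroundNoise(clean, 0.1, seed = 7)
  expect_identical(frames(noisy), frames(noisy2))
})

test_that("noise parameter 0.2 implies a signal-to-noise ratio of 5", {
  expect_identical(snRatio(0.2), 5)
  expect_identical(snRatio(0), Inf)
})

test_that("central cropping follows the floor rule", {
  t1 <- makeTraj(matrix(c(1, 2), 1, 2), extent = c(30, 30))
  s <- renderSeries(t1)  # 300 x 300
  expect_identical(dim(frames(cropCenter(s, 300)))[1:2], c(300L, 300L))
  expect_equal(frames(cropCenter(s, 300)), frames(s))
  c256 <- cropCenter(s, 256)
  expect_equal(frames(c256)[1, 1, 1], frames(s)[23, 23, 1])
  c257 <- cropCenter(s, 257)
  expect_equal(frames(c257)[1, 1, 1], frames(s)[22, 22, 1])
  expect_identical(pixelSize(c256), pixelSize(s))
  expect_error(cropCenter(s, 301))
})

test_that("TIFF stacks round-trip at 32-bit float precision", {
  t1 <- makeTraj(matrix(runif(20, 0, 6), 10, 2), nt = 10L)
  s <- addBackgroundNoise(renderSeries(t1, peakIntensity = 3), 0.2, seed = 1)
  path <- withr::local_tempfile(fileext = ".tif")
  writeTiff(s, path)
  back <- readTiff(path, pixelSize = pixelSize(s), frameTime = frameTime(s))
  expect_identical(dim(frames(back)), dim(frames(s)))
  span <- diff(range(frames(s)))
  expect_lt(max(abs(frames(back) - frames(s))), 1e-6 * span)
  # a second round trip stays at float precision (no error accumulation)
  path2 <- withr::local_tempfile(fileext = ".tif")
  writeTiff(back, path2)
  back2 <- readTiff(path2, pixelSize = pixelSize(s), frameTime = frameTime(s))
  expect_lt(max(abs(frames(back2) - frames(back))), 1e-6 * span)
  expect_error(readTiff(withr::local_tempfile(fileext = ".tif"),
                        0.1, 1), class = "IOError")
})
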