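# Single-species, two-component and two-free-species fitting.

test_that("single-species fit inverts the exact closed-form CF", {
  k2 <- seq(0.5, 50, length.out = 40)
  tau <- seq(0, 10)
  vals <- exp(-outer(k2, 0.01 * tau + 0.04))
  cf <- syntheticCF(k2, tau, vals)
  fs <- fitSingleSpecies(cf)
  expect_equal(fs$D, 0.01, tolerance = 1e-8)
  expect_equal(fs$omega0, 0.4, tolerance = 1e-8)
  # static particles: D = 0
  vals0 <- exp(-outer(k2, rep(0.04, length(tau))))
  fs0 <- fitSingleSpecies(syntheticCF(k2, tau, vals0))
  expect_lt(abs(fs0$D), 1e-10)
  expect_error(fitSingleSpecies(cf, tauLags = 1:2), class = "FitError")
})

test_that("free-diffusion simulation recovers D and the PSF radius", {
  free <- freeRun()
  fs <- fitSingleSpecies(free$cf, tauLags = 1:10)
  expect_lt(abs(fs$D / 0.01 - 1), 0.1)
  expect_lt(abs(fs$omega0 / 0.28 - 1), 0.1)
})

test_that("two-component fit inverts exact two-Gaussian data to 4+ digits", {
  k2 <- seq(0.5, 150, length.out = 60)
  tau <- seq(0, 20)
  vals <- sapply(tau, function(t)
    0.5 * exp(-k2 * 0.1) + 0.5 * exp(-k2 * 0.01))
  vals[, 1] <- 1  # tau = 0 row of a normalized CF
  cf <- syntheticCF(k2, tau, vals, normalized = TRUE)
  fit <- fitTwoComponent(cf)
  conv <- fit@converged
  expect_true(all(conv))
  expect_true(all(fit@separated))
  expect_equal(unname(fit@gM[conv]), rep(0.1, sum(conv)), tolerance = 1e-4)
  expect_equal(unname(fit@gMu[conv]), rep(0.01, sum(conv)), tolerance = 1e-4)
  expect_equal(unname(fit@aM[conv]), rep(0.5, sum(conv)), tolerance = 1e-4)
  expect_equal(unname(fit@aMu[conv]), rep(0.5, sum(conv)), tolerance = 1e-4)
  # labeling invariant
  expect_true(all(fit@gM[conv] >= fit@gMu[conv]))
})

test_that("two free species produce exponents linear in lag", {
  k2 <- seq(0.5, 120, length.out = 50)
  tau <- seq(0, 15)
  vals <- sapply(tau, function(t)
    0.6 * exp(-k2 * 0.05 * t) + 0.4 * exp(-k2 * 0.005 * t))
  vals[, 1] <- 1
  cf <- syntheticCF(k2, as.numeric(tau), vals, normalized = TRUE)
  fit <- fitTwoComponent(cf)
  sep <- fit@separated
  expect_gt(sum(sep), 10)
  fM <- lm(fit@gM[sep] ~ fit@tau[sep])
  fMu <- lm(fit@gMu[sep] ~ fit@tau[sep])
  expect_equal(unname(coef(fM)[2]), 0.05, tolerance = 0.01)
  expect_equal(unname(coef(fMu)[2]), 0.005, tolerance = 0.01)
  expect_gt(suppressWarnings(summary(fM))$r.squared, 0.999)
})

test_that("confined simulation: micro exponent saturates, macro keeps growing", {
  conf <- confinedRun()
  fit <- fitTwoComponent(conf$cf)
  sep <- which(fit@separated)
  expect_gt(length(sep), 20)
  half <- sep[sep > stats::median(sep)]
  early <- sep[sep <= stats::median(sep)]
  # macro grows throughout; micro's late increments are an order smaller
  gMuEarlySlope <- coef(lm(fit@gMu[early] ~ fit@tau[early]))[2]
  gMuLateSlope <- coef(lm(fit@gMu[half] ~ fit@tau[half]))[2]
  gMLateSlope <- coef(lm(fit@gM[half] ~ fit@tau[half]))[2]
  expect_gt(gMLateSlope, 10 * gMuLateSlope)
  expect_lt(gMuLateSlope, gMuEarlySlope + 1e-6)
})

test_that("parameter extraction reproduces exact linear exponent tracks", {
  n <- 40L
  tau <- seq_len(n) * 0.5
  fit <- new("TwoComponentFit", tau = tau,
             aM = rep(0.4, n), aMu = rep(0.6, n),
             gM = 0.01 * tau + 0.05, gMu = pmin(0.002 * tau, 0.008),
             seGM = rep(0.001, n), seGMu = rep(0.001, n),
             residual = rep(0.01, n), converged = rep(TRUE, n),
             separated = rep(TRUE, n), k2Range = c(0, 200))
  pars <- extractParameters(fit, earlyWindow = c(1L, 6L),
                            lateWindow = c(31L, 40L))
  expect_equal(pars@dM, 0.01, tolerance = 1e-10)
  expect_equal(pars@dMu, 0.002, tolerance = 1e-10)
  expect_equal(pars@plateauMu, 0.008, tolerance = 1e-10)
  expect_equal(pars@satAM, 0.4, tolerance = 1e-10)
  expect_equal(pars@satAMu, 0.6, tolerance = 1e-10)
  expect_equal(pars@effectiveRadius, 2 * sqrt(0.008), tolerance = 1e-10)
  expect_error(extractParameters(fit, earlyWindow = c(1L, 6L),
                                 lateWindow = c(39L, 45L)),
               class = "WindowError")
})

test_that("confined defaults give D_in < D_M < D_out and a resolved plateau", {
  conf <- confinedRun()
  res <- analyzeImageSeries(conf$series, maxTau = 60L)
  p <- res$parameters
  expect_gt(p@dM, 0.001)
  expect_lt(p@dM, 0.015)
  expect_lt(p@dMu, 0.001)  # micro mobility below D_in
  expect_gt(p@plateauMu, 0.001)
  expect_lt(p@plateauMu, 0.02)
  expect_gt(p@satAMu, p@satAM)  # majority of particles confined at beta ~ 0.46
})

test_that("global two-free-species fit recovers a simulated 50/50 mixture", {
  k2 <- seq(0.5, 120, length.out = 50)
  tau <- seq(0, 15)
  # exact surface first
  vals <- sapply(tau, function(t)
    0.5 * exp(-k2 * 0.1 * t) + 0.5 * exp(-k2 * 0.01 * t))
  vals[, 1] <- 1
  cf <- syntheticCF(k2, as.numeric(tau), vals, normalized = TRUE)
  out <- fitTwoFreeSpecies(cf)
  expect_equal(out$D1, 0.1, tolerance = 1e-6)
  expect_equal(out$D2, 0.01, tolerance = 1e-6)
  expect_equal(out$N1frac, 0.5, tolerance = 1e-6)
  expect_false(out$degenerate)
  # single species input: degenerate fit is detected, not an error
  vals1 <- sapply(tau, function(t) exp(-k2 * 0.05 * t))
  vals1[, 1] <- 1
  out1 <- fitTwoFreeSpecies(syntheticCF(k2, as.numeric(tau), vals1,
                                        normalized = TRUE))
  expect_true(out1$degenerate ||
                min(out1$N1frac, 1 - out1$N1frac) < 0.05)

  # simulated mixture: render two free populations jointly; the periodic
  # uncropped frames avoid boundary-flux decorrelation of the fast species
  cfgA <- simulationConfig(regionPx = 128L, nFrames = 650L,
                           burnInFrames = 50L, areaFraction = 0,
                           DOut = 0.1, frameTime = 0.4,
                           particleDensity = 2.5, seed = 71L)
  cfgB <- initialize(cfgA, DOut = 0.01, seed = 72L)
  runA <- simulateConfinedDiffusion(cfgA)
  runB <- simulateConfinedDiffusion(cfgB)
  serA <- renderSeries(runA$trajectories)
  serB <- renderSeries(runB$trajectories)
  mix <- initialize(serA, frames = frames(serA) + frames(serB))
  ncf <- normalizeCF(kicsCorrelation(mix, maxTau = 20L))
  rec <- fitTwoFreeSpecies(ncf, k2Range = c(0, 80))
  expect_lt(abs(rec$D1 / 0.1 - 1), 0.15)
  expect_lt(abs(rec$D2 / 0.01 - 1), 0.15)
  expect_lt(abs(rec$N1frac - 0.5), 0.1)
})
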