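# Shared fixtures and independent oracles for the test suite.
# Heavier simulated scenarios are built once per session and memoised.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, builder(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# small free-diffusion run shared by the kICS and fitting tests
freeRun <- function() fixture("freeRun", function() {
  cfg <- simulationConfig(regionPx = 144L, nFrames = 1100L,
                          burnInFrames = 100L, areaFraction = 0,
                          frameTime = 0.4, particleDensity = 5, seed = 11L)
  run <- simulateConfinedDiffusion(cfg)
  series <- cropCenter(renderSeries(run$trajectories), 128L)
  list(config = cfg, run = run, series = series,
       cf = kicsCorrelation(series, maxTau = 30L))
})

# small confined run at the default physical parameters
confinedRun <- function() fixture("confinedRun", function() {
  cfg <- simulationConfig(regionPx = 144L, nFrames = 1100L,
                          burnInFrames = 100L, seed = 5L)
  run <- simulateConfinedDiffusion(cfg)
  series <- cropCenter(renderSeries(run$trajectories), 128L)
  list(config = cfg, run = run, series = series,
       cf = normalizeCF(kicsCorrelation(series, maxTau = 60L)))
})

# independent oracle: inside-a-domain test by direct distance computation
oracleInside <- function(pos, field) {
  ctr <- domainCenters(field)
  r2 <- domainRadius(field)^2
  if (nrow(ctr) == 0L) return(rep(FALSE, nrow(pos)))
  vapply(seq_len(nrow(pos)), function(i) {
    any((ctr[, 1] - pos[i, 1])^2 + (ctr[, 2] - pos[i, 2])^2 < r2)
  }, logical(1))
}

# independent oracle: ensemble MSD by direct double loop over a lag list
oracleMSD <- function(traj, lags) {
  pos <- positions(traj)
  nt <- dim(pos)[3]
  W <- regionExtent(traj)[1]; H <- regionExtent(traj)[2]
  vapply(lags, function(lag) {
    acc <- 0; n <- 0L
    for (t in seq_len(nt - lag)) {
      dx <- pos[, 1, t + lag] - pos[, 1, t]
      dy <- pos[, 2, t + lag] - pos[, 2, t]
      dx <- dx - W * round(dx / W)
      dy <- dy - H * round(dy / H)
      acc <- acc + sum(dx^2 + dy^2)
      n <- n + length(dx)
    }
    acc / n
  }, numeric(1))
}

# build a KICSCorrelation object directly from closed-form values
syntheticCF <- function(k2, tau, values, normalized = FALSE,
                        pixelSize = 0.1) {
  new("KICSCorrelation", k2Grid = k2, tauGrid = tau, values = values,
      nPairs = as.integer(rep(1000L, length(tau))),
      normalized = normalized, mask = rep(FALSE, length(k2)),
      pixelSize = pixelSize, omega0Hint = NA_real_, imagRatio = 0)
}

# --- sweep fixtures shared by the acceptance suite ---------------------------
# Trend sweeps run at a 96 px region (9.6 um, 450 frames) with 8 seeds per
# value and median aggregation; the radius sweep needs room for the largest
# domains and runs at 144 px with the size-adapted auto frame time.

trendBase <- function() readRunConfig(NULL, list(
  simulation = list(region_px = 96L, n_frames = 450L, burn_in_frames = 50L,
                    frame_time = 0.4, seed = 1L),
  analysis = list(max_tau = 60L, crop_px = 80L)))

sweepMedians <- function(sw, by) {
  ok <- sw[sw$ok, ]
  ok$value <- ok[[by]]
  stats::aggregate(
    cbind(D_M, D_mu, plateau_mu, sat_A_M, sat_A_mu, beta_mean) ~ value,
    ok, median, na.action = stats::na.pass, na.rm = TRUE)
}

ratioSweep <- function() fixture("ratioSweep", function() {
  sw <- suppressWarnings(suppressMessages(
    runSweep(trendBase(), "D_in", c(0.01, 0.005, 0.002, 0.001),
             replicates = 8L)))
  agg <- sweepMedians(sw, "D_in")
  agg$ratio <- 0.01 / agg$value
  agg[order(agg$ratio), ]
})

areaSweep <- function() fixture("areaSweep", function() {
  sw <- suppressWarnings(suppressMessages(
    runSweep(trendBase(), "area_fraction", c(0.005, 0.02, 0.035, 0.05),
             replicates = 8L)))
  sweepMedians(sw, "area_fraction")
})

pinSweep <- function() fixture("pinSweep", function() {
  rows <- list()
  # P_out = 1 - P_in; 0.8 is the upper end at which the two-component
  # decomposition still operates reliably at this problem size
  for (pin in c(0.2, 0.4, 0.6, 0.8)) {
    for (rep in 1:8) {
      cfg <- readRunConfig(NULL, list(
        simulation = list(region_px = 96L, n_frames = 450L,
                          burn_in_frames = 50L, frame_time = 0.4,
                          P_in = pin, P_out = 1 - pin,
                          seed = as.integer(1000 + 7919 * rep +
                                              round(100 * pin))),
        analysis = list(max_tau = 60L, crop_px = 80L)))
      r <- suppressWarnings(tryCatch(runScenario(cfg),
                                     error = function(e) NULL))
      if (is.null(r)) next
      rows[[length(rows) + 1L]] <- data.frame(
        value = pin, D_M = r$parameters@dM, D_mu = r$parameters@dMu,
        plateau_mu = r$parameters@plateauMu,
        sat_A_M = r$parameters@satAM, sat_A_mu = r$parameters@satAMu,
        beta_mean = r$beta@betaMean, ok = TRUE)
    }
  }
  sw <- do.call(rbind, rows)
  sweepMedians(sw, "value")
})

radiusSweep <- function() fixture("radiusSweep", function() {
  base <- readRunConfig(NULL, list(
    simulation = list(region_px = 144L, n_frames = 1100L,
                      burn_in_frames = 100L, seed = 1L),
    analysis = list(max_tau = 60L, crop_px = 128L)))
  sw <- suppressWarnings(suppressMessages(
    runSweep(base, "domain_radius", c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
             replicates = 2L)))
  agg <- stats::aggregate(
    cbind(D_M, D_mu, plateau_mu, effective_radius, sat_A_M, sat_A_mu,
          beta_mean) ~ domain_radius,
    sw[sw$ok, ], mean, na.action = stats::na.pass, na.rm = TRUE)
  agg
})

expectMonotone <- function(x, direction = c("decreasing", "increasing")) {
  direction <- match.arg(direction)
  d <- diff(x)
  if (direction == "decreasing") expect_true(all(d <= 0)) else
    expect_true(all(d >= 0))
}
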