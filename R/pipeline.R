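# Configuration-driven orchestration: full runs, parameter sweeps, fixtures.

.analysisDefaults <- function() {
  list(max_tau = 100L, k2_min = 0, k2_max = 200,
       early_window = NULL, late_window = NULL, subtract_mean = TRUE,
       crop_px = NULL, psf_radius = 0.28, peak_intensity = 1,
       noise_param = 0)
}

#' Read a run configuration file
#'
#' YAML file with namespaced sections: `simulation.*` (keys matching the
#' [simulationConfig()] fields in snake_case), `analysis.*` (`max_tau`,
#' `k2_min`, `k2_max`, `early_window`, `late_window`, `subtract_mean`,
#' `crop_px`, `psf_radius`, `peak_intensity`, `noise_param`), and `io.*`
#' (`input_tiff`, `output_dir`). Unknown keys are a config error. Values
#' given in `overrides` (a named nested list) take precedence over the
#' file.
#'
#' @param path YAML config path, or `NULL` for all-defaults.
#' @param overrides nested named list overriding file values.
#' @return validated run-config list with elements `simulation`
#'   ([SimulationConfig-class]), `analysis`, `io`.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) ioError(sprintf("config file not found: '%s'", path))
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) configError("config file must hold a YAML mapping")
  bad <- setdiff(names(raw), c("simulation", "analysis", "io"))
  if (length(bad))
    configError(sprintf("unknown config section(s): %s",
                        paste(bad, collapse = ", ")))
  raw <- modifyList(raw, overrides)
  sim <- configFromList(if (is.null(raw$simulation)) list() else raw$simulation)
  ana <- .analysisDefaults()
  if (!is.null(raw$analysis)) {
    bad <- setdiff(names(raw$analysis), names(ana))
    if (length(bad))
      configError(sprintf("unknown analysis key(s): %s",
                          paste(bad, collapse = ", ")))
    ana <- modifyList(ana, raw$analysis)
  }
  if (ana$max_tau < 1L) configError("analysis.max_tau must be >= 1")
  if (ana$k2_max <= ana$k2_min) configError("analysis.k2_max must exceed k2_min")
  if (ana$noise_param < 0) configError("analysis.noise_param must be >= 0")
  io <- list(input_tiff = NULL, output_dir = NULL)
  if (!is.null(raw$io)) {
    bad <- setdiff(names(raw$io), names(io))
    if (length(bad))
      configError(sprintf("unknown io key(s): %s", paste(bad, collapse = ", ")))
    io <- modifyList(io, raw$io)
  }
  list(simulation = sim, analysis = ana, io = io)
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(list(simulation = configAsList(config$simulation),
                                analysis = config$analysis)), tmp)
  unname(tools::md5sum(tmp))
}

.provenance <- function(config, seed) {
  list(package = "ckics",
       version = as.character(packageVersion("ckics")),
       r_version = as.character(getRversion()),
       seed = seed,
       config_hash = .configHash(config),
       simulation = configAsList(config$simulation),
       analysis = config$analysis)
}

#' Run the full simulation-to-parameters pipeline
#'
#' Simulates confined diffusion, renders (and optionally adds noise to and
#' crops) the image series, computes and normalizes the kICS CF, fits the
#' two-component model, extracts confinement parameters, and writes six
#' artifacts to `outputDir`: `series.tif` (+ its `.range` sidecar),
#' `cf.csv`, `fits.csv`, `parameters.json`, `beta.csv` and
#' `provenance.json`. Reruns with the same config are bit-identical for the
#' simulation outputs and numerically identical for the fits.
#'
#' @param config run-config list from [readRunConfig()] (or `NULL` for
#'   defaults).
#' @param outputDir output directory, created if needed.
#' @return invisibly, a list with the in-memory objects (`trajectories`,
#'   `domains`, `series`, `cf`, `fit`, `parameters`, `beta`).
#' @export
runFull <- function(config = NULL, outputDir) {
  if (is.null(config) || !is.list(config) || is.null(config$simulation))
    config <- readRunConfig(NULL, if (is.list(config)) config else list())
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  sim <- config$simulation
  ana <- config$analysis
  run <- simulateConfinedDiffusion(sim)
  series <- renderSeries(run$trajectories, psfRadius = ana$psf_radius,
                         pixelSize = sim@pixelSize,
                         peakIntensity = ana$peak_intensity)
  if (ana$noise_param > 0)
    series <- addBackgroundNoise(series, ana$noise_param)
  if (!is.null(ana$crop_px)) series <- cropCenter(series, ana$crop_px)
  writeTiff(series, file.path(outputDir, "series.tif"))

  maxTau <- min(ana$max_tau, nFrames(series) - 1L)
  cf <- normalizeCF(kicsCorrelation(series, maxTau = maxTau,
                                    subtractMean = ana$subtract_mean))
  cfTable(cf, file.path(outputDir, "cf.csv"))
  fit <- fitTwoComponent(cf, k2Range = c(ana$k2_min, ana$k2_max))
  fitTable(fit, file.path(outputDir, "fits.csv"))
  pars <- extractParameters(fit, earlyWindow = ana$early_window,
                            lateWindow = ana$late_window)
  beta <- partitionCoefficient(run$trajectories, run$domains)
  write.csv(data.frame(frame = seq_along(beta@betaPerFrame),
                       beta = beta@betaPerFrame),
            file.path(outputDir, "beta.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(parametersAsList(pars), list(beta_mean = beta@betaMean,
                                   seed = sim@seed,
                                   config_hash = .configHash(config))),
    file.path(outputDir, "parameters.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(.provenance(config, sim@seed),
                       file.path(outputDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(trajectories = run$trajectories, domains = run$domains,
                 series = series, cf = cf, fit = fit, parameters = pars,
                 beta = beta))
}

#' @rdname runFull
#' @param pars a [ConfinementParameters-class].
#' @export
parametersAsList <- function(pars) {
  list(D_M = pars@dM, D_mu = pars@dMu, plateau_mu = pars@plateauMu,
       sat_A_M = pars@satAM, sat_A_mu = pars@satAMu,
       effective_radius = pars@effectiveRadius,
       early_window = pars@earlyWindow, late_window = pars@lateWindow)
}

#' Analyze one simulated configuration in memory
#'
#' Simulation + rendering + analysis without writing artifacts; the
#' workhorse behind [runSweep()].
#'
#' @param config run-config list (see [readRunConfig()]).
#' @return list with `parameters`, `beta`, `fit`, `cf`.
#' @export
runScenario <- function(config) {
  sim <- config$simulation
  ana <- config$analysis
  run <- simulateConfinedDiffusion(sim)
  series <- renderSeries(run$trajectories, psfRadius = ana$psf_radius,
                         pixelSize = sim@pixelSize,
                         peakIntensity = ana$peak_intensity)
  if (ana$noise_param > 0)
    series <- addBackgroundNoise(series, ana$noise_param)
  if (!is.null(ana$crop_px)) series <- cropCenter(series, ana$crop_px)
  maxTau <- min(ana$max_tau, nFrames(series) - 1L)
  res <- analyzeImageSeries(series, maxTau = maxTau,
                            k2Range = c(ana$k2_min, ana$k2_max),
                            earlyWindow = ana$early_window,
                            lateWindow = ana$late_window,
                            subtractMean = ana$subtract_mean)
  res$beta <- partitionCoefficient(run$trajectories, run$domains)
  res
}

#' Sweep one simulation parameter
#'
#' Reruns the full pipeline for each value of one [simulationConfig()]
#' field (snake_case name, e.g. `"domain_radius"`), with `replicates`
#' independent seeds per value derived deterministically from the base
#' seed. Per-run failures are recorded (`ok = FALSE`) and skipped; the
#' sweep fails only if every run fails.
#'
#' @param baseConfig run-config list (see [readRunConfig()]).
#' @param parameter simulation field to vary.
#' @param values vector of parameter values (non-empty).
#' @param replicates seeds per value.
#' @param path optional CSV output path for the aggregate table.
#' @return data.frame with one row per (value, replicate): the confinement
#'   parameters, `beta_mean`, `seed` and `ok`.
#' @export
runSweep <- function(baseConfig = NULL, parameter, values, replicates = 1L,
                     path = NULL) {
  if (is.null(baseConfig)) baseConfig <- readRunConfig()
  if (length(values) == 0L) configError("sweep values must be non-empty")
  simList <- configAsList(baseConfig$simulation)
  if (!parameter %in% setdiff(names(simList), "seed"))
    configError(sprintf("'%s' is not a sweepable simulation field", parameter))
  baseSeed <- simList$seed
  rows <- list()
  idx <- 0L
  for (vi in seq_along(values)) {
    for (rep in seq_len(replicates)) {
      idx <- idx + 1L
      seed <- (baseSeed + 104729L * (vi - 1L) + 7919L * (rep - 1L)) %%
        .Machine$integer.max
      simList2 <- simList
      simList2[[parameter]] <- values[vi]
      simList2$seed <- seed
      cfg <- list(simulation = configFromList(simList2),
                  analysis = baseConfig$analysis, io = baseConfig$io)
      res <- tryCatch(runScenario(cfg), error = function(e) e)
      if (inherits(res, "error")) {
        message(sprintf("sweep %s=%s rep %d failed: %s", parameter,
                        format(values[vi]), rep, conditionMessage(res)))
        rows[[idx]] <- data.frame(
          value = values[vi], replicate = rep, seed = seed, ok = FALSE,
          D_M = NA_real_, D_mu = NA_real_, plateau_mu = NA_real_,
          sat_A_M = NA_real_, sat_A_mu = NA_real_,
          effective_radius = NA_real_, beta_mean = NA_real_)
      } else {
        p <- res$parameters
        rows[[idx]] <- data.frame(
          value = values[vi], replicate = rep, seed = seed, ok = TRUE,
          D_M = p@dM, D_mu = p@dMu, plateau_mu = p@plateauMu,
          sat_A_M = p@satAM, sat_A_mu = p@satAMu,
          effective_radius = p@effectiveRadius,
          beta_mean = res$beta@betaMean)
      }
    }
  }
  out <- do.call(rbind, rows)
  names(out)[1] <- parameter
  if (all(!out$ok)) fitError("every sweep run failed")
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}

#' Generate reference fixtures
#'
#' Writes three scenario stacks with ground-truth sidecar YAML files: free
#' diffusion (no domains), a 50/50 two-free-species mixture, and the
#' default confined scenario. `scale = "tiny"` (128 px region, 500 frames,
#' cropped to 112 px) is sized for quick checks; `scale = "full"` uses the
#' full default scenario (300 px, 2200 frames, 256 px crop).
#'
#' @param outputDir output directory, created if needed.
#' @param scale `"tiny"` or `"full"`.
#' @param seed base seed.
#' @return invisibly, the vector of files written.
#' @export
makeFixtures <- function(outputDir, scale = c("tiny", "full"), seed = 1L) {
  scale <- match.arg(scale)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  tiny <- scale == "tiny"
  regionPx <- if (tiny) 128L else 300L
  nFrames <- if (tiny) 550L else 2200L
  burn <- if (tiny) 50L else 200L
  crop <- if (tiny) 112L else 256L
  dens <- if (tiny) 3 else 5
  written <- character()
  emit <- function(name, series, truth) {
    tifPath <- file.path(outputDir, paste0(name, ".tif"))
    writeTiff(series, tifPath)
    yaml::write_yaml(truth, file.path(outputDir, paste0(name, ".truth.yml")))
    written <<- c(written, tifPath, paste0(tifPath, ".range"),
                  file.path(outputDir, paste0(name, ".truth.yml")))
  }
  # free diffusion
  cfgF <- simulationConfig(regionPx = regionPx, nFrames = nFrames,
                           burnInFrames = burn, areaFraction = 0,
                           frameTime = 0.4, particleDensity = dens,
                           seed = seed)
  runF <- simulateConfinedDiffusion(cfgF)
  serF <- cropCenter(renderSeries(runF$trajectories), crop)
  emit("free_diffusion", serF,
       list(kind = "free", D = cfgF@DOut, frame_time = 0.4, seed = seed,
            pixel_size = cfgF@pixelSize, psf_radius = 0.28))
  # two free species (half density each), rendered jointly
  cfgA <- simulationConfig(regionPx = regionPx, nFrames = nFrames,
                           burnInFrames = burn, areaFraction = 0,
                           DOut = 0.1, frameTime = 0.4,
                           particleDensity = dens / 2, seed = seed + 1L)
  cfgB <- initialize(cfgA, DOut = 0.01, seed = seed + 2L)
  runA <- simulateConfinedDiffusion(cfgA)
  runB <- simulateConfinedDiffusion(cfgB)
  serA <- renderSeries(runA$trajectories)
  serB <- renderSeries(runB$trajectories)
  serAB <- cropCenter(initialize(serA, frames = serA@frames + serB@frames),
                      crop)
  emit("two_species", serAB,
       list(kind = "two_species", D1 = 0.1, D2 = 0.01, N1_frac = 0.5,
            frame_time = 0.4, seed = seed, pixel_size = cfgA@pixelSize,
            psf_radius = 0.28))
  # confined defaults
  cfgC <- simulationConfig(regionPx = regionPx, nFrames = nFrames,
                           burnInFrames = burn, particleDensity = dens,
                           seed = seed + 3L)
  runC <- simulateConfinedDiffusion(cfgC)
  serC <- cropCenter(renderSeries(runC$trajectories), crop)
  beta <- partitionCoefficient(runC$trajectories, runC$domains)
  emit("confined_default", serC,
       list(kind = "confined", D_in = cfgC@DIn, D_out = cfgC@DOut,
            P_in = cfgC@PIn, P_out = cfgC@POut,
            domain_radius = cfgC@domainRadius,
            area_fraction = cfgC@areaFraction,
            beta_mean = beta@betaMean,
            frame_time = resolvedFrameTime(cfgC), seed = seed,
            pixel_size = cfgC@pixelSize, psf_radius = 0.28))
  invisible(written)
}
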