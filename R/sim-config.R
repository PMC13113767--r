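#' Create a simulation configuration
#'
#' Defaults reproduce the standard confined-diffusion scenario: a 300 px
#' (30 um) region at 0.1 um/px, 2200 frames with 200 burn-in frames, 0.2 um
#' domains at 5% coverage, D_in = 0.001 and D_out = 0.01 um^2/s, P_in = 0.5,
#' P_out = 0.1, and 5 particles/um^2. The frame time defaults to "auto",
#' resolved as `(domainRadius/5)^2 / (4 * DIn)` so that the substep length
#' inside a domain is a fifth of the domain radius.
#'
#' @param regionPx pixels per side of the square region.
#' @param pixelSize um per pixel.
#' @param nFrames total simulated frames (burn-in included).
#' @param burnInFrames leading frames discarded before analysis.
#' @param frameTime seconds per frame, or `"auto"`/`NA` to derive it from the
#'   domain radius and `DIn`.
#' @param DIn,DOut diffusion coefficients inside/outside domains (um^2/s).
#' @param PIn,POut probabilities to enter/escape a domain at a boundary
#'   encounter.
#' @param domainRadius domain radius (um).
#' @param areaFraction fraction of the region covered by domains.
#' @param particleDensity particles per um^2.
#' @param substepsPerFrame diffusion substeps per frame.
#' @param boundaryPolicy `"reject_step"` (cancel a blocked crossing substep)
#'   or `"reflect"` (specular reflection off the domain circle).
#' @param seed integer RNG seed driving placement, initialization, stepping
#'   and noise in that order.
#' @return A [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(regionPx = 64L, nFrames = 50L, burnInFrames = 10L)
#' resolvedFrameTime(cfg)
#' @export
simulationConfig <- function(regionPx = 300L, pixelSize = 0.1,
                             nFrames = 2200L, burnInFrames = 200L,
                             frameTime = "auto",
                             DIn = 0.001, DOut = 0.01,
                             PIn = 0.5, POut = 0.1,
                             domainRadius = 0.2, areaFraction = 0.05,
                             particleDensity = 5,
                             substepsPerFrame = 1L,
                             boundaryPolicy = c("reject_step", "reflect"),
                             seed = 1L) {
  if (identical(frameTime, "auto")) frameTime <- NA_real_
  boundaryPolicy <- match.arg(boundaryPolicy)
  new("SimulationConfig",
      regionPx = as.integer(regionPx), pixelSize = as.numeric(pixelSize),
      nFrames = as.integer(nFrames), burnInFrames = as.integer(burnInFrames),
      frameTime = as.numeric(frameTime),
      DIn = as.numeric(DIn), DOut = as.numeric(DOut),
      PIn = as.numeric(PIn), POut = as.numeric(POut),
      domainRadius = as.numeric(domainRadius),
      areaFraction = as.numeric(areaFraction),
      particleDensity = as.numeric(particleDensity),
      substepsPerFrame = as.integer(substepsPerFrame),
      boundaryPolicy = boundaryPolicy, seed = as.integer(seed))
}

#' Frame time matched to the domain size
#'
#' The automatic frame time `(radius/5)^2 / (4 * DIn)` samples the motion
#' inside a domain at displacement steps of one fifth of the domain radius,
#' so that a domain of any size is traversed over a comparable number of
#' frames.
#'
#' @param domainRadius domain radius (um).
#' @param DIn diffusion coefficient inside domains (um^2/s), must be > 0.
#' @return Frame time in seconds.
#' @examples
#' autoFrameTime(0.2, 0.001)  # 0.4 s
#' @export
autoFrameTime <- function(domainRadius, DIn) {
  if (!is.numeric(DIn) || length(DIn) != 1L || is.na(DIn) || DIn <= 0)
    configError("frameTime 'auto' requires DIn > 0")
  if (domainRadius <= 0)
    configError("frameTime 'auto' requires domainRadius > 0")
  (domainRadius / 5)^2 / (4 * DIn)
}

#' @rdname simulationConfig
#' @param config a [SimulationConfig-class] object.
#' @export
resolvedFrameTime <- function(config) {
  if (is.na(config@frameTime))
    autoFrameTime(config@domainRadius, config@DIn)
  else config@frameTime
}

# plain named list (for provenance records and config files)
configAsList <- function(config) {
  list(
    region_px = config@regionPx, pixel_size = config@pixelSize,
    n_frames = config@nFrames, burn_in_frames = config@burnInFrames,
    frame_time = if (is.na(config@frameTime)) "auto" else config@frameTime,
    D_in = config@DIn, D_out = config@DOut,
    P_in = config@PIn, P_out = config@POut,
    domain_radius = config@domainRadius,
    area_fraction = config@areaFraction,
    particle_density = config@particleDensity,
    substeps_per_frame = config@substepsPerFrame,
    boundary_policy = config@boundaryPolicy,
    seed = config@seed
  )
}

# inverse of configAsList; unknown keys are a config error
configFromList <- function(x) {
  known <- c("region_px", "pixel_size", "n_frames", "burn_in_frames",
             "frame_time", "D_in", "D_out", "P_in", "P_out", "domain_radius",
             "area_fraction", "particle_density", "substeps_per_frame",
             "boundary_policy", "seed")
  bad <- setdiff(names(x), known)
  if (length(bad))
    configError(sprintf("unknown simulation config key(s): %s",
                        paste(bad, collapse = ", ")))
  defaults <- configAsList(simulationConfig())
  x <- modifyList(defaults, x)
  tryCatch(
    simulationConfig(
      regionPx = x$region_px, pixelSize = x$pixel_size,
      nFrames = x$n_frames, burnInFrames = x$burn_in_frames,
      frameTime = if (identical(x$frame_time, "auto")) "auto" else
        as.numeric(x$frame_time),
      DIn = x$D_in, DOut = x$D_out, PIn = x$P_in, POut = x$P_out,
      domainRadius = x$domain_radius, areaFraction = x$area_fraction,
      particleDensity = x$particle_density,
      substepsPerFrame = x$substeps_per_frame,
      boundaryPolicy = x$boundary_policy, seed = x$seed),
    error = function(e) configError(conditionMessage(e)))
}
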