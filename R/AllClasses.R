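#' Simulation configuration
#'
#' All physical and numerical parameters of a confined-diffusion run.
#' Construct with [simulationConfig()], which supplies the defaults used
#' throughout (0.1 um pixels, D_in = 0.001 and D_out = 0.01 um^2/s,
#' P_in = 0.5, P_out = 0.1, 0.2 um domains at 5% coverage, 5 particles/um^2,
#' 2200 frames of which the first 200 are burn-in).
#'
#' @slot regionPx integer, pixels per side of the simulated square region.
#' @slot pixelSize numeric, um per pixel.
#' @slot nFrames integer, total simulated frames (burn-in included).
#' @slot burnInFrames integer, leading frames discarded so partitioning
#'   reaches steady state.
#' @slot frameTime numeric, seconds per frame; `NA` means "auto", resolved as
#'   `(domainRadius/5)^2 / (4 * DIn)` (see [autoFrameTime()]).
#' @slot DIn,DOut numeric, diffusion coefficients inside/outside domains
#'   (um^2/s).
#' @slot PIn,POut numeric, probabilities to enter/escape a domain on a
#'   boundary encounter.
#' @slot domainRadius numeric, domain radius (um).
#' @slot areaFraction numeric, fraction of region area covered by domains.
#' @slot particleDensity numeric, particles per um^2.
#' @slot substepsPerFrame integer, diffusion substeps per frame (>= 1).
#' @slot boundaryPolicy character, `"reject_step"` or `"reflect"` for blocked
#'   boundary crossings.
#' @slot seed integer RNG seed.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    regionPx = "integer",
    pixelSize = "numeric",
    nFrames = "integer",
    burnInFrames = "integer",
    frameTime = "numeric",
    DIn = "numeric",
    DOut = "numeric",
    PIn = "numeric",
    POut = "numeric",
    domainRadius = "numeric",
    areaFraction = "numeric",
    particleDensity = "numeric",
    substepsPerFrame = "integer",
    boundaryPolicy = "character",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  chk <- function(cond, m) if (!isTRUE(cond)) msg <<- c(msg, m)
  chk(object@regionPx >= 1L, "regionPx must be >= 1")
  chk(object@pixelSize > 0, "pixelSize must be > 0")
  chk(object@nFrames >= 1L, "nFrames must be >= 1")
  chk(object@burnInFrames >= 0L && object@burnInFrames < object@nFrames,
      "burnInFrames must be in [0, nFrames)")
  chk(is.na(object@frameTime) || object@frameTime > 0,
      "frameTime must be > 0 (or NA for auto)")
  chk(object@DIn >= 0, "DIn must be >= 0")
  chk(object@DOut >= 0, "DOut must be >= 0")
  chk(object@PIn >= 0 && object@PIn <= 1, "PIn must be in [0, 1]")
  chk(object@POut >= 0 && object@POut <= 1, "POut must be in [0, 1]")
  chk(object@domainRadius >= 0, "domainRadius must be >= 0")
  chk(object@areaFraction >= 0 && object@areaFraction < 1,
      "areaFraction must be in [0, 1)")
  chk(object@particleDensity >= 0, "particleDensity must be >= 0")
  chk(object@substepsPerFrame >= 1L, "substepsPerFrame must be >= 1")
  chk(object@boundaryPolicy %in% c("reject_step", "reflect"),
      "boundaryPolicy must be 'reject_step' or 'reflect'")
  chk(is.na(object@frameTime) == FALSE || object@DIn > 0,
      "frameTime 'auto' requires DIn > 0")
  if (length(msg)) msg else TRUE
})

#' Static field of circular confinement domains
#'
#' Non-overlapping circular domains placed uniformly at random with centers at
#' least two radii apart. Created by [placeDomains()].
#'
#' @slot centers numeric matrix (n x 2) of domain centers (um).
#' @slot radius numeric, common domain radius (um).
#' @slot regionExtent numeric length-2, region width and height (um).
#' @slot achievedFraction numeric, realized area coverage n*pi*r^2 / area.
#' @exportClass DomainField
setClass("DomainField",
  representation(
    centers = "matrix",
    radius = "numeric",
    regionExtent = "numeric",
    achievedFraction = "numeric"
  )
)

setValidity("DomainField", function(object) {
  msg <- character()
  ctr <- object@centers
  if (!is.numeric(ctr) || ncol(ctr) != 2L)
    return("centers must be a numeric n x 2 matrix")
  if (length(object@regionExtent) != 2L || any(object@regionExtent <= 0))
    return("regionExtent must be two positive lengths")
  if (nrow(ctr)) {
    if (any(ctr[, 1] < 0 | ctr[, 1] > object@regionExtent[1] |
            ctr[, 2] < 0 | ctr[, 2] > object@regionExtent[2]))
      msg <- c(msg, "all centers must lie inside the region")
    if (nrow(ctr) > 1L) {
      dmin <- min(stats::dist(ctr))
      if (dmin < 2 * object@radius * (1 - 1e-12))
        msg <- c(msg, "centers must be at least two radii apart")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Ground-truth particle trajectories
#'
#' Continuous (sub-pixel) particle positions for every retained frame,
#' together with the inside-a-domain state used for partition statistics.
#' Produced by [simulateConfinedDiffusion()].
#'
#' @slot positions numeric array (nParticles x 2 x nFrames), um, periodic-
#'   wrapped into the region.
#' @slot insideFlags logical matrix (nParticles x nFrames).
#' @slot frameTime numeric, seconds between retained frames.
#' @slot regionExtent numeric length-2, region width and height (um).
#' @exportClass TrajectorySet
setClass("TrajectorySet",
  representation(
    positions = "array",
    insideFlags = "matrix",
    frameTime = "numeric",
    regionExtent = "numeric"
  )
)

setValidity("TrajectorySet", function(object) {
  d <- dim(object@positions)
  if (length(d) != 3L || d[2] != 2L)
    return("positions must be an nParticles x 2 x nFrames array")
  if (!identical(dim(object@insideFlags), d[c(1L, 3L)]))
    return("insideFlags must be nParticles x nFrames")
  if (object@frameTime <= 0) return("frameTime must be > 0")
  if (length(object@regionExtent) != 2L || any(object@regionExtent <= 0))
    return("regionExtent must be two positive lengths")
  if (d[1] > 0 && (min(object@positions) < 0 ||
      max(object@positions[, 1, ]) >= object@regionExtent[1] + 1e-9 ||
      max(object@positions[, 2, ]) >= object@regionExtent[2] + 1e-9))
    return("positions must lie inside the region after periodic wrapping")
  TRUE
})

#' Partition statistics
#'
#' The fraction of particles inside domains, per retained frame and averaged
#' over time (the partition coefficient beta). Produced by
#' [partitionCoefficient()].
#'
#' @slot betaPerFrame numeric vector, fraction inside per retained frame.
#' @slot betaMean numeric, time average of `betaPerFrame`.
#' @slot nDomains integer, number of domains in the field.
#' @slot meanOccupancy numeric, average particles per domain (NA without
#'   domains).
#' @exportClass PartitionStats
setClass("PartitionStats",
  representation(
    betaPerFrame = "numeric",
    betaMean = "numeric",
    nDomains = "integer",
    meanOccupancy = "numeric"
  )
)

setValidity("PartitionStats", function(object) {
  b <- object@betaPerFrame
  if (length(b) && (min(b) < 0 || max(b) > 1))
    return("betaPerFrame values must be in [0, 1]")
  if (length(b) && abs(object@betaMean - mean(b)) > 1e-12)
    return("betaMean must equal mean(betaPerFrame)")
  TRUE
})

#' Fluorescence image time series
#'
#' Pixelated frames with spatial and temporal calibration. Noiseless frames
#' come out of [renderSeries()]; [addBackgroundNoise()] adds the additive
#' Gaussian background whose standard deviation is `noiseParam` times the
#' peak particle intensity (implied signal-to-noise ratio 1/noiseParam).
#'
#' @slot frames numeric array (rows x cols x nFrames); row = y, column = x.
#' @slot pixelSize numeric, um per pixel.
#' @slot frameTime numeric, seconds per frame.
#' @slot psfRadius numeric, e^-2 radius omega0 of the lateral Gaussian PSF
#'   (um). The Gaussian sigma is omega0/2.
#' @slot peakIntensity numeric, PSF peak intensity I0 (arbitrary units).
#' @slot noiseParam numeric, background noise parameter (0 = noiseless).
#' @exportClass ImageSeries
setClass("ImageSeries",
  representation(
    frames = "array",
    pixelSize = "numeric",
    frameTime = "numeric",
    psfRadius = "numeric",
    peakIntensity = "numeric",
    noiseParam = "numeric"
  )
)

setValidity("ImageSeries", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a rows x cols x nFrames array")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  if (object@frameTime <= 0) return("frameTime must be > 0")
  if (object@psfRadius <= 0) return("psfRadius must be > 0")
  if (object@noiseParam < 0) return("noiseParam must be >= 0")
  TRUE
})

#' Circularly averaged k-space correlation function
#'
#' The temporal correlation of the spatially Fourier-transformed image
#' series, averaged over annuli of one frequency step in |k| (DC mode
#' excluded) and optionally normalized by its tau = 0 row. Wavenumbers are
#' angular: k = 2*pi*f with f in cycles/um.
#'
#' @slot k2Grid numeric, annulus-center k^2 values (um^-2), strictly
#'   increasing; each is the mean k^2 of the annulus member modes.
#' @slot tauGrid numeric, time lags in seconds starting at 0.
#' @slot values numeric matrix (length(k2Grid) x length(tauGrid)).
#' @slot nPairs integer, frame pairs averaged at each lag.
#' @slot normalized logical, TRUE after [normalizeCF()].
#' @slot mask logical, bins excluded from fitting (near-zero tau = 0 power).
#' @slot pixelSize numeric, um per pixel of the source series.
#' @slot omega0Hint numeric, e^-2 PSF radius carried over from the source
#'   series when known (um), else NA.
#' @slot imagRatio numeric, max |Im|/max |Re| of the raw CF (should be ~0 for
#'   a statistically stationary series).
#' @exportClass KICSCorrelation
setClass("KICSCorrelation",
  representation(
    k2Grid = "numeric",
    tauGrid = "numeric",
    values = "matrix",
    nPairs = "integer",
    normalized = "logical",
    mask = "logical",
    pixelSize = "numeric",
    omega0Hint = "numeric",
    imagRatio = "numeric"
  )
)

setValidity("KICSCorrelation", function(object) {
  msg <- character()
  if (length(object@tauGrid) == 0 || object@tauGrid[1] != 0)
    msg <- c(msg, "tauGrid must start at 0")
  if (!identical(dim(object@values),
                 c(length(object@k2Grid), length(object@tauGrid))))
    msg <- c(msg, "values must be k2 x tau")
  if (length(object@k2Grid) > 1 && any(diff(object@k2Grid) <= 0))
    msg <- c(msg, "k2Grid must be strictly increasing")
  if (length(object@nPairs) != length(object@tauGrid))
    msg <- c(msg, "nPairs must have one entry per lag")
  if (length(object@mask) != length(object@k2Grid))
    msg <- c(msg, "mask must have one entry per k2 bin")
  if (isTRUE(object@normalized) && length(object@k2Grid)) {
    ok <- object@values[!object@mask, 1]
    if (length(ok) && max(abs(ok - 1)) > 1e-8)
      msg <- c(msg, "normalized CF must be 1 at tau = 0 for unmasked bins")
  }
  if (length(msg)) msg else TRUE
})

#' Per-lag two-component fit results
#'
#' For each time lag, amplitudes and k^2-exponents of the two-Gaussian decay
#' A_M exp(-k^2 g_M) + A_mu exp(-k^2 g_mu) fitted to the normalized CF.
#' Components are labeled so that g_M >= g_mu (macro decays faster in k^2).
#'
#' @slot tau numeric, fitted lags (s), excludes tau = 0.
#' @slot aM,aMu numeric, component amplitudes.
#' @slot gM,gMu numeric, component exponents (um^2).
#' @slot seGM,seGMu numeric, per-lag standard errors of the exponents (from
#'   the Levenberg-Marquardt covariance; NA where unavailable).
#' @slot residual numeric, per-lag RMS residual.
#' @slot converged logical, per-lag convergence flag.
#' @slot separated logical, TRUE where the fit resolves two genuinely
#'   distinct components (both amplitude fractions >= 1% and g_M at least
#'   20% above g_mu); near-degenerate lags carry an arbitrary split and are
#'   excluded from trend characterization.
#' @slot k2Range numeric length-2, k^2 fit window used (um^-2).
#' @exportClass TwoComponentFit
setClass("TwoComponentFit",
  representation(
    tau = "numeric",
    aM = "numeric",
    aMu = "numeric",
    gM = "numeric",
    gMu = "numeric",
    seGM = "numeric",
    seGMu = "numeric",
    residual = "numeric",
    converged = "logical",
    separated = "logical",
    k2Range = "numeric"
  )
)

setValidity("TwoComponentFit", function(object) {
  n <- length(object@tau)
  for (s in c("aM", "aMu", "gM", "gMu", "seGM", "seGMu", "residual"))
    if (length(slot(object, s)) != n) return("per-lag slots must align")
  if (length(object@converged) != n || length(object@separated) != n)
    return("per-lag slots must align")
  conv <- object@converged
  if (any(conv)) {
    if (min(c(object@aM[conv], object@aMu[conv])) < 0)
      return("amplitudes must be >= 0")
    if (min(c(object@gM[conv], object@gMu[conv])) < 0)
      return("exponents must be >= 0")
    if (any(object@gM[conv] < object@gMu[conv] - 1e-12))
      return("labeling requires g_M >= g_mu at every converged lag")
  }
  TRUE
})

#' Extracted confinement parameters
#'
#' The headline c-kICS outputs: macro and micro diffusion coefficients from
#' early-lag linear fits of the exponents, the late-lag plateau of the micro
#' exponent, the late-lag amplitude saturations (row-renormalized so they
#' read as fractions), and the plateau-derived effective confinement radius
#' 2*sqrt(plateau).
#'
#' @slot dM,dMu numeric, macro/micro diffusion coefficients (um^2/s).
#' @slot plateauMu numeric, late-lag mean of g_mu (um^2).
#' @slot satAM,satAMu numeric, late-lag amplitude saturations (fractions).
#' @slot effectiveRadius numeric, 2*sqrt(plateauMu) (um).
#' @slot earlyWindow,lateWindow integer length-2, index windows into the
#'   fitted lags.
#' @slot ci numeric matrix (parameter x 2) of 95% confidence bounds.
#' @exportClass ConfinementParameters
setClass("ConfinementParameters",
  representation(
    dM = "numeric",
    dMu = "numeric",
    plateauMu = "numeric",
    satAM = "numeric",
    satAMu = "numeric",
    effectiveRadius = "numeric",
    earlyWindow = "integer",
    lateWindow = "integer",
    ci = "matrix"
  )
)

setValidity("ConfinementParameters", function(object) {
  msg <- character()
  # NA marks a quantity the fit could not resolve; bounds apply otherwise
  if (isTRUE(object@dM < 0) || isTRUE(object@dMu < 0))
    msg <- c(msg, "diffusion coefficients must be >= 0")
  if (isTRUE(object@satAM < 0) || isTRUE(object@satAM > 1 + 1e-6) ||
      isTRUE(object@satAMu < 0) || isTRUE(object@satAMu > 1 + 1e-6))
    msg <- c(msg, "amplitude saturations must be fractions")
  if (length(object@earlyWindow) != 2L || length(object@lateWindow) != 2L)
    msg <- c(msg, "windows must be index pairs")
  else if (object@earlyWindow[2] >= object@lateWindow[1])
    msg <- c(msg, "early and late windows must be disjoint (early first)")
  if (length(msg)) msg else TRUE
})
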