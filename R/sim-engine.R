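# Brownian dynamics with static circular microdomains.

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

#' Place non-overlapping circular domains
#'
#' Domain centers are drawn uniformly over the region by bounded rejection
#' sampling, accepting a candidate only if it is at least two radii away from
#' every accepted center (which forbids overlap). The number of domains is
#' `round(areaFraction * area / (pi * radius^2))`.
#'
#' @param regionExtent numeric length-2, region width and height (um).
#' @param radius domain radius (um).
#' @param areaFraction requested fractional area coverage.
#' @param seed optional integer seed; `NULL` continues the current RNG
#'   stream.
#' @param maxAttempts rejection-sampling budget per domain; exhausting it
#'   raises a `PackingError` (the request is too dense for the sampler).
#' @return A [DomainField-class].
#' @examples
#' placeDomains(c(30, 30), 0.2, 0.05, seed = 1)
#' @export
placeDomains <- function(regionExtent, radius, areaFraction, seed = NULL,
                         maxAttempts = 10000L) {
  regionExtent <- as.numeric(regionExtent)
  if (length(regionExtent) == 1L) regionExtent <- rep(regionExtent, 2L)
  stopifnot(length(regionExtent) == 2L, all(regionExtent > 0),
            radius >= 0, areaFraction >= 0, areaFraction < 1)
  area <- prod(regionExtent)
  n <- if (areaFraction == 0 || radius == 0) 0L
       else as.integer(round(areaFraction * area / (pi * radius^2)))
  centers <- matrix(numeric(0), 0L, 2L)
  if (n > 0L) {
    withSeed(seed, {
      centers <- matrix(NA_real_, n, 2L)
      minSq <- (2 * radius)^2
      for (i in seq_len(n)) {
        placed <- FALSE
        for (a in seq_len(maxAttempts)) {
          cand <- c(runif(1, 0, regionExtent[1]), runif(1, 0, regionExtent[2]))
          if (i == 1L) { ok <- TRUE } else {
            prev <- centers[seq_len(i - 1L), , drop = FALSE]
            ok <- min((prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2) >= minSq
          }
          if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
        }
        if (!placed)
          packingError(sprintf(
            "could not place domain %d of %d (radius %.3g, fraction %.3g) within %d attempts",
            i, n, radius, areaFraction, maxAttempts))
      }
    })
  }
  new("DomainField", centers = centers, radius = as.numeric(radius),
      regionExtent = regionExtent,
      achievedFraction = n * pi * radius^2 / area)
}

#' Initialize particle positions
#'
#' `round(density * area)` point particles uniform over the region.
#'
#' @param density particles per um^2.
#' @param regionExtent numeric length-2 (um).
#' @param seed optional integer seed; `NULL` continues the current stream.
#' @return numeric matrix (n x 2) of positions in um.
#' @export
initParticles <- function(density, regionExtent, seed = NULL) {
  regionExtent <- as.numeric(regionExtent)
  if (length(regionExtent) == 1L) regionExtent <- rep(regionExtent, 2L)
  stopifnot(density >= 0, length(regionExtent) == 2L, all(regionExtent > 0))
  n <- as.integer(round(density * prod(regionExtent)))
  withSeed(seed, {
    cbind(x = runif(n, 0, regionExtent[1]), y = runif(n, 0, regionExtent[2]))
  })
}

#' Advance particles by whole frames
#'
#' Each frame consists of `substepsPerFrame` Gaussian substeps of per-axis
#' standard deviation `sqrt(2 D dt)`, with D chosen by the particle's region
#' at the start of the substep. A substep whose endpoint crosses a domain
#' boundary is accepted with probability `PIn` (entering) or `POut`
#' (escaping); a blocked substep is cancelled (`"reject_step"`) or reflected
#' off the domain circle (`"reflect"`). Positions wrap periodically.
#'
#' @param positionsMat numeric matrix (n x 2) of current positions (um).
#' @param domains a [DomainField-class].
#' @param config a [SimulationConfig-class] (supplies D, P, frame time,
#'   substeps, policy; region comes from `domains`).
#' @param frames number of frames to advance.
#' @return list with `positions` (n x 2 matrix) and `inside` (logical) after
#'   the last frame.
#' @export
stepParticles <- function(positionsMat, domains, config, frames = 1L) {
  stopifnot(is.matrix(positionsMat), ncol(positionsMat) == 2L, frames >= 1L)
  res <- cpp_simulate(
    positionsMat, domains@centers[, 1], domains@centers[, 2],
    domains@radius, domains@regionExtent[1], domains@regionExtent[2],
    nFrames = as.integer(frames) + 1L, burnIn = as.integer(frames),
    substeps = config@substepsPerFrame,
    frameTime = resolvedFrameTime(config),
    DIn = config@DIn, DOut = config@DOut,
    PIn = config@PIn, POut = config@POut,
    reflectPolicy = as.integer(config@boundaryPolicy == "reflect"))
  list(positions = res$positions[, , 1L], inside = as.logical(res$inside[, 1L]))
}

#' Simulate confined diffusion
#'
#' Runs the full Brownian-dynamics simulation under `config`: domains are
#' placed, particles initialized uniformly, and the system is advanced for
#' `nFrames` frames of which the first `burnInFrames` are discarded so the
#' partitioning reaches steady state. All randomness flows from
#' `config@seed` through one RNG stream (placement, then initialization,
#' then stepping), so runs are bit-reproducible.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `trajectories` ([TrajectorySet-class]) and
#'   `domains` ([DomainField-class]).
#' @examples
#' cfg <- simulationConfig(regionPx = 64L, nFrames = 30L, burnInFrames = 5L,
#'                         frameTime = 0.1, seed = 7L)
#' run <- simulateConfinedDiffusion(cfg)
#' run$trajectories
#' @export
simulateConfinedDiffusion <- function(config) {
  validObject(config)
  extent <- rep(config@regionPx * config@pixelSize, 2L)
  ft <- resolvedFrameTime(config)
  set.seed(config@seed)
  domains <- placeDomains(extent, config@domainRadius, config@areaFraction)
  pos0 <- initParticles(config@particleDensity, extent)
  res <- cpp_simulate(
    pos0, domains@centers[, 1], domains@centers[, 2], domains@radius,
    extent[1], extent[2],
    nFrames = config@nFrames, burnIn = config@burnInFrames,
    substeps = config@substepsPerFrame, frameTime = ft,
    DIn = config@DIn, DOut = config@DOut,
    PIn = config@PIn, POut = config@POut,
    reflectPolicy = as.integer(config@boundaryPolicy == "reflect"))
  traj <- new("TrajectorySet", positions = res$positions,
              insideFlags = res$inside, frameTime = ft,
              regionExtent = extent)
  list(trajectories = traj, domains = domains)
}

#' Partition coefficient from trajectories
#'
#' beta(t) is the fraction of particles inside any domain at retained frame
#' t; the partition coefficient beta is its time average.
#'
#' @param traj a [TrajectorySet-class].
#' @param domains the [DomainField-class] from the same run.
#' @return A [PartitionStats-class].
#' @export
partitionCoefficient <- function(traj, domains) {
  flags <- traj@insideFlags
  np <- nrow(flags)
  perFrame <- if (np == 0L) rep(0, ncol(flags)) else colMeans(flags)
  nd <- nrow(domains@centers)
  occ <- if (nd > 0L) mean(colSums(flags)) / nd else NA_real_
  new("PartitionStats", betaPerFrame = perFrame, betaMean = mean(perFrame),
      nDomains = nd, meanOccupancy = occ)
}

#' Effective diffusion under partitioning
#'
#' The effective diffusion coefficient measured in the presence of trapping
#' domains, `D_eff = D_free * (1 - beta)`.
#'
#' @param DFree free-diffusion coefficient (um^2/s).
#' @param beta partition coefficient in \[0, 1\].
#' @return `DFree * (1 - beta)`.
#' @examples
#' effectiveDiffusion(0.01, 0.3)  # 0.007
#' @export
effectiveDiffusion <- function(DFree, beta) {
  if (any(!is.finite(beta)) || any(beta < 0) || any(beta > 1))
    stop("beta must be in [0, 1]")
  if (any(DFree < 0)) stop("DFree must be >= 0")
  DFree * (1 - beta)
}

#' Ensemble mean squared displacement
#'
#' MSD over time lags, averaged over particles and time origins. Periodic
#' wrapping is undone by the minimal-image convention on successive frames
#' (valid while per-frame displacements are much smaller than the region).
#' For free diffusion the MSD is `4 D tau`.
#'
#' @param traj a [TrajectorySet-class].
#' @param maxLag largest lag (frames); default a quarter of the series.
#' @return data.frame with `lag` (frames), `tau` (s) and `msd` (um^2).
#' @export
trajectoryMSD <- function(traj, maxLag = NULL) {
  pos <- traj@positions
  nt <- dim(pos)[3]
  if (is.null(maxLag)) maxLag <- max(1L, nt %/% 4L)
  maxLag <- min(maxLag, nt - 1L)
  W <- traj@regionExtent[1]; H <- traj@regionExtent[2]
  np <- dim(pos)[1]
  # unwrap: minimal-image per-frame increments, then cumulative sum
  px <- matrix(pos[, 1, ], nrow = np)
  py <- matrix(pos[, 2, ], nrow = np)
  dx <- px[, -1, drop = FALSE] - px[, -nt, drop = FALSE]
  dy <- py[, -1, drop = FALSE] - py[, -nt, drop = FALSE]
  dx <- dx - W * round(dx / W)
  dy <- dy - H * round(dy / H)
  rowCumsum <- function(m) {
    cs <- apply(m, 1, cumsum)
    if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)
    t(cs)
  }
  ux <- cbind(0, rowCumsum(dx))
  uy <- cbind(0, rowCumsum(dy))
  msd <- vapply(seq_len(maxLag), function(lag) {
    ddx <- ux[, (1 + lag):nt, drop = FALSE] - ux[, 1:(nt - lag), drop = FALSE]
    ddy <- uy[, (1 + lag):nt, drop = FALSE] - uy[, 1:(nt - lag), drop = FALSE]
    mean(ddx^2 + ddy^2)
  }, numeric(1))
  data.frame(lag = seq_len(maxLag), tau = seq_len(maxLag) * traj@frameTime,
             msd = msd)
}

#' Export trajectories as a tidy table
#'
#' One row per particle per frame: `particle`, `frame`, `x_um`, `y_um`,
#' `inside`. Written tab-separated when `path` is given.
#'
#' @param traj a [TrajectorySet-class].
#' @param path optional output path.
#' @return the data.frame, invisibly when written.
#' @export
exportTrajectories <- function(traj, path = NULL) {
  d <- dim(traj@positions)
  df <- data.frame(
    particle = rep(seq_len(d[1]), times = d[3]),
    frame = rep(seq_len(d[3]), each = d[1]),
    x_um = as.vector(traj@positions[, 1, ]),
    y_um = as.vector(traj@positions[, 2, ]),
    inside = as.vector(traj@insideFlags))
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(df))
  }
  df
}
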