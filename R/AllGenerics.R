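# Accessor generics and show methods for the core classes.

#' @name accessors
#' @title Accessors for ckics objects
#' @description Small accessor functions for the S4 containers; prefer these
#'   over direct slot access.
#' @param x a ckics object.
#' @param object a ckics object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("frameTime", function(x) standardGeneric("frameTime"))
#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("insideFlags", function(x) standardGeneric("insideFlags"))
#' @rdname accessors
#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))
#' @rdname accessors
#' @export
setGeneric("regionExtent", function(x) standardGeneric("regionExtent"))
#' @rdname accessors
#' @export
setGeneric("domainCenters", function(x) standardGeneric("domainCenters"))
#' @rdname accessors
#' @export
setGeneric("domainRadius", function(x) standardGeneric("domainRadius"))
#' @rdname accessors
#' @export
setGeneric("nDomains", function(x) standardGeneric("nDomains"))
#' @rdname accessors
#' @export
setGeneric("betaMean", function(x) standardGeneric("betaMean"))
#' @rdname accessors
#' @export
setGeneric("betaPerFrame", function(x) standardGeneric("betaPerFrame"))
#' @rdname accessors
#' @export
setGeneric("k2Grid", function(x) standardGeneric("k2Grid"))
#' @rdname accessors
#' @export
setGeneric("tauGrid", function(x) standardGeneric("tauGrid"))
#' @rdname accessors
#' @export
setGeneric("cfValues", function(x) standardGeneric("cfValues"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setGeneric("binMask", function(x) standardGeneric("binMask"))

#' @rdname accessors
#' @export
setMethod("pixelSize", "SimulationConfig", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "ImageSeries", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "KICSCorrelation", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("frameTime", "TrajectorySet", function(x) x@frameTime)
#' @rdname accessors
#' @export
setMethod("frameTime", "ImageSeries", function(x) x@frameTime)
#' @rdname accessors
#' @export
setMethod("frames", "ImageSeries", function(x) x@frames)
#' @rdname accessors
#' @export
setMethod("nFrames", "ImageSeries", function(x) dim(x@frames)[3])
#' @rdname accessors
#' @export
setMethod("nFrames", "TrajectorySet", function(x) dim(x@positions)[3])
#' @rdname accessors
#' @export
setMethod("positions", "TrajectorySet", function(x) x@positions)
#' @rdname accessors
#' @export
setMethod("insideFlags", "TrajectorySet", function(x) x@insideFlags)
#' @rdname accessors
#' @export
setMethod("nParticles", "TrajectorySet", function(x) dim(x@positions)[1])
#' @rdname accessors
#' @export
setMethod("regionExtent", "TrajectorySet", function(x) x@regionExtent)
#' @rdname accessors
#' @export
setMethod("regionExtent", "DomainField", function(x) x@regionExtent)
#' @rdname accessors
#' @export
setMethod("domainCenters", "DomainField", function(x) x@centers)
#' @rdname accessors
#' @export
setMethod("domainRadius", "DomainField", function(x) x@radius)
#' @rdname accessors
#' @export
setMethod("nDomains", "DomainField", function(x) nrow(x@centers))
#' @rdname accessors
#' @export
setMethod("nDomains", "PartitionStats", function(x) x@nDomains)
#' @rdname accessors
#' @export
setMethod("betaMean", "PartitionStats", function(x) x@betaMean)
#' @rdname accessors
#' @export
setMethod("betaPerFrame", "PartitionStats", function(x) x@betaPerFrame)
#' @rdname accessors
#' @export
setMethod("k2Grid", "KICSCorrelation", function(x) x@k2Grid)
#' @rdname accessors
#' @export
setMethod("tauGrid", "KICSCorrelation", function(x) x@tauGrid)
#' @rdname accessors
#' @export
setMethod("cfValues", "KICSCorrelation", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("isNormalized", "KICSCorrelation", function(x) x@normalized)
#' @rdname accessors
#' @export
setMethod("binMask", "KICSCorrelation", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("show", "SimulationConfig", function(object) {
  ft <- if (is.na(object@frameTime))
    sprintf("auto (%.4g s)", autoFrameTime(object@domainRadius, object@DIn))
  else sprintf("%.4g s", object@frameTime)
  cat("SimulationConfig:",
      sprintf("%d px region (%.3g um px), %d frames (%d burn-in), frame time %s",
              object@regionPx, object@pixelSize, object@nFrames,
              object@burnInFrames, ft), "\n")
  cat(sprintf("  D_in %.4g, D_out %.4g um^2/s; P_in %.3g, P_out %.3g\n",
              object@DIn, object@DOut, object@PIn, object@POut))
  cat(sprintf("  domains: r %.3g um, area fraction %.3g; density %.3g /um^2; seed %d\n",
              object@domainRadius, object@areaFraction,
              object@particleDensity, object@seed))
})

#' @rdname accessors
#' @export
setMethod("show", "DomainField", function(object) {
  cat(sprintf("DomainField: %d domains of radius %.3g um in %.3g x %.3g um (coverage %.3g)\n",
              nrow(object@centers), object@radius, object@regionExtent[1],
              object@regionExtent[2], object@achievedFraction))
})

#' @rdname accessors
#' @export
setMethod("show", "TrajectorySet", function(object) {
  d <- dim(object@positions)
  cat(sprintf("TrajectorySet: %d particles x %d frames, frame time %.4g s, region %.3g x %.3g um\n",
              d[1], d[3], object@frameTime, object@regionExtent[1],
              object@regionExtent[2]))
})

#' @rdname accessors
#' @export
setMethod("show", "PartitionStats", function(object) {
  cat(sprintf("PartitionStats: beta = %.4g over %d frames (%d domains, %.3g particles/domain)\n",
              object@betaMean, length(object@betaPerFrame), object@nDomains,
              object@meanOccupancy))
})

#' @rdname accessors
#' @export
setMethod("show", "ImageSeries", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ImageSeries: %d x %d px x %d frames; pixel %.3g um, frame %.4g s, omega0 %.3g um, noise %.3g\n",
              d[1], d[2], d[3], object@pixelSize, object@frameTime,
              object@psfRadius, object@noiseParam))
})

#' @rdname accessors
#' @export
setMethod("show", "KICSCorrelation", function(object) {
  cat(sprintf("KICSCorrelation: %d k^2 bins (%.3g-%.3g um^-2) x %d lags (to %.4g s); %s, %d masked\n",
              length(object@k2Grid), min(object@k2Grid), max(object@k2Grid),
              length(object@tauGrid), max(object@tauGrid),
              if (object@normalized) "normalized" else "raw",
              sum(object@mask)))
})

#' @rdname accessors
#' @export
setMethod("show", "TwoComponentFit", function(object) {
  cat(sprintf("TwoComponentFit: %d lags (%d converged), k^2 range %.3g-%.3g um^-2\n",
              length(object@tau), sum(object@converged),
              object@k2Range[1], object@k2Range[2]))
})

#' @rdname accessors
#' @export
setMethod("show", "ConfinementParameters", function(object) {
  cat("ConfinementParameters:\n")
  cat(sprintf("  D_M  %.4g um^2/s   D_mu %.4g um^2/s\n", object@dM, object@dMu))
  cat(sprintf("  Plateau_mu %.4g um^2 (effective radius %.3g um)\n",
              object@plateauMu, object@effectiveRadius))
  cat(sprintf("  Sat A_M %.3g   Sat A_mu %.3g\n", object@satAM, object@satAMu))
  cat(sprintf("  windows: early lags %d-%d, late lags %d-%d\n",
              object@earlyWindow[1], object@earlyWindow[2],
              object@lateWindow[1], object@lateWindow[2]))
})
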