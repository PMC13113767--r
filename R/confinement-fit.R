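# One- and two-component Gaussian decay fits of the kICS CF and the
# characterization of their lag trends into confinement parameters.

.selBins <- function(cf, k2Range) {
  cf@k2Grid >= k2Range[1] & cf@k2Grid <= k2Range[2] & !cf@mask
}

#' Single-species kICS fit
#'
#' For one freely diffusing species the raw CF decays as
#' `exp(-k^2 (D tau + omega0^2 / 4))` times a constant, so `ln r` is linear
#' in k^2 at every lag with slope `-(D tau + omega0^2/4)`. The per-lag
#' slopes are fitted linearly against tau: the slope of that line is D and
#' its intercept is omega0^2 / 4.
#'
#' @param cf a raw (unnormalized) [KICSCorrelation-class].
#' @param k2Range k^2 fit window (um^-2); bins outside it, masked bins and
#'   non-positive CF values are dropped.
#' @param tauLags lag indices (in frames, >= 1) used for the slope-vs-tau
#'   fit; default the first 10 available lags. At least 3 required.
#' @return list with `D` (um^2/s), `omega0` (um), the per-lag `slopes`
#'   data.frame, and standard errors `seD`.
#' @examples
#' # exact closed-form CF: D = 0.01, omega0 = 0.4
#' k2 <- seq(0.5, 50, length.out = 40)
#' tau <- 0:10
#' vals <- exp(-outer(k2, 0.01 * tau + 0.04))
#' cf <- new("KICSCorrelation", k2Grid = k2, tauGrid = as.numeric(tau),
#'           values = vals, nPairs = rep(100L, length(tau)),
#'           normalized = FALSE, mask = rep(FALSE, length(k2)),
#'           pixelSize = 0.1, omega0Hint = NA_real_, imagRatio = 0)
#' fitSingleSpecies(cf)
#' @export
fitSingleSpecies <- function(cf, k2Range = c(0, 200), tauLags = NULL) {
  if (cf@normalized)
    stop("single-species fitting uses the unnormalized CF")
  nLag <- length(cf@tauGrid) - 1L
  if (is.null(tauLags)) tauLags <- seq_len(min(10L, nLag))
  tauLags <- tauLags[tauLags >= 1L & tauLags <= nLag]
  if (length(tauLags) < 3L)
    fitError("need at least 3 lags for the slope-vs-tau fit")
  sel0 <- .selBins(cf, k2Range)
  slopes <- vapply(tauLags, function(lag) {
    y <- cf@values[, lag + 1L]
    sel <- sel0 & is.finite(y) & y > 0
    if (sum(sel) < 4L)
      fitError(sprintf("fewer than 4 usable k^2 bins at lag %d", lag))
    # weights y^2: delta-method variance of log(y) under additive CF noise,
    # keeps the deep-decay tail from biasing the slope
    fit <- lm(log(y[sel]) ~ cf@k2Grid[sel], weights = y[sel]^2)
    coef(fit)[2]
  }, numeric(1))
  tau <- cf@tauGrid[tauLags + 1L]
  lfit <- lm(I(-slopes) ~ tau)
  # exact synthetic input gives a perfect fit; the SE summary still works
  sm <- suppressWarnings(summary(lfit))$coefficients
  D <- unname(coef(lfit)[2])
  icpt <- unname(coef(lfit)[1])
  list(D = D, omega0 = 2 * sqrt(max(icpt, 0)),
       seD = unname(sm[2, 2]),
       slopes = data.frame(tau = tau, negSlope = -unname(slopes)))
}

# two-Gaussian model at one lag, via the bare Levenberg-Marquardt driver
# (nls.lm): tolerates the degenerate-but-legitimate endpoint where one
# amplitude converges to zero.
.fitTwoGaussOne <- function(k2, y, start) {
  par0 <- unlist(start)[c("a1", "g1", "a2", "g2")]
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = par0,
      lower = c(0, 0, 0, 0), upper = c(2, Inf, 2, Inf),
      fn = function(p) y - (p[1] * exp(-k2 * p[2]) + p[3] * exp(-k2 * p[4])),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) return(NULL)
  p <- fit$par
  names(p) <- c("a1", "g1", "a2", "g2")
  # exponent standard errors from the LM normal-equations matrix
  dof <- max(1L, length(y) - 4L)
  sigma2 <- sum(fit$fvec^2) / dof
  se <- rep(NA_real_, 4L)
  vc <- tryCatch(chol2inv(chol(fit$hessian)) * sigma2,
                 error = function(e) NULL)
  if (!is.null(vc)) se <- sqrt(pmax(diag(vc), 0))
  names(se) <- names(p)
  list(p = p, se = se, rms = sqrt(mean(fit$fvec^2)))
}

#' Two-component Gaussian fit of the normalized CF, per lag
#'
#' At every lag tau > 0 the normalized CF is fitted over the k^2 window with
#' `A_M exp(-k^2 g_M) + A_mu exp(-k^2 g_mu)`. The starting point comes from
#' a single-exponential estimate (amplitude split 50/50, second exponent a
#' tenth of the first); amplitudes are bounded to \[0, 2\] and exponents to
#' \[0, Inf). Components are labeled per lag so that g_M >= g_mu, then label
#' continuity between neighboring lags is restored where swapping reduces
#' the total jump. Non-converged lags are flagged, not fatal; if more than
#' half fail a `FitError` is raised.
#'
#' @param cf a normalized [KICSCorrelation-class].
#' @param k2Range k^2 fit window (um^-2); needs >= 8 usable bins.
#' @return A [TwoComponentFit-class].
#' @export
fitTwoComponent <- function(cf, k2Range = c(0, 200)) {
  if (!cf@normalized)
    stop("two-component fitting uses the normalized CF (see normalizeCF)")
  sel <- .selBins(cf, k2Range)
  if (sum(sel) < 8L)
    fitError(sprintf("only %d usable k^2 bins in [%.3g, %.3g]; need >= 8",
                     sum(sel), k2Range[1], k2Range[2]))
  k2 <- cf@k2Grid[sel]
  nLag <- length(cf@tauGrid) - 1L
  aM <- aMu <- gM <- gMu <- seM <- seMu <- resid <- rep(NA_real_, nLag)
  conv <- rep(FALSE, nLag)
  lastStart <- NULL
  # Fit from the largest lag downward: components are well separated at
  # late lags, and warm-starting each lag from the one above keeps the fit
  # determined where the exponents become nearly degenerate (early lags).
  for (lag in rev(seq_len(nLag))) {
    y <- cf@values[sel, lag + 1L]
    ok <- is.finite(y)
    if (sum(ok) < 8L) next
    pos <- ok & y > 0
    g0 <- if (sum(pos) >= 4L)
      max(1e-4, -unname(coef(lm(log(y[pos]) ~ k2[pos]))[2]))
    else 1e-3
    starts <- list(list(a1 = 0.5, g1 = g0, a2 = 0.5, g2 = g0 / 10),
                   list(a1 = 0.5, g1 = 4 * g0, a2 = 0.5, g2 = g0 / 4),
                   list(a1 = 0.2, g1 = 10 * g0, a2 = 0.8, g2 = g0))
    if (!is.null(lastStart)) starts <- c(list(lastStart), starts)
    # multi-start: keep the lowest-residual solution
    res <- NULL
    for (st in starts) {
      cand <- .fitTwoGaussOne(k2[ok], y[ok], st)
      if (!is.null(cand) && (is.null(res) || cand$rms < res$rms * (1 - 1e-8)))
        res <- cand
    }
    if (is.null(res)) next
    p <- res$p
    if (p[["g1"]] >= p[["g2"]]) {
      gM[lag] <- p[["g1"]]; aM[lag] <- p[["a1"]]; seM[lag] <- res$se[["g1"]]
      gMu[lag] <- p[["g2"]]; aMu[lag] <- p[["a2"]]; seMu[lag] <- res$se[["g2"]]
    } else {
      gM[lag] <- p[["g2"]]; aM[lag] <- p[["a2"]]; seM[lag] <- res$se[["g2"]]
      gMu[lag] <- p[["g1"]]; aMu[lag] <- p[["a1"]]; seMu[lag] <- res$se[["g1"]]
    }
    resid[lag] <- res$rms
    conv[lag] <- TRUE
    lastStart <- list(a1 = unname(p[["a1"]]), g1 = unname(p[["g1"]]),
                      a2 = unname(p[["a2"]]), g2 = unname(p[["g2"]]))
  }
  if (sum(conv) < ceiling(nLag / 2))
    fitError(sprintf("two-component fit converged at only %d of %d lags",
                     sum(conv), nLag))
  # Per-lag labeling is by exponent magnitude (g_M >= g_mu); warm-starting
  # each lag from the one above keeps the component tracks continuous
  # where the exponents cross between lags. Lags where the two components
  # are not genuinely resolved (an amplitude collapses to zero, or the
  # exponents merge) are flagged: their macro/micro split is arbitrary.
  tot <- aM + aMu
  separated <- conv & is.finite(tot) & tot > 0 &
    pmin(aM, aMu) / tot >= 0.01 & gM > 1.2 * gMu
  separated[is.na(separated)] <- FALSE
  new("TwoComponentFit", tau = cf@tauGrid[-1], aM = aM, aMu = aMu,
      gM = gM, gMu = gMu, seGM = seM, seGMu = seMu,
      residual = resid, converged = conv, separated = separated,
      k2Range = as.numeric(k2Range))
}

#' Per-lag fit table
#'
#' @param fit a [TwoComponentFit-class].
#' @param path optional CSV output path.
#' @return data.frame with `tau`, `A_M`, `A_mu`, `g_M`, `g_mu`, `residual`,
#'   `converged`.
#' @export
fitTable <- function(fit, path = NULL) {
  df <- data.frame(tau = fit@tau, A_M = fit@aM, A_mu = fit@aMu,
                   g_M = fit@gM, g_mu = fit@gMu,
                   se_g_M = fit@seGM, se_g_mu = fit@seGMu,
                   residual = fit@residual,
                   converged = fit@converged, separated = fit@separated)
  if (!is.null(path)) {
    write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

.windowIdx <- function(w, n, what) {
  w <- as.integer(w)
  if (length(w) != 2L || any(is.na(w)) || w[1] < 1L || w[2] > n || w[1] > w[2])
    windowError(sprintf("invalid %s window [%d, %d] for %d lags",
                        what, w[1], w[2], n))
  w
}

#' Extract confinement parameters from per-lag fits
#'
#' Characterizes the lag trends of the two-component fit: D_M and D_mu are
#' the slopes of linear fits of g_M(tau) and g_mu(tau) over the early
#' window; Plateau_mu is the mean of g_mu over the late window (the
#' saturation level, units um^2); the amplitude saturations are late-window
#' means of the row-renormalized amplitudes `A / (A_M + A_mu)` so they read
#' as fractions; and the effective confinement radius is
#' `2 * sqrt(Plateau_mu)` (a particle confined to a disc of radius R has a
#' long-lag mean squared displacement of R^2 and the Gaussian exponent
#' carries MSD/4). Negative fitted slopes are clamped to zero (the reported
#' confidence interval retains the unclamped fit).
#'
#' Only lags flagged `separated` enter the diffusion regressions and the
#' amplitude saturations: at very early lags the two exponents have not yet
#' diverged and at very late lags the macro correlation has fully decayed,
#' and in both regimes the per-lag split between components is arbitrary.
#'
#' The plateau is more robust than the full decomposition and uses a
#' documented per-lag fallback chain. A micro exponent counts as resolved
#' when it exceeds the window resolution floor `0.05 / k2max` (i.e. it is
#' not pinned at the zero bound); otherwise, a lag where both
#' exponents agree within 20% contributes their common value (the
#' components have merged into one effective decay), and a lag where the
#' unresolved component also carries less than 30% of the amplitude
#' contributes the dominant component's exponent (the residual minor
#' component is the flat tail of the static domain structure, not a decay).
#'
#' @param fit a [TwoComponentFit-class].
#' @param earlyWindow integer length-2 lag-index window for the diffusion
#'   slopes; default the first 12 resolved (separated) lags.
#' @param lateWindow integer length-2 lag-index window for the saturations;
#'   default the last 25% of resolved lags.
#' @return A [ConfinementParameters-class].
#' @export
extractParameters <- function(fit, earlyWindow = NULL, lateWindow = NULL) {
  n <- length(fit@tau)
  usable <- which(fit@separated)
  convAll <- which(fit@converged)
  if (length(convAll) < 6L)
    windowError("fewer than 6 converged lags; nothing to characterize")
  anchor <- if (length(usable) >= 6L) usable else convAll
  if (is.null(earlyWindow))
    earlyWindow <- c(anchor[1], anchor[min(12L, length(anchor))])
  if (is.null(lateWindow)) {
    nLate <- max(3L, length(anchor) %/% 4L)
    lateUse <- utils::tail(anchor, nLate)
    lateWindow <- c(lateUse[1], lateUse[length(lateUse)])
  }
  if (lateWindow[1] <= earlyWindow[2])
    earlyWindow[2] <- max(earlyWindow[1], lateWindow[1] - 1L)
  earlyWindow <- .windowIdx(earlyWindow, n, "early")
  lateWindow <- .windowIdx(lateWindow, n, "late")
  early <- usable[usable >= earlyWindow[1] & usable <= earlyWindow[2]]
  late <- usable[usable >= lateWindow[1] & usable <= lateWindow[2]]

  # inverse-variance weights from the per-lag exponent standard errors,
  # falling back to an unweighted fit when they are unavailable
  slopeFit <- function(g, se, idx) {
    if (length(idx) < 3L) return(c(slope = NA_real_, se = NA_real_))
    w <- 1 / se[idx]^2
    if (any(!is.finite(w))) w <- NULL
    f <- lm(g[idx] ~ fit@tau[idx], weights = w)
    sm <- summary(f)$coefficients
    sse <- if (nrow(sm) >= 2L) sm[2, 2] else NA_real_
    c(slope = unname(coef(f)[2]), se = unname(sse))
  }
  fM <- slopeFit(fit@gM, fit@seGM, early)
  fMu <- slopeFit(fit@gMu, fit@seGMu, early)
  tot <- fit@aM + fit@aMu
  fracM <- fit@aM[late] / tot[late]
  fracMu <- fit@aMu[late] / tot[late]

  # plateau fallback chain over all converged lags of the late window
  gFloor <- 0.05 / fit@k2Range[2]
  lateAll <- convAll[convAll >= lateWindow[1] & convAll <= lateWindow[2]]
  microG <- vapply(lateAll, function(i) {
    fmin <- min(fit@aM[i], fit@aMu[i]) / tot[i]
    if (fit@separated[i] && fit@gMu[i] >= gFloor) return(fit@gMu[i])
    if (fmin >= 0.01 && fit@gM[i] <= 1.2 * fit@gMu[i] + 1e-12)
      return((fit@gM[i] + fit@gMu[i]) / 2)
    if (fit@gMu[i] < gFloor && fmin < 0.3) return(fit@gM[i])
    NA_real_
  }, numeric(1))
  microG <- microG[is.finite(microG)]
  if (length(microG) < 3L && length(late) < 3L)
    windowError("late window has fewer than 3 lags with a resolved plateau")
  plateau <- if (length(microG) >= 3L) mean(microG) else NA_real_
  semean <- function(x) sd(x) / sqrt(length(x))
  tq <- qt(0.975, max(1L, length(microG) - 1L))
  tqe <- qt(0.975, max(1L, length(early) - 2L))
  tqa <- qt(0.975, max(1L, length(late) - 1L))
  naCI <- c(NA_real_, NA_real_)
  ci <- rbind(
    dM = fM["slope"] + c(-1, 1) * tqe * fM["se"],
    dMu = fMu["slope"] + c(-1, 1) * tqe * fMu["se"],
    plateauMu = if (is.na(plateau)) naCI else
      plateau + c(-1, 1) * tq * semean(microG),
    satAM = if (length(late) < 3L) naCI else
      mean(fracM) + c(-1, 1) * tqa * semean(fracM),
    satAMu = if (length(late) < 3L) naCI else
      mean(fracMu) + c(-1, 1) * tqa * semean(fracMu))
  colnames(ci) <- c("lower", "upper")
  clamp01 <- function(x) if (length(x) == 0 || is.na(x)) NA_real_ else
    min(1, max(0, x))
  new("ConfinementParameters",
      dM = if (is.na(fM[["slope"]])) NA_real_ else max(0, fM[["slope"]]),
      dMu = if (is.na(fMu[["slope"]])) NA_real_ else max(0, fMu[["slope"]]),
      plateauMu = plateau,
      satAM = if (length(late) < 3L) NA_real_ else clamp01(mean(fracM)),
      satAMu = if (length(late) < 3L) NA_real_ else clamp01(mean(fracMu)),
      effectiveRadius = if (is.na(plateau)) NA_real_ else
        2 * sqrt(max(plateau, 0)),
      earlyWindow = earlyWindow, lateWindow = lateWindow, ci = ci)
}

#' Global two-free-species fit
#'
#' Validation mode for a mixture of two freely diffusing species: a single
#' nonlinear fit across the whole (k^2, tau > 0) surface of the normalized
#' CF with exponents constrained to be linear in tau,
#' `p exp(-k^2 D1 tau) + (1 - p) exp(-k^2 D2 tau)`. Components are labeled
#' so D1 >= D2.
#'
#' @param cf a normalized [KICSCorrelation-class].
#' @param k2Range k^2 fit window (um^-2).
#' @return list with `D1`, `D2` (um^2/s), `N1frac` (number fraction of the
#'   faster species) and `degenerate` (TRUE when D1 and D2 are within 10% of
#'   their mean, i.e. a single species describes the data).
#' @export
fitTwoFreeSpecies <- function(cf, k2Range = c(0, 200)) {
  if (!cf@normalized)
    stop("two-species fitting uses the normalized CF (see normalizeCF)")
  sel <- .selBins(cf, k2Range)
  if (sum(sel) < 8L)
    fitError("need >= 8 usable k^2 bins")
  nLag <- length(cf@tauGrid) - 1L
  grid <- expand.grid(k2 = cf@k2Grid[sel], tau = cf@tauGrid[-1])
  grid$y <- as.vector(cf@values[sel, -1])
  grid <- grid[is.finite(grid$y), ]
  # seed from the mid-lag single-exponential slope
  midLag <- max(1L, nLag %/% 2L)
  ymid <- cf@values[sel, midLag + 1L]
  pos <- is.finite(ymid) & ymid > 0
  D0 <- if (sum(pos) >= 4L)
    max(1e-5, -unname(coef(lm(log(ymid[pos]) ~ cf@k2Grid[sel][pos]))[2]) /
          cf@tauGrid[midLag + 1L])
  else 1e-3
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(p = 0.5, D1 = D0, D2 = D0 / 10),
      lower = c(0, 0, 0), upper = c(1, Inf, Inf),
      fn = function(q) grid$y - (q[1] * exp(-grid$k2 * q[2] * grid$tau) +
                                   (1 - q[1]) * exp(-grid$k2 * q[3] * grid$tau)),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      fitError(sprintf("two-species fit failed: %s", conditionMessage(e))))
  if (!(fit$info %in% 1:4))
    fitError(sprintf("two-species fit did not converge (info = %d)", fit$info))
  p <- fit$par
  D1 <- p[["D1"]]; D2 <- p[["D2"]]; frac <- p[["p"]]
  if (D2 > D1) { tmp <- D1; D1 <- D2; D2 <- tmp; frac <- 1 - frac }
  list(D1 = D1, D2 = D2, N1frac = frac,
       degenerate = (D1 - D2) < 0.1 * (D1 + D2) / 2)
}

#' One-call analysis of an image series
#'
#' Computes the kICS CF, normalizes it, runs the per-lag two-component fit
#' and extracts the confinement parameters.
#'
#' @param series an [ImageSeries-class].
#' @param maxTau largest lag in frames.
#' @param k2Range k^2 fit window (um^-2).
#' @param earlyWindow,lateWindow lag-index windows (see
#'   [extractParameters()]).
#' @param subtractMean remove per-frame spatial means before the FFT.
#' @return list with `cf` (normalized CF), `fit` ([TwoComponentFit-class])
#'   and `parameters` ([ConfinementParameters-class]).
#' @export
analyzeImageSeries <- function(series, maxTau = 100L, k2Range = c(0, 200),
                               earlyWindow = NULL, lateWindow = NULL,
                               subtractMean = TRUE) {
  cf <- normalizeCF(kicsCorrelation(series, maxTau = maxTau,
                                    subtractMean = subtractMean))
  fit <- fitTwoComponent(cf, k2Range = k2Range)
  pars <- extractParameters(fit, earlyWindow = earlyWindow,
                            lateWindow = lateWindow)
  list(cf = cf, fit = fit, parameters = pars)
}
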