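---
title: "Confinement kICS: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confinement kICS: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ckics)
```

# The problem

Membrane proteins rarely diffuse freely: cholesterol- and
sphingomyelin-enriched microdomains, protein complexes and cytoskeletal
structures transiently trap them. k-space image correlation spectroscopy
(kICS) measures transport from a fluorescence-microscopy image time series
by correlating the spatially Fourier-transformed frames across time lags;
because the analysis works in reciprocal space, probe photophysics enters
only through amplitudes, not through the transport-driven decay.
Confinement kICS (c-kICS) extends this to heterogeneous membranes in which
one molecular species alternates between free diffusion and confinement in
microdomains: the correlation function then behaves as a sum of two
Gaussian decays in $k^2$ whose amplitudes and exponents depend on the lag
$\tau$, and the lag trends of those per-lag fits carry the confinement
parameters.

This package provides all four stages: a Brownian-dynamics simulator with
static circular domains, a fluorescence image synthesizer, the correlation
pipeline, and the one- and two-component fitting machinery.

# Models

## Free diffusion (single species)

For one freely diffusing species with diffusion coefficient $D$ imaged
with a Gaussian point-spread function of $e^{-2}$ radius $\omega_0$, the
circularly averaged k-space temporal correlation function decays as

$$ r(k^2, \tau) \propto e^{-k^2\,(D\tau + \omega_0^2/4)} . $$

`fitSingleSpecies()` inverts this directly: $\ln r$ is fitted linearly
against $k^2$ at each lag (weighted by $r^2$, the delta-method variance of
$\ln r$ under additive noise on $r$, which keeps the deep-decay tail from
biasing the slope), and the per-lag slopes are fitted linearly against
$\tau$; the slope of that line is $D$ and its intercept $\omega_0^2/4$.
The second stage doubles as a PSF self-check: the recovered
$\hat\omega_0$ should match the imaging system.

## Two free species

For two non-interconverting species the normalized CF is

$$ \frac{r(k^2,\tau)}{r(k^2,0)}
   = \frac{N_1 e^{-k^2 D_1 \tau} + N_2 e^{-k^2 D_2 \tau}}{N_1 + N_2}, $$

with both exponents strictly linear in $\tau$. `fitTwoFreeSpecies()` fits
this globally across the whole $(k^2, \tau)$ surface and reports $D_1 \ge
D_2$ and the number fraction; it flags the degenerate case $D_1 \approx
D_2$ instead of failing. This is the validation mode for the $M = 2$
free-population limit.

## Confined + free interconversion (c-kICS)

When one species alternates between confinement and free diffusion, each
lag of the normalized CF is fitted with

$$ r(k^2,\tau)/r(k^2,0) \;=\;
   A_M(\tau)\, e^{-k^2 g_M(\tau)} + A_\mu(\tau)\, e^{-k^2 g_\mu(\tau)}, $$

with components labeled so $g_M \ge g_\mu$. The macro component reflects
transport over large distances between confinement episodes: $g_M(\tau)$
grows with lag and its early-lag slope is reported as $D_M$. The micro
component reflects motion at domain scale: $g_\mu(\tau)$ initially grows
(slope $D_\mu$) and then saturates at $\mathrm{Plateau}_\mu$, the effective
confined area scale (um^2). Since a particle confined to a disc of radius
$R$ has a long-lag mean-squared displacement of $\approx R^2$ and the
Gaussian exponent carries MSD/4, the package reports
`effectiveRadius = 2 * sqrt(plateauMu)` as the length-scale convention.
The late-lag means of the row-renormalized amplitudes
$A/(A_M + A_\mu)$ are the amplitude saturations, which track the fractions
of free and confined particles.

The source literature quotes the plateau inconsistently (a saturation
"level" in um next to "4 x plateau = one pixel squared" in um^2); this
package fixes the operational definition above — plateau in um^2, length
scale $2\sqrt{\mathrm{Plateau}_\mu}$ — under which both readings are
dimensionally coherent.

## Partition coefficient

From the simulator's ground truth, $\beta(t)$ is the fraction of particles
inside any domain at frame $t$ and $\beta$ its time average
(`partitionCoefficient()`). It links free and effective diffusion through

$$ D_\mathrm{eff} = D_\mathrm{free}\,(1 - \beta) $$

(`effectiveDiffusion()`), and the amplitude saturations should track
$1-\beta$ and $\beta$ respectively.

# The simulator

`simulateConfinedDiffusion()` performs Brownian dynamics on a periodic
square region containing static, non-overlapping circular domains:

* Domains are placed by bounded rejection sampling, uniform over the
  region with centers at least two radii apart
  (`round(areaFraction * area / (pi r^2))` of them). A request the
  sequential sampler cannot satisfy raises a `PackingError`.
* Particles start uniform; each frame consists of `substepsPerFrame`
  Gaussian substeps with per-axis standard deviation $\sqrt{2 D \Delta t}$,
  with $D$ chosen by the particle's compartment at the start of the
  substep ($D_{in}$ inside, $D_{out}$ outside).
* A substep whose endpoint crosses the domain boundary is accepted with
  probability $P_{in}$ (entering) or $P_{out}$ (escaping). A blocked
  crossing is resolved by `boundaryPolicy`: `"reject_step"` (default)
  cancels the substep, `"reflect"` reflects the endpoint across the
  domain circle. The two policies bias near-boundary dwell time slightly
  differently; the default is the more literal reading of an
  accept/reject boundary rule.
* The first `burnInFrames` frames are discarded so the in/out
  partitioning reaches steady state before any statistics are collected.
* One RNG stream seeded by `seed` drives placement, initialization,
  stepping and (later) noise, in that documented order, so whole runs are
  bit-reproducible.

The default frame time is size-adapted, $t_{frame} = (r/5)^2 / (4
D_{in})$: the RMS substep inside a domain is then a fifth of the domain
radius regardless of size, so confined motion is sampled over a comparable
number of frames in every scenario. A fixed `frameTime` can always be
supplied instead; the D_out/D_in sweep in the acceptance suite does so
(0.4 s, the value the formula yields at the default $D_{in}$), because
re-deriving the frame time from the swept $D_{in}$ would change the
temporal sampling together with the physical parameter under study.

Defaults (a 30 um region at 0.1 um pixels, 2200 frames with 200 burn-in,
$D_{in} = 0.001$, $D_{out} = 0.01$ um^2/s, $P_{in} = 0.5$,
$P_{out} = 0.1$, 0.2 um domains at 5% coverage, 5 particles/um^2) define
the reference confined scenario; every sweep varies one parameter around
them.

What the generator deliberately does not emulate: photobleaching and
blinking (amplitudes would rescale, transport decays would not), mobile or
overlapping domains, diffusion-coefficient gradients at boundaries,
directed flow, and meshwork (picket-fence) confinement. Passing tests
therefore validate the estimator pipeline under the stated model, not
against every complication of live-cell data.

# Image synthesis

`renderSeries()` evaluates, at each pixel center, the sum of Gaussian
PSFs centered at the exact sub-pixel particle coordinates:
$I(i,j) = I_0 \sum_n e^{-(i-x_n)^2/2\sigma^2} e^{-(j-y_n)^2/2\sigma^2}$.
The user-facing `psfRadius` is the $e^{-2}$ radius $\omega_0$ (default
0.28 um), so $\sigma = \omega_0/2$; this convention matters because
$\omega_0^2/4$ is the intercept of every single-species fit. The PSF
support is truncated at $5\sigma$ (error < 1e-5 of the peak). Because
rendering is evaluated at exact coordinates, sub-pixel motion always
changes the image: the pipeline has no artificial pixel-quantization floor
(see Limitations for the consequence).

`addBackgroundNoise()` adds i.i.d. zero-mean Gaussian noise with standard
deviation `noiseParam * peakIntensity` to every pixel; the implied
signal-to-noise ratio is `1/noiseParam` (0.2 corresponds to SN = 5). White
noise raises only the $\tau = 0$ power (a k-independent pedestal); lags
$\tau \ge 1$ stay unbiased in expectation, which is why normalization by
the zero-lag row and a noise-aware upper $k^2$ bound keep noisy data
analyzable.

`cropCenter()` models the experimental region-of-interest crop (the
reference scenario analyzes the central 256 of 300 px; reduced-scale runs
crop proportionally). Cropping breaks periodicity and lets fast particles
enter and leave the analyzed window; this adds a small extra decorrelation
for fast species (measured at roughly +15-20% on a fast species' fitted D
at a 11 um window), which is one reason the window should not be made too
small relative to $\sqrt{4 D \tau_{max}}$.

TIFF stacks are written as 32-bit float grayscale with intensities packed
affinely into [0, 1] (the range restriction of the underlying writer) and
the transform recorded in a one-line `<path>.range` sidecar; round trips
are exact to float32 precision.

# Correlation pipeline

`spatialTransform()` removes each frame's spatial mean (so the uniform
background does not dominate the DC mode; configurable) and applies a 2D
FFT per frame. Wavenumbers are angular, $k = 2\pi f$, so $k^2$ values for
0.1 um pixels span up to ~987 um^-2 with fitting customarily restricted
to $k^2 \le 200$ um^-2.

`temporalCorrelation()` averages $\tilde I(\mathbf k, t)\,
\tilde I^*(\mathbf k, t+\tau)$ over all $n - \tau$ frame pairs, computed
as a zero-padded FFT cross-correlation along time (algebraically identical
to the direct pair sum; verified against it in the tests). The imaginary
residue, zero in expectation for stationary series, is kept as a
diagnostic and warns above 5% of the real part.

`circularAverage()` averages modes over annuli one frequency step wide up
to the Nyquist ring (128 bins for a 256 px frame), excluding DC; each
bin's center is the mean $k^2$ of its member modes, not the nominal ring
radius, avoiding a small-$k$ bias. `normalizeCF()` divides by the
$\tau = 0$ row and masks bins whose zero-lag power is below a relative
floor (1e-8) instead of amplifying noise.

No windowing/apodization is applied before the FFT: simulated periodic
frames do not need it, and cropped experimental frames accept the leakage,
consistent with how such crops are analyzed in practice.

# Numerical choices in the fitting

* Per-lag two-component fits use the bare Levenberg-Marquardt driver
  (`minpack.lm::nls.lm`) with bounds $A \in [0, 2]$, $g \ge 0$. The
  wrapped `nls` interface is avoided deliberately: it rebuilds an `nls`
  model object at the solution and fails on the legitimate degenerate
  endpoint where one amplitude converges to zero.
* Multi-start: each lag tries the previous lag's solution (lags are fitted
  from the largest lag downward, where the components are well separated)
  plus three spread seeds derived from the global single-exponential
  slope; the lowest-residual solution wins.
* Per-lag exponent standard errors come from the LM normal-equations
  matrix and provide inverse-variance weights for the lag-trend
  regressions.
* A lag is flagged `separated` only when both amplitude fractions are at
  least 1% and $g_M > 1.2\, g_\mu$. Near-degenerate lags (very early, when
  the exponents have not diverged; very late, when the macro correlation
  has fully decayed) carry an arbitrary component split and are excluded
  from the trend fits and saturations.
* Default windows: the early window is the first 12 separated lags, the
  late window the last 25%; both are configurable, and both are reported
  inside the returned object.
* The plateau uses a more robust per-lag fallback chain: a resolved micro
  exponent (above the window resolution floor $0.05/k^2_{max}$) counts
  directly; a lag whose exponents agree within 20% contributes their
  common value (the two components have merged into one effective decay);
  a lag whose unresolved component is pinned at zero with under 30% of
  the amplitude contributes the dominant exponent (the minor component is
  then the flat high-k tail of the static domain structure, not a decay).
  This matters because for domain radii >= 0.3 um under the size-adapted
  frame time, the macro decay per lag is commensurate with the
  static-domain lobe width and the two-Gaussian decomposition genuinely
  merges — at full problem size as well as at reduced size.
* `fitSingleSpecies` drops non-positive CF values before taking logs and
  weights by $r^2$; `fitTwoComponent` requires at least 8 usable bins and
  raises a `FitError` if more than half the lags fail.

# Static domain structure: what the late-lag CF really measures

Static domains with elevated occupancy imprint a time-independent spatial
pattern on the images. Its power does not decay with $\tau$, so the
normalized CF converges at late lags to the static fraction of each
mode's power, and the micro component's saturated exponent measures the
k-space width of that static structure — which is exactly why
$\mathrm{Plateau}_\mu$ tracks the domain area. The same fact explains two
desk-scale behaviors worth knowing: at low $k$ the static pattern
dominates ($\beta^2 N / n_{domains}$ is ~6 under the default scenario), so
the macro component is a small additive decay on a large static baseline;
and beyond the static lobe the disc form factor's non-Gaussian tail can
capture one fit component (the pinned-at-zero case handled by the plateau
fallback above).

# Known limitations

* **$D_M$ at reduced scale.** The asymptotic slope of $g_M(\tau)$ equals
  the free-segment $D_{out}$ in every scenario; the confinement-induced
  suppression of $D_M$ lives in the early crossover lags where the
  components are barely separated, and its replicate scatter at the
  problem sizes used in the test suite (9.6-14.4 um regions, 400-1000
  frames) is comparable to the trend amplitude across sweeps. The
  saturation amplitudes and $\beta$ are far better powered and carry the
  same confinement ordering.
* **No pixel-quantization floor.** Because rendering is exact in
  sub-pixel position, the zero-radius extrapolation of the plateau tends
  to zero rather than to one pixel area; a simulator that bins particle
  positions to pixels before convolving with the PSF produces a
  pixel-area floor instead. Sub-resolution domains still produce a
  saturated, radius-independent length scale here (the optical and
  sampling limit), just with a smaller intercept.
* **Experimental data.** Reading a measured TIFF stack requires the pixel
  size and frame time as arguments; EMCCD gain, readout noise and
  photophysics are not modeled.

# Problem sizes used by the tests and the acceptance script

Unit and property tests simulate 6.4-21 um regions with 30-1000 retained
frames. The acceptance suite uses a 14.4 um region (144 px), 1000
retained frames and the central 128 px for the free-diffusion recovery
and the radius sweep (two to three seeds per radius), and a 9.6 um region with 400
retained frames and eight seeds per value (median-aggregated) for the
D_out/D_in, area-fraction and P_in/P_out trend sweeps. The P_in grid
stops at 0.8 (P_out = 0.2): at P_in/P_out = 9 the macro component is no
longer resolvable at this problem size and roughly half the replicate
runs yield no two-component decomposition at all. These sizes hold
the replicate scatter of the saturation amplitudes and beta to a few
percent; the full reference scenario (30 um, 2000 retained frames) runs
in a few minutes through `runFull()` if desired.

# A worked run

```{r}
cfg <- readRunConfig(NULL, list(
  simulation = list(region_px = 144L, n_frames = 1100L,
                    burn_in_frames = 100L, seed = 5L),
  analysis = list(max_tau = 60L, crop_px = 128L)))
res <- runFull(cfg, "ckics_demo")
res$parameters
betaMean(res$beta)
```
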