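# ckics — confinement k-space image correlation spectroscopy

`ckics` measures how membrane proteins diffuse in heterogeneous 2D
environments — free diffusion interrupted by trapping in static
microdomains — from ordinary fluorescence-microscopy image time series.
It implements confinement k-space image correlation spectroscopy (c-kICS)
end to end:

* a Brownian-dynamics **simulator** of particles partitioning in and out
  of static circular domains (diffusion coefficients `D_in`/`D_out`,
  boundary-crossing probabilities `P_in`/`P_out`, domain radius and area
  fraction, periodic boundaries, burn-in to partitioning steady state);
* a **fluorescence image synthesizer** (Gaussian PSF of e⁻² radius ω₀
  evaluated at exact sub-pixel particle positions, additive white
  background noise with SN = 1/noise, central-region cropping, float TIFF
  I/O);
* the **kICS correlation pipeline**: per-frame spatial FFT (angular
  wavenumbers, k = 2πf), temporal correlation over all frame pairs,
  circular averaging over Nyquist annuli, zero-lag normalization;
* the **confinement fits**: for one free species,
  r(k², τ) ∝ exp(−k²(Dτ + ω₀²/4)) inverted by weighted log-linear fits;
  for confined systems, per-lag two-component fits
  A_M e^(−k² g_M) + A_μ e^(−k² g_μ) whose lag trends yield the c-kICS
  parameters: macro and micro diffusion coefficients **D_M**, **D_μ**
  (μm²/s), the micro-component plateau **Plateau_μ** (μm², with effective
  confinement radius 2·√Plateau_μ), and the amplitude saturations
  **Sat A_M**, **Sat A_μ**; plus the ground-truth partition coefficient
  **β** and the effective diffusion law D_eff = D_free(1 − β).

## Worked example

Simulate the default confined scenario at reduced size, render, correlate
and fit:

```r
library(ckics)

cfg <- simulationConfig(regionPx = 144L, nFrames = 1100L,
                        burnInFrames = 100L, seed = 5L)
run    <- simulateConfinedDiffusion(cfg)          # trajectories + domains
series <- cropCenter(renderSeries(run$trajectories), 128L)
res    <- analyzeImageSeries(series, maxTau = 60L)
res$parameters
#> ConfinementParameters:
#>   D_M  0.008915 um^2/s   D_mu 0.0001234 um^2/s
#>   Plateau_mu 0.004982 um^2 (effective radius 0.141 um)
#>   Sat A_M 0.101   Sat A_mu 0.899
#>   windows: early lags 8-19, late lags 44-54
betaMean(partitionCoefficient(run$trajectories, run$domains))
#> [1] 0.455865
```

Read: particles free between trappings move at D_M ≈ 0.0089 μm²/s (below
the set D_out = 0.01 because of trapping, above D_in = 0.001); motion at
domain scale is nearly stalled (D_μ ≈ 1e-4); the micro component
saturates at ~0.005 μm², an effective confinement radius of ~0.14 μm for
the 0.2 μm domains; and ~90% of the correlation amplitude at late lags
sits in the confined component, consistent with β ≈ 0.46.

`runFull(config, dir)` writes the whole artifact set (TIFF stack, CF and
per-lag fit tables, parameter JSON, β series, provenance record);
`runSweep()` reruns the pipeline over one simulation parameter with
deterministic per-replicate seeds. A command-line wrapper with
`simulate / render / analyze / full / sweep / fixtures` subcommands is in
`inst/scripts/ckics.R`.

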