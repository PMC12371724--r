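---
title: "Methods: process design and particle sizing for SNaP microparticles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: process design and particle sizing for SNaP microparticles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snapmp)
```

Sequential nanoprecipitation (SNaP) makes polymeric microparticles in two
continuous mixing steps: a first micromixer precipitates polymer cores out of
an organic stream into antisolvent, the cores grow by Brownian aggregation
while the stream transits a delay channel, and a second mixer adds stabilizer
that arrests growth. Particle size is therefore set by two levers — the core
stream concentration `C_core` and the delay time `T_d` — as long as the
process stays inside its stable operating window. This package implements the
quantitative side of that picture: solution-property calculators that define
the window, image-based sizing that measures the outcome, growth-law fits
that test the mechanism, and drug-loading/release metrics for the resulting
particles.

## The process model

**Solution viscosity.** The intrinsic viscosity of the core polymer comes
from the Mark–Houwink–Sakurada power law $[\eta] = K M^a$ and enters a
Huggins expansion for the solution viscosity,
$\eta = \eta_s (1 + [\eta]c + k_H [\eta]^2 c^2)$, truncated at second order.
The expansion is a dilute/semi-dilute description: it is meaningful below the
overlap concentration and should not be extrapolated above it. Two choices
matter:

* *Concentration basis.* `c` is the **polymer-only** concentration by
  default (`core_polymer_concentration()`), i.e. the polymer mass fraction
  times total dissolved solids: small-molecule dye or drug adds solids but
  essentially no viscosity. For a formulation carrying 2 wt % dye at 40
  mg/mL total solids, the polymer concentration is 39.2 mg/mL. A `basis =
  "total"` switch is provided for sensitivity analysis.
* *Huggins coefficient.* `k_H = 0.3`, the conventional good-solvent value;
  it is exposed as an argument everywhere it appears.

**Chain dimensions and the stability boundary.** The ideal-chain radius of
gyration $R_g = \sqrt{N b^2 / 6}$ (N Kuhn segments of length b) feeds the
coil overlap concentration $C^* \simeq 3M / (4 \pi N_A R_g^3)$. Above
$C^*$ chains entangle and precipitation no longer proceeds through individual
collapsed globules; the package treats $C^*$ as the hard upper boundary of
the operating window. For the reference 17.5 kDa PLA (N = 121, b = 8.81 Å)
these give $R_g \approx 39.6$ Å and $C^* \approx 112$ mg/mL.

**Delay time.** `delay_time()` is pure plug-flow arithmetic: fixed channel
volume plus tubing cross-section × length, divided by the summed stream flow
rates, reported in ms. Tubing is described by inner diameter (mm) and length
(cm) — deliberately not by "cross-sectional area", to avoid clashing with
the Mark–Houwink exponent in configuration files.

**Growth prediction.** Diffusion-limited (Smoluchowski) aggregation of core
material at mass concentration C in a medium of viscosity $\eta$ gives
$R = (t\,k_B T\,C / (\pi \eta \rho))^{1/3}$. Internally everything is
converted to SI; the interface stays in ms, mg/mL, mPa·s and µm. Three
ambiguities are resolved as explicit parameters rather than silently:

* *Temperature* defaults to 298.15 K (ambient operation).
* *Which viscosity?* The organic-stream solution viscosity is the default
  choice (`design_summary()` wires it through automatically), but
  `growth_conditions()` accepts any caller-supplied value, since the medium
  in the delay channel is a solvent/antisolvent mixture whose viscosity is
  not directly measured.
* *Which concentration?* A `dilution` factor (default 1, i.e. the organic
  stream value) divides `C_core` to represent post-mixing dilution.

The prediction's value is its **scaling**: radius grows with the cube root
of time and concentration, and inversely with the cube root of viscosity
(`test` suite asserts these to 1e-12 relative). Absolute magnitudes depend
on nucleation details the model does not contain, so the package never fits
the prefactor to measured sizes — the collapse fit below is linear-empirical
instead.

## Image-based sizing

Micrographs of SNaP particles show bright, highly spherical discs, often
partially occluding each other. `detect_particles()` implements a circular
Hough transform: image gradients are computed by central differences, pixels
above `edge_sensitivity` (default 0.25 of the maximum gradient magnitude)
vote along their gradient direction — which for a bright particle on a dark
background points toward the disc center — into one accumulator slice per
candidate radius (1 px steps). Slices are box-smoothed, scores are
normalized by circumference so radii compete fairly, and the best radius is
kept per pixel. Candidate peaks are taken above `accumulator_threshold`
(default 0.15 of the strongest peak) with an absolute perimeter-support
floor (`min_support`, default 0.3) so a blank noisy frame yields no
detections. Greedy non-maximum suppression enforces
`min_center_separation` (ties: higher score, then smaller radius), and each
surviving candidate is refined by an algebraic least-squares circle fit to
the edge pixels that support it, giving sub-pixel radii (the 1 px
accumulator step alone would floor the radius error at ~0.5 px). The
decisive acceptance test is then geometric rather than vote-based: a
detection is kept only if aligned edge pixels cover at least
`min_arc_coverage` (default 0.55) of its refined perimeter. This two-stage
design — a permissive accumulator gate followed by a strict arc-coverage
filter — was calibrated on the package's synthetic occluded fields: a
single conservative accumulator cut (e.g. 0.4 of the maximum, a sensible
default for clean scenes) silently drops heavily occluded particles, while
raw-vote thresholds loose enough to keep them admit phantom circles;
perimeter coverage separates the two cleanly because an occluded true
circle still exposes a long coherent arc. Detections whose refined radius
leaves the search range are dropped rather than clamped, which would bias
the distribution.

Pooled diameters (per-image scale × 2 × radius) are summarized by
`size_distribution()`; the polydispersity index is the relative variance
$\sigma^2/D^2$ using the **population** variance — with the recommended
≥ 2000 pooled particles the sample/population distinction is far below
reporting precision, and the population form keeps the PDI an exact moment
ratio of the data in hand.

## Growth-law fitting and regimes

`fit_growth_exponent()` is unweighted OLS of log radius on log delay time
per concentration — unweighted because batch means, not replicate-level
data, are what size tables report; replicate SDs are carried for display
only. The slope is invariant to fitting radius versus diameter and to the
logarithm base (asserted numerically), so neither choice needs to be
standardized. `collapse_fit()` regresses diameter on
$(T_d \cdot C_{core})^{1/3}$ **with** an intercept: forcing the line
through the origin is a physical statement (zero size at zero time) that
measured nucleation offsets do not support, and the intercept lets the data
say so. `estimate_growth_exponent()` pools concentrations with a shared
slope and per-concentration intercepts; it is the dataset-level estimator
used in parameter-recovery checks.

`classify_regime()` places a concentration on the phase diagram:
at or above $C^*$ the process is unstable (macroscopic precipitates);
within 85 % of $C^*$, or when the observed growth exponent falls below
0.15, size decouples from delay time (entanglement onset); otherwise growth
is diffusion-limited. The 0.85 and 0.15 thresholds are package choices
consistent with observed behaviour near and above the boundary — a system
following the cube-root law shows exponents near 0.33, a decoupled one near
0.03, so any cutoff well separated from both (0.10–0.20) classifies
identically; both are arguments.

## Drug metrics

Loading is drug mass over total solids (wt %), encapsulation efficiency is
loading over target loading, and cumulative release is released
concentration over initial concentration per time point. Release values are
**not** clamped to 100 % and are allowed to decrease between time points
(sampling an agitated dispersion is noisy); a decrease triggers a warning
rather than an error, because silently "repairing" a measured curve hides
exactly the artifact a scientist should see.

## What the synthetic generators emulate — and what they do not

`generate_micrograph()` renders anti-aliased discs with a ~2 px soft edge
ramp (emulating secondary-electron edge gradients), per-disc brightness
jitter, rejection-sampled placement with a pairwise occlusion cap (default
30 % of a disc's area), and additive Gaussian background noise clipped to
valid intensities. It returns the exact ground-truth circle table and is
bit-deterministic per seed. It does **not** model SEM charging, astigmatism,
focus gradients, non-spherical aggregates or particles cut by the frame —
so a passing detection suite demonstrates the algorithm's geometric
correctness under realistic crowding and noise, not robustness to every
instrumental artifact of real micrographs.

`generate_growth_dataset()` produces batch-mean diameters on
$2(k\,t\,C)^{e}$ with multiplicative lognormal noise of unit mean per
replicate (default CV 5 %, three replicates, the 3 × 3 concentration ×
delay-time grid at 40–80 mg/mL and 30–90 ms that a size-tuning study
uses). The default prefactor $k = 4.3 \times 10^{-4}$ places diameters in
the 1.5–3 µm range those conditions produce.

`simulate_aggregation()` is a Marcus–Lushnikov constant-kernel coalescence
process: every cluster pair merges at the same rate (2/n per pair), total
mass is conserved exactly at every event, and mean cluster mass grows
linearly in time in the scaling regime, so the mass-equivalent radius
$m^{1/3}$ grows as $t^{1/3}$. The constant kernel is chosen deliberately:
it reproduces the same cube-root radius growth as the full Brownian kernel
with far simpler dynamics, making it an independent *oracle* for the
exponent — it is not a physical simulator of precipitation.
`aggregation_exponent()` regresses over mean masses between 10 and a tenth
of the monomer count, where the process has forgotten its initial condition
but finite-size depletion has not yet bent the trajectory.

## Problem sizes and numerical choices in the test suite

The shipped tests run the image pipeline on eight 1024 × 768 fields of 260
particles (≈ 2100 pooled particles, matching the ≥ 2000-particle pooling
the sizing methodology calls for), 200 seeded growth-dataset recoveries,
and coalescence trajectories of 10^4 monomers — sizes chosen so each
property is measured with comfortable statistical margin while the whole
suite runs in well under a minute per stage on one core. Exact identities
(scaling laws, mass conservation, PDI scale invariance) are asserted to
1e-12 relative; statistical recoveries use the margins stated in the test
descriptions (recall ≥ 0.95, exponent within ±0.05, PDI within 0.05).

## Known limitations

* No mixing-geometry CFD: the package flags `C_core` against `C^*` but does
  not predict the viscosity-dependent failure of less robust mixer
  geometries.
* The Hough detector assumes near-circular projections; elongated or fused
  aggregates are not segmented (they are exactly what the regime
  classification is meant to help avoid).
* Release kinetics are summarized empirically (burst + sustained rate); no
  mechanistic matrix-diffusion model is fitted.

## A worked example

```{r example, eval = FALSE}
cfg <- read_design_config(
  system.file("extdata", "pla_design.yaml", package = "snapmp"))
report <- run_report(cfg)
report$design
tidy(report$growth)
glance(report$growth)
```
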