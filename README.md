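# snapmp

Quantitative tools for **Sequential NanoPrecipitation (SNaP)** microparticle
manufacture — a continuous two-mixer process in which polymer cores
precipitate in a first micromixer, grow by Brownian aggregation during a
controlled delay, and are arrested by stabilizer in a second mixer. Particle
size is tuned by the core stream concentration `C_core` and the inter-mixer
delay time `T_d`, provided the process stays inside its stable operating
window. The package is written for formulation and process scientists who
want to design such runs, size the resulting particles from SEM images, and
test whether their data follow diffusion-limited growth.

It provides four connected toolsets, plus seeded synthetic-data generators
so every stage can be exercised with known ground truth:

* **Process design** — intrinsic viscosity `[η] = K·M^a`
  (Mark–Houwink–Sakurada) and solution viscosity
  `η = η_s(1 + [η]c + k_H[η]²c²)` (Huggins); ideal-chain radius of gyration
  `R_g = √(N b²/6)` and coil overlap concentration
  `C* ≃ 3M/(4π N_A R_g³)`; plug-flow delay time; the Smoluchowski
  diffusion-limited growth radius `R = (t k_B T C / (π η ρ))^{1/3}`; and
  mass throughput.
* **Image-based sizing** — circular Hough transform detection of spherical
  particles in grayscale micrographs (robust to partial occlusion), pooling
  across fields of view, and the polydispersity index `PDI = σ²/D²`.
* **Growth-law analysis** — per-concentration log–log slope fits (1/3 under
  diffusion-limited growth), the `(T_d·C_core)^{1/3}` scaling collapse, and
  classification of concentrations into diffusion-limited / entanglement
  onset / unstable regimes relative to `C*`.
* **Drug metrics** — drug loading (wt %), encapsulation efficiency (% of
  target), cumulative release curves and burst/sustained summaries.

Everything is tibble-in / tibble-out and pipe-friendly, with
`tidy()`/`glance()` methods for fitted objects and `autoplot()` methods for
the main result types.

## Worked example

The bundled configuration describes 17.5 kDa PLA in THF (2 wt % dye in the
solids) feeding a dual-inlet vortex mixer through a 30 ms delay channel at
2 × 60 mL/min, together with a measured size table (four concentrations ×
three delay times):

```r
library(snapmp)
cfg <- read_design_config(
  system.file("extdata", "pla_design.yaml", package = "snapmp"))
report <- run_report(cfg)

report$design
#> # A tibble: 1 × 9
#>   intrinsic_viscosity_ml_g viscosity_mpas rg_angstrom c_star_mg_ml delay_time_ms
#>                      <dbl>          <dbl>       <dbl>        <dbl>         <dbl>
#> 1                     23.1          0.989        39.6         112.          30.0
#>   predicted_radius_um predicted_diameter_um throughput_g_h regime
#> 1               0.108                 0.217            144 diffusion_limited

tidy(report$growth)
#> # A tibble: 4 × 6
#>   c_core  slope intercept r_squared     n regime
#>    <dbl>  <dbl>     <dbl>     <dbl> <int> <chr>
#> 1     40 0.303     -1.27      0.961     3 diffusion_limited
#> 2     60 0.261     -0.935     0.986     3 diffusion_limited
#> 3     80 0.314     -1.08      0.958     3 diffusion_limited
#> 4    100 0.0345     0.236     0.758     3 entanglement_onset
```

Reading the output: the 40 mg/mL organic stream has viscosity 0.989 mPa·s
(the same model gives 2.21 mPa·s at 100 mg/mL — a doubling that matters for
mixer choice); the chain dimensions put the overlap concentration at
112 mg/mL, so 40 mg/mL sits safely in the diffusion-limited regime while
100 mg/mL is flagged as entanglement onset — visible in the fits, where
40–80 mg/mL show log–log slopes near 1/3 but 100 mg/mL shows 0.03 (size
decoupled from delay time). The collapse of the 40/60/80 data onto
`(T_d·C_core)^{1/3}` achieves r² = 0.965 (`glance(report$growth)`). At
60 mL/min core flow the process delivers 144 g/h of particles. The
predicted Smoluchowski radius documents the cube-root scaling; absolute
sizes also depend on nucleation, which the package deliberately does not
fit.

Sizing synthetic (or real) micrographs:

```r
g <- generate_micrograph(micrograph_spec(particle_count = 300, seed = 1))
det <- detect_particles(g$micrograph,
                        detection_params(radius_min = 8, radius_max = 40))
pool_distributions(det)
#> <snap_size_distribution> n = 294, mean 1.995 um, sd 0.384 um, PDI 0.037
```

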