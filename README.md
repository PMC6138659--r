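# netphases

Quantitative single-cell analysis of NETosis — the programmed death of
neutrophils that ends with the expulsion of chromatin as a neutrophil
extracellular trap (NET) — from chromatin-stained time-lapse microscopy
and AFM force spectroscopy.

The projected chromatin area *A(t)* of a stimulated neutrophil dissects
NETosis into three phases: **P1** (activation; intact lobulated nucleus,
constant area, 0 → *t*₁), **P2** (chromatin expansion and cell rounding,
*t*₁ → *t*₃, with maximal intracellular expansion at *t*₂ and the end of
the uniform expansion at *t*_D), and **P3** (membrane rupture and NET
release after *t*₃). The package is written for biophysicists and
quantitative cell biologists who want to run this analysis — or validate
variants of it — on area-time traces and force curves:

- **Segmentation** (`segment_chromatin()`, `extract_traces()`): edge
  carving (Sobel + Otsu), morphological closing and filling, half-maximum
  boundary refinement; areas are pixel counts × pixel_size², intensity is
  normalised per trace.
- **Phase detection** (`detect_phases()`): a deterministic changepoint
  algorithm replacing the manual assignment of *t*₁, *t*_D, *t*₂, *t*₃,
  with population classification (population 1: *t*₂ ≠ *t*₃; population
  2: rupture at maximal expansion) and sub-frame refinement.
- **Swelling biophysics** (`fit_diffusion()`, `swelling_pressure()`,
  `arrhenius_activation_energy()`, `laplace_pressure()`,
  `rupture_delay_analysis()`): the expansion as a 2D diffusion process
  *A* ≈ 4*Dt*; the entropic swelling pressure
  *p*(*t*) = η(*R*)/*l_p*² · d*R*/d*t* · *R* with η(*R*) = η₀(R₀/R)³ and
  the cubic-lattice mesh size *l_p* = √(*V*/*L*) for the ~2 m genome;
  Arrhenius activation energy of P1; Young–Laplace membrane pressure
  *p* = 2*T*/*R*; 2D KDE and exponential contour of the
  pressure/size–rupture-delay relationship.
- **AFM mechanics** (`fit_hertz_pyramidal()`, `grid_modulus()`,
  `detect_tether_steps()`, `tether_tension()`,
  `constant_height_pressure()`): pyramidal-tip Hertz fits
  *F* = *E*/(1−ν²)·tan α/√2·δ², centre+4-neighbour grid averaging,
  tether tensions *T* = *F*²/(8*B*π²), and constant-height swelling
  pressure *p*(*t*) = *F*(*t*)/*A* with mirror-reset stitching.
- **Rupture geometry** (`velocity_field()`, `fit_cell_ellipse()`,
  `retraction_speeds()`, `rupture_angle()`, `predict_rupture_point()`):
  chromatin velocity fields on 15×15 px windows, second-moment ellipse
  fits, rupture-axis retraction speeds, rupture-angle statistics and
  rupture-point prediction from areas of slow chromatin movement.
- **Synthetic data** (`cohort_config()`, `generate_cell_trace()`,
  `render_movie()`, `generate_cohort()`, `generate_force_data()`): a
  calibrated generator of movies, cohorts and AFM signals with ground
  truth for every downstream stage (the study's imaging data are not
  publicly deposited).

## Worked example

Simulate one cell, analyse it end-to-end, and compute its biophysics:

```r
library(netphases)

cfg <- cohort_config(seed = 42)          # the study-calibrated defaults
sim <- generate_cell_trace(cfg, 1)       # trace + ground truth
stk <- render_movie(sim$trace, sim$truth, cfg,
                    t_max = sim$truth$t3_min + 16)
tr  <- extract_traces(stk)[[1]]          # segment the movie back
ann <- detect_phases(tr)
ann
#> NETosis phase fit
#>   t1 = 64.73 min, tD = 81.00 min, t2 = 93.55 min, t3 = 125.39 min
#>   P1 = 64.73 min, P2 = 60.66 min, rupture delay = 31.85 min, population 1

fit_diffusion(tr, ann)$D1_um2_per_s      # free-expansion diffusion constant
#> [1] 0.01097
attr(swelling_pressure(tr, ann), "pressure_at_t2_Pa")
#> [1] 1.03
```

The detected time points match this cell's ground truth (t1 = 64.59,
t2 = 93.74, t3 = 125.84 min) to within half a frame; the diffusion
constant recovers the configured 0.0108 µm²/s within 2% at default
imaging noise (within 1% on a noiseless trace), and the ~1 Pa swelling
pressure at maximal expansion is the model's order-of-magnitude scale
for a cell of this size.

Closed-form estimates need no simulation:

```r
arrhenius_activation_energy(227.5, 296.65, 55.0, 310.15)  # P1 durations
#> [1] 80.45        # kJ/mol — enzyme-catalysed kinetics in P1
laplace_pressure(0.07e-3, um_to_m(effective_radius(151)))
#> [1] 20.2         # Pa — membrane pressure from late-P2 tension
```

A full cohort (`run_pipeline(pipeline_config(seed = 42))`) simulates,
segments and annotates 139 cells and reports cohort means ± SEM of the
three time points, the diffusion constant and the pressure at *t*₂.

## Package layout

```
R/                 implementation (one file per analysis stage)
tests/testthat/    unit, property and acceptance tests
scripts/           acceptance script
vignettes/         methods vignette: models, calibration, design choices
```
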