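# tendondti

Simulation toolkit relating the collagen-fiber microstructure of tendon
and ligament to diffusion tensor MRI (DTI) metrics.

DTI is increasingly used to assess dense connective tissue
non-invasively, but what a change in mean diffusivity (MD), axial/radial
diffusivity (AD/RD) or fractional anisotropy (FA) *means* at the fiber
level is unclear: tendon fibers are ~50 um wide, diffusion times must stay
short to preserve signal, and water diffuses both inside fibers and in the
interstitial space between them. `tendondti` answers this with a
simulation pipeline:

1. **Geometry** — crimped square-lattice unit cells
   (`build_unit_cell`) and dispersed intersecting-cylinder voxel domains
   (`build_dispersed_domain`) whose polar angles follow the transversely
   isotropic von Mises distribution matched to the
   Holzapfel–Gasser–Ogden dispersion parameter kappa in [0, 1/3]
   (`kappa_to_concentration`, `sample_orientation`), plus a sampler
   emulating microscopy-derived parameter statistics (`sample_shg_params`).
2. **MRI** — a Monte-Carlo random-walk solver for the Bloch–Torrey
   dynamics of a two-compartment system (fiber water: D = 1 um^2/ms,
   T2 = 20 ms, water fraction 0.22; interstitial water: D = 2, T2 = 62,
   fraction 1) with impermeable membranes and phase-consistent periodic
   boundaries, under a PGSE sequence (delta = 4 ms, Delta = 10 ms,
   b = 400 s/mm^2 = gamma^2 G^2 delta^2 (Delta − delta/3), TE = 18 ms,
   12 directions + b0): `simulate_dwi`, `simulate_signal`.
3. **DTI** — log-linear least-squares tensor fit and the scalar metrics
   MD = (λ1+λ2+λ3)/3, AD = λ1, RD = (λ2+λ3)/2 and FA:
   `fit_tensor`, `compute_metrics`.
4. **Sensitivity** — Saltelli sampling (2N(p+1) rows on a scrambled Sobol
   sequence) and Jansen/Saltelli Sobol index estimators with bootstrap
   CIs: `saltelli_sample`, `sobol_indices`.
5. **Models & studies** — the closed-form FA–kappa mappings
   (`direct_mapping_fa`: AD/RD = (1−2κ)/κ; `dispersed_mg_fa`:
   AD/RD = 3κ + (1+ν)(1−3κ), Maxwell–Garnett radial diffusion) and the
   orchestrated experiments `run_sensitivity_study`,
   `run_dispersion_study`, `compare_fa_models`.

## Worked example

Simulate a dispersed fiber network (volume fraction 0.85, fiber diameter
50 um, dispersion kappa = 0.05) and fit the tensor:

```r
library(tendondti)
set.seed(11)
dom <- build_dispersed_domain(50, 0.85, 0.05, dims = c(150, 150, 300), dx = 2)
volume_fraction(dom)
#> [1] 0.8447336
cfg <- solver_config(dom, n_walkers = 3e5, seed = 21)
dwi <- simulate_dwi(dom, seq = pgse_sequence(), cfg = cfg)
summary(fit_tensor(dwi))
#> DTI metrics: MD = 1.32  AD = 1.496  RD = 1.232  FA = 0.1152
```

MD ≈ 1.3 um^2/ms and FA ≈ 0.12: even at only 5% dispersion the diffusion
tensor is far more isotropic than the fiber orientation distribution. The
closed-form models at the same condition predict much higher anisotropy —
`direct_mapping_fa(0.05)` → 0.87, `dispersed_mg_fa(0.05, 0.85)` → 0.33 —
because both neglect the radial mobility of water inside ~50 um fibers at
short diffusion times. `compare_fa_models(run_dispersion_study(...))`
tabulates this gap across a kappa grid, and
`plot(fa_model_curves(0.85), add_sim = ...)` reproduces the three-curve
comparison figure.

The sensitivity experiment works the same way at configurable scale:

```r
st <- run_sensitivity_study(N = 64, n_walkers = 2e4, seed = 5)
st$indices$md$first_order
#>          parameter      S1     ST ST_conf
#> 1         diameter  0.0089 0.1007  0.0297
#> 2          spacing  0.8875 0.9571  0.2680
#> 3 crimp_wavelength -0.0661 0.0355  0.0189
#> 4     crimp_height -0.0386 0.0313  0.0138
```

MD variance is dominated by fiber spacing, and both crimp parameters are
near-irrelevant — crimp morphology is essentially invisible to DTI at
these encoding parameters.

## Notes

The methods vignette (`vignettes/tendondti-methods.Rmd`) documents the
solver contracts, the kappa convention, numerical tolerances, the
desk-scale presets versus the full-scale study designs, and known
limitations — including a two-compartment weighting regime in which
square-lattice conditions are interstitial-dominated, which materially
affects which microstructural parameters DTI metrics respond to.
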