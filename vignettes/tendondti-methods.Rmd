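---
title: "Simulating diffusion tensor MRI of tendon microstructure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating diffusion tensor MRI of tendon microstructure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(tendondti)
```

## The problem

Tendon and ligament are dense, highly organized collagen tissues. Diffusion
tensor imaging (DTI) infers microstructure from the directional attenuation
of the MR signal by water diffusion, but the mapping from fiber-level
geometry (diameter, spacing, crimp, dispersion) to the four DTI metrics —
mean diffusivity (MD), axial diffusivity (AD), radial diffusivity (RD) and
fractional anisotropy (FA) — is not obvious at tendon length scales, where
fibers are tens of micrometres wide and clinically usable diffusion times
are short. `tendondti` closes that loop in silico: it synthesizes
fiber-network voxel domains, simulates a pulsed-gradient spin-echo (PGSE)
acquisition over them, fits the diffusion tensor, and asks which
microstructural parameters the DTI metrics actually respond to.

## The two-compartment signal model

Each voxel domain is biphasic: collagen fibers (label 1) embedded in
interstitial water (label 0). Each compartment carries its own diffusivity,
transverse relaxation time and mobile water fraction:

| compartment        | D (um^2/ms) | T2 (ms) | water fraction |
|--------------------|------------|---------|----------------|
| collagen fiber     | 1          | 20      | 0.22           |
| interstitial water | 2          | 62      | 1              |

The fiber water fraction of 0.22 reflects that most of the fiber volume is
collagen molecule and tightly bound water whose T2 is far too short to
survive an 18 ms echo; those pools are not simulated. Membranes between the
compartments are impermeable: a water molecule never changes compartment,
so each compartment's transverse magnetization evolves independently and
the voxel signal is the weighted sum of the two.

The default acquisition is a single-shell PGSE protocol: gradient lobes of
duration delta = 4 ms separated by Delta = 10 ms, b = 400 s/mm^2
(equivalently 0.4 ms/um^2), echo time TE = 18 ms, 12 diffusion-encoding
directions plus one b0 measurement. The gradient amplitude follows
Stejskal-Tanner, `b = gamma^2 G^2 delta^2 (Delta - delta/3)`, about
0.2 T/m at these settings. The direction set is a deterministic
electrostatic-repulsion design on the hemisphere; any well-spread set of at
least six non-collinear directions determines the tensor, and
`fit_tensor()` accepts arbitrary sets.

## The random-walk solver

The Bloch-Torrey dynamics are integrated by Monte-Carlo random walk:

* Walkers start uniformly over the domain; each carries the statistical
  weight `water_fraction * exp(-TE / T2)` of its starting compartment, so
  the b0 signal is exactly the relaxation-weighted density sum.
* Per time step each walker takes independent axis steps of length
  `sqrt(2 D dt)` with random sign. A step whose target voxel belongs to the
  other compartment is rejected for that axis only, which realizes a
  zero-flux (impermeable) membrane without suppressing diffusion parallel
  to the wall.
* Label lookup wraps periodically on all axes, while the positions entering
  the phase integral are never wrapped — the accrued phase is that of an
  infinite periodic medium, the phase-consistent analogue of periodic
  boundaries.
* The PGSE phase along direction g is `gamma G g . (I1 - I2)`, where I1 and
  I2 are the time integrals of position over the two gradient lobes
  (midpoint rule, fractional weights at lobe edges); the sign flip encodes
  the refocusing pulse placed midway between the lobes. T2 decay is applied
  over the full TE through the walker weights, including the image-formation
  window after the second lobe.

Because the phase is a linear functional of the per-walker lobe integrals,
one set of trajectories serves the b0 measurement and every gradient
direction. This common-random-numbers reuse cuts the cost of a 13-signal
acquisition by an order of magnitude and correlates the Monte-Carlo noise
across directions, which *reduces* the variance of fitted-tensor contrasts;
it is the same device grid-based solvers get for free.

Numerical choices:

* `dt = dx^2 / (24 Dmax)` by default, i.e. a per-step RMS displacement of
  half a voxel, capped at 125 us. For 1-um grids this is ~20.8 us; finer
  grids push dt below 20 us because boundary fidelity, not the nominal
  operating band, is the binding constraint.
* The per-axis rejection scheme biases near-wall propagators at
  O(step length); the dedicated convergence test verifies that restricted
  radial ADC error shrinks as dt (hence the step) is refined.
* Walker randomness comes from a package-internal xorshift128+ stream, so a
  given `solver_config(seed=)` is bitwise reproducible and independent of
  R's RNG state.
* Degenerate domains consisting of a single compartment are legal and are
  exactly the cases with closed-form signals, `S/S0 = exp(-b D)`; the test
  suite holds the solver to 2% there and to 0.5% on the b0 sum.

## Synthetic microstructure

**Square-lattice unit cells** (`build_unit_cell`): one fiber of diameter d
in a periodic cell of width d + s over one crimp wavelength. Crimp is a
sine displacement of the circular cross-section along x; *crimp height is
interpreted as the peak-to-peak excursion*, so the sine amplitude is
height/2 (the convention of crimp measurements in microscopy, where
"height" is the full band width). The per-slice cross-section stays
circular, which makes the per-slice area fraction z-invariant — a free
analytic check, as is the volume fraction `pi d^2 / (4 (d+s)^2)` and its
square-lattice ceiling of pi/4 ~ 0.785. The grid uses 40-60 voxels per
cross-section axis (~1 um), and the z extent is rounded to a whole voxel
count with the sine period taken over the rounded extent, keeping the cell
exactly periodic. When d + height exceeds the cell, the crimped fiber
overlaps its periodic images; the overlap is unioned and logged.

**Parameter emulator** (`sample_shg_params`): microscopy-derived reference
statistics (mean/SD: diameter 51/22.3 um, spacing 10.6/4.3 um, crimp
wavelength 64.3/15.9 um, crimp height 10.9/3.2 um) sampled as independent
truncated normals with a 0.1 um positivity floor. The emulator reproduces
marginal means and SDs; it deliberately ignores any correlation between
parameters (not available from summary statistics) and all spatial
heterogeneity of real tissue — passing tests show the pipeline responds
correctly to these marginals, not that real tendons are captured.

**Dispersed networks** (`build_dispersed_domain`): straight cylinders with
uniform random seed points, azimuth uniform in [0, 2 pi), and polar angle
theta drawn from the transversely isotropic von Mises density
`rho(theta) ~ exp(b cos 2 theta)` weighted by solid angle, folded onto the
hemisphere. The concentration b is obtained from the dispersion parameter
kappa of the Holzapfel-Gasser-Ogden (HGO) structure-tensor family by
inverting `kappa = (1/4) Int rho sin^3 theta dtheta` to 1e-6. This is the
one convention under which kappa = 1/3 is exactly isotropic and
`(1/2) E[sin^2 theta] = kappa` holds exactly, which the sampler tests
exploit. Fibers extend until they exit the domain (no geometric wrap — the
simulator's periodic phase handling stands in for tissue continuation),
are voxelized by the voxel-centre-in-cylinder rule, and may intersect;
placement stops when the voxelized volume fraction is within 0.01 of
target, with candidates that would overshoot rejected and redrawn, a cap of
1e6 attempts, and an error after 1000 consecutive rejections (a reliable
signal that the request is geometrically infeasible, e.g. very large fibers
in a small box at a tight tolerance).

The reference dispersed-study scale is 500 x 500 x 2000 um at 1 um
resolution with 5 replicates per condition — a compute-cluster workload.
The package's desk preset shrinks the domain to 150 x 150 x 300 um with 2
replicates; fiber-count statistics (~30 fibers per domain) are large
enough that replicate spread, not domain truncation, dominates the
variance, and the checks on this preset carry correspondingly widened
tolerances (15-20%). Resolution matters more than extent: at 2 um the
thin interstitial sheets between 50-um fibers at volume fraction 0.85 are
only 1-2 voxels wide, which reads as extra radial restriction and biases
FA down by ~0.02-0.03. Headline reproductions therefore keep the
reference 1 um grid on the reduced domain; the 2 um grid is reserved for
exploratory sweeps with smaller fibers (>= 15 voxels across a 30 um
fiber), where the trend structure, not the absolute FA, is of interest.

## Tensor fit and metrics

`fit_tensor()` solves `ln(S_i/S0) = -b g_i' D g_i` by ordinary log-domain
least squares — appropriate for noiseless simulated signals on a single
shell — and eigen-decomposes the symmetric result. Metrics follow the
standard definitions `MD = (l1+l2+l3)/3`, `AD = l1`, `RD = (l2+l3)/2`, and
the normalized eigenvalue-dispersion FA; a zero tensor has FA 0 by
convention, and negative eigenvalues (solver noise only) are clamped for FA
with a warning. For axially symmetric tensors FA reduces to
`(beta-1)/sqrt(beta^2+2)` with `beta = AD/RD`, the algebraic bridge to the
closed-form dispersion models, asserted to 1e-12 in the tests.

## Closed-form FA-dispersion models

Two single-parameter mappings predict FA from kappa:

* **direct mapping** — `AD/RD = (1-2 kappa)/kappa`: perfectly aligned
  fibers imply vanishing radial diffusivity, so FA(kappa→0) = 1 (handled as
  an explicit limit, not a division error).
* **dispersed Maxwell-Garnett** — `AD/RD = 3 kappa + (1+nu)(1-3 kappa)`:
  radial diffusion around aligned insulating cylinders at volume fraction
  nu follows the Maxwell-Garnett effective-medium estimate; at kappa = 0
  and nu = 0.85 this gives FA ~ 0.365.

Both curves are monotone non-increasing in kappa and coincide at the
isotropic point FA(1/3) = 0; the Maxwell-Garnett curve lies below the
direct mapping everywhere else. The simulations sit below both: at short
diffusion times the fiber-interior water still diffuses radially, so
measured FA at kappa = 0 is ~0.15, far from either model — the package's
central reproducible result (`compare_fa_models()`).

## Sobol sensitivity analysis

`saltelli_sample()` builds the radial Saltelli design (blocks A, B, AB_i,
BA_i; `2N(p+1)` rows with second-order estimation) on a digitally
scrambled Sobol sequence implemented in-package (Gray-code construction,
primitive-polynomial direction numbers, up to 10 dimensions; the scramble
is a per-dimension random XOR shift, which preserves equidistribution).
N must be a power of two — the sequence's balance properties collapse
otherwise, which is why the constructor rejects other values with
guidance. `sobol_indices()` uses the Jansen (1999) estimators for S1/ST
and the Saltelli (2002) estimator for S2, with percentile-bootstrap 95%
intervals over resampled base rows (1000 resamples by default). Small
negative estimates are reported as-is and only truncated at zero in plots.
The estimators are validated against the analytic Ishigami indices and
additive-model identities.

Note that any independent per-run noise (here, walker sampling noise)
enters every total-order index as an unattributable variance floor of
`var(noise)/var(output)`; the study presets size the walker count so this
floor sits well below the effect sizes of interest for MD and RD.

## Study orchestration and problem sizes

`run_sensitivity_study()` chains sampler → unit cell → PGSE simulation →
tensor fit → Sobol estimation, with optional CSV checkpointing for
resumable long runs and failed-row accounting (desk-scale runs abort on
NaN rather than silently dropping rows). `run_dispersion_study()` sweeps
(diameter, volume fraction, kappa) grids with replicate domains and
aggregates per-metric means and SDs. Default problem sizes are chosen so
the full test suite and the acceptance script complete on one CPU in
minutes: sensitivity at N = 128 with 1e4 walkers per cell, dispersion on
the desk preset with 2-3e5 walkers. The reference scales (N = 1024,
10,240 cells; 250 combinations x 5 replicates of 500 x 500 x 2000 um
domains) are recorded in `study_presets()` and run unchanged — only
longer.

## Known limitations

* The solver's per-axis rejection membrane is first-order accurate in the
  step length; sub-voxel surface curvature is voxelized. Both effects are
  controlled by the dt rule and verified by convergence tests, but very
  thin interstitial gaps (<2 voxels) will read as over-restricted.
* Thermal/MRI noise is deliberately absent: metrics are noiseless
  population values, not estimates from noisy magnitude images.
* Fibers are straight (dispersed networks) or sinusoidally crimped
  circular cylinders (lattice); splitting/merging fibers, diameter
  variability and magic-angle/bound-water relaxation effects are out of
  scope.
* Under the two-compartment weighting table above, the interstitial
  compartment dominates the square-lattice signal (~88% at the mean
  microstructure), so lattice DTI metrics are most responsive to the
  interstitial geometry (spacing); published reference values for
  lattice conditions that presuppose a fiber-dominated signal cannot be
  reached under this table, and the acceptance checks report that
  discrepancy honestly rather than re-weighting the compartments.

## A worked desk-scale comparison

```{r, eval = FALSE}
set.seed(1)
ds <- run_dispersion_study(kappas = c(0, 0.05, 0.1, 0.2, 1/3))
cmp <- compare_fa_models(ds, nu = 0.85, diameter = 50)
plot(fa_model_curves(0.85), add_sim = cmp)
```

At kappa = 0 the three FA values line up as simulation < Maxwell-Garnett <
direct mapping (~0.15 < ~0.37 < 1), the gap closing as kappa approaches
1/3 while the simulation retains a small residual anisotropy — diffusion
tensors in tendon-like geometry are substantially more isotropic than the
underlying fiber structure tensor.
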