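---
title: "Methods: broken-rod Kratky analysis and the CLEX reaction-diffusion model"
author: "brokenrod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: broken-rod Kratky analysis and the CLEX reaction-diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brokenrod)
```

## The scientific problem

When alginate gels with Ca²⁺, chains associate laterally into multi-chain
junction zones. In small-angle X-ray scattering the local structure of such
a gel behaves like a population of short cylindrical segments ("broken
rods"): over the window where the segment length is long against 1/q, the
scattering is dominated by the rod cross-section. In the Kratky
representation, `y(q) = q²I(q)`, a rod of cross-sectional radius `Rc`
produces

$$y(q) = q\,k\,\left[\frac{J_1(qR_c)}{qR_c}\right]^2,$$

a curve that rises linearly from the origin with slope `k/4` and peaks at
`q·Rc = x* ≈ 1.3566`, the positive root of `2x J0(x) = 3 J1(x)`. Thin single
chains (`Rc ≈ 0.2 nm`) put the peak far beyond the measured window
(0.103–3.26 nm⁻¹), so a dilute solution shows a linearly rising Kratky plot;
junction zones of radius 2.6–3.0 nm put it near `q ≈ 0.5 nm⁻¹`. A gelling
sample is modelled as the two-component mixture

$$q^2 I(q) = q\,k_1\!\left[\frac{J_1(qR_{c1})}{qR_{c1}}\right]^2
          + q\,k_2\!\left[\frac{J_1(qR_{c2})}{qR_{c2}}\right]^2 + \mathrm{const},$$

with `Rc1 < Rc2` by definition (thin chains first) and amplitudes `k1, k2`
proportional to the weight fractions of the two populations. The additive
constant lives in Kratky space exactly as written — it is *not* a flat
background in `I(q)`; this matters when buffer subtraction leaves a small
residual.

The package fits this model to every frame of a time-resolved series and
assembles `Rc1(t)`, `Rc2(t)` and `w2(t)`; a companion reaction–diffusion
module simulates how competitive ligand exchange (CLEX) releases Ca²⁺ at the
contact zone of two solutions and converts alginate into gel.

## Numerical treatment of the form factor

- `J1(x)/x` is evaluated by `besselJ` away from the origin and by its power
  series `1/2 − x²/16 + x⁴/384` for `|x| < 1e-4`, so the `q → 0` limit is
  analytic rather than 0/0.
- `kratky_peak()` scans a ≥2000-point grid and refines the maximum by
  derivative-free local search to `1e-4 nm⁻¹` — far below any physically
  meaningful shift over this q window. A curve that is non-decreasing across
  the window returns `NA` (peak outside range) rather than an edge value.
- Radii are restricted to `(0, 50] nm` everywhere. 50 nm is far above any
  junction-zone radius this model is meant for and the cap prevents runaway
  fits in which a huge rod mimics a constant.

## Per-frame fitting

Fits minimise the weighted squared residual in Kratky space with
`minpack.lm::nls.lm` under box constraints (`rc ∈ [0.05, 50] nm`,
`k ≥ 0`, `const ≥ 0`), with weights `1/σ_y²` when the profile carries
uncertainties and unit weights otherwise (the source data's treatment is not
stated, so weighting follows the information actually present). Convergence
tolerance is `1e-10` on the relative cost change. Component ordering is
enforced by a post-fit swap, which makes the result invariant to label
permutations of the starting point.

Two practical points dominate the robustness of this fit, and both are
consequences of the Kratky transform amplifying high-q noise as `q²σ`:

1. **Peak detection for the initial guess.** On noisy profiles the argmax of
   a smoothed curve is routinely captured by the high-q tail. The guess
   therefore scores candidate peaks by their significance,
   `(ȳ − tail)/se(ȳ)`, using a running mean and its standard error; without
   uncertainties it falls back to a plain smoothed argmax with a 5%
   prominence requirement. A detected peak at `q_pk` seeds
   `Rc2 = x*/q_pk`, `Rc1 = Rc2/3`, amplitude from the low-q slope
   (`slope = (k1+k2)/4`), constant from the high-q tail median.
2. **Multi-start optimisation.** The cost surface has local minima when the
   two radii start close together, or when the visible peak actually belongs
   to the thin component (weak-amplitude conditions late in gelation at high
   pH). Each model order is therefore fitted from several deterministic
   starts — the warm start from the previous frame where available, the
   data-driven guess, a wider-split variant (`Rc1 = Rc2/6`), a
   swapped-interpretation variant (guessed peak assigned to `Rc1`), and a
   window-scale start whose peak sits mid-window — and the lowest-cost
   converged fit represents that order.

### Model selection

Early frames contain a single population; forcing two components there
produces unidentifiable parameters. Both model orders are fitted and
compared by `BIC = n ln(cost/n) + p ln(n)`; the two-component model must
beat the one-component model by more than 2 (the conventional "positive
evidence" threshold) or parsimony wins. No selection criterion is given with
the source analysis; BIC with this tie-break is this package's decision.

### Weight fractions

`w_i = k_i/(k1 + k2)`. The amplitudes are stated only to "relate" to weight
fractions; normalising by the amplitude sum reproduces statements of the
form "60% junction zones and 40% chains". An alternative reading — mass per
unit length of a cylinder scales as `Rc²`, so `w_i ∝ k_i Rc_i²` — is exposed
as `fit_config(wf_mode = "mass")` but is not the default.

### Series fitting

`fit_series()` runs frames in time order with warm starts: a 5 s cadence
makes consecutive frames nearly continuous in parameter space, which
stabilises the weakly identified early frames. Non-convergent frames carry
the previous parameters forward and are flagged, never dropped, so the time
course always has one row per frame. Replicate runs are combined by
`average_timecourses()`, which aligns frames to the nearest time (within
half a frame interval) and averages pointwise.

The default fit window is the full instrument range 0.103–3.26 nm⁻¹.
`fit_config(q_max = 2)` excludes the high-q region where, late in gelation,
a broader distribution of lateral association modes makes the two-component
model deviate.

## The synthetic generator

Ground truth follows saturating-exponential trajectories through the
reported anchor values; only anchors are published, so the functional form
between them is this package's choice (a saturating exponential is the
natural relaxation form for a diffusion-fed process). The presets:

| preset | Rc1 (nm) | Rc2 (nm) | w2 | amplitude |
|---|---|---|---|---|
| pH7.0 | 0.2 → 0.9 (τ = 60 s) | 2.6 → 2.9 | 0 → ~0.6 at 2 min → ~0.8 at 10 h | 1.0 |
| pH7.4 | 0.2 → 0.93 (τ = 70 s) | 2.6 → 2.9 | plateau ~0.6 | 0.8 |
| pH8.0 | 0.2 → 0.9 (τ = 90 s) | 2.5 | ~0.5 at 180 s → 0.25 at 10 h | 0.4 |
| pH8.0-alt | as pH8.0 | 2.5 | → 0.75 at 10 h | 0.4 |
| GDL-control | identical to pH7.0 | | | |

The second component appears at `switch_time = 10 s`. The late-time weight
fractions at pH 8.0 are described in two mutually inconsistent ways in the
source narrative (the thin-chain fraction falling to 25% vs the
junction-zone fraction halving); both readings are provided as separate
presets and no intent is guessed.

Noise is Gaussian with standard deviation `noise_level·sqrt(I + bg)` — the
Gaussian limit of photon counting, with the exposure time folded into the
single `noise_level` knob; no count statistics are published, and at
synchrotron count rates Poisson sampling would be indistinguishable. The
default `noise_level = 0.015` gives a buffer-subtracted full-gel frame a
Kratky-peak signal-to-noise ratio of about 30. The buffer is modelled as a
smooth low-q power law plus constant (`0.02 q^{-1.3} + 0.05`) and rendered
as the average of 16 exposures, the usual beamline practice of measuring
the buffer once with a long effective exposure; subtraction therefore adds
little variance to individual frames.

What the generator does *not* emulate: instrumental smearing, detector
geometry, inter-rod structure factor, absolute intensity calibration (the
scale is arbitrary; unit amplitude), and the hydrodynamics of where the
contact point lands relative to the beam (only its effect — time-shifted
trajectories — could be emulated by a custom `param_trajectory`). Passing
recovery tests on these fixtures therefore demonstrates the estimator's
correctness and precision under the assumed noise model, not robustness to
un-modelled systematics.

## The reaction–diffusion model

Two solutions meet at `x = 0`: CaEDTA (`C1`) on the left, ZnEDDA (`C2`) on
the right, alginate everywhere. The exchange
`ZnEDDA + CaEDTA → ZnEDTA + Ca²⁺ + EDDA²⁻` is second order with rate
constant κ:

$$\partial_t C_1 = D_1 \partial_x^2 C_1 - \kappa C_1 C_2, \qquad
  \partial_t C_2 = D_2 \partial_x^2 C_2 - \kappa C_1 C_2,$$
$$\partial_t C_3 = D_{Ca} \partial_x^2 C_3 + \kappa C_1 C_2
    - r_b k_b C_3 A, \qquad
  \partial_t G = k_b C_3 A,\quad A = A_0 - G.$$

(The printed form of the `C1` equation carries a `∂²C2/∂x²` term; it is
implemented as `∂²C1/∂x²` — the `C2` equation is its exact twin and the
cross-diffusion reading is a typographical slip.)

Defaults: `D1 = D2 = D_Ca = 0.78e-9 m²/s`, `κ = 1e4 M⁻¹s⁻¹` (large enough
that exchange is not rate limiting — doubling it changes the centre-ROI gel
at 120 s by under 1%), `C1⁰ = C2⁰ = 60 mM`, alginate `A0 = 0.0505 M`
monomer (1% w/v at 198 g/mol). The gelation step — free Ca²⁺ binding
ungelled alginate — is modelled as a second-order irreversible reaction with
`k_b = 1e4 M⁻¹s⁻¹` ("fast" regime) consuming `r_b = 0.5` Ca²⁺ per monomer
gelled (one ion per G-G pair in the egg-box picture). The binding capacity,
gelation rate and Ca²⁺ diffusivity used in the original simulations are not
printed (they defer to an earlier gelling model); these defaults are
explicit, documented placeholders and all comparisons against the published
concentration profiles are qualitative only. Aggregate exchange products
(ZnEDTA + EDDA) are tracked as a bookkeeping field and feed no kinetics.

Numerics: finite-volume method of lines on a uniform cell-centred grid (400
cells over ±2.5 mm by default), zero-flux boundaries, stiff integration with
`deSolve::ode.1D` (lsoda, banded Jacobian) at `rtol = 1e-8`. The
cell-centred grid represents the step initial condition exactly and makes
the midpoint-rule box integrals discretely conserved, so mass-balance drift
measures solver error alone. A run aborts if either chelate is depleted by
more than 0.1% at its own boundary — the box must emulate an infinite
reservoir, matching the published boundary treatment. Output defaults to
every 12 s over 120 s; ROI summaries average the gel field over 50 µm
windows at the interface and 200 µm off-centre, by trapezoid with
interpolated window edges.

## Problem sizes and tolerances used in validation

The test suite validates on 200-point q grids, series of ~30 frames, 50-seed
replicate ensembles for recovery/selection rates, and 400-cell
reaction–diffusion grids; these sizes keep the full suite fast while leaving
every statistical check comfortably powered. Key frozen tolerances: J1
versus an independent truncated-series oracle to `1e-10` relative;
noiseless parameter recovery to `1e-6` relative; zero-noise anchor recovery
through the full pipeline to `1e-4` relative; κ = 0 diffusion against the
closed-form erfc profile to `1e-3` of the initial concentration;
conservation to `1e-6` relative.

## Known limitations

- The broken-rod (decoupling) approximation is treated as exact over the
  fitted window; its q-validity limits are not modelled, only configurable.
- No polydispersity in the radii and no rod-length dependence: each
  population is a single sharp cross-section.
- Errors on fitted parameters are not propagated (no bootstrap/MCMC); the
  replicate spread in the synthetic ensembles is the available measure of
  estimator precision.
- The reaction–diffusion module is 1D and its binding parameters are
  placeholders; it reproduces orderings and regimes (front propagation,
  centre-vs-offset kinetics), not absolute published curves.
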