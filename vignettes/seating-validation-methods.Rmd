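---
title: "Methods: seat-interface metrics, frame transforms, material laws and synthetic study conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seat-interface metrics, frame transforms, material laws and synthetic study conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitpress)
```

# What this package computes

Validating a seated human-body model against bench measurements comes down
to a small set of comparison quantities: contact forces on the seat back
(SB), seat pan (SP) and foot support (FS) expressed in frames where shear
and normal components separate; pressure-mat statistics (contact area CA,
peak pressure PP, mean pressure MP, fore-aft load proportions); and the
compression of the soft tissue column under the ischial tuberosities (ITs),
summarised as mean thickness and volume reduction R inside cylindrical
regions of interest. `sitpress` implements each of these metrics, the
uniaxial material laws of the flesh and the cushions, and a seeded
synthetic-data generator that emulates the measurement chain, so the whole
pipeline can be exercised and regression-tested without a finite-element
solver or a test rig.

The bundled reference dataset (`reference_forces_global()`,
`reference_pressure_params()`, `reference_tissue_table()`) carries the
published measured/simulated values of a single-subject validation
experiment on a reconfigurable seat: four configurations with seat-pan
angle (SPA) 0°–15° in 5° steps, seat-pan-to-backrest angle (SP2BA) fixed at
100°, subject weight force 784.8 N. All quantities are kept at their
published precision.

# Coordinate frames and force balance

The global frame has x pointing forward-horizontal and z upward, with y
lateral (right-handed); all forces live in the seat's sagittal symmetry
plane, so only (fx, fz) are carried. Each surface's local frame is the
global frame rotated about y by the surface tilt:

* seat pan: `SPA`;
* backrest: `SPA + SP2BA − 90` (its tilt from vertical, so the local x axis
  lies in the backrest plane);
* foot support: 0 (horizontal).

The rotation is `fx_L = fx_G cos α + fz_G sin α`,
`fz_L = −fx_G sin α + fz_G cos α`. The positive-x convention is stated
nowhere in the source material's text (it is figure-only); the convention
above was chosen because it reproduces, for every bundled condition, the
published local force pairs from the published global ones to within the
0.1 N printing precision. That numerical closure is part of the test suite.

Static balance sums the three global reactions and the weight:
`Sum_Fx = Σ fx`, `Sum_Fz = Σ fz + W` (reactions are measured negative-z, so
the weight enters positive). One published residual (the flattest
condition) prints with the opposite sign to what the column arithmetic
gives; the package reports the signed residual *and* its magnitude, and the
comparisons assert magnitudes. The bundled weight is the published 784.8 N,
which differs slightly from mass × g (79.5 kg × 9.81 = 779.9 N);
`seat_config()` takes the weight as an input rather than deriving it.

Sim-vs-Exp statistics are `D = Sim − Exp` per condition,
`D% = 100 D / |Exp|` (flagged undefined when `|Exp| < 1e-9`), and All-row
means over conditions, with the All-row `D%` evaluated at the means.

# Pressure-map metrics

Pressure mats report a 48 × 48 grid at 12.7 mm pitch, in kPa. Because mat
calibration drifts, each trial is corrected by a scalar
`fcorr = F / (Σ p_ij · pitch² · 10⁻³)` that makes the map integral equal
the load-cell normal force on that surface; `fcorr` is computed per trial
and per surface. Correction is idempotent: after applying it, recomputing
gives 1.

On the corrected map, CA counts cells above a contact threshold times the
cell area, PP is the maximal cell, and MP is the corrected load on active
cells divided by CA — equal to `F/CA` whenever all load lies on active
cells. The threshold default is 0.1 kPa: the source material does not state
one, and 0.1 kPa sits below the mat's rated floor (≈1.4 kPa) while cleanly
excluding numerical noise; it is configurable everywhere.

Profiles sum the grid along one index: `SOC[r] = Σ_c p[r, c]` (lateral
profile along the fore-aft axis) and `SOR[c] = Σ_r p[r, c]` (frontal
profile); both conserve the grid total.

The four-region partition works on the SOC profile (not the 2-D peak): with
`X_beg`/`X_end` the first/last active rows and `X_max` the profile peak
(rear-most row on ties, for determinism), `X_mid1` is the midpoint of
(`X_max`, `X_end`) and `X_mid2` the midpoint of (`X_mid1`, `X_end`), both
rounded to the nearest row with exact halves resolved toward `X_end`.
Regions are half-open row ranges I = [X_beg, X_max), II = [X_max, X_mid1),
III = [X_mid1, X_mid2), IV = [X_mid2, X_end]; proportions are percentages
of the active-span load and sum to 100 by construction. Zero-width regions
(e.g. a single active row) contribute 0 % and are flagged; the half-open
scheme assigns their mass to the following region without double counting.

For simulated maps the published MP does not everywhere equal `F/CA` at
printed precision; the exact definition used there is not recoverable, so
this package documents and applies one definition uniformly: MP =
active-cell mean of the corrected map. `X_beg` and `X_end` share one
threshold; nothing in the source suggests they should differ.

# Soft-tissue ROI metrics

Two cylinders (20 and 50 mm diameter) probe the tissue under the IT. The
axis is perpendicular to the seat-pan plane and passes through the ischium
point closest to the seat; the cylinder's upper face plane contains that
point and the body extends 200 mm seat-ward (enough to cover any tissue
column). The landmark is taken from the *unloaded* state and the ROI is
then frozen in the seat frame and applied identically to both states — this
keeps `R = 0` for identical meshes and makes uniform axial compression to
stretch λ give exactly `R = (1 − λ)·100`, which the tests assert to ±0.5.

Metrics are computed by ray casting rather than exact mesh clipping: rays
parallel to the axis on a square grid (default 0.5 mm) over the
cross-section, per-ray tissue chord = length inside the skin boundary and
outside the bone boundary, clipped to the cylinder. Mean thickness averages
chords over rays that hit tissue; volume sums chord × cell area. The two
are consistent by construction (`v = t_mean × hit area`), the
discretisation error is controlled by the grid (≤1 % against the analytic
cylinder at 0.5 mm; halving the grid moves smooth fixtures by <0.5 %), and
the approach is robust on hexahedral meshes where exact clipping is
fragile. Ray/triangle intersections use 2-D barycentric tests in the ROI
frame; coincident crossings on shared coplanar edges are de-duplicated
before pairing crossings into inside-intervals.

`R = (1 − V_loaded / V_preload)·100` follows directly. The published
per-condition thickness/R values are not recoverable from thickness alone
(volume vs thickness measure different things), so they serve as
qualitative anchors: the synthetic fixtures are parameterised so the
unloaded thickness is ≈40 mm (the published preload values are 38.8–41.2
mm) and so that enabling sliding increases R in both ROIs, the ordering the
published with/without-sliding contrast shows.

# Material laws

**Flesh.** Lumped muscle/adipose tissue is an incompressible one-term Ogden
material; with exponent 2 it is the neo-Hookean solid used in the reference
model (shear modulus 3 kPa, Poisson 0.499 and density carried as metadata).
Uniaxial nominal stress is
`σ(λ) = Σ μ_i (λ^(α_i−1) − λ^(−α_i/2−1))`, the derivative of
`W(λ) = Σ (μ_i/α_i)(λ^α_i + 2 λ^(−α_i/2) − 3)`; the tests check the closed
form against numerical differentiation of `W` to 1e-8 relative.

**Cushion foam.** Low-density seat foam follows a tabulated loading curve
(piecewise-linear, no extrapolation past the last knot, scaled by a
constant factor — 1.15 for the reference cushions, the correction the
original study applied to its measured curves after mass-validation tests).
Unloading is hysteretic, controlled by an unloading factor HU ∈ (0, 1] and
a shape factor SHAPE > 0. The functional form used here,

`σ_U(ε) = σ_L(ε)·[HU + (1 − HU)·(W(ε)/W(ε_max))^SHAPE]`,

with `W` the exact trapezoid energy of the loading curve, is **this
package's definition**: the named factors come from a commercial solver's
material model whose internal equations are proprietary-manual material, so
numerical identity with any solver is not claimed. The form satisfies every
qualitative requirement attached to the factors: continuity with the
loading branch at the cycle peak, `σ_U ≤ σ_L` everywhere, elastic recovery
at HU = 1, dissipation increasing with SHAPE, and non-negative cycle
dissipation. The reloading decay constant BETA is fixed at 0 (its reference
default), so reloading follows the loading curve and the response is
rate-independent.

`identify_unloading_params()` inverts the law: a coarse HU × SHAPE grid
seeds a Nelder–Mead refinement (on logit/log-transformed parameters to
respect the bounds) minimising the RMSE against a measured unloading
branch. On clean synthetic branches it recovers the generating pairs —
including the reference cushions' (0.65, 8) and (0.65, 5) — to within 1 %,
and within 10 % under 2 % multiplicative noise. At HU = 1 the branch is
elastic and SHAPE drops out of the residual; the fit reports it
unidentifiable rather than returning an arbitrary number.

The bundled loading curve (`synthetic_foam_curve()`) is a constructed
flexible-PU-shaped curve (elastic toe, ≈4–6 kPa buckling plateau,
densification past 60 % strain): the source material plots but does not
tabulate its measured curves, and every operation is parametric in the
curve, so a documented synthetic stand-in is used for defaults and tests.

# The synthetic study conditions

The generator module produces the three input families, each a pure
function of parameters and seed (repeated calls are bit-identical):

* **Pressure maps** — two IT Gaussian blobs plus a thigh ridge on the
  native grid, rescaled so the true integral equals the target normal
  force, divided by a known calibration error (so `correction_factor()`
  must recover it — the tests assert the round-trip to 1e-6), then
  multiplied by log-normal sensor noise with cv 0.05, a deliberate mid
  range choice for a mat rated at about ±10 % of scale.
* **Force sets** — global reactions satisfying `Σfx = 0`, `Σfz + W = 0`
  exactly (vertical loads split ≈12/78/10 % over SB/SP/FS, shear from the
  surface tilt plus a friction-like term, the foot support closing the
  horizontal balance), then Gaussian measurement noise (5 N default) for an
  Exp-like draw and a small systematic shear bias for a Sim-like one. The
  noiseless sets balance to <1e-9 N.
* **Tissue pairs** — a 140 × 140 × 40 mm hexahedral flesh block (the
  reference model's 40 mm under-IT thickness) capped by a hemispherical
  bone boundary resting flat-face-down on its top face; the ischium
  landmark is the centre of that face. Loading applies the axial stretch
  solving the series flesh/foam equilibrium at the applied stress (≈8.5 kPa
  under the IT at SPA 0, easing slightly as the pan tilts and load shifts
  to the backrest). Sliding is kinematic: the axial stretch deepens toward
  the axis with a smooth cos² radial profile, and a volume-motivated
  outward radial flow (vanishing at the seat face) carries the displaced
  material sideways — it reproduces the *discriminating power* of the R
  metric (sliding raises R in both ROIs at equal stress), not the contact
  mechanics of real tissue.

What passing tests on these fixtures shows — and does not show: they
demonstrate that the metrics are implemented correctly (round-trips,
closed-form cases, orderings, conservation laws) under idealised geometry
and noise. They do not validate any biomechanical model: real pressure maps
have asymmetries, sensor dropouts and registration error; real tissue
deformation involves contact, anisotropy and muscle tone that the
kinematic sliding mode does not represent.

# Numerical choices and problem sizes

* Contact threshold 0.1 kPa; partition midpoints round half toward
  `X_end`; profile-peak ties resolve rear-most.
* Ray grid 0.5 mm for quantitative ROI work; the pipeline demonstrations
  and some property tests use 1 mm with 10 mm meshes, where the slab and
  ordering properties hold identically at a fraction of the cost.
* Root finding by bisection/`uniroot` at 1e-9–1e-12 tolerance; HU/SHAPE
  refinement with `reltol` 1e-14.
* The demo fixture set covers the study's four conditions × Exp/Sim, with
  5 mm tissue meshes; reports print at the published precision (0.1 N,
  0.1 kPa, 1 mm², 0.1 mm, 0.1 %).
* Degenerate inputs are rejected with messages (zero-pressure grids, missing
  surfaces, non-monotone curves, stress beyond the tabulated curve,
  zero-volume pre-load ROI) rather than propagated as NaN; undefined
  quantities that can occur in valid runs (MP with empty contact, D% at
  zero reference) are flagged `NA`.

# Known limitations

* Sagittal-plane forces only; no lateral components, moments, or torques.
* The scalar `fcorr` is the only sensor-calibration model; no per-cell
  calibration, no map registration between trials, and no backrest region
  partition (the four-region scheme is defined for the seat pan).
* The hysteretic unloading law is a documented surrogate for a proprietary
  solver model; HU/SHAPE values fitted with it transfer to other
  implementations only qualitatively.
* Tissue metrics assume the boundary surfaces are closed and the ROI axis
  is sensibly oriented; rays are parallel, so strongly folded skin within
  the ROI would need a finer grid.
* The generators emulate one subject's measurement chain, not inter-subject
  variability.
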