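---
title: "Beam-matching audits of linac photon beams: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beam-matching audits of linac photon beams: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beamaudit)
```

## The problem

When a clinic runs several beam-matched linacs, one treatment-planning
beam model serves all machines and patients may be moved between them
without replanning. The matching claim is verified by an audit over
water-phantom commissioning data: percentage-depth-dose (PDD) curves and
lateral dose profiles of flattened (FF) and flattening-filter-free (FFF)
6 MV beams, measured at 90 cm SSD for square fields from 3×3 to
10×10 cm², are reduced to a small set of parameters and compared against
a baseline under stated tolerances, complemented by a point-wise 1D gamma
comparison of the curves themselves. `beamaudit` implements the parameter
extraction, the gamma engine, the tolerance verdicts and the report, plus
a synthetic beam generator with closed-form ground truth that exercises
every stage.

## Audit parameters and tolerances

| parameter | definition | deviation units | study / vendor limit |
|---|---|---|---|
| d_max | depth of maximum dose | mm | 1 / 1 |
| PDD10 | dose at 100 mm depth, % of maximum | % of baseline | 1 / 1 |
| flatness (FF) | 100·D_max/D_min over the central 80% of field size | % of baseline | 1 / 2 |
| unflatness (FFF) | D_CAX / D_offaxis at the standard offset | % of baseline | 1 / 2 |
| symmetry | max over x of 100·max(D(x)/D(−x), D(−x)/D(x)), central 80% | % of baseline | 1 / 2 |
| penumbra | 80–20% edge width, mean of sides | mm | 1 / 1 |
| output factor | D(field)/D(10×10) at reference depth | % of baseline | 1 (2 for ≤ 4 cm) / 2 |

The unflatness offset is 60% of the half field side for fields smaller
than 10×10 cm² and 80% at and above it, evaluated on the *nominal*
(header) field size — the conventional offsets (e.g. 40 mm for 10×10) are
nominal quantities. The denominator averages the two mirrored offsets,
which removes first-order sensitivity to residual asymmetry while leaving
the symmetric cone shape untouched.

Deviations are always `measured − reference`, computed unrounded and
displayed at table precision (2 decimals); JSON reports keep full
precision. A deviation exactly at a limit passes.

## Curve handling

Scan curves live in a plain-text dialect (`# key: value` headers plus
`position_mm,dose` CSV rows, one blank-line-separated block per curve).
Positions are mm, signed off-axis for profiles (negative = toward
gun/A-bank); the dose scale is whatever the detector produced —
normalization is always an explicit, documented step, never a side effect
of I/O. Non-uniform sampling (2 mm centrally, 1 mm in the penumbra
region) is preserved.

Profile analyses run on a 0.1 mm grid obtained by *natural cubic spline*
resampling. This is a deliberate choice: on a 1 mm measurement grid,
linear chords across the curved 80% and 20% shoulder regions bias the
penumbra width by about +0.05 mm — the same order as the accuracy we
claim — while the spline reproduces the smooth underlying physics to
well below 0.01 mm. Level crossings on that grid are then linear (no
overshoot at the crossing itself). Noise-sensitive operations do *not*
differentiate or extremize the spline directly (see below).

## Estimator choices for noisy scans

Two parameters required more than the textbook recipe once realistic
measurement noise (0.2% of maximum, Gaussian) is present.

**Depth of maximum dose.** The 6 MV PDD peak is flat and asymmetric: the
dose stays within 0.2% of its maximum over several millimetres. A local
quadratic vertex through the sample maximum and its neighbours is exact
on noise-free curves but has ≈1 mm standard deviation at 0.2% noise, and
every generic smoothing or windowed-polynomial variant we measured trades
that variance for a bias of 0.2–2 mm driven by the peak's asymmetry.
`find_dmax()` therefore defaults to fitting the two-exponential
build-up/attenuation model `A(1 − e^(−βz))e^(−μz)` to the whole curve
(amplitude profiled out, β and μ optimized on log scale) and reporting
its analytic maximum `ln(1 + β/μ)/β`. The fit is exact on noise-free
model curves, unbiased with ≈0.02 mm SD under 0.2% noise, and is accepted
only when it actually describes the data (RMS residual < 1% of maximum);
otherwise — for example on deliberately non-physical test shapes — the
method falls back to the quadratic vertex, which remains available as
`method = "vertex"`.

**FFF field edge and renormalization.** The FFF field edge is the
inflection point of the falling profile, and the FFF penumbra is defined
on the profile rescaled so the inflection dose sits at 50% — so any noise
in the inflection estimate propagates through the renormalization factor
into both 80% and 20% crossings. Differentiating a spline of the measured
samples (even after 2 mm smoothing) leaves ≈0.5 mm penumbra SD at 0.2%
noise. Instead each edge is fitted with the model
`(a₀ + a₁x)·Φ(±(x − x₀)/s) + b₀ + b₁x` — an erf edge with linear
in-field modulation and linear background, which contains the
cone-modulated erf edge exactly — and the fitted curve supplies both the
inflection position and the dose there. Noise-free bias is ≈0.002 mm;
noisy penumbra recovery is within 0.3 mm in 100/100 seeds. If the fit
fails or misdescribes the edge (residual > 3% of CAX dose), the
spline-derivative locator in the 20–80% corridor is used as fallback,
with ties between derivative extrema broken by largest gradient.

**Smoothing for worst-case statistics.** Flatness and symmetry are
max-statistics, and noise only ever inflates them. Following standard
measurement-software practice, both apply a 4 mm moving average (two
central sampling intervals; `smooth_mm = 0` disables) on a
linearly-resampled grid before the extremum search. Constants and linear
tilts are preserved exactly by the moving average, so the analytic test
cases are unaffected; mirrored-ratio curvature effects cancel between
+x and −x, keeping symmetry unbiased.

## The gamma engine

For each evaluated point the engine computes
γ = min over r′ of √(((r′−r)/DTA)² + ((D_ref(r′) − D_eval(r))/(DD·D_norm))²),
with D_norm the reference maximum (global normalization, the field
standard; a CAX option exists) and no low-dose threshold by default, so
field-edge failures are counted. Two implementation details matter:

* The minimum over the piecewise-linear reference is computed *exactly*,
  segment by segment, as a closed-form point-to-segment distance in gamma
  space. A resampled-grid minimizer at 0.01·DTA spacing — a common
  implementation — errs by up to ~0.035 in γ near zero on steep ramps,
  because with a 1% DD criterion the dose axis dominates the gamma-space
  metric. The exact minimum restores the γ(k·DD, k·DTA) = γ/k scaling law
  to machine precision and matches an independent continuous oracle to
  1e-9.
* The search window starts at ±3·DTA and widens automatically whenever
  the found minimum exceeds the window-edge distance term, so every
  reported γ — including values above 3 — is a certified global minimum
  (a candidate outside a window of half-width w·DTA necessarily has
  γ > w).

The evaluated curve keeps its own sample grid: pass rates count measured
points, matching the way individual edge points are reported in audits.

## The synthetic generator

`make_pdd()` samples P(z) = (1 − e^(−βz))·e^(−μz), scaled to 100 at its
analytic maximum, defaults β = 0.25 /mm, μ = 0.005 /mm (d_max ≈ 15.7 mm,
PDD10 ≈ 66.9% — a realistic 6 MV beam), at 1 mm steps over 300 mm.
`make_profile()` samples
D(x) = 50·[erf((F/2−x)/(σ√2)) + erf((F/2+x)/(σ√2))]·(1−c|x|)·(1+a·x/(F/2)),
on the 2 mm central / 1 mm penumbra-region grid, then applies a CAX
shift and seeded Gaussian noise relative to the maximum. The cone factor
is piecewise-linear in |x| precisely so that the unflatness ground truth
is closed-form at any offset; the erf edge makes the FF penumbra truth
closed-form (1.6832·σ per side). Everything else (FFF inflection
positions, FFF penumbra, symmetry) is computed on a 0.01 mm dense grid of
the analytic model — an order of magnitude finer than any pipeline grid.
Ground-truth symmetry applies the pipeline's own frame convention
(recenter at the 50% midpoint first), since a tilt moves that midpoint
and "mirror ratio" is only defined once the frame is fixed.

Two honest caveats on idealized expectations. The unflatness of a pure
erf profile at the 40 mm offset is *not* 1: the edge droop contributes
≈0.6% at σ = 4 mm, so the naive cone-only value 1/(1 − c·40 mm) (≈1.148
for c = 0.00322/mm) is only reached for sharp edges (σ ≲ 2.5 mm); the
generator's ground truth uses the exact model ratio. Similarly, widening
σ to inflate the penumbra also moves unflatness/flatness whenever the
offset sits within a few σ of the edge — the "exactly one record fails"
demonstration therefore uses σ = 2.5 mm, where the side effect is ≈0.3%.

What a green synthetic test establishes: that the estimators recover the
stated truth of this model family at the stated noise level, and that the
audit bookkeeping flags exactly the perturbations it should. What it does
not establish: behaviour on detector-volume-convolved, electron-
contaminated or asymmetric-horn real beams, absolute dosimetry, or any
2D/3D dose comparison — all outside the model family and out of scope.

## Numerical conventions

* Reporting: d_max to 0.01 mm, percentages to 2 decimals, unflatness to
  3; all comparisons and verdicts use unrounded values.
* Level crossings: linear interpolation between bracketing grid points;
  apex resolution: quadratic vertex (or model fit) only.
* Side selection in penumbra: among multiple noise-induced crossings of
  one level, the crossing closest to that side's field edge is used.
* Reports are emitted with stable record ordering and fixed rounding, so
  regeneration from identical inputs is byte-identical.
* The audit configuration file is JSON (tolerance table, gamma criteria,
  baseline paths); YAML is deliberately not supported to keep the
  dependency footprint at `jsonlite`.
* Seeds: every stochastic element (generator noise, cohort machines) is
  seeded explicitly and restores the caller's RNG state.

## Known limitations

* The depth-dose model fit assumes the two-exponential family; scans
  dominated by contaminant electrons near the surface would push the fit
  toward its residual gate and back to the vertex estimator.
* The erf-edge fit assumes monotone edges within the 5–95% corridor;
  exotic profiles (wedges, split fields) will take the fallback path.
* Output-factor logic covers square fields only; no equivalent-square
  mapping, no small-field detector correction factors.
* Gamma is 1D by design; plan-level 2D/3D pass rates enter the audit only
  as externally supplied per-plan numbers via `aggregate_pass_rates()`.
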