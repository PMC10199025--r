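---
title: "Spatiotemporal mapping of left-ventricular geometries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal mapping of left-ventricular geometries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvmap)
```

## The problem

Different cardiac imaging protocols systematically disagree about the same
heart. Real-time 3D echocardiography (3DE) tends to underestimate
left-ventricular (LV) volumes relative to cardiac magnetic resonance (CMR),
the disagreement varies regionally over the ventricular wall, and the two
acquisitions sample the cardiac cycle at different rates and under different
heart rates. Any study that pools geometry-derived indices (volumes, mass,
ejection fraction, strain) across protocols inherits these biases.

`lvmap` implements a two-stage correction that acts on the geometry itself
rather than on individual indices:

1. **Temporal alignment.** Per subject, the two acquisitions' cavity-volume
   traces are aligned by a penalty-modified dynamic time warping (DTW),
   producing a one-to-one correspondence between 30 uniformly spaced
   source-protocol frames and 30 warped target-protocol timepoints.
2. **Geometric mapping.** Across subjects, the aligned, flattened
   spatiotemporal geometries (290 surface points x 3 coordinates x 30
   frames = 26,100 variables) are related by partial least squares (PLS)
   regression fitted with NIPALS, and new source-protocol sequences are
   mapped into target-protocol space.

Because the clinical paired dataset this class of method is developed on is
not publicly available, the package ships a first-class synthetic
paired-population generator with a known injected inter-protocol bias;
every stage of the pipeline is validated against that ground truth.

## Geometry representation

Each surface (endocardium, epicardium) is sampled at 145 points: one apical
point plus 9 rings of 16 meridians, ordered apex to base. The 16 x 9
factorisation is a deliberate choice: it divides exactly into the
apical/mid/basal thirds and the 60- and 90-degree circumferential sectors
of the AHA 17-segment model. Points are expressed in the cardiac coordinate
frame: `x` along the long axis pointing from the basal centroid to the apex,
origin at one third of the base-to-apex distance at end-diastole (base at
`-L/3`, apex at `+2L/3`), and `y` obtained by rotating the projected
inferior right-ventricular insertion direction by 70 degrees about the long
axis. The rotation sense (right-handed about `+x` by default) and the
70-degree offset are conventions exposed as arguments, since only the axis
line, the origin position and the angular offset are anatomically fixed.

### Cavity volume

Volumes are computed with the divergence theorem over a closed
triangulation (the open basal end is closed by a flat fan to the basal-ring
centroid). A flat triangulation of the 145-point grid, however, carries the
chord deficit of a 16-gon: it underestimates a convex cross-section by
about 2.5%, and an 80 x 30 x 30 mm half prolate spheroid by 3.3% in total.
The volume operator therefore evaluates the same divergence sum on a
spline-refined surface: periodic cubic interpolation circumferentially and
natural cubic interpolation apex-to-base, at a subdivision factor of 4.
Both refinements are fixed linear operators (cached interpolation
matrices), so the refined volume scales *exactly* like the underlying
geometry under affine scaling — a property the synthetic generator relies
on to hit volume targets exactly. At the default grid the half-spheroid
error is -0.25%, and the empirical convergence order under grid refinement
is about 2.

Wall mass is `(epicardial enclosed volume - cavity volume) x density`, with
density defaulting to the conventional 1.05 g/ml.

### Clinical indices

EDV is the volume at the first frame (acquisition is R-wave triggered, so
frame 0 is treated as end-diastole by definition, not as the maximum-volume
frame); ESV is the cycle minimum; EF follows from the two. Global
longitudinal strain (GLS) uses endocardial arc lengths summed apex-to-base
per meridian and averaged over the 16 meridians; the reported GLS is the
signed minimum over systole (whether the original evaluation used systole
only or the whole cycle is not documented; for these smooth traces the two
coincide to within the trough flatness). Rate indices (PER, PFR_E, PFR_A,
PSR) are central differences of the 30-sample uniformly resampled traces,
scaled to absolute time by the cycle duration, consistent with the temporal
grid of the mapping pipeline. Discrete extrema are refined by the vertex of
the parabola through the extremal sample and its cyclic neighbours, which
removes the error made when the true peak falls between samples. PER and
PSR are reported as signed minima (negative); the E- and A-wave peaks are
the two most prominent local maxima of dV/dt in diastole (prominence
ranking, earlier = E); monophasic filling reports PFR_A as missing rather
than zero.

## Temporal alignment

Volume traces are linearly interpolated to `n = 30` (template, source
protocol) and `m = 60` (secondary, target protocol) uniform samples spanning
the closed cycle `[0, 1]`, and normalised to `[0, 1]` in amplitude. The
discrepancy is `d(i, j) = (t_i - s_j)^2` and the cumulative cost follows

```
gamma(i, j) = d(i, j) + min[ gamma(i-1, j), gamma(i-1, j-1), gamma(i, j-1) + p ]
```

with the penalty `p` equal to the maximum per-phase difference between the
two normalised signals (the secondary signal interpolated onto the
template's phases — the comparison grid is otherwise ambiguous when
`n != m`). The printed recursion attaches `p` to the `(i, j-1)`
predecessor; the prose that motivates it (penalising a step forward in `i`
but not `j`) describes the `(i-1, j)` predecessor instead. The package
implements the recursion as printed by default and exposes the textual
variant behind `variant = "text"`; both variants are verified against
exhaustive path enumeration. Backtracking breaks ties deterministically:
diagonal first, then `(i-1, j)`, then `(i, j-1)`. Boundary cells use only
their admissible predecessor, with the penalty applied on first-row
horizontal steps under the default placement.

The warped index `j'_i` is the mean of all secondary indices paired with
template index `i`; target geometry is evaluated at the 30 warped
fractional indices by linear interpolation of the 60-frame resampled
sequence. The penalty is computed once per pair, not re-estimated after
warping. Alignment is strictly within-subject.

One behaviour worth knowing: when a sequence is aligned with itself at
`m = n` the warp is exactly the identity and the aligned target reproduces
the uniform resampling to machine precision. At `m = 2n` the two
resamplings of the same trace differ at interpolation scale, so the optimal
path may wander within flat trace regions (diastasis); the resulting
geometry deviations stay at sub-millimetre scale but are not numerically
zero.

## PLS mapping

Both geometry matrices are mean-centred and z-normalised per column
(sample standard deviation; constant columns are masked and restored
exactly on inversion). The mapping is PLS2 NIPALS regression with X- and
Y-deflation: per component, the power iteration extracts the
covariance-maximising score pair, converging when the normalised X-score
vector changes by less than `1e-10` between iterations (at most 5000
iterations; late components on noise-dominated residuals have nearly
degenerate spectra and converge slowly, which is why the cap is generous).
Non-convergence is an error naming the component.

As an implementation note, the power iteration is run through the n x n
Gram matrices of the deflated data — algebraically identical to iterating
the 26,100-dimensional weight vector, since every iterate lives in the row
space — and the deflated matrices are never formed: Grams are deflated
incrementally and loadings are recovered from the original matrices through
the orthogonality of successive scores. This makes a leave-one-out sweep
over 138 subjects a matter of minutes rather than hours, with predictions
agreeing with an independent reference implementation (mixOmics) to
`1e-6` and better.

The number of components is chosen by 5-fold cross-validation on the full
dataset (seeded shuffle, contiguous blocks), minimising the mean squared
prediction error; ties resolve to the smaller count. The selection is made
once and reused inside leave-one-out evaluation, mirroring common practice;
because that mildly leaks information across folds, a strict mode
(`reselectPerFold = TRUE`) re-runs the selection inside every fold. On the
default synthetic population the CV error is still decreasing slowly at the
top of the default candidate range (`kMax = 10`), so the selector picks 10;
the bias-correction results are insensitive to a component or two either
way.

Prediction standardizes new source rows with the training X parameters,
projects through `T = X W (P'W)^{-1}`, applies the Y-loadings, and
de-standardizes with the training Y parameters. Prediction is affine in the
inputs, and with the full component count on tall full-rank problems it
reproduces ordinary least squares.

## The synthetic population

The generator is the package's study definition, not a test fixture. Each
subject is a truncated half prolate spheroid (base plane at the equator)
whose semi-axes are modulated over the cycle so the cavity volume follows
an analytic physiological trace: raised-cosine ejection to end-systole at
phase ~0.35, a raised-cosine E-wave, a slow linear diastasis, and a
raised-cosine A-wave from phase 0.75. The raised-cosine limbs keep the
peak filling and ejection rates wide enough that a 30-sample central
difference recovers them to within 5% — sharper splines were tried first
and produced unphysiological 600+ ml/s E-peaks that no 30-frame acquisition
could resolve. Volume change is split between longitudinal shortening
(`a ~ s^0.2`) and radial narrowing, yielding systolic GLS near -20% at
normal EF; wall volume is held constant over the cycle (incompressible
myocardium), so mass is time-invariant. Because the discretised volume is
exactly `c * a * b^2` for fixed angular sampling (linear refinement
operators commute with affine maps), the short semi-axis is calibrated once
against the discretised surface and the EDV and EF targets are hit
essentially exactly. A low-order random harmonic modulation gives each
subject a non-axisymmetric shape; with the modulation disabled the surface
is an exact surface of revolution.

Subjects are drawn from a control-like stratum (EDV ~ N(141, 33) ml,
EF ~ N(62, 5)%, wall 8 mm) and a disease-like stratum (EDV ~ N(160, 41) ml,
EF ~ N(50, 10)%, wall 11 mm) in a 84:54 ratio, with heart rate N(65, 8) bpm
and target-protocol frame counts of 25-35 — magnitudes typical of adult
clinical cohorts. All randomness flows from one master seed through named
per-subject sub-seeds.

The source protocol is derived from the same parametric truth under a bias
model with global, regional and temporal components: a volume scale
(default 0.86), a contractility scale compressing the volume excursion
(0.765), long-axis foreshortening (0.95, volume-preserving via radial
re-inflation), a wall-volume scale (0.92), a smooth outward offset field
peaking in the basal anterolateral wall (2 mm), a strictly monotone
temporal warp `u(phi) = phi + A sin(2 pi phi)/(2 pi)` with per-subject
`|A|` in 0.1-0.25, a heart-rate change N(-1, 6) bpm, source frame counts of
30-45, and isotropic point noise of 0.5 mm. The defaults were set so the
population-mean before-mapping biases land near EDV -16 ml, ESV +13 ml,
EF -14 points, LVM -11 g and GLS +5 points — the sign pattern and rough
magnitudes reported for 3DE against CMR in the clinical literature. The
realised values on the default population are EDV -15, ESV +12, EF -14,
LVM -9, GLS +2. These are emulation targets for the generator, not claims
about any particular dataset.

What the generator deliberately does not model: image formation (speckle,
shadowing, MR artefacts), observer variability in contouring, valve-plane
motion distinct from the parametric base, regional wall-motion
abnormalities, and arrhythmic beat-to-beat variation. Passing the
end-to-end criteria therefore demonstrates that the pipeline recovers a
smooth, consistent inter-protocol mapping in the presence of temporal
warping, regional offset fields and point noise — not that it corrects
every bias structure real images can produce.

## Agreement evaluation

Index agreement is summarised source-minus-target: mean bias, SD of
differences, 95% limits of agreement (`bias +/- 1.96 SD`), ICC for absolute
agreement from the two-way model (ICC(A,1), identical under the mixed- and
random-effects formulations), and two-tailed paired t-tests with the 0.01
significance threshold. Geometry agreement is the pooled RMSE of
corresponding points (each point contributes its squared Euclidean
distance), globally or per AHA segment at ED and ES. Trace similarity is
the cumulative DTW distance between the 30-sample raw-amplitude traces
using the same penalty scheme as the alignment stage and the squared
discrepancy by default; flags expose amplitude normalisation and an
absolute-difference accumulation, since the accumulated quantity and its
units are conventions. Note that with the penalty enabled the metric is not
exactly homogeneous of degree 2 in amplitude (the penalty is linear);
penalty-free accumulation scales exactly as `lambda^2`.

## Numerical choices and degenerate inputs

- Uniform resampling spans the *closed* cycle `[0, 1]` (first and last
  samples both at end-diastole), which pins the DTW endpoints naturally;
  traces and geometry interpolate periodically with period 1.
- Constant signals cannot be amplitude-normalised (error); constant
  dataset columns are masked during standardization and restored on
  inversion.
- Degenerate landmarks (apex on the basal centroid, RV insertion on the
  long axis) and inverted or self-intersecting surfaces (non-positive
  signed volume) raise errors rather than producing silent nonsense.
- A population of identical subjects exhausts the residual variance at
  component 1; the fit truncates gracefully and predictions fall back to
  the training mean, so leave-one-out error is exactly zero.
- The paired t-test treats numerically constant differences explicitly
  (infinite statistic for a nonzero constant, undefined for zero).
- Problem sizes in the validation suite: DP-vs-enumeration at n <= 5,
  m <= 7 over 100 seeded pairs; path contracts at n = 30, m = 60 over
  1000 pairs; PLS oracle equivalence on 20 seeded problems up to 50 x 40;
  the end-to-end bias-correction experiment at the full N = 138 with
  leave-one-out. These sizes keep the whole suite within a few minutes on
  a single core while exercising every contract at full fidelity.

## Known limitations

- The 145-point sampling pattern of the original 16-element modelling
  pipeline is not public; the canonical 16 x 9 grid here is a
  reconstruction that preserves counts and AHA compatibility, so
  point-for-point correspondence with any specific clinical tool is not
  claimed.
- The basal cap is flat (fan to the basal centroid); if the source data's
  convention followed the mitral annulus plane, absolute volumes shift
  slightly while all comparative results are unaffected.
- PLS components are selected once on the full dataset by default (see
  above); use `reselectPerFold = TRUE` for a strictly nested protocol.
- The mapped sequence inherits the source acquisition's cycle duration for
  rate indices; when heart rates differ strongly between protocols,
  rate-index agreement partly reflects that physiological difference.
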