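---
title: "Reconstructing cell tracks on hidden curved surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing cell tracks on hidden curved surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Live 3D imaging of migrating cells (immune cells crawling under an
embryonic epithelium, neutrophils moving over a yolk syncytium) usually
captures motion that is in truth two-dimensional: the cells are confined
to a curved surface that the microscope never images directly. The
standard analysis — dropping the z coordinate and computing directional
statistics in the xy plane — distorts exactly the quantities of
interest. A step taken on a tilted part of the surface is foreshortened;
turning angles and angles toward an attractant (a wound) acquire
artifacts that can manufacture a spurious bias or hide a real one.

`curvetrack` implements two reconstructions of a faithful 2D
representation from the 3D point cloud alone, without a surface mesh or
fiducial marks, plus the machinery needed to validate them:

* **Unwrapping** (`unwrap()`): a geometric two-pass construction for
  convex, mildly curved surfaces.
* **Riemannian (metric) manifold learning** (`manifold_learn()`): a
  nonlinear embedding together with an estimated position-dependent
  metric tensor that corrects all downstream lengths and angles.
* A **random-walk simulator on parametric surfaces**
  (`simulate_walk()`), supplying ground truth.
* **Directional statistics** (`bias_angles()`, `persistence_angles()`,
  `straightness_index()`, `deviation_distance()`, `compare_methods()`).

## Directional statistics

For every step of a track we measure the *bias angle* (signed angle
between the displacement and the direction toward the attractant) and
the *persistence angle* (signed turning angle between consecutive
displacements), counterclockwise positive, in `[-pi, pi)`. Binned with
36 equal bins (10 degrees) they form the bias and persistence
distributions; the *straightness index* `D` of a track is its net
displacement over its path length. A non-biased, non-persistent
(Brownian) walk has uniform bias and persistence distributions — any
structure seen after projection is an artifact of the representation.
The *deviation distance* between a computed and a true distribution is
the total-variation distance of the binned densities (in `[0, 1]`;
L2 and Kolmogorov–Smirnov alternatives are available).

## The random-walk model and simulator

Walks live on parametric surfaces (plane, sphere, spherical cap,
ellipsoid, cylinder). Each step draws a heading in the local tangent
plane from a von Mises kernel centered on the tangent-projected
direction to the target (concentration = `bias`) and/or the
parallel-transported previous heading (concentration = `persistence`);
the product of the two kernels is again von Mises with the resultant
parameters. `bias = persistence = 0` gives uniform headings. Stepping
is projected-Euler: advance the step length `L` along the tangent
heading, then project orthogonally back to the surface — exact on
planes and cylinder generators, with `O(L^2 * curvature)` geodesic
error elsewhere. The previous heading is transported by projecting the
previous 3D step direction onto the new tangent plane.

Simulated patches are *bounded with reflecting edges*. We first tried
free walks seeded inside a patch, but within 200 steps individual
walkers leave any chartable region (e.g. cross a hemisphere's equator),
which invalidates every single-chart method at once for reasons that
have nothing to do with the methods. Reflection is the standard model
for movement confined to a tissue region; the drawn headings — the
ground truth the distributions are compared against — remain exactly
von Mises / uniform.

The simulator records, per step, the drawn heading, the intrinsic bias
angle and the intrinsic turning angle in the tangent plane. These are
the "true" angles: on curved or bounded geometry they, and not the flat
analytic kernels, are the reference used by `compare_methods()`; for
the Brownian model both coincide (uniform).

### Validation presets

Six geometries of increasing difficulty, all unit scale, with walk step
length 0.03–0.04 (well below every curvature radius) and an attractant
placed just outside the patch rim like a wound adjacent to the imaged
field: `plane` (control), `cylinder` (developable: unwrapping must be
exact), `hemisphere` (60 degree dome), `sphere` (80 degree cap),
`ellipsoid_mild` (semi-axes 2, 1.2, 1), and `ellipsoid_thin` (5, 1,
0.2 — the thin regime where plain manifold learning collapses). Patch
areas are balanced so that 50 tracks of 150–200 steps sample every
preset at a comparable density; the study scale of the validation suite
(50 tracks x 200 steps = 10^4 steps) follows the package's standard
simulated-experiment size. Three walk classes (`brownian`, `biased`
with concentration 2, `biased_persistent` with 2 and 1) complete the
grid; `validate_methods()` runs it.

## Method 1: unwrapping

Pass 1 slices the cloud into equal-count slabs along a slicing axis
(default: the coordinate axis of greatest extent), fits an ellipse to
each slab's in-plane points, and replaces each point's in-plane
position by its signed arc length along the ellipse from a reference
meridian — the slab strips are "unrolled onto straight lines". The
intermediate is cylindrical-like (flat along the unrolled direction).
Pass 2 repeats the flattening orthogonally: slicing along the arc
coordinate, fitting the orthogonal profile (distance-from-center as a
function of the axis coordinate) with a smoothing spline, and replacing
the axis coordinate by arc length along that profile. On developable
data both passes are exact; on doubly curved surfaces the residual
distortion is a shear growing with the angular distance from the
reference meridian — the method's stated domain is convex surfaces of
small intrinsic curvature.

Numerical design choices that implementation experience forced:

* **Per-slab fits.** The classic direct least-squares (conic) ellipse
  fit is exact for full ellipses but strongly biased on partial arcs —
  and a slab of a convex surface is always a partial arc. Each slab is
  therefore refined by a geometric (orthogonal-distance) Gauss–Newton
  fit seeded by the conic and algebraic-circle fits, keeping whichever
  has the lowest orthogonal residual.
* **The slice family.** Even good independent per-slab fits have
  parameter noise that shears the chart (a 0.01 center wobble over a
  0.1 slab spacing is a 0.1 rad angle error). The slab anchors are
  therefore refined into a global smooth family
  `(w - c(s))' M (w - c(s)) = k(s)` — centers linear in the axis
  coordinate, constant normalized shape `M`, smooth positive size
  profile `k(s)` — by minimizing the Sampson distance over all points
  (two starts; the anisotropy of `M` is box-bounded because unbounded
  eccentricity is a spurious Sampson minimum). This family is exact for
  every quadric; the final `k(s)` is re-estimated with a smoothing
  spline so non-quadric convex profiles are followed too.
* **Reference meridian** at the pooled data centroid's angular
  position (centering the chart on the data minimizes the worst-case
  shear); arc lengths by fixed-order Gauss–Legendre quadrature
  (exponentially convergent); foot points by a robust bracketed root
  solver; pass-2 slab arc functions share a common anchor coordinate
  and are blended with a smooth kernel in the arc coordinate (hard
  interval blending kinks the chart at every slab boundary).
* **Degenerate inputs.** Globally flat clouds are developed exactly by
  rotation; exactly collinear slabs switch the pass to a line
  development; slabs with fewer than 5 points raise a coverage error
  suggesting fewer slices. Off-surface points are mapped to their foot
  and their residual distance is reported per point, never discarded.

## Method 2: Riemannian manifold learning

Any invertible smooth 2D embedding of the data misrepresents geometry
somewhere; the misrepresentation is exactly encoded in the pullback
metric tensor — a position-dependent symmetric positive-semidefinite
2x2 matrix `g(i)`. We obtain 2D coordinates by locally linear embedding
and estimate the *co-metric* `h = g^{-1}` from a graph Laplacian `L`
applied to products of the embedding coordinate functions,

`h^{kl} = -1/2 [ L(f_k f_l) - f_k L f_l - f_l L f_k ]`,

which equals a kernel-weighted local covariance of coordinate
differences. `L` is the density-renormalized (alpha = 1) random-walk
graph Laplacian on a symmetric kNN graph with heat-kernel weights
`exp(-d^2/eps^2)`, scaled by `4/eps^2`, which converges to (minus) the
Laplace–Beltrami operator regardless of sampling density — important
because tracks oversample where cells dwell. Angles, step lengths and
velocities are then computed with `g` at each step's origin (turning
angles with `g` at the shared point), which removes the embedding's
arbitrary stretch: on flat data the statistics are invariant under any
affine reparameterization of the embedding.

Estimator details that matter:

* **Bandwidth** `eps` (the scale below which the surface is treated as
  flat) defaults to the median 10th-neighbor distance and is the one
  parameter the user may need to adjust.
* **Self-calibration.** Truncating the kernel at k neighbors deflates
  its second moment and would bias all lengths by a constant factor.
  Applying the same h-estimator to the three 3D coordinate functions
  must yield trace 2 (the manifold dimension); the per-point factor
  enforcing this calibrates the truncation away exactly and absorbs
  most boundary deficit.
* **Variance.** The pointwise estimator is a ~k-sample covariance; the
  true field is smooth, so two neighborhood-averaging passes are
  applied before inversion (large variance reduction, negligible
  bias). The pseudo-inverse floors eigenvalues at `1e-8` of the trace
  and records the rank used.
* **Boundary.** Points whose neighborhood centroid is displaced by
  more than half the rms neighbor distance are flagged as boundary;
  the estimator is biased there. Flagged steps are included in the
  statistics by default (the flag is available for exclusion).
* **Degeneracy.** On thin, sparsely sampled surfaces the embedding
  collapses: the second coordinate becomes a function of the first and
  the data are read as a 1D line. This is detected where it is
  unambiguous — a rank-1 co-metric at most points — and raised as an
  explicit dimensionality error rather than silently producing angles
  from a collapsed chart. Disconnected neighbor graphs (data too
  sparse to form one chart at all) are reported with their component
  sizes.

The "Euclidean manifold learning" baseline — the same embedding with
the metric forced to the identity — is available throughout and is the
foil the metric is compared against: on anisotropic patches (the
ellipsoids) it distorts angle distributions severely.

## What the validation does and does not show

`validate_methods()` and the acceptance checks simulate the preset
grid, reconstruct with every method, and compare deviation distances
with paired track bootstraps. At the validation scale: cylinder
development is exact to 1e-6; metric manifold learning recovers uniform
Brownian bias and persistence on the hemisphere (chi-square at 10^4
steps) and beats its Euclidean variant on the ellipsoids with clear CI
separation; unwrapping recovers persistence but its bias distribution
on a 60 degree dome fails a chi-square test at 10^4 steps — chart
straight lines toward a rim attractant deviate from geodesics by up to
~0.3 rad at the azimuthal extremes, an intrinsic limitation of any
single flat chart of a doubly curved dome, detected with certainty at
this sample size even though the per-step turning fidelity is ~0.05 rad
rms. Similarly, on a rotationally symmetric dome the pooled PCA plane
coincides with the xy plane, so the PCA baseline is statistically
indistinguishable from — not worse than — the xy projection there; its
characteristic additional artifacts require tilted, anisotropic
geometry.

The simulator emulates surface-confined, constant-speed,
von Mises-directed walks with uniform frame intervals. Real tracking
data additionally contain localization noise transverse to the surface,
missing frames, heterogeneous cell speeds and possibly time-varying
attractant fields; none of these are modeled, so passing the validation
grid demonstrates correctness of the reconstructions, not robustness to
every property of real data. Off-surface noise enters the methods only
through the ellipse residuals and the graph bandwidth, both of which
degrade gracefully, but gap handling (`steps(gap = )`) is a convention,
not something the underlying experiments constrain.

## A worked example

```{r, eval = FALSE}
library(curvetrack)

pr  <- surface_preset("hemisphere")
m   <- walk_model(step_length = pr$step_length)      # Brownian
sim <- simulate_walk(pr$surface, m, n_tracks = 50, n_steps = 200,
                     seed = 1)

cmp <- compare_methods(sim$tracks, target3d = pr$target, truth = m)
cmp$table

ch <- unwrap(sim$tracks)               # chart + per-point residuals
mm <- manifold_learn(sim$tracks)       # embedding + metric field
plot(ch); plot(mm)
```
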