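---
title: "Dual-pose 2D/3D registration: model, parameters and design notes"
author: "DualPoseReg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-pose 2D/3D registration: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DualPoseReg)
```

## The problem

Intra-operative X-ray images must often be related to a pre-operative CT
volume. When the imaging geometry is known, this reduces to estimating the
six-degree-of-freedom (6-DOF) rigid pose of the CT volume — translations
$(t_X, t_Y, t_Z)$ in mm and rotations $(\theta_X, \theta_Y, \theta_Z)$ in
degrees about the world axes — that makes simulated radiographs of the volume
agree with the acquired ones. A single view constrains the two in-plane
translations and the in-plane rotation well, but is nearly blind to the depth
translation along the viewing axis: moving the volume towards the source only
rescales the projection slightly. This package therefore registers against
*two* views at once, a frontal and a lateral radiograph related by a fixed
quarter-turn about the patient's longitudinal axis, so that each translation
axis is in-plane for at least one view.

The estimation pipeline is: render digitally reconstructed radiographs
(DRRs) of the posed volume, reduce both the DRRs and the references to Canny
contour-point sets, score each view with a banded contour-point similarity,
combine the views into a composite score, and maximize that score over the
pose with a phased differential-evolution (DE) optimizer.

## Geometry and rendering

A pose acts on the volume as $p \mapsto R\,(p - c) + c + t$ with
$R = R_z R_y R_x$ (extrinsic rotations about fixed world axes, right-handed)
and $c$ the volume center. The composition order of the three axis rotations
is a convention; it is fixed, documented, and deliberately **not**
configurable — a silently mismatched convention between two components is
much worse than either convention.

The frontal camera places a point source at $(0, 0, -1000)$ mm and a detector
plane centered at $(0, 0, 200)$ mm (both configurable), giving a
magnification of 1.2 at the isocenter. The lateral view is defined by the
frontal-to-lateral transform `TransMat`, by default a $+90^\circ$ rotation
about the world Y axis; the lateral DRR is rendered with the *frontal* camera
after composing `LateralMat = TransMat %*% FrontalMat`, which is
mathematically identical to rotating the camera the other way (the fixed
lateral camera returned by `makeDefaultGeometry("lateral")` has its source on
the +X axis). Using one code path for fixture generation and the objective
guarantees bit-identical images on both sides of a test.

Each detector pixel casts one ray from the source through the pixel center.
Sample points are spaced uniformly along the ray (default step: half the
smallest voxel spacing), pulled back into the volume frame by the inverse
pose, interpolated trilinearly, and accumulated as
$\text{step} \times \sum_k v(p_k)$ — a Riemann approximation of the line
integral whose error against an analytic chord length is bounded by the step
(tested against a ray–box oracle). Points outside the volume contribute 0
(air). CT intensities are integrated as-is; no attenuation-law conversion is
applied, since any monotone rescaling is absorbed by the min–max grayscale
conversion that follows. Whether a log transform should precede the grayscale
conversion is unknowable from first principles here; the linear min–max map
onto [0, 255] is the default, and a fixed window can be configured instead
when min–max interacts badly with edge detection on nearly-empty images.

The batch renderer (`renderBatch`) exists as an explicit order-preserving
API: each entry is bit-identical to the corresponding single call. On GPU
systems such an interface allows amortizing device start-up across a whole
DE generation; here it is evaluated sequentially — parallelism is an
implementation detail excluded from the contract.

## Contour-point similarity

Both images are reduced to Canny edge maps (Gaussian $\sigma = 1$ px,
Sobel gradients, non-maximum suppression, hysteresis). For every *reference*
contour point, the nearest *floating* contour point within the square window
of half-width $\lceil b \rceil$ px is found (Euclidean distance $d$) and
scored

$$ s(d) = \begin{cases} 1 & d = 0 \\ w_1 & 0 < d \le a \\ w_2 & a < d \le b \\ 0 & d > b \end{cases} $$

and the similarity is the mean score over reference points. Defaults:
$a = 1$, $b = 3$ px, $w_1 = 0.8$, $w_2 = 0.5$ — one-pixel jitter costs 20%,
and the score saturates to zero beyond a $7 \times 7$ neighborhood, which
keeps the similarity sensitive exactly at the scale of the success criterion
(3 mm at a 2 mm detector pitch is 1.8 px in-plane). One floating point may
serve several reference points; no one-to-one assignment is enforced. The
measure is intentionally asymmetric: the references are extracted once per
run, floating contours once per candidate pose.

The two views combine as $\mathrm{Sim} = w_f\,\mathrm{Sim}_f +
w_l\,\mathrm{Sim}_l$ with $w_f = 0.6 > w_l = 0.4$: the frontal view is the
primary evidence, the lateral an auxiliary corrector, and $w_f + w_l = 1$
keeps the composite in $[0, 1]$. Single-view mode returns
$\mathrm{Sim}_f$ alone.

**Automatic Canny thresholds.** The hysteresis thresholds default to
$0.10\,/\,0.20$ of the maximum gradient magnitude. An alternative percentile
rule (70th/90th percentiles of the positive magnitudes) is available via
`autoRule = "quantile"` but is *not* the default, for a reason worth
recording: percentiles adapt to the distribution of gradients, so two images
of the same scene with different noise content get very different thresholds.
On a noisy reference / noiseless DRR pair the percentile rule dropped half
the true DRR edges (the 90th percentile of a nearly-noise-free image sits
above many real edge strengths), capping the similarity at the true pose near
0.53. Thresholds anchored to the strongest edge in the image are stable
across the pair; with them the true-pose similarity on the same pair is
0.995.

## Phased differential evolution

The optimizer is DE with DE/rand/2 mutation
($V = X_{r_1} + F (X_{r_2} - X_{r_3}) + F (X_{r_4} - X_{r_5})$, five
mutually distinct donors, all different from the target), binomial crossover
with a forced coordinate, and greedy one-to-one selection (strictly better
trials replace their targets; ties keep the incumbent, updated in place
within a generation). Two deliberate deviations from textbook DE:

* **Stage-switched controls.** The run is split at the halfway generation
  (ceiling for odd budgets). The scale factor is $F = 0.5$ first and $0.8$
  second; the crossover rate starts above $0.5$ (default 0.9) and drops below
  $0.5$ (default 0.3). Early on, a modest $F$ with aggressive crossover mixes
  the population towards promising basins; later, larger difference vectors
  with conservative crossover refine coordinates nearly independently. The
  configuration validator enforces the $CR$ ordering.
* **Per-dimension F scaling.** In registration, the depth translation
  ($t_Z$, index 3 of the pose vector) changes the images far less per mm than
  the in-plane parameters, so its effective step is damped by a factor 0.8
  (configurable vector; all other dimensions 1.0). Exposing the whole vector
  covers both readings of "a smaller F on the depth axis" — damped in both
  stages, or held constant across them.

Mutants are clipped to the search box *before* crossover, so trials are
always feasible. The optimizer minimizes; registration passes the negated
composite similarity. The RNG draw order is fixed and documented (donor
indices by rejection sampling, then the forced coordinate, then one uniform
per dimension), which makes a straight-line replay oracle possible in the
tests: an independent reimplementation fed the same seed must reproduce the
populations exactly.

Exactly $NP \times (G_{\max} + 1)$ objective evaluations are performed.
Registration defaults follow the clinical protocol of the method: $NP = 10$,
$G_{\max} = 50$; the benchmark protocol uses $NP = 30$, $G_{\max} = 1000$.

## Benchmark functions

Six standard test functions characterize the optimizer: Schwefel 2.22, 1.2
and 2.21 (unimodal), the two Generalized Penalized functions (multimodal,
with the canonical $u(x, a, k, m)$ boundary penalty — $a = 10$ for the
first, $a = 5$ for the second, $(k, m) = (100, 4)$ for both) and the Kowalik
11-term least-squares problem ($D = 4$, box $[-5, 5]^4$, global minimum
$3.0749 \times 10^{-4}$, embedded canonical data table). Dimensions are not
part of the published protocol; $D = 30$ is used for the first five (the
conventional choice in the benchmark literature) and Kowalik's canonical
arity 4 for the sixth. The convergence runner performs 1000 iterations at
population 30 per seed and accepts any optimizer implementing the
`optimizePDE` calling convention, so alternatives can be compared without
touching the harness.

## The synthetic phantom and what it does (not) show

Clinical CT/X-ray pairs cannot ship with a package, so the end-to-end loop is
exercised on a procedural phantom: a 96 mm cube at 1 mm voxels, soft-tissue
background 100, and a "spine": four bone cylinders (intensity 300, radius
12 mm, 18 mm long) stacked along Y, plus a thin posterior box as a
spinous-process analogue. The box is load-bearing: without it the phantom is
rotationally symmetric about its long axis and $\theta_Y$ would be
unidentifiable from projections, so recovery tests would fail for reasons
unrelated to the method. Reference images receive additive Gaussian noise
(sd 2 on the 8-bit scale, clamped) from a seeded stream; ground-truth poses
are drawn uniformly within ±4 mm / ±4° per axis, emulating a manual initial
registration that is a few mm/degrees off.

The recovery experiment registers 10 such fixtures in both dual- and
single-view mode with identical seeds, a ±10 mm / ±10° search box centered
on the zero pose, $NP = 10$, $G_{\max} = 50$, and a 128 × 128 detector at
2 mm pitch with 1 mm ray sampling — sizes chosen so a full dual run costs
tens of seconds on one CPU core while the 3°/3 mm success criterion remains
meaningful (1.5–1.8 px at this pitch). Success requires *every* per-axis
rotation error below 3° and translation error below 3 mm (strict
inequalities, evaluated per axis because per-axis errors are what the
clinical tables report; an aggregate-norm variant sits behind a flag).

What passing shows: the full chain — rendering, edge extraction, similarity,
optimization, dual-view composition — recovers poses to well under the
tolerance on data whose ground truth is known exactly, and the dual view
specifically repairs the depth axis that single-view registration leaves
under-constrained. What it does not show: performance on clinical images,
whose soft-tissue clutter, scatter, beam hardening and anatomy-dependent
contour quality the phantom does not emulate. Published success rates on
hospital data are not reproducible from this package and are not claimed by
it.

## Numerical choices and degenerate inputs

* Ray/box intersection by the slab method; rays that miss contribute 0, and
  a geometry where *no* ray hits the volume yields a warning plus an all-zero
  image rather than an error.
* Trilinear support is $[\mathrm{origin}, \mathrm{origin} +
  \mathrm{spacing} \cdot (\mathrm{dim} - 1)]$; sampling exactly on the upper
  face clamps into the last cell.
* Min–max grayscale of a constant image returns all zeros; constant images
  then produce empty contour sets, which are an *error* for the reference
  side (an empty reference indicates a broken pipeline, not similarity 0)
  and score 0 on the floating side.
* Nearest-contour ties at equal distance cannot change the score (the score
  depends only on the distance); the window scan resolves them in row-major
  order.
* Angle wrapping stores pose angles in $(-180, 180]$; pose errors take the
  shorter arc, so 179° vs −179° is a 2° error.
* A single run seed is split into labelled per-module streams
  (`deriveSeed`), so a change in how many draws one stage consumes cannot
  silently shift another stage's realization.

## Known limitations

Monoenergetic line integrals without scatter or detector blur; rigid poses
only; no multi-resolution pyramid (the banded similarity already gives the
optimizer a usable gradient at the working resolution); Canny is the only
edge detector offered; the optimizer interface accommodates alternative
metaheuristics but none are bundled.
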