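---
title: "Organ-contour-driven auto-matching: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organ-contour-driven auto-matching: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organmatch)
```

## The problem

In image-guided radiotherapy of cervical cancer, the cervix and uterus move
and deform between the planning image and each of the 23–25 daily treatment
fractions, by amounts that bone-based patient positioning cannot correct.
Manual soft-tissue matching of the daily image to the plan is slow and
suffers from inter-observer variability. `organmatch` implements an
automatic alternative: given triangulated surface models of the cervix and
uterus from the planning image (the *reference* models) and from the daily
image (the *daily* models), both expressed in a common patient frame after
bone co-registration, it computes the rigid couch correction that best
aligns the daily organs with the reference, scores the result against the
planning target volume (PTV), and provides a synthetic pelvic phantom so
the whole chain can be exercised and validated without patient data.

All geometry lives in the LPS patient frame (+x left, +y posterior,
+z superior), in millimetres. Pitch, yaw and roll are rotations about the
x, z and y axes respectively, in degrees.

## The cost model

Daily-model vertices are split into those *outside* the closed reference
surface of the same organ and those *inside* it. With `d_i` the distances
of the `i` outside vertices to the reference surface and `D_t` those of the
`t` inside vertices, the per-organ cost is

$$\mathrm{Cost}_A \;=\; W_\mathrm{out}\,\frac{\sum d_i^2}{i}
\;+\; W_\mathrm{in}\,\frac{\sum D_t^2}{t},$$

a group with no members contributing zero, and the total cost is the sum of
the cervix and uterus costs, each organ scored against its own reference
only. Three named weight scenarios are built in, ordered
(`w_out_cervix`, `w_in_cervix`, `w_out_uterus`, `w_in_uterus`):

* **A** = (1, 1, 1, 1) — the unweighted reference condition;
* **B** = (10, 5, 10, 5) — outside vertices up-weighted for both organs;
* **C** = (10, 5, 2, 0.5) — the cervix prioritized over the uterus.

Two consequences of taking the formula literally are worth knowing. First,
vertices lying exactly on the reference surface (within 1e-6 mm) count as
inside with distance zero, so identical daily and reference models cost
exactly 0. Second, *strictly interior* vertices do incur cost (`D > 0`), so
a daily organ shrunk concentrically inside its reference is penalized even
though it is geometrically "covered". We keep this reading — it penalizes
deeply displaced configurations and keeps the cost a genuine measure of
surface agreement — and flag it as an interpretation the formula forces.

## Geometric primitives

Distances are exact nearest point-to-triangle distances over all reference
faces (Ericson's closest-point construction), accelerated by a
bounding-sphere pruning pass that only skips triangles provably farther
than the current best, so the result equals the brute-force minimum. The
unit tests hold this equality to 1e-9 against an independently coded
brute-force oracle.

Containment uses the sign of the offset from the closest surface point
against the angle-weighted pseudonormal of the closest feature (face, edge
or vertex), which is exact for closed, consistently wound meshes and costs
O(1) on top of the nearest-point query. Where the test degenerates (cosine
below 1e-6), the generalized winding number thresholded at 0.5 decides, and
jittered-ray parity decides any remaining ties. The three tests are
mutually cross-checked in the test suite on random off-surface points.

Meshes are validated on construction and on read: vertices deduplicated on
a 1e-6 mm grid, degenerate faces dropped, closedness enforced (every edge
shared by exactly two faces — violations are reported naming a defective
edge), winding made consistent by propagation across shared edges and
oriented outward by requiring positive signed volume. STL (ASCII and
binary), PLY (ASCII) and OBJ are supported; none of these formats carries
units, and coordinates are taken as millimetres.

## The step-halving ("dichotomy") optimizer

The two organs move as one rigid body. Positioning runs in two phases,
once each, translation first:

1. **Translation.** The first commanded move is the full pooled-centroid
   difference (reference minus daily). Every move — including this one —
   is accepted only if the cost strictly decreases (relative tolerance
   1e-9) and reverted otherwise. Subsequent iterations test signed
   axis-aligned steps in the fixed order x+, x−, y+, y−, z+, z−; the step
   magnitude starts at half the commanded centroid-shift length, halves
   each iteration regardless of acceptance, and is floored at 1 mm — the
   translational accuracy of a treatment couch. Each magnitude is swept
   repeatedly until a full sweep accepts nothing; the phase ends when the
   full 1 mm sweep accepts nothing.
2. **Rotation.** The same scheme about the pooled daily centroid at the
   start of the phase, starting at 45°, halving, floored at 0.5° (the
   rotational couch accuracy), sweeping pitch±, yaw±, roll± in fixed
   order.

Because acceptance requires strict decrease and the cost is bounded below
by zero, the accepted-cost sequence is strictly decreasing and both phases
terminate; a 500-evaluation cap per phase guards pathological inputs and
returns the best state reached with a flag.

Design choices the source scheme leaves open, and how we fixed them:

* **Move directions.** Axis-aligned signed candidates in a fixed order with
  greedy acceptance. Couch corrections are commanded per axis, and
  per-direction results are the clinically reported quantities.
* **Initial sweep magnitude.** Half the centroid-shift length (clamped to
  at least 1 mm). The centroid move itself recovers a pure translation
  exactly, so the sweeps only polish residuals and deformation effects.
* **Rotation center.** The pooled vertex centroid of both daily organs at
  the start of the rotational phase, fixed thereafter; the centroid
  minimizes translation–rotation coupling.
* **Reported rotation.** The (pitch, yaw, roll) Euler decomposition (in
  this package's fixed z·y·x convention) of the *net* accumulated rotation
  matrix. Summing the signed increments per axis would be meaningless for
  a non-commuting sequence containing 45° exploratory moves and could not
  be executed by a couch; within the ±3° clinical range the two readings
  agree to better than 0.01°.
* **Clamp semantics.** With a rotation limit set (default 3°, a typical
  couch tolerance), any candidate whose net rotation would exceed the
  limit on any axis is *skipped* — the limit constrains the search rather
  than truncating an unconstrained result, so every reported state was
  actually evaluated. With the limit at 0 the rotational phase can accept
  nothing and the result equals translation-only positioning exactly.
* **Ties revert.** An exactly unchanged cost counts as "did not decrease".

## PTV construction and coverage

PTVs are built by expanding each *reference* organ and taking the union.
Each vertex moves outward along its area-weighted unit normal `n` by

$$m(n) = \lVert (m_x n_x,\; m_y n_y,\; m_z n_z) \rVert_2,$$

where `m_x` is the R margin if `n_x < 0` else L, `m_y` is A if `n_y < 0`
else P, and `m_z` is I if `n_z < 0` else S. For an isotropic specification
this reduces to a uniform normal offset; on an icosphere the offset
surface matches the analytic enlarged sphere to within 2% at subdivision 3
(tested). Two presets are provided: isotropic 5 mm, and the anisotropic
margins (R, L, A, P, S, I) = (5, 5, 15, 15, 10, 10) mm for the cervix and
(10, 10, 20, 20, 15, 15) mm for the uterus (cervix margins 5 mm smaller
than the uterine ones). The directional offset approximates a Minkowski
sum with an octant-wise ellipsoid; exact Minkowski expansion is out of
scope, and treatment-planning systems themselves differ in the operator
they use.

PTV containment is the *either-inside* predicate over the two expanded
surfaces — no fragile mesh boolean is attempted; the exported "union" mesh
is the advisory overlay of the two closed components. Coverage is the
fraction of daily-model vertices inside the PTV, per organ and combined,
with the total vertex count as denominator (the only reading under which
the clinical "coverage of 95% or higher" is well defined). Vertex-offset
expansion preserves the closed topology by construction; the closed-surface
invariant is re-checked after expansion, but a globally self-intersecting
expansion of a strongly concave organ would need a mesh-boolean repair this
package does not attempt (it does not arise for the phantom shapes and the
preset margins).

## The synthetic phantom

The generator stands in for patient data, which are not distributable. It
emulates the *structure* of inter-fraction cervix–uterus motion, not its
biomechanics:

* **Shapes.** Superellipsoids with squareness 0.8 (slightly boxy), cervix
  semi-axes 15 × 15 × 20 mm at the origin, uterus 25 × 20 × 40 mm with its
  long axis tilted 30° anterior of S–I (an anteverted uterus), stacked
  superior-anterior. Squareness below 1 makes rotations observable in the
  cost (for spheres a rotation about the center would be a no-op), and the
  anteverted anisotropic uterus makes *pitch* the most identifiable
  rotation — matching the clinical observation that pitch dominates while
  yaw and roll corrections are near zero. Volumes (~25 and ~170 cm³) sit
  in the anatomical range. The default resolution (icosphere subdivision
  3) gives 642 vertices per organ: stable classification at seconds-scale
  matching.
* **Motion.** The daily pair is the reference pair under a known rigid
  transform about the pooled reference centroid. When sampled, per-axis
  translations are uniform with half-widths (7.5, 15, 15) mm — A–P and S–I
  twice R–L, reproducing the reported anisotropy in which posterior and
  superior displacements exceed 10 mm in roughly a tenth of fractions
  while R–L essentially never does. Sampled pitch motion is uniform in
  (−6°, 14°) — biased posterior tilt, so the computed corrections (its
  inverse) are dominated by negative pitch — with yaw and roll in ±1°.
* **Deformation.** An optional smooth radial field (random low-order
  polynomial harmonics in the direction vector, scaled to a stated
  amplitude in mm) applied per organ after the rigid motion. Amplitude 0
  gives an exactly rigid phantom (vertexwise); amplitudes are capped at
  20% of the smallest semi-axis to avoid self-intersection. The
  deformation changes volume by less than the first-order bound 3·a/r_min
  (tested).

Everything is bit-reproducible from a seed, and cohort generation derives
per-case seeds deterministically from a master seed.

What the phantom does **not** emulate: bladder/rectum-filling biomechanics,
contouring error and inter-observer variability, image noise, or
non-rigid cervix-vs-uterus articulation (both organs share one rigid truth
plus independent smooth noise). Passing phantom tests therefore
demonstrates the algorithm's correctness and its behavior under controlled
motion, not clinical performance on patients.

## Cohort evaluation

`run_cohort()` applies the full chain to every case × scenario:
translational positioning, an *unconstrained* rotational phase whose angles
are the reported correction (clinical rotation statistics are reported
unclamped, showing where corrections beyond 3° would be needed), and a
clamped (default 3°) rotational phase whose result is scored for coverage
against both PTV presets — the correction a couch would actually be
allowed to execute. Summaries report per-direction medians, interquartile
ranges and 10 mm exceedance percentages (a +12 mm `ty` counts as posterior
exceedance only), per-axis rotation medians and IQRs, and the percentage
of fractions reaching 80% and 95% coverage per PTV and mode. Scenario
contrasts use paired t-tests with Bonferroni correction (raw p times the
family size, capped at 1; family size defaults to pairs × variables and is
configurable) at significance level 0.05 — the field's customary analysis,
kept even though rotation distributions are visibly non-normal; degenerate
zero-variance differences take the paired-t limits (t = 0, p = 1 for
all-zero differences; p = 0 for a constant nonzero difference).

## Known limitations

* **Weakly identifiable rotations.** The phantom cervix is nearly
  axisymmetric about S–I, and both organs sit far from the pooled
  centroid. A large yaw or roll exploratory move about that distant center
  acts mostly as a lever-arm *translation*, which can genuinely reduce the
  mean-squared cost of a roll-misaligned phantom (we measure a 45° yaw
  move halving the cost of a 15° roll misfit). The greedy step-halving
  search can then settle in such a basin: pitch and yaw truths up to 20°
  are recovered to within the 0.5° floor, but roll truths above ~5° retain
  residuals around 0.6–1.1° even though the final alignment cost collapses
  to ~2% of the original. This is a property of the published greedy
  scheme on this geometry, not of the implementation; clinically it is
  immaterial (roll corrections observed in patients are essentially zero),
  but users fitting other anatomies should check identifiability.
* **No alternation.** Translation and rotation run once each, in that
  order; a rotation-induced translation residual is not revisited. The
  end-to-end recovery tests bound the combined effect (≤ 2 mm per axis on
  coupled phantoms).
* **Interior-vertex penalty.** See the cost-model note above: nested
  configurations are penalized by construction.
* **Expansion operator.** Directional vertex offset, not an exact
  Minkowski sum; no self-intersection repair.
* **Test problem sizes.** The packaged tests run phantoms at 162–642
  vertices per organ, 100-case translation sweeps and 50-case rotation
  sweeps, and 20-fraction cohorts in the acceptance script — sizes chosen
  so a full validation runs in minutes on a laptop while keeping every
  stage's contract exercised at the default study conditions.

## A worked call

```{r example, eval = FALSE}
ph <- make_phantom(phantom_spec(seed = 7, translation = c(6, -8, 4)))
fit <- auto_match(ph$daily_cervix, ph$daily_uterus,
                  ph$ref_cervix, ph$ref_uterus,
                  scenario("A"), clamp_deg = 3)
fit
glance(fit)
res <- evaluate_fraction(ph$daily_cervix, ph$daily_uterus,
                         ph$ref_cervix, ph$ref_uterus,
                         scenario("A"), margin_preset("aniso"))
res$coverage
```
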