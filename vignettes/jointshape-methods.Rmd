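---
title: "Shape modeling and articular analysis of bone joints with jointshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape modeling and articular analysis of bone joints with jointshape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointshape)
```

## What the package computes

`jointshape` analyzes cohorts of segmented bone surface meshes at the
level of a whole joint. It combines two strands:

1. **Correspondence-based statistical shape modeling.** Each bone is
   represented by an ordered set of correspondence particles (the same
   index marks the same anatomical location on every subject). PCA of the
   Procrustes-aligned particle coordinates yields *modes of variation*;
   Horn's parallel analysis decides how many modes are signal; walking
   the mean shape ±2 SD along a mode and mapping surface distances
   visualizes what each mode does anatomically.
2. **Joint-level articular analysis in the weightbearing pose.** On each
   subject's original (scanner-frame) bones, articular regions are seeded
   from the second principal curvature, *coverage* is established by
   surface-normal ray intersection between the two mated regions,
   *joint-space distance* is the closest-point distance from covered
   nodes to the opposing bone, and the *congruence index* summarizes how
   well the two surfaces conform. Per-subject node values are carried to
   the cohort's shared correspondence particles so population means and
   SDs can be mapped across the articular surface.

The intended application is the ankle (tibia, fibula, talus; tibiotalar,
tibiofibular and talofibular articulations imaged under load), but every
function is bone-agnostic and fully exercised by the built-in synthetic
generators.

## Model and procedure

### Alignment

Subjects are mutually aligned by rigid point-to-surface ICP of a
reference bone (the talus by default, preserving each subject's
weightbearing tibia/fibula pose relative to its talus), using a seeded
uniform vertex sample and a least-squares (Kabsch) inner solver that
never returns reflections. The ICP objective is asserted non-increasing
at every iteration. A common proximal cutting plane — perpendicular to
the shaft axis at the most proximal level present in *all* aligned
specimens (the minimum over subjects of per-subject maxima) — crops
shaft geometry that is not shared by the cohort; the clip is exact, with
new vertices on the plane and an open (uncapped) boundary.

### Correspondence

Particles are seeded on a template subject by farthest-point sampling
(P = 1024 per bone by default) and propagated to each subject by ICP plus
closest-point projection onto that subject's surface. The template is the
medoid subject (minimal summed closest-point RMS to the rest). This is a
deliberately simple template-propagation scheme: it does **not** optimize
particle entropy across the cohort the way dedicated correspondence
tools do, so per-mode variance fractions on real data should be read as
approximate. Its virtues are determinism (bit-identical under a fixed
seed), a hard surface-proximity guarantee (every particle within 0.5 mm
of its subject's surface, enforced), and nested particle sets (coverage
of the surface improves monotonically as P doubles).

### Shape modes

Generalized Procrustes analysis aligns the per-subject particle arrays;
with `remove_scale = TRUE` each configuration is normalized to unit
centroid size, removing size from the analysis, and shapes are then
rescaled by the mean original centroid size so eigenvalues remain in
mm². PCA uses the n−1 covariance via SVD. Mode SD is √eigenvalue; ±2 SD
warps move the mean particles and carry the mean surface along by
thin-plate-spline interpolation (3D biharmonic kernel `r`, zero
regularization: particle displacements are exact interpolation
constraints). Two variance summaries are reported because both are in
circulation: each mode's fraction of the *total* variance and its
fraction of the *significant-mode* variance.

**Parallel analysis.** Retention compares the eigenvalues of the
column-standardized data against the 95th percentile of eigenvalues of
200 standard-normal matrices of the same shape, stopping at the first
mode that fails. Reps and percentile are configurable; the null is
seeded and the whole procedure is deterministic.

### Curvature

Per-vertex mean curvature uses the cotangent mean-curvature normal over
mixed Voronoi areas, signed by the outward vertex normal (convex bone
regions have H > 0); Gaussian curvature uses the angle defect. These are
standard discrete estimators validated against closed forms on spheres,
cylinders, planes and tori rather than against any particular legacy
implementation. Principal curvatures follow from
K = H ± √(H² − G); discrete estimates can violate H² ≥ G, so negative
discriminants are clamped to zero and flagged per vertex. The "second
principal curvature" used for region seeding is the algebraically
smaller K_min. Boundary vertices lack a full one-ring; their estimates
are computed but flagged and excluded from region seeding.

### Coverage, joint space, congruence

Candidate articular regions threshold K_min (sign-aware: strongly
negative for sockets and grooves, positive for convex caps), keep the
largest connected component, and optionally dilate by mesh rings. A
vertex is *covered* when the ray along its outward normal hits a
candidate face of the mated region within `max_ray_length` (10 mm
default) — and only front-side hits count, so back-to-back surfaces have
zero coverage. Covered area sums faces whose three vertices are covered.
Joint space is the unsigned point-to-triangle distance from covered
nodes to the opposing bone (subchondral bone to bone; cartilage is
invisible to the imaging this is designed for). For congruence, each
covered node on the first surface is paired with its nearest covered
vertex on the second; with the small-angle approximation for the angle
between principal directions (cos 2α ≈ 1, justified by the perpendicular
pairing of evaluation points):

- D = K_min − K_max on each surface,
- Δ = |D₁ + D₂|,
- K^e_min = H₁ + H₂ − Δ/2, K^e_max = H₁ + H₂ + Δ/2,
- CI = √((K^e_min² + K^e_max²)/2).

CI is 0 exactly for locally spherical (umbilic) conforming contact, is
invariant to swapping the two surfaces, and scales as 1/s when all
lengths scale by s. One consequence of taking the small-angle form
literally deserves emphasis: for perfectly conforming *non-umbilic*
pairs (e.g. mated congruent cylinders of radius r) the formula yields
CI = 1/r rather than 0. This is a property of the printed
approximation, is covered by a regression test, and is deliberately not
"fixed".

### Population maps and statistics

Per-subject node values are read at each subject's mapped particle
(nearest vertex to the mean particle after alignment; ties broken by
lowest index). A particle enters the population map when it has a value
for at least half the subjects (configurable). Because the pooling
convention behind cohort summaries of this kind is often left implicit,
both are reported: pooled over all (subject, particle) values, and
across per-particle means; minima and maxima are pooled extremes.
Coverage areas of the two mated surfaces are compared with a paired
t-test; Cohen's d for paired data is mean(d)/sd(d) with the conventional
small/medium/large labels at 0.2/0.5/0.8; post-hoc power and required
sample sizes use the noncentral t distribution (noncentrality d·√n,
two-tailed α), cross-checked in the tests against an independent
evaluation and the normal-approximation closed form
((z₁₋α/₂ + z_power)/d)².

## Synthetic generators: what they emulate, what they do not

`make_joint()` builds mated open patches — sphere-in-socket, cylinder
pairs, plane pairs, and a torus-band trochlea (saddle) — with exact
per-point curvature and gap oracles, bone-outward normals, optional
center offsets and vertex noise. `make_population()` plants k orthonormal
smooth displacement modes (explicitly orthogonalized against the
similarity-transform tangent space, so planted modes are pure shape, not
pose or size), draws coefficients Normal(0, SD²), adds vertex noise, and
poses each subject with a random similarity transform, optionally
mirroring a fraction as left-sided. `simulate_joint_cohort()` combines
both for end-to-end runs.

These fixtures validate geometry, recovery and calibration, but they are
not anatomy: real bones have spatially correlated segmentation error,
non-Gaussian shape variation, imperfectly mated surfaces and regionally
varying mesh quality. Passing the synthetic suite demonstrates that the
machinery is correct and calibrated, not that any particular anatomical
result will reproduce; shape-mode fractions on real data additionally
depend on the correspondence optimizer, where this package deliberately
substitutes the simpler propagation scheme described above.

Default study conditions used in the tests: cohorts of 5–10 subjects for
end-to-end runs (40 for mode-recovery checks, matching the scale of the
motivating cohort of 27 plus headroom for stable sample covariances),
1024 particles per bone (reduced to 48–200 in fast tests), vertex noise
0.01–0.05 mm against 1 mm-class mesh resolution, planted mode SDs of a
few mm. These were chosen once as representative of weightbearing CT
bone morphometry and are stated in each test.

## Numerical choices and edge cases

- PLY I/O supports ascii and binary little-endian; binary round trips
  are bit-exact, ascii carries 17 significant digits. Stored normals are
  ignored; orientation always comes from face winding.
- Smoothing is Taubin's λ/μ scheme (0.5/−0.53, 10 iterations default);
  decimation is quadric edge collapse with midpoint placement.
  Parameters are recorded in the pipeline provenance output.
- Clipping classifies vertices with a 1e-9 on-plane tolerance; cut
  points are cached per edge so adjacent faces share boundary vertices
  and no degenerate faces arise from cuts through vertices.
- GPA is defined up to a global rigid motion; the implementation keeps
  the initialization frame (the first subject's orientation) and, inside
  the correspondence model, restores the cohort's average centroid so
  the mean stays in the ICP-aligned millimetre frame.
- Degenerate statistics (zero-variance differences) are flagged rather
  than propagated as NaN: identical pairs report t = 0, d = 0, p = 1.
- All randomness (ICP sampling, farthest-point start, parallel-analysis
  null, generators) flows from explicit integer seeds; reruns are
  bit-identical.

## Known limitations

- The correspondence scheme is template-propagation, not entropy
  optimization; correspondence quality degrades for cohorts with large
  shape differences, and mode variance fractions inherit that error.
- Coverage and congruence are evaluated on subchondral bone; no
  cartilage model is included.
- The congruence formula is the literal small-angle form discussed
  above.
- Multi-domain shape modeling (modes of relative bone pose) is out of
  scope; the pipeline models each bone's shape independently and only
  the articular analyses see the joint as a whole.

## Reproducing the shipped numbers

`scripts/acceptance.R` recomputes the desk-scale congruence value from
scratch via the analytic joint oracle and the congruence algebra, and the
test suite (`tests/testthat/`) regenerates every synthetic fixture and
oracle value at run time; no stored data is involved anywhere.
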