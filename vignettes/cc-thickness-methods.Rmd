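---
title: "Laplace-equation corpus callosum morphometry: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laplace-equation corpus callosum morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmorph)
```

This vignette is the package's own account of the science it implements:
the geometric model, the boundary conditions and numerical choices behind
it, the parameters a user may want to touch, what the synthetic fixtures
establish (and what they cannot), and the known limitations.

## 1. The analysis object and the pipeline

The object of analysis is the mid-sagittal cross-section of the corpus
callosum (CC): a bent, ribbon-like 2D shape bounded below by the
fornix-facing (inferior) boundary and above by the superior boundary, with
two anatomical endpoints — the rostrum tip anteriorly and the inferior
splenium tip posteriorly. The pipeline is

1. **mid-sagittal plane**: rigid registration of whole-brain label
   centroids to a template (Kabsch/SVD), template mid-plane pulled back by
   the inverse transform;
2. **pose standardization**: AC at the origin, PC on the anterior-posterior
   axis, mid-plane normal on the left-right axis;
3. **meshing**: iso-0.5 marching-squares contour of the (possibly soft)
   CC mask, constrained Delaunay triangulation of its interior;
4. **Laplace thickness**: harmonic potential, intercallosal line, conjugate
   level paths;
5. **metrics and sub-segmentation**.

Steps that require trained networks in the original setting (plane-adjacent
segmentation, AC/PC localization) are inputs here: the package consumes
masks and landmark coordinates.

## 2. The thickness model

On the meshed CC domain $\Omega$ we solve $\Delta u = 0$ with Dirichlet
data $u = -1$ on the inferior chain and $u = +1$ on the superior chain.
The zero level set of $u$ — the *intercallosal line* — runs from the
anterior to the posterior endpoint midway (in the harmonic sense) between
the two boundaries, and is the backbone for length, curvature, profile
sampling, and the shape-aware sub-segmentation.

Thickness does not trace gradient streamlines. Instead we compute the
harmonic conjugate $v$: in the continuum, $\nabla v = R_{90}\nabla u$
makes $u + iv$ holomorphic, so level curves of $v$ are exactly the
streamlines of $\nabla u$. Discretely, $v$ is the least-squares potential
of the rotated gradient — the solution of the cotangent-Laplacian Poisson
problem whose right-hand side is the divergence of $R_{90}\nabla u$,
area-weighted, with the gauge $v = 0$ at the anterior endpoint and the
sign fixed so $v$ increases toward the posterior endpoint. The local
thickness at a point on the intercallosal line is the length of the
$v$-level polyline through it, clipped to the connected component through
the sample point; its ends must land on oppositely labeled boundary
chains, otherwise the sample is flagged missing rather than failing the
run. An explicit per-triangle streamline tracer
(`thickness_by_streamline`) is kept in the package as an independent
route; the suite requires 2% agreement between the two on every fixture.

### Boundary conditions at the endpoints

The charges $\pm 1$ determine the field on the long boundaries but leave
the short boundary segments at the two CC ends unconstrained. Driving the
Dirichlet data all the way into the endpoints creates a step-data
singularity there (locally $u = \tfrac{2}{\pi}\theta$ with conjugate
$v = -\tfrac{2}{\pi}\ln r$), which would bend the near-end level paths
into small arcs around the endpoint and destroy the analytic solutions on
the test shapes. We therefore treat the boundary between each endpoint and
the first boundary *corner* as a natural (zero-Neumann) **end cap**:

- on a straight ribbon the exact solution is then the linear field
  $u = 2s/h - 1$, which the linear finite elements reproduce to solver
  precision;
- on an annulus sector ($r_1 = 10$, $r_2 = 15$ mm) the exact solution is
  $u = 2\ln(r/r_1)/\ln(r_2/r_1) - 1$, reproduced to $10^{-3}$ at a 0.25 mm
  edge length, with $v \propto \theta$ and radial cross-cuts of length
  exactly $r_2 - r_1$.

Caps are auto-detected (`detect_end_caps`): walking the boundary from each
endpoint, the cap ends at the first vertex where the boundary direction —
averaged over a 0.75 mm window to suppress rasterization wiggle — turns by
more than 40°; within the look-ahead window the vertex with the strongest
single-edge turn is taken as the corner. If no corner appears within 25%
of the boundary length, a fixed 2 mm fallback cap is used (with a
warning). The endpoints are *not* pinned to $u = 0$: pinning would distort
the annulus solution by $\approx 0.1$ near the caps, and the zero level
set terminates on the caps within one edge length of the endpoint vertices
anyway (an invariant the tests assert).

### Discretization

The cotangent-weight linear FEM Laplacian is assembled per triangle and
solved with a sparse Cholesky factorization (Matrix package). Meshes come
from a purpose-built constrained Delaunay triangulator (`src/cdt.cpp`,
Bowyer-Watson insertion, constrained-edge recovery by flips,
centroid-in-polygon classification): boundary polygons are densified to
the target edge length with points placed exactly on the input segments,
so the mesh boundary *is* the contour and the triangle areas sum to the
polygon's shoelace area to $10^{-9}$; the interior is filled with a
hexagonal lattice (deterministically jittered by $10^{-4}$ edge lengths to
avoid cocircular degeneracies). No R triangulation package is available in
the target environment, which is why this primitive is built here.

Level sets are extracted by marching triangles with linear edge
interpolation and chained into polylines; each polyline point carries its
mesh edge and interpolation weight so that other fields ($v$, positions)
interpolate exactly along it.

## 3. Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `max_edge` | 0.75 mm (pipeline) | target mesh edge; FEM error is $O(h^2)$ in $u$, $O(h)$ in gradients |
| `profile_n` | 100 | thickness samples at $s_i = (i-0.5)/n$ in arc length; half-step offset avoids degenerate end samples |
| charges | inferior −1, superior +1 | sign-agnostic downstream; fixed convention |
| cap window / angle | 0.75 mm / 40° | corner detector scales; robust for 0.25–1 mm rasters |
| `half_width` (slices) | 2.5 mm | slice stack covers ≥ 2.5 mm left/right; 5 mm corrected volume |
| CC-index fractions | 0.1, 0.5, 0.9 | arc-length stand-ins for the classical genu/body/splenium thicknesses; configurable |
| Witelson fractions | 1/3, 1/2, 2/3, 4/5 | classical scheme defaults |
| Hofer-Frahm fractions | 1/6, 1/2, 2/3, 3/4 | classical scheme defaults |
| curvature `resample_mm` | 1 mm | see below |

**Curvature.** Mean unsigned curvature is the turning-angle sum divided by
arc length. Raw level-set polylines zigzag at sub-edge scale, which
inflates the raw turning sum by ~25% on the annulus fixture; the line is
therefore resampled at 1 mm arc spacing first, and the sum is normalized
by the arc span between the first and last segment midpoints (for chords
of a circle the inscribed turning sum then equals the swept angle exactly,
so the estimator is unbiased on arcs: measured $1/\sqrt{150}$ to 0.02%).
`resample_mm = 0` restores the raw definition.

**CC index.** Thicknesses at three profile fractions divided by the
anterior-posterior extent. The AP axis is taken as the chord between the
two endpoint vertices — identical to the anterior axis after pose
standardization, and it keeps the index (like every other metric, which
the tests require) invariant under in-plane rigid motion of the input
mask.

**5 mm volume.** Each slice contributes its area times the overlap of its
spacing band with $[-2.5, 2.5]$ mm, so the reported volume reflects a
consistent 5 mm width at any voxel size (exactly $5A$ for 5×1 mm or
11×0.5 mm constant-area slices).

## 4. The synthetic world

`generate_ribbon` rasterizes an arched band: a circular-arc centerline
(default radius 20 mm, half-turn span, so length 62.8 mm and curvature
0.05 mm⁻¹) with half-width growing linearly 2.5 → 4 mm toward the
posterior end — CC-like scale and topology, with AC/PC placed 5 mm beyond
the downward-pointing ends so the endpoint rule and chain labeling face
realistic geometry. Ends are *flat* caps (the analytic test shapes are
flat-capped, and flat caps produce the boundary corners the cap detector
expects); rounded caps are available. Rasterization is anti-aliased by
default (4×4 subpixel coverage), emulating the thresholded soft
segmentation maps that make sub-voxel contours meaningful; binary
rasterization (accuracy limited to half a pixel) and a
boundary-pixel-flip noise model are available for robustness tests.
`generate_label_volume` builds paired 3D label maps under a known rigid
transform (16 spherical blobs in a 112³ volume — a scaled-down analog of a
whole-brain segmentation, sized so that nearest-neighbor resampling error
stays below the 0.1° registration-recovery budget).
`generate_test_retest` produces per-subject scan pairs under small pose
jitter with covariates for the group-model and ICC machinery.

What a green test establishes: exactness of the geometry code on shapes
with closed-form answers, sub-voxel recovery through the full rasterized
path, determinism, calibration of the statistics. What it does not: tissue
contrast, segmentation failure modes (fornix fusion, lesions), partial
voluming beyond linear coverage, or any claim about real MRI accuracy.

## 5. Numerical tolerances and degenerate inputs

- $u$: $10^{-6}$ (linear solutions, exact up to solver tolerance) and
  $10^{-3}$ (log solution at $h = 0.25$ mm, $O(h^2)$).
- $v$: P1 gradients are $O(h)$, so conjugate residuals against the
  analytic $\theta$-field are discretization-limited: RMS $\le 10^{-3}$,
  max $\approx 2\times 10^{-3}$ at $h = 0.25$ mm, halving with $h$.
  Orthogonality of $\nabla u$ and $\nabla v$ is exact on linear fields and
  holds to median $|\cos| \approx 10^{-2}$ on curved ones.
- Thickness: 1% on analytic fixtures; RMSE ≤ 0.25 mm through the default
  0.5 mm rasterized path. The one to two outermost samples on rasterized
  shapes may cut the rounded cap corner and read up to ~0.9 mm low; the
  half-step sampling and the RMSE criterion absorb this, but users reading
  single end samples should know they are the least reliable positions
  (consistent with reliability dropping at the CC endpoints in practice).
- Degenerate triangles abort the Laplace solve with the offending indices;
  empty masks, self-intersecting contours, coincident endpoints, adjacent
  endpoints, rank-deficient registrations and designs, and slice stacks
  not covering the 5 mm band are all explicit errors.
- Plane disagreement uses midpoint polar quadrature (256×512), exact for
  parallel planes and within 1% of a $10^6$-sample Monte-Carlo oracle for
  tilted ones.

## 6. Open design choices, resolved

- **Endpoint rule**: nearest boundary vertex to AC (anterior) and PC
  (posterior); the alternative extremal-projection rule onto the AC-PC
  line is implemented (`rule = "projection"`). The exact upstream
  construction is not public; the default is declared, not asserted.
- **Profile sampling**: uniform in arc length (not in $v$); uniform-$v$
  sampling would oversample thin regions where $|\nabla u|$ is large.
- **Sub-segmentation fractions along the new scheme**: measured along the
  intercallosal *arc length* (not the endpoint chord), matching
  "perpendicular to the intercallosal line".
- **Group models**: two-sided $t$ tests on the group coefficient,
  patients coded 1 (negative $\beta$ = reduction in patients); BH step-up
  across the 100 positions. ICC is the two-way random, single-measure,
  absolute-agreement form, which penalizes systematic offsets — the
  property that distinguishes test-retest agreement from mere correlation.
- **Statistical invariants with spec-level defects** (ledgered): the BH
  step-up is *not* idempotent on arbitrary adjusted vectors (only constant
  vectors are fixed points), and slice coverage is not monotone in spacing
  (it is always ≥ the requested half-width); tests assert the corrected
  properties.

## 7. Known limitations

- The package analyzes one mid-sagittal mask (or mesh) at a time; 3D
  surface-based statistics and multi-slice meshing are out of scope.
- Binary masks limit boundary accuracy to half a pixel; soft masks are
  strongly preferred inputs.
- The conjugate-potential construction assumes a simply connected domain;
  masks with holes are reduced to their largest outer contour.
- Head-pose standardization puts PC exactly on the AP axis only when AC
  and PC lie on the mid-plane (anatomically they do; the residual is the
  landmarks' off-plane distance).
- The cap detector assumes the CC ends are corner-delimited; on extremely
  smooth, round-ended shapes it falls back to a fixed 2 mm cap and warns.
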