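---
title: "Silhouette-based camera recovery and texture stitching: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Silhouette-based camera recovery and texture stitching: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents how `phototex` works, which knobs matter, and
where its design departs from the obvious construction — the kind of
information a maintainer or a careful user needs before trusting the
output on their own specimens.

## 1. The problem and its geometry

The input is a triangle mesh `M` of a specimen (typically segmented from
a micro-CT scan, in mm) and a set of photographs taken free-hand: the
specimen was rotated by hand, so nothing is known about each camera
except the lens (focal length and sensor width) and a rough working
distance `r0`. Because the mesh has no texture yet, the only signal
shared between a photograph and the model is the *silhouette*.

A camera pose is `c = (θ, φ, r, δx, δy, δz)`: spherical coordinates
about the mesh mass center plus three local rotations. The frame is
built from axis rotations,

```
pos = R_y(θ) R_z(φ) (r, 0, 0)'
ray = R_y(θ) R_z(φ) R_x(δx) R_y(δy) R_z(δz) (−1, 0, 0)'
up  =            same chain applied to (0, 1, 0)'
```

with right-handed active rotations (`R_y(β)` maps `(1,0,0)` to
`(cos β, 0, −sin β)`). With `δ = 0` the ray points exactly at the mass
center; `δx` rolls the image, while small `δy`/`δz` translate it
horizontally/vertically. Projection is plain pinhole, `x' = x·f/z`, with
the image origin top-left, the principal point at the image center, and
pixel centers at half-integers. None of these conventions is observable
individually — only round trips are — so they are fixed once, package
wide, and verified by render/recover round-trip tests.

The matching cost is the directed mean boundary distance: the Euclidean
distance transform `I^d` of the photograph's silhouette boundary,
averaged under the boundary pixels of the rendered silhouette. It is
zero iff every rendered boundary pixel lies on the photo boundary, and
it is the quantity the acceptance threshold (0.7 px) and all reported
costs refer to. Note its *directedness*: a render missing a feature the
photo has is penalized only indirectly. In practice the optimum is still
sharp for asymmetric specimens; for near-symmetric ones (spheres,
radially symmetric fruit) no silhouette method can identify the pose —
this is the documented failure mode, and the reason the synthetic
fixtures are deliberately lobed.

## 2. The three-stage solver

**Coarse search.** Candidate directions are the vertices of a subdivided
icosahedron (`10·4^k + 2`; `k = 4` gives the 2562 used at full scale),
crossed with distances `r0 + {0, ±10, ±20, ±30}` mm. Every candidate is
rendered once with `δ = 0` (the renders are cached and shared across
photographs with the same `r0`). Because `δ` is not sampled, the
in-image effect of camera rotation is compensated in 2D instead: the
render boundary is rotated about its silhouette centroid over a 1°
grid and translated onto the photo centroid, and the compensated cost
ranks the candidates. The winning rotation α and centroid offset seed
the local rotations (`δx = −α`, `δy`/`δz` from the arctangent of the
screen offsets over the focal length).

**Gradient descent.** Central differences with per-dimension offsets
(0.1° for the five angles, 10 mm for r) give a six-vector gradient that
is scaled per dimension (`s = (1e-4, 1e-4, 1e1, 1e-7, 1e-7, 1e-7)`) and
followed with a backtracking line search. Two implementation details
matter on this objective, which is a *staircase* (renders are binary and
pixel-quantized):

* the line search backtracks from large steps (`h = 2^12` down to
  `2^-10`), accepting the first strict improvement — with unit-bounded
  steps the printed scales move the pose by far less than one pixel's
  worth and the stage would stall immediately;
* when both central-difference samples land on the same flat stair the
  quotient is pure noise, so the stencil is widened (offsets doubled, up
  to 32×) until a descending step is found.

**Hill climbing.** A seeded random walk: pick one dimension, add a
uniform offset (±0.01 rad for angles, ±0.1 mm for r), keep the proposal
only if the cost strictly decreases. This polishes the last
sub-pixel-scale misfit and escapes shallow local minima that gradient
descent cannot see.

**Multi-start.** The 2D-compensated ranking is an approximation, and on
real ranking noise the true basin frequently sits 2nd–10th rather than
1st. `estimate_camera_pose()` therefore refines the `n_starts` (default
5) best-ranked candidates independently and keeps the lowest final cost;
`n_starts = 1` reproduces the classic single-chain algorithm. On the
synthetic evaluation this one change cuts the median position error by
roughly half an order of magnitude and its cost is linear in `n_starts`.

For ranking only, candidate boundaries are subsampled to at most
`rank_boundary_cap` (200) pixels — the cost is a mean, so a uniform
subsample estimates it without bias, and winners are re-scored on full
boundaries by the later stages. All public metric functions are exact.

## 3. What the fixtures emulate — and what they do not

`make_mesh()` produces watertight star-shaped meshes: a subdivided
icosphere whose radial field carries seeded random protrusions, scaled
to a ~60 mm bounding diagonal. The `insectoid` variant (16 narrow,
high-amplitude lobes) is the evaluation default because pose
identifiability lives in silhouette detail: a test guards that its
silhouettes from 24 equally spaced azimuths are pairwise at least 1 px
apart in chamfer distance. `make_eval_set()` samples ground-truth poses
from `r ∈ [540, 560]` mm, `θ ∈ [0, 2π]`, `φ ∈ [−0.7π/2, 0.7π/2]`,
`δx ∈ [0, 2π]`, `δy, δz ∈ [−0.006π, 0.006π]` and renders both binary
silhouettes and flat-colored photographs.

The evaluation optics deserve a note. With the matching frame fixed at
462 × 306 (1/8 of the 3696 × 2448 camera frame), the focal length sets
how many pixels the specimen subtends, and that in turn sets an
*information floor*: at a wide-angle 18 mm framing a 60 mm specimen
spans ~38 px, one boundary pixel corresponds to ~14 mm of camera motion,
and we measured poses 25–40 mm from truth whose silhouettes rasterize
*identically* — no solver can do better than the image contains.
`eval_intrinsics()` therefore uses a frame-filling 105 mm telephoto
framing (the long end of a standard 18–105 zoom; close-up specimen
photography fills the frame), under which the specimen spans ~224 px and
1 px ≈ 1 mm. Under these conditions the full solver reaches a median
position error near 1 mm at ~550 mm range.

What the fixtures do *not* emulate: real segmentation noise in the
masks (graph-cut binarization artifacts, pin shadows), exposure and
color differences between photographs, lens distortion, and mesh error
from real CT segmentation. Passing the synthetic recovery bounds
therefore demonstrates the solver and pipeline logic, not robustness to
photographic nuisance factors.

Synthetic CT volumes (`make_volume()`) are parity-count voxelizations of
the fixture mesh with salt-and-pepper noise; the segmentation chain
(seeded region growing at a threshold, optional ball-kernel
opening/closing, cavity filling) recovers them to within two voxel
diagonals of the original surface. Region growing runs first, so
isolated bright noise never joins the specimen; the growing seed is
chosen on a 3×3×3-smoothed copy so a lone bright voxel cannot win.

## 4. Isosurfacing

The label volume is isosurfaced at 0.5 after one pass of 3×3×3 box
smoothing of the indicator, with linear interpolation of the crossing
along voxel edges. The extraction marches a translation-invariant
6-tetrahedra decomposition of each cell: every shared cell face is cut
by the same diagonal from both sides, so the mesh is watertight and
edge-manifold by construction, with no case tables to transcribe. The
smoothing matters quantitatively: isosurfacing a raw binary indicator
inflates surface area by ~28% on a digitized sphere (staircase
faceting); with one smoothing pass the area is within 0.2% of `4πR²`.
A fixture test cross-checks the geometry against an independent
marching-cubes implementation. Thin single-voxel features do not survive
the smoothing; pass `smooth_iters = 0` to keep them (at the cost of
faceting).

## 5. UV atlas

Charts are grown greedily over face adjacency under a normal-cone
criterion (default 35°: a face joins while its normal deviates from the
chart seed's by no more than the cone). Each chart is flattened by
orthogonal projection onto its area-weighted average normal plane —
legitimate precisely because the charts are built near-flat, which
bounds the projection distortion; a chart that folds over (a projected
triangle flips orientation) is split in two and re-flattened. Flattened
charts are shelf-packed by decreasing height with a 2-texel gutter, and
the texel→(face, barycentric) map is filled by rasterizing the UV
triangles. The atlas is deliberately simple: it trades texture-space
efficiency (~25% occupancy at default settings) for robustness and
determinism.

## 6. Texturing, stitching, occlusion fill

Back-projection walks atlas texels: the surface point is projected into
the photograph and kept only if it lands in the mask foreground, passes
a depth-buffer visibility test (slack `depth_tol = 1` mm against a
render from the same camera), and faces the camera
(`−ray·normal > 0.01`). Colors are sampled bilinearly by default;
`sample_mode = "nearest"` exists for piecewise-constant synthetic
photographs where interpolation across color discontinuities is not an
error but an unwanted blend.

Overlaps between two textures are resolved by a minimum s-t cut over the
4-neighbor texel graph (edges never cross chart gutters), computed with
`igraph`. Neighbor capacities are the summed RGB mismatch
`‖I_A(p)−I_B(p)‖ + ‖I_A(q)−I_B(q)‖`, so cuts prefer to pass where the
two textures already agree and the seam is invisible. Texels adjacent to
a region only one texture covers are hard-linked (capacity 10^6) to that
texture's terminal. Every overlap texel additionally gets terminal
capacities `w·(1 + I^n)` from the facing maps (`I^n = −ray·normal`,
larger = more frontal): severing a frontal texture's link is expensive,
so sharper texture wins where colors tie. The orientation of this term
is easy to get backwards — assigning a texel to A severs its *B*-link —
and is pinned by an exhaustive-enumeration test on 12-texel overlaps.
Multi-photo merging folds pairwise in a deterministic order (decreasing
coverage, then pose cost, then name). Stitching never blends: each texel
is copied from exactly one source, recorded in the `source_id` map.

Texels never covered by any accepted photograph are filled by boundary
diffusion (wave-by-wave mean of covered 4-neighbors) and then smoothed;
charts with no coverage at all have no boundary to copy, so they are
seeded with the global mean covered color. Optional exemplar synthesis
then replaces the blur: reference patches are sampled at
surface-area-uniform random points and read from the chart's planar
parameterization — the chart plane stands in for a local geodesic
(exponential-map) frame, which is exact in the flat limit and accurate
to the normal-cone bound otherwise; patches crossing chart boundaries or
touching the missing region are discarded. Each target patch is matched
to its L2-nearest reference and blended with a cosine falloff, over
(default) 3 rounds. Synthesized texels are flagged `-1` in the source
map: they are plausible texture, not measurement, and downstream users
can mask them.

## 7. Numerical choices and degeneracies

* Rasterization is pixel-center coverage with a top/left tie rule and no
  antialiasing, identically in the fast fused cost path and the full
  renderer, so a re-render from a reported pose reproduces the reported
  cost bit for bit. No back-face culling: CT meshes may carry flipped
  faces.
* The distance transform is the exact Euclidean transform
  (Felzenszwalb–Huttenlocher two-pass), with a large finite sentinel
  (1e18) instead of infinity in the lower-envelope recursion.
* The rotation search samples the distance field bilinearly at the
  rotated boundary positions; samples leaving the frame clamp to the
  border value rather than disqualifying the candidate.
* Hill-climbing and every other stochastic component take an explicit
  seed, and the package snapshots/restores the caller's RNG state, so
  identical configurations are bit-reproducible and never perturb user
  code.
* Degenerate inputs fail loudly: empty silhouettes, all-background
  volumes, non-manifold meshes for charting, fully uncovered atlases,
  and missing regions too large to leave any valid reference patch.

## 8. Problem sizes used by the shipped checks

The test suite and the acceptance script choose sizes that exercise the
full algorithms at laptop scale: fixtures at icosphere subdivision 3–4
(1280–5120 faces), atlases at 192–256 texels, volumes around 40–70
voxels per side, and camera-recovery batches of 10 (tests) and 20
(acceptance script) cases at the full 2562-direction / 1000-iteration
solver settings. Module tests use a 42-direction grid, which exercises
identical code paths at a fraction of the cost.

## 9. Known limitations

* Silhouette matching cannot disambiguate near-symmetric objects; costs
  stay low while poses are wrong. Inspect the per-photo costs *and* the
  reconstruction.
* The directed cost ignores photo features absent from the render; a
  grossly wrong mesh can still score moderately.
* No exposure harmonization or gradient-domain seam smoothing: seams are
  invisible only insofar as the photographs agree photometrically.
* The planar chart flattening is not a low-stretch global
  parameterization; texture density varies a few percent within a chart.
* Real-data inputs must be binarized upstream; mask quality directly
  bounds pose accuracy.
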