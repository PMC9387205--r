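---
title: "Encoding high-dimensional data as perceptual colors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding high-dimensional data as perceptual colors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colorcloud)
```

## The idea

When a dataset has one high-dimensional profile per entity — a gene's
expression across cells, a sample's taxonomic composition — and those
entities must be shown *somewhere else* (on a network, a map, a tree), the
spatial coordinates are already spoken for. Color is the channel that
remains. `colorcloud` turns each profile into a color such that the
perceptual difference between two colors approximates the distance between
the two profiles.

This works because of two facts. First, UMAP reduces high-dimensional data
to three dimensions while partially preserving Euclidean distances, both
locally and globally. Second, the CIELAB color space was designed to be
approximately perceptually uniform: Euclidean distance between two
$(L^*, a^*, b^*)$ triples approximates how different the two colors look.
Composing the two — reduce to 3D, then place the 3D cloud inside CIELAB —
yields a color per entity whose pairwise perceptual differences mirror the
data's structure.

The complication is that a computer monitor cannot display every CIELAB
triple. The displayable region (the *gamut*) is the image of the sRGB unit
cube under the sRGB→CIELAB transform: an irregular, non-convex, roughly
spindle-shaped solid. The core of the package is an optimization that
places the point cloud inside this solid as large as possible.

## The fit

Given a 3D cloud $X = \{x_i\}$, we first normalize it: translate the
centroid to the origin and divide by the maximum point norm, so every cloud
enters the optimizer at unit radius. The normalization is stored with the
fit so the identical mapping can later be applied to new points in the same
coordinate frame.

We then search over a seven-parameter similarity transform

$$ x \mapsto s\,R(\theta_1,\theta_2,\theta_3)\,x + t, $$

with translation $t \in \mathbb{R}^3$, rotation angles applied intrinsically
about the $L^*$, $a^*$, $b^*$ axes in that fixed order, and uniform scale
$s > 0$. Similarity transforms preserve all pairwise distance *ratios*, which
is exactly the property the encoding must keep; non-uniform scaling or
shearing would distort them and is deliberately excluded.

Only the convex hull of the cloud enters the objective: if every hull vertex
is inside a convex region, every point is. (The gamut is not perfectly
convex; see *Limitations*.) Working on the hull — typically a few dozen
vertices even for clouds of thousands of points — makes each objective
evaluation cheap and nearly independent of the input size.

The objective, maximized with Nelder–Mead, is

$$ f(t, \theta, s) \;=\;
   \frac{\sum_k w_k\,\mathrm{ext}_k}{\sum_k w_k}
   \;-\; \lambda \sum_{v \in \mathrm{hull}} \mathrm{overshoot}(v), $$

where $\mathrm{ext}_k$ is the extent (max minus min) of the transformed hull
along CIELAB axis $k$, the $w_k \ge 0$ are user weights, and
$\mathrm{overshoot}(v)$ is the CIELAB distance by which a transformed vertex
protrudes outside the gamut (zero inside). Equal weights reward overall
spread; raising one weight prioritizes spreading the cloud along that axis —
for instance $w = (2, 1, 1)$ emphasizes lightness differences, which survive
grayscale printing.

### Why the penalty sums over vertices

The penalty must dominate the size term at the boundary, or the optimizer
will happily buy spread by letting points protrude. The marginal size gain
from pushing a single vertex outward in direction $u$ is at most
$\sum_k w_k |u_k| / \sum_k w_k \le \sqrt{3}/3 \approx 0.58$ per CIELAB unit.
Summing overshoots makes the marginal *cost* of any one protruding vertex
equal to $\lambda$, independent of how many vertices the hull has, so the
default $\lambda = 10$ keeps every vertex essentially inside at any optimum.
Averaging the overshoots instead would divide that cost by the vertex count
$V$: for $V \gtrsim 17$ protrusion would become profitable, and in
experiments on a 500-point Gaussian cloud a mean-based penalty indeed left
vertices almost 10 CIELAB units outside. With the sum form the measured
maximum hull overshoot at the optimum is 0.

A related observation, visible in the package's own property tests: the
penalty weight only has to clear the $\sqrt{3}/3$ threshold. At
$\lambda \le 0.58$-ish the objective is unbounded (size grows faster than
the penalty as $s \to \infty$) and the fit diverges; anywhere above it,
larger $\lambda$ only shaves the last fraction of a unit of residual
protrusion, at a slightly smaller fitted scale.

### Multi-start strategy

Nelder–Mead is a local, derivative-free method, and the objective is
non-convex (the gamut is an irregular solid; rotations wrap around). We
therefore run 25 starts: the first from the identity rotation, the rest
from rotation angles drawn uniformly from $[0, 2\pi)^3$ under the fit seed.
Every start begins translated to a fixed interior point of the gamut (the
image of mid-gray, roughly $L^* = 53.4$, $a^* = b^* = 0$) at initial scale
40 — comfortably inside for a unit-radius cloud, so early iterations explore
orientation rather than fight the penalty. All starts are returned ranked;
ties break toward the lowest start index, making output deterministic given
the seed. The rigid-invariance property (pre-rotating the input changes the
best objective by well under 2%) is the practical check that 25 starts are
enough at these problem sizes.

### Gamut geometry

Membership is analytic: a Lab point is displayable iff its inverse image
under the CIELAB→sRGB transform lands in the unit cube. This is exact — no
precomputed boundary mesh, no resolution artifacts; the triangulated mesh
the package can produce is for visualization only. Overshoot is measured
along the ray from the fixed interior point: the boundary crossing is
located by bisection (48 halvings, i.e. ~$10^{-14}$ relative precision) and
the overshoot is the distance from the point to that crossing. This is a
ray distance, not the true nearest-boundary distance; it is cheap, exact in
the limit, deterministic, and an upper bound on the true distance, which is
all a penalty needs. The construction assumes the gamut is star-shaped from
the interior point, which the test suite probes empirically on a thousand
random rays.

The color conversions themselves use the D65/2° white point
$(X_n, Y_n, Z_n) = (95.047, 100, 108.883)$ and the piecewise sRGB transfer
function (threshold 0.04045/0.0031308, slope 12.92, exponent 2.4), chosen
over the $\gamma = 2.2$ approximation for exact invertibility. The
sRGB→XYZ matrix is derived at full precision from the sRGB primary
chromaticities with its columns scaled so that RGB $(1,1,1)$ maps exactly
to the reference white; this makes the neutral axis exactly achromatic
($|a^*|, |b^*| < 10^{-13}$ for $r=g=b$), which the published 7-digit
rounded matrix does not quite achieve. Round trips through the conversion
pair are accurate to ~$10^{-15}$ per channel. Hex output rounds half away
from zero, so tables are bit-reproducible across platforms.

## Reduction tracks

Three tracks turn raw data into the 3D cloud; a fourth accepts 3D data
directly (from any reduction method the user prefers).

* **High-dimensional** (`reduce_highdim()`): centered PCA to 50 components
  (capped at the data's rank), then UMAP to 3D with 15 neighbors.
* **Single-cell** (`reduce_single_cell()`): the entities colored are
  *genes*, described by their expression across cells. Counts are
  normalized per cell, $x' = \log(1 + x \cdot 10^4 / \text{cell total})$,
  with no gene centering or scaling, then reduced by uncentered PCA
  (truncated SVD) to 50 components and UMAP with 50 neighbors. Natural log
  is the default — it is what the standard log-normalization in single-cell
  toolkits actually computes, although that procedure is often described as
  a log2 transform; a `log_base` argument exposes the choice, which is a
  monotone rescaling and does not change neighbor structure. Cells with
  zero totals are dropped with a warning. Graph-based clustering of the
  genes, which single-cell pipelines often run at this stage, is omitted:
  cluster labels would never be consumed — the colors depend only on the
  coordinates.
* **Distance matrix** (`reduce_distance()`): a square symmetric matrix used
  as a precomputed metric for UMAP (15 neighbors).

UMAP runs single-threaded with a fixed seed, so every track is
deterministic: same input, same seed, identical coordinates. Parameters the
method does not pin down (`min_dist`, metric for the first two tracks)
stay at the embedding library's defaults.

## Synthetic data and what the tests show

The generators in `synth_*()`/`generate_fixture()` produce datasets whose
ground truth is known by construction:

* `clusters3d` — 3 spherical Gaussian clusters in 3D, centers 10σ apart:
  an idealized "already reduced" cloud.
* `highdim-clusters` — the same design in 50 dimensions (300 points).
* `sc-counts` — 90 genes × 60 cells; genes in one of 3 modules share a
  block-structured Poisson mean (5 inside the module's cell block, 0.2
  outside), giving a realistically sparse (>50% zeros) count matrix.
* `cliques-dist` — 60 entities in 3 cliques, within-distance ~0.1,
  between ~10, 10% symmetric jitter.

On each, the end-to-end check is that entities from the same group end up
with more similar colors (mean within-group CIELAB distance below mean
between-group distance — in practice 20–50× smaller). These fixtures have
clean, well-separated, isotropic structure. Passing them demonstrates the
pipeline's mechanics — normalization, embedding, fit, encoding — not
robustness to what real data add: overlapping clusters, batch effects,
library-size gradients, dropout beyond Poisson sparsity, or manifolds with
no cluster structure at all. On real data the color encoding is only as
faithful as the 3D embedding underneath it.

Problem sizes throughout the examples and tests (500-point clouds, 25
starts, 50–300 entities per track) are desk-scale choices that exercise
every code path; the fit cost is driven by the hull size, not the cloud
size, so much larger inputs mainly pay in the reduction step.

## Numerical choices and degenerate inputs

* Convex hull: incremental 3D quickhull with tolerance $10^{-9}$ relative
  to the cloud's extent. Coplanar, collinear, or tiny ($N \le 4$) clouds
  return all distinct points — the fit then simply optimizes a flat or
  small hull. Duplicate coordinates are allowed (distinct entities may
  coincide after reduction); the hull deduplicates internally but every
  entity keeps its color.
* A single-point cloud is handled specially: its normalization radius is
  set to 1 and the fit places it at the interior point with objective 0.
* Nelder–Mead runs with relative convergence tolerance $10^{-8}$ and at
  most 2000 iterations per start; non-positive scale proposals are rejected
  by a steep penalty ramp rather than a hard error, which keeps the simplex
  away from $s \le 0$ without breaking its geometry.
* Encoding applies the stored normalization and best transform to any
  points in the fitted frame. Interior (non-hull) points can land slightly
  outside the gamut where it is locally non-convex, and new points can land
  anywhere; by default these are clamped channel-wise in sRGB and counted
  in a warning, while `clamp = FALSE` turns them into an error naming the
  points. The Lab columns of the output are always the pre-clamp values,
  so distance ratios remain exact in Lab even when a hex code was clamped.
* Fits serialize to JSON with 17 significant digits (exact double round
  trip); color tables are written as TSV with shortest-round-trip numerics
  and re-read with a correctly rounding parser, so a written table re-reads
  bit-identically.

## Limitations

* The gamut is not convex, so hull containment does not strictly guarantee
  whole-cloud containment; the encode step therefore re-checks every point
  and clamps (or errors). In practice, fitted clouds show zero or
  negligible interior overshoot.
* Nelder–Mead with 25 starts offers no global-optimality guarantee; the
  objective achieved is reproducible, and invariance checks bound the
  practical variation, but a different start set can find a mirror-image
  or rotated coloring of equal quality — alternative ranked solutions are
  returned for exactly this reason.
* Colors are only comparable *within* one fit. Two datasets fitted
  separately get unrelated color frames; to share a frame, fit once and
  re-apply the saved transform to the other dataset.
* Perceptual uniformity of CIELAB is approximate (it degrades for large
  distances), and about 8% of viewers perceive color differently; encoding
  along the $L^*$ axis (via weights) is the robust channel for them and
  for grayscale reproduction.
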