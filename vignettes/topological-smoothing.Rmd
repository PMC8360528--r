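---
title: "Topology-preserving smoothing of retinotopic maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-preserving smoothing of retinotopic maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinosmooth)
```

## The problem

Retinotopic maps assign to every location on the visual cortical surface a
position in the visual field (eccentricity and polar angle). Estimated
voxel-by-voxel from fMRI with population receptive field (pRF) models, these
maps are noisy: when the triangulated cortical patch is mapped into
visual-field coordinates, a substantial fraction of triangles reverses
orientation. Such *flipped triangles* violate what is known about the
underlying biology — the cortex-to-retina correspondence preserves local
neighbourhood relations — and they break downstream analyses that assume an
orientation-preserving map (visual field sign, area boundaries, cortical
magnification).

Generic smoothers (neighbourhood averages, medians, Laplacian smoothing)
reduce but do not eliminate flips. This package implements a smoother whose
output is *guaranteed* to be free of them.

## The model

Work on a 2D parametric domain: the cortical patch, cut as a geodesic disk
and flattened to the unit disk (`flatten_to_disk()`, a discrete harmonic map
with the boundary pinned to the circle — one-to-one onto a convex target by
the Rado–Kneser–Choquet theorem, so the chart itself introduces no flips).
Write parametric points as complex numbers $u = u^{(1)} + iu^{(2)}$ and the
per-vertex visual coordinates as $\hat f = \hat f^{(1)} + i \hat f^{(2)}$.

The local distortion of the piecewise-linear map $u \mapsto \hat f$ is
captured per triangle by the **Beltrami coefficient**

$$\mu \;=\;
\frac{\partial \hat f/\partial u^{(1)} + i\,\partial \hat f/\partial u^{(2)}}
     {\partial \hat f/\partial u^{(1)} - i\,\partial \hat f/\partial u^{(2)}},$$

constant on each face because the interpolant is linear. $\mu = 0$ means the
face is mapped conformally; $|\mu| < 1$ means orientation is preserved; and
$|\mu| > 1$ is exactly a flipped face (equivalently the Jacobian determinant
$J = |f_z|^2(1 - |\mu|^2)$ is negative). The smoother seeks coordinates that
fit the data, are smooth, and satisfy the hard constraint
$\max_T |\mu_T| < 1$:

$$\hat f = \arg\min \int W\,|\hat f - v|^2 + s\,|\nabla \hat f|^2,
\qquad \text{s.t. } \|\mu_{\hat f}\|_\infty < 1 .$$

Two sub-steps alternate:

1. **Smoothing.** `laplacian_smooth()` solves the normal equations
   $(K + 2sDW)\hat f = 2sDW f$ per coordinate, with $K$ the cotangent
   stiffness matrix and $D$ the dual-cell (mixed Voronoi) areas. The
   convention follows the data-fidelity form: **small $s$ means heavy
   smoothing** (the gradient term dominates), large $s$ reproduces the
   input. The weights $W_i \ge 0$ downweight unreliable vertices (for real
   pRF data, $W_i = \max(R^2_i, 0)/100$); a vertex with $W_i = 0$ is
   interpolated harmonically. `gcv_select()` chooses $s$ by generalized
   cross-validation when no value is prescribed.

2. **Topological projection.** Faces with $|\mu| > 1$ are "chopped":
   $\mu' = \mu/(|\mu| + \epsilon)$, preserving the argument and pulling the
   magnitude below one. The map is then reconstructed from $\mu'$ by the
   **Linear Beltrami Solver** (`solve_lbs()`): writing $\mu = \rho + i\tau$,
   the map with Beltrami coefficient $\mu$ satisfies the elliptic PDEs
   $\nabla \cdot A \nabla f^{(1)} = 0$ and
   $\nabla \cdot A \nabla f^{(2)} = 0$ with
   $$\alpha_1 = \frac{(\rho - 1)^2 + \tau^2}{\rho^2 + \tau^2 - 1},\quad
     \alpha_2 = \frac{-2\tau}{\rho^2 + \tau^2 - 1},\quad
     \alpha_3 = \frac{(\rho + 1)^2 + \tau^2}{\rho^2 + \tau^2 - 1},$$
   discretized with face-constant gradients and dual-cell divergence
   (`assemble_divergence()`), and solved with Dirichlet boundary values
   $v_B$; both real systems share one factorization. The Beltrami
   coefficient uniquely encodes the map given its boundary values, and the
   map-to-$\mu$-to-map round trip is exact to solver tolerance (tested to
   $10^{-6}$ and, in exact-arithmetic cases, to machine precision).

## The solver loop

`qc_smooth()` (wrapped by the fitting interface `topo_smooth()`) performs:

1. infer initial boundary values $v_B$ from the one-ring average-smoothed
   field, by local linear extrapolation from the interior collar (so a wild
   raw value sitting *on* the boundary never pollutes its own anchor);
2. one smoothing pass with the boundary pinned at $v_B$;
3. repeat until $\max|\mu| < 1$ with zero flipped faces: chop, reconstruct
   with the LBS under $v_B$, and refresh $v_B$ by per-vertex local linear
   fits near the boundary, moving each boundary value by at most
   $\epsilon_B$ (the boundary change tolerance) per iteration.

The iterate returned is always the *projected* map, so the output satisfies
the topology constraint exactly; an input that already satisfies it is
returned untouched. Design notes on the loop:

* **Why smooth once rather than between projections?** For the benchmark
  setting ($s = 10^{-3}$ on the fidelity term) the smoothing solution is
  governed almost entirely by the boundary values — re-running it between
  projection passes would simply overwrite the projection's repairs with
  the same near-harmonic field and the loop would cycle. Smoothing is
  therefore applied once per boundary state, and the projection (whose
  output feeds the convergence test) iterates until the constraint holds.
* **Why per-vertex boundary fits with a step limit?** A single affine fit
  over the whole collar is a poor model of a curved retinotopic map and
  would drag well-behaved boundary stretches toward a global plane. Local
  fits track the interior trend; limiting each update to $\epsilon_B$ keeps
  the boundary anchored to its initial values on the time scale of a few
  iterations while still letting a locally folded stretch (the typical
  cause of unrepairable flips) migrate to consistency.
* **Degenerate cases.** Anti-conformal faces ($f_z \approx 0$, detected at
  relative tolerance $10^{-12}$) carry a finite sentinel magnitude $10^9$
  and are projected to magnitude $1/(1+\epsilon)$ with argument 0. Faces
  inside the $10^{-6}$ guard band just *below* $|\mu| = 1$, where the LBS
  coefficients blow up, are projected too. Non-convergence within
  `max_iter` raises an error carrying the $\max|\mu|$ trace — a
  flip-containing map is never returned silently.

## Multi-area maps: the extended polar angle

The raw polar angle $\theta \in [0, 2\pi)$ is numerically discontinuous at
the horizontal meridian ("phase jumping"), and the visual field sign
alternates between adjacent areas, so V1/V2/V3 cannot be smoothed jointly in
raw coordinates. `extend_polar()` applies an affine re-coding per (region,
hemisphere) — e.g. left V1v: $T(\theta) = \theta + \pi$; right V2v:
$T(\theta) = -\theta + \pi$ — plus a fixed multiple of $2\pi$ per region so
the six extended ranges tile $[-\pi/2,\, 5\pi/2]$ as one continuous monotone
chain V3d→V2d→V1d→V1v→V2v→V3v for either hemisphere. The coding is
bijective: `invert_extended_polar()` recovers the raw angle and the area
label exactly (ties at shared borders resolve to the earlier region in the
order V1v, V1d, V2v, V2d, V3v, V3d). `topo_smooth()` smooths
$ecc + i\,T(\theta)$ for multi-area patches and Cartesian visual coordinates
$x + iy$ for single-area patches; both codings are exposed because the
appropriate choice depends on whether area borders are present.

## Synthetic validation

### Complex-log grid

`gen_log_model()` builds the standard validation problem: a
12 × 12 grid over eccentricity $[0, 4.5]°$ × polar angle
$[-\pi/2, \pi/2]$ (144 vertices, 242 triangles after splitting each quad —
with diagonals chosen so that no triangle has all three corners on the
boundary, since such a face's orientation would be dictated entirely by
Dirichlet data and be unrepairable), mapped to the plane by
$u = k\,\ln(v^{(1)} + i\,v^{(2)})$ with $k = 0.5$ — a standard
approximation of the visual-field-to-flattened-cortex map. Noise is applied
to the *visual-field* coordinates before the log map,
$u_{noisy} = k \ln(v + \eta)$, $\eta \sim N(0, \sigma^2)$ per coordinate
with $\sigma = C/\sqrt{\mathrm{PSNR}}$ and $C = 0.61°$ (the calibration
script under `scripts/` documents the choice). Two properties make this the
right noise model here: the log map rescales perturbations and triangle
sizes by the same local Jacobian, so triangles flip at a spatially uniform
rate; and the deviation of the perturbed map, measured in visual-field
degrees, is exactly $|\eta|$. Eccentricity perturbations are reflected at
zero — negative eccentricity lies outside the model's domain. What this
generator does *not* emulate: spatially correlated pRF errors, the
heavy-tailed failure modes of real fits, and cortical mesh irregularity;
passing these benchmarks shows the machinery works at realistic noise
levels, not that real data meet the generator's assumptions.

`run_table_experiment("log_model", psnr = 10)` repeats, over 50 noise draws:
generate → smooth with each method (one-ring average, one-ring median,
GCV-weighted Laplacian, and the topological smoother with $s = 10^{-3}$,
$\epsilon_B = 0.01$) → score. Metrics (`evaluate_map()`): mean per-vertex
Euclidean deviation from ground truth in visual-field degrees; angle
distortion (degrees of deviation from orthogonality of the mapped
coordinate tangents — zero for conformal maps, but not a function of
$|\mu|$ alone: a pure axis stretch also scores zero); and the flip count
(median over replicates). Paired two-sided permutation tests
(`permutation_test()`) compare each method to the topological smoother. At
both noise levels the topological smoother leaves zero flipped triangles on
every replicate while matching the best baseline's value deviation and
clearly winning on angle distortion.

### pRF simulation and decoding

The second experiment injects noise at the signal level.
`simulate_prf_signal()` implements the pRF forward model
$y = \beta\,(\int r(v'; v, \sigma)\, s(t, v')\,dv')^n * h(t)$ with an
isotropic Gaussian field, a binary wedge/ring/bar aperture movie
(`make_stimulus()`; the union of frames covers the stimulated disk) and a
canonical double-gamma HRF; signals are normalized to unit variance and
white noise added. `fit_prf()` decodes by dictionary search over candidate
centers/sizes/exponents (gain in closed form) with optional Nelder–Mead
refinement; on noiseless signals it recovers centers within half a grid
step, sizes within 10%, and $R^2 = 100$.

The benchmark preset (`prf_preset()`) is a documented desk-scale reduction
of the full experiment: ground-truth centers on a 0.32° grid spanning
$[0, 6.4]° \times [0, 4.8]°$ ($\sigma = 0.4°$, gain 1, exponent 0.5), a
900 s stimulus at 50 × 50 pixels, and a 0.08° decoding grid. The stimulus
duration was fixed once so that decoding with noise sd 2.5 flips roughly a
fifth of the triangles — the operating point this experiment is about; at
reduced scale the flip *percentage*, not the count, is the comparable
quantity. The topological smoother applied to the decoded centers again
returns zero flipped triangles with the least angle distortion, and its
refit $R^2$ matches the unsmoothed decode.

## Numerical choices, defaults, limitations

* `s = 0.001` (fidelity-form smoothing weight), `eps_proj = 0.01`,
  `eps_boundary = 0.01` (synthetic units; for real pRF data in Cartesian
  degrees a tolerance of ~0.5° is reasonable), `max_iter = 100`. The dual
  cell is circumcentric with obtuse triangles clamped to the mixed-area
  rule; a barycentric dual is available. Sparse systems are solved by
  direct factorization (meshes of 10³–10⁴ vertices).
* Problem sizes used by the shipped benchmarks: 50 replicates of the
  12 × 12 grid per noise level, and one 21 × 16 decoding run (1271 voxels
  would be the 0.16° preset; the default uses 336), chosen to keep a full
  validation run around a minute on one core.
* The flattening is harmonic, not conformal. Harmonicity guarantees a
  flip-free chart, which is all the smoother requires (topology composes
  through topological maps); but measured $\mu$ values then describe the
  composite map, not the cortex-to-field map alone. The synthetic
  benchmarks use planar grids where the chart is the identity, so their
  $\mu$-based metrics are chart-free.
* Geodesic patch cutting uses Dijkstra distances on the edge graph — patch
  selection does not need exact polyhedral geodesics.
* Not covered: multi-boundary patches, sphere parameterizations,
  landmark-constrained reconstruction, areas beyond V3, and template
  registration.
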