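# retinosmooth

Topology-preserving smoothing of retinotopic maps.

Retinotopic maps — the correspondence between positions on the visual
cortical surface and positions in the visual field — are estimated
voxel-by-voxel from fMRI with population receptive field (pRF) models, and
the estimates are noisy. Mapped into visual-field coordinates, many
triangles of the cortical mesh reverse orientation ("flipped triangles"),
contradicting the topological order of the underlying cortex–retina
correspondence and breaking analyses that rely on it (visual field sign,
area borders, cortical magnification). Generic smoothing reduces the number
of flips but does not eliminate them.

This package smooths such maps under the hard constraint that the result be
*topological*. On a disk-flattened patch with parametric coordinates
$u = u^{(1)} + iu^{(2)}$ and per-vertex visual coordinates
$\hat f = \hat f^{(1)} + i\hat f^{(2)}$, the per-face Beltrami coefficient

$$\mu = \frac{\partial\hat f/\partial u^{(1)} + i\,\partial\hat f/\partial u^{(2)}}
             {\partial\hat f/\partial u^{(1)} - i\,\partial\hat f/\partial u^{(2)}}$$

measures local distortion: $|\mu| < 1$ iff the face preserves orientation.
The smoother minimizes a weighted fidelity-plus-smoothness energy subject to
$\|\mu\|_\infty < 1$, alternating weighted Laplacian smoothing with
*topological projection*: coefficients with $|\mu| > 1$ are chopped to
$\mu' = \mu/(|\mu| + \epsilon)$ and the map is rebuilt from $\mu'$ by the
Linear Beltrami Solver ($\nabla\cdot A\nabla f = 0$ with Dirichlet boundary
values). The returned map always satisfies $\max|\mu| < 1$ — zero flipped
triangles, by construction.

Also included: harmonic disk flattening and geodesic patch extraction,
extended polar-angle coding for joint V1/V2/V3 smoothing, baseline
smoothers, a pRF forward model and decoder, and the synthetic benchmark
suite (complex-log grid and simulated-fMRI decoding) with distortion
metrics and permutation tests.

## Worked example

Synthetic retinotopy from the complex-log model at PSNR 10, smoothed back
to a topological map:

```r
library(retinosmooth)

dat <- gen_log_model(psnr = 10, seed = 7)   # 12 x 12 grid, 242 faces
fit <- topo_smooth(dat$v, faces = dat$mesh$faces, values = dat$u_noisy)
fit
#> Topology-preserving retinotopic map smoother
#>   144 vertices, 242 faces, coding: raw
#>   converged in 0 iteration(s); flipped faces 52 -> 0; final max|mu| = 0.3932

ev_raw <- evaluate_map(dat$v, dat$v_noisy, dat$v, dat$mesh$faces)
ev_fit <- evaluate_map(dat$v, exp(fit$f / 0.5), dat$v, dat$mesh$faces)
```

which prints

```
raw:      value deviation 0.241 deg, 52 flipped faces
smoothed: value deviation 0.144 deg, 0 flipped faces
```

The noisy map misorients 52 of 242 triangles; the smoothed map misorients
none, and its mean visual-field error (0.144°) is well below the raw noise
level (0.241°). `plot(fit)` draws the mapped mesh before and after, shading
flipped faces; `summary(fit)` reports the max-$|\mu|$ trace;
`coef()`, `fitted()` and `residuals()` behave as usual. For real data,
`topo_smooth()` accepts a `triangle_mesh` (flattened internally), per-vertex
eccentricity/angle with area labels and hemisphere for multi-area patches
(`coords = "ecc_extang"`), and $R^2$-based fidelity weights.

Benchmark tables comparing no smoothing, average, median, Laplacian (GCV)
and the topological smoother are produced by

```r
run_table_experiment("log_model", psnr = 10, n_rep = 50, seed = 1)
run_table_experiment("prf", seed = 1)       # simulated-fMRI decoding
```

A thin command-line front end lives at `inst/cli/retinotopo.R`
(`flatten`, `smooth`, `simulate`, `benchmark`).

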