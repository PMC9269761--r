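# hbgvf — active contour segmentation with Hessian-based gradient vector flow

`hbgvf` segments objects in 2-D grayscale images with parametric active
contours (snakes) driven by gradient-vector-flow external forces.  It is
aimed at people working on boundary delineation in biological and medical
imaging who need a snake whose external force both *reaches far* (large
capture range, convergence into concavities) and *respects weak edges*
(no leakage toward nearby stronger structures).

The package implements six external force fields behind one interface —
GVF, GGVF, VEF, NGVF, CN-GGVF, and its centerpiece, the **Hessian-based
GVF (HBGVF)** — plus a semi-implicit snake solver, synthetic benchmark
scenes with analytic ground-truth boundaries, and a small CLI.

## The method

The classic GVF field `v = (u, v)` minimizes

    ∬ μ (|∇u|² + |∇v|²) + |∇f|² |v − ∇f|² dx dy,

diffusing the gradient of the edge map `f = |∇(G_σ ∗ I)|²` isotropically
across the image.  HBGVF rewrites the smoothness term as
`(∇u)ᵀ D ∇u` and builds the per-pixel symmetric PSD tensor `D` from the
image Hessian's eigen-structure: its eigenvectors are the Hessian's
(feature-crossing and along-feature axes), and its eigenvalues are

    η₁ = 1 / (1 + (|∇I| / K)²)   across the feature,   η₂ = 1   along it.

The resulting flow

    uₜ = μ div(D ∇u) − |∇f|² (u − fₓ)

diffuses isotropically in homogeneous regions (`D = I` exactly where
`|∇I| = 0`) but suppresses diffusion across edges (`η₁ → 0` as `|∇I|`
grows), so the field keeps weak-edge information that plain GVF smooths
away, while retaining GVF's capture range.  The snake then evolves under
`c_{t+1} = (I + τ(−αD₂ + βD₄))⁻¹ (c_t + τ v(c_t))`.

## Worked example

Segment the U-shaped concavity benchmark with an HBGVF snake at the
reference parameters (α = β = 0.1, τ = 0.5, μ = 0.2, K = 0.1, field
dt = 1, M·N field iterations):

```r
library(hbgvf)
scene <- make_ushape(size = 64)                    # bright U on dark, analytic boundary
em    <- edge_map(scene$image, sigma = 1)
tens  <- diffusion_tensor(scene$image, K = 0.1, sigma = 1)
field <- hbgvf(em, tens, mu = 0.2, dt = 1)         # 64*64 = 4096 iterations
fit   <- snake(field, circle_contour(31.5, 31.5, 28),
               max_iter = 3000, tol = 0.001)
summary(fit)
#> Snake fit (hbgvf field)
#>   points:      225
#>   iterations:  3000 (max_iter reached)
#>   perimeter:   224.81 px
#>   area:        1827.77 px^2 (counter-clockwise)
#>   alpha=0.1 beta=0.1 tau=0.5 tol=0.001 force_mode=raw
mean(contour_distance(coef(fit), scene$boundary))
#> [1] 0.2324809
```

The fitted contour follows the analytic boundary to ~0.23 px on average,
*including inside the notch* — the behavior the anisotropic tensor is for.
`plot(fit, image = scene$image, boundary = scene$boundary)` overlays the
initial (dashed), final (red) and true (green) contours.  On the
complementary weak-edge benchmark (`make_weak_edge_ring()`, a double ring
whose outer edge is blurred along one arc), the HBGVF snake at μ = 0.1,
K = 0.01 holds the blurred arc at ~0.3 px while plain GVF at the same μ
collapses ~12 px onto the inner ring.

A command-line front end with `field`, `segment`, `make-fixtures` and
`compare` subcommands lives at `inst/cli/snakefield.R`:

```sh
Rscript inst/cli/snakefield.R segment image.png --method hbgvf \
    --K 0.1 --mu 0.2 --init circle:31.5,31.5,28 \
    --out contour.json --overlay overlay.png
```

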