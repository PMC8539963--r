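# anisograd

Gradient-domain image processing with variational anisotropic diffusion.

## The problem

Gradient-domain techniques edit an image `u0` by building a modified
gradient field `G = f(∇u0)` and reintegrating it, classically by solving
the Poisson equation `∇²u = ∇·G` via gradient descent:

    ∂u/∂t = ∇²u − ∇·G

Because `G` is in general not a gradient field, the unconstrained Poisson
solution smears the inconsistency across the whole image, producing the
familiar haloing and blurring artefacts near strong edges. The standard
remedy replaces the Laplacian with an anisotropic diffusion term,

    ∂u/∂t = ∇·D·(∇u − G)

with the diffusion tensor `D` assembled ad hoc from the Di Zenzo structure
tensor `S = ∇u·∇u` (colour-summed). This package implements, alongside
those two baselines, the variational formulation of anisotropic
gradient-domain processing: the energy

    E(u) = ∫ ψ(λ′₊, λ′₋) dΩ

is expressed in the eigenvalues λ′± of the **difference structure tensor**

    S′ = (∇u − G)·(∇u − G),

and its Euler–Lagrange gradient flow is

    ∂u/∂t = ∇·D′·(∇u − G),   D′ = d(λ′₊) θ′₊θ′₊ᵀ + d(λ′₋) θ′₋θ′₋ᵀ,

where θ′± are the eigenvectors of S′ and the diffusivities `d = 2∂ψ/∂λ`
come from an edge-stopping potential ψ (Perona–Malik rational or
exponential, regularised total variation, or linear — the linear choice
recovers the Poisson method exactly). Diffusion is therefore stopped
across directions where the evolving gradient still disagrees strongly
with the target, which is precisely where Poisson reintegration rings.

Application front-ends construct `G` for:

* **linear local contrast enhancement** — `G = a∇u0`, `a > 1`;
* **gamma local contrast enhancement** — `G = sign(∇u0)|∇u0|^γ`,
  `0 < γ < 1`, element-wise;
* **colour-image daltonisation** — `G = ∇u0 + (∇u0·e_d) e_c`, where `e_d`
  is the principal direction of the information lost under a
  colour-vision-deficiency simulation and `e_c` a chromatic direction the
  deficient observer retains.

All evolution uses an explicit forward-Euler scheme with forward
differences for gradients and a balancing backward difference for the
divergence (the two operators are exact negative adjoints), Neumann
boundaries, and a per-iteration rebuild of the diffusion tensor.

## Worked example

Contrast enhancement (`a = 2`) of a step-edge test image, Poisson versus
variational reintegration at an equal 400-iteration budget:

```r
library(anisograd)
u0 <- fixture_image("step_edge", 48, 48)
G  <- linear_target(u0, a = 2)
poisson     <- evolve(u0, G, solver_config(iterations = 400, tensor_source = "none"))
variational <- evolve(u0, G, solver_config(iterations = 400, tensor_source = "difference",
                                           psi = make_psi("perona_malik_log", K = 1e-3)))
halo_metric(poisson$image, u0)
#> [1] 0.2905538
halo_metric(variational$image, u0)
#> [1] 1.600804e-05
tail(variational$energy, 3)
#>    iteration        value   max_update
#> 39       380 0.0003070509 2.158535e-08
#> 40       390 0.0003070509 2.131178e-08
#> 41       400 0.0003070508 2.104926e-08
```

The halo metric is the worst overshoot beyond the source image's
per-channel range: the Poisson result overshoots the `[0.2, 0.8]` edge
levels by 0.29 (severe ringing), the variational result by under 2e-5.
The recorded energy trace is monotonically decreasing, as expected for a
gradient flow.

Estimating a daltonisation basis from a red–green test chart and the
shipped protanope simulation:

```r
chart <- fixture_image("red_green_chart", 64, 64)
basis <- estimate_basis(chart, cvd_simulate(chart))
basis
#> <daltonisation_basis>
#>   e_d = (0.9921, -0.1256, -0.0045)
#>   e_c = (-0.0806, -0.6633, 0.7440)
```

`e_d` points along the protan confusion direction (dominated by the red
channel); `e_c` is orthogonal to both `e_d` and the grey axis, so the
reintroduced detail is visible to the observer without lightness shifts.

The same pipelines are available from the shell:

```sh
Rscript inst/cli/anisograd enhance-linear --a 2 --solver variational --K 1e-3 in.png out.png
Rscript inst/cli/anisograd enhance-gamma --gamma 0.7 --solver poisson in.png out.png
Rscript inst/cli/anisograd daltonise --simulate out_sim.png in.png out.png
Rscript inst/cli/anisograd fixtures --kind step_edge --seed 42 edge.png
```

Each run writes the output image plus a replayable `*.manifest` and an
energy-trace log.

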