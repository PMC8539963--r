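---
title: "Variational anisotropic gradient-domain image processing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variational anisotropic gradient-domain image processing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anisograd)
```

## The model

Gradient-domain image processing edits an image $u_0 : \Omega \to C$
(with $\Omega \subset \mathbb{R}^2$ the pixel domain and $C$ a 1- or
3-dimensional intensity space) by constructing a target field
$G = f(\nabla u_0)$ and reintegrating it. The classical route minimises
the Poisson energy
$\tfrac12\int_\Omega \lVert \nabla u - G \rVert_F^2\,d\Omega$, whose
gradient descent is $\partial_t u = \nabla^2 u - \nabla\cdot G$. Because
$G$ is generally curl-inconsistent, the unconstrained solution
redistributes the inconsistency globally and overshoots near strong
edges (haloing).

This package implements the variational anisotropic generalisation. Let

$$S' = (\nabla u - G)\cdot(\nabla u - G)$$

be the *difference structure tensor* — the Di Zenzo structure tensor of
the residual field, with the product summed over colour channels — and
let $\lambda'_\pm, \theta'_\pm$ be its per-pixel eigenvalues and
eigenvectors. The energy is

$$E(u) = \int_\Omega \psi(\lambda'_+, \lambda'_-)\, d\Omega ,$$

for an edge-stopping potential $\psi$. Its Euler–Lagrange gradient flow
is

$$\partial_t u = \nabla\cdot D'\,(\nabla u - G), \qquad
  D' = d(\lambda'_+)\,\theta'_+\theta_+^{\prime T}
     + d(\lambda'_-)\,\theta'_-\theta_-^{\prime T},
  \qquad d = 2\,\partial\psi/\partial\lambda .$$

The flow diffuses the residual: where $\nabla u$ already matches $G$ the
tensor is the full diffusivity and the solver behaves like Poisson;
where the residual is strong, diffusion across its principal direction
is shut down, which is exactly where Poisson reintegration rings. Two
baselines share the same engine: `tensor_source = "none"` (identity
tensor, the Poisson method) and `tensor_source = "standard"` (the ad hoc
anisotropic variant, with the tensor built from $S = \nabla u \cdot
\nabla u$ of the evolving image instead of the residual).

Assumptions worth stating: intensities are processed as stored (display-
encoded values treated as intensities, matching common gradient-domain
practice); the structure tensor is pointwise, with no Gaussian pre- or
post-smoothing; and colour coupling enters solely through the
channel-summed tensor.

## The potential catalogue and its normalisation

`make_psi()` provides four potentials. With
$s = \lambda_+ + \lambda_-$:

| name | $\psi$ | induced $d(\lambda)$ | $d_{\max}$ |
|---|---|---|---|
| `linear` | $s/2$ | $1$ | 1 |
| `total_variation` | $\sqrt{s + \varepsilon^2} - \varepsilon$ | $1/\sqrt{s+\varepsilon^2}$ | $1/\varepsilon$ |
| `perona_malik_log` | $\tfrac{K^2}{2}\sum_\pm \ln(1+\lambda_\pm/K^2)$ | $1/(1+\lambda/K^2)$ | 1 |
| `perona_malik_exp` | $\tfrac{K^2}{2}\sum_\pm (1-e^{-\lambda_\pm/K^2})$ | $e^{-\lambda/K^2}$ | 1 |

The identity $d = 2\,\partial\psi/\partial\lambda$ holds uniformly for
every entry (it is verified numerically in the test suite). The
Perona–Malik potentials are deliberately scaled so that the *induced
diffusivities* are the classical edge-stopping coefficients with
$d(0) = 1$; the alternative — keeping the textbook potential and letting
$d(0) = 2$ — is the same flow under a global time rescaling but would
halve the usable time step. A constant is added to the exponential
potential and $-\varepsilon$ to the TV potential so that
$\psi(0,0) = 0$, making the energy of a perfectly reintegrated image
exactly zero. The $\varepsilon^2$ inside the TV root (default
$\varepsilon = 10^{-4}$) removes the $s=0$ singularity; it is the
standard regularisation, and the resulting $d_{\max} = 1/\varepsilon$
feeds the stability bound below.

The Perona–Malik potentials come in a *split* form (default; independent
$d(\lambda_+)$, $d(\lambda_-)$, genuinely anisotropic, matching the form
in which the eigenvalue-wise potential is written) and an *isotropic*
form $\psi = \phi(s)$, for which the tensor provably collapses to the
scalar $2\phi'(s)\,I$ regardless of eigenvector tie-breaking — this is
asserted to $10^{-10}$ in the tests.

## Parameters

* **K** (intensity-gradient units per pixel): the edge-stopping scale.
  Residual gradients below $K$ diffuse freely; above $K$ they are
  preserved. Defaults follow the reference parameterisation for contrast
  enhancement: $K = 10^{-3}$ for the variational solver and
  $K = 3\times10^{-4}$ for the ad hoc solver — different because the two
  tensors are built from fields of different magnitude. (Published
  figure captions for the same experiments state the two values the
  other way round; the running-text values are used here.) For
  daltonisation no reference value exists; the default is $K = 0.1$,
  chosen once on the ground that the chromatic compensation gradients
  being reintegrated are $O(0.1)$, so the edge-stopping scale must sit
  at that order for the flow to act at all.
* **dt** (dimensionless, default 0.2): explicit-Euler step. The
  five-point scheme is stable for $dt \le 0.25/d_{\max}$; with the
  catalogue's $d_{\max} = 1$ the default sits at 80 % of the bound.
  `evolve()` warns but proceeds when the bound is exceeded (useful for
  deliberate stress tests); a non-finite iterate aborts with its
  iteration index.
* **iterations** (default 1000) and **convergence_tol** (off by
  default): the evolution is run to a fixed budget, or stopped early
  when the maximum per-iteration update falls below the tolerance.
* **a** (> 1) and **gamma** (in (0,1)): enhancement strengths, defaults
  2 and 0.7.

## Discretisation

Forward differences define $\nabla u$ and $G$, with the forward
difference at the last row/column set to zero — a replicate (Neumann,
no-flux) boundary, the natural choice for a conservative diffusion when
no boundary condition is otherwise specified. The divergence uses
backward differences with the complementary convention, which makes it
the *exact* negative adjoint of the gradient: the discrete
summation-by-parts identity
$\sum \nabla u \cdot V = -\sum u\, \mathrm{div}\,V$ holds to machine
precision (asserted at $10^{-12}$). This balance is what makes the
explicit update an exact discrete gradient descent on $E$, and it has
two testable consequences: the recorded energy trace is non-increasing,
and the flow conserves per-channel means for $G = 0$ (no flux across the
frame).

The diffusion tensor is rebuilt from the current iterate every iteration
(one-step lagged diffusivity). Per pixel the tensor is assembled as
$D = d_-I + (d_+-d_-)\,\theta_+\theta_+^T$, so isotropic potentials give
an exactly scalar tensor and the linear potential gives exactly the
identity — the variational solver then reproduces the Poisson iterate
sequence bit for bit, a reduction the acceptance checks assert at
$10^{-12}$ per step.

Eigenpairs of the symmetric $2\times2$ tensors use the closed form
$\lambda_\pm = \tfrac12\big(t_{11}+t_{22} \pm
\sqrt{(t_{11}-t_{22})^2 + 4t_{12}^2}\big)$, with the better-conditioned
of the two analytic eigenvector candidates selected per pixel. Ties are
handled deterministically: pixels with eigenvalue gap below
$10^{-12}\times$trace (or zero trace) return the axis-aligned pair
$(1,0),(0,1)$ — legitimate because such tensors are isotropic to
rounding — and the sign of $\theta_+$ is fixed so its first nonzero
component is positive. $\theta_-$ is $\theta_+$ rotated by $+90^\circ$,
guaranteeing exact orthonormality. No values are clipped during
evolution; clipping to $[0,1]$ and round-half-up 8-bit quantisation
happen only at image export, so the dynamics match the continuous model.

## Daltonisation choices

The deficiency simulation is the standard linear confusion-line
projection (Viénot-style $3\times3$ matrices for protanopia and
deuteranopia, rows summing to one so greys are preserved); any linear
simulator can be substituted via a plain-text matrix file. $e_d$ is the
dominant eigenvector of the *uncentred* second moment of the per-pixel
original-minus-simulation differences — the differences are already
deviations from "no loss", so centring (available as an option) would
discard the mean loss itself. $e_c$ is the normalised cross product of
the grey axis and $e_d$, which satisfies both orthogonality requirements
by construction.

One choice deserves emphasis: both signs of $e_c$ satisfy the
orthogonality constraints, but they are not interchangeable. The
compensation $(\nabla u_0 \cdot e_d)\,e_c$ must *reinforce* the contrast
that survives simulation; with the wrong sign it cancels it, and on a
red–green chart the simulated result ends up with *less* edge structure
than the unprocessed simulation. The sign is therefore chosen
data-dependently (and deterministically): the one that makes the
simulated compensation correlate positively with the simulated original
gradient, with a green-component-non-negative rule as tie-break and as
fallback when no simulation matrix is supplied.

## What the synthetic fixtures do and do not show

The generator produces constants, ramps, step edges, disks, a red–green
patch chart, and seeded smooth random fields (binomially smoothed
uniform noise in $[0.1, 0.9]$). These probe the mechanisms directly: the
step edge isolates halo formation; the smooth random field exercises
generic curl-inconsistent targets with interior extrema; the chart's
patches differ mainly along the red–green opponent axis so that
simulated structure genuinely collapses. They do not emulate natural
images — no texture spectra, no sensor noise, no saturated regions — so
passing tests demonstrate correctness of the operators and the claimed
qualitative orderings (halo suppression, variational/ad hoc
near-equivalence, detail restoration), not photographic quality. Halo is
quantified as out-of-range overshoot relative to the source image's
per-channel range — the simplest faithful proxy for visible ringing; it
is not a perceptual metric.

Verification sizes were chosen to keep every check comfortably
sub-minute while remaining in the regime where the asymptotics are
visible: fixed points and energy descent on $64\times64$ colour fields,
the dense-oracle Poisson comparison on $24\times24$ (where the direct
solve of the gauge-fixed Neumann system is exact and cheap), halo runs
on $48\times48$ at equal 400-iteration budgets, and $10^4$ random
symmetric PSD tensors against the numerical eigensolver.

## Known limitations

* Explicit Euler only: thousands of iterations are needed for
  low-frequency convergence; no multigrid, FFT or semi-implicit path.
* The TV potential's $d_{\max} = 1/\varepsilon$ makes the stability
  bound on `dt` severe ($2.5\times10^{-5}$ at the default
  $\varepsilon$); TV is best used through the early-stopping interface
  or with a larger $\varepsilon$.
* The dichromat model is linear; piecewise LMS projections (Brettel-type
  half-planes) are out of scope, as are perceptual colour spaces and
  perceptual evaluation of daltonisation quality.
* Processing happens in the stored RGB encoding; no linearisation is
  applied before the PDE.
* With strong edge-stopping ($K$ far below the residual scale) the
  variational flow intentionally freezes most of the image; global
  brightness redistribution that Poisson performs will then not happen.
  This is the halo/contrast trade-off at the heart of the method, not a
  defect, but it means $K$ must be chosen relative to the gradient
  magnitudes the application injects.
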