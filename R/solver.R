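#' Solver configuration for the explicit gradient-domain evolution
#'
#' @param dt Explicit-Euler time step (dimensionless). The 2D five-point
#'   scheme is stable for `dt <= 0.25 / d_max`, where `d_max` is the
#'   largest diffusivity the potential can produce; [evolve()] warns (but
#'   proceeds) if the bound is violated.
#' @param iterations Maximum number of iterations (default 1000).
#' @param tensor_source Which tensor steers the diffusion:
#'   `"none"` — identity tensor, i.e. the classical Poisson gradient
#'   descent `du/dt = lap(u) - div(G)`;
#'   `"standard"` — ad hoc anisotropic variant, tensor rebuilt every
#'   iteration from the structure tensor of the evolving gradient;
#'   `"difference"` — variational formulation, tensor rebuilt from the
#'   difference structure tensor of the residual `grad(u) - G`.
#' @param psi A `psi_model` from [make_psi()]; ignored for
#'   `tensor_source = "none"`.
#' @param convergence_tol Optional early-stop threshold on the maximum
#'   absolute update `dt * max|div(D (grad u - G))|` per iteration;
#'   `NULL` disables early stopping.
#' @param energy_every Record the energy every this many iterations
#'   (default 10; the initial energy is always recorded).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dt = 0.2, iterations = 1000L,
                          tensor_source = c("difference", "standard", "none"),
                          psi = make_psi("perona_malik_log", K = 1e-3),
                          convergence_tol = NULL,
                          energy_every = 10L) {
  tensor_source <- match.arg(tensor_source)
  stopifnot(is.numeric(dt), length(dt) == 1L, is.finite(dt), dt > 0)
  iterations <- as.integer(iterations)
  stopifnot(iterations >= 1L)
  if (!inherits(psi, "psi_model")) stop("psi must be a psi_model", call. = FALSE)
  if (!is.null(convergence_tol)) {
    stopifnot(is.numeric(convergence_tol), convergence_tol > 0)
  }
  energy_every <- max(1L, as.integer(energy_every))
  structure(
    list(dt = dt, iterations = iterations, tensor_source = tensor_source,
         psi = psi, convergence_tol = convergence_tol,
         energy_every = energy_every),
    class = "solver_config"
  )
}

#' Evolve an image towards a target gradient field
#'
#' Explicit (forward) Euler integration of the gradient-domain diffusion
#' PDE `du/dt = div(D (grad u - G))` per colour channel, starting from
#' `u0`. Forward differences are used for the gradients and a backward
#' difference for the divergence, balancing the scheme so the spatial
#' operator is the exact negative of the discrete energy gradient.
#' Depending on `tensor_source`, `D` is the identity (Poisson), the
#' tensor assembled from the structure tensor of `grad(u)` (ad hoc
#' anisotropic), or from the difference structure tensor of
#' `grad(u) - G` (variational anisotropic); in the latter two cases it is
#' recomputed every iteration from the current iterate (lagged
#' diffusivity). Values are not clipped during evolution; clipping to
#' \[0,1\] is an export concern (see [save_image()]).
#'
#' @param u0 Initial image (`H x W x C` array or matrix).
#' @param G Target gradient field, `H x W x 2 x C`.
#' @param config A [solver_config()].
#' @param record_iterates If `TRUE`, every iterate is kept (for
#'   small-problem diagnostics only).
#' @return A list of class `evolve_result`:
#'   `image` — the final iterate (not clipped);
#'   `energy` — data frame with `iteration` and `value`, the diffusion
#'     energy `sum psi(lambda'_+, lambda'_-)` sampled every
#'     `energy_every` iterations (for `tensor_source = "none"` the energy
#'     is evaluated with the configured `psi` for diagnostic purposes);
#'   `iterations_run`, `converged`; and `iterates` when requested.
#' @examples
#' u0 <- fixture_image("smooth_random", 16, 16, channels = 1, seed = 1)
#' G <- linear_target(u0, a = 1)   # target equals the current gradient
#' res <- evolve(u0, G, solver_config(iterations = 10))
#' max(abs(res$image - u0))        # fixed point: exactly 0
#' @export
evolve <- function(u0, G, config = solver_config(), record_iterates = FALSE) {
  u <- as_image_field(u0)
  .check_gradient_field(G, "G")
  if (!identical(dim(G)[c(1L, 2L, 4L)], dim(u))) {
    stop("G and u0 dimensions do not match", call. = FALSE)
  }
  stopifnot(inherits(config, "solver_config"))
  psi <- config$psi
  dt <- config$dt
  mode <- config$tensor_source
  d_max <- if (mode == "none") 1 else psi$d_max
  if (dt > 0.25 / d_max * (1 + 1e-12)) {
    warning(sprintf(
      "dt = %g exceeds the explicit stability bound 0.25/d_max = %g; proceeding",
      dt, 0.25 / d_max), call. = FALSE)
  }
  trace_it <- 0L
  trace_val <- energy(u, G, psi)
  trace_upd <- NA_real_
  iterates <- if (record_iterates) vector("list", config$iterations) else NULL
  converged <- FALSE
  it_run <- 0L
  for (it in seq_len(config$iterations)) {
    gu <- .grad(u)
    R <- gu - G
    Fv <- if (mode == "none") {
      R
    } else {
      S <- if (mode == "standard") .stens(gu) else .stens(R)
      D <- diffusion_tensor(eigensystem(S), psi)
      .apply_tensor(D, R)
    }
    upd <- .div(Fv)
    if (!all(is.finite(upd))) {
      stop(sprintf("non-finite update at iteration %d; evolution aborted", it),
           call. = FALSE)
    }
    u <- u + dt * upd
    it_run <- it
    if (record_iterates) iterates[[it]] <- u
    max_upd <- dt * max(abs(upd))
    if (it %% config$energy_every == 0L) {
      trace_it <- c(trace_it, it)
      trace_val <- c(trace_val, energy(u, G, psi))
      trace_upd <- c(trace_upd, max_upd)
    }
    if (!is.null(config$convergence_tol) &&
        max_upd < config$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(
      image = u,
      energy = data.frame(iteration = trace_it, value = trace_val,
                          max_update = trace_upd),
      iterations_run = it_run,
      converged = converged,
      iterates = if (record_iterates) iterates[seq_len(it_run)] else NULL
    ),
    class = "evolve_result"
  )
}

#' Diffusion energy of an image relative to a target gradient field
#'
#' Evaluates `E = sum_pixels psi(lambda'_+, lambda'_-)` (unit pixel area),
#' where `lambda'_pm` are the eigenvalues of the difference structure
#' tensor of `grad(u) - G`. For the linear potential this reduces to half
#' the squared Frobenius norm of the residual, the classical Poisson
#' energy; the evolution of [evolve()] with `tensor_source = "difference"`
#' is the discrete gradient flow of this functional.
#'
#' @param u Image field.
#' @param G Target gradient field.
#' @param psi A `psi_model`.
#' @return A single number.
#' @export
energy <- function(u, G, psi) {
  u <- as_image_field(u, check = FALSE)
  eig <- eigensystem(.stens(.grad(u) - G))
  sum(psi$psi(eig$lambda_plus, eig$lambda_minus))
}

#' @export
print.evolve_result <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf(
    "<evolve_result %d x %d x %d> %d iterations%s, final energy %.6g\n",
    d[1], d[2], d[3], x$iterations_run,
    if (x$converged) " (converged)" else "",
    x$energy$value[nrow(x$energy)]))
  invisible(x)
}

#' @export
print.solver_config <- function(x, ...) {
  cat(sprintf("<solver_config> tensor_source = %s, dt = %g, iterations = %d, psi = %s\n",
              x$tensor_source, x$dt, x$iterations, x$psi$name))
  invisible(x)
}
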