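#' Di Zenzo structure tensor of a gradient field
#'
#' Per pixel, the 2x2 symmetric tensor `S = g g^T` summed over colour
#' channels: `S_kl = sum_rho g_k,rho g_l,rho`. Its eigenvectors give the
#' directions of maximal/minimal local colour change, its eigenvalues the
#' squared rates of change along them.
#'
#' @param grad A gradient field, `H x W x 2 x C` (see [compute_gradient()]).
#' @return An object of class `sym_tensor_field`: a list with `H x W`
#'   matrices `t11`, `t12`, `t22`.
#' @export
structure_tensor <- function(grad) {
  .check_gradient_field(grad, "grad")
  .stens(grad)
}

.stens <- function(grad) {
  d <- dim(grad)
  H <- d[1]; W <- d[2]; C <- d[4]
  gx <- matrix(grad[, , 1L, ], H * W, C)
  gy <- matrix(grad[, , 2L, ], H * W, C)
  structure(
    list(
      t11 = matrix(rowSums(gx * gx), H, W),
      t12 = matrix(rowSums(gx * gy), H, W),
      t22 = matrix(rowSums(gy * gy), H, W)
    ),
    class = "sym_tensor_field"
  )
}

#' Difference structure tensor
#'
#' The structure tensor of the residual between the gradient of the
#' evolving image and the target field: `S' = (grad_u - G)(grad_u - G)^T`,
#' summed over colour channels. This tensor, rather than the plain
#' structure tensor, steers the diffusion in the variational solver: where
#' the evolving gradient already agrees with the target the residual
#' vanishes and diffusion is unimpeded; where they disagree strongly the
#' diffusion is stopped across the residual direction.
#'
#' @param grad_u Gradient field of the evolving image.
#' @param G Target gradient field of identical shape.
#' @return A `sym_tensor_field`.
#' @export
difference_structure_tensor <- function(grad_u, G) {
  .check_gradient_field(grad_u, "grad_u")
  .check_gradient_field(G, "G")
  if (!identical(dim(grad_u), dim(G))) {
    stop("grad_u and G must have identical dimensions", call. = FALSE)
  }
  .stens(grad_u - G)
}

#' Closed-form eigenanalysis of a 2x2 symmetric tensor field
#'
#' Per pixel, the eigenvalues are
#' `lambda_pm = (t11 + t22)/2 +- sqrt(((t11 - t22)/2)^2 + t12^2)`,
#' and `theta_plus` is the unit eigenvector of `lambda_plus`.
#' `theta_minus` is `theta_plus` rotated by +90 degrees, i.e.
#' `(-theta_plus_y, theta_plus_x)`, so the pair is exactly orthonormal.
#'
#' Deterministic conventions: the sign of `theta_plus` is fixed so that its
#' first nonzero component is positive; degenerate pixels (eigenvalue gap
#' below `1e-12` times the trace, or zero trace) return the axis-aligned
#' pair `(1,0)`, `(0,1)` — the tensor is then (near-)isotropic and any
#' orthonormal pair is valid, so a fixed choice keeps results reproducible.
#'
#' @param tensor A `sym_tensor_field`.
#' @return An object of class `eigen_system_field`: list with `H x W`
#'   matrices `lambda_plus`, `lambda_minus`, `theta_plus_x`, `theta_plus_y`
#'   and the trace `s = lambda_plus + lambda_minus`.
#' @export
eigensystem <- function(tensor) {
  t11 <- tensor$t11; t12 <- tensor$t12; t22 <- tensor$t22
  tr <- t11 + t22
  half_diff <- (t11 - t22) / 2
  disc <- sqrt(half_diff * half_diff + t12 * t12)
  lp <- tr / 2 + disc
  lm <- tr / 2 - disc
  # eigenvector candidates (t12, lp - t11) and (lp - t22, t12); keep the
  # better-conditioned (larger-norm) one per pixel
  vax <- t12;       vay <- lp - t11
  vbx <- lp - t22;  vby <- t12
  na2 <- vax * vax + vay * vay
  nb2 <- vbx * vbx + vby * vby
  useb <- nb2 > na2
  vx <- ifelse(useb, vbx, vax)
  vy <- ifelse(useb, vby, vay)
  nrm2 <- vx * vx + vy * vy
  deg <- (2 * disc <= 1e-12 * tr) | (tr <= 0) | (nrm2 == 0)
  vx[deg] <- 1; vy[deg] <- 0; nrm2[deg] <- 1
  nrm <- sqrt(nrm2)
  vx <- vx / nrm
  vy <- vy / nrm
  flip <- (vx < 0) | (vx == 0 & vy < 0)
  vx[flip] <- -vx[flip]
  vy[flip] <- -vy[flip]
  structure(
    list(lambda_plus = lp, lambda_minus = lm,
         theta_plus_x = vx, theta_plus_y = vy, s = tr),
    class = "eigen_system_field"
  )
}

#' Assemble the diffusion tensor from an eigensystem and a potential
#'
#' Per pixel,
#' `D = d_plus(lambda_plus) theta_plus theta_plus^T +
#'      d_minus(lambda_minus) theta_minus theta_minus^T`,
#' where the diffusivities `d = 2 * dpsi/dlambda` come from the
#' edge-stopping potential (see [make_psi()]). `d_plus` controls diffusion
#' across the direction of maximal change (edges), `d_minus` along it, so
#' an edge-stopping `d` suppresses smearing across edges while still
#' allowing diffusion along them.
#'
#' The assembly uses `D = d_minus I + (d_plus - d_minus) theta_plus
#' theta_plus^T`, so isotropic potentials (`d_plus == d_minus`) yield an
#' exactly scalar tensor irrespective of the eigenvector tie-break.
#'
#' @param eig An `eigen_system_field`.
#' @param psi A `psi_model` from [make_psi()].
#' @return An object of class `diffusion_tensor_field`: list with `H x W`
#'   matrices `d11`, `d12`, `d22`.
#' @export
diffusion_tensor <- function(eig, psi) {
  stopifnot(inherits(psi, "psi_model"))
  dp <- psi$d_plus(eig$lambda_plus, eig$lambda_minus)
  dm <- psi$d_minus(eig$lambda_plus, eig$lambda_minus)
  gap <- dp - dm
  vx <- eig$theta_plus_x
  vy <- eig$theta_plus_y
  structure(
    list(
      d11 = dm + gap * vx * vx,
      d12 = gap * vx * vy,
      d22 = dm + gap * vy * vy
    ),
    class = "diffusion_tensor_field"
  )
}

#' Apply a per-pixel 2x2 tensor to a gradient field
#'
#' Pointwise matrix-vector product: for every pixel and every colour
#' channel, the spatial 2-vector of `V` is multiplied by the pixel's 2x2
#' tensor.
#'
#' @param D A `diffusion_tensor_field` (or any list with `d11`, `d12`,
#'   `d22` matrices of matching size).
#' @param V A gradient field `H x W x 2 x C`.
#' @return A gradient field of the same shape.
#' @export
apply_tensor <- function(D, V) {
  .check_gradient_field(V, "V")
  if (!identical(dim(D$d11), dim(V)[c(1L, 2L)])) {
    stop("tensor and field dimensions do not match", call. = FALSE)
  }
  .apply_tensor(D, V)
}

.apply_tensor <- function(D, V) {
  d <- dim(V)
  fx <- array(V[, , 1L, ], c(d[1], d[2], d[4]))
  fy <- array(V[, , 2L, ], c(d[1], d[2], d[4]))
  # c(matrix) recycles over the channel dimension of the H x W x C slabs
  out <- array(0, d)
  out[, , 1L, ] <- fx * c(D$d11) + fy * c(D$d12)
  out[, , 2L, ] <- fx * c(D$d12) + fy * c(D$d22)
  out
}

#' @export
print.sym_tensor_field <- function(x, ...) {
  d <- dim(x$t11)
  cat(sprintf("<sym_tensor_field %d x %d> components t11, t12, t22\n", d[1], d[2]))
  invisible(x)
}

#' @export
print.eigen_system_field <- function(x, ...) {
  d <- dim(x$lambda_plus)
  cat(sprintf("<eigen_system_field %d x %d> lambda range [%.3g, %.3g]\n",
              d[1], d[2], min(x$lambda_minus), max(x$lambda_plus)))
  invisible(x)
}

#' @export
print.diffusion_tensor_field <- function(x, ...) {
  d <- dim(x$d11)
  cat(sprintf("<diffusion_tensor_field %d x %d>\n", d[1], d[2]))
  invisible(x)
}
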