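#' Linear contrast-enhancement target
#'
#' The target field `G = a * grad(u0)`: a uniform scaling of the original
#' image gradient. With `a > 1`, reintegrating `G` enhances local
#' contrast; `a = 1` returns the original gradient (a fixed point of the
#' solver, useful for testing).
#'
#' @param u0 Image field.
#' @param a Positive scalar gain (`a > 1` for enhancement).
#' @return A gradient field `H x W x 2 x C`.
#' @export
linear_target <- function(u0, a) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0) {
    stop("a must be a positive number", call. = FALSE)
  }
  a * compute_gradient(u0)
}

#' Gamma contrast-enhancement target
#'
#' Element-wise gamma compression of the gradient:
#' `G = sign(grad(u0)) * |grad(u0)|^gamma` with `0 < gamma <= 1`, applied
#' independently to every scalar component. Because the components lie in
#' \[-1, 1\], the power `gamma < 1` expands small gradients (boosting
#' faint detail) more than large ones. `sign(0) * |0|^gamma` is 0, so the
#' map is continuous and odd.
#'
#' @param u0 Image field.
#' @param gamma Exponent in `(0, 1]` (`gamma = 1` is the identity).
#' @return A gradient field `H x W x 2 x C`.
#' @export
gamma_target <- function(u0, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0 || gamma > 1) {
    stop("gamma must lie in (0, 1]", call. = FALSE)
  }
  g <- compute_gradient(u0)
  sign(g) * abs(g)^gamma
}

#' Built-in colour-vision-deficiency simulation matrices
#'
#' Standard 3x3 linear dichromat simulation matrices in RGB (Vienot-style
#' confusion-line projections). Rows sum to one, so achromatic colours
#' are preserved exactly; colours along the relevant confusion line are
#' collapsed towards each other.
#'
#' @param type `"protan"` (default) or `"deutan"`.
#' @return A 3x3 numeric matrix acting on RGB column vectors.
#' @export
cvd_matrix <- function(type = c("protan", "deutan")) {
  type <- match.arg(type)
  switch(type,
    protan = matrix(c(
      0.11238,  0.88762, 0.00000,
      0.11238,  0.88762, 0.00000,
      0.00401, -0.00401, 1.00000
    ), 3, 3, byrow = TRUE),
    deutan = matrix(c(
       0.29275, 0.70725, 0.00000,
       0.29275, 0.70725, 0.00000,
      -0.02234, 0.02234, 1.00000
    ), 3, 3, byrow = TRUE)
  )
}

#' Read a 3x3 simulation matrix from a plain-text file
#'
#' The file holds nine whitespace-separated numbers, row-major. Any
#' linear simulation model can be plugged into the daltonisation pipeline
#' this way.
#'
#' @param path File path.
#' @return A 3x3 numeric matrix.
#' @export
read_cvd_matrix <- function(path) {
  vals <- scan(path, what = double(), quiet = TRUE, comment.char = "#")
  if (length(vals) != 9L) {
    stop("expected 9 numbers (row-major 3x3) in ", path,
         ", got ", length(vals), call. = FALSE)
  }
  matrix(vals, 3, 3, byrow = TRUE)
}

#' Simulate colour-vision deficiency
#'
#' Applies a linear 3x3 simulation matrix per pixel and clips the result
#' to \[0, 1\]. This predicts how a dichromat perceives the image; it is
#' used both to estimate the direction of lost information
#' ([estimate_basis()]) and to evaluate daltonisation results.
#'
#' @param u0 A 3-channel image field.
#' @param sim_matrix 3x3 matrix (default: the shipped protanope matrix).
#' @return A 3-channel image field in \[0, 1\].
#' @export
cvd_simulate <- function(u0, sim_matrix = cvd_matrix("protan")) {
  u <- as_image_field(u0)
  d <- dim(u)
  if (d[3] != 3L) {
    stop("colour-vision-deficiency simulation requires a 3-channel image",
         call. = FALSE)
  }
  stopifnot(is.matrix(sim_matrix), identical(dim(sim_matrix), c(3L, 3L)))
  X <- matrix(u, d[1] * d[2], 3L) %*% t(sim_matrix)
  X[X < 0] <- 0
  X[X > 1] <- 1
  array(X, d)
}

#' Estimate the daltonisation basis (e_d, e_c)
#'
#' From the per-pixel difference between the original image and its
#' deficiency simulation, computes
#' `e_d` — the principal deficiency direction: the dominant eigenvector of
#' the (by default uncentred) 3x3 second-moment matrix of the difference
#' vectors. The differences are already deviations from "no loss", so the
#' uncentred moment is the natural choice; set `centre = TRUE` to use the
#' covariance instead. The sign is fixed so the largest-magnitude
#' component is positive.
#' `e_c` — the chromatic compensation direction: the normalised cross
#' product of the grey axis `(1,1,1)/sqrt(3)` and `e_d`, hence orthogonal
#' to both (maximally visible to the deficient observer, no lightness
#' shift).
#'
#' Both signs of `e_c` satisfy the orthogonality constraints; they are
#' not equivalent, however, because the compensation
#' `(grad(u0) . e_d) e_c` must reinforce, not cancel, whatever contrast
#' survives the simulation. When a simulation matrix is supplied the sign
#' is therefore chosen so that the simulated compensation correlates
#' positively with the simulated original gradient (a deterministic,
#' data-driven choice); when the correlation is zero, or no matrix is
#' given, the green component of `e_c` is made non-negative.
#'
#' @param u0 Original 3-channel image.
#' @param sim Its deficiency simulation (same shape).
#' @param sim_matrix The 3x3 linear simulation matrix that produced
#'   `sim` (stored in the returned basis and used for the `e_c` sign
#'   choice); `NULL` to fall back to the green-component sign rule.
#' @param centre Subtract the mean difference before the moment matrix?
#'   Default `FALSE`.
#' @return An object of class `daltonisation_basis`: list with unit
#'   3-vectors `e_d` and `e_c` and the `sim_matrix` (possibly `NULL`).
#' @export
estimate_basis <- function(u0, sim, sim_matrix = cvd_matrix("protan"),
                           centre = FALSE) {
  u <- as_image_field(u0)
  v <- as_image_field(sim)
  if (!identical(dim(u), dim(v))) {
    stop("u0 and sim must have identical dimensions", call. = FALSE)
  }
  if (dim(u)[3] != 3L) stop("daltonisation requires 3-channel images", call. = FALSE)
  n <- dim(u)[1] * dim(u)[2]
  Dm <- matrix(u - v, n, 3L)
  if (centre) Dm <- sweep(Dm, 2L, colMeans(Dm))
  M <- crossprod(Dm) / n
  scale <- max(abs(M))
  if (scale == 0) {
    stop("nothing to daltonise: simulation is identical to the original",
         call. = FALSE)
  }
  e_d <- eigen(M, symmetric = TRUE)$vectors[, 1L]
  e_d <- e_d / sqrt(sum(e_d^2))
  lead <- which(abs(e_d) >= max(abs(e_d)) - 1e-12)[1L]  # first of near-ties
  if (e_d[lead] < 0) e_d <- -e_d
  grey <- c(1, 1, 1) / sqrt(3)
  e_c <- c(
    grey[2] * e_d[3] - grey[3] * e_d[2],
    grey[3] * e_d[1] - grey[1] * e_d[3],
    grey[1] * e_d[2] - grey[2] * e_d[1]
  )
  nc <- sqrt(sum(e_c^2))
  if (nc < 1e-8) {
    stop("principal deficiency direction is parallel to the grey axis; ",
         "chromatic compensation direction is undefined", call. = FALSE)
  }
  e_c <- e_c / nc
  flip_by_green <- function(v) if (v[2] < 0) -v else v
  if (is.null(sim_matrix)) {
    e_c <- flip_by_green(e_c)
  } else {
    stopifnot(is.matrix(sim_matrix), identical(dim(sim_matrix), c(3L, 3L)))
    # correlate the simulated compensation with the surviving simulated
    # gradient: score = sum_k,pix (g.e_d) * (M g . M e_c)
    g <- compute_gradient(u)
    mec <- as.vector(sim_matrix %*% e_c)
    score <- 0
    for (k in 1:2) {
      gk <- matrix(g[, , k, ], n, 3L)
      proj_d <- gk %*% e_d
      sim_g <- gk %*% t(sim_matrix)
      score <- score + sum(proj_d * (sim_g %*% mec))
    }
    if (score < 0) e_c <- -e_c else if (score == 0) e_c <- flip_by_green(e_c)
  }
  structure(list(e_d = e_d, e_c = e_c, sim_matrix = sim_matrix),
            class = "daltonisation_basis")
}

#' Daltonisation target field
#'
#' `G = grad(u0) + (grad(u0) . e_d) e_c`: the component of the colour
#' gradient that a deficient observer cannot see (its projection onto
#' `e_d`) is added back along the visible chromatic direction `e_c`. The
#' dot product is over colour coordinates, taken independently for each
#' spatial axis.
#'
#' @param u0 Original 3-channel image.
#' @param basis A `daltonisation_basis` from [estimate_basis()].
#' @return A gradient field `H x W x 2 x 3`.
#' @export
daltonisation_target <- function(u0, basis) {
  u <- as_image_field(u0)
  if (dim(u)[3] != 3L) stop("daltonisation requires a 3-channel image", call. = FALSE)
  if (!inherits(basis, "daltonisation_basis")) {
    stop("basis must be a daltonisation_basis", call. = FALSE)
  }
  g <- compute_gradient(u)
  e_d <- basis$e_d
  e_c <- basis$e_c
  out <- g
  for (k in 1:2) {
    proj <- g[, , k, 1] * e_d[1] + g[, , k, 2] * e_d[2] + g[, , k, 3] * e_d[3]
    for (rho in 1:3) {
      out[, , k, rho] <- out[, , k, rho] + proj * e_c[rho]
    }
  }
  out
}

#' @export
print.daltonisation_basis <- function(x, ...) {
  cat(sprintf("<daltonisation_basis>\n  e_d = (%.4f, %.4f, %.4f)\n  e_c = (%.4f, %.4f, %.4f)\n",
              x$e_d[1], x$e_d[2], x$e_d[3], x$e_c[1], x$e_c[2], x$e_c[3]))
  invisible(x)
}
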