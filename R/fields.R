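#' Coerce to an image field
#'
#' Images are represented as plain numeric arrays of dimension
#' `height x width x channels` with intensities on an unconstrained real
#' scale (nominally in \[0,1\]; values are only clipped at export, see
#' [save_image()]). Greyscale images may be supplied as plain matrices and
#' are promoted to a single-channel array.
#'
#' @param x A numeric matrix (`H x W`) or array (`H x W x C`) with
#'   `C` in `{1, 3}`.
#' @param check Validate finiteness and dimensions (default `TRUE`).
#' @return A numeric array of dimension `H x W x C`.
#' @examples
#' u <- as_image_field(matrix(0.5, 8, 8))
#' dim(u)
#' @export
as_image_field <- function(x, check = TRUE) {
  if (is.matrix(x)) {
    x <- array(x, c(nrow(x), ncol(x), 1L))
  }
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("image must be an H x W matrix or an H x W x C array", call. = FALSE)
  }
  if (check) {
    d <- dim(x)
    if (!d[3] %in% c(1L, 3L)) {
      stop("image must have 1 or 3 channels, got ", d[3], call. = FALSE)
    }
    if (d[1] < 2L || d[2] < 2L) {
      stop("image must be at least 2 x 2 pixels", call. = FALSE)
    }
    if (!all(is.finite(x))) {
      stop("image contains non-finite values", call. = FALSE)
    }
  }
  storage.mode(x) <- "double"
  x
}

#' Discrete image gradient (forward differences, Neumann boundary)
#'
#' Computes the per-channel spatial gradient of an image with forward
#' differences. The component along axis 1 is the x (column) direction,
#' axis 2 the y (row) direction. At the last column/row the forward
#' difference is set to zero, i.e. the image is implicitly replicated
#' beyond its frame (no flux across the boundary). This convention pairs
#' with the backward-difference [divergence()] so that the two operators
#' are exact negative adjoints of one another.
#'
#' @param image An image field (see [as_image_field()]).
#' @return A gradient field: numeric array `H x W x 2 x C`, where the third
#'   index selects the spatial axis (1 = x/columns, 2 = y/rows).
#' @examples
#' u <- as_image_field(matrix(seq(0, 1, length.out = 16), 4, 4))
#' g <- compute_gradient(u)
#' g[1, , 1, 1]  # forward differences along the first row, zero at the end
#' @export
compute_gradient <- function(image) {
  u <- as_image_field(image)
  .grad(u)
}

# unvalidated gradient kernel used in the solver inner loop
.grad <- function(u) {
  d <- dim(u)
  H <- d[1]; W <- d[2]; C <- d[3]
  g <- array(0, c(H, W, 2L, C))
  g[, -W, 1L, ] <- u[, -1L, , drop = FALSE] - u[, -W, , drop = FALSE]
  g[-H, , 2L, ] <- u[-1L, , , drop = FALSE] - u[-H, , , drop = FALSE]
  g
}

# extract spatial-axis slab k of a gradient field as an H x W x C array
.slab <- function(field, k) {
  d <- dim(field)
  array(field[, , k, ], c(d[1], d[2], d[4]))
}

.check_gradient_field <- function(field, name = "field") {
  if (!is.array(field) || length(dim(field)) != 4L || dim(field)[3] != 2L) {
    stop(name, " must be an H x W x 2 x C array", call. = FALSE)
  }
  if (!all(is.finite(field))) {
    stop(name, " contains non-finite values", call. = FALSE)
  }
  invisible(field)
}

#' Discrete divergence (backward differences)
#'
#' Backward-difference divergence of a per-channel vector field, with the
#' boundary convention that makes it the exact negative adjoint of
#' [compute_gradient()]: the last column of the x component and the last
#' row of the y component are ignored (they carry no flux under the
#' forward-difference convention), the backward difference at the first
#' column/row sees a zero neighbour. Balancing forward gradients with
#' backward divergence keeps the overall five-point scheme centred and
#' conservative: the divergence sums to zero over the image.
#'
#' @param field A gradient-shaped field, `H x W x 2 x C`.
#' @return Numeric array `H x W x C`.
#' @export
divergence <- function(field) {
  .check_gradient_field(field)
  .div(field)
}

.div <- function(field) {
  d <- dim(field)
  H <- d[1]; W <- d[2]; C <- d[4]
  fx <- array(field[, , 1L, ], c(H, W, C))
  fy <- array(field[, , 2L, ], c(H, W, C))
  fx[, W, ] <- 0
  fy[H, , ] <- 0
  dx <- fx
  dx[, -1L, ] <- fx[, -1L, , drop = FALSE] - fx[, -W, , drop = FALSE]
  dy <- fy
  dy[-1L, , ] <- fy[-1L, , , drop = FALSE] - fy[-H, , , drop = FALSE]
  dx + dy
}
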