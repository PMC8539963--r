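# Independent oracles and small random-input generators used across tests.
# Everything here is deliberately written without reusing the package's
# internal difference operators: loops and base linear algebra only.

# 1D Neumann (no-flux) second-difference matrix, stencil [1, -2, 1] with
# [-1, 1] boundary rows.
neumann_lap_1d <- function(n) {
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i > 1) { L[i, i - 1] <- 1; L[i, i] <- L[i, i] - 1 }
    if (i < n) { L[i, i + 1] <- 1; L[i, i] <- L[i, i] - 1 }
  }
  L
}

# Direct dense solve of the Neumann Poisson system lap(u) = div(G), the
# additive-constant gauge fixed by a rank-one mean term; returns the
# mean-zero solution per channel.
poisson_oracle <- function(G) {
  d <- dim(G); H <- d[1]; W <- d[2]; C <- d[4]
  n <- H * W
  L <- kronecker(neumann_lap_1d(W), diag(H)) +
       kronecker(diag(W), neumann_lap_1d(H))
  A <- L + matrix(1 / n, n, n)
  out <- array(0, c(H, W, C))
  for (ch in seq_len(C)) {
    fx <- G[, , 1, ch]; fy <- G[, , 2, ch]
    b <- matrix(0, H, W)
    for (i in 1:H) for (j in 1:W) {
      vx  <- if (j < W) fx[i, j] else 0
      vxm <- if (j > 1 && j - 1 < W) fx[i, j - 1] else 0
      vy  <- if (i < H) fy[i, j] else 0
      vym <- if (i > 1 && i - 1 < H) fy[i - 1, j] else 0
      b[i, j] <- (vx - vxm) + (vy - vym)
    }
    x <- solve(A, as.vector(b))
    out[, , ch] <- matrix(x - mean(x), H, W)
  }
  out
}

# n random symmetric PSD 2x2 tensors (as B^T B), returned as a 3-column
# matrix (t11, t12, t22)
random_psd_tensors <- function(n, seed = 1) {
  set.seed(seed)
  B11 <- rnorm(n); B12 <- rnorm(n); B21 <- rnorm(n); B22 <- rnorm(n)
  cbind(
    t11 = B11^2 + B21^2,
    t12 = B11 * B12 + B21 * B22,
    t22 = B12^2 + B22^2
  )
}

random_gradient_field <- function(H, W, C, seed = 1, sd = 1) {
  set.seed(seed)
  array(rnorm(H * W * 2 * C, sd = sd), c(H, W, 2L, C))
}

random_image <- function(H, W, C, seed = 1) {
  set.seed(seed)
  array(runif(H * W * C), c(H, W, C))
}

# eigendecomposition of a single (t11, t12, t22) tensor by the generic
# numerical symmetric solver
eigen_oracle <- function(t11, t12, t22) {
  eigen(matrix(c(t11, t12, t12, t22), 2, 2), symmetric = TRUE)
}
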