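test_that("apply_tensor performs the pointwise matrix-vector product", {
  V <- random_gradient_field(5, 4, 3, seed = 2)
  id <- list(d11 = matrix(1, 5, 4), d12 = matrix(0, 5, 4),
             d22 = matrix(1, 5, 4))
  expect_equal(apply_tensor(id, V), V)

  Dh <- list(d11 = matrix(0.5, 2, 2), d12 = matrix(0, 2, 2),
             d22 = matrix(1, 2, 2))
  V1 <- array(0, c(2, 2, 2, 1)); V1[1, 1, 1, 1] <- 2; V1[1, 1, 2, 1] <- 4
  out <- apply_tensor(Dh, V1)
  expect_equal(c(out[1, 1, 1, 1], out[1, 1, 2, 1]), c(1, 4))

  # linearity in the tensor: halving D halves the output
  set.seed(4)
  D <- list(d11 = matrix(runif(20), 5, 4), d12 = matrix(runif(20) - 0.5, 5, 4),
            d22 = matrix(runif(20), 5, 4))
  Dh <- list(d11 = D$d11 / 2, d12 = D$d12 / 2, d22 = D$d22 / 2)
  expect_equal(apply_tensor(Dh, V), apply_tensor(D, V) / 2)
  expect_error(apply_tensor(D, random_gradient_field(3, 3, 1)), "match")
})

test_that("G = grad(u0) is an exact fixed point for every solver and psi", {
  u0 <- fixture_image("smooth_random", 16, 16, channels = 3, seed = 8)
  G <- compute_gradient(u0)
  for (m in c("none", "standard", "difference")) {
    for (nm in psi_catalogue()) {
      cfg <- solver_config(iterations = 25, tensor_source = m,
                           psi = make_psi(nm, K = 1e-3))
      res <- suppressWarnings(evolve(u0, G, cfg))
      expect_equal(max(abs(res$image - u0)), 0, info = paste(m, nm))
    }
  }
})

test_that("the variational solver with the linear potential reproduces Poisson steps", {
  u0 <- fixture_image("smooth_random", 16, 16, channels = 3, seed = 12)
  G <- gamma_target(u0, 0.6)
  p <- evolve(u0, G, solver_config(iterations = 30, tensor_source = "none",
                                   psi = make_psi("linear")),
              record_iterates = TRUE)
  v <- evolve(u0, G, solver_config(iterations = 30, tensor_source = "difference",
                                   psi = make_psi("linear")),
              record_iterates = TRUE)
  for (it in seq_along(p$iterates)) {
    expect_lt(max(abs(p$iterates[[it]] - v$iterates[[it]])), 1e-12)
  }
})

test_that("the flow is conservative: channel means invariant for G = 0", {
  u0 <- fixture_image("smooth_random", 20, 20, channels = 3, seed = 3)
  G0 <- array(0, c(20, 20, 2, 3))
  for (m in c("none", "difference")) {
    res <- evolve(u0, G0, solver_config(iterations = 40, tensor_source = m),
                  record_iterates = TRUE)
    m0 <- apply(u0, 3, mean)
    for (u in res$iterates) {
      expect_lt(max(abs(apply(u, 3, mean) - m0)), 1e-10)
    }
  }
})

test_that("Poisson mode decouples channels; anisotropic modes do not", {
  u0 <- fixture_image("red_green_chart", 16, 16)
  G <- linear_target(u0, 1.5)
  joint <- evolve(u0, G, solver_config(iterations = 30, tensor_source = "none",
                                       psi = make_psi("linear")))$image
  sep <- array(0, dim(u0))
  for (ch in 1:3) {
    r <- evolve(u0[, , ch, drop = FALSE], G[, , , ch, drop = FALSE],
                solver_config(iterations = 30, tensor_source = "none",
                              psi = make_psi("linear")))
    sep[, , ch] <- r$image[, , 1]
  }
  expect_equal(joint, sep)

  # anisotropic coupling: per-channel evolution differs on a colour image
  cfg <- solver_config(iterations = 30, tensor_source = "difference",
                       psi = make_psi("perona_malik_log", K = 0.1))
  joint_a <- evolve(u0, G, cfg)$image
  sep_a <- array(0, dim(u0))
  for (ch in 1:3) {
    sep_a[, , ch] <- evolve(u0[, , ch, drop = FALSE], G[, , , ch, drop = FALSE],
                            cfg)$image[, , 1]
  }
  expect_gt(max(abs(joint_a - sep_a)), 1e-6)
})

test_that("energy evaluates the potential of the residual tensor", {
  u <- random_image(10, 10, 3, seed = 6)
  G <- compute_gradient(u)
  psi <- make_psi("perona_malik_log", K = 1e-3)
  expect_equal(energy(u, G, psi), 0)

  # linear potential: half the squared Frobenius norm of the residual
  G2 <- random_gradient_field(10, 10, 3, seed = 7, sd = 0.1)
  R <- compute_gradient(u) - G2
  expect_equal(energy(u, G2, make_psi("linear")), sum(R^2) / 2,
               tolerance = 1e-10)

  # an isolated residual with lambda_plus = K^2, lambda_minus = 0
  # contributes psi(K^2, 0) = (K^2/2) log 2
  K <- 1e-3
  u0 <- array(0.3, c(8, 8, 1))
  Gp <- compute_gradient(u0)
  Gp[4, 4, 1, 1] <- Gp[4, 4, 1, 1] - K
  expect_equal(energy(u0, Gp, psi), K^2 / 2 * log(2), tolerance = 1e-12)
})

test_that("energy trace is non-increasing for the variational gradient flow", {
  u0 <- fixture_image("smooth_random", 32, 32, channels = 3, seed = 21)
  G <- linear_target(u0, 2)
  for (nm in c("perona_malik_log", "perona_malik_exp")) {
    res <- evolve(u0, G, solver_config(iterations = 300,
                                       tensor_source = "difference",
                                       psi = make_psi(nm, K = 1e-3)))
    v <- res$energy$value
    expect_true(all(diff(v) <= 1e-9 * abs(v[-length(v)])), info = nm)
  }
})

test_that("stability violations warn and numeric blow-up aborts with an index", {
  u0 <- fixture_image("smooth_random", 12, 12, channels = 1, seed = 5)
  G <- linear_target(u0, 2)
  expect_warning(
    evolve(u0, G, solver_config(dt = 0.4, iterations = 2, tensor_source = "none",
                                psi = make_psi("linear"))),
    "stability")
  expect_error(
    suppressWarnings(
      evolve(u0, G, solver_config(dt = 1e150, iterations = 50,
                                  tensor_source = "none",
                                  psi = make_psi("linear")))),
    "iteration")
})

test_that("early stopping triggers on the update norm", {
  u0 <- fixture_image("smooth_random", 12, 12, channels = 1, seed = 5)
  G <- linear_target(u0, 2)
  res <- evolve(u0, G, solver_config(iterations = 50000, tensor_source = "none",
                                     psi = make_psi("linear"),
                                     convergence_tol = 1e-8))
  expect_true(res$converged)
  expect_lt(res$iterations_run, 50000)
})
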