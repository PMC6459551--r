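test_that("laplacian has the defining algebraic properties", {
  expect_equal(laplacian(matrix(1, 2, 2)), matrix(c(1, -1, -1, 1), 2, 2))
  withr::with_seed(2, {
    for (k in 1:5) {
      S <- matrix(runif(25), 5, 5)
      L <- laplacian(S)
      expect_equal(L, t(L))
      expect_equal(unname(rowSums(L)), rep(0, 5), tolerance = 1e-12)
      expect_gte(min(eigen(L, symmetric = TRUE)$values), -1e-10)
    }
  })
  # normalised flavour: still symmetric PSD with zero eigenvalue
  S <- matrix(runif(16), 4, 4)
  Ln <- laplacian(S, normalized = TRUE)
  expect_equal(Ln, t(Ln))
  ev <- eigen(Ln, symmetric = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("simplex projection is exact", {
  v <- c(0.2, 0.3, 0.5)
  expect_equal(simplex_project(v), v)
  expect_equal(simplex_project(c(0.5, 0.5, 0.5)), rep(1 / 3, 3))
  expect_equal(simplex_project(c(2, 0, 0)), c(1, 0, 0))
  withr::with_seed(7, {
    for (k in 1:200) {
      n <- sample(2:5, 1)
      v <- rnorm(n, sd = 2)
      x <- simplex_project(v)
      expect_equal(sum(x), 1, tolerance = 1e-12)
      expect_true(all(x >= 0))
      expect_equal(x, simplex_qp_oracle(v), tolerance = 1e-8)
    }
  })
})

test_that("affinity updates are projections of the weighted view average", {
  withr::with_seed(3, {
    V <- matrix(runif(16), 4, 4)
    V <- V / rowSums(V) # rows already on the simplex
    F <- matrix(rnorm(20), 4, 5)
  })
  # alpha = 0, single simplex-row view: projection is the identity
  expect_equal(update_sd(list(V), 1, F, 0), V, tolerance = 1e-12)
  # alpha = 0, two equally weighted views: projection of the mean
  W <- matrix(runif(16), 4, 4)
  SD <- update_sd(list(V, W), c(0.5, 0.5), F, 0)
  expect_equal(SD, t(apply((V + W) / 2, 1, simplex_project)),
               tolerance = 1e-12)
  expect_row_stochastic(SD)
  # transposition symmetry between the two spaces
  expect_equal(update_sm(list(V), 1, t(F), 0.3),
               update_sd(list(V), 1, F, 0.3))
})

test_that("label consistency pulls affinities toward similar score profiles", {
  withr::with_seed(8, {
    V <- matrix(runif(16), 4, 4)
    F_same <- matrix(rnorm(20), 4, 5)
    F_same[3, ] <- F_same[1, ] # diseases 1 and 3 share a profile
    F_diff <- F_same
    F_diff[3, ] <- F_diff[3, ] + 5
  })
  S_same <- update_sd(list(V), 1, F_same, alpha = 0.4)
  S_diff <- update_sd(list(V), 1, F_diff, alpha = 0.4)
  expect_gte(S_same[1, 3], S_diff[1, 3])
})

test_that("affinity update rows solve the per-row quadratic program", {
  withr::with_seed(13, {
    views <- replicate(4, {
      A <- matrix(runif(25), 5, 5)
      (A + t(A)) / 2
    }, simplify = FALSE)
    w <- runif(4, 0.1, 1)
    F <- matrix(rnorm(30), 5, 6)
  })
  alpha <- 0.2
  S <- update_sd(views, w, F, alpha)
  # re-derive each row's QP target independently and solve by KKT enumeration
  for (i in 1:5) {
    z <- sapply(1:5, function(j) sum((F[i, ] - F[j, ])^2))
    target <- (Reduce(`+`, Map(`*`, w, views))[i, ] - alpha / 2 * z) / sum(w)
    expect_equal(unname(S[i, ]), simplex_qp_oracle(target), tolerance = 1e-8)
  }
})

test_that("propagation solve satisfies its Sylvester equation", {
  # zero coefficients: the equation collapses to F = Y, bit-exact
  Y <- random_binary_matrix(5, 7, seed = 3)
  SD <- diag(5)
  SM <- diag(7)
  expect_identical(solve_propagation(SD, SM, Y, 0, 0), Y)
  withr::with_seed(21, {
    for (k in 1:5) {
      SD <- matrix(runif(36), 6, 6)
      SM <- matrix(runif(81), 9, 9)
      Y <- random_binary_matrix(6, 9, seed = 100 + k)
      a <- runif(1, 0, 2)
      b <- runif(1, 0, 2)
      F <- solve_propagation(SD, SM, Y, a, b)
      res <- (a * laplacian(SD) + diag(6)) %*% F + F %*% (b * laplacian(SM)) - Y
      expect_lte(norm(res, "F") / norm(Y, "F"), 1e-8)
    }
  })
  expect_error(solve_propagation(diag(3), diag(7), Y, 1, 1), "Shapes")
})

test_that("propagation solve equals the Kronecker-vectorised oracle", {
  withr::with_seed(31, {
    SD <- matrix(runif(36), 6, 6)
    SM <- matrix(runif(81), 9, 9)
  })
  Y <- random_binary_matrix(6, 9, seed = 5)
  expect_equal(solve_propagation(SD, SM, Y, 0.7, 0.3),
               kron_sylvester_oracle(SD, SM, Y, 0.7, 0.3), tolerance = 1e-8)
  # 2x2 toy
  SD2 <- matrix(c(0.6, 0.4, 0.4, 0.6), 2, 2)
  SM2 <- matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2)
  Y2 <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(solve_propagation(SD2, SM2, Y2, 1.5, 0.5),
               kron_sylvester_oracle(SD2, SM2, Y2, 1.5, 0.5),
               tolerance = 1e-10)
})

test_that("view weights are inverse Frobenius distances", {
  S <- diag(4)
  V1 <- S + 1 # ||S - V1||_F = 4 -> weight 1/8
  expect_equal(unname(update_view_weights(S, list(V1))), 1 / 8)
  # equidistant views get equal weights; a coincident view hits the guard
  V2 <- S - 1
  w <- update_view_weights(S, list(V1, V2))
  expect_equal(w[[1]], w[[2]])
  w3 <- update_view_weights(S, list(S, V1))
  expect_equal(unname(w3[1]), 1 / (2 * 1e-10))
  expect_gt(w3[[1]], w3[[2]])
})

test_that("objective matches an independent term-wise recomputation", {
  # all terms vanish when the graphs equal their single views and F = Y
  Y <- random_binary_matrix(3, 4, seed = 2)
  V <- diag(3)
  W <- diag(4)
  expect_equal(amvml_objective(V, W, Y, Y, list(V), list(W), 1, 1, 0, 0), 0)
  withr::with_seed(17, {
    SD <- matrix(runif(9), 3, 3)
    SM <- matrix(runif(16), 4, 4)
    F <- matrix(rnorm(12), 3, 4)
    V2 <- matrix(runif(9), 3, 3)
    W2 <- matrix(runif(16), 4, 4)
  })
  wd <- c(0.3, 0.7)
  wm <- c(0.5, 0.5)
  got <- amvml_objective(SD, SM, F, Y, list(V, V2), list(W, W2), wd, wm,
                         alpha = 0.11, beta = 0.07)
  # term-by-term, with the trace forms written out longhand
  exp_val <- wd[1] * sum((SD - V)^2) + wd[2] * sum((SD - V2)^2) +
    wm[1] * sum((SM - W)^2) + wm[2] * sum((SM - W2)^2) +
    2 * 0.11 * sum(vapply(1:ncol(F), function(c) {
      t(F[, c]) %*% laplacian(SD) %*% F[, c]
    }, numeric(1))) +
    2 * 0.07 * sum(vapply(1:nrow(F), function(r) {
      t(F[r, ]) %*% laplacian(SM) %*% F[r, ]
    }, numeric(1))) +
    sum((F - Y)^2)
  expect_equal(got, exp_val, tolerance = 1e-10)
  expect_gte(got, 0)
})

test_that("fit produces row-stochastic graphs and a monotone trace", {
  inst <- tiny_instance()
  fit <- amvml(inst$Y, inst$views_d, inst$views_m,
               control = amvml_control(alpha = 1e-3, beta = 1e-3))
  expect_row_stochastic(fit$SD)
  expect_row_stochastic(fit$SM)
  drops <- unlist(tapply(fit$trace$objective, fit$trace$outer, diff))
  expect_true(all(drops <= 1e-9))
  expect_equal(dimnames(fit$F), dimnames(unclass(inst$Y)))
})

test_that("zero trade-offs reduce the fit to the label matrix", {
  inst <- tiny_instance(seed = 9)
  fit <- amvml(inst$Y, inst$views_d, inst$views_m,
               control = amvml_control(alpha = 0, beta = 0))
  expect_identical(fit$F, unclass(inst$Y))
  expect_equal(fit$inner_iterations[1], 2) # second pass confirms stationarity
})

test_that("identical row-stochastic views are a fixed point at zero trade-off", {
  # symmetric and row-stochastic: convex mix of identity and the flat graph
  V <- 0.5 * diag(12) + 0.5 / 12
  W <- 0.3 * diag(15) + 0.7 / 15
  inst <- tiny_instance()
  fit <- amvml(inst$Y, list(V, V), list(W, W),
               control = amvml_control(alpha = 0, beta = 0, max_outer = 1))
  expect_equal(unname(fit$SD), V, tolerance = 1e-10)
  expect_equal(unname(fit$SM), W, tolerance = 1e-10)
})

test_that("prediction ranking is invariant to scaling the labels", {
  inst <- tiny_instance(seed = 11)
  fit1 <- amvml(inst$Y, inst$views_d, inst$views_m)
  Y5 <- unclass(inst$Y) * 5
  # bypass the binary constructor: propagation is linear in Y
  F5 <- solve_propagation(fit1$SD, fit1$SM, Y5,
                          2 * fit1$control$alpha, 2 * fit1$control$beta)
  expect_equal(F5, 5 * fit1$F, tolerance = 1e-9)
  expect_equal(order(F5), order(fit1$F))
})

test_that("fit rejects malformed inputs", {
  inst <- tiny_instance()
  expect_error(amvml(inst$Y, list(matrix(1, 3, 3)), inst$views_m), "3x3")
  expect_error(amvml_control(alpha = -1), "non-negative")
  expect_error(amvml_control(max_inner = 0), "caps")
})
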