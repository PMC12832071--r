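test_that("glasso solves the trivial cases exactly", {
  Sd <- diag(c(2, 0.5, 1.5))
  fit <- glasso_fit(Sd, 0.3)
  expect_equal(fit$K, diag(1 / c(2, 0.5, 1.5)), tolerance = 1e-8)

  set.seed(7)
  A <- matrix(rnorm(9), 3)
  S <- stats::cov2cor(crossprod(A) + diag(3) * 0.5)
  fit0 <- glasso_fit(S, 0, tol = 1e-9)
  expect_equal(fit0$K, solve(S), tolerance = 1e-7, ignore_attr = TRUE)

  expect_error(glasso_fit(matrix(1:4, 2), 0.1), "symmetric")
  expect_error(glasso_fit(diag(c(1, -1)), 0.1), "positive diagonal")
  expect_error(glasso_fit(diag(2), -0.1), ">= 0")
})

test_that("precision_to_pcor normalizes and flips signs", {
  expect_equal(precision_to_pcor(diag(3)), matrix(0, 3, 3))
  K <- matrix(c(1, -0.5, -0.5, 1), 2)
  expect_equal(precision_to_pcor(K)[1, 2], 0.5)
  expect_error(precision_to_pcor(diag(c(1, 0))), "positive diagonal")
})

test_that("pcor matches the regression-residual oracle on simulated data", {
  set.seed(21)
  K <- planted_precision(4, list(list(1, 2, 0.4), list(2, 3, -0.3),
                                 list(3, 4, 0.25)))
  X <- rmvnorm <- {
    ch <- chol(solve(K))
    matrix(rnorm(50000 * 4), ncol = 4) %*% ch
  }
  W <- precision_to_pcor(K)
  for (pair in list(c(1, 2), c(2, 3), c(1, 4))) {
    i <- pair[1]; j <- pair[2]
    ri <- resid(lm(X[, i] ~ X[, -c(i, j)]))
    rj <- resid(lm(X[, j] ~ X[, -c(i, j)]))
    expect_equal(cor(ri, rj), W[i, j], tolerance = 0.02)
  }
})

test_that("EBIC matches its definition and prefers true sparsity", {
  set.seed(3)
  A <- matrix(rnorm(25), 5)
  S <- stats::cov2cor(crossprod(A) + diag(5))
  K <- glasso_fit(S, 0.2)$K
  E <- sum(K[upper.tri(K)] != 0)
  ll <- determinant(K)$modulus[1] - sum(S * K)
  n <- 250
  expect_equal(ebic_score(K, S, n, gamma = 0), -n * ll + E * log(n))
  expect_equal(ebic_score(K, S, n, gamma = 0.5),
               -n * ll + E * log(n) + 4 * E * 0.5 * log(5))

  # independent data: the diagonal model beats the saturated one
  set.seed(4)
  Xind <- matrix(rnorm(1000 * 6), ncol = 6)
  Sx <- cor(Xind)
  K_sat <- solve(Sx)
  K_diag <- diag(1 / diag(Sx))
  expect_lt(ebic_score(K_diag, Sx, 1000), ebic_score(K_sat, Sx, 1000))
})

test_that("estimate_ggm selects along a monotone path and names bad items", {
  tr <- make_ground_truth(p_bps = 4, p_kads = 4, edge_density = 0.25,
                          seed = 5)
  X <- wave_matrix(simulate_panel(tr, 600, seed = 6)$data, 1)
  net <- estimate_ggm(X)
  expect_s3_class(net, "ggm_network")
  expect_true(is_square_sym <- max(abs(net$weights - t(net$weights))) < 1e-12)
  expect_equal(diag(net$weights), setNames(rep(0, 8), colnames(X)))
  expect_true(all(abs(net$weights) <= 1))
  # sparsity nonincreasing in lambda (path is stored largest-first)
  expect_true(all(diff(net$path$edges) >= 0))
  expect_equal(net$path$lambda[1], max(abs(cor(X)[upper.tri(cor(X))])))

  Xbad <- cbind(X, CONST = 1)
  expect_error(estimate_ggm(Xbad), "CONST")
})

test_that("duplicating every subject leaves the selected weights unchanged", {
  tr <- make_ground_truth(p_bps = 4, p_kads = 4, edge_density = 0.2, seed = 2)
  X <- wave_matrix(simulate_panel(tr, 400, seed = 3)$data, 1)
  g1 <- estimate_ggm(X)
  g2 <- estimate_ggm(rbind(X, X))
  expect_equal(g2$weights, g1$weights, tolerance = 1e-10)
  expect_equal(g2$n_obs, 2 * g1$n_obs)
})

test_that("estimation is equivariant under node relabeling", {
  tr <- make_ground_truth(p_bps = 3, p_kads = 3, edge_density = 0.3, seed = 8)
  X <- wave_matrix(simulate_panel(tr, 500, seed = 9)$data, 1)
  perm <- c(4, 2, 6, 1, 3, 5)
  g <- estimate_ggm(X)
  gp <- estimate_ggm(X[, perm])
  expect_equal(gp$weights, g$weights[perm, perm], tolerance = 1e-8)
  cp <- centrality(gp); c0 <- centrality(g)
  expect_equal(cp$strength, c0$strength[perm], tolerance = 1e-8)
})

test_that("centrality handles empty, star and mixed-sign networks", {
  empty <- matrix(0, 4, 4)
  ce <- centrality(empty)
  expect_true(all(ce$strength == 0) && all(ce$z_strength == 0))
  expect_true(attr(ce, "degenerate"))

  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 0.2
  cs <- centrality(star)
  expect_equal(cs$strength, c(0.8, rep(0.2, 4)))
  expect_equal(cs$expected_influence, cs$strength)  # all-positive weights

  mixed <- star
  mixed[1, 2] <- mixed[2, 1] <- -0.2
  cm <- centrality(mixed)
  expect_lt(cm$expected_influence[1], cm$strength[1])
})
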