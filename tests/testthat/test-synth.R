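test_that("ground truths are reproducible and density 0 means independence", {
  t1 <- make_ground_truth(p_bps = 4, p_kads = 4, edge_density = 0.3, seed = 7)
  t2 <- make_ground_truth(p_bps = 4, p_kads = 4, edge_density = 0.3, seed = 7)
  expect_identical(t1, t2)

  t0 <- make_ground_truth(p_bps = 4, p_kads = 4, edge_density = 0, seed = 1)
  expect_true(all(t0$B == 0))
  expect_true(all(t0$K_w[upper.tri(t0$K_w)] == 0))
})

test_that("generated precision matrices are positive definite", {
  tr <- make_ground_truth(p_bps = 2, p_kads = 2, edge_density = 0.5, seed = 1)
  expect_gt(min(eigen(tr$K_w, symmetric = TRUE)$values), 0)
  expect_gte(min(eigen(tr$Sigma_B, symmetric = TRUE)$values), -1e-10)
  expect_lt(max(abs(eigen(tr$B, only.values = TRUE)$values)), 1)
})

test_that("explicit constructor enforces the truth invariants", {
  expect_error(ground_truth(B = diag(2) * 1.2, K_w = diag(2),
                            Sigma_B = diag(2)), "spectral radius")
  expect_error(ground_truth(B = matrix(0, 2, 2), K_w = -diag(2),
                            Sigma_B = diag(2)), "positive definite")
  tr <- ground_truth(B = matrix(0, 3, 3), K_w = diag(3), Sigma_B = diag(3))
  expect_s3_class(tr, "ground_truth")
  expect_false(any(vapply(tr$thresholds, is.unsorted, TRUE)))
})

test_that("fully independent truth gives uncorrelated waves", {
  tr <- ground_truth(B = matrix(0, 5, 5), K_w = diag(5),
                     Sigma_B = matrix(0, 5, 5))
  rep <- simulate_panel(tr, 4000, seed = 2)
  for (j in 1:5) {
    r <- cor(rep$latent[, j, 1], rep$latent[, j, 2])
    expect_lt(abs(r), 3 / sqrt(4000))
  }
})

test_that("between variance drives the cross-wave correlation (ICC 0.5)", {
  tr <- ground_truth(B = matrix(0, 4, 4), K_w = diag(4), Sigma_B = diag(4))
  rep <- simulate_panel(tr, 5000, seed = 3)
  for (j in 1:4) {
    r <- cor(rep$latent[, j, 1], rep$latent[, j, 2])
    expect_lt(abs(r - 0.5), 0.05)
  }
})

test_that("lag-1 latent covariance matches B V from the Lyapunov solution", {
  set.seed(10)
  B <- matrix(0, 6, 6)
  B[cbind(1:6, 1:6)] <- 0.3
  B[1, 2] <- 0.4; B[3, 5] <- -0.35
  tr <- ground_truth(B = B, K_w = diag(6), Sigma_B = matrix(0, 6, 6))
  rep <- simulate_panel(tr, 2000, seed = 4)
  # with Sigma_B = 0 the latent scores are the within deviations themselves
  emp <- cov(rep$latent[, , 2], rep$latent[, , 1])
  expect_equal(emp, B %*% tr$V, tolerance = 0.12, ignore_attr = TRUE)
})

test_that("the process is stationary across many waves", {
  set.seed(11)
  B <- diag(0.4, 4); B[2, 1] <- 0.3
  tr <- ground_truth(B = B, K_w = diag(4), Sigma_B = matrix(0, 4, 4))
  rep <- simulate_panel(tr, 3000, waves = 10, seed = 5)
  expect_equal(cov(rep$latent[, , 10]), tr$V, tolerance = 0.12,
               ignore_attr = TRUE)
})

test_that("observed scores are the thresholded latent scores", {
  tr <- make_ground_truth(p_bps = 3, p_kads = 3, edge_density = 0.3,
                          seed = 9)
  rep <- simulate_panel(tr, 200, seed = 6)
  for (j in seq_len(tr$p)) {
    expected <- tr$schema$scale_min[j] +
      findInterval(rep$latent[, j, ], tr$thresholds[[j]])
    expect_equal(as.vector(rep$data$values[, j, ]), expected)
    expect_true(all(rep$data$values[, j, ] >= tr$schema$scale_min[j]))
    expect_true(all(rep$data$values[, j, ] <= tr$schema$scale_max[j]))
  }
})

test_that("MCAR injection hits the requested rate and is seeded", {
  tr <- make_ground_truth(seed = 1)
  rep <- simulate_panel(tr, 3296, seed = 7)
  expect_identical(inject_mcar(rep$data, 0), rep$data)
  m1 <- inject_mcar(rep$data, 0.1, seed = 8)
  m2 <- inject_mcar(rep$data, 0.1, seed = 8)
  expect_identical(m1$values, m2$values)
  expect_equal(mean(is.na(m1$values)), 0.1, tolerance = 0.01)
  expect_error(inject_mcar(rep$data, 0.6), "rate")
})

test_that("simulation is bit-identical end to end under fixed seeds", {
  run <- function() {
    tr <- make_ground_truth(p_bps = 3, p_kads = 3, edge_density = 0.2,
                            seed = 2)
    inject_mcar(simulate_panel(tr, 50, seed = 3)$data, 0.1, seed = 4)
  }
  expect_identical(run(), run())
})

test_that("simulator guards its preconditions", {
  tr <- make_ground_truth(seed = 1)
  expect_error(simulate_panel(tr, 100, waves = 1), "2 waves")
  expect_error(simulate_panel(tr, 1), "2 subjects")
  expect_error(make_ground_truth(p_bps = 1, p_kads = 1), "3 items")
})
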