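test_that("Little's test reports the no-missingness case explicitly", {
  X <- matrix(rnorm(50 * 3), 50)
  res <- little_mcar(X)
  expect_equal(res$statistic, 0)
  expect_true(is.na(res$p.value))
  expect_match(res$note, "no missingness")
})

test_that("Little's test rejects strongly value-dependent missingness", {
  set.seed(81)
  n <- 800
  z <- rnorm(n)
  X <- cbind(x1 = z + rnorm(n), x2 = z + rnorm(n), x3 = rnorm(n))
  # x2 goes missing when the observed x1 is large: MAR, not MCAR
  X[X[, 1] > 0.5, 2] <- NA
  res <- little_mcar(X)
  expect_lt(res$p.value, 0.01)
  expect_gt(res$df, 0)
})

test_that("EM recovers the mean and covariance under MCAR", {
  set.seed(82)
  n <- 1500
  S <- matrix(c(1, .6, .3, .6, 1, .4, .3, .4, 1), 3)
  X <- matrix(rnorm(n * 3), n) %*% chol(S) + 1
  Xm <- X
  Xm[matrix(runif(n * 3) < 0.15, n)] <- NA
  fit <- panelsym:::em_norm(Xm)
  expect_true(fit$converged)
  expect_equal(fit$mu, rep(1, 3), tolerance = 0.1, ignore_attr = TRUE)
  expect_equal(fit$Sigma, S, tolerance = 0.12, ignore_attr = TRUE)
})

test_that("mice_pmm leaves complete data and observed cells untouched", {
  set.seed(83)
  X <- matrix(rnorm(120 * 4), 120)
  imp <- mice_pmm(X, m = 3, iterations = 2, seed = 1)
  expect_length(imp$datasets, 3)
  for (d in imp$datasets) expect_equal(d, X)

  Xm <- X
  Xm[matrix(runif(480) < 0.1, 120)] <- NA
  imp2 <- mice_pmm(Xm, m = 4, iterations = 3, seed = 2)
  obs <- !is.na(Xm)
  for (d in imp2$datasets) {
    expect_false(anyNA(d))
    expect_equal(d[obs], Xm[obs])  # observed cells never altered
  }
})

test_that("pmm imputations are donated observed values; binary goes logistic", {
  set.seed(84)
  n <- 200
  lat <- rnorm(n)
  ord <- findInterval(lat, c(-0.5, 0.5)) + 1      # 3-category item
  bin <- as.numeric(lat + rnorm(n) > 0)           # binary covariate
  X <- cbind(ord = ord, bin = bin, cont = lat + rnorm(n))
  Xm <- X
  Xm[sample(n, 30), "ord"] <- NA
  Xm[sample(n, 30), "bin"] <- NA
  imp <- mice_pmm(Xm, m = 2, iterations = 3, seed = 3)
  for (d in imp$datasets) {
    expect_true(all(d[, "ord"] %in% unique(na.omit(Xm[, "ord"]))))
    expect_true(all(d[, "bin"] %in% c(0, 1)))
  }
  expect_error(mice_pmm(cbind(X, all_na = NA_real_)), "fully missing")
  expect_error(mice_pmm(Xm[1:20, ]), "30 observed")
})

test_that("imputation chains are reproducible and panel-aware", {
  tr <- make_ground_truth(p_bps = 3, p_kads = 3, edge_density = 0.2,
                          seed = 85)
  data <- inject_mcar(simulate_panel(tr, 150, seed = 86)$data, 0.08,
                      seed = 87)
  i1 <- mice_pmm(data, m = 2, iterations = 2, seed = 4)
  i2 <- mice_pmm(data, m = 2, iterations = 2, seed = 4)
  expect_identical(i1$datasets[[1]]$values, i2$datasets[[1]]$values)
  expect_s3_class(i1$datasets[[1]], "panel_data")
  expect_false(anyNA(i1$datasets[[1]]$values))
  # imputed ordinal cells respect the schema range (donor property)
  expect_true(all(i1$datasets[[1]]$values[, 1, ] %in% 1:5))
})

test_that("Rubin pooling follows the worked formulas", {
  same <- rubin_pool(rep(2.5, 4), rep(0.3, 4))
  expect_equal(same$point, 2.5)
  expect_equal(same$between_var, 0)
  expect_equal(same$total_var, 0.3)
  expect_identical(same$df, Inf)

  pair <- rubin_pool(c(1, 3), c(1, 1))
  expect_equal(pair$point, 2)
  expect_equal(pair$within_var, 1)
  expect_equal(pair$between_var, 2)
  expect_equal(pair$total_var, 1 + 1.5 * 2)
  expect_equal(pair$df, (2 - 1) * (1 + 1 / (1.5 * 2))^2)

  # permutation invariance in the imputation index
  est <- c(0.2, 0.5, 0.1, 0.9); va <- c(1, 2, 3, 4) / 10
  perm <- c(3, 1, 4, 2)
  expect_equal(rubin_pool(est, va), rubin_pool(est[perm], va[perm]))
  expect_error(rubin_pool(1, 1), "at least 2")
})

test_that("pooled network weights honour mean and majority rules", {
  m1 <- matrix(c(0, 0.4, 0.4, 0), 2)
  m2 <- matrix(0, 2, 2)
  expect_equal(pool_edge_weights(list(m1, m2))[1, 2], 0.2)
  expect_equal(pool_edge_weights(list(m1, m2), rule = "majority")[1, 2], 0)
  expect_equal(pool_edge_weights(list(m1, m1, m2),
                                 rule = "majority")[1, 2], 0.4 * 2 / 3)
})

test_that("with vanishing missingness pooled weights equal complete-data weights", {
  tr <- make_ground_truth(p_bps = 3, p_kads = 3, edge_density = 0.3,
                          seed = 88)
  data <- simulate_panel(tr, 400, seed = 89)$data
  imp <- mice_pmm(data, m = 3, iterations = 2, seed = 5)  # rate 0 exactly
  nets <- lapply(imp$datasets, function(d)
    edge_weights(estimate_ggm(wave_matrix(d, 1), n_lambda = 20)))
  full <- edge_weights(estimate_ggm(wave_matrix(data, 1), n_lambda = 20))
  expect_equal(pool_edge_weights(nets), full)
})
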