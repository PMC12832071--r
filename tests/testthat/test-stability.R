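# A cheap data-dependent "network" for bootstrap machinery tests: the
# zero-diagonal correlation matrix.
cor_net <- function(d) {
  W <- cor(d)
  diag(W) <- 0
  W
}

test_that("bootstrap CIs collapse for a constant estimator and are seeded", {
  set.seed(61)
  X <- matrix(rnorm(200 * 4), 200)
  Wfix <- matrix(0.3, 4, 4); diag(Wfix) <- 0
  boot <- bootstrap_edges(X, function(d) Wfix, n_boot = 100, seed = 1)
  expect_equal(boot$ci_lower, boot$ci_upper, ignore_attr = TRUE)
  expect_equal(boot$ci_lower[1, 2], 0.3)

  b1 <- bootstrap_edges(X, cor_net, n_boot = 100, seed = 5)
  b2 <- bootstrap_edges(X, cor_net, n_boot = 100, seed = 5)
  expect_identical(b1$replicates, b2$replicates)
  expect_error(bootstrap_edges(X, cor_net, n_boot = 50), "at least 100")
})

test_that("bootstrap aborts when the estimator keeps failing on replicates", {
  set.seed(20)
  X <- matrix(rnorm(100 * 3), 100)
  # succeeds on the original sample but fails on any resample with ties
  est <- function(d) {
    if (anyDuplicated(d)) stop("degenerate resample")
    cor_net(d)
  }
  expect_error(bootstrap_edges(X, est, n_boot = 100, seed = 1), "5%")
})

test_that("bootstrap CIs cover zero on edge-free truths and relabel cleanly", {
  covered <- unlist(lapply(1:20, function(s) {
    X <- withr::with_seed(600 + s, matrix(rnorm(300 * 4), 300))
    boot <- bootstrap_edges(X, cor_net, n_boot = 100, seed = s)
    ut <- upper.tri(boot$ci_lower)
    boot$ci_lower[ut] <= 0 & boot$ci_upper[ut] >= 0
  }))
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.995)

  # percentile CIs are equivariant under node relabeling
  X <- withr::with_seed(699, matrix(rnorm(200 * 4), 200))
  perm <- c(3, 1, 4, 2)
  b0 <- bootstrap_edges(X, cor_net, n_boot = 100, seed = 9)
  bp <- bootstrap_edges(X[, perm], cor_net, n_boot = 100, seed = 9)
  expect_equal(bp$ci_lower, b0$ci_lower[perm, perm], ignore_attr = TRUE)
  expect_equal(bp$ci_upper, b0$ci_upper[perm, perm], ignore_attr = TRUE)
})

test_that("edge difference test flags separated edges and not collinear ones", {
  set.seed(62)
  n <- 1000
  z <- rnorm(n)
  X <- cbind(a = z + 0.7 * rnorm(n), b = z + 0.7 * rnorm(n),
             c = rnorm(n), d = rnorm(n))
  boot <- bootstrap_edges(X, cor_net, n_boot = 200, seed = 2)
  strong_vs_null <- edge_difference_test(boot, c(1, 2), c(3, 4))
  expect_true(strong_vs_null$different)
  expect_error(edge_difference_test(boot, c(1, 2), c(2, 1)), "itself")
})

test_that("collinear replicate pairs are never flagged different", {
  set.seed(63)
  X <- matrix(rnorm(300 * 3), 300)
  # estimator writes the same value into two distinct edges
  est <- function(d) {
    r <- cor(d)[1, 2]
    W <- matrix(0, 3, 3)
    W[1, 2] <- W[2, 1] <- r
    W[1, 3] <- W[3, 1] <- r
    W
  }
  boot <- bootstrap_edges(X, est, n_boot = 150, seed = 3)
  expect_false(edge_difference_test(boot, c(1, 2), c(1, 3))$different)
})

test_that("case-drop CS equals the maximum drop for a data-ignoring estimator", {
  set.seed(64)
  X <- matrix(rnorm(300 * 4), 300)
  Wfix <- matrix(c(0, .1, .2, .3,
                   .1, 0, .4, .5,
                   .2, .4, 0, .6,
                   .3, .5, .6, 0), 4)
  cs <- casedrop_cs(X, function(d) Wfix, n_boot = 20, seed = 4)
  expect_equal(cs$cs_value, 0.7)
  expect_true(all(cs$cors == 1))
})

test_that("CS is nondecreasing as the correlation threshold is lowered", {
  set.seed(65)
  tr <- make_ground_truth(p_bps = 3, p_kads = 3, edge_density = 0.4,
                          seed = 66)
  X <- wave_matrix(simulate_panel(tr, 500, seed = 67)$data, 1)
  vals <- vapply(c(0.9, 0.7, 0.5), function(th) {
    casedrop_cs(X, cor_net, n_boot = 40, cor_threshold = th,
                seed = 5)$cs_value
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("case-drop guards its preconditions and is reproducible", {
  X <- matrix(rnorm(20 * 4), 20)
  expect_error(casedrop_cs(X, cor_net, drop_props = 0.9), "0.75")
  expect_error(casedrop_cs(X, cor_net, drop_props = 0.7, n_boot = 5),
               "p \\+ 5")
  X2 <- matrix(rnorm(400 * 4), 400)
  c1 <- casedrop_cs(X2, cor_net, n_boot = 10, seed = 9)
  c2 <- casedrop_cs(X2, cor_net, n_boot = 10, seed = 9)
  expect_identical(c1$cors, c2$cors)
})
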