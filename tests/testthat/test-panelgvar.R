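test_that("between/within split does the arithmetic exactly", {
  vals <- array(NA_real_, c(3, 2, 2))
  vals[1, , ] <- cbind(c(4, 2), c(2, 4))   # item x wave
  vals[2, , ] <- cbind(c(3, 1), c(3, 1))
  vals[3, , ] <- cbind(c(5, NA), c(1, 2))  # missing -> excluded
  sch <- data.frame(item_id = c("A", "B"), wording = "", scale_min = 1L,
                    scale_max = 5L, reverse_coded = FALSE, domain_label = "")
  class(sch) <- c("item_schema", "data.frame")
  data <- panel_data(vals, rep("g", 3), sch)
  sp <- between_within_split(data)
  expect_equal(sp$n_excluded, 1)
  expect_equal(unname(sp$means[1, ]), c(3, 3))
  expect_equal(unname(sp$deviations[1, , ]), cbind(c(1, -1), c(-1, 1)))
  expect_equal(unname(sp$deviations[2, , ]), matrix(0, 2, 2))  # constant
  # centering identity: deviations sum to zero within subject and item
  expect_true(all(apply(sp$deviations, c(1, 2), sum) == 0))
})

test_that("with two variables the between edge equals the marginal correlation", {
  set.seed(51)
  z <- rnorm(400)
  means <- cbind(a = z + rnorm(400), b = 0.8 * z + rnorm(400))
  r <- cor(means)[1, 2]
  W <- estimate_between(means, alpha = 0.05)
  expect_equal(W[1, 2], r, tolerance = 1e-10)
  expect_equal(diag(W), c(0, 0), ignore_attr = TRUE)
})

test_that("between estimation guards and prunes", {
  set.seed(52)
  means <- matrix(rnorm(30 * 4), 30)
  expect_error(estimate_between(means[1:5, ]), "n > p")
  # alpha ~ 0 prunes everything on null data
  expect_true(all(estimate_between(means, alpha = 1e-8) == 0))
})

test_that("the two-wave estimator matches its population reduction", {
  set.seed(53)
  B <- diag(0.3, 6)
  B[2, 1] <- 0.4; B[5, 3] <- -0.3
  K_w <- planted_precision(6, list(list(1, 4, 0.35)))
  tr <- ground_truth(B = B, K_w = K_w, Sigma_B = diag(0.5, 6))
  rep <- simulate_panel(tr, 6000, seed = 54)
  pop <- pop_twowave(tr)
  # run on the latent scale to isolate the estimator from discretization
  lat <- rep$latent
  means <- (lat[, , 1] + lat[, , 2]) / 2
  dev <- array(0, c(dim(lat)[1], 6, 2))
  dev[, , 1] <- lat[, , 1] - means
  dev[, , 2] <- lat[, , 2] - means
  est <- estimate_temporal_contemporaneous(dev, alpha = 0.01)
  big_t <- abs(pop$temporal) > 0.1
  expect_equal(est$temporal[big_t], pop$temporal[big_t], tolerance = 0.1,
               ignore_attr = TRUE)
  big_c <- abs(pop$contemporaneous) > 0.1
  expect_equal(est$contemporaneous[big_c], pop$contemporaneous[big_c],
               tolerance = 0.1, ignore_attr = TRUE)
})

test_that("a single node yields empty temporal and contemporaneous networks", {
  dev <- array(rnorm(40), c(20, 1, 2))
  dev[, , 1] <- -dev[, , 2]
  est <- estimate_temporal_contemporaneous(dev)
  expect_equal(est$temporal, matrix(0, 1, 1), ignore_attr = TRUE)
  expect_equal(est$contemporaneous, matrix(0, 1, 1), ignore_attr = TRUE)
})

test_that("the full fit is permutation-equivariant", {
  tr <- make_ground_truth(p_bps = 3, p_kads = 3, edge_density = 0.3,
                          seed = 55)
  rep <- simulate_panel(tr, 1200, seed = 56)
  perm <- c(3, 1, 5, 2, 6, 4)
  fit <- fit_panelgvar(rep$data)
  vperm <- rep$data$values[, perm, ]
  sch <- rep$data$schema[perm, ]
  class(sch) <- c("item_schema", "data.frame")
  fitp <- fit_panelgvar(panel_data(vperm, rep$data$group, sch))
  expect_equal(fitp$between, fit$between[perm, perm], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fitp$temporal, fit$temporal[perm, perm], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fitp$contemporaneous, fit$contemporaneous[perm, perm],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(abs(fit$between) <= 1) &&
                all(abs(fit$contemporaneous) <= 1))
  expect_equal(diag(fit$between), setNames(rep(0, 6), tr$item_ids))
})
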