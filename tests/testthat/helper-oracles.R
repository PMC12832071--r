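# Shared oracles and fixtures. Oracles are deliberately independent of the
# implementation paths they check: dense Nelder-Mead optimization for the
# penalized likelihoods, population moment algebra for the two-wave
# decomposition, and glmnet as an external lasso reference.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Nelder-Mead maximization with restarts from the incumbent; good to ~1e-8
# on the small (<= 10 parameter) problems used here.
nm_maximize <- function(fn, start, restarts = 25, maxit = 20000) {
  best <- list(par = start, value = fn(start))
  for (r in seq_len(restarts)) {
    fit <- optim(best$par, fn, method = "Nelder-Mead",
                 control = list(fnscale = -1, maxit = maxit,
                                reltol = 1e-14))
    if (fit$value > best$value + 1e-12) {
      best <- fit
    } else {
      best <- list(par = fit$par, value = max(fit$value, best$value))
      if (r > 3) break
    }
  }
  best
}

# Dense-optimizer oracle for the graphical lasso objective: optimize over
# the p(p+1)/2 free entries of a symmetric matrix, rejecting non-PD points.
oracle_glasso_objective <- function(S, lam, starts = NULL) {
  p <- nrow(S)
  ut <- upper.tri(S, diag = TRUE)
  to_K <- function(par) {
    K <- matrix(0, p, p)
    K[ut] <- par
    K <- K + t(K) - diag(diag(K), p)
    K
  }
  fn <- function(par) {
    v <- glasso_objective(to_K(par), S, lam)
    if (!is.finite(v)) -1e10 else v
  }
  starts <- starts %||% list(diag(1 / diag(S), p)[ut],
                             solve(S + diag(lam + 1e-3, p))[ut])
  best <- -Inf
  for (s in starts) best <- max(best, nm_maximize(fn, s)$value)
  best
}

# Planted sparse precision: identity with K[i,j] = -r so the partial
# correlation of the pair is exactly r.
planted_precision <- function(p, edges) {
  K <- diag(p)
  for (e in edges) {
    K[e[[1]], e[[2]]] <- K[e[[2]], e[[1]]] <- -e[[3]]
  }
  ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  stopifnot(ev > 0)
  K
}

# Population two-wave reduction of a ground truth: the covariance of the
# half-differences d = (y2 - y1)/2 and the functionals the panelgvar
# estimator targets (own-lag excluded temporal regression, sign-flipped;
# partial correlations of d).
pop_twowave <- function(truth) {
  BmI <- truth$B - diag(truth$p)
  C <- (BmI %*% truth$V %*% t(BmI) + solve(truth$K_w)) / 4
  p <- truth$p
  temporal <- matrix(0, p, p)
  for (j in seq_len(p)) {
    temporal[seq_len(p)[-j], j] <-
      -solve(C[-j, -j, drop = FALSE], C[-j, j])
  }
  contemporaneous <- precision_to_pcor(solve(C))
  list(C = C, temporal = temporal, contemporaneous = contemporaneous)
}

# Independence ground truth (no edges anywhere) on p generic items.
independence_truth <- function(p) {
  ground_truth(B = matrix(0, p, p), K_w = diag(p), Sigma_B = diag(p))
}

# Fast GGM settings for simulation-heavy tests.
fast_ggm <- function(d, ...) estimate_ggm(d, n_lambda = 20, ...)

# Continuous (latent-scale) data matrices avoid discretization noise in
# estimator recovery tests.
latent_wave <- function(rep, wave) rep$latent[, , wave]
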