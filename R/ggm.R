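# Sparse Gaussian graphical models: graphical lasso, EBIC path selection,
# partial-correlation weights and node centrality.

#' Graphical lasso at a single penalty
#'
#' Maximizes the penalized Gaussian log-likelihood
#' \deqn{\log\det K - tr(SK) - \lambda \sum_{i \ne j} |K_{ij}|}
#' over positive-definite precision matrices `K` by block coordinate descent
#' (the diagonal is unpenalized). Small entries are set exactly to zero.
#'
#' @param S symmetric covariance/correlation matrix with positive diagonal.
#' @param lam penalty (>= 0).
#' @param tol convergence tolerance on the maximum parameter change.
#' @param max_iter sweep cap; non-convergence is an error.
#' @return list with `K` (precision), `W` (estimated covariance), `iter`.
#' @export
glasso_fit <- function(S, lam, tol = 1e-5, max_iter = 1000) {
  S <- as.matrix(S)
  if (!is_square_symmetric(S, tol = 1e-6)) stop("S must be symmetric")
  if (any(diag(S) <= 0)) stop("S needs a positive diagonal")
  if (lam < 0) stop("lam must be >= 0")
  fit <- cpp_glasso((S + t(S)) / 2, lam, tol, max_iter)
  if (!fit$converged) {
    stop("graphical lasso did not converge in ", max_iter,
         " sweeps (last sweep ", fit$iter, "); increase max_iter or tol",
         call. = FALSE)
  }
  dimnames(fit$K) <- dimnames(S)
  list(K = fit$K, W = fit$W, iter = fit$iter)
}

#' Penalized log-likelihood of a precision matrix
#' @param K precision matrix.
#' @param S covariance matrix.
#' @param lam off-diagonal l1 penalty.
#' @return scalar objective value (`-Inf` when `K` is not positive definite).
#' @export
glasso_objective <- function(K, S, lam) {
  cpp_glasso_objective(as.matrix(K), as.matrix(S), lam)
}

#' Convert a precision matrix to partial correlations
#'
#' `w_ij = -K_ij / sqrt(K_ii K_jj)` off the diagonal; the diagonal is zero.
#'
#' @param K symmetric matrix with positive diagonal.
#' @return partial-correlation matrix with zero diagonal.
#' @export
precision_to_pcor <- function(K) {
  K <- as.matrix(K)
  if (any(diag(K) <= 0)) stop("precision matrix needs a positive diagonal")
  d <- 1 / sqrt(diag(K))
  W <- -K * outer(d, d)
  diag(W) <- 0
  W
}

#' Extended Bayesian information criterion for a fitted GGM
#'
#' `EBIC = -n (log det K - tr(SK)) + E log n + 4 E gamma log p`, with `E`
#' the number of nonzero upper-triangle off-diagonal entries of `K`.
#' `gamma = 0` reduces to the BIC.
#'
#' @param K fitted precision matrix.
#' @param S sample covariance.
#' @param n sample size.
#' @param gamma sparsity hyperparameter (>= 0).
#' @return scalar EBIC (lower is better).
#' @export
ebic_score <- function(K, S, n, gamma = 0.5) {
  K <- as.matrix(K); S <- as.matrix(S)
  E <- sum(K[upper.tri(K)] != 0)
  p <- nrow(K)
  fit <- determinant(K, logarithm = TRUE)
  if (fit$sign <= 0) stop("K must be positive definite")
  ll <- as.numeric(fit$modulus) - sum(S * K)
  -n * ll + E * log(n) + 4 * E * gamma * log(p)
}

#' Estimate a Gaussian graphical model with EBIC-selected glasso
#'
#' Standardizes the items, fits a warm-started graphical-lasso path of
#' `n_lambda` log-spaced penalties from `lambda_max` (the largest absolute
#' off-diagonal correlation, giving an empty graph) down to
#' `lambda_min_ratio * lambda_max`, and returns the partial-correlation
#' network minimizing the EBIC.
#'
#' @param data numeric matrix (subjects x items), complete cases; or a
#'   [panel_data] plus `wave` to select one wave.
#' @param gamma EBIC hyperparameter (default 0.5, the conventional choice).
#' @param n_lambda path length (default 100).
#' @param lambda_min_ratio smallest/largest penalty ratio (default 0.01).
#' @param wave wave selector when `data` is a `panel_data`.
#' @param tol,max_iter solver controls.
#' @return An object of class `ggm_network`: `weights` (partial
#'   correlations), `K`, `lambda_selected`, `ebic_gamma`, `n_obs`,
#'   `node_labels` and the per-lambda `path` table.
#' @export
estimate_ggm <- function(data, gamma = 0.5, n_lambda = 100,
                         lambda_min_ratio = 0.01, wave = NULL,
                         tol = 1e-5, max_iter = 1000) {
  if (inherits(data, "panel_data")) {
    if (is.null(wave)) stop("supply `wave` when passing a panel_data")
    data <- wave_matrix(data, wave)
  }
  X <- as.matrix(data)
  X <- X[complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  if (n <= 3) stop("need more than 3 complete observations")
  Xs <- standardize_cols(X)
  S <- crossprod(Xs) / (n - 1)
  p <- ncol(S)
  lam_max <- max(abs(S[upper.tri(S)]))
  if (lam_max < 1e-12) lam_max <- 1e-12
  lambdas <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                     length.out = n_lambda))
  fit <- cpp_ggm_path(S, n, lambdas, gamma, tol, max_iter)
  if (!fit$converged) {
    stop("graphical lasso path did not fully converge; increase max_iter")
  }
  K <- fit$K
  labels <- colnames(X) %||% paste0("V", seq_len(p))
  dimnames(K) <- list(labels, labels)
  W <- precision_to_pcor(K)
  structure(list(weights = W, K = K,
                 lambda_selected = lambdas[fit$lambda_index],
                 ebic_gamma = gamma, n_obs = n, node_labels = labels,
                 path = data.frame(lambda = lambdas,
                                   edges = as.integer(fit$edges),
                                   ebic = as.numeric(fit$ebic))),
            class = "ggm_network")
}

#' @export
print.ggm_network <- function(x, ...) {
  cat("<ggm_network> p =", length(x$node_labels),
      " edges =", sum(x$weights[upper.tri(x$weights)] != 0),
      " lambda =", signif(x$lambda_selected, 3),
      " (gamma =", x$ebic_gamma, ", n =", x$n_obs, ")\n")
  invisible(x)
}

# Weight-matrix accessor shared by the bootstrap/comparison machinery.

#' Extract the edge-weight matrix of a fitted network
#' @param net a network object (or a bare matrix, returned as-is).
#' @return numeric weight matrix.
#' @export
edge_weights <- function(net) UseMethod("edge_weights")

#' @export
edge_weights.ggm_network <- function(net) net$weights

#' @export
edge_weights.clpn_network <- function(net) net$beta

#' @export
edge_weights.matrix <- function(net) net

#' @export
edge_weights.default <- function(net) {
  stop("no edge_weights method for class ", paste(class(net), collapse = "/"))
}

#' Node centrality of an undirected network
#'
#' Strength is the sum of absolute edge weights incident to a node;
#' expected influence (EI) is the signed sum. Standardized columns are
#' z-scores across nodes; when a centrality is constant across nodes the
#' z-scores are returned as zero and flagged via `attr(, "degenerate")`.
#'
#' @param net a `ggm_network` or weight matrix.
#' @return data.frame (class `centrality_table`) with columns `node`,
#'   `strength`, `expected_influence`, `z_strength`, `z_expected_influence`.
#' @export
centrality <- function(net) {
  W <- edge_weights(net)
  labels <- colnames(W) %||% paste0("V", seq_len(ncol(W)))
  strength <- rowSums(abs(W))
  ei <- rowSums(W)
  zs <- zscore_safe(strength)
  zei <- zscore_safe(ei)
  out <- data.frame(node = labels, strength = strength,
                    expected_influence = ei,
                    z_strength = as.numeric(zs),
                    z_expected_influence = as.numeric(zei),
                    row.names = NULL)
  attr(out, "degenerate") <- attr(zs, "degenerate") || attr(zei, "degenerate")
  class(out) <- c("centrality_table", "data.frame")
  out
}
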