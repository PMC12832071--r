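# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seed from a master seed and a stage tag.
# Kept below 2^31 so it is always a valid R integer seed.
#' @noRd
derive_seed <- function(master, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(master) * 48271 + h * 16807) %% 2147483587L + 1)
}

# z-standardize columns; refuses constant columns (names reported).
#' @noRd
standardize_cols <- function(X, label = "item") {
  X <- as.matrix(X)
  sds <- apply(X, 2, sd)
  bad <- which(!is.finite(sds) | sds == 0)
  if (length(bad)) {
    stop("constant ", label, "(s) with zero variance: ",
         paste(colnames(X)[bad] %||% bad, collapse = ", "), call. = FALSE)
  }
  scale(X)[, , drop = FALSE]
}

# z-scores across a vector; returns zeros plus a degenerate flag when the
# scale collapses (all values equal).
#' @noRd
zscore_safe <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    structure(rep(0, length(x)), degenerate = TRUE)
  } else {
    structure((x - mean(x)) / s, degenerate = FALSE)
  }
}

#' @noRd
is_square_symmetric <- function(M, tol = 1e-8) {
  is.matrix(M) && nrow(M) == ncol(M) && max(abs(M - t(M))) <= tol
}

# Draw from N(mu, Sigma) by Cholesky with a tiny jitter fallback for
# positive semi-definite Sigma.
#' @noRd
rmvnorm_chol <- function(n, mu, Sigma) {
  p <- length(mu)
  ch <- tryCatch(chol(Sigma), error = function(e) {
    ev <- eigen(Sigma, symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    chol(ev$vectors %*% diag(lam + 1e-10, p) %*% t(ev$vectors))
  })
  Z <- matrix(rnorm(n * p), n, p)
  sweep(Z %*% ch, 2, mu, "+")
}

# Solve the discrete Lyapunov equation V = B V B' + Q via vectorization.
#' @noRd
solve_lyapunov <- function(B, Q) {
  p <- nrow(B)
  if (max(abs(eigen(B, only.values = TRUE)$values)) >= 1) {
    stop("temporal matrix is not stationary (spectral radius >= 1)",
         call. = FALSE)
  }
  v <- solve(diag(p * p) - kronecker(B, B), as.vector(Q))
  V <- matrix(v, p, p)
  (V + t(V)) / 2
}

# Upper-triangle edge index pairs for a p-node undirected network.
#' @noRd
upper_pairs <- function(p) {
  which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
}
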