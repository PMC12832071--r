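# Cross-lagged panel network: penalized node-wise regressions of each
# wave-2 item on all wave-1 items. Autoregressive (self-lag) coefficients
# are estimated alongside the cross-lagged ones but reported separately and
# zeroed on the network diagonal, so the display and the centralities
# foreground between-symptom prediction.

#' Lasso regression by coordinate descent
#'
#' Minimizes `(1/2n) ||y - X b||^2 + lam ||b||_1`. Inputs are used as given;
#' standardize beforehand when standardized coefficients are wanted.
#'
#' @param y outcome vector.
#' @param X predictor matrix.
#' @param lam penalty (>= 0).
#' @param tol,max_iter solver controls.
#' @return coefficient vector.
#' @export
lasso_regress <- function(y, X, lam, tol = 1e-8, max_iter = 10000) {
  X <- as.matrix(X)
  fit <- cpp_lasso_cd(X, as.numeric(y), lam, tol, max_iter,
                      numeric(ncol(X)))
  if (!fit$converged) {
    stop("lasso did not converge after ", fit$iter, " sweeps", call. = FALSE)
  }
  setNames(as.numeric(fit$beta), colnames(X))
}

# Log-spaced penalty path for a standardized regression problem.
#' @noRd
lasso_lambda_path <- function(X, y, n_lambda, lambda_min_ratio) {
  lam_max <- max(abs(crossprod(X, y)) / nrow(X))
  if (lam_max < 1e-12) lam_max <- 1e-12
  exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
          length.out = n_lambda))
}

#' Fit a cross-lagged panel network
#'
#' For each item `j`, the standardized wave-2 score is lasso-regressed on
#' all standardized wave-1 scores (self-lag included, so cross-lagged
#' effects are adjusted for autoregression). The per-node penalty is chosen
#' either by EBIC over the path (default; cross-validation minimizing mean
#' squared error systematically over-selects in sparse null settings) or by
#' k-fold cross-validation (deterministic folds under `seed`, minimizing
#' mean squared prediction error, ties broken toward the larger penalty).
#' The fitted self-lag coefficient is moved to `auto` and the network
#' diagonal set to zero.
#'
#' @param data a two-wave [panel_data]; only complete cases are used.
#' @param selection `"ebic"` (default) or `"cv"`.
#' @param n_folds folds for cross-validation (default 10).
#' @param seed integer seed fixing the fold assignment.
#' @param gamma EBIC hyperparameter when `selection = "ebic"`.
#' @param n_lambda,lambda_min_ratio penalty-path controls.
#' @return An object of class `clpn_network`: `beta` (directed p x p,
#'   `beta[i, j]` = effect of item i at wave 1 on item j at wave 2, zero
#'   diagonal), `auto` (self-lag coefficients), `lambda_selected`,
#'   `selection`, `n_obs`, `node_labels`.
#' @export
fit_clpn <- function(data, selection = c("ebic", "cv"), n_folds = 10,
                     seed = 1, gamma = 0.5, n_lambda = 50,
                     lambda_min_ratio = 0.01) {
  selection <- match.arg(selection)
  stopifnot(inherits(data, "panel_data"))
  if (length(data$wave_labels) != 2) stop("CLPN needs exactly two waves")
  X1 <- wave_matrix(data, 1)
  X2 <- wave_matrix(data, 2)
  keep <- complete.cases(X1) & complete.cases(X2)
  X1 <- X1[keep, , drop = FALSE]
  X2 <- X2[keep, , drop = FALSE]
  n <- nrow(X1)
  p <- ncol(X1)
  if (n < 2 * n_folds) stop("too few complete cases for ", n_folds, " folds")
  # wave-specific standardization so betas are comparable across nodes
  X1s <- standardize_cols(X1)
  X2s <- standardize_cols(X2)
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  beta <- matrix(0, p, p, dimnames = list(colnames(X1), colnames(X1)))
  auto <- numeric(p)
  lambda_sel <- numeric(p)
  for (j in seq_len(p)) {
    y <- X2s[, j]
    lambdas <- lasso_lambda_path(X1s, y, n_lambda, lambda_min_ratio)
    if (selection == "cv") {
      cv_err <- matrix(NA_real_, n_folds, length(lambdas))
      for (f in seq_len(n_folds)) {
        tr <- folds != f
        fit <- cpp_lasso_path(X1s[tr, , drop = FALSE], y[tr], lambdas,
                              1e-7, 10000)
        pred <- X1s[!tr, , drop = FALSE] %*% fit$beta
        cv_err[f, ] <- colMeans((y[!tr] - pred)^2)
      }
      mse <- colMeans(cv_err)
      k_best <- which(mse <= min(mse) + 1e-12)[1]  # ties -> larger penalty
    } else {
      fit_all <- cpp_lasso_path(X1s, y, lambdas, 1e-7, 10000)
      rss <- colSums((y - X1s %*% fit_all$beta)^2)
      df <- colSums(fit_all$beta != 0)
      ebic <- n * log(rss / n) + df * log(n) + 2 * gamma * df * log(p)
      k_best <- which.min(ebic)
    }
    b <- lasso_regress(y, X1s, lambdas[k_best], tol = 1e-8)
    auto[j] <- b[j]
    b[j] <- 0
    beta[, j] <- b
    lambda_sel[j] <- lambdas[k_best]
  }
  names(auto) <- colnames(X1)
  structure(list(beta = beta, auto = auto, lambda_selected = lambda_sel,
                 selection = selection, n_obs = n,
                 node_labels = colnames(X1)),
            class = "clpn_network")
}

#' @export
print.clpn_network <- function(x, ...) {
  cat("<clpn_network> p =", length(x$node_labels),
      " cross-lagged edges =", sum(x$beta != 0),
      " selection =", x$selection, " (n =", x$n_obs, ")\n")
  invisible(x)
}

#' In/out expected influence of a directed network
#'
#' OEI (out-expected influence) of node i is the signed sum of its outgoing
#' cross-lagged weights (row sums); IEI (in-expected influence) is the
#' signed sum of incoming weights (column sums). The two columns always
#' share the same grand total. z-scores are computed across nodes, with a
#' degenerate-scale flag when a column is constant.
#'
#' @param net a `clpn_network` or directed weight matrix (diagonal ignored).
#' @return data.frame with columns `node`, `oei`, `iei`, `z_oei`, `z_iei`.
#' @export
directed_centrality <- function(net) {
  B <- edge_weights(net)
  diag(B) <- 0
  labels <- colnames(B) %||% paste0("V", seq_len(ncol(B)))
  oei <- rowSums(B)
  iei <- colSums(B)
  zo <- zscore_safe(oei)
  zi <- zscore_safe(iei)
  out <- data.frame(node = labels, oei = oei, iei = iei,
                    z_oei = as.numeric(zo), z_iei = as.numeric(zi),
                    row.names = NULL)
  attr(out, "degenerate") <- attr(zo, "degenerate") || attr(zi, "degenerate")
  class(out) <- c("centrality_table", "data.frame")
  out
}
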