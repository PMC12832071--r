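# Between/within decomposition for two-wave panels, in the spirit of panel
# graphical vector autoregression, using a non-regularized moment-based
# estimate-then-prune procedure: estimate partial associations at each
# level, then set non-significant entries to zero.
#
# Two-wave caveat (documented, and reflected in the tests): with exactly two
# waves, within-person deviations at the waves are exact negatives of each
# other (d and -d with d = (y2 - y1)/2). The own-item lag is therefore a
# perfect predictor and is excluded from the temporal regressions; the
# "temporal" network estimates the sign-flipped deviation regression, i.e.
# a functional of cov(d), not the generating lag matrix itself. Recovery
# tests compare against the same functional evaluated on the known truth.

#' Split panel data into person means and within-person deviations
#'
#' @param data a two-wave [panel_data]. Subjects with any missing cell are
#'   excluded (impute first to keep them).
#' @return list with `means` (subjects x items), `deviations`
#'   (subjects x items x waves, summing to zero within subject/item) and
#'   `n_excluded`.
#' @export
between_within_split <- function(data) {
  stopifnot(inherits(data, "panel_data"))
  if (length(data$wave_labels) != 2) stop("exactly two waves required")
  X1 <- wave_matrix(data, 1)
  X2 <- wave_matrix(data, 2)
  keep <- complete.cases(X1) & complete.cases(X2)
  n_excluded <- sum(!keep)
  X1 <- X1[keep, , drop = FALSE]
  X2 <- X2[keep, , drop = FALSE]
  means <- (X1 + X2) / 2
  dev <- array(0, c(nrow(X1), ncol(X1), 2),
               dimnames = list(NULL, colnames(X1), data$wave_labels))
  dev[, , 1] <- X1 - means
  dev[, , 2] <- X2 - means
  list(means = means, deviations = dev, n_excluded = n_excluded)
}

# Fisher-z pruning of a partial-correlation matrix with effective sample
# size n - p - 1 (p - 2 controlled variables plus the usual 3).
#' @noRd
prune_pcor <- function(W, n, alpha) {
  p <- ncol(W)
  n_eff <- n - p - 1
  if (n_eff <= 0) stop("too few subjects for Fisher-z pruning")
  z <- atanh(pmin(pmax(W, -0.9999), 0.9999)) * sqrt(n_eff)
  pval <- 2 * pnorm(-abs(z))
  W[pval >= alpha] <- 0
  diag(W) <- 0
  W
}

# Eigenvalue flooring so a moment-corrected covariance stays invertible.
#' @noRd
make_pd <- function(S, floor_frac = 1e-6) {
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
  floor_val <- floor_frac * max(ev$values, 1e-12)
  if (min(ev$values) >= floor_val) return(S)
  lam <- pmax(ev$values, floor_val)
  out <- ev$vectors %*% diag(lam, nrow(S)) %*% t(ev$vectors)
  dimnames(out) <- dimnames(S)
  out
}

#' Between-person network from person means
#'
#' Partial correlations from the inverse correlation matrix of stable
#' person means, with each entry tested by the Fisher z-transform at level
#' `alpha` (effective n = n - p - 1) and non-significant entries set to
#' zero. Person means of a two-wave panel still contain half the
#' within-person variance; pass `within_correction` (the covariance of the
#' within-person half-differences) to subtract it and target the
#' between-person covariance unbiasedly.
#'
#' @param means subjects x items matrix of person means.
#' @param alpha pruning significance level (default 0.01).
#' @param within_correction optional p x p matrix subtracted from
#'   `cov(means)` before inversion.
#' @param ridge optional ridge added to the correlation diagonal when the
#'   matrix is numerically singular.
#' @return symmetric pruned partial-correlation matrix (zero diagonal).
#' @export
estimate_between <- function(means, alpha = 0.01, within_correction = NULL,
                             ridge = 0) {
  means <- as.matrix(means)
  n <- nrow(means)
  p <- ncol(means)
  if (n <= p + 2) stop("need n > p + 2 subjects")
  S <- cov(means)
  if (!is.null(within_correction)) S <- S - within_correction
  S <- make_pd(S)
  R <- stats::cov2cor(S)
  if (ridge > 0) R <- R + diag(ridge, p)
  K <- tryCatch(solve(R), error = function(e)
    stop("singular correlation matrix; use more subjects or a ridge ",
         "fallback (`ridge` argument)", call. = FALSE))
  W <- precision_to_pcor(K)
  prune_pcor(W, n, alpha)
}

#' Temporal and contemporaneous networks from within-person deviations
#'
#' Temporal network: for each item `j`, the wave-2 deviation is regressed
#' by least squares on the wave-1 deviations of all *other* items (the
#' own-item lag is excluded: with two waves it is a perfect predictor; the
#' diagonal is structurally zero). Coefficients with t-test p-values above
#' `alpha` are pruned. Contemporaneous network: partial correlations among
#' the deviations (equivalently, correlations of the residuals after
#' regressing each pair on all remaining items), Fisher-z pruned.
#'
#' @param deviations subjects x items x 2 array from
#'   [between_within_split()].
#' @param alpha pruning level (default 0.01).
#' @return list with `temporal` (directed, `[i, j]` = effect of item i at
#'   wave 1 on item j at wave 2) and `contemporaneous` (symmetric).
#' @export
estimate_temporal_contemporaneous <- function(deviations, alpha = 0.01) {
  d <- deviations[, , 2, drop = TRUE]  # wave-2 deviations; wave 1 is -d
  if (is.null(dim(d))) d <- matrix(d, ncol = 1)
  n <- nrow(d)
  p <- ncol(d)
  labels <- colnames(d) %||% paste0("V", seq_len(p))
  temporal <- matrix(0, p, p, dimnames = list(labels, labels))
  if (p >= 2) {
    for (j in seq_len(p)) {
      Xj <- d[, -j, drop = FALSE]
      colnames(Xj) <- paste0("x", seq_len(ncol(Xj)))
      fit <- lm(y ~ ., data = data.frame(y = d[, j], Xj))
      sm <- summary(fit)$coefficients
      coefs <- numeric(p - 1)
      for (k in seq_len(p - 1)) {
        rn <- paste0("x", k)
        if (rn %in% rownames(sm) && is.finite(sm[rn, 4]) &&
            sm[rn, 4] < alpha) {
          # regressing on wave-1 deviations (-d) flips coefficient signs
          coefs[k] <- -sm[rn, 1]
        }
      }
      temporal[seq_len(p)[-j], j] <- coefs
    }
    R <- cor(d)
    K <- solve(R)
    contemporaneous <- prune_pcor(precision_to_pcor(K), n, alpha)
    dimnames(contemporaneous) <- list(labels, labels)
  } else {
    contemporaneous <- matrix(0, 1, 1, dimnames = list(labels, labels))
  }
  list(temporal = temporal, contemporaneous = contemporaneous)
}

#' Fit the full between/temporal/contemporaneous decomposition
#'
#' Runs [between_within_split()], [estimate_between()] (with the two-wave
#' within-noise correction on by default) and
#' [estimate_temporal_contemporaneous()].
#'
#' @param data a two-wave [panel_data] (complete cases used).
#' @param alpha pruning level for all three networks (default 0.01).
#' @param between_correction subtract the within-deviation covariance from
#'   the person-mean covariance before inversion (default TRUE).
#' @param ridge see [estimate_between()].
#' @return object of class `panelgvar_result` with elements `between`,
#'   `temporal`, `contemporaneous`, `pruning_alpha`, `n_obs`, `n_excluded`.
#' @export
fit_panelgvar <- function(data, alpha = 0.01, between_correction = TRUE,
                          ridge = 0) {
  sp <- between_within_split(data)
  corr <- if (between_correction) cov(sp$deviations[, , 2]) else NULL
  between <- estimate_between(sp$means, alpha, within_correction = corr,
                              ridge = ridge)
  tc <- estimate_temporal_contemporaneous(sp$deviations, alpha)
  structure(list(between = between, temporal = tc$temporal,
                 contemporaneous = tc$contemporaneous,
                 pruning_alpha = alpha, n_obs = nrow(sp$means),
                 n_excluded = sp$n_excluded),
            class = "panelgvar_result")
}

#' @export
print.panelgvar_result <- function(x, ...) {
  cnt <- function(M) sum(M[upper.tri(M)] != 0)
  cat("<panelgvar_result> n =", x$n_obs,
      "(", x$n_excluded, "excluded )\n")
  cat("  between edges:", cnt(x$between),
      " temporal edges:", sum(x$temporal != 0),
      " contemporaneous edges:", cnt(x$contemporaneous),
      " (alpha =", x$pruning_alpha, ")\n")
  invisible(x)
}
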