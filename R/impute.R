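# Missing-data machinery: EM for the multivariate-normal model, Little's
# MCAR test, chained-equation imputation with predictive mean matching, and
# Rubin's-rules pooling.

# ML mean/covariance under multivariate normality with arbitrary missing
# patterns, by EM. Returns list(mu, Sigma, iterations, converged).
#' @noRd
em_norm <- function(X, max_iter = 200, tol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  miss <- is.na(X)
  pattern <- apply(miss, 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pattern)
  mu <- colMeans(X, na.rm = TRUE)
  Sigma <- diag(apply(X, 2, var, na.rm = TRUE), p)
  it <- 0; converged <- FALSE
  for (it in seq_len(max_iter)) {
    sum_x <- numeric(p)
    sum_xx <- matrix(0, p, p)
    for (rows in groups) {
      o <- !miss[rows[1], ]
      m <- !o
      Xo <- X[rows, o, drop = FALSE]
      if (!any(m)) {
        sum_x <- sum_x + colSums(X[rows, , drop = FALSE])
        sum_xx <- sum_xx + crossprod(X[rows, , drop = FALSE])
        next
      }
      if (!any(o)) {
        xm <- matrix(mu[m], length(rows), sum(m), byrow = TRUE)
        Cm <- Sigma[m, m, drop = FALSE]
      } else {
        Soo_inv <- solve(Sigma[o, o, drop = FALSE])
        A <- Sigma[m, o, drop = FALSE] %*% Soo_inv
        resid <- sweep(Xo, 2, mu[o])
        xm <- sweep(resid %*% t(A), 2, mu[m], "+")
        Cm <- Sigma[m, m, drop = FALSE] - A %*% Sigma[o, m, drop = FALSE]
      }
      Xfill <- X[rows, , drop = FALSE]
      Xfill[, m] <- xm
      sum_x <- sum_x + colSums(Xfill)
      cp <- crossprod(Xfill)
      cp[m, m] <- cp[m, m] + length(rows) * Cm
      sum_xx <- sum_xx + cp
    }
    mu_new <- sum_x / n
    Sigma_new <- sum_xx / n - tcrossprod(mu_new)
    Sigma_new <- (Sigma_new + t(Sigma_new)) / 2
    delta <- max(abs(mu_new - mu), abs(Sigma_new - Sigma))
    mu <- mu_new; Sigma <- Sigma_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(mu = mu, Sigma = Sigma, iterations = it, converged = converged)
}

#' Little's MCAR test
#'
#' Chi-square test of the missing-completely-at-random hypothesis: with ML
#' mean/covariance estimated by EM, the statistic sums, over missingness
#' patterns, the Mahalanobis distance of each pattern's observed-variable
#' mean from the grand mean,
#' `d^2 = sum_j n_j (ybar_j - mu_oj)' Sigma_oj^{-1} (ybar_j - mu_oj)`, with
#' `df = sum_j p_j - p`. A large statistic indicates missingness that
#' depends on the data.
#'
#' @param data subjects x variables numeric matrix with `NA` for missing.
#' @param min_pattern_n patterns with fewer rows are dropped from the
#'   statistic (logged in the result); default 1 keeps everything.
#' @return list with `statistic`, `df`, `p.value`, `n_patterns`,
#'   `patterns_dropped`, `missing_rate`. With no missing cells, a
#'   "no missingness" result with `p.value = NA`.
#' @export
little_mcar <- function(data, min_pattern_n = 1) {
  X <- as.matrix(data)
  n <- nrow(X); p <- ncol(X)
  miss <- is.na(X)
  if (!any(miss)) {
    return(list(statistic = 0, df = NA_integer_, p.value = NA_real_,
                n_patterns = 1L, patterns_dropped = 0L, missing_rate = 0,
                note = "no missingness; MCAR test undefined"))
  }
  pattern <- apply(miss, 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pattern)
  fit <- em_norm(X)
  d2 <- 0
  df <- 0L
  dropped <- 0L
  used <- 0L
  for (rows in groups) {
    o <- !miss[rows[1], ]
    if (!any(o)) next
    if (length(rows) < min_pattern_n) { dropped <- dropped + 1L; next }
    ybar <- colMeans(X[rows, o, drop = FALSE])
    dev <- ybar - fit$mu[o]
    d2 <- d2 + length(rows) *
      drop(crossprod(dev, solve(fit$Sigma[o, o, drop = FALSE], dev)))
    df <- df + sum(o)
    used <- used + 1L
  }
  df <- df - p
  list(statistic = d2, df = df, p.value = pchisq(d2, df, lower.tail = FALSE),
       n_patterns = used, patterns_dropped = dropped,
       missing_rate = mean(miss))
}

# One chained-equations pass over the variables with missing cells.
#' @noRd
pmm_cycle <- function(Xc, miss, k_donors) {
  p <- ncol(Xc)
  for (j in seq_len(p)) {
    mj <- miss[, j]
    if (!any(mj)) next
    y <- Xc[!mj, j]
    distinct <- unique(y)
    Xo <- cbind(1, Xc[!mj, -j, drop = FALSE])
    Xm <- cbind(1, Xc[mj, -j, drop = FALSE])
    if (length(distinct) <= 2) {
      # binary variable: logistic regression draw
      lev <- sort(distinct)
      yy <- as.integer(y == lev[length(lev)])
      fit <- suppressWarnings(
        stats::glm.fit(Xo, yy, family = stats::binomial()))
      eta <- drop(Xm %*% ifelse(is.na(fit$coefficients), 0,
                                fit$coefficients))
      pr <- 1 / (1 + exp(-eta))
      Xc[mj, j] <- ifelse(runif(sum(mj)) < pr, lev[length(lev)], lev[1])
      next
    }
    XtX <- crossprod(Xo)
    ridge <- diag(1e-6 * mean(diag(XtX)), ncol(XtX))
    beta <- solve(XtX + ridge, crossprod(Xo, y))
    pred_obs <- drop(Xo %*% beta)
    pred_mis <- drop(Xm %*% beta)
    k <- min(k_donors, length(y))
    for (r in seq_along(pred_mis)) {
      donors <- order(abs(pred_obs - pred_mis[r]))[seq_len(k)]
      Xc[which(mj)[r], j] <- y[donors[sample.int(k, 1)]]
    }
  }
  Xc
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Generates `m` completed copies of the input. Missing cells are first
#' filled by random draws from each variable's observed marginal; the
#' variables are then visited cyclically, each regressed on all others over
#' its originally observed rows (ridge-stabilized when needed), and every
#' missing cell receives the observed value of one of the `k_donors`
#' nearest donors by predicted value (so imputed values are always values
#' actually observed for that variable). Binary variables are imputed by a
#' logistic-regression draw instead. Chains are independent given `seed`.
#'
#' @param data numeric matrix/data.frame with `NA`, or a [panel_data]
#'   (imputed on its wide item-by-wave layout).
#' @param m number of imputations (default 10).
#' @param iterations chained-equation cycles per imputation (default 10).
#' @param k_donors donor-pool size (default 5).
#' @param seed integer seed.
#' @return object of class `imputation_set`: `m`, `datasets` (list of
#'   completed objects of the same type as the input), `iterations`,
#'   `k_donors`, `seed`.
#' @export
mice_pmm <- function(data, m = 10, iterations = 10, k_donors = 5, seed = 1) {
  is_panel <- inherits(data, "panel_data")
  X <- if (is_panel) panel_wide(data) else as.matrix(data)
  n <- nrow(X); p <- ncol(X)
  miss <- is.na(X)
  n_obs_var <- colSums(!miss)
  if (any(n_obs_var == 0)) stop("variable(s) fully missing cannot be imputed")
  if (any(n_obs_var < 30)) {
    stop("every variable needs at least 30 observed values")
  }
  datasets <- vector("list", m)
  for (chain in seq_len(m)) {
    withr::with_seed(derive_seed(seed, paste0("chain", chain)), {
      Xc <- X
      for (j in seq_len(p)) {
        mj <- miss[, j]
        if (any(mj)) Xc[mj, j] <- sample(X[!mj, j], sum(mj), replace = TRUE)
      }
      if (any(miss)) {
        for (it in seq_len(iterations)) Xc <- pmm_cycle(Xc, miss, k_donors)
      }
      datasets[[chain]] <- if (is_panel) {
        panel_from_wide(Xc, data)
      } else {
        Xc
      }
    })
  }
  structure(list(m = m, datasets = datasets, method = "pmm",
                 iterations = iterations, k_donors = k_donors, seed = seed),
            class = "imputation_set")
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Point estimate = mean of the per-imputation estimates; total variance =
#' mean within-imputation variance plus `(1 + 1/m)` times the
#' between-imputation variance; degrees of freedom
#' `(m - 1) (1 + within / ((1 + 1/m) between))^2` (infinite, flagged, when
#' the between-imputation variance is zero).
#'
#' @param estimates numeric vector of per-imputation estimates (m >= 2).
#' @param variances per-imputation variances of the estimate.
#' @return list with `point`, `within_var`, `between_var`, `total_var`,
#'   `df`, `m`.
#' @export
rubin_pool <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2) stop("need at least 2 imputations")
  if (length(variances) != m) stop("estimates and variances differ in length")
  point <- mean(estimates)
  within <- mean(variances)
  between <- var(estimates)
  total <- within + (1 + 1 / m) * between
  df <- if (between == 0) Inf else
    (m - 1) * (1 + within / ((1 + 1 / m) * between))^2
  list(point = point, within_var = within, between_var = between,
       total_var = total, df = df, m = m)
}

#' Pool network weight matrices across imputations
#'
#' Element-wise Rubin point estimate (mean) of per-imputation weight
#' matrices. With `rule = "majority"`, entries that are nonzero in at most
#' half of the imputations are set to zero after averaging.
#'
#' @param mats list of weight matrices of identical dimension.
#' @param rule `"mean"` (default) or `"majority"`.
#' @return pooled weight matrix.
#' @export
pool_edge_weights <- function(mats, rule = c("mean", "majority")) {
  rule <- match.arg(rule)
  pooled <- Reduce(`+`, mats) / length(mats)
  if (rule == "majority") {
    nz <- Reduce(`+`, lapply(mats, function(M) M != 0))
    pooled[nz <= length(mats) / 2] <- 0
  }
  pooled
}
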