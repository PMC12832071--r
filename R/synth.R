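# Synthetic two-wave Likert panel generator with known network ground truth.
#
# Generative model (per subject i, wave t):
#   person mean   m_i   ~ N(mu, Sigma_B)          (stable between-person part)
#   deviations    eta_1 ~ N(0, V),  eta_t = B eta_{t-1} + eps_t,
#                 eps_t ~ N(0, K_w^{-1}),  V = B V B' + K_w^{-1} (stationary)
#   latent score  y_it  = m_i + eta_it
#   observed      ordinal category of y_it among the item's thresholds.
# B carries the temporal network, K_w the within-person contemporaneous
# partial correlations, Sigma_B the between-person covariance.

#' Construct a ground truth from explicit matrices
#'
#' Low-level constructor used when a test or simulation needs a *planted*
#' structure (a specific cross-lagged path, contemporaneous partial
#' correlation, or between-person edge) rather than the random truth of
#' [make_ground_truth()]. Validates stationarity and positive definiteness
#' and builds equiprobable thresholds unless supplied.
#'
#' @param B p x p temporal coefficient matrix (spectral radius < 1);
#'   `B[i, j]` is the effect of item j's deviation at wave t-1 on item i's
#'   deviation at wave t (rows index the target, as usual for VAR matrices).
#' @param K_w p x p within-person precision (symmetric positive definite).
#' @param Sigma_B p x p between-person covariance (positive semi-definite).
#' @param mu latent grand means (default zero).
#' @param schema item schema; default: generic 5-point items.
#' @param thresholds optional list of strictly increasing cut-points.
#' @param seed seed recorded on the object.
#' @return `ground_truth` object.
#' @export
ground_truth <- function(B, K_w, Sigma_B, mu = NULL, schema = NULL,
                         thresholds = NULL, seed = NA_integer_) {
  p <- nrow(B)
  stopifnot(is_square_symmetric(K_w, 1e-8), is_square_symmetric(Sigma_B, 1e-8),
            ncol(B) == p, nrow(K_w) == p, nrow(Sigma_B) == p)
  if (max(abs(eigen(B, only.values = TRUE)$values)) >= 1) {
    stop("B must have spectral radius < 1")
  }
  if (min(eigen(K_w, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("K_w must be positive definite")
  }
  if (min(eigen(Sigma_B, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("Sigma_B must be positive semi-definite")
  }
  mu <- mu %||% rep(0, p)
  if (is.null(schema)) {
    schema <- data.frame(
      item_id = paste0("V", seq_len(p)), wording = "synthetic item",
      scale_min = 1L, scale_max = 5L, reverse_coded = FALSE,
      domain_label = "synthetic")
    class(schema) <- c("item_schema", "data.frame")
  }
  V <- solve_lyapunov(B, solve(K_w))
  if (is.null(thresholds)) {
    tot_sd <- sqrt(diag(Sigma_B) + diag(V))
    thresholds <- lapply(seq_len(p), function(j) {
      ncat <- schema$scale_max[j] - schema$scale_min[j] + 1
      qnorm(seq_len(ncat - 1) / ncat, mean = mu[j], sd = tot_sd[j])
    })
  }
  if (any(vapply(thresholds, function(th) is.unsorted(th, strictly = TRUE),
                 TRUE))) {
    stop("thresholds must be strictly increasing per item")
  }
  names(thresholds) <- schema$item_id
  structure(list(p = p, item_ids = schema$item_id, schema = schema,
                 B = B, K_w = K_w, Sigma_B = Sigma_B, mu = mu, V = V,
                 thresholds = thresholds, seed = seed),
            class = "ground_truth")
}

#' Build a random network ground truth for the simulator
#'
#' Draws a sparse temporal matrix `B` (stationary: spectral radius < 1), a
#' sparse positive-definite within-person precision `K_w`, and a
#' between-person covariance `Sigma_B` with sparse partial-correlation
#' structure. With `edge_density = 0` every network is empty (full
#' independence truth). Thresholds default to equiprobable categories of
#' each item's marginal latent distribution.
#'
#' @param p_bps,p_kads number of procrastination (Likert 1--5) and
#'   depression (0--3) items; defaults mirror the 9 + 11 item instruments.
#' @param edge_density probability that any off-diagonal entry is nonzero.
#' @param effect_scale upper bound on temporal edge magnitudes (cross-lagged
#'   weights in field data rarely exceed ~0.4, the default).
#' @param seed integer seed; the truth is reproducible given the seed.
#' @return An object of class `ground_truth`.
#' @export
make_ground_truth <- function(p_bps = 9, p_kads = 11, edge_density = 0.1,
                              effect_scale = 0.4, seed = 1) {
  p <- p_bps + p_kads
  if (p < 3) stop("need at least 3 items")
  if (edge_density < 0 || edge_density > 1) stop("edge_density must be in [0,1]")
  if (effect_scale <= 0) stop("effect_scale must be positive")
  schema <- if (p_bps == 9 && p_kads == 11) {
    sch <- bps_kads_schema()
    sch$reverse_coded <- FALSE  # generator emits already-oriented items
    sch
  } else {
    sch <- data.frame(
      item_id = c(if (p_bps) paste0("BPS", seq_len(p_bps)),
                  if (p_kads) paste0("KADS", seq_len(p_kads))),
      wording = "synthetic item",
      scale_min = c(rep(1L, p_bps), rep(0L, p_kads)),
      scale_max = c(rep(5L, p_bps), rep(3L, p_kads)),
      reverse_coded = FALSE, domain_label = "synthetic")
    class(sch) <- c("item_schema", "data.frame")
    sch
  }
  withr::with_seed(seed, {
    sparse_entries <- function() {
      mask <- matrix(rbinom(p * p, 1, edge_density), p, p)
      mag <- matrix(runif(p * p, 0.5 * effect_scale, effect_scale), p, p)
      sgn <- matrix(sample(c(-1, 1), p * p, replace = TRUE), p, p)
      mask * mag * sgn
    }
    # temporal matrix: autoregressive diagonal + sparse cross-lagged entries
    B <- sparse_entries()
    diag(B) <- if (edge_density > 0) runif(p, 0.15, 0.35) else 0
    rho <- max(abs(eigen(B, only.values = TRUE)$values))
    if (rho >= 0.95) {
      fac <- 0.9 / rho
      if (fac < 0.25) {
        stop("edge_density/effect_scale combination cannot be made ",
             "stationary without destroying the requested magnitudes")
      }
      B <- B * fac
    }
    sparse_precision <- function(lo = 0.15, hi = 0.35) {
      A <- matrix(0, p, p)
      ut <- upper.tri(A)
      nz <- rbinom(sum(ut), 1, edge_density) == 1
      vals <- runif(sum(ut), lo, hi) * sample(c(-1, 1), sum(ut), TRUE) * nz
      A[ut] <- vals
      A <- A + t(A)
      K <- A
      diag(K) <- 1 + rowSums(abs(A))  # diagonal dominance => positive definite
      K
    }
    K_w <- sparse_precision()
    Sigma_B <- stats::cov2cor(solve(sparse_precision()))
    mu <- rep(0, p)
    V <- solve_lyapunov(B, solve(K_w))
    tot_sd <- sqrt(diag(Sigma_B) + diag(V))
    thresholds <- lapply(seq_len(p), function(j) {
      ncat <- schema$scale_max[j] - schema$scale_min[j] + 1
      qnorm(seq_len(ncat - 1) / ncat, mean = mu[j], sd = tot_sd[j])
    })
    names(thresholds) <- schema$item_id
    structure(list(p = p, item_ids = schema$item_id, schema = schema,
                   B = B, K_w = K_w, Sigma_B = Sigma_B, mu = mu,
                   V = V, thresholds = thresholds, seed = seed),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> p =", x$p, "\n")
  cat("  temporal edges:", sum(x$B[row(x$B) != col(x$B)] != 0),
      " contemporaneous edges:", sum(x$K_w[upper.tri(x$K_w)] != 0),
      " between edges:", sum(abs(solve(x$Sigma_B)[upper.tri(x$Sigma_B)]) > 1e-8),
      "\n")
  invisible(x)
}

# Map latent values to ordinal categories via the item thresholds.
#' @noRd
discretize_latent <- function(latent, truth) {
  obs <- latent
  for (j in seq_len(truth$p)) {
    cuts <- truth$thresholds[[j]]
    obs[, j, ] <- truth$schema$scale_min[j] +
      findInterval(latent[, j, ], cuts)
  }
  obs
}

#' Simulate a two-wave ordinal panel from a ground truth
#'
#' Draws person means from `Sigma_B`, a stationary lag-1 latent process from
#' `(B, K_w)`, and discretizes against the item thresholds. The latent array
#' is kept so estimator recovery can be tested on both scales.
#'
#' @param truth a [make_ground_truth()] object.
#' @param n number of subjects (>= 2).
#' @param waves number of waves (>= 2; analyses in the package use 2).
#' @param seed integer seed.
#' @param group single group label attached to the dataset.
#' @return A `sim_report`: list with `truth`, `latent`
#'   (subjects x items x waves) and `data` (a [panel_data]).
#' @export
simulate_panel <- function(truth, n, waves = 2, seed = 1, group = "all") {
  stopifnot(inherits(truth, "ground_truth"))
  if (waves < 2) stop("need at least 2 waves")
  if (n < 2) stop("need at least 2 subjects")
  p <- truth$p
  withr::with_seed(seed, {
    m <- rmvnorm_chol(n, truth$mu, truth$Sigma_B)
    Psi <- solve(truth$K_w)
    latent <- array(NA_real_, c(n, p, waves))
    eta <- rmvnorm_chol(n, rep(0, p), truth$V)
    latent[, , 1] <- m + eta
    for (t in 2:waves) {
      eta <- eta %*% t(truth$B) + rmvnorm_chol(n, rep(0, p), Psi)
      latent[, , t] <- m + eta
    }
    obs <- discretize_latent(latent, truth)
    labels <- if (waves == 2) c("T1", "T3") else paste0("W", seq_len(waves))
    data <- panel_data(obs, rep(group, n), truth$schema, wave_labels = labels)
    structure(list(truth = truth, latent = latent, data = data),
              class = "sim_report")
  })
}

#' Inject missing-completely-at-random cells
#'
#' Each observed cell is independently set missing with probability `rate`.
#'
#' @param data a [panel_data] object.
#' @param rate missingness probability in `[0, 0.5)`; field panel studies
#'   typically report under 10 percent.
#' @param seed integer seed.
#' @return The masked `panel_data`.
#' @export
inject_mcar <- function(data, rate, seed = 1) {
  if (rate < 0 || rate >= 0.5) stop("rate must be in [0, 0.5)")
  if (rate == 0) return(data)
  withr::with_seed(seed, {
    mask <- array(runif(length(data$values)) < rate, dim(data$values))
    out <- data
    out$values[mask & !is.na(out$values)] <- NA
    out
  })
}

#' Simulate a two-group study (shared or distinct truths)
#'
#' Convenience wrapper for group-comparison testing: group A and group B are
#' simulated from `truth_a` and `truth_b` (pass the same object to emulate
#' the comparison-test null) and concatenated into one stratified dataset.
#'
#' @param truth_a,truth_b ground truths for the two groups.
#' @param n_a,n_b group sizes; the default 1500 + 1500 emulates a cohort of
#'   about three thousand adolescents split by sex.
#' @param labels group labels.
#' @param mcar_rate optional MCAR missingness applied to the pooled data.
#' @param seed master seed; per-group seeds are derived deterministically.
#' @return list with `data` (pooled [panel_data]), `truth_a`, `truth_b`.
#' @export
simulate_study <- function(truth_a, truth_b = truth_a, n_a = 1500,
                           n_b = 1500, labels = c("male", "female"),
                           mcar_rate = 0, seed = 1) {
  rep_a <- simulate_panel(truth_a, n_a, seed = derive_seed(seed, "group_a"),
                          group = labels[1])
  rep_b <- simulate_panel(truth_b, n_b, seed = derive_seed(seed, "group_b"),
                          group = labels[2])
  vals <- array(NA_real_, c(n_a + n_b, truth_a$p, 2))
  vals[seq_len(n_a), , ] <- rep_a$data$values
  vals[n_a + seq_len(n_b), , ] <- rep_b$data$values
  data <- panel_data(vals, c(rep(labels[1], n_a), rep(labels[2], n_b)),
                     truth_a$schema)
  if (mcar_rate > 0) {
    data <- inject_mcar(data, mcar_rate, seed = derive_seed(seed, "mcar"))
  }
  list(data = data, truth_a = truth_a, truth_b = truth_b)
}
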