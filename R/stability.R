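# Bootstrap machinery: edge-weight confidence intervals, edge-difference
# tests, case-drop centrality stability and the CS coefficient.

# Subset observational units (rows of a matrix / subjects of a panel).
#' @noRd
subset_units <- function(data, idx) {
  if (inherits(data, "panel_data")) {
    panel_data(data$values[idx, , , drop = FALSE],
               as.character(data$group)[idx], data$schema,
               wave_labels = data$wave_labels,
               id = paste0("R", seq_along(idx)), validate_range = FALSE)
  } else {
    data[idx, , drop = FALSE]
  }
}

#' @noRd
n_units <- function(data) {
  if (inherits(data, "panel_data")) dim(data$values)[1] else nrow(data)
}

#' Nonparametric bootstrap of network edge weights
#'
#' Resamples subjects with replacement, re-estimates the network, and
#' stores the per-replicate weight matrices; 95% confidence intervals are
#' the 2.5/97.5 empirical percentiles. A replicate on which the estimator
#' fails is retried with a fresh resample; more than 5% failures aborts.
#'
#' @param data subjects x items matrix or [panel_data].
#' @param estimator function mapping `data` to a network object or weight
#'   matrix (e.g. `function(d) estimate_ggm(d)`).
#' @param n_boot number of replicates (>= 100; default 1000).
#' @param seed integer seed.
#' @param ci confidence level (default 0.95).
#' @return object of class `bootstrap_distribution`: `replicates`
#'   (n_boot x p x p array), `ci_lower`/`ci_upper` matrices, `observed`
#'   weights, `n_boot`, `n_retries`, `seed`.
#' @export
bootstrap_edges <- function(data, estimator, n_boot = 1000, seed = 1,
                            ci = 0.95) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  n <- n_units(data)
  observed <- edge_weights(estimator(data))
  p <- ncol(observed)
  reps <- array(NA_real_, c(n_boot, p, p))
  retries <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        W <- tryCatch(edge_weights(estimator(subset_units(data, idx))),
                      error = function(e) NULL)
        if (!is.null(W)) break
        retries <- retries + 1L
        if (retries > 0.05 * n_boot) {
          stop("estimator failed on more than 5% of bootstrap replicates",
               call. = FALSE)
        }
      }
      reps[b, , ] <- W
    }
  })
  a <- (1 - ci) / 2
  ci_lower <- apply(reps, c(2, 3), quantile, probs = a)
  ci_upper <- apply(reps, c(2, 3), quantile, probs = 1 - a)
  dimnames(ci_lower) <- dimnames(ci_upper) <- dimnames(observed)
  structure(list(replicates = reps, observed = observed,
                 ci_lower = ci_lower, ci_upper = ci_upper,
                 n_boot = n_boot, n_retries = retries, ci = ci,
                 seed = seed),
            class = "bootstrap_distribution")
}

#' Bootstrap edge-weight difference test
#'
#' Two edges are flagged as different when the 95% percentile interval of
#' their per-replicate weight difference excludes zero.
#'
#' @param boot a [bootstrap_edges()] result.
#' @param edge_a,edge_b length-2 integer (or node-label) vectors indexing
#'   the two edges.
#' @return list with `different` (logical), `ci_of_difference`,
#'   `observed_difference`.
#' @export
edge_difference_test <- function(boot, edge_a, edge_b) {
  stopifnot(inherits(boot, "bootstrap_distribution"))
  ix <- function(e) {
    if (is.character(e)) match(e, colnames(boot$observed)) else as.integer(e)
  }
  a <- ix(edge_a); b <- ix(edge_b)
  if (all(sort(a) == sort(b))) stop("edge compared with itself")
  diffs <- boot$replicates[, a[1], a[2]] - boot$replicates[, b[1], b[2]]
  alpha <- (1 - boot$ci) / 2
  ci <- unname(quantile(diffs, c(alpha, 1 - alpha)))
  list(different = ci[1] > 0 || ci[2] < 0, ci_of_difference = ci,
       observed_difference = boot$observed[a[1], a[2]] -
         boot$observed[b[1], b[2]])
}

#' Case-drop bootstrap and the correlation-stability (CS) coefficient
#'
#' For each drop proportion, repeatedly re-estimates the network on a
#' random subject subset and correlates the subsample node centralities
#' with the full-sample ones. The CS coefficient is the largest drop
#' proportion at which at least `prob` of the correlations stay at or above
#' `cor_threshold` (0 when none does); the field's guideline regards
#' CS >= 0.5 as adequate stability.
#'
#' @param data subjects x items matrix or [panel_data].
#' @param estimator network estimator, as in [bootstrap_edges()].
#' @param centrality_fn maps a network to a numeric vector of node
#'   centralities (default: strength via [centrality()]).
#' @param drop_props drop proportions (default 0.1..0.7 by 0.1).
#' @param n_boot replicates per proportion (default 250).
#' @param cor_threshold,prob CS convention: threshold 0.7 correlation with
#'   95% probability (defaults).
#' @param cor_method `"spearman"` (default, robust to scale) or `"pearson"`.
#' @param seed integer seed; streams are independent across proportions.
#' @return object of class `cs_profile`: `drop_props`, `cors`
#'   (proportion x replicate matrix), `cs_value`.
#' @export
casedrop_cs <- function(data, estimator,
                        centrality_fn = function(net) centrality(net)$strength,
                        drop_props = seq(0.1, 0.7, by = 0.1), n_boot = 250,
                        cor_threshold = 0.7, prob = 0.95,
                        cor_method = c("spearman", "pearson"), seed = 1) {
  cor_method <- match.arg(cor_method)
  if (any(drop_props <= 0 | drop_props > 0.75)) {
    stop("drop proportions must lie in (0, 0.75]")
  }
  drop_props <- sort(drop_props)
  n <- n_units(data)
  full <- centrality_fn(estimator(data))
  p <- length(full)
  if (floor(n * (1 - max(drop_props))) < p + 5) {
    stop("largest drop proportion leaves fewer than p + 5 subjects")
  }
  cors <- matrix(NA_real_, length(drop_props), n_boot,
                 dimnames = list(paste0("drop", drop_props), NULL))
  for (k in seq_along(drop_props)) {
    m <- floor(n * (1 - drop_props[k]))
    withr::with_seed(derive_seed(seed, paste0("drop", k)), {
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n, m)
        cent <- tryCatch(centrality_fn(estimator(subset_units(data, idx))),
                         error = function(e) rep(NA_real_, p))
        cors[k, b] <- suppressWarnings(
          cor(full, cent, method = cor_method, use = "complete.obs"))
      }
    })
  }
  # constant centralities make the correlation NA; count them as stable
  # only when the subsample reproduced the (constant) original exactly
  cors[is.na(cors)] <- if (sd(full) == 0) 1 else 0
  ok <- rowMeans(cors >= cor_threshold) >= prob
  cs_value <- if (any(ok)) max(drop_props[ok]) else 0
  structure(list(drop_props = drop_props, cors = cors, cs_value = cs_value,
                 cor_threshold = cor_threshold, prob = prob,
                 cor_method = cor_method, n_boot = n_boot, seed = seed),
            class = "cs_profile")
}

#' @export
print.cs_profile <- function(x, ...) {
  cat("<cs_profile> CS =", x$cs_value, "(threshold", x$cor_threshold,
      ", prob", x$prob, ")\n")
  invisible(x)
}
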