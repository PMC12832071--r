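# Orchestration of the full sex-stratified analysis: load -> reverse-code
# -> MCAR check -> impute -> per-group networks (cross-lagged,
# contemporaneous, between) with Rubin pooling -> centralities ->
# stability -> permutation group comparison.

#' Analysis configuration
#'
#' Collects every tunable of [run_study()] in one serializable object. All
#' randomness downstream is derived deterministically from `seed`.
#'
#' @param input optional path to a wide-format panel file (see
#'   [load_panel()]); omit when passing data directly to [run_study()].
#' @param group_col,wave_labels file layout, as in [load_panel()].
#' @param reverse_items item ids to reverse-code; `NULL` uses the schema's
#'   flags, `character(0)` disables recoding.
#' @param gamma EBIC hyperparameter for GGM estimation.
#' @param alpha pruning level for the between/within decomposition.
#' @param selection CLPN penalty selection, `"ebic"` (default) or `"cv"`.
#' @param n_folds CLPN cross-validation folds.
#' @param n_lambda GGM penalty-path length.
#' @param contemporaneous source of the contemporaneous network:
#'   within-person residual structure (`"panelgvar"`) or a cross-sectional
#'   GGM at wave 1 (`"ggm"`).
#' @param nct_wave wave whose cross-sectional networks the group comparison
#'   permutes (default 1).
#' @param n_boot_edges,n_boot_casedrop,drop_props bootstrap settings.
#' @param n_perm permutations for the group-comparison test.
#' @param m_imputations,mice_iterations,k_donors imputation settings.
#' @param seed master seed.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(input = NULL, group_col = "sex",
                            wave_labels = c("T1", "T3"),
                            reverse_items = NULL, gamma = 0.5, alpha = 0.01,
                            selection = "ebic", n_folds = 10, n_lambda = 100,
                            contemporaneous = c("panelgvar", "ggm"),
                            nct_wave = 1, n_boot_edges = 1000,
                            n_boot_casedrop = 250,
                            drop_props = seq(0.1, 0.7, by = 0.1),
                            n_perm = 1000, m_imputations = 10,
                            mice_iterations = 10, k_donors = 5, seed = 1) {
  contemporaneous <- match.arg(contemporaneous)
  structure(as.list(environment()), class = "analysis_config")
}

#' Strongest edges of a network
#'
#' Edges sorted by absolute weight, descending; ties are broken
#' lexicographically by (source id, target id). Symmetric networks
#' contribute each unordered pair once; directed networks every ordered
#' off-diagonal pair.
#'
#' @param network a network object or weight matrix.
#' @param k number of edges to return.
#' @return data.frame with `source`, `target`, `weight`.
#' @export
top_edges <- function(network, k = 3) {
  if (k < 1) stop("k must be >= 1")
  W <- edge_weights(network)
  labels <- colnames(W) %||% paste0("V", seq_len(ncol(W)))
  if (is_square_symmetric(W)) {
    idx <- which(upper.tri(W), arr.ind = TRUE)
  } else {
    idx <- which(row(W) != col(W), arr.ind = TRUE)
  }
  df <- data.frame(source = labels[idx[, 1]], target = labels[idx[, 2]],
                   weight = W[idx])
  ord <- order(-abs(df$weight), df$source, df$target)
  head(df[ord, , drop = FALSE], k)
}

# Subset a panel_data to one group level.
#' @noRd
subset_group <- function(data, level) {
  subset_units(data, which(data$group == level))
}

# Contemporaneous-network estimator chosen by config, as a closure over a
# two-wave panel (used for estimation and for its bootstrap).
#' @noRd
contemporaneous_estimator <- function(config) {
  if (config$contemporaneous == "panelgvar") {
    function(d) fit_panelgvar(d, alpha = config$alpha)$contemporaneous
  } else {
    function(d) estimate_ggm(wave_matrix(d, 1), gamma = config$gamma,
                             n_lambda = config$n_lambda)
  }
}

#' Run the full study pipeline
#'
#' Executes, per group stratum: chained-equation imputation (when data are
#' missing), cross-lagged panel network with in/out expected influence,
#' contemporaneous and between-person networks, Rubin pooling of edge
#' weights across imputations, bootstrap edge confidence intervals,
#' case-drop CS coefficients, and finally a permutation comparison of the
#' two groups' cross-sectional networks. Bit-identical under a fixed
#' config + data.
#'
#' @param config an [analysis_config()].
#' @param data optional [panel_data]; when `NULL`, `config$input` is loaded.
#' @return object of class `study_report`.
#' @export
run_study <- function(config, data = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  stage <- "load"
  out <- tryCatch({
    if (is.null(data)) {
      data <- load_panel(config$input, group_col = config$group_col,
                         wave_labels = config$wave_labels)
    }
    stage <- "reverse_code"
    data <- reverse_code(data, config$reverse_items)
    stage <- "mcar"
    wide <- panel_wide(data)
    mcar <- little_mcar(wide)
    stage <- "per_group"
    groups <- levels(data$group)
    if (length(groups) != 2) stop("expected exactly two groups")
    group_reports <- lapply(groups, function(g) {
      gdat <- subset_group(data, g)
      gseed <- derive_seed(config$seed, paste0("group_", g))
      if (anyNA(gdat$values)) {
        imp <- mice_pmm(gdat, m = config$m_imputations,
                        iterations = config$mice_iterations,
                        k_donors = config$k_donors,
                        seed = derive_seed(gseed, "impute"))
        completed <- imp$datasets
      } else {
        completed <- list(gdat)
      }
      cest <- contemporaneous_estimator(config)
      fits <- lapply(seq_along(completed), function(i) {
        d <- completed[[i]]
        clpn <- fit_clpn(d, selection = config$selection,
                         n_folds = config$n_folds,
                         seed = derive_seed(gseed, paste0("clpn", i)))
        pg <- fit_panelgvar(d, alpha = config$alpha)
        contemp <- if (config$contemporaneous == "panelgvar") {
          pg$contemporaneous
        } else {
          edge_weights(cest(d))
        }
        list(clpn = clpn, between = pg$between, contemp = contemp)
      })
      beta <- pool_edge_weights(lapply(fits, function(f) f$clpn$beta))
      auto <- rowMeans(sapply(fits, function(f) f$clpn$auto))
      between <- pool_edge_weights(lapply(fits, function(f) f$between))
      contemp <- pool_edge_weights(lapply(fits, function(f) f$contemp))
      d1 <- completed[[1]]
      boot <- bootstrap_edges(d1, cest, n_boot = config$n_boot_edges,
                              seed = derive_seed(gseed, "boot"))
      cs_oei <- casedrop_cs(
        d1, function(d) fit_clpn(d, selection = config$selection,
                                 n_folds = config$n_folds,
                                 seed = derive_seed(gseed, "cs_clpn")),
        centrality_fn = function(net) directed_centrality(net)$oei,
        drop_props = config$drop_props, n_boot = config$n_boot_casedrop,
        seed = derive_seed(gseed, "cs_oei"))
      cs_strength <- casedrop_cs(
        d1, cest,
        centrality_fn = function(net) centrality(net)$strength,
        drop_props = config$drop_props, n_boot = config$n_boot_casedrop,
        seed = derive_seed(gseed, "cs_strength"))
      list(group = g, n = n_units(gdat),
           m_imputations = length(completed),
           clpn = beta, auto = auto, between = between,
           contemporaneous = contemp,
           directed_centrality = directed_centrality(beta),
           strength_centrality = centrality(contemp),
           top_cross_lagged = top_edges(beta, 3),
           edge_ci = list(lower = boot$ci_lower, upper = boot$ci_upper),
           cs = c(oei = cs_oei$cs_value, strength = cs_strength$cs_value))
    })
    names(group_reports) <- groups
    stage <- "nct"
    first_imp <- lapply(groups, function(g) {
      gdat <- subset_group(data, g)
      if (anyNA(gdat$values)) {
        gseed <- derive_seed(config$seed, paste0("group_", g))
        gdat <- mice_pmm(gdat, m = 1, iterations = config$mice_iterations,
                         k_donors = config$k_donors,
                         seed = derive_seed(gseed, "impute"))$datasets[[1]]
      }
      wave_matrix(gdat, config$nct_wave)
    })
    nct <- nct_compare(first_imp[[1]], first_imp[[2]],
                       function(d) estimate_ggm(d, gamma = config$gamma,
                                                n_lambda = config$n_lambda),
                       n_perm = config$n_perm,
                       seed = derive_seed(config$seed, "nct"))
    structure(list(config = config, groups = group_reports, nct = nct,
                   missingness = list(rate = mean(is.na(data$values)),
                                      mcar = mcar)),
              class = "study_report")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "' (master seed ",
         config$seed, "): ", conditionMessage(e), call. = FALSE)
  })
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> groups:", paste(names(x$groups), collapse = ", "), "\n")
  cat(sprintf("  missing rate %.2f%%; NCT S = %.3f (p = %.3f), M = %.3f (p = %.3f)\n",
              100 * x$missingness$rate, x$nct$S_obs, x$nct$p_S,
              x$nct$M_obs, x$nct$p_M))
  for (g in names(x$groups)) {
    te <- x$groups[[g]]$top_cross_lagged
    cat("  ", g, " top cross-lagged: ",
        paste(sprintf("%s->%s (%.2f)", te$source, te$target, te$weight),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Edge list in the export format source,target,weight,network_type,group.
#' @noRd
edge_list_df <- function(W, type, group) {
  labels <- colnames(W) %||% paste0("V", seq_len(ncol(W)))
  idx <- if (is_square_symmetric(W)) {
    which(upper.tri(W) & W != 0, arr.ind = TRUE)
  } else {
    which(row(W) != col(W) & W != 0, arr.ind = TRUE)
  }
  if (!nrow(idx)) {
    return(data.frame(source = character(), target = character(),
                      weight = numeric(), network_type = character(),
                      group = character()))
  }
  data.frame(source = labels[idx[, 1]], target = labels[idx[, 2]],
             weight = W[idx], network_type = type, group = group)
}

#' Write a study report to a directory
#'
#' Emits per-group edge lists (`edges.csv`, with columns
#' `source,target,weight,network_type,group`), centrality tables and a
#' machine-readable `summary.json`.
#'
#' @param report a [run_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edges <- do.call(rbind, unlist(lapply(names(report$groups), function(g) {
    gr <- report$groups[[g]]
    list(edge_list_df(gr$clpn, "temporal", g),
         edge_list_df(gr$contemporaneous, "contemporaneous", g),
         edge_list_df(gr$between, "between", g))
  }), recursive = FALSE))
  write.csv(edges, file.path(dir, "edges.csv"), row.names = FALSE)
  for (g in names(report$groups)) {
    gr <- report$groups[[g]]
    write.csv(cbind(gr$directed_centrality,
                    strength = gr$strength_centrality$strength),
              file.path(dir, paste0("centrality_", g, ".csv")),
              row.names = FALSE)
  }
  summary <- list(
    nct = list(S = report$nct$S_obs, p_S = report$nct$p_S,
               M = report$nct$M_obs, p_M = report$nct$p_M,
               n_perm = report$nct$n_perm),
    missing_rate = report$missingness$rate,
    mcar_p = report$missingness$mcar$p.value,
    cs = lapply(report$groups, function(gr) as.list(gr$cs)),
    top_cross_lagged = lapply(report$groups, function(gr)
      gr$top_cross_lagged))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
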