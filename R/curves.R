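#' Analysis configuration
#'
#' Bundles every tunable of the window/SCN/metric/AUC pipeline.  Defaults are
#' the study conditions: window width 10, step 1, sparsity grid 0.05-0.50 in
#' steps of 0.05, signed-correlation edge ranking, 100 rewired surrogates for
#' small-world normalization, 10 modularity restarts, and 5000 permutations
#' for inference.
#'
#' @param width,step sliding-window width and step (subjects).
#' @param grid sparsity grid, see [sparsity_grid()].
#' @param edge_rank `"signed"` or `"abs"` edge ranking.
#' @param residualize_age residualize thickness on age within windows before
#'   correlating (sensitivity analysis; default off, the window is the age
#'   control).
#' @param global_metrics global metric curves to compute; any of `"C"`,
#'   `"L"`, `"Eglob"`, `"Eloc"`, `"Q"`, `"mod_num"`, `"gamma"`, `"lambda"`,
#'   `"sigma"`.
#' @param nodal_metrics nodal metric curves; any of `"Nlp"`, `"Bc"`.
#' @param n_null rewired surrogates per graph for the normalized metrics
#'   (needed only when `gamma`/`lambda`/`sigma` are requested).
#' @param swap_factor attempted swaps per surrogate, as a multiple of the
#'   edge count.
#' @param modularity_restarts randomized restarts of the modularity
#'   optimizer.
#' @param n_perm permutations for group inference.
#' @param alpha significance threshold on FDR-adjusted q-values.
#' @param seed master integer seed; all randomized stages draw named
#'   substreams from it.
#' @return an object of class `"scn_config"`.
#' @export
scn_config <- function(width = 10L, step = 1L, grid = sparsity_grid(),
                       edge_rank = c("signed", "abs"),
                       residualize_age = FALSE,
                       global_metrics = c("C", "L", "Eglob", "Eloc",
                                          "Q", "mod_num",
                                          "gamma", "lambda", "sigma"),
                       nodal_metrics = c("Nlp", "Bc"),
                       n_null = 100L, swap_factor = 10L,
                       modularity_restarts = 10L,
                       n_perm = 5000L, alpha = 0.05, seed = 1L) {
  edge_rank <- match.arg(edge_rank)
  all_glob <- c("C", "L", "Eglob", "Eloc", "Q", "mod_num",
                "gamma", "lambda", "sigma")
  fail_if(!all(global_metrics %in% all_glob),
          "unknown global metric(s): %s",
          paste(setdiff(global_metrics, all_glob), collapse = ", "))
  fail_if(!all(nodal_metrics %in% c("Nlp", "Bc")),
          "unknown nodal metric(s): %s",
          paste(setdiff(nodal_metrics, c("Nlp", "Bc")), collapse = ", "))
  norm_req <- any(c("gamma", "lambda", "sigma") %in% global_metrics)
  fail_if(norm_req && n_null < 1,
          "n_null: normalized metrics require at least one surrogate")
  cfg <- list(width = as.integer(width), step = as.integer(step),
              grid = grid, edge_rank = edge_rank,
              residualize_age = isTRUE(residualize_age),
              global_metrics = global_metrics,
              nodal_metrics = nodal_metrics,
              n_null = if (norm_req) as.integer(n_null) else 0L,
              swap_factor = as.integer(swap_factor),
              modularity_restarts = as.integer(modularity_restarts),
              n_perm = as.integer(n_perm), alpha = alpha,
              seed = as.integer(seed))
  class(cfg) <- "scn_config"
  cfg
}

#' Trapezoidal area under a metric curve
#'
#' `AUC = sum_t (y_t + y_{t+1}) / 2 * (s_{t+1} - s_t)` over the sparsity
#' grid; the threshold-free summary scalar used for all group comparisons.
#' A curve containing non-finite values yields `NA`.
#'
#' @param y metric values, same length as `grid` (>= 2).
#' @param grid sparsity values.
#' @return scalar area.
#' @examples
#' auc_trapz(rep(1, 10), sparsity_grid())   # 0.45
#' @export
auc_trapz <- function(y, grid) {
  fail_if(length(y) != length(grid), "curve and grid lengths differ (%d vs %d)",
          length(y), length(grid))
  fail_if(length(y) < 2, "need at least two grid points")
  if (any(!is.finite(y))) return(NA_real_)
  sum((y[-1] + y[-length(y)]) / 2 * diff(grid))
}

# column-wise trapezoid over the first dimension of a [T x ...] slab
auc_cols <- function(mat, grid) {
  apply(mat, seq_along(dim(mat))[-1], auc_trapz, grid = grid)
}

# internal batch driver: curves for a list of correlation matrices
curves_for_matrices <- function(rmats, config, seed) {
  want_nodal <- length(config$nodal_metrics) > 0
  want_basic <- any(c("C", "L", "Eglob", "Eloc") %in% config$global_metrics)
  want_comm <- any(c("Q", "mod_num") %in% config$global_metrics)
  n_null <- if (any(c("gamma", "lambda", "sigma") %in% config$global_metrics))
    config$n_null else 0L
  res <- cpp_curves(rmats, config$grid, config$edge_rank == "abs",
                    want_nodal, want_basic, want_comm,
                    config$modularity_restarts, n_null,
                    config$swap_factor, as.numeric(seed))
  res
}

#' Metric curves and AUCs for one covariance network
#'
#' Thresholds a correlation matrix at every sparsity of the grid and computes
#' the requested global and nodal metrics at each threshold, plus the
#' trapezoidal AUC of every curve.  Failures at individual thresholds
#' (disconnected graphs) are flagged per threshold, not fatal.
#'
#' @param m correlation matrix (e.g. from [correlation_matrix()]).
#' @param config an [scn_config()].
#' @param seed integer seed for the surrogate ensemble and modularity
#'   restarts; defaults to the config seed.
#' @return an object of class `"metric_profile"`: list with `sparsity`,
#'   `edge_counts`, `connected` (logical per threshold), `global` (matrix
#'   thresholds x metrics), `nodal` (list of node x threshold matrices),
#'   `auc_global` (named vector) and `auc_nodal` (list of node vectors).
#' @export
metric_curves <- function(m, config = scn_config(), seed = config$seed) {
  res <- curves_for_matrices(list(m), config, seed)
  tidy_profile(res, config, w = 1L, regions = rownames(m))
}

tidy_profile <- function(res, config, w, regions) {
  tt <- length(config$grid)
  glob <- matrix(NA_real_, tt, length(config$global_metrics),
                 dimnames = list(NULL, config$global_metrics))
  for (mn in config$global_metrics) glob[, mn] <- res[[mn]][, w]
  nodal <- lapply(config$nodal_metrics, function(mn) {
    slab <- res[[mn]][, , w]
    rownames(slab) <- regions
    slab
  })
  names(nodal) <- config$nodal_metrics
  out <- list(sparsity = config$grid,
              edge_counts = res$edge_counts,
              connected = res$connected[, w],
              global = glob,
              nodal = nodal,
              auc_global = apply(glob, 2, auc_trapz, grid = config$grid),
              auc_nodal = lapply(nodal, function(slab)
                apply(slab, 1, auc_trapz, grid = config$grid)))
  class(out) <- "metric_profile"
  out
}

#' @export
print.metric_profile <- function(x, ...) {
  cat(sprintf("metric profile: %d thresholds (%.2f-%.2f), %d global, %d nodal metrics\n",
              length(x$sparsity), min(x$sparsity), max(x$sparsity),
              ncol(x$global), length(x$nodal)))
  cat("global AUCs:\n")
  print(round(x$auc_global, 4))
  invisible(x)
}

#' Window-level metric AUCs for every group of a cohort
#'
#' The complete per-group pipeline: sort by age, slide windows, correlate,
#' threshold across the grid, compute metric curves, and summarize each curve
#' as its AUC.  This is the quantity on which all group inference operates
#' (each window contributes one observation).
#'
#' @param cohort a thickness table with a `group` column.
#' @param config an [scn_config()].
#' @param seed integer seed (defaults to the config seed).
#' @param regions region labels defining node order.
#' @return list with elements `groups` (group names), `window_counts`,
#'   `global` (per group: windows x metrics AUC matrix), `nodal` (per group:
#'   list per nodal metric of windows x nodes AUC matrices), and
#'   `disconnected` (per group: count of disconnected window/threshold
#'   cells).
#' @export
cohort_aucs <- function(cohort, config = scn_config(), seed = config$seed,
                        regions = dk_atlas()$label) {
  groups <- if (is.factor(cohort$group)) levels(cohort$group)
            else unique(as.character(cohort$group))
  out <- list(groups = groups, window_counts = integer(0),
              global = list(), nodal = list(), disconnected = list())
  tt <- length(config$grid)
  for (gi in seq_along(groups)) {
    sub <- cohort[cohort$group == groups[gi], , drop = FALSE]
    wins <- make_windows(sub, config$width, config$step)
    rmats <- lapply(wins, function(w)
      correlation_matrix(w, sub, regions = regions,
                         residualize_age = config$residualize_age))
    res <- curves_for_matrices(rmats, config,
                               derive_seed(seed, paste0("curves:", groups[gi])))
    nw <- length(wins)
    glob_auc <- matrix(NA_real_, nw, length(config$global_metrics),
                       dimnames = list(NULL, config$global_metrics))
    for (mn in config$global_metrics)
      glob_auc[, mn] <- apply(matrix(res[[mn]], nrow = tt), 2,
                              auc_trapz, grid = config$grid)
    nodal_auc <- lapply(config$nodal_metrics, function(mn) {
      arr <- res[[mn]]                       # n x T x W
      mat <- matrix(NA_real_, nw, length(regions),
                    dimnames = list(NULL, regions))
      for (w in seq_len(nw))
        mat[w, ] <- apply(arr[, , w, drop = FALSE][, , 1], 1, auc_trapz,
                          grid = config$grid)
      mat
    })
    names(nodal_auc) <- config$nodal_metrics
    out$window_counts[groups[gi]] <- nw
    out$global[[groups[gi]]] <- glob_auc
    out$nodal[[groups[gi]]] <- nodal_auc
    out$disconnected[[groups[gi]]] <- sum(!res$connected)
  }
  out
}
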