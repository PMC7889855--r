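## Stability filter: repeat the stochastic selection n_runs times and retain
## only features confirmed in at least retention_fraction of the runs.

#' Parameters for stability-filtered feature selection
#'
#' @param n_runs number of independent selection runs per gene (default 50).
#' @param retention_fraction fraction of runs in which a feature must be
#'   confirmed to be retained (default 0.95; compared as an exact rational,
#'   so 48/50 passes and 47/50 fails).
#' @param max_iterations per-run iteration budget (default 100).
#' @param alpha level of the per-iteration binomial decision test.
#' @param n_trees trees per forest fit.
#' @param base_seed seed of run 0; run r uses `base_seed + r`.
#' @param count_tentative if `TRUE`, features still Tentative at the
#'   iteration budget count as selected in that run; the default counts
#'   Confirmed only (the conservative reading of "significant").
#' @param importance forest importance measure compared against the shadow
#'   maximum: `"impurity"` (in-sample variance reduction, the default) or
#'   `"permutation"` (out-of-bag permutation importance, Z-scaled — the
#'   measure of the original shadow-feature algorithm).
#' @param mtry candidate features per split; `NULL` for the forest default
#'   (square root of the feature count).
#' @param max_depth tree depth cap; `NULL` for unlimited.
#' @return list of class `selection_params`.
#' @export
selection_params <- function(n_runs = 50L, retention_fraction = 0.95,
                             max_iterations = 100L, alpha = 0.05,
                             n_trees = 100L, base_seed = 1L,
                             count_tentative = FALSE,
                             importance = c("impurity", "permutation"),
                             mtry = NULL, max_depth = NULL) {
  stopifnot(n_runs >= 1L, retention_fraction > 0, retention_fraction <= 1,
            alpha > 0, alpha < 1, max_iterations >= 1L, n_trees >= 1L)
  structure(list(n_runs = as.integer(n_runs),
                 retention_fraction = retention_fraction,
                 max_iterations = as.integer(max_iterations),
                 alpha = alpha, n_trees = as.integer(n_trees),
                 base_seed = as.integer(base_seed),
                 count_tentative = isTRUE(count_tentative),
                 importance = match.arg(importance),
                 mtry = mtry, max_depth = max_depth),
            class = "selection_params")
}

## Retention bookkeeping given per-feature confirmed-run counts; exposed to
## make the >= 95%-of-runs arithmetic testable in isolation.
selection_result <- function(target_gene_id, counts, params,
                             feature_meta = NULL) {
  thr <- count_threshold(params$retention_fraction, params$n_runs)
  retention <- counts / params$n_runs
  structure(list(target_gene_id = target_gene_id,
                 n_runs = params$n_runs,
                 retention_fraction = params$retention_fraction,
                 counts = counts,
                 retention = retention,
                 retained = names(counts)[counts >= thr],
                 feature_meta = feature_meta),
            class = "stability_selection")
}

#' Stability-filtered all-relevant feature selection
#'
#' Runs [boruta_select()] `n_runs` times with seeds
#' `base_seed, base_seed + 1, ...` and retains the features confirmed in at
#' least `retention_fraction` of the runs.
#'
#' @param design a `hub_design`.
#' @param params a [selection_params()] list.
#' @return object of class `stability_selection`: `target_gene_id`,
#'   `counts` (confirmed-run count per feature), `retention` (fractions),
#'   `retained` (feature ids), and the design's `feature_meta`.
#' @export
stability_select <- function(design, params = selection_params()) {
  feat <- colnames(design$features)
  counts <- setNames(integer(length(feat)), feat)
  for (r in seq_len(params$n_runs) - 1L) {
    fit <- boruta_select(design, seed = params$base_seed + r, params = params)
    sel <- fit$confirmed
    if (params$count_tentative) sel <- c(sel, fit$tentative)
    counts[sel] <- counts[sel] + 1L
  }
  selection_result(design$target_gene_id, counts, params, design$feature_meta)
}

#' @export
print.stability_selection <- function(x, ...) {
  cat("Stability selection for gene '", x$target_gene_id, "' (",
      x$n_runs, " runs, retention >= ", x$retention_fraction * 100, "%)\n",
      "  retained ", length(x$retained), " of ", length(x$counts),
      " feature(s)", sep = "")
  if (length(x$retained)) cat(": ", paste(x$retained, collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' @method summary stability_selection
#' @export
summary.stability_selection <- function(object, ...) {
  df <- data.frame(feature_id = names(object$counts),
                   confirmed_runs = as.integer(object$counts),
                   retention = as.numeric(object$retention),
                   retained = names(object$counts) %in% object$retained,
                   row.names = NULL)
  df[order(-df$retention, df$feature_id), ]
}
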