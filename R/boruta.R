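## All-relevant feature selection by the shadow-feature (Boruta-style)
## algorithm over a random-forest importance measure.
##
## Each iteration appends a permuted "shadow" copy of every still-active
## feature, fits a forest (ranger, impurity importance), and scores a hit
## for every undecided real feature whose importance beats the best shadow.
## Features are confirmed/rejected by a two-sided binomial test on their
## hit count at level alpha, Bonferroni-corrected across the currently
## undecided features; iteration stops when all features are decided or the
## iteration budget is exhausted (undecided features end Tentative).

save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' One Boruta-style all-relevant selection run
#'
#' @param design a `hub_design` (or any list with `response` and `features`).
#' @param seed integer seed; the run is fully deterministic given
#'   `(design, seed, params)`.
#' @param params a [selection_params()] list (uses `max_iterations`,
#'   `alpha`, `n_trees`).
#' @return object of class `boruta_fit`: list with `confirmed`, `rejected`,
#'   `tentative` (character vectors of feature ids), `hits`, `n_iterations`.
#' @export
boruta_select <- function(design, seed, params = selection_params()) {
  X <- design$features
  y <- as.numeric(design$response)
  if (nrow(X) < 2L) stop("need at least 2 samples")
  if (ncol(X) < 1L) stop("need at least 1 candidate feature")
  if (var(y) == 0) stop("response is constant")
  feat <- colnames(X)
  decision <- setNames(rep("undecided", length(feat)), feat)
  ## zero-variance features carry no information: reject up front
  zv <- apply(X, 2L, var) == 0
  if (any(zv)) {
    decision[zv] <- "rejected"
    message("auto-rejected zero-variance feature(s): ",
            paste(feat[zv], collapse = ", "))
  }
  hits <- setNames(integer(length(feat)), feat)
  old <- save_rng()
  on.exit(restore_rng(old))
  set.seed(as.integer(seed))
  n <- nrow(X)
  it <- 0L
  while (any(decision == "undecided") && it < params$max_iterations) {
    it <- it + 1L
    active <- feat[decision != "rejected"]
    Xa <- X[, active, drop = FALSE]
    ## shadows: permuted copies of active features, padded to >= 5
    n_sh <- max(length(active), 5L)
    sh_src <- active[((seq_len(n_sh) - 1L) %% length(active)) + 1L]
    Xs <- vapply(sh_src, function(f) X[, f][sample.int(n)], numeric(n))
    colnames(Xs) <- paste0("shadow_", seq_len(n_sh))
    dat <- as.data.frame(cbind(Xa, Xs))
    fit <- ranger::ranger(x = dat, y = y, num.trees = params$n_trees,
                          importance = params$importance,
                          scale.permutation.importance =
                            params$importance == "permutation",
                          mtry = params$mtry,
                          max.depth = params$max_depth,
                          num.threads = 1L,
                          seed = sample.int(.Machine$integer.max, 1L))
    imp <- fit$variable.importance
    shadow_max <- max(imp[colnames(Xs)])
    und <- feat[decision == "undecided"]
    beat <- und[imp[und] > shadow_max]
    hits[beat] <- hits[beat] + 1L
    ## two-sided binomial test on hit counts, corrected twice: Bonferroni
    ## over the full candidate set (adjusting only over the still-undecided
    ## features would let the last lucky survivor confirm against a trivial
    ## threshold) and alpha/iteration for testing the same feature at every
    ## iteration (without it the constant-level sequential test is
    ## anti-conservative)
    m <- length(feat)
    p_hi <- pbinom(hits[und] - 1L, it, 0.5, lower.tail = FALSE)
    p_lo <- pbinom(hits[und], it, 0.5)
    p_two <- pmin(1, 2 * pmin(p_hi, p_lo))
    sig <- (p_two * m <= params$alpha) & (p_two <= params$alpha / it)
    decision[und[sig & hits[und] > it / 2]] <- "confirmed"
    decision[und[sig & hits[und] < it / 2]] <- "rejected"
  }
  structure(list(confirmed = feat[decision == "confirmed"],
                 rejected = feat[decision == "rejected"],
                 tentative = feat[decision == "undecided"],
                 hits = hits, n_iterations = it),
            class = "boruta_fit")
}

#' @export
print.boruta_fit <- function(x, ...) {
  cat("Boruta-style selection: ", length(x$confirmed), " confirmed, ",
      length(x$rejected), " rejected, ", length(x$tentative),
      " tentative after ", x$n_iterations, " iteration(s)\n", sep = "")
  if (length(x$confirmed)) cat("  confirmed: ",
                               paste(x$confirmed, collapse = ", "), "\n", sep = "")
  invisible(x)
}
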