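#' Lag-1 autocorrelation of a sampled series
#'
#' The estimator pairs each sample with its successor and shares one mean:
#' `sum_{m=1}^{M-1} (x_m - xbar)(x_{m+1} - xbar) / sum_{m=1}^{M} (x_m - xbar)^2`.
#' A constant series has zero denominator and yields `NA` (an undefined
#' signal, not an error), which downstream aggregation and scoring skip.
#'
#' @param series numeric vector of at least 2 samples.
#' @return A value in `[-1, 1]`, or `NA` for a constant series.
#' @examples
#' lag1_autocorrelation(c(1, -1, 1, -1)) # -3/4
#' @export
lag1_autocorrelation <- function(series) {
  m <- length(series)
  if (m < 2L) stop("need at least 2 samples", call. = FALSE)
  centred <- series - mean(series)
  denom <- sum(centred^2)
  if (denom == 0) return(NA_real_)
  sum(centred[-m] * centred[-1L]) / denom
}

#' Sample standard deviation of a node series
#'
#' Denominator `M - 1`.
#'
#' @inheritParams lag1_autocorrelation
#' @return Non-negative standard deviation.
#' @export
node_sd <- function(series) {
  if (length(series) < 2L) stop("need at least 2 samples", call. = FALSE)
  stats::sd(series)
}

#' Dominant eigenvalue of a node set's sample covariance matrix
#'
#' The largest eigenvalue of the `k x k` sample covariance (denominator
#' `M - 1`) of the node-set columns, clamped at 0 against round-off.
#'
#' @param samples numeric `M x k` matrix of samples (rows) by nodes
#'   (columns).
#' @return Non-negative scalar, or `NA` for an empty node set (`k = 0`).
#' @export
dominant_cov_eigenvalue <- function(samples) {
  samples <- as.matrix(samples)
  if (ncol(samples) == 0L) return(NA_real_)
  if (nrow(samples) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (ncol(samples) == 1L) return(stats::var(samples[, 1L]))
  ev <- eigen(stats::cov(samples), symmetric = TRUE, only.values = TRUE)
  max(ev$values[1L], 0)
}

#' Early warning signals for one node set in one sample block
#'
#' The five signals of critical slowing down: the dominant eigenvalue of
#' the node-set covariance matrix, and the maximum and mean of the
#' node-level standard deviation and lag-1 autocorrelation. Nodes whose
#' autocorrelation is undefined (constant series) are excluded from the
#' autocorrelation aggregates; an empty node set yields all-`NA` signals.
#'
#' @param block a sample block from [run_sweep()] (`$blocks[[k]]`), or any
#'   list with an `M x N` `samples` matrix.
#' @param node_set integer vector of node indices (1-based), possibly
#'   empty.
#' @return A one-row tibble: `n_nodes`, `dom_eig`, `max_sd`, `avg_sd`,
#'   `max_ac`, `avg_ac`.
#' @export
compute_signals <- function(block, node_set) {
  samples <- block$samples
  node_set <- as.integer(node_set)
  if (length(node_set) > 0 &&
      (anyDuplicated(node_set) || min(node_set) < 1L ||
       max(node_set) > ncol(samples)))
    stop("node_set must be distinct indices in 1..N", call. = FALSE)
  if (length(node_set) == 0L)
    return(tibble::tibble(n_nodes = 0L, dom_eig = NA_real_,
                          max_sd = NA_real_, avg_sd = NA_real_,
                          max_ac = NA_real_, avg_ac = NA_real_))
  sub <- samples[, node_set, drop = FALSE]
  sds <- apply(sub, 2L, node_sd)
  acs <- apply(sub, 2L, lag1_autocorrelation)
  acs <- acs[!is.na(acs)]
  tibble::tibble(
    n_nodes = length(node_set),
    dom_eig = dominant_cov_eigenvalue(sub),
    max_sd = max(sds), avg_sd = mean(sds),
    max_ac = if (length(acs)) max(acs) else NA_real_,
    avg_ac = if (length(acs)) mean(acs) else NA_real_
  )
}

#' Signal names
#'
#' The five early warning signals computed per node set.
#' @return Character vector.
#' @export
signal_names <- function() c("dom_eig", "max_sd", "avg_sd", "max_ac", "avg_ac")

#' Compute early warning signals along a sweep
#'
#' For each parameter value of a sweep, re-selects every requested node set
#' (membership is recomputed at each value; see [select_node_set()]) and
#' computes the five early warning signals from that block's `M` samples.
#'
#' @param sweep a [run_sweep()] result.
#' @param node_sets character vector of node-set kinds (see
#'   [select_node_set()]); default the nine defined kinds.
#' @param n sentinel set size for the fixed-size kinds; default 5.
#' @param membership_samples number of leading samples used for node-set
#'   membership scores (means, s.d., correlations); default all `M`.
#'   Signals always use all `M` samples.
#' @param seed integer seed for the `"random"` node set (a child seed per
#'   parameter value is derived from it); defaults to the sweep's seed.
#' @return A tibble with one row per (parameter value, node set):
#'   `param_value`, `node_set`, `n_nodes`, and the five signal columns.
#' @export
sweep_signals <- function(sweep, node_sets = node_set_kinds(), n = 5L,
                          membership_samples = NULL, seed = NULL) {
  stopifnot(inherits(sweep, "dw_sweep"))
  node_sets <- match.arg(node_sets, node_set_kinds(), several.ok = TRUE)
  seed <- seed %||% sweep$config$seed
  rand_seeds <- child_seeds(seed + 1L, length(sweep$blocks))
  purrr::imap(sweep$blocks, function(block, k) {
    purrr::map(node_sets, function(kind) {
      members <- select_node_set(
        kind, block, net = sweep$net, initial_side = sweep$initial_side,
        threshold = sweep$threshold, n = n,
        membership_samples = membership_samples,
        seed = rand_seeds[k])
      dplyr::bind_cols(
        tibble::tibble(param_value = block$param_value, node_set = kind),
        compute_signals(block, members))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}
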