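#' Node-set kinds
#'
#' The nine node-set selection rules available to [select_node_set()] and
#' [sweep_signals()].
#' @return Character vector.
#' @export
node_set_kinds <- function() {
  c("all", "lower_state", "upper_state", "high_input", "low_input",
    "lower_half", "random", "large_correlation", "large_sd")
}

#' Input scores R_i
#'
#' `R_i = sum_j a_ij * xbar_j`: the summed mean states of a node's
#' neighbours. Nodes with many neighbours, or with neighbours that have
#' already transitioned to the upper state, score high and are candidates
#' to tip next as the coupling strength grows.
#'
#' @param net a [as_dw_network()] object.
#' @param means numeric vector of per-node mean states, length `N`.
#' @return A tibble with columns `node` and `score`.
#' @examples
#' net <- as_dw_network(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
#' input_scores(net, c(1, 1, 7))$score # 1, 8, 1
#' @export
input_scores <- function(net, means) {
  stopifnot(inherits(net, "dw_network"))
  if (length(means) != net$N)
    stop("means must have one entry per node", call. = FALSE)
  tibble::tibble(node = seq_len(net$N),
                 score = as.numeric(net$adjacency %*% means))
}

#' Correlation-based input scores R'_i
#'
#' `R'_i = sum_{j != i} cor(x_i, x_j) * xbar_j` with Pearson correlations
#' over the samples: a structure-free proxy for [input_scores()] when the
#' adjacency matrix is unknown. Pairs involving a constant series have
#' undefined correlation and contribute 0.
#'
#' @param block a sample block (`$blocks[[k]]` of a [run_sweep()] result),
#'   or any list with an `M x N` `samples` matrix.
#' @param membership_samples use only this many leading samples (default
#'   all).
#' @return A tibble with columns `node` and `score`.
#' @export
correlation_scores <- function(block, membership_samples = NULL) {
  samples <- block$samples
  if (!is.null(membership_samples))
    samples <- samples[seq_len(membership_samples), , drop = FALSE]
  if (nrow(samples) < 3L) stop("need at least 3 samples", call. = FALSE)
  n <- ncol(samples)
  cm <- suppressWarnings(stats::cor(samples))
  cm[!is.finite(cm)] <- 0 # constant series: undefined correlation drops out
  diag(cm) <- 0
  means <- colMeans(samples)
  tibble::tibble(node = seq_len(n), score = as.numeric(cm %*% means))
}

# top-n / bottom-n with deterministic tie-break by lowest node index
top_n_nodes <- function(scores, candidates, n, decreasing = TRUE) {
  if (length(candidates) <= n) return(sort(candidates))
  sc <- scores[candidates]
  ord <- order(sc, candidates, decreasing = c(decreasing, FALSE),
               method = "radix")
  sort(candidates[ord[seq_len(n)]])
}

#' Select a sentinel node set
#'
#' Implements the nine selection rules, re-evaluated at every bifurcation
#' parameter value:
#' * `"all"`: every node.
#' * `"lower_state"` / `"upper_state"`: nodes in that macro state at the
#'   end of relaxation (instantaneous state against `threshold`); may be
#'   empty.
#' * `"high_input"` / `"low_input"`: the `n` available nodes with the
#'   largest / smallest input score `R_i` ([input_scores()]).
#' * `"lower_half"`: available lower-state nodes with `R_i` strictly below
#'   the median `R_i` of available lower-state nodes.
#' * `"random"`: `n` nodes uniformly without replacement from all nodes.
#' * `"large_correlation"`: the `n` available nodes with the largest
#'   correlation score `R'_i` ([correlation_scores()]).
#' * `"large_sd"`: the `n` available nodes with the largest sample
#'   standard deviation.
#'
#' "Available" nodes are those still in their original macro state (the
#' `initial_side` of the sweep) and hence still able to tip. If fewer than
#' `n` candidates exist, all candidates are returned. Ties in rankings are
#' broken by lowest node index.
#'
#' @param kind one of [node_set_kinds()].
#' @param block a sample block with `samples` (`M x N`) and
#'   `state_at_relax`.
#' @param net a [as_dw_network()] object; required for the `R_i`-based
#'   kinds (`high_input`, `low_input`, `lower_half`).
#' @param initial_side `"lower"` or `"upper"`: the macro state nodes
#'   started the sweep in.
#' @param threshold macro-state classification boundary (see
#'   [classification_thresholds()]).
#' @param n sentinel set size for fixed-size kinds; default 5.
#' @param membership_samples number of leading samples used for the
#'   selection scores (means, s.d., correlations); default all `M`.
#' @param seed integer seed for `kind = "random"`.
#' @return Sorted integer vector of node indices (possibly empty).
#' @export
select_node_set <- function(kind, block, net = NULL,
                            initial_side = c("lower", "upper"),
                            threshold, n = 5L, membership_samples = NULL,
                            seed = NULL) {
  kind <- match.arg(kind, node_set_kinds())
  initial_side <- match.arg(initial_side)
  samples <- block$samples
  N <- ncol(samples)
  if (kind == "all") return(seq_len(N))
  if (kind == "random") {
    if (!is.null(seed)) set.seed(seed)
    return(sort(sample.int(N, min(n, N))))
  }
  labels <- classify_states(block$state_at_relax, threshold)
  if (kind == "lower_state") return(which(labels == "lower"))
  if (kind == "upper_state") return(which(labels == "upper"))

  available <- which(labels == initial_side)
  msub <- if (is.null(membership_samples)) samples else
    samples[seq_len(membership_samples), , drop = FALSE]
  if (kind == "large_sd") {
    sds <- apply(msub, 2L, stats::sd)
    return(top_n_nodes(sds, available, n))
  }
  if (kind == "large_correlation") {
    sc <- correlation_scores(list(samples = msub))$score
    return(top_n_nodes(sc, available, n))
  }
  # R_i-based kinds need the network
  if (is.null(net))
    stop("kind '", kind, "' requires the network structure", call. = FALSE)
  ri <- input_scores(net, colMeans(msub))$score
  if (kind == "high_input") return(top_n_nodes(ri, available, n))
  if (kind == "low_input")
    return(top_n_nodes(ri, available, n, decreasing = FALSE))
  # lower_half
  if (initial_side == "upper")
    stop("the lower_half node set is not defined for upper-start sweeps",
         call. = FALSE)
  cand <- intersect(which(labels == "lower"), available)
  if (length(cand) == 0L) return(integer(0))
  sort(cand[ri[cand] < stats::median(ri[cand])])
}
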