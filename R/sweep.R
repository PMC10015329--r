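#' Configure a quasi-static bifurcation sweep
#'
#' The sweep protocol: at each value of the bifurcation parameter the
#' system is reset to its initial condition, relaxed for `relax_time` TU,
#' then sampled for `sample_window` TU at intervals of `sample_interval`
#' (giving `M = sample_window / sample_interval` samples per node). The
#' parameter then moves by `step` and the procedure repeats until the
#' fraction of transitioned nodes exceeds `stop_fraction`.
#'
#' @param bif_param `"D"` (coupling strength) or `"u"` (uniform stressor).
#' @param start first parameter value; default 0.01 (lower-start D sweep).
#' @param step increment per sweep value; its sign sets the direction.
#'   Default 0.005.
#' @param relax_time relaxation time before sampling (TU); default 50.
#' @param sample_window sampling window length (TU); default 25.
#' @param sample_interval spacing between samples (TU); default 0.1, giving
#'   `M = 250`.
#' @param dt Euler--Maruyama step (TU); default 0.01.
#' @param stop_fraction stop at the first value where the transitioned
#'   fraction strictly exceeds this; default 0.9.
#' @param initial_side `"lower"` (all nodes start at `r1`, parameter
#'   increasing) or `"upper"` (all nodes start at `r3`, parameter
#'   decreasing).
#' @param max_values safety cap on the number of parameter values; the
#'   sweep errors if it is reached without termination. Default 1000.
#' @param seed integer seed; one child seed per parameter value is derived
#'   from it, so earlier blocks are unchanged if the sweep is truncated.
#' @return A `dw_sweep_config` list.
#' @examples
#' sweep_config(seed = 1)
#' @export
sweep_config <- function(bif_param = c("D", "u"), start = 0.01, step = 0.005,
                         relax_time = 50, sample_window = 25,
                         sample_interval = 0.1, dt = 0.01,
                         stop_fraction = 0.9,
                         initial_side = c("lower", "upper"),
                         max_values = 1000L, seed = 1L) {
  bif_param <- match.arg(bif_param)
  initial_side <- match.arg(initial_side)
  if (step == 0) stop("step must be non-zero", call. = FALSE)
  if (!(stop_fraction > 0 && stop_fraction <= 1))
    stop("stop_fraction must be in (0, 1]", call. = FALSE)
  M <- round(sample_window / sample_interval)
  if (M < 2) stop("sampling window must contain at least 2 samples",
                  call. = FALSE)
  if (initial_side == "lower" && step < 0)
    stop("lower-start sweeps move the parameter upward (step > 0)",
         call. = FALSE)
  if (initial_side == "upper" && step > 0)
    stop("upper-start sweeps move the parameter downward (step < 0)",
         call. = FALSE)
  structure(list(bif_param = bif_param, start = start, step = step,
                 relax_time = relax_time, sample_window = sample_window,
                 sample_interval = sample_interval, M = as.integer(M),
                 dt = dt, stop_fraction = stop_fraction,
                 initial_side = initial_side,
                 max_values = as.integer(max_values),
                 seed = as.integer(seed)),
            class = "dw_sweep_config")
}

# deterministic child seeds, one per parameter value, independent of how
# far the sweep actually runs
child_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a quasi-static bifurcation sweep
#'
#' For each parameter value: reset all nodes to the initial condition
#' (`r1` for lower-start, `r3` for upper-start), integrate
#' `relax_time + sample_window` TU by Euler--Maruyama, record the state at
#' the end of relaxation and `M` equally spaced samples, and classify each
#' node's macro state from its sample mean against the analytic threshold
#' ([classification_thresholds()]; the lower threshold for lower-start
#' sweeps, the upper one for upper-start). The sweep stops at the first
#' value where the transitioned fraction strictly exceeds
#' `config$stop_fraction`; that terminal block is retained and flagged.
#'
#' @param net a [as_dw_network()] object.
#' @param params a [double_well_params()] object; for a `"D"` sweep the
#'   `D` entry is overridden per value (its `u` is kept, e.g. `u = -15`
#'   for upper-start sweeps), and vice versa for a `"u"` sweep.
#' @param config a [sweep_config()] object.
#' @return A `dw_sweep`: list with `summary` (a tibble with one row per
#'   parameter value: `param_value`, `n_upper`, `n_transitioned`,
#'   `terminal`), `blocks` (per-value sample blocks with `samples`
#'   (`M x N`), `state_at_relax`, `means`, `sds`), plus `threshold`,
#'   `config`, `params` and `net`.
#' @examples
#' \donttest{
#' net <- generate_er(20, 4, seed = 1)
#' sw <- run_sweep(net, double_well_params(), sweep_config(seed = 1))
#' sw$summary
#' }
#' @export
run_sweep <- function(net, params, config) {
  stopifnot(inherits(net, "dw_network"), inherits(params, "dw_params"),
            inherits(config, "dw_sweep_config"))
  thr_both <- classification_thresholds(params$r1, params$r2, params$r3)
  threshold <- unname(
    if (config$initial_side == "lower") thr_both["lower"] else thr_both["upper"]
  )
  x0 <- rep(if (config$initial_side == "lower") params$r1 else params$r3,
            net$N)
  n_steps <- round((config$relax_time + config$sample_window) / config$dt)
  relax_steps <- round(config$relax_time / config$dt)
  rec_every <- round(config$sample_interval / config$dt)
  seeds <- child_seeds(config$seed, config$max_values)

  blocks <- vector("list", config$max_values)
  rows <- vector("list", config$max_values)
  terminated <- FALSE
  k <- 0L
  while (k < config$max_values) {
    k <- k + 1L
    value <- config$start + (k - 1L) * config$step
    p <- params
    if (config$bif_param == "D") p$D <- value else p$u <- value
    if (p$D < 0)
      stop("sweep drove the coupling strength D below 0", call. = FALSE)
    set.seed(seeds[k])
    rec <- em_integrate_cpp(net$adjacency, x0, p$r1, p$r2, p$r3, p$D, p$u,
                            p$s, config$dt, as.integer(n_steps),
                            as.integer(relax_steps), as.integer(rec_every))
    state_at_relax <- rec[1L, ]
    samples <- rec[-1L, , drop = FALSE] # M x N
    means <- colMeans(samples)
    sds <- apply(samples, 2L, stats::sd)
    labels <- classify_states(means, threshold)
    n_upper <- sum(labels == "upper")
    n_trans <- sum(labels != config$initial_side)
    terminal <- n_trans / net$N > config$stop_fraction
    blocks[[k]] <- structure(
      list(param_value = value,
           sample_times = config$relax_time +
             config$sample_interval * seq_len(config$M),
           samples = samples, state_at_relax = state_at_relax,
           means = means, sds = sds, labels = labels),
      class = "dw_block")
    rows[[k]] <- tibble::tibble(param_value = value, n_upper = n_upper,
                                n_transitioned = n_trans,
                                terminal = terminal)
    if (terminal) {
      terminated <- TRUE
      break
    }
  }
  if (!terminated)
    stop("sweep did not terminate within max_values = ", config$max_values,
         " parameter values", call. = FALSE)
  structure(list(summary = dplyr::bind_rows(rows[seq_len(k)]),
                 blocks = blocks[seq_len(k)], threshold = threshold,
                 initial_side = config$initial_side, config = config,
                 params = params, net = net),
            class = "dw_sweep")
}

#' @export
print.dw_sweep <- function(x, ...) {
  cat(sprintf(
    "<dw_sweep> %s-start %s sweep: %d values in [%g, %g], %d/%d transitioned\n",
    x$initial_side, x$config$bif_param, nrow(x$summary),
    min(x$summary$param_value), max(x$summary$param_value),
    dplyr::last(x$summary$n_transitioned), x$net$N))
  invisible(x)
}

#' Find stable ranges of the bifurcation parameter
#'
#' A stable range is a maximal run of consecutive parameter values over
#' which the equilibrium macro-state counts are constant; a value at which
#' the count changes begins a new range. A range qualifies for Kendall-tau
#' scoring when it contains at least `min_len` unique parameter values.
#'
#' @param sweep a [run_sweep()] result, or a data frame with columns
#'   `param_value` and `n_transitioned` (ordered along the sweep).
#' @param min_len minimum number of unique parameter values for a range to
#'   qualify; default 15.
#' @return A tibble with one row per range: `range_id`, `start`, `end`,
#'   `n_values`, `count` (transitioned-node count) and `qualifies`.
#' @export
find_stable_ranges <- function(sweep, min_len = 15L) {
  summary <- if (inherits(sweep, "dw_sweep")) sweep$summary else
    tibble::as_tibble(sweep)
  stopifnot(all(c("param_value", "n_transitioned") %in% names(summary)),
            nrow(summary) > 0L)
  cnt <- summary$n_transitioned
  range_id <- cumsum(c(1L, as.integer(diff(cnt) != 0)))
  summary |>
    dplyr::mutate(.range = range_id) |>
    dplyr::group_by(.data$.range) |>
    dplyr::summarise(start = min(.data$param_value),
                     end = max(.data$param_value),
                     n_values = dplyr::n_distinct(.data$param_value),
                     count = .data$n_transitioned[1L],
                     .groups = "drop") |>
    dplyr::rename(range_id = ".range") |>
    dplyr::mutate(qualifies = .data$n_values >= min_len)
}
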