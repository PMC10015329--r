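#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall rank correlation between the bifurcation
#' parameter and an early warning signal. Parameter values within a stable
#' range are distinct by construction, so tau-b coincides with tau-a
#' whenever the signal is tie-free. If one side is entirely tied the
#' correlation is undefined and `NA` is returned.
#'
#' @param xs,ys equal-length numeric vectors (length >= 2).
#' @return A value in `[-1, 1]`, or `NA` when undefined.
#' @examples
#' kendall_tau(1:4, c(1, 3, 2, 4)) # 2/3
#' @export
kendall_tau <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("xs and ys must have equal length",
                                     call. = FALSE)
  if (length(xs) < 2L) stop("need at least 2 observations", call. = FALSE)
  suppressWarnings(stats::cor(xs, ys, method = "kendall"))
}

#' Score a sweep's early warning signals by Kendall tau
#'
#' Within every qualifying stable range, correlates the bifurcation
#' parameter with each (node set, signal) series by [kendall_tau()], then
#' averages over ranges. Missing signal values (undefined autocorrelation,
#' empty node sets) are dropped pair-wise; a range contributes to a
#' combination only if at least `min_len` defined pairs remain. Signed tau
#' is reported: in upper-start (parameter-decreasing) sweeps a strongly
#' negative tau means the signal grows as the parameter falls towards the
#' transition.
#'
#' @param signals a [sweep_signals()] table.
#' @param ranges a [find_stable_ranges()] table.
#' @param min_len minimum defined pairs per range; default 15, matching
#'   the stable-range qualification rule.
#' @return A `dw_tau_report`: list with `per_range` (tibble: `node_set`,
#'   `signal`, `range_id`, `range_start`, `range_end`, `tau`) and
#'   `average` (tibble: `node_set`, `signal`, `avg_tau`, `n_ranges`).
#'   An empty report (with a warning) if no range qualifies.
#' @export
score_sweep <- function(signals, ranges, min_len = 15L) {
  qual <- dplyr::filter(ranges, .data$qualifies)
  long <- tidyr::pivot_longer(signals, cols = dplyr::all_of(signal_names()),
                              names_to = "signal", values_to = "value")
  if (nrow(qual) == 0L) {
    warning("no qualifying stable ranges; empty tau report", call. = FALSE)
    per_range <- tibble::tibble(node_set = character(), signal = character(),
                                range_id = integer(), range_start = double(),
                                range_end = double(), tau = double())
  } else {
    per_range <- purrr::pmap(
      list(qual$range_id, qual$start, qual$end),
      function(rid, lo, hi) {
        long |>
          dplyr::filter(.data$param_value >= lo, .data$param_value <= hi,
                        !is.na(.data$value)) |>
          dplyr::group_by(.data$node_set, .data$signal) |>
          dplyr::filter(dplyr::n() >= min_len) |>
          dplyr::summarise(
            tau = kendall_tau(.data$param_value, .data$value),
            .groups = "drop") |>
          dplyr::mutate(range_id = rid, range_start = lo, range_end = hi)
      }) |>
      dplyr::bind_rows() |>
      dplyr::filter(!is.na(.data$tau)) |>
      dplyr::select("node_set", "signal", "range_id", "range_start",
                    "range_end", "tau")
  }
  average <- per_range |>
    dplyr::group_by(.data$node_set, .data$signal) |>
    dplyr::summarise(avg_tau = mean(.data$tau), n_ranges = dplyr::n(),
                     .groups = "drop")
  structure(list(per_range = per_range, average = average,
                 min_len = min_len),
            class = "dw_tau_report")
}

#' @export
print.dw_tau_report <- function(x, ...) {
  cat("<dw_tau_report> average Kendall tau over",
      length(unique(x$per_range$range_id)), "qualifying stable range(s)\n")
  print(x$average, n = Inf)
  invisible(x)
}

#' @rdname score_sweep
#' @param x a `dw_tau_report`.
#' @param ... unused.
#' @return `tidy()`: the per-range tau tibble. `glance()`: a one-row
#'   summary (`n_ranges`, `n_combinations`, `mean_avg_tau`,
#'   `min_avg_tau`).
#' @method tidy dw_tau_report
#' @export
tidy.dw_tau_report <- function(x, ...) x$per_range

#' @rdname score_sweep
#' @method glance dw_tau_report
#' @export
glance.dw_tau_report <- function(x, ...) {
  tibble::tibble(
    n_ranges = length(unique(x$per_range$range_id)),
    n_combinations = nrow(x$average),
    mean_avg_tau = if (nrow(x$average)) mean(x$average$avg_tau) else NA_real_,
    min_avg_tau = if (nrow(x$average)) min(x$average$avg_tau) else NA_real_)
}

#' Kendall tau for the stable range preceding each transition
#'
#' A transition is a parameter value at which the equilibrium macro-state
#' count changes (the first value of each new stable range). For every
#' transition whose preceding range qualifies, reports tau over that range
#' for each (node set, signal), labelled by the transition's parameter
#' value and the number of nodes that switched.
#'
#' @inheritParams score_sweep
#' @return A tibble: `transition_at`, `n_switched`, `node_set`, `signal`,
#'   `range_id`, `tau`.
#' @export
per_transition_tau <- function(signals, ranges, min_len = 15L) {
  report <- score_sweep(signals, ranges, min_len = min_len)
  ranges <- dplyr::arrange(ranges, .data$range_id)
  if (nrow(ranges) < 2L)
    return(tibble::tibble(transition_at = double(), n_switched = integer(),
                          node_set = character(), signal = character(),
                          range_id = integer(), tau = double()))
  # first value of the next range along the sweep direction
  decreasing <- ranges$start[2L] < ranges$start[1L]
  trans <- tibble::tibble(
    transition_at = if (decreasing) ranges$end[-1L] else ranges$start[-1L],
    n_switched = abs(diff(ranges$count)),
    range_id = ranges$range_id[-nrow(ranges)])
  trans |>
    dplyr::inner_join(report$per_range, by = "range_id") |>
    dplyr::select("transition_at", "n_switched", "node_set", "signal",
                  "range_id", "tau")
}
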