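#' Plot a sweep: transitioned nodes and an early warning signal
#'
#' Shows the number of transitioned nodes at equilibrium against the
#' bifurcation parameter and, when a [sweep_signals()] table is supplied,
#' overlays one signal per node set (rescaled to the node-count axis).
#'
#' @param object a [run_sweep()] result.
#' @param signals optional [sweep_signals()] table.
#' @param signal which signal column to overlay; default `"avg_ac"`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot dw_sweep
#' @export
autoplot.dw_sweep <- function(object, signals = NULL, signal = "avg_ac",
                              ...) {
  p <- ggplot2::ggplot(object$summary,
                       ggplot2::aes(x = .data$param_value)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$n_transitioned),
                       colour = "grey50") +
    ggplot2::labs(x = object$config$bif_param,
                  y = "transitioned nodes at equilibrium") +
    ggplot2::theme_minimal()
  if (!is.null(signals)) {
    sig <- dplyr::filter(signals, !is.na(.data[[signal]]))
    rng <- range(sig[[signal]], na.rm = TRUE)
    span <- max(rng[2] - rng[1], .Machine$double.eps)
    scale <- max(object$summary$n_transitioned) / span
    sig <- dplyr::mutate(sig,
                         .scaled = (.data[[signal]] - rng[1]) * scale)
    p <- p +
      ggplot2::geom_line(
        data = sig,
        ggplot2::aes(y = .data$.scaled, colour = .data$node_set)) +
      ggplot2::labs(colour = "node set",
                    subtitle = paste(signal, "(rescaled)"))
  }
  p
}

#' Plot a tau report: average Kendall tau per signal and node set
#'
#' @param object a [score_sweep()] report.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot dw_tau_report
#' @export
autoplot.dw_tau_report <- function(object, ...) {
  ggplot2::ggplot(object$average,
                  ggplot2::aes(x = .data$avg_tau, y = .data$signal,
                               shape = .data$node_set,
                               colour = .data$node_set)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "average Kendall tau over stable ranges",
                  y = NULL, shape = "node set", colour = "node set") +
    ggplot2::theme_minimal()
}
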