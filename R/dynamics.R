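#' Double-well model parameters
#'
#' Parameters of the coupled double-well stochastic dynamics
#' \deqn{dx_i/dt = -(x_i - r_1)(x_i - r_2)(x_i - r_3)
#'       + D \sum_j a_{ij} x_j + u + s \xi_i,}
#' where \eqn{r_1 < r_2 < r_3} locate the lower stable, unstable and upper
#' stable equilibria of an isolated node, `D >= 0` is the coupling strength,
#' `u` is a uniform stressor applied to every node and `s` is the standard
#' deviation parameter of the white-noise term.
#'
#' @param r1,r2,r3 equilibrium locations, `r1 < r2 < r3`; defaults `(1, 4, 7)`.
#' @param D coupling strength (>= 0).
#' @param u uniform stressor (default 0).
#' @param s noise standard-deviation parameter (>= 0; default 0.05).
#' @return A `dw_params` list.
#' @examples
#' double_well_params()
#' @export
double_well_params <- function(r1 = 1, r2 = 4, r3 = 7, D = 0, u = 0,
                               s = 0.05) {
  if (!(r1 < r2 && r2 < r3))
    stop("need r1 < r2 < r3", call. = FALSE)
  if (D < 0) stop("D must be >= 0", call. = FALSE)
  if (s < 0) stop("s must be >= 0", call. = FALSE)
  structure(list(r1 = r1, r2 = r2, r3 = r3, D = D, u = u, s = s),
            class = "dw_params")
}

#' @export
print.dw_params <- function(x, ...) {
  cat(sprintf("<dw_params> r = (%g, %g, %g), D = %g, u = %g, s = %g\n",
              x$r1, x$r2, x$r3, x$D, x$u, x$s))
  invisible(x)
}

#' Deterministic drift of the coupled double-well model
#'
#' Evaluates the noise-free part of the dynamics,
#' `-(x_i - r1)(x_i - r2)(x_i - r3) + D * sum_j a_ij x_j + u`, at a state
#' vector.
#'
#' @param x numeric state vector, one entry per node.
#' @param net a [as_dw_network()] object; may be `NULL` for a single
#'   uncoupled node.
#' @param params a [double_well_params()] object.
#' @return Numeric vector of time derivatives (state units per TU).
#' @examples
#' drift(c(1, 4, 7), NULL, double_well_params(D = 0))
#' @export
drift <- function(x, net, params) {
  stopifnot(inherits(params, "dw_params"))
  cubic <- -(x - params$r1) * (x - params$r2) * (x - params$r3)
  if (is.null(net)) {
    if (params$D != 0 && length(x) > 1)
      stop("a network is required when D > 0 and N > 1", call. = FALSE)
    coupling <- 0
  } else {
    stopifnot(inherits(net, "dw_network"))
    if (length(x) != net$N)
      stop("state vector length does not match network size", call. = FALSE)
    coupling <- params$D * as.numeric(net$adjacency %*% x)
  }
  cubic + coupling + params$u
}

#' Macro-state classification thresholds
#'
#' The boundary between the lower and upper macro states is placed at the
#' critical points of the cubic term `-(x - r1)(x - r2)(x - r3)`, i.e. the
#' two real roots of its derivative:
#' `x = [(r1+r2+r3) +/- sqrt((r1+r2+r3)^2 - 3(r1 r2 + r1 r3 + r2 r3))] / 3`.
#' With the default equilibria `(1, 4, 7)` these are `4 - sqrt(3) ~ 2.268`
#' (used to classify nodes in lower-start sweeps) and `4 + sqrt(3) ~ 5.732`
#' (used in upper-start sweeps).
#'
#' @param r1,r2,r3 equilibrium locations, `r1 < r2 < r3`.
#' @return Named numeric vector `c(lower = ..., upper = ...)`, ascending.
#' @examples
#' classification_thresholds(1, 4, 7)
#' @export
classification_thresholds <- function(r1 = 1, r2 = 4, r3 = 7) {
  if (!(r1 < r2 && r2 < r3))
    stop("need r1 < r2 < r3", call. = FALSE)
  s1 <- r1 + r2 + r3
  s2 <- r1 * r2 + r1 * r3 + r2 * r3
  disc <- s1^2 - 3 * s2
  stopifnot(disc > 0) # guaranteed for r1 < r2 < r3
  c(lower = (s1 - sqrt(disc)) / 3, upper = (s1 + sqrt(disc)) / 3)
}

#' Classify node states into lower/upper macro states
#'
#' A node is in the lower macro state iff its state is strictly below the
#' threshold; the boundary value itself is assigned to the upper state.
#'
#' @param x numeric state vector.
#' @param threshold classification boundary (state units).
#' @return Character vector of `"lower"` / `"upper"` labels.
#' @examples
#' classify_states(c(1, 7), 2.268)
#' @export
classify_states <- function(x, threshold) {
  stopifnot(is.finite(threshold))
  ifelse(x < threshold, "lower", "upper")
}

#' Integrate the coupled double-well SDE
#'
#' Euler--Maruyama integration with fixed step `dt`: each step adds
#' `drift * dt + s * sqrt(dt) * Z` with independent standard-normal `Z` per
#' node. Draws use R's RNG, so `seed` makes trajectories bitwise
#' reproducible.
#'
#' @inheritParams drift
#' @param x0 initial state; a scalar is recycled to all nodes.
#' @param duration total integration time (TU), a positive multiple of `dt`.
#' @param dt time step (TU); default 0.01.
#' @param seed integer seed, or `NULL` to continue the current RNG stream.
#' @param record_every record the state every this many steps (default 1);
#'   the initial state is always included.
#' @return A `dw_trajectory`: list with `times` and an
#'   `n_records x N` `states` matrix.
#' @examples
#' tr <- integrate_dw(NULL, double_well_params(s = 0), x0 = 5, duration = 50)
#' tail(tr$states[, 1], 1) # -> 7, the upper equilibrium
#' @export
integrate_dw <- function(net, params, x0, duration, dt = 0.01, seed = NULL,
                         record_every = 1L) {
  stopifnot(inherits(params, "dw_params"))
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  n_steps <- round(duration / dt)
  if (n_steps < 1 || abs(n_steps * dt - duration) > 1e-8)
    stop("duration must be a positive multiple of dt", call. = FALSE)
  if (is.null(net)) {
    adj <- matrix(0L, length(x0), length(x0))
    if (params$D != 0 && length(x0) > 1)
      stop("a network is required when D > 0 and N > 1", call. = FALSE)
    n <- length(x0)
  } else {
    stopifnot(inherits(net, "dw_network"))
    adj <- net$adjacency
    n <- net$N
  }
  x0 <- rep_len(as.numeric(x0), n)
  if (!is.null(seed)) set.seed(seed)
  states <- em_integrate_cpp(adj, x0, params$r1, params$r2, params$r3,
                             params$D, params$u, params$s, dt,
                             as.integer(n_steps), 0L,
                             as.integer(record_every))
  times <- seq(0L, n_steps, by = record_every) * dt
  structure(list(times = times, states = states, dt = dt),
            class = "dw_trajectory")
}

#' @export
print.dw_trajectory <- function(x, ...) {
  cat(sprintf("<dw_trajectory> %d nodes, %d records over [0, %g] TU\n",
              ncol(x$states), length(x$times), max(x$times)))
  invisible(x)
}

#' @rdname integrate_dw
#' @param x a `dw_trajectory`.
#' @param ... unused.
#' @return `as_tibble()`: a tibble with a `time` column and one
#'   `node_<i>` column per node.
#' @method as_tibble dw_trajectory
#' @export
as_tibble.dw_trajectory <- function(x, ...) {
  st <- as.data.frame(x$states)
  names(st) <- paste0("node_", seq_len(ncol(st)))
  tibble::as_tibble(cbind(data.frame(time = x$times), st))
}
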