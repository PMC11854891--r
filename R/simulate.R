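# R-level simulation interface over the compiled fixed-step integrators.
#
# Conventions shared by the three families:
#  * coupling d is the per-link strength; d = sigma / k_max normalizes a
#    global coupling sigma by the largest degree,
#  * an initial transient is integrated and discarded before recording,
#  * runs are deterministic given (network, parameters, initial state).

chialvo_defaults <- list(a = 0.89, b = 0.6, c = 0.28)
rossler_defaults <- list(a = 0.165, b = 0.4, c = 8.5)

new_simulation_run <- function(family, d, meta, ...) {
  structure(c(list(family = family, d = d, meta = meta), list(...)),
            class = "simulation_run")
}

#' @export
print.simulation_run <- function(x, ...) {
  cat(sprintf("<simulation_run> %s, N = %d, d = %g\n",
              x$family, x$meta$N, x$d))
  invisible(x)
}

#' Simulate a network of Kuramoto phase oscillators
#'
#' Integrates `dtheta_i/dt = omega_i + d * sum_j a_ij sin(theta_j - theta_i)`
#' with a fixed-step fourth-order Runge-Kutta scheme. The recorded observable
#' per node is the instantaneous frequency, i.e. the right-hand side
#' evaluated at the retained instants (not a finite difference), sampled
#' every `sample_stride` integration steps; phases at the same instants are
#' retained for the order parameter.
#'
#' @param net a `network_spec`.
#' @param params a `node_params` of family `"kuramoto"` (natural frequencies).
#' @param d per-link coupling strength.
#' @param T_samples number of retained samples per node (default 2000).
#' @param dt integration step (default 0.01 time units).
#' @param transient time units discarded before recording (default 500).
#' @param sample_stride integration steps between retained samples
#'   (default 200, i.e. a sampling time of 2 time units).
#' @param theta0 initial phases; default uniform on `(-pi, pi]` (seeded).
#' @param seed RNG seed for the default initial condition.
#' @return a `simulation_run` with matrices `freq` and `theta`
#'   (`T_samples x N`) and the `final_state` phase vector for continuation.
#' @export
simulate_kuramoto <- function(net, params, d, T_samples = 2000L, dt = 0.01,
                              transient = 500, sample_stride = 200L,
                              theta0 = NULL, seed = NULL) {
  stopifnot(inherits(net, "network_spec"), inherits(params, "node_params"))
  if (params$family != "kuramoto") stop("params are not Kuramoto frequencies", call. = FALSE)
  N <- net$n_nodes
  if (is.null(theta0))
    theta0 <- with_local_seed(seed, runif(N, -pi, pi))
  res <- kuramoto_rk4_cpp(net_edges(net), params$values, d, theta0, dt,
                          as.integer(round(transient / dt)),
                          as.integer(T_samples), as.integer(sample_stride))
  new_simulation_run("kuramoto", d,
                     meta = list(N = N, dt = dt, transient = transient,
                                 T_samples = T_samples, sample_stride = sample_stride,
                                 seed = seed),
                     freq = res$freq, theta = res$theta,
                     final_state = res$final_state)
}

#' Simulate a network of electrically coupled Chialvo neural maps
#'
#' Iterates the two-dimensional Chialvo map
#' `x(t+1) = x^2 exp(y - x) + I + d * sum_j a_ij (x_j - x_i)`,
#' `y(t+1) = a y - b x + c` with `a = 0.89`, `b = 0.6`, `c = 0.28`
#' (periodic/quasi-periodic spiking regime). Strict local maxima of `x`
#' above `spike_threshold` are extracted on the fly; this spike-maxima
#' sequence is both the ordinal-symbolization input and the basis of the
#' spike phase used for the order parameter.
#'
#' @param net a `network_spec`.
#' @param params a `node_params` of family `"chialvo"` (bias currents `I`).
#' @param d per-link coupling strength.
#' @param n_iters retained iterations.
#' @param transient_iters discarded iterations (default 5000).
#' @param spike_threshold maxima gate (default 0.5).
#' @param state0 optional list with `x`, `y` vectors for continuation.
#' @param store_series also return the full `x` series (`n_iters x N`);
#'   memory-hungry, default `FALSE`.
#' @param seed RNG seed for the default random initial state.
#' @return a `simulation_run` with per-node lists `maxima` (values) and
#'   `maxima_t` (1-based retained-iteration indices), plus `final_state`.
#' @export
simulate_chialvo <- function(net, params, d, n_iters = 100000L,
                             transient_iters = 5000L, spike_threshold = 0.5,
                             state0 = NULL, store_series = FALSE, seed = NULL) {
  stopifnot(inherits(net, "network_spec"), inherits(params, "node_params"))
  if (params$family != "chialvo") stop("params are not Chialvo bias currents", call. = FALSE)
  N <- net$n_nodes
  if (is.null(state0))
    state0 <- with_local_seed(seed, list(x = runif(N, 0, 1), y = runif(N, 0, 1)))
  res <- chialvo_cpp(net_edges(net), params$values, d, state0$x, state0$y,
                     chialvo_defaults$a, chialvo_defaults$b, chialvo_defaults$c,
                     as.integer(transient_iters), as.integer(n_iters),
                     spike_threshold, store_series)
  out <- new_simulation_run("chialvo", d,
                            meta = list(N = N, n_iters = n_iters,
                                        transient_iters = transient_iters,
                                        spike_threshold = spike_threshold, seed = seed),
                            maxima = res$maxima, maxima_t = res$maxima_t,
                            final_state = list(x = res$x_final, y = res$y_final))
  if (store_series) out$x <- res$x
  out
}

#' Simulate a network of Roessler oscillators coupled through y
#'
#' Integrates `dx/dt = -w y - z`, `dy/dt = w x + a y + d * sum_j a_ij (y_j -
#' y_i)`, `dz/dt = b + z (x - c)` with `a = 0.165`, `b = 0.4`, `c = 8.5`
#' (phase-coherent chaos) by fixed-step RK4. Strict local minima of `y` on
#' the integration grid are collected per node (the Poincare-section series
#' used for ordinal symbolization), and the geometric phase
#' `atan2(y, x)` is recorded every `phase_stride` steps for the order
#' parameter.
#'
#' @param net a `network_spec`.
#' @param params a `node_params` of family `"rossler"` (frequency parameters `w`).
#' @param d per-link coupling strength.
#' @param n_steps retained integration steps.
#' @param dt integration step (default 0.01).
#' @param transient time units discarded before recording (default 500).
#' @param phase_stride steps between recorded phases (default 20).
#' @param state0 optional numeric vector of length `3 N` (x1,y1,z1,x2,...)
#'   for continuation.
#' @param store_series also return the full state at `series_stride` spacing.
#' @param series_stride spacing for `store_series` (default 10).
#' @param seed RNG seed for the default random initial state.
#' @return a `simulation_run` with per-node `minima` values/indices, a
#'   `theta` matrix, and `final_state`.
#' @export
simulate_rossler <- function(net, params, d, n_steps = 1500000L, dt = 0.01,
                             transient = 500, phase_stride = 20L,
                             state0 = NULL, store_series = FALSE,
                             series_stride = 10L, seed = NULL) {
  stopifnot(inherits(net, "network_spec"), inherits(params, "node_params"))
  if (params$family != "rossler") stop("params are not Roessler frequencies", call. = FALSE)
  N <- net$n_nodes
  if (is.null(state0)) {
    state0 <- with_local_seed(seed, {
      s <- numeric(3 * N)
      s[seq(1, 3 * N, 3)] <- runif(N, -4, 4)
      s[seq(2, 3 * N, 3)] <- runif(N, -4, 4)
      s[seq(3, 3 * N, 3)] <- runif(N, 0, 0.5)
      s
    })
  }
  res <- rossler_rk4_cpp(net_edges(net), params$values, d, state0,
                         rossler_defaults$a, rossler_defaults$b, rossler_defaults$c,
                         dt, as.integer(round(transient / dt)),
                         as.integer(n_steps), as.integer(phase_stride),
                         store_series, as.integer(series_stride))
  out <- new_simulation_run("rossler", d,
                            meta = list(N = N, dt = dt, transient = transient,
                                        n_steps = n_steps, phase_stride = phase_stride,
                                        seed = seed),
                            minima = res$minima, minima_t = res$minima_t,
                            theta = res$theta, final_state = res$final_state)
  if (store_series) out$series <- res$series
  out
}

#' Isolated Chialvo map orbit
#'
#' Single uncoupled neuron, convenient for inspecting the spiking regime and
#' for generating test fixtures.
#'
#' @param I bias current.
#' @param n_iters retained iterations.
#' @param transient_iters discarded iterations.
#' @param x0,y0 initial state.
#' @return list with `x` series, spike `maxima` values and `maxima_t` indices.
#' @export
chialvo_orbit <- function(I, n_iters = 5000L, transient_iters = 1000L,
                          x0 = 0.5, y0 = 0.5) {
  e <- matrix(integer(0), 0, 2)
  res <- chialvo_cpp(e, I, 0, x0, y0,
                     chialvo_defaults$a, chialvo_defaults$b, chialvo_defaults$c,
                     as.integer(transient_iters), as.integer(n_iters), 0.5, TRUE)
  list(x = drop(res$x), maxima = res$maxima[[1]], maxima_t = res$maxima_t[[1]])
}

#' Isolated Roessler orbit
#'
#' @param w frequency parameter.
#' @param t_max retained time units.
#' @param dt integration step.
#' @param transient discarded time units.
#' @param state0 initial `(x, y, z)`.
#' @return list with `time`, `x`, `y`, `z` (at `dt` spacing) and the
#'   y-minima values.
#' @export
rossler_orbit <- function(w, t_max = 500, dt = 0.01, transient = 200,
                          state0 = c(1, 1, 0.1)) {
  e <- matrix(integer(0), 0, 2)
  n <- as.integer(round(t_max / dt))
  res <- rossler_rk4_cpp(e, w, 0, state0,
                         rossler_defaults$a, rossler_defaults$b, rossler_defaults$c,
                         dt, as.integer(round(transient / dt)), n, 1L, TRUE, 1L)
  list(time = (seq_len(n) - 1L) * dt,
       x = res$series[, 1], y = res$series[, 2], z = res$series[, 3],
       minima = res$minima[[1]], minima_t = res$minima_t[[1]])
}

# vector fields / map exposed at R level (oracles, convergence checks)
kuramoto_rhs_r <- function(theta, omega, adjacency, d) {
  s <- sin(outer(theta, theta, function(a, b) b - a))  # s[i, j] = sin(th_j - th_i)
  omega + d * rowSums(adjacency * s)
}

rossler_rhs_r <- function(state, w, a = rossler_defaults$a,
                          b = rossler_defaults$b, c = rossler_defaults$c) {
  c(-w * state[2] - state[3],
    w * state[1] + a * state[2],
    b + state[3] * (state[1] - c))
}

chialvo_step_r <- function(x, y, I, a = chialvo_defaults$a,
                           b = chialvo_defaults$b, c = chialvo_defaults$c) {
  c(x^2 * exp(y - x) + I, a * y - b * x + c)
}

#' Spike phase of a Chialvo membrane-potential series
#'
#' The phase advances by `2 pi` at every spike and is linearly interpolated
#' between consecutive spike times: for `t_n <= t < t_{n+1}`,
#' `theta(t) = 2 pi n + 2 pi (t - t_n) / (t_{n+1} - t_n)` with `n` counting
#' spikes from 0. Spikes are strict local maxima of `x` above
#' `spike_threshold`. Outside the first/last spike the phase is `NA`.
#'
#' @param x membrane-potential series.
#' @param spike_threshold spike gate (default 0.5).
#' @return numeric vector of phases, same length as `x`.
#' @export
chialvo_phase <- function(x, spike_threshold = 0.5) {
  ps <- poincare_section(x, kind = "maxima", threshold = spike_threshold)
  spike_phase(ps$indices, seq_along(x))
}

# Eq.-13-style piecewise-linear phase from spike times, evaluated at t_eval.
# NA outside [first spike, last spike).
spike_phase <- function(spike_times, t_eval) {
  if (length(spike_times) < 2L)
    stop("phase undefined: need at least 2 spikes", call. = FALSE)
  n <- findInterval(t_eval, spike_times)  # 0 before first spike
  out <- rep(NA_real_, length(t_eval))
  ok <- n >= 1L & n < length(spike_times)
  tn <- spike_times[n[ok]]
  tn1 <- spike_times[n[ok] + 1L]
  out[ok] <- 2 * pi * (n[ok] - 1L) + 2 * pi * (t_eval[ok] - tn) / (tn1 - tn)
  at_last <- t_eval == spike_times[length(spike_times)]
  out[at_last] <- 2 * pi * (length(spike_times) - 1L)
  out
}

#' Geometric phase of a Roessler-like rotation
#'
#' Quadrant-aware angle `atan2(y, x)`, unwrapped to a continuous phase.
#' Samples with `x = y = 0` inherit the previous angle.
#'
#' @param x,y coordinate series of equal length.
#' @return unwrapped phase series.
#' @export
rossler_phase <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length", call. = FALSE)
  th <- atan2(y, x)
  zero <- x == 0 & y == 0
  if (any(zero)) {
    for (i in which(zero)) th[i] <- if (i > 1L) th[i - 1L] else 0
  }
  unwrap_phase(th)
}

unwrap_phase <- function(th) {
  if (length(th) < 2L) return(th)
  d <- diff(th)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(th[1], th[1] + cumsum(d))
}
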