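# Forward/backward adiabatic continuation in the coupling strength d.
# The stationary state at each grid point seeds the next one, which is what
# makes the hysteresis loop of an explosive transition observable.

#' Phase order parameter
#'
#' Modulus of the population-mean unit phasor, time-averaged:
#' `R = < |mean_j exp(i theta_j(t))| >_t`. `R = 1` for identical phases,
#' `R -> 0` for incoherent ones.
#'
#' @param phases numeric matrix (rows = time, columns = nodes) or a vector
#'   treated as a single snapshot. Rows containing `NA` are dropped.
#' @return scalar in `[0, 1]` (`NA` if no complete rows).
#' @export
order_parameter <- function(phases) {
  if (is.null(dim(phases))) phases <- matrix(phases, nrow = 1L)
  if (!is.numeric(phases)) stop("phases must be numeric", call. = FALSE)
  ok <- rowSums(is.na(phases)) == 0L
  if (!any(ok)) return(NA_real_)
  z <- exp(1i * phases[ok, , drop = FALSE])
  mean(Mod(rowMeans(z)))
}

sweep_defaults <- function(family) {
  base <- list(D = 3L, tau = 1L, block_mode = "disjoint", T_samples = 2000L,
               warn_short = FALSE)
  extra <- switch(family,
    kuramoto = list(dt = 0.01, sample_stride = 200L, transient = 500),
    chialvo = list(transient_iters = 5000L, iters_per_sample = 45L,
                   spike_threshold = 0.5, phase_grid_stride = 5L),
    rossler = list(dt = 0.01, transient = 500, steps_per_sample = 700L,
                   phase_stride = 20L))
  c(base, extra)
}

new_sweep_result <- function(direction, d, R, nodes, family, net, seed,
                             control, final_state = NULL, partial = FALSE) {
  structure(list(direction = direction, d = d, R = R, nodes = nodes,
                 family = family, degrees = net$degrees, seed = seed,
                 control = control, final_state = final_state,
                 partial = partial),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s %s sweep, %d grid points%s\n",
              x$family, x$direction, length(x$d),
              if (x$partial) " (PARTIAL: integration failed)" else ""))
  if (length(x$d))
    cat(sprintf("  d in [%g, %g], R in [%.3f, %.3f]\n",
                min(x$d), max(x$d), min(x$R), max(x$R)))
  invisible(x)
}

# per-node observables at one coupling point; returns list(R, df, state)
sweep_point <- function(net, params, d, state, ctl, seed_point) {
  family <- params$family
  N <- net$n_nodes
  if (family == "kuramoto") {
    run <- simulate_kuramoto(net, params, d, T_samples = ctl$T_samples,
                             dt = ctl$dt, transient = ctl$transient,
                             sample_stride = ctl$sample_stride,
                             theta0 = state, seed = seed_point)
    series <- lapply(seq_len(N), function(i) run$freq[, i])
    R <- order_parameter(run$theta)
    state_out <- run$final_state
  } else if (family == "chialvo") {
    n_iters <- as.integer(ctl$T_samples * ctl$iters_per_sample)
    run <- simulate_chialvo(net, params, d, n_iters = n_iters,
                            transient_iters = ctl$transient_iters,
                            spike_threshold = ctl$spike_threshold,
                            state0 = state, seed = seed_point)
    series <- lapply(seq_len(N), function(i) {
      v <- run$maxima[[i]]
      if (length(v) > ctl$T_samples) v[seq_len(ctl$T_samples)] else v
    })
    R <- chialvo_order_parameter(run$maxima_t, n_iters, ctl$phase_grid_stride)
    state_out <- run$final_state
  } else {
    n_steps <- as.integer(ctl$T_samples * ctl$steps_per_sample)
    run <- simulate_rossler(net, params, d, n_steps = n_steps, dt = ctl$dt,
                            transient = ctl$transient,
                            phase_stride = ctl$phase_stride,
                            state0 = state, seed = seed_point)
    series <- lapply(seq_len(N), function(i) {
      v <- run$minima[[i]]
      if (length(v) > ctl$T_samples) v[seq_len(ctl$T_samples)] else v
    })
    R <- order_parameter(run$theta)
    state_out <- run$final_state
  }
  ent <- lapply(series, function(v) {
    series_entropies(v, D = ctl$D, tau = ctl$tau, block_mode = ctl$block_mode,
                     warn_short = ctl$warn_short)
  })
  df <- data.frame(
    d = d, node = seq_len(N), degree = net$degrees,
    H = vapply(ent, `[[`, numeric(1), "H"),
    HT = vapply(ent, `[[`, numeric(1), "HT"),
    sigma_f = vapply(series, function(v) if (length(v) >= 2) fluctuation_std(v) else NA_real_, numeric(1)),
    ac1 = vapply(series, function(v) {
      if (length(v) < 3) return(NA_real_)
      suppressWarnings(autocorrelation_lag(v, 1L))
    }, numeric(1)))
  list(R = R, df = df, state = state_out)
}

# order parameter from spike times via the piecewise-linear spike phase
chialvo_order_parameter <- function(maxima_t, n_iters, stride) {
  if (any(vapply(maxima_t, length, integer(1)) < 2L)) return(NA_real_)
  lo <- max(vapply(maxima_t, function(t) t[1], integer(1)))
  hi <- min(vapply(maxima_t, function(t) t[length(t)], integer(1)))
  if (hi <= lo) return(NA_real_)
  grid <- seq(lo, hi, by = stride)
  ph <- vapply(maxima_t, function(t) spike_phase(t, grid), numeric(length(grid)))
  order_parameter(ph)
}

aligned_state <- function(net, family) {
  N <- net$n_nodes
  switch(family,
         kuramoto = rep(0, N),
         chialvo = list(x = rep(0.5, N), y = rep(0.5, N)),
         rossler = rep(c(1, 1, 0.1), N))
}

#' Adiabatic coupling sweep
#'
#' Runs the model along a grid of coupling strengths, carrying the final
#' state of each point over as the initial condition of the next. Forward
#' sweeps ascend the grid from a random initial condition; backward sweeps
#' descend it starting from an aligned (synchronous) state at the largest
#' coupling. At each point the order parameter `R` and, per node, the
#' normalized permutation entropy `H`, the OPT entropy `HT`, the fluctuation
#' standard deviation and the lag-1 autocorrelation are computed from the
#' family's observable series (Kuramoto: sampled instantaneous frequency;
#' Chialvo: spike-maxima sequence; Roessler: Poincare minima of `y`).
#'
#' @param net a `network_spec`.
#' @param params a `node_params` for one of the three families.
#' @param d_grid coupling grid (given in increasing order).
#' @param direction `"forward"` or `"backward"`.
#' @param seed RNG seed for the initial condition of the first grid point.
#' @param control named list overriding the family defaults: `D`, `tau`,
#'   `block_mode`, `T_samples`, and the family's integration settings (see
#'   the simulators). `T_samples` is the length of the analyzed series per
#'   node and grid point.
#' @return a `sweep_result`; on an integration failure the points computed
#'   so far are returned with `partial = TRUE` (with a warning).
#' @export
run_sweep <- function(net, params, d_grid, direction = c("forward", "backward"),
                      seed = NULL, control = list()) {
  stopifnot(inherits(net, "network_spec"), inherits(params, "node_params"))
  direction <- match.arg(direction)
  ctl <- utils::modifyList(sweep_defaults(params$family), control)
  d_grid <- sort(as.numeric(d_grid))
  if (direction == "backward") d_grid <- rev(d_grid)
  if (length(d_grid) == 0L)
    return(new_sweep_result(direction, numeric(0), numeric(0),
                            data.frame(), params$family, net, seed, ctl))
  state <- if (direction == "forward") NULL else aligned_state(net, params$family)
  R <- numeric(0)
  rows <- list()
  partial <- FALSE
  for (k in seq_along(d_grid)) {
    pt <- tryCatch(
      sweep_point(net, params, d_grid[k], state, ctl,
                  seed_point = if (k == 1L) seed else NULL),
      error = function(e) e)
    if (inherits(pt, "error")) {
      warning(sprintf("sweep aborted at d = %g: %s", d_grid[k],
                      conditionMessage(pt)), call. = FALSE)
      partial <- TRUE
      d_grid <- d_grid[seq_len(k - 1L)]
      break
    }
    R[k] <- pt$R
    rows[[k]] <- pt$df
    state <- pt$state
  }
  new_sweep_result(direction, d_grid, R, do.call(rbind, rows),
                   params$family, net, seed, ctl, final_state = state,
                   partial = partial)
}

#' Critical coupling of an abrupt transition
#'
#' Scans the order-parameter curve in sweep order for the first grid step
#' whose change in `R` (rise for forward sweeps, drop for backward ones)
#' exceeds `jump_threshold`, and returns the coupling at which the jumped
#' state first appears. If no step exceeds the threshold the sweep is
#' flagged non-explosive and the coupling of the largest step is returned
#' (first index on ties).
#'
#' @param sr a `sweep_result` with at least 2 grid points.
#' @param jump_threshold minimum one-step change in `R` that counts as a
#'   jump (default 0.4).
#' @return list of class `"critical_coupling"`: `d`, `explosive`, `jump`
#'   (the step size), `index`.
#' @export
critical_coupling <- function(sr, jump_threshold = 0.4) {
  stopifnot(inherits(sr, "sweep_result"))
  if (length(sr$d) < 2L) stop("need at least 2 grid points", call. = FALSE)
  dR <- diff(sr$R)
  if (sr$direction == "backward") dR <- -dR
  hit <- which(dR > jump_threshold)
  if (length(hit)) {
    i <- hit[1L] + 1L
    out <- list(d = sr$d[i], explosive = TRUE, jump = dR[hit[1L]], index = i)
  } else {
    i <- which.max(dR) + 1L
    out <- list(d = sr$d[i], explosive = FALSE, jump = max(dR), index = i)
  }
  structure(out, class = "critical_coupling")
}

#' @export
print.critical_coupling <- function(x, ...) {
  cat(sprintf("<critical_coupling> d_c = %g (%s, step %.3f)\n",
              x$d, if (x$explosive) "explosive" else "non-explosive", x$jump))
  invisible(x)
}

#' Hysteresis width between forward and backward transitions
#'
#' Difference between the forward (synchronization) and backward
#' (desynchronization) critical couplings, floored at zero. Both sweeps must
#' be classified explosive; otherwise the width is undefined and `NA` is
#' returned with a warning.
#'
#' @param forward,backward `sweep_result` or `critical_coupling` objects.
#' @param jump_threshold passed to [critical_coupling()] when sweeps are given.
#' @return nonnegative scalar, or `NA` if either transition is non-explosive.
#' @export
hysteresis_width <- function(forward, backward, jump_threshold = 0.4) {
  as_cc <- function(x) {
    if (inherits(x, "critical_coupling")) x
    else critical_coupling(x, jump_threshold)
  }
  f <- as_cc(forward); b <- as_cc(backward)
  if (!f$explosive || !b$explosive) {
    warning("hysteresis width undefined: at least one sweep is non-explosive",
            call. = FALSE)
    return(NA_real_)
  }
  max(0, f$d - b$d)
}

#' Repeat a sweep over independent realizations
#'
#' Re-runs [run_sweep()] `n_seeds` times. Star networks keep their topology
#' but redraw the quenched leaf disorder and initial conditions per
#' realization; scale-free topologies are redrawn entirely (independent
#' network realizations).
#'
#' @param family `"kuramoto"`, `"chialvo"` or `"rossler"`.
#' @param topology `"star"` or `"scale_free"`.
#' @param N nodes (star: exact; scale-free: before simplification).
#' @param d_grid coupling grid.
#' @param direction sweep direction.
#' @param n_seeds number of realizations.
#' @param seed base seed; realization `r` uses `seed + r`.
#' @param mean_degree,gamma scale-free generator settings.
#' @param alpha,xi heterogeneity settings (see [assign_heterogeneity()]).
#' @param control sweep control overrides (see [run_sweep()]).
#' @return object of class `"sweep_ensemble"`: list of `sweep_result`s plus
#'   the generating settings.
#' @export
run_sweep_ensemble <- function(family, topology = c("star", "scale_free"), N,
                               d_grid, direction = "forward", n_seeds = 10L,
                               seed = 1L, mean_degree = 4, gamma = 2.25,
                               alpha = NULL, xi = NULL, control = list()) {
  topology <- match.arg(topology)
  sweeps <- vector("list", n_seeds)
  for (r in seq_len(n_seeds)) {
    s <- seed + r
    net <- if (topology == "star") build_star(N)
           else build_scale_free(N, mean_degree, gamma, seed = s)
    params <- assign_heterogeneity(net, family, alpha = alpha, xi = xi, seed = s)
    sweeps[[r]] <- run_sweep(net, params, d_grid, direction, seed = s,
                             control = control)
  }
  structure(list(sweeps = sweeps, family = family, topology = topology,
                 N = N, direction = direction, seed = seed),
            class = "sweep_ensemble")
}

#' @export
print.sweep_ensemble <- function(x, ...) {
  cat(sprintf("<sweep_ensemble> %s on %s (N = %d), %d realization(s), %s\n",
              x$family, x$topology, x$N, length(x$sweeps), x$direction))
  invisible(x)
}

#' Realization-averaged summary of a sweep ensemble
#'
#' @param object a `sweep_ensemble`.
#' @param ... unused.
#' @return list with `R` (data.frame `d`, `R` averaged over realizations)
#'   and `classes` (data.frame `d`, `k`, `N_k`, `H`, `HT`, `sigma_f`, `ac1`,
#'   node values pooled by degree across realizations).
#' @export
summary.sweep_ensemble <- function(object, ...) {
  nodes <- do.call(rbind, lapply(object$sweeps, `[[`, "nodes"))
  Rdf <- do.call(rbind, lapply(object$sweeps, function(s)
    data.frame(d = s$d, R = s$R)))
  Rmean <- aggregate(R ~ d, Rdf, mean, na.action = stats::na.omit)
  cls <- aggregate(cbind(H, HT, sigma_f, ac1) ~ d + degree, nodes, mean,
                   na.action = stats::na.omit)
  sizes <- aggregate(node ~ d + degree, nodes, length)
  names(sizes)[3] <- "N_k"
  cls <- merge(cls, sizes, by = c("d", "degree"))
  names(cls)[names(cls) == "degree"] <- "k"
  cls <- cls[order(cls$d, cls$k), c("d", "k", "N_k", "H", "HT", "sigma_f", "ac1")]
  rownames(cls) <- NULL
  list(R = Rmean[order(Rmean$d), ], classes = cls)
}

#' @importFrom stats aggregate
NULL
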