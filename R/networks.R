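# Topologies and degree-correlated heterogeneity assignments.
# Star and scale-free graphs are the two structures on which degree-frequency
# correlation induces explosive synchronization.

new_network_spec <- function(adjacency, topology, seed = NULL) {
  degrees <- as.integer(rowSums(adjacency))
  structure(list(n_nodes = nrow(adjacency),
                 adjacency = adjacency,
                 degrees = degrees,
                 k_max = max(degrees),
                 topology = topology,
                 seed = seed),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %s, N = %d, <k> = %.2f, k_max = %d\n",
              x$topology, x$n_nodes, mean(x$degrees), x$k_max))
  invisible(x)
}

#' Star network
#'
#' Hub-and-spokes graph: node 1 is the hub (degree `N - 1`), nodes
#' `2..N` are leaves of degree 1. With degree-correlated node parameters this
#' is the minimal topology displaying explosive synchronization.
#'
#' @param N number of nodes, `>= 3`.
#' @return a `network_spec` (symmetric 0/1 adjacency, zero diagonal).
#' @export
#' @examples
#' build_star(31)
build_star <- function(N) {
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 3L) stop("N must be >= 3", call. = FALSE)
  A <- matrix(0L, N, N)
  A[1, 2:N] <- 1L
  A[2:N, 1] <- 1L
  new_network_spec(A, topology = "star")
}

#' Scale-free network via the configuration model
#'
#' Samples a truncated power-law degree sequence `P(k) ~ k^-gamma` on
#' `[k_min, floor(sqrt(N * mean_degree))]`, with `k_min` chosen so that the
#' expected degree matches `mean_degree`, wires it with the configuration
#' model, removes self-loops and multi-edges, and keeps the largest connected
#' component. Resamples (up to `max_tries`) until the realized mean degree is
#' within 15% of the target.
#'
#' @param N number of nodes before simplification, `>= 10`.
#' @param mean_degree target mean degree (default 4).
#' @param gamma power-law exponent of the degree distribution (default 2.25).
#' @param seed optional RNG seed (local to this call).
#' @param max_tries resampling attempts before giving up.
#' @return a `network_spec`; `n_nodes` can be slightly below `N` because only
#'   the giant component is kept.
#' @export
build_scale_free <- function(N, mean_degree = 4, gamma = 2.25, seed = NULL,
                             max_tries = 100L) {
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 10L) stop("N must be >= 10", call. = FALSE)
  with_local_seed(seed, {
    # natural cutoff N^(1/(gamma-1)): keeps the empirical CCDF a clean power
    # law over the fitted range and lets the largest hubs reach the degrees
    # where sentinel behaviour is expected
    k_cap <- max(min(N - 1L, floor(N^(1 / (gamma - 1)))),
                 ceiling(mean_degree) + 1L)
    # smallest k_min whose truncated power-law mean reaches the target
    k_min_best <- 1L
    err_best <- Inf
    for (k_min in seq_len(k_cap - 1L)) {
      ks <- k_min:k_cap
      m <- sum(ks^(1 - gamma)) / sum(ks^(-gamma))
      if (abs(m - mean_degree) < err_best) {
        err_best <- abs(m - mean_degree)
        k_min_best <- k_min
      }
    }
    ks <- k_min_best:k_cap
    pk <- ks^(-gamma)
    for (try in seq_len(max_tries)) {
      deg <- sample(ks, N, replace = TRUE, prob = pk)
      if (sum(deg) %% 2L == 1L) deg[which.max(deg)] <- deg[which.max(deg)] + 1L
      g <- try(igraph::sample_degseq(deg, method = "configuration"), silent = TRUE)
      if (inherits(g, "try-error")) next
      g <- igraph::simplify(g)
      comp <- igraph::components(g)
      g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
      kk <- igraph::degree(g)
      if (abs(mean(kk) - mean_degree) <= 0.15 * mean_degree &&
          igraph::vcount(g) >= 10L) {
        A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
        storage.mode(A) <- "integer"
        out <- new_network_spec(A, topology = "scale_free", seed = seed)
        out$sampled_degrees <- deg  # pre-wiring power-law draw
        return(out)
      }
    }
    stop(sprintf("could not realize a scale-free graph with <k> = %g within %d attempts",
                 mean_degree, max_tries), call. = FALSE)
  })
}

# edge list (2-column, i < j) for the compiled integrators
net_edges <- function(net) {
  idx <- which(upper.tri(net$adjacency) & net$adjacency == 1L, arr.ind = TRUE)
  storage.mode(idx) <- "integer"
  unname(idx)
}

# evaluate `code` under a temporary RNG state when seed is non-NULL
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Degree-correlated node heterogeneity
#'
#' Assigns each node the internal parameter that sets its natural time scale:
#' the natural frequency `omega` for Kuramoto oscillators, the bias current
#' `I` for Chialvo maps, the frequency parameter `w` for Roessler
#' oscillators. Correlating this parameter with node degree is the standard
#' recipe for inducing explosive synchronization on heterogeneous graphs.
#'
#' Default rules:
#' * `kuramoto` + star: hub `omega = 1.3`, leaves `1 + 0.005 * eps` with
#'   `eps ~ U(0, 1)` (quenched disorder).
#' * `chialvo` + star: hub `I = 0.050`, leaves `0.049 + 1e-4 * eps`.
#' * `chialvo` + scale-free: `I = 0.049 + alpha * k`, `alpha = 3e-5`.
#' * `rossler`: `w = 1.06 + alpha * k`, `alpha = 2.73e-4`; on a star the
#'   leaves additionally receive jitter `U(0, xi)` (default `xi = 1e-4`),
#'   which keeps the backward branch able to desynchronize without closing
#'   the hub-leaf frequency gap.
#'
#' @param net a `network_spec`.
#' @param family `"kuramoto"`, `"chialvo"` or `"rossler"`.
#' @param alpha slope of the degree correlation; default depends on family.
#' @param xi width of the uniform leaf disorder on star graphs.
#' @param seed optional RNG seed (local to this call).
#' @return an object of class `"node_params"`: list with `family`, `values`
#'   (one parameter per node), `alpha`, `xi`, `seed`.
#' @export
assign_heterogeneity <- function(net, family = c("kuramoto", "chialvo", "rossler"),
                                 alpha = NULL, xi = NULL, seed = NULL) {
  stopifnot(inherits(net, "network_spec"))
  family <- match.arg(family)
  star <- net$topology == "star"
  N <- net$n_nodes
  values <- with_local_seed(seed, {
    switch(family,
      kuramoto = {
        if (is.null(xi)) xi <- 0.005
        if (star) {
          v <- 1 + xi * runif(N)
          v[1] <- 1.3
          v
        } else {
          if (is.null(alpha)) alpha <- 0.01
          1 + alpha * net$degrees
        }
      },
      chialvo = {
        if (star) {
          if (is.null(xi)) xi <- 1e-4
          v <- 0.049 + xi * runif(N)
          v[1] <- 0.050
          v
        } else {
          if (is.null(alpha)) alpha <- 3e-5
          0.049 + alpha * net$degrees
        }
      },
      rossler = {
        if (is.null(alpha)) alpha <- 2.73e-4
        v <- 1.06 + alpha * net$degrees
        if (star) {
          if (is.null(xi)) xi <- 1e-4
          v[2:N] <- v[2:N] + xi * runif(N - 1L)
        }
        v
      })
  })
  structure(list(family = family, values = values, alpha = alpha, xi = xi,
                 seed = seed),
            class = "node_params")
}

#' @export
print.node_params <- function(x, ...) {
  cat(sprintf("<node_params> %s, N = %d, range [%.6g, %.6g]\n",
              x$family, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}
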