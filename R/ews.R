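# Local early-warning indicators: degree-class OPT entropy averages, the
# comparison statistics (fluctuation SD, lag-1 autocorrelation), the
# hub-vs-leaf alarm rule and the degree-cutoff analysis.

#' Degree-class averages of a per-node quantity
#'
#' Arithmetic mean of a node-level value within each distinct degree class.
#' Nodes of equal degree play statistically equivalent roles in the network,
#' so class averages (e.g., `<HT>_k`) are the natural sentinel-node summary.
#'
#' @param values numeric vector, one value per node.
#' @param degrees integer vector of node degrees, same length.
#' @param d coupling at which the values were measured (metadata, optional).
#' @return object of class `"k_class_profile"`: data.frame with columns `k`,
#'   `N_k`, `mean`, plus attribute `d`.
#' @export
k_class_average <- function(values, degrees, d = NA_real_) {
  if (length(values) != length(degrees))
    stop("values and degrees must have the same length", call. = FALSE)
  ks <- sort(unique(degrees))
  out <- data.frame(
    k = ks,
    N_k = vapply(ks, function(k) sum(degrees == k), integer(1)),
    mean = vapply(ks, function(k) mean(values[degrees == k]), numeric(1)))
  structure(out, class = c("k_class_profile", "data.frame"), d = d)
}

#' Fluctuation standard deviation
#'
#' Population standard deviation `sqrt(<x^2> - <x>^2)` of a node's observable
#' series, a classical variance-based early-warning statistic.
#'
#' @param x numeric vector, `length(x) >= 2`.
#' @return nonnegative scalar (0 for a constant series).
#' @export
fluctuation_std <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  v <- mean(x^2) - mean(x)^2
  sqrt(max(v, 0))
}

#' Lag-l autocorrelation (uncentered)
#'
#' Normalized inner product
#' `sum_t x(t) x(t+l) / sqrt(sum_t x(t)^2 * sum_t x(t+l)^2)` over the
#' overlapping window, with no mean subtraction. Set `centered = TRUE` for
#' the conventional mean-subtracted variant.
#'
#' @param x numeric vector, `length(x) > l`.
#' @param l lag in samples (default 1).
#' @param centered subtract the series mean first (default `FALSE`).
#' @return scalar in `[-1, 1]`; `NA` with a warning if either window has
#'   zero norm.
#' @export
autocorrelation_lag <- function(x, l = 1L, centered = FALSE) {
  l <- as.integer(l)
  n <- length(x)
  if (n <= l) stop("series must be longer than the lag", call. = FALSE)
  if (centered) x <- x - mean(x)
  a <- x[seq_len(n - l)]
  b <- x[seq_len(n - l) + l]
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) {
    warning("zero-norm window: autocorrelation undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(a * b) / den
}

#' Hub-vs-reference early-warning trace
#'
#' Builds, along the coupling grid, the difference
#' `Delta(d) = <HT>_hub - <HT>_ref` between the most-connected degree class
#' and the least-connected (reference) class, the quantity on which the
#' alarm rule operates. Hub and reference classes are identified per
#' realization (each realization's own maximum/minimum degree) and averaged.
#'
#' @param ensemble a `sweep_ensemble` (or a single `sweep_result`).
#' @param measure node column to trace: `"HT"` (default), `"H"`,
#'   `"sigma_f"` or `"ac1"`.
#' @return object of class `"ews_trace"`: data.frame with columns `d`,
#'   `hub`, `ref`, `delta`.
#' @export
ews_trace <- function(ensemble, measure = c("HT", "H", "sigma_f", "ac1")) {
  measure <- match.arg(measure)
  sweeps <- if (inherits(ensemble, "sweep_ensemble")) ensemble$sweeps
            else if (inherits(ensemble, "sweep_result")) list(ensemble)
            else stop("need a sweep_ensemble or sweep_result", call. = FALSE)
  fml <- stats::as.formula(paste(measure, "~ d"))
  per <- lapply(sweeps, function(s) {
    nd <- s$nodes
    kmax <- max(nd$degree); kmin <- min(nd$degree)
    hub <- aggregate(fml, nd[nd$degree == kmax, ], mean,
                     na.action = stats::na.omit)
    ref <- aggregate(fml, nd[nd$degree == kmin, ], mean,
                     na.action = stats::na.omit)
    names(hub)[2] <- "hub"; names(ref)[2] <- "ref"
    merge(hub, ref, by = "d")
  })
  all <- do.call(rbind, per)
  out <- aggregate(cbind(hub, ref) ~ d, all, mean)
  out <- out[order(out$d), ]
  out$delta <- out$hub - out$ref
  rownames(out) <- NULL
  structure(out, class = c("ews_trace", "data.frame"), measure = measure)
}

#' Early-warning alarm on the hub-minus-reference entropy difference
#'
#' Estimates a baseline from the lowest-coupling grid points and raises an
#' alarm at the first coupling where `Delta(d)` exceeds
#' `baseline mean + n_sigma * baseline SD` and stays above it for
#' `persistence` consecutive grid points.
#'
#' @param trace an `ews_trace`, or a data.frame with columns `d` and `delta`,
#'   with at least 5 grid points.
#' @param n_sigma threshold multiplier (default 3).
#' @param baseline_n number of lowest-coupling points forming the baseline
#'   (default 3).
#' @param persistence consecutive exceedances required (default 2; suppresses
#'   single-point noise alarms).
#' @return object of class `"ews_alarm"`: list with `alarm_d` (`NA` if the
#'   alarm never fires), `index`, `threshold`, `baseline_mean`,
#'   `baseline_sd`, `n_sigma`, `persistence`.
#' @export
ews_alarm <- function(trace, n_sigma = 3, baseline_n = 3L, persistence = 2L) {
  if (!is.data.frame(trace) || !all(c("d", "delta") %in% names(trace)))
    stop("trace must have columns d and delta", call. = FALSE)
  o <- order(trace$d)
  d <- trace$d[o]; delta <- trace$delta[o]
  if (length(d) < 5L) stop("insufficient grid: need at least 5 points", call. = FALSE)
  base <- delta[seq_len(baseline_n)]
  m <- mean(base); s <- stats::sd(base)
  thr <- m + n_sigma * s
  above <- delta > thr
  above[is.na(above)] <- FALSE
  idx <- NA_integer_
  run_ok <- function(i) all(above[i:min(i + persistence - 1L, length(above))]) &&
    (i + persistence - 1L) <= length(above)
  for (i in seq(baseline_n + 1L, length(above))) {
    if (above[i] && run_ok(i)) { idx <- i; break }
  }
  structure(list(alarm_d = if (is.na(idx)) NA_real_ else d[idx],
                 index = idx, threshold = thr, baseline_mean = m,
                 baseline_sd = s, n_sigma = n_sigma, persistence = persistence),
            class = "ews_alarm")
}

#' @export
print.ews_alarm <- function(x, ...) {
  if (is.na(x$alarm_d))
    cat(sprintf("<ews_alarm> no alarm (threshold %.4g = mean %.4g + %g sd)\n",
                x$threshold, x$baseline_mean, x$n_sigma))
  else
    cat(sprintf("<ews_alarm> alarm at d = %g (threshold %.4g, %g sigma, persistence %d)\n",
                x$alarm_d, x$threshold, x$n_sigma, x$persistence))
  invisible(x)
}

#' Degree cutoff separating sensitive sentinel classes
#'
#' Compares two degree-class OPT entropy profiles, one far from the
#' transition and one near it, and returns the smallest degree above which
#' the near-transition profile exceeds the far one by more than `margin`
#' for every larger observed class. Nodes above this cutoff are candidate
#' early-warning sensors.
#'
#' @param profile_low `k_class_profile` measured at small coupling.
#' @param profile_near `k_class_profile` measured near (but before) the
#'   transition.
#' @param margin required excess in `<HT>_k` (default 0.05).
#' @return the cutoff degree, or `NA` if no class satisfies the condition.
#' @export
degree_cutoff <- function(profile_low, profile_near, margin = 0.05) {
  stopifnot(inherits(profile_low, "k_class_profile"),
            inherits(profile_near, "k_class_profile"))
  common <- intersect(profile_low$k, profile_near$k)
  if (length(common) == 0L)
    stop("profiles have disjoint degree supports", call. = FALSE)
  lo <- profile_low[match(common, profile_low$k), ]
  ne <- profile_near[match(common, profile_near$k), ]
  excess <- ne$mean - lo$mean
  ok <- excess > margin
  # largest suffix of degree classes that all exceed the margin
  tail_ok <- rev(cumprod(rev(ok))) == 1
  if (!any(tail_ok)) return(NA_real_)
  common[which(tail_ok)[1L]]
}

#' Normalize an entropy trace to its uncoupled baseline
#'
#' Elementwise division `HT(d) / HT(0)`, used to compare nodes whose
#' uncoupled entropies differ (e.g., experimental circuits).
#'
#' @param ht_series numeric vector of entropies along the coupling grid.
#' @param baseline_value entropy of the uncoupled system (`> 0`).
#' @return normalized series.
#' @export
normalize_entropy_trace <- function(ht_series, baseline_value) {
  if (!is.numeric(baseline_value) || length(baseline_value) != 1L ||
      is.na(baseline_value) || baseline_value <= 0)
    stop("baseline must be a positive scalar", call. = FALSE)
  ht_series / baseline_value
}
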