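#' @useDynLib optews, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm sd setNames
#' @importFrom utils read.table write.table packageVersion
"_PACKAGE"

max_pattern_length <- 7L

#' All permutations of 1..D in lexicographic order
#'
#' Helper enumerating the `D!` orderings that `D` distinct values can take.
#' Row `r` is the permutation of lexicographic rank `r` (1-based); ordinal
#' symbols produced by [encode_patterns()] index into this table.
#'
#' @param D pattern length, an integer in `[2, 7]`.
#' @return an integer matrix with `factorial(D)` rows and `D` columns.
#' @export
#' @examples
#' all_patterns(3)
all_patterns <- function(D) {
  all_patterns_raw(check_D(D))
}

# recursion body without argument checks (check_D rejects D < 2 for users)
all_patterns_raw <- function(D) {
  if (D == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_patterns_raw(D - 1L)
  out <- matrix(0L, factorial(D), D)
  row <- 1L
  for (first in seq_len(D)) {
    rest <- setdiff(seq_len(D), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

check_D <- function(D) {
  D <- as.integer(D)
  if (length(D) != 1L || is.na(D) || D < 2L || D > max_pattern_length)
    stop("D must be a single integer in [2, ", max_pattern_length, "]", call. = FALSE)
  D
}

# Lexicographic rank (1-based) of sorting permutations given as rows of `o`,
# via the Lehmer code: rank = 1 + sum_i #{j > i : o_j < o_i} * (D - i)!
lehmer_rank <- function(o) {
  D <- ncol(o)
  rank <- rep(1, nrow(o))
  for (i in seq_len(D - 1L)) {
    ci <- rep(0L, nrow(o))
    for (j in (i + 1L):D) ci <- ci + (o[, j] < o[, i])
    rank <- rank + ci * factorial(D - i)
  }
  as.integer(rank)
}

#' Construct a symbol sequence from precomputed ordinal symbols
#'
#' Mostly useful for feeding hand-crafted symbol streams into
#' [pattern_distribution()] and [transition_matrix()]; time series are
#' normally symbolized with [encode_patterns()].
#'
#' @param symbols integer vector with values in `[1, factorial(D)]`.
#' @param D pattern length the symbols refer to.
#' @param tau sampling lag metadata (default 1).
#' @param block_mode `"disjoint"` or `"overlapping"` (metadata).
#' @return an object of class `"symbol_sequence"`.
#' @export
symbol_sequence <- function(symbols, D, tau = 1L,
                            block_mode = c("disjoint", "overlapping")) {
  D <- check_D(D)
  block_mode <- match.arg(block_mode)
  symbols <- as.integer(symbols)
  if (anyNA(symbols) || any(symbols < 1L) || any(symbols > factorial(D)))
    stop("symbols must lie in [1, D!]", call. = FALSE)
  structure(list(symbols = symbols, D = D, tau = as.integer(tau),
                 block_mode = block_mode, L = length(symbols)),
            class = "symbol_sequence")
}

#' @export
print.symbol_sequence <- function(x, ...) {
  cat(sprintf("<symbol_sequence> D = %d, tau = %d, %s blocks, L = %d\n",
              x$D, x$tau, x$block_mode, x$L))
  invisible(x)
}

#' Symbolize a scalar time series into ordinal patterns
#'
#' Divides the series into blocks of `D` samples taken `tau` apart and maps
#' each block to the 1-based lexicographic rank of the permutation that sorts
#' it in ascending order. Ties are broken by temporal order: the earlier
#' sample receives the lower rank (stable sort). In `"disjoint"` mode blocks
#' advance by `tau * D` samples, giving `L = floor(T / (tau * D))` blocks; in
#' `"overlapping"` mode (the usual Bandt-Pompe stride of 1),
#' `L = T - (D - 1) * tau`.
#'
#' @param x numeric vector, the time series (all values finite).
#' @param D pattern length (embedding dimension), `2 <= D <= 7`.
#' @param tau sampling lag in samples, `>= 1`.
#' @param block_mode `"disjoint"` (default) or `"overlapping"`.
#' @param warn_short warn when `L < 10 * factorial(D)`, too few blocks for
#'   reliable pattern statistics. Default `TRUE`.
#' @return a [symbol_sequence()] object.
#' @seealso [pattern_distribution()], [transition_matrix()]
#' @export
#' @examples
#' encode_patterns(c(4, 7, 9), D = 3)$symbols    # fully ascending -> rank 1
#' encode_patterns(c(9, 7, 4), D = 3)$symbols    # fully descending -> rank 6
encode_patterns <- function(x, D = 3L, tau = 1L,
                            block_mode = c("disjoint", "overlapping"),
                            warn_short = TRUE) {
  D <- check_D(D)
  block_mode <- match.arg(block_mode)
  tau <- as.integer(tau)
  if (tau < 1L) stop("tau must be >= 1", call. = FALSE)
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("series contains non-finite values", call. = FALSE)
  n <- length(x)
  min_len <- if (block_mode == "disjoint") tau * D else (D - 1L) * tau + 1L
  if (n < min_len)
    stop(sprintf("series too short: need at least %d samples, got %d", min_len, n),
         call. = FALSE)
  if (block_mode == "disjoint") {
    L <- n %/% (tau * D)
    starts <- 1L + (seq_len(L) - 1L) * tau * D
  } else {
    L <- n - (D - 1L) * tau
    starts <- seq_len(L)
  }
  # block matrix: row = block, col = position within block
  idx <- outer(starts, (seq_len(D) - 1L) * tau, `+`)
  v <- matrix(x[idx], nrow = L, ncol = D)
  # stable ranks: earlier sample wins ties
  r <- matrix(1L, L, D)
  for (j in seq_len(D)) {
    for (k in seq_len(D)) {
      if (k == j) next
      r[, j] <- r[, j] + (v[, k] < v[, j]) + (k < j & v[, k] == v[, j])
    }
  }
  # sorting permutation o = inverse of the rank vector
  o <- matrix(0L, L, D)
  for (j in seq_len(D)) o[cbind(seq_len(L), r[, j])] <- j
  symbols <- lehmer_rank(o)
  if (warn_short && L < 10L * factorial(D))
    warning(sprintf("only L = %d blocks for D = %d; pattern statistics need L >> D! (say L >= %d)",
                    L, D, 10L * factorial(D)), call. = FALSE)
  symbol_sequence(symbols, D = D, tau = tau, block_mode = block_mode)
}

#' Ordinal pattern probability distribution
#'
#' Relative frequency of each of the `D!` patterns in a symbol sequence;
#' unobserved patterns get probability zero.
#'
#' @param s a [symbol_sequence()].
#' @return an object of class `"pattern_distribution"` with fields `probs`,
#'   `counts`, `D`, `L`.
#' @export
pattern_distribution <- function(s) {
  stopifnot(inherits(s, "symbol_sequence"))
  if (s$L < 1L) stop("empty symbol sequence", call. = FALSE)
  nf <- factorial(s$D)
  counts <- tabulate(s$symbols, nbins = nf)
  structure(list(probs = counts / s$L, counts = counts, D = s$D, L = s$L),
            class = "pattern_distribution")
}

#' @export
print.pattern_distribution <- function(x, ...) {
  cat(sprintf("<pattern_distribution> D = %d (%d patterns), L = %d, H = %.4f\n",
              x$D, length(x$probs), x$L, normalized_permutation_entropy(x)))
  invisible(x)
}

as_prob_vector <- function(P) {
  if (inherits(P, "pattern_distribution")) P$probs
  else if (is.numeric(P)) P
  else stop("P must be a pattern_distribution or a probability vector", call. = FALSE)
}

# Shannon entropy in nats with the 0 * log 0 = 0 convention
shannon <- function(p) {
  p <- p[p > 0]
  s <- -sum(p * log(p))
  if (s <= 0) 0 else s  # avoid IEEE negative zero for degenerate inputs
}

#' Permutation entropy (nats)
#'
#' Shannon entropy of the ordinal pattern distribution, natural logarithm,
#' with the convention that zero-probability terms contribute nothing.
#'
#' @param P a `pattern_distribution` or a numeric probability vector.
#' @return nonnegative scalar, in nats.
#' @export
permutation_entropy <- function(P) shannon(as_prob_vector(P))

#' Normalized permutation entropy
#'
#' Permutation entropy divided by its maximum `log(D!)` (attained by the
#' uniform pattern distribution), so the result lies in `[0, 1]`.
#'
#' @inheritParams permutation_entropy
#' @return scalar in `[0, 1]`.
#' @export
normalized_permutation_entropy <- function(P) {
  p <- as_prob_vector(P)
  shannon(p) / log(length(p))
}

#' Ordinal pattern transition matrix
#'
#' Conditional probabilities `p[l, m]` that pattern `m` immediately follows
#' pattern `l` in the symbol sequence, including self-transitions. Source
#' counts exclude the final symbol (which has no successor). Rows of patterns
#' never observed as a source are identically zero.
#'
#' @param s a [symbol_sequence()] with at least two symbols.
#' @return an object of class `"transition_matrix"` with fields `probs`
#'   (`D! x D!`), `pair_counts`, `pattern_counts` (source occurrences), `D`.
#' @export
transition_matrix <- function(s) {
  stopifnot(inherits(s, "symbol_sequence"))
  if (s$L < 2L) stop("need at least 2 symbols for transitions", call. = FALSE)
  nf <- factorial(s$D)
  from <- s$symbols[-s$L]
  to <- s$symbols[-1L]
  pair_counts <- matrix(tabulate((to - 1L) * nf + from, nbins = nf * nf), nf, nf)
  pattern_counts <- tabulate(from, nbins = nf)
  probs <- pair_counts / ifelse(pattern_counts > 0L, pattern_counts, 1L)
  structure(list(probs = probs, pair_counts = pair_counts,
                 pattern_counts = pattern_counts, D = s$D),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> D = %d (%d x %d), observed source patterns: %d, HT = %.4f\n",
              x$D, nrow(x$probs), ncol(x$probs), sum(x$pattern_counts > 0),
              opt_entropy(x)))
  invisible(x)
}

#' Local (per-pattern) transition entropy
#'
#' Normalized Shannon entropy of the successor distribution of one pattern:
#' how unpredictable the next ordinal pattern is, given the current one is
#' `l`. Patterns never observed as a source have entropy 0.
#'
#' @param M a [transition_matrix()].
#' @param l pattern index in `[1, D!]`.
#' @return scalar in `[0, 1]`.
#' @export
local_pattern_entropy <- function(M, l) {
  stopifnot(inherits(M, "transition_matrix"))
  nf <- nrow(M$probs)
  l <- as.integer(l)
  if (length(l) != 1L || is.na(l) || l < 1L || l > nf)
    stop(sprintf("pattern index must be in [1, %d]", nf), call. = FALSE)
  shannon(M$probs[l, ]) / log(nf)
}

#' Ordinal pattern transition (OPT) entropy
#'
#' Plain average over all `D!` patterns of their local transition entropies,
#' including the zero contributions of unobserved patterns. A perfectly
#' predictable symbol stream (e.g., periodic) gives 0; an i.i.d. uniform
#' stream approaches 1. Because missing patterns contribute zeros, series
#' that visit few patterns have deflated OPT entropy by construction.
#'
#' @param M a [transition_matrix()].
#' @return scalar in `[0, 1]`.
#' @export
opt_entropy <- function(M) {
  stopifnot(inherits(M, "transition_matrix"))
  nf <- nrow(M$probs)
  mean(vapply(seq_len(nf), function(l) shannon(M$probs[l, ]), numeric(1))) / log(nf)
}

#' Poincare section by strict local extrema
#'
#' Reduces a signal to the discrete sequence of its strict local maxima (or
#' minima), the usual Poincare-section surrogate for oscillatory and spiking
#' signals. An extremum is a sample strictly above (below) both neighbours;
#' plateaus therefore yield no extremum. For maxima an optional `threshold`
#' keeps only values `> threshold` (e.g., 0.5 to isolate spikes of a Chialvo
#' neuron); for minima it keeps values `< threshold`.
#'
#' @param x numeric vector, `length(x) >= 3`.
#' @param kind `"maxima"` or `"minima"`.
#' @param threshold optional amplitude gate (see above).
#' @return an object of class `"poincare_series"` with fields `values`,
#'   `indices` (sample positions, strictly increasing), `kind`, `threshold`.
#'   May be empty (e.g., for monotone input); this is not an error.
#' @export
poincare_section <- function(x, kind = c("maxima", "minima"), threshold = NULL) {
  kind <- match.arg(kind)
  x <- as.numeric(x)
  if (length(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (!all(is.finite(x))) stop("series contains non-finite values", call. = FALSE)
  mid <- 2:(length(x) - 1L)
  hit <- if (kind == "maxima") x[mid] > x[mid - 1L] & x[mid] > x[mid + 1L]
         else                  x[mid] < x[mid - 1L] & x[mid] < x[mid + 1L]
  idx <- mid[hit]
  val <- x[idx]
  if (!is.null(threshold)) {
    keep <- if (kind == "maxima") val > threshold else val < threshold
    idx <- idx[keep]; val <- val[keep]
  }
  structure(list(values = val, indices = idx, kind = kind,
                 threshold = threshold),
            class = "poincare_series")
}

#' @export
print.poincare_series <- function(x, ...) {
  cat(sprintf("<poincare_series> %d %s%s\n", length(x$values), x$kind,
              if (is.null(x$threshold)) "" else sprintf(" (threshold %g)", x$threshold)))
  invisible(x)
}

#' Permutation and OPT entropy of a scalar series in one call
#'
#' Convenience pipeline: optional Poincare reduction, ordinal symbolization,
#' then both entropies. This is the per-node quantity tracked along coupling
#' sweeps.
#'
#' @inheritParams encode_patterns
#' @param poincare `"none"` (symbolize the raw series), `"maxima"` or
#'   `"minima"` (symbolize the extremum sequence, with `tau = 1`).
#' @param threshold amplitude gate passed to [poincare_section()].
#' @return list with `H` (normalized permutation entropy), `HT` (OPT
#'   entropy), `L` (number of blocks), and the `symbol_sequence`.
#'   If the reduced series is too short for even one transition, `H` and
#'   `HT` are `NA`.
#' @export
series_entropies <- function(x, D = 3L, tau = 1L,
                             block_mode = c("disjoint", "overlapping"),
                             poincare = c("none", "maxima", "minima"),
                             threshold = NULL, warn_short = TRUE) {
  poincare <- match.arg(poincare)
  block_mode <- match.arg(block_mode)
  if (poincare != "none") {
    ps <- poincare_section(x, kind = poincare, threshold = threshold)
    x <- ps$values
    tau <- 1L
  }
  D <- check_D(D)
  min_len <- if (block_mode == "disjoint") tau * D * 2L else (D - 1L) * tau + 2L
  if (length(x) < min_len)
    return(list(H = NA_real_, HT = NA_real_, L = 0L, symbols = NULL))
  s <- encode_patterns(x, D = D, tau = tau, block_mode = block_mode,
                       warn_short = warn_short)
  list(H = normalized_permutation_entropy(pattern_distribution(s)),
       HT = opt_entropy(transition_matrix(s)),
       L = s$L, symbols = s)
}
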