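# Brute-force oracles, written independently of the package internals:
# selection-sort symbolization, loop-based counting, permutations enumerated
# by filtering the full index grid.

# all permutations of 1..D, lexicographically sorted, via expand.grid filter
bf_all_perms <- function(D) {
  g <- as.matrix(expand.grid(rev(replicate(D, seq_len(D), simplify = FALSE))))
  g <- g[, rev(seq_len(D)), drop = FALSE]
  keep <- apply(g, 1, function(r) length(unique(r)) == D)
  p <- g[keep, , drop = FALSE]
  p[do.call(order, as.data.frame(p)), , drop = FALSE]
}

# sorting permutation by repeated minimum selection; ties -> earliest index
bf_sort_perm <- function(v) {
  idx <- seq_along(v)
  out <- integer(0)
  while (length(idx)) {
    best <- idx[1]
    for (i in idx) if (v[i] < v[best]) best <- i
    out <- c(out, best)
    idx <- setdiff(idx, best)
  }
  out
}

bf_symbolize <- function(x, D, tau, mode) {
  perms <- bf_all_perms(D)
  starts <- if (mode == "disjoint") {
    L <- floor(length(x) / (tau * D))
    if (L < 1) integer(0) else 1 + (0:(L - 1)) * tau * D
  } else {
    L <- length(x) - (D - 1) * tau
    if (L < 1) integer(0) else 1:L
  }
  vapply(starts, function(t0) {
    o <- bf_sort_perm(x[t0 + (0:(D - 1)) * tau])
    which(apply(perms, 1, function(p) all(p == o)))
  }, integer(1))
}

bf_distribution <- function(sym, nf) {
  counts <- integer(nf)
  for (s in sym) counts[s] <- counts[s] + 1
  counts / length(sym)
}

bf_transition <- function(sym, nf) {
  pair <- matrix(0L, nf, nf)
  src <- integer(nf)
  for (t in seq_len(length(sym) - 1)) {
    pair[sym[t], sym[t + 1]] <- pair[sym[t], sym[t + 1]] + 1L
    src[sym[t]] <- src[sym[t]] + 1L
  }
  probs <- matrix(0, nf, nf)
  for (l in seq_len(nf)) if (src[l] > 0) probs[l, ] <- pair[l, ] / src[l]
  probs
}

bf_H <- function(p) {
  pp <- p[p > 0]
  -sum(pp * log(pp)) / log(length(p))
}

bf_HT <- function(probs) {
  nf <- nrow(probs)
  hl <- vapply(seq_len(nf), function(l) {
    pp <- probs[l, ][probs[l, ] > 0]
    -sum(pp * log(pp))
  }, numeric(1))
  mean(hl) / log(nf)
}

# tiny star helper used across files
tiny_kuramoto <- function(N = 5, d = 0.01, T_samples = 50, seed = 1) {
  net <- build_star(N)
  params <- assign_heterogeneity(net, "kuramoto", seed = seed)
  simulate_kuramoto(net, params, d, T_samples = T_samples, transient = 10,
                    seed = seed)
}
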