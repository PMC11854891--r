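# Ordinal symbolization and the entropic quantities built on it.

test_that("monotone blocks map to the extreme lexicographic ranks", {
  expect_equal(encode_patterns(c(4, 7, 9), D = 3, warn_short = FALSE)$symbols, 1L)
  expect_equal(encode_patterns(c(9, 7, 4), D = 3, warn_short = FALSE)$symbols,
               factorial(3L))
  expect_equal(encode_patterns(1:16, D = 4, warn_short = FALSE)$symbols,
               rep(1L, 4))
})

test_that("ties are broken by temporal order (earlier sample ranks lower)", {
  # block (1, 1, 0): ascending order visits position 3 first, then (tied)
  # positions 1 and 2 in temporal order -> sorting permutation (3, 1, 2),
  # the 5th of the six permutations in lexicographic order
  expect_equal(encode_patterns(c(1, 1, 0), D = 3, warn_short = FALSE)$symbols, 5L)
  # all-equal block behaves as ascending
  expect_equal(encode_patterns(c(2, 2, 2), D = 3, warn_short = FALSE)$symbols, 1L)
})

test_that("block accounting matches the disjoint and overlapping formulas", {
  x <- rnorm(101)
  s1 <- encode_patterns(x, D = 3, tau = 2, block_mode = "disjoint", warn_short = FALSE)
  expect_equal(s1$L, floor(101 / 6))
  s2 <- encode_patterns(x, D = 3, tau = 2, block_mode = "overlapping", warn_short = FALSE)
  expect_equal(s2$L, 101 - 4)
  expect_error(encode_patterns(c(1, 2), D = 3), "too short")
  expect_error(encode_patterns(c(1, NA, 3, 4), D = 2), "non-finite")
})

test_that("i.i.d. uniform series visits all patterns at near-equal frequency", {
  set.seed(42)
  s <- encode_patterns(runif(2000), D = 3, block_mode = "disjoint")
  p <- pattern_distribution(s)
  expect_true(all(abs(p$probs - 1 / 6) < 0.05))
  expect_equal(sum(p$probs), 1, tolerance = 1e-12)
})

test_that("pattern distribution and entropies obey their closed forms", {
  p1 <- pattern_distribution(symbol_sequence(c(1, 1, 1), 3))
  expect_equal(p1$probs, c(1, 0, 0, 0, 0, 0))
  expect_equal(permutation_entropy(p1), 0)
  expect_equal(normalized_permutation_entropy(p1), 0)

  p2 <- pattern_distribution(symbol_sequence(c(1, 2, 1, 2), 3))
  expect_equal(p2$probs, c(0.5, 0.5, 0, 0, 0, 0))
  expect_equal(permutation_entropy(p2), log(2))
  expect_equal(normalized_permutation_entropy(p2), log(2) / log(6))

  expect_equal(permutation_entropy(rep(1 / 6, 6)), log(6))
  expect_equal(normalized_permutation_entropy(rep(1 / 6, 6)), 1)

  set.seed(7)
  p3 <- pattern_distribution(symbol_sequence(sample(1:6, 6000, TRUE), 3))
  expect_true(max(abs(p3$probs - 1 / 6)) < 0.03)
})

test_that("transition matrix rows are conditional successor distributions", {
  M <- transition_matrix(symbol_sequence(c(1, 2, 1, 2, 1), 3))
  expect_equal(M$probs[1, 2], 1)
  expect_equal(M$probs[2, 1], 1)
  expect_equal(sum(M$probs), 2)
  expect_equal(M$pattern_counts, c(2L, 2L, 0L, 0L, 0L, 0L))

  M2 <- transition_matrix(symbol_sequence(rep(1L, 4), 3))
  expect_equal(M2$probs[1, 1], 1)

  set.seed(11)
  s <- symbol_sequence(sample(1:6, 60000, TRUE), 3)
  M3 <- transition_matrix(s)
  expect_true(all(abs(M3$probs - 1 / 6) < 0.02))
  expect_error(transition_matrix(symbol_sequence(1L, 3)), "at least 2")
})

test_that("local pattern entropy handles deterministic, uniform and absent rows", {
  M <- transition_matrix(symbol_sequence(c(1, 2, 1, 2, 1), 3))
  expect_equal(local_pattern_entropy(M, 1), 0)   # deterministic successor
  expect_equal(local_pattern_entropy(M, 3), 0)   # never observed
  expect_error(local_pattern_entropy(M, 7), "index")
  expect_error(local_pattern_entropy(M, 0), "index")

  set.seed(12)
  s <- symbol_sequence(sample(1:6, 120000, TRUE), 3)
  Mu <- transition_matrix(s)
  expect_equal(local_pattern_entropy(Mu, 2), 1, tolerance = 1e-3)

  Mhalf <- Mu
  Mhalf$probs[1, ] <- c(0.5, 0.5, 0, 0, 0, 0)
  expect_equal(local_pattern_entropy(Mhalf, 1), log(2) / log(6))
})

test_that("OPT entropy spans its limits: periodic 0, uniform random near 1", {
  per <- transition_matrix(symbol_sequence(rep(c(1L, 2L), 50), 3))
  expect_equal(opt_entropy(per), 0)

  set.seed(13)
  rnd <- transition_matrix(symbol_sequence(sample(1:6, 60000, TRUE), 3))
  expect_gt(opt_entropy(rnd), 0.98)
  expect_lte(opt_entropy(rnd), 1)
})

test_that("entropies equal an independent brute-force recount", {
  set.seed(99)
  for (rep in 1:25) {
    D <- sample(2:4, 1)
    tau <- sample(1:2, 1)
    mode <- sample(c("disjoint", "overlapping"), 1)
    n <- sample(30:500, 1)
    x <- if (rep %% 2) rnorm(n) else sample(0:3, n, TRUE)  # ties included
    s <- encode_patterns(x, D, tau, mode, warn_short = FALSE)
    expect_identical(s$symbols, bf_symbolize(x, D, tau, mode))
    nf <- factorial(D)
    p <- pattern_distribution(s)
    expect_identical(p$probs, bf_distribution(s$symbols, nf))
    M <- transition_matrix(s)
    expect_identical(M$probs, bf_transition(s$symbols, nf))
    expect_identical(normalized_permutation_entropy(p), bf_H(p$probs))
    expect_identical(opt_entropy(M), bf_HT(M$probs))
  }
})

test_that("monotone series have zero permutation and OPT entropy", {
  for (n in c(12, 57, 301)) {
    e <- series_entropies(seq_len(n) + runif(n, 0, 0.4), warn_short = FALSE)
    expect_equal(e$H, 0)
    expect_equal(e$HT, 0)
  }
})

test_that("disjoint and overlapping modes agree on white noise at large n", {
  set.seed(21)
  x <- runif(1e5)
  pd <- pattern_distribution(encode_patterns(x, 3, 1, "disjoint"))
  po <- pattern_distribution(encode_patterns(x, 3, 1, "overlapping"))
  expect_true(max(abs(pd$probs - po$probs)) < 0.01)
})

test_that("entropy bounds hold for arbitrary symbol streams", {
  set.seed(31)
  for (i in 1:20) {
    s <- symbol_sequence(sample(1:6, sample(10:200, 1), TRUE,
                                prob = runif(6) + 0.05), 3)
    H <- normalized_permutation_entropy(pattern_distribution(s))
    HT <- opt_entropy(transition_matrix(s))
    expect_gte(H, 0); expect_lte(H, 1)
    expect_gte(HT, 0); expect_lte(HT, 1)
  }
})

test_that("Poincare section keeps strict extrema and honours the threshold", {
  x <- sin(0.1 * 0:999)
  ps <- poincare_section(x, "maxima")
  expect_true(all(abs(ps$values - 1) < 1e-2))
  expect_true(all(diff(ps$indices) > 0))

  expect_length(poincare_section(1:50, "maxima")$values, 0)
  expect_length(poincare_section(c(0, 1, 1, 0), "maxima")$values, 0)  # plateau

  y <- c(0, 1, 0, 0.4, 0, 2, 0)
  expect_equal(poincare_section(y, "maxima", threshold = 0.5)$values, c(1, 2))
  expect_equal(poincare_section(-y, "minima")$values, c(-1, -0.4, -2))
  expect_error(poincare_section(c(1, 2), "maxima"), "3 samples")
})

test_that("short-series guard warns instead of failing", {
  expect_warning(encode_patterns(rnorm(30), D = 3), "L >> D!")
  expect_silent(encode_patterns(rnorm(30), D = 3, warn_short = FALSE))
})
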