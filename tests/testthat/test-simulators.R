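# Fixed-step integrators for the three model families.

test_that("uncoupled Kuramoto oscillators keep their natural frequencies", {
  net <- build_star(5)
  params <- assign_heterogeneity(net, "kuramoto", seed = 1)
  run <- simulate_kuramoto(net, params, d = 0, T_samples = 40, transient = 5,
                           seed = 1)
  for (i in 1:5)
    expect_true(all(abs(run$freq[, i] - params$values[i]) < 1e-9))
})

test_that("two detuned oscillators lock above the classic critical coupling", {
  net <- build_star(3)  # path a-b-c; use nodes 1-2 via custom frequencies
  params <- assign_heterogeneity(net, "kuramoto", seed = 1)
  params$values <- c(1.0, 1.2, 1.2)
  run <- simulate_kuramoto(net, params, d = 0.25, T_samples = 200,
                           transient = 200, seed = 2)
  spread <- apply(run$freq, 1, function(r) max(r) - min(r))
  expect_true(mean(spread) < 1e-3)  # frequency-locked
})

test_that("the Kuramoto star frequency-locks far above the forward jump", {
  net <- build_star(31)
  params <- assign_heterogeneity(net, "kuramoto", seed = 3)
  run <- simulate_kuramoto(net, params, d = 0.09, T_samples = 100,
                           transient = 400, seed = 3)
  mf <- colMeans(run$freq)
  expect_lt(max(mf) - min(mf), 1e-3)
})

test_that("undirected coupling cancels pairwise in the frequency sum", {
  net <- build_star(9)
  params <- assign_heterogeneity(net, "kuramoto", seed = 4)
  run <- simulate_kuramoto(net, params, d = 0.02, T_samples = 50,
                           transient = 20, seed = 4)
  sums <- rowSums(run$freq)
  expect_true(all(abs(sums - sum(params$values)) < 1e-9))
})

test_that("halving the integration step leaves retained phases unchanged", {
  net <- build_star(7)
  params <- assign_heterogeneity(net, "kuramoto", seed = 5)
  th0 <- runif(7, -pi, pi)
  a <- simulate_kuramoto(net, params, 0.02, T_samples = 50, dt = 0.01,
                         transient = 100, sample_stride = 200L, theta0 = th0)
  b <- simulate_kuramoto(net, params, 0.02, T_samples = 50, dt = 0.005,
                         transient = 100, sample_stride = 400L, theta0 = th0)
  dphi <- (a$theta - b$theta + pi) %% (2 * pi) - pi
  expect_lt(max(abs(dphi)), 1e-5)
})

test_that("the Chialvo map iterates exactly and spikes faster at higher bias", {
  step <- optews:::chialvo_step_r(1, 1, I = 0.05)
  expect_equal(step, c(1.05, 0.57))  # x' = 1 * e^0 + 0.05, y' = 0.89 - 0.6 + 0.28

  o5 <- chialvo_orbit(0.05, n_iters = 8000)
  o6 <- chialvo_orbit(0.06, n_iters = 8000)
  expect_gt(length(o6$maxima), length(o5$maxima))
  expect_true(all(o5$maxima > 0.5))
})

test_that("uncoupled Chialvo nodes ignore the adjacency structure", {
  net <- build_star(6)
  params <- assign_heterogeneity(net, "chialvo", seed = 6)
  s0 <- list(x = runif(6), y = runif(6))
  a <- simulate_chialvo(net, params, 0, n_iters = 3000, state0 = s0)
  # permute the network (relabel leaves) but keep identical nodes/states
  perm_net <- build_star(6)
  b <- simulate_chialvo(perm_net, params, 0, n_iters = 3000, state0 = s0)
  expect_identical(a$maxima, b$maxima)
  expect_identical(a$final_state, b$final_state)
})

test_that("isolated Roessler orbit is bounded chaos with z reinjection bursts", {
  o <- rossler_orbit(1.06, t_max = 400, transient = 200)
  expect_true(all(is.finite(c(o$x, o$y, o$z))))
  expect_lt(max(abs(o$x)), 30)
  expect_gt(mean(o$z > 1), 0.05)   # episodic spiral-out excursions
  expect_lt(mean(o$z > 1), 0.6)
  expect_gt(length(o$minima), 50)
})

test_that("Roessler equilibria found from the reduced quadratic null the field", {
  a <- 0.165; b <- 0.4; c <- 8.5
  for (w in c(1.0, 1.06)) {
    # y* solves a y^2 + c w y + b = 0; x* = -(a/w) y*, z* = -w y*
    ys <- Re(polyroot(c(b, c * w, a)))
    for (y in ys) {
      st <- c(-(a / w) * y, y, -w * y)
      expect_lt(max(abs(optews:::rossler_rhs_r(st, w))), 1e-8)
    }
  }
})

test_that("Roessler rotation frequency increases with the frequency parameter", {
  wind <- function(w) {
    o <- rossler_orbit(w, t_max = 300, transient = 200)
    ph <- rossler_phase(o$x, o$y)
    (ph[length(ph)] - ph[1]) / 300
  }
  expect_gt(abs(wind(1.20)), abs(wind(1.06)))
})

test_that("simulation runs are bit-reproducible under identical seeds", {
  net <- build_star(8)
  pk <- assign_heterogeneity(net, "kuramoto", seed = 7)
  r1 <- simulate_kuramoto(net, pk, 0.01, T_samples = 30, transient = 10, seed = 9)
  r2 <- simulate_kuramoto(net, pk, 0.01, T_samples = 30, transient = 10, seed = 9)
  expect_identical(r1$freq, r2$freq)

  pr <- assign_heterogeneity(net, "rossler", seed = 7)
  s1 <- simulate_rossler(net, pr, 1e-3, n_steps = 20000, transient = 20, seed = 9)
  s2 <- simulate_rossler(net, pr, 1e-3, n_steps = 20000, transient = 20, seed = 9)
  expect_identical(s1$minima, s2$minima)
  expect_identical(s1$final_state, s2$final_state)
})

test_that("spike phases interpolate linearly and advance 2*pi per spike", {
  th <- optews:::spike_phase(c(0, 10, 20), c(0, 5, 10, 15, 20))
  expect_equal(th, c(0, pi, 2 * pi, 3 * pi, 4 * pi))
  expect_error(optews:::spike_phase(c(3), 1:10), "2 spikes")

  # constant-rate spiking -> linear phase
  x <- rep(0, 100); x[seq(5, 95, by = 10)] <- 1
  ph <- chialvo_phase(x, spike_threshold = 0.5)
  t_in <- which(!is.na(ph))
  expect_equal(diff(ph[t_in]), rep(2 * pi / 10, length(t_in) - 1))
})

test_that("geometric phase is quadrant-aware and unwraps continuously", {
  expect_equal(rossler_phase(1, 1), pi / 4)
  t <- seq(0, 20, by = 0.01)
  ph <- rossler_phase(cos(t), sin(t))
  expect_true(max(abs(ph - (t + ph[1]))) < 1e-6)
  # x = y = 0 carries the previous angle
  ph2 <- rossler_phase(c(1, 0, -1), c(0, 0, 0))
  expect_equal(ph2[2], ph2[1])
})

test_that("Chialvo divergence raises a stability error", {
  net <- build_star(3)
  params <- assign_heterogeneity(net, "chialvo", seed = 1)
  # absurd recovery-variable state overflows x' = x^2 exp(y - x)
  expect_error(simulate_chialvo(net, params, 0, n_iters = 1000,
                                state0 = list(x = c(1, 1, 1), y = c(800, 800, 800))),
               "diverged")
})
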