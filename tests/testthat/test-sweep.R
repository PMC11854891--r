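# Order parameter, adiabatic continuation, jump detection, hysteresis.

test_that("order parameter spans its limits and matches the random-phase law", {
  expect_equal(order_parameter(rep(1.3, 20)), 1)
  expect_equal(order_parameter(2 * pi * (0:30) / 31), 0, tolerance = 1e-12)

  set.seed(17)
  Rs <- replicate(1000, order_parameter(runif(31, 0, 2 * pi)))
  expect_equal(mean(Rs), sqrt(pi) / (2 * sqrt(31)), tolerance = 0.02)

  # global phase shift leaves R unchanged
  th <- matrix(runif(200), 20, 10)
  expect_equal(order_parameter(th), order_parameter(th + 1.234),
               tolerance = 1e-12)
  expect_error(order_parameter(letters), "numeric")
})

test_that("identical oscillators at strong coupling reach full synchrony", {
  net <- build_star(10)
  params <- assign_heterogeneity(net, "kuramoto", seed = 2)
  params$values <- rep(1, 10)
  run <- simulate_kuramoto(net, params, d = 1, T_samples = 50, transient = 200,
                           seed = 2)
  expect_gt(order_parameter(run$theta), 0.99)
})

test_that("critical coupling detection classifies steps and smooth ramps", {
  fake <- function(d, R, direction = "forward") {
    structure(list(direction = direction, d = d, R = R,
                   nodes = data.frame(), family = "kuramoto",
                   degrees = integer(0), seed = NULL, control = list(),
                   partial = FALSE), class = "sweep_result")
  }
  cc <- critical_coupling(fake(c(1, 2, 3), c(0.1, 0.1, 0.95)))
  expect_true(cc$explosive)
  expect_equal(cc$d, 3)

  ramp <- critical_coupling(fake(1:9, seq(0.1, 0.9, by = 0.1)))
  expect_false(ramp$explosive)

  flat <- critical_coupling(fake(1:5, rep(0.3, 5)))
  expect_false(flat$explosive)
  expect_equal(flat$d, 2)  # first index on ties

  # backward sweeps jump downward in sweep order
  bc <- critical_coupling(fake(c(3, 2, 1), c(0.95, 0.9, 0.2), "backward"))
  expect_true(bc$explosive)
  expect_equal(bc$d, 1)

  expect_error(critical_coupling(fake(1, 0.5)), "2 grid points")
})

test_that("hysteresis width is the floored distance between critical couplings", {
  cc <- function(d, expl) structure(list(d = d, explosive = expl, jump = 0.5,
                                         index = 2L), class = "critical_coupling")
  expect_equal(hysteresis_width(cc(0.9e-3, TRUE), cc(0.5e-3, TRUE)), 0.4e-3)
  expect_equal(hysteresis_width(cc(1, TRUE), cc(1, TRUE)), 0)
  expect_equal(hysteresis_width(cc(1, TRUE), cc(2, TRUE)), 0)  # floored
  expect_warning(w <- hysteresis_width(cc(1, FALSE), cc(0.5, TRUE)),
                 "non-explosive")
  expect_true(is.na(w))
})

test_that("a zero-length grid yields an empty sweep", {
  net <- build_star(5)
  params <- assign_heterogeneity(net, "kuramoto", seed = 1)
  sr <- run_sweep(net, params, numeric(0), "forward")
  expect_length(sr$d, 0)
  expect_length(sr$R, 0)
})

test_that("sweeps record per-node entropies and comparison statistics", {
  net <- build_star(7)
  params <- assign_heterogeneity(net, "kuramoto", seed = 3)
  sr <- run_sweep(net, params, c(0.005, 0.01), "forward", seed = 3,
                  control = list(T_samples = 120, transient = 20))
  expect_equal(sr$d, c(0.005, 0.01))
  expect_equal(nrow(sr$nodes), 14)
  expect_true(all(c("H", "HT", "sigma_f", "ac1") %in% names(sr$nodes)))
  expect_true(all(sr$R >= 0 & sr$R <= 1))
  expect_true(all(sr$nodes$HT >= 0 & sr$nodes$HT <= 1, na.rm = TRUE))
})

test_that("state carryover stays consistent with long cold-start relaxation", {
  net <- build_star(31)
  params <- assign_heterogeneity(net, "kuramoto", seed = 4)
  grid <- c(0.002, 0.004, 0.006)
  sw <- run_sweep(net, params, grid, "forward", seed = 4,
                  control = list(T_samples = 150, transient = 100))
  for (k in 2:3) {
    cold <- simulate_kuramoto(net, params, grid[k], T_samples = 150,
                              transient = 600, seed = 40 + k)
    expect_lt(abs(sw$R[k] - order_parameter(cold$theta)), 0.1)
  }
})

test_that("backward sweeps descend the grid from an aligned state", {
  net <- build_star(11)
  params <- assign_heterogeneity(net, "kuramoto", seed = 5)
  sr <- run_sweep(net, params, c(0.01, 0.05), "backward", seed = 5,
                  control = list(T_samples = 100, transient = 100))
  expect_equal(sr$d, c(0.05, 0.01))
  expect_gt(sr$R[1], 0.9)  # synchronous at the largest coupling
})

test_that("ensembles average into tidy degree-class summaries", {
  ens <- run_sweep_ensemble("kuramoto", "star", 7, c(0.004, 0.008),
                            n_seeds = 2, seed = 11,
                            control = list(T_samples = 120, transient = 20))
  sm <- summary(ens)
  expect_equal(sm$R$d, c(0.004, 0.008))
  expect_equal(sort(unique(sm$classes$k)), c(1, 6))
  expect_equal(unique(sm$classes$N_k[sm$classes$k == 1]), 12)  # 6 leaves x 2 seeds
  expect_true(all(sm$classes$HT >= 0 & sm$classes$HT <= 1))
})
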