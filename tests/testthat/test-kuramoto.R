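two_osc <- oscillator_network(matrix(c(0, 1, 1, 0), 2, 2))

test_that("init_phases is seed-deterministic and covers the circle", {
  cfg <- sim_config(seed = 42)
  expect_identical(init_phases(5, cfg), init_phases(5, cfg))
  expect_false(identical(init_phases(5, cfg),
                         init_phases(5, sim_config(seed = 43))))
  th <- init_phases(2000, sim_config(seed = 1))
  expect_true(all(th >= 0 & th < 2 * pi))
  expect_lt(order_parameter(th), 0.1) # near-uniform spread
  expect_identical(init_phases(4, sim_config(init = "zero")), rep(0, 4))
})

test_that("phase_velocity matches hand computations", {
  cfg <- sim_config(omega = 0, K = 1)
  expect_equal(phase_velocity(c(0, pi / 2), two_osc, cfg), c(1, -1))
  expect_equal(phase_velocity(c(1.3, 1.3), two_osc, cfg), c(0, 0))
  expect_equal(phase_velocity(c(1, 2), two_osc, sim_config(omega = 0.7, K = 0)),
               c(0.7, 0.7))
  # literal convention flips the coupling term's sign
  expect_equal(phase_velocity(c(0, pi / 2), two_osc,
                              sim_config(omega = 0, K = 1, sign = "literal")),
               c(-1, 1))
  expect_error(phase_velocity(c(0, 0, 0), two_osc, cfg), "does not match")
})

test_that("symmetric attractive coupling conserves the mean phase velocity", {
  for (seed in 1:5) {
    net <- derive_coupling(random_web(seed))
    th <- withr::with_seed(seed, stats::runif(net$n, 0, 2 * pi))
    om <- withr::with_seed(seed + 100, stats::runif(net$n, -1, 1))
    v <- phase_velocity(th, net, sim_config(omega = om, K = 0.8))
    expect_equal(mean(v), mean(om), tolerance = 1e-12)
  }
})

test_that("two-oscillator integration matches the closed form", {
  # for the coupled pair, delta = theta1 - theta2 obeys
  # d(delta)/dt = -2 K sin(delta), i.e. tan(delta/2) = tan(delta0/2) e^(-2Kt)
  cfg <- sim_config(omega = 0.01, K = 0.5, t_end = 10, dt = 0.01)
  traj <- integrate_kuramoto(two_osc, cfg, initial = c(1, 0))
  delta <- (traj$phases[, 1] - traj$phases[, 2] + pi) %% (2 * pi) - pi
  expected <- 2 * atan(tan(0.5) * exp(-2 * cfg$K * traj$times))
  expect_equal(delta, expected, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("K = 0 reduces to linear phase drift", {
  net <- coffee_fixture()$network
  cfg <- sim_config(omega = 0.01, K = 0, t_end = 20, seed = 3)
  th0 <- init_phases(net$n, cfg)
  traj <- integrate_kuramoto(net, cfg, initial = th0)
  expected <- (outer(traj$times, rep(0.01, net$n)) +
                 matrix(th0, length(traj$times), net$n, byrow = TRUE)) %% (2 * pi)
  expect_lt(max(circ_diff(traj$phases, expected)), 1e-9)
})

test_that("the compiled integrator agrees with a plain-R RK4 and deSolve", {
  net <- derive_coupling(random_web(7))
  cfg <- sim_config(omega = 0.01, K = 0.6, t_end = 2, dt = 0.01, seed = 7)
  th0 <- init_phases(net$n, cfg)
  traj <- integrate_kuramoto(net, cfg, initial = th0)
  ref <- rk4_r(net, cfg, th0)
  expect_lt(max(circ_diff(traj$phases, ref)), 1e-10)

  ode <- deSolve::ode(
    y = th0, times = traj$times, method = "rk4",
    parms = NULL,
    func = function(t, y, parms) list(phase_velocity(y, net, cfg)))
  expect_lt(max(circ_diff(traj$phases, ode[, -1] %% (2 * pi))), 1e-8)
})

test_that("halving the step barely moves the fixture trajectory", {
  net <- coffee_fixture()$network
  th0 <- init_phases(net$n, sim_config(seed = 5))
  a <- integrate_kuramoto(net, sim_config(K = 0.5, dt = 0.01), initial = th0)
  b <- integrate_kuramoto(net, sim_config(K = 0.5, dt = 0.005), initial = th0)
  expect_lt(max(circ_diff(final_phases(a), final_phases(b))), 1e-6)
})

test_that("the literal sign convention repels an in-phase pair", {
  att <- integrate_kuramoto(two_osc, sim_config(omega = 0, K = 1, t_end = 5),
                            initial = c(0, 0.2))
  lit <- integrate_kuramoto(two_osc,
                            sim_config(omega = 0, K = 1, t_end = 5,
                                       sign = "literal"),
                            initial = c(0, 0.2))
  gap <- function(tr) abs(diff(final_phases(tr)))
  expect_lt(gap(att), 0.01)
  expect_gt(gap(lit), 1) # driven away toward the antiphase state
})

test_that("trajectories are reproducible and finite", {
  net <- coffee_fixture()$network
  cfg <- sim_config(K = 0.8, t_end = 5, seed = 9)
  a <- integrate_kuramoto(net, cfg)
  b <- integrate_kuramoto(net, cfg)
  expect_identical(a$phases, b$phases)
  expect_true(all(is.finite(a$phases)))
  expect_true(all(a$phases >= 0 & a$phases < 2 * pi))
  expect_identical(dim(a$phases), c(length(a$times), net$n))
})

test_that("phases_at matches grid samples and rejects off-grid times", {
  traj <- integrate_kuramoto(two_osc, sim_config(t_end = 1, seed = 2))
  expect_identical(phases_at(traj, 0.5), traj$phases[51, ])
  expect_identical(phases_at(traj, 1), final_phases(traj))
  expect_error(phases_at(traj, 2), "outside")
})

test_that("order parameter hits its closed-form landmarks", {
  expect_identical(order_parameter(rep(1.3, 10)), 1)
  expect_equal(order_parameter(2 * pi * (0:9) / 10), 0, tolerance = 1e-12)
  expect_equal(order_parameter(c(0, pi / 2)), sqrt(2) / 2)
  # rotation invariance
  th <- withr::with_seed(4, stats::runif(15, 0, 2 * pi))
  expect_equal(order_parameter(th), order_parameter(th + 1.1))
  expect_error(order_parameter(numeric(0)), "empty")
  ts <- order_parameter_ts(integrate_kuramoto(two_osc,
                                              sim_config(t_end = 1, seed = 1)))
  expect_identical(names(ts), c("time", "r"))
  expect_true(all(ts$r >= 0 & ts$r <= 1))
})
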