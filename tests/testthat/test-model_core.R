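test_that("default parameters match the published calibration", {
  p <- ks_params()
  expect_equal(p$sigma, 5.555e-6)
  expect_equal(p$beta_a, 1.111e-5)
  expect_equal(p$beta_r, -1.111e-5)
  expect_equal(p$alpha_a, 1500)
  expect_equal(p$gamma_a, 0.01)
  expect_equal(p$D_a, 1e-6)
  expect_equal(p$s_a, 0.01)
  expect_equal(p$gamma_r, 0.001)
  expect_equal(p$D_r, 1e-5)
  expect_equal(p$s_r, 0.001)
  expect_equal(p$rho_max, 28000)
  expect_equal(p$cushion, 2000)
  expect_equal(p$scale, 2)
  expect_equal(p$rho_bar, 9000)
  # the design relations behind the calibration
  expect_equal(p$beta_a, 2 * p$sigma)
  expect_equal(p$beta_r, -p$beta_a)
})

test_that("parameter invariants are enforced", {
  expect_error(ks_params(sigma = -1), "sigma")
  expect_error(ks_params(gamma_a = 0), "gamma_a")
  expect_error(ks_params(dim = 3), "dim")
  expect_warning(ks_params(beta_r = 1e-5), "repellent")
})

test_that("signal potential follows the Weber-law logarithm", {
  a <- 1500
  b <- 1.111e-5
  expect_equal(signal_potential(0, a, b), -b * log(a))
  # hand-derived value at U = alpha (e - 1)
  expect_equal(signal_potential(a * (exp(1) - 1), a, b), -b * (1 + log(a)))
  # monotone decreasing for attractant, increasing for repellent
  U <- seq(0, 5e4, length.out = 50)
  expect_true(all(diff(signal_potential(U, a, b)) < 0))
  expect_true(all(diff(signal_potential(U, a, -b)) > 0))
  expect_error(signal_potential(-1, a, b), "U")
  expect_error(signal_potential(1, 0, b), "alpha")
})

test_that("signal potential derivative is exact and antisymmetric", {
  p <- ks_params()
  expect_equal(signal_potential_deriv(0, 1500, 2 * p$sigma),
               -2 * p$sigma / 1500)
  # attractant + repellent derivatives cancel at equal concentrations
  U <- c(0, 100, 9000, 27000)
  expect_equal(signal_potential_deriv(U, p$alpha_a, p$beta_a) +
                 signal_potential_deriv(U, p$alpha_r, p$beta_r),
               rep(0, length(U)))
  # central-difference oracle
  d_num <- central_diff(function(u) signal_potential(u, 1500, 1.111e-5),
                        5000)
  expect_equal(signal_potential_deriv(5000, 1500, 1.111e-5), d_num,
               tolerance = 1e-6)
})

test_that("crowding potential has tanh shape, bounds and midpoint", {
  p <- ks_params()
  expect_equal(crowding_potential(p$rho_max, p), p$sigma * p$scale / 2)
  expect_equal(crowding_potential(p$rho_max, p), 5.555e-6)
  expect_lt(crowding_potential(0, p), 1e-17)
  expect_equal(crowding_potential(1e9, p), p$sigma * p$scale,
               tolerance = 1e-12)
  rho <- seq(0, 6e4, length.out = 200)
  v <- crowding_potential(rho, p)
  expect_true(all(diff(v) > 0))
  expect_true(all(v > 0 & v < p$sigma * p$scale))
  expect_error(crowding_potential(-1, p), "rho")
})

test_that("crowding potential derivative peaks at rho_max and matches FD", {
  p <- ks_params()
  rho <- seq(0, 6e4, length.out = 400)
  d <- crowding_potential_deriv(rho, p)
  expect_true(all(d > 0))
  expect_equal(rho[which.max(d)], p$rho_max, tolerance = 200)
  expect_equal(crowding_potential_deriv(p$rho_max, p),
               p$sigma * p$scale / (2 * p$cushion))
  # negligible at threshold densities (~3.4e-20, vs sigma ~ 5.6e-6)
  expect_lt(crowding_potential_deriv(1500, p), 1e-19)
  d_num <- central_diff(function(r) crowding_potential(r, p), 27000,
                        h = 0.01)
  expect_equal(crowding_potential_deriv(27000, p), d_num,
               tolerance = 1e-6)
})

test_that("derivatives match central differences over a log-spaced grid", {
  p <- ks_params()
  for (U in 10^seq(1, 4.5, by = 0.5)) {
    expect_equal(signal_potential_deriv(U, p$alpha_a, p$beta_a),
                 central_diff(function(u) {
                   signal_potential(u, p$alpha_a, p$beta_a)
                 }, U),
                 tolerance = 1e-6)
    expect_equal(crowding_potential_deriv(U, p),
                 central_diff(function(r) crowding_potential(r, p), U,
                              h = max(U * 1e-5, 1e-3)),
                 tolerance = 1e-6)
  }
})

test_that("total potential adds terms and cancels symmetric signals", {
  p <- ks_params()
  # beta_r = -beta_a, alpha_r = alpha_a: signal terms cancel pointwise
  expect_equal(total_potential(9000, 10500 - 1500, 10500 - 1500, p),
               crowding_potential(9000, p) +
                 signal_potential(9000, p$alpha_a, p$beta_a) +
                 signal_potential(9000, p$alpha_r, p$beta_r))
  expect_equal(total_potential(9000, 9000, 9000, p),
               crowding_potential(9000, p))
  p1 <- ks_params(repellent = FALSE)
  expect_equal(total_potential(5000, 2000, params = p1),
               signal_potential(2000, p1$alpha_a, p1$beta_a) +
                 crowding_potential(5000, p1))
  # with symmetric parameters the two signal potentials sum to a
  # constant independent of the common concentration
  U <- 10^seq(0, 5, length.out = 30)
  s <- signal_potential(U, p$alpha_a, p$beta_a) +
    signal_potential(U, p$alpha_r, p$beta_r)
  expect_equal(max(s) - min(s), 0)
})

test_that("uniform steady state scales linearly and equals rho_bar", {
  p <- ks_params()
  expect_equal(uniform_steady_state(9000, p),
               c(U_a = 9000, U_r = 9000))
  expect_equal(uniform_steady_state(0, p), c(U_a = 0, U_r = 0))
  expect_equal(uniform_steady_state(2357, p),
               c(U_a = 2357, U_r = 2357))
})

test_that("signal ranges reproduce the published length scales", {
  expect_equal(signal_range(1e-6, 0.01), 0.01)   # attractant: 100 um
  expect_equal(signal_range(1e-5, 0.001), 0.1)   # repellent: 1 mm
  expect_equal(signal_range(0.42, 0.42), 1)
  expect_error(signal_range(-1, 1), "must be > 0")
})

test_that("slowdown factor is exponential in t/tau and scales movement only", {
  sch <- slowdown_schedule(tau = 3600)
  expect_equal(slowdown_factor(0, sch), 1)
  expect_equal(slowdown_factor(3600, sch), exp(-1))
  expect_equal(slowdown_factor(100, NULL), 1)
  expect_equal(slowdown_factor(100, slowdown_schedule()), 1)
  expect_error(slowdown_factor(-1, sch), "t")
  expect_error(slowdown_schedule(tau = -5), "tau")
  p <- ks_params()
  pe <- effective_params(p, 3600, sch)
  expect_equal(pe$sigma, p$sigma * exp(-1))
  expect_equal(pe$beta_a, p$beta_a * exp(-1))
  expect_equal(pe$beta_r, p$beta_r * exp(-1))
  expect_equal(pe$gamma_a, p$gamma_a) # chemical kinetics untouched
  expect_equal(pe$D_r, p$D_r)
})
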