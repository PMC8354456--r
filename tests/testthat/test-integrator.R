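test_that("step controller validates its settings", {
  c1 <- step_controller()
  expect_true(c1$cfl)
  expect_error(step_controller(rtol = -1), "rtol")
  expect_error(step_controller(dt_init = 1e-12, dt_min = 1e-3), "dt_min")
})

test_that("cfl limit is the cell-crossing time and scales with velocity", {
  p <- ks_params()
  g <- small_grid_1d(64)
  st <- uniform_state(g, p)
  expect_identical(cfl_limit(st, p, g), Inf)
  # attractant ramp creates a known velocity; doubling the coupling
  # doubles the velocity and halves the cap
  ramp <- 9000 + 500 * sin(2 * pi * g$x)
  st2 <- field_state(0, rep(9000, 64), ramp, rep(9000, 64), g)
  cap1 <- cfl_limit(st2, p, g)
  v <- velocity_field(st2, p, g)
  expect_equal(cap1, g$spacing[1] / max(abs(v$vx)))
  p2 <- ks_params(beta_a = 2 * 1.111e-5)
  # crowding contribution is identical (rho uniform), so the signal
  # part doubles exactly
  expect_equal(cfl_limit(st2, p2, g), cap1 / 2, tolerance = 1e-10)
})

test_that("pure diffusion decays a sine mode at the closed-form rate", {
  # beta = 0 and negligible crowding reduce the worm equation to the
  # heat equation; the discrete mode decays as exp(-sigma k_d^2 t)
  p0 <- ks_params(dim = 1, repellent = FALSE, beta_a = 0, scale = 1e-300)
  g <- periodic_grid(128, 1)
  m <- 2
  mode <- sin(2 * pi * m * g$x)
  rho0 <- p0$rho_bar * (1 + 0.5 * mode)
  st <- field_state(0, rho0, rep(p0$rho_bar, 128), NULL, g)
  kd2 <- -spatial_operators(mode, g)$laplacian[5] / mode[5]
  t_end <- 0.25 / (p0$sigma * kd2) # decay to ~78%
  out <- advance(st, t_end, p0, g,
                 controller = step_controller(rtol = 1e-6, atol = 1e-6))
  amp <- 2 * sum((out$rho / p0$rho_bar - 1) * mode) / length(mode)
  ratio_exact <- exp(-p0$sigma * kd2 * t_end)
  expect_equal(amp / 0.5, ratio_exact, tolerance = 1e-5)
})

test_that("uniform steady state is a fixed point of the integrator", {
  p <- ks_params()
  g <- small_grid_1d(64)
  st <- uniform_state(g, p)
  out <- advance(st, 1e5, p, g)
  expect_equal(out$rho, st$rho, tolerance = 1e-9)
  expect_equal(out$U_a, st$U_a, tolerance = 1e-9)
  expect_equal(out$U_r, st$U_r, tolerance = 1e-9)
  expect_equal(out$t, 1e5)
})

test_that("chemical relaxation to steady state follows the linear rate", {
  # uniform worms, perturbed attractant: each mode relaxes to s rho/gamma
  # at rate gamma + D k_d^2
  p0 <- ks_params(dim = 1, repellent = FALSE, beta_a = 0, scale = 1e-300)
  g <- periodic_grid(128, 1)
  m <- 3
  mode <- sin(2 * pi * m * g$x)
  Ueq <- p0$s_a * p0$rho_bar / p0$gamma_a
  st <- field_state(0, rep(p0$rho_bar, 128), Ueq * (1 + 0.4 * mode), NULL, g)
  kd2 <- -spatial_operators(mode, g)$laplacian[5] / mode[5]
  rate <- p0$gamma_a + p0$D_a * kd2
  t_end <- 1 / rate
  out <- advance(st, t_end, p0, g,
                 controller = step_controller(rtol = 1e-6, atol = 1e-6))
  amp <- 2 * sum((out$U_a / Ueq - 1) * mode) / length(mode)
  expect_equal(amp / 0.4, exp(-1), tolerance = 1e-3)
})

test_that("worm number is conserved through a full aggregation run", {
  p <- ks_params(dim = 1)
  g <- periodic_grid(256, 1)
  st <- uniform_noisy_ic(9000, 0.01, 21, g, p)
  m0 <- total_mass(st$rho, g)
  out <- advance(st, 2e4, p, g,
                 controller = step_controller(rtol = 1e-4, atol = 1e-2,
                                              cfl = FALSE))
  expect_gt(max(out$rho), 0.8 * p$rho_max) # aggregates actually formed
  expect_lt(abs(total_mass(out$rho, g) - m0) / m0, 1e-6)
  expect_true(all(out$rho > 0))
})

test_that("perturbations amplify above threshold and decay below", {
  g <- periodic_grid(256, 1)
  # above threshold: variance grows at least tenfold within 10^4 s
  p_hi <- ks_params(dim = 1, rho_bar = 9000)
  st_hi <- uniform_noisy_ic(9000, 0.01, 5, g, p_hi)
  v0 <- stats::var(as.numeric(st_hi$rho))
  out_hi <- advance(st_hi, 1e4, p_hi, g,
                    controller = step_controller(rtol = 1e-4, atol = 1e-2,
                                                 cfl = FALSE))
  expect_gt(stats::var(as.numeric(out_hi$rho)) / v0, 10)
  # below threshold: variance decays
  p_lo <- ks_params(dim = 1, rho_bar = 1000)
  st_lo <- uniform_noisy_ic(1000, 0.01, 5, g, p_lo)
  v0l <- stats::var(as.numeric(st_lo$rho))
  vprev <- v0l
  st <- st_lo
  for (tt in c(2000, 6000, 10000)) {
    st <- advance(st, tt, p_lo, g,
                  controller = step_controller(rtol = 1e-5, atol = 1e-3))
    vnow <- stats::var(as.numeric(st$rho))
    expect_lt(vnow, vprev)
    vprev <- vnow
  }
  expect_lt(vprev / v0l, 0.5)
})

test_that("a seeded mode grows at the linear-theory rate while small", {
  p <- ks_params(dim = 1, rho_bar = 9000)
  g <- periodic_grid(256, 1)
  m <- 8 # k = 16 pi rad/cm, well inside the unstable band
  k <- 2 * pi * m / g$extent[1]
  mode <- sin(k * g$x)
  eps <- 2e-3
  uss <- uniform_steady_state(9000, p)
  st <- field_state(0, 9000 * (1 + eps * mode), rep(uss["U_a"], 256),
                    rep(uss["U_r"], 256), g)
  amp_of <- function(s) 2 * sum((s$rho / 9000 - 1) * mode) / length(mode)
  ctrl <- step_controller(rtol = 1e-6, atol = 1e-4)
  s1 <- advance(st, 500, p, g, controller = ctrl)
  s2 <- advance(s1, 1500, p, g, controller = ctrl)
  expect_lt(max(abs(s2$rho / 9000 - 1)), 0.05) # still in the linear window
  lam_sim <- log(amp_of(s2) / amp_of(s1)) / 1000
  lam_lin <- growth_rates(k, 9000, p)$growth_rate
  expect_equal(lam_sim, lam_lin, tolerance = 0.05)
})

test_that("slowdown attenuates aggregation relative to the plain model", {
  p <- ks_params(dim = 1, rho_bar = 9000)
  g <- periodic_grid(256, 1)
  st <- uniform_noisy_ic(9000, 0.01, 3, g, p)
  sch <- slowdown_schedule(tau = 900)
  ctrl <- step_controller(rtol = 1e-4, atol = 1e-2, cfl = FALSE)
  out <- advance(st, 5e4, p, g, schedule = sch, controller = ctrl)
  out2 <- advance(st, 5e4, p, g, controller = ctrl)
  expect_gt(max(out2$rho), 0.8 * p$rho_max) # plain model reaches plateau
  expect_lt(max(out$rho), max(out2$rho))    # slowdown falls short of it
})

test_that("integration reports diagnostics and validates its target time", {
  p <- ks_params()
  g <- small_grid_1d(32)
  st <- uniform_state(g, p)
  out <- advance(st, 100, p, g)
  expect_gt(attr(out, "steps"), 0)
  expect_gte(attr(out, "rejected"), 0)
  expect_error(advance(st, -5, p, g), "t_target")
})
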