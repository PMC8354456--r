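#' Uniform initial condition with multiplicative Gaussian noise
#'
#' Worm density \code{rho_bar * (1 + noise_frac * Z)} with independent
#' standard normal \code{Z} per grid point, clipped to the positivity
#' floor and renormalized so the total worm number is exactly
#' \code{rho_bar * domain volume}; signals start at the uniform steady
#' state. With \code{noise_frac = 0.01} and \code{rho_bar = 9000} the
#' density perturbation has standard deviation 90 cm^-d.
#'
#' @param rho_bar mean density (cm^-d).
#' @param noise_frac noise standard deviation as a fraction of
#'   \code{rho_bar}, \code{>= 0}.
#' @param seed RNG seed (an integer) for reproducibility.
#' @param grid a \code{\link{periodic_grid}}.
#' @param params a \code{\link{ks_params}} object.
#' @return A \code{\link{field_state}} at t = 0.
#' @export
uniform_noisy_ic <- function(rho_bar, noise_frac, seed, grid, params) {
  if (noise_frac < 0) stop("`noise_frac` must be >= 0", call. = FALSE)
  np <- prod(grid$n)
  as_field <- function(v) {
    if (grid$dim == 2L) matrix(v, grid$n[1], grid$n[2]) else v
  }
  rho <- rep(rho_bar, np)
  if (noise_frac > 0) {
    set.seed(seed)
    rho <- rho_bar * (1 + noise_frac * stats::rnorm(np))
    rho <- pmax(rho, 1e-6 * rho_bar)
    rho <- rho * (rho_bar * np / sum(rho))
  }
  uss <- uniform_steady_state(rho_bar, params)
  field_state(0, as_field(rho), as_field(rep(uss["U_a"], np)),
              if (params$repellent) as_field(rep(uss["U_r"], np)), grid)
}

#' Center-sphere initial condition for full-scale runs
#'
#' The density profile left by a sphere of worms of radius \code{R}
#' placed at the domain center whose contents fell vertically onto the
#' surface: a hemisphere-height bump
#' \code{rho = b_rho + a_rho * sqrt(max(0, 1 - r^2/R^2))} over a small
#' uniform background (the background avoids zero densities, for which
#' the worm equation is undefined). The bump amplitude
#' \code{a_rho = 3 (rho_bar - b_rho) w^2 / (2 pi R^2)} makes the total
#' worm number exactly \code{rho_bar * w^2}: with the defaults on a
#' 6 cm x 6 cm domain, 3600 background worms plus 68 400 in the central
#' 2 cm diameter circle, 72 000 in all. Multiplicative Gaussian noise of
#' relative standard deviation \code{noise_frac} is then applied
#' pointwise.
#'
#' @param grid a 2D \code{\link{periodic_grid}} with extent at least
#'   \code{2 R}.
#' @param params a \code{\link{ks_params}} object.
#' @param rho_bar target mean density (cm^-2).
#' @param b_rho uniform background density (cm^-2).
#' @param R bump radius (cm).
#' @param noise_frac relative noise standard deviation.
#' @param seed RNG seed.
#' @return A \code{\link{field_state}} at t = 0.
#' @export
center_sphere_ic <- function(grid, params, rho_bar = 2000, b_rho = 100,
                             R = 1, noise_frac = 0.01, seed = 1) {
  if (grid$dim != 2L) stop("center-sphere IC requires a 2D grid",
                           call. = FALSE)
  if (any(grid$extent < 2 * R))
    stop("domain too small for bump radius R", call. = FALSE)
  w <- grid$extent[1]
  h <- grid$extent[2]
  a_rho <- 3 * (rho_bar - b_rho) * w * h / (2 * pi * R^2)
  r2 <- outer((grid$x - w / 2)^2, (grid$y - h / 2)^2, "+")
  rho <- b_rho + a_rho * sqrt(pmax(1 - r2 / R^2, 0))
  if (noise_frac > 0) {
    set.seed(seed)
    rho <- rho * (1 + noise_frac * stats::rnorm(length(rho)))
    rho <- pmax(rho, 1e-6 * rho_bar)
  }
  uss_b <- uniform_steady_state(b_rho, params)
  np <- prod(grid$n)
  field_state(0, rho,
              matrix(uss_b["U_a"], grid$n[1], grid$n[2]),
              if (params$repellent) matrix(uss_b["U_r"], grid$n[1], grid$n[2]),
              grid)
}

#' Noise injection schedule
#'
#' Injection times \code{t_n = 10^(n/2)} s for n = 0..10: 1 s, 3.16 s,
#' 10 s, ..., 100 000 s. The geometric spacing concentrates injections
#' early, when the worms move fast, and spares the slow approach to
#' equilibrium.
#'
#' @return Numeric vector of 11 times (s).
#' @export
noise_schedule <- function() 10^((0:10) / 2)

#' Inject geometric Brownian noise into the density field
#'
#' Models continuous environmental noise accumulated since the previous
#' injection as an independent geometric Brownian motion per grid point:
#' the density is multiplied by \code{exp(P)} with
#' \code{P ~ Normal(0, variance_rate * dt_since_last)} i.i.d. per point,
#' then rescaled globally so the total worm number is exactly unchanged.
#' Signal fields are untouched.
#'
#' @param state a \code{\link{field_state}}.
#' @param dt_since_last time since the previous injection (s), \code{> 0}.
#' @param variance_rate variance accumulated per second (1/s).
#' @return The perturbed \code{\link{field_state}}.
#' @export
inject_noise <- function(state, dt_since_last, variance_rate = 1e-6) {
  if (dt_since_last <= 0) stop("`dt_since_last` must be > 0", call. = FALSE)
  m0 <- sum(state$rho)
  P <- stats::rnorm(length(state$rho),
                    sd = sqrt(variance_rate * dt_since_last))
  rho <- state$rho * exp(P)
  state$rho <- rho * (m0 / sum(rho))
  state
}

#' Scenario configuration
#'
#' Bundles everything needed for a reproducible numerical experiment:
#' model variant, domain, resolution, initial condition, noise handling,
#' slowdown, end time and snapshot times. Presets reproduce the
#' published numerical experiments at configurable scale:
#' \describe{
#'   \item{fig2-1d / fig2-2d}{attractant-only model, 1 cm domain,
#'     \code{rho_bar} = 9000, 1 percent initial noise, 200 000 s.}
#'   \item{fig3-1d / fig3-2d}{attractant+repellent model, otherwise as
#'     above.}
#'   \item{fig5}{slowdown variant of fig3-2d; \code{tau} defaults to
#'     1800 s (aggregation arrested) and is configurable.}
#'   \item{fig6}{full-scale attractant+repellent run: 6 cm x 6 cm,
#'     center-sphere initial condition (72 000 worms), geometric
#'     Brownian noise injections at \code{\link{noise_schedule}} times;
#'     default resolution 64 points/cm (the published 384 points/cm is
#'     configurable but far from desk scale).}
#' }
#'
#' @param preset one of \code{"fig2-1d"}, \code{"fig2-2d"},
#'   \code{"fig3-1d"}, \code{"fig3-2d"}, \code{"fig5"}, \code{"fig6"},
#'   or \code{"custom"}.
#' @param seed integer seed controlling the initial noise and all
#'   injections.
#' @param ... overrides for any configuration element: \code{rho_bar},
#'   \code{extent}, \code{n}, \code{t_end}, \code{snapshot_times},
#'   \code{noise_frac}, \code{tau}, \code{injections}, \code{params},
#'   \code{controller}, \code{ic} (\code{"uniform"} or
#'   \code{"center-sphere"}).
#' @return An object of class \code{"ks_scenario"}.
#' @export
ks_scenario <- function(preset = "fig3-2d", seed = 1, ...) {
  presets <- list(
    "fig2-1d" = list(repellent = FALSE, dim = 1L, n = 1024L, extent = 1,
                     rho_bar = 9000, ic = "uniform", noise_frac = 0.01,
                     injections = FALSE, tau = NULL, t_end = 2e5),
    "fig2-2d" = list(repellent = FALSE, dim = 2L, n = c(128L, 128L),
                     extent = 1, rho_bar = 9000, ic = "uniform",
                     noise_frac = 0.01, injections = FALSE, tau = NULL,
                     t_end = 2e5),
    "fig3-1d" = list(repellent = TRUE, dim = 1L, n = 1024L, extent = 1,
                     rho_bar = 9000, ic = "uniform", noise_frac = 0.01,
                     injections = FALSE, tau = NULL, t_end = 2e5),
    "fig3-2d" = list(repellent = TRUE, dim = 2L, n = c(128L, 128L),
                     extent = 1, rho_bar = 9000, ic = "uniform",
                     noise_frac = 0.01, injections = FALSE, tau = NULL,
                     t_end = 2e5),
    "fig5" = list(repellent = TRUE, dim = 2L, n = c(128L, 128L),
                  extent = 1, rho_bar = 9000, ic = "uniform",
                  noise_frac = 0.01, injections = FALSE, tau = 1800,
                  t_end = 2e5),
    "fig6" = list(repellent = TRUE, dim = 2L, n = c(384L, 384L),
                  extent = 6, rho_bar = 2000, ic = "center-sphere",
                  noise_frac = 0.01, injections = TRUE, tau = NULL,
                  t_end = 2e5),
    "custom" = list(repellent = TRUE, dim = 2L, n = c(128L, 128L),
                    extent = 1, rho_bar = 9000, ic = "uniform",
                    noise_frac = 0.01, injections = FALSE, tau = NULL,
                    t_end = 2e5))
  if (!preset %in% names(presets))
    stop("unknown preset: ", preset, call. = FALSE)
  cfg <- presets[[preset]]
  cfg$preset <- preset
  cfg$seed <- as.integer(seed)
  cfg$snapshot_times <- NULL
  cfg$params <- NULL
  cfg$controller <- NULL
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(cfg), "params", "controller",
                                    "snapshot_times"))
  if (length(unknown))
    stop("unknown scenario option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  if (cfg$t_end < 0) stop("`t_end` must be >= 0", call. = FALSE)
  class(cfg) <- "ks_scenario"
  cfg
}

#' Run a scenario
#'
#' Builds the grid, parameters, initial condition and schedules from a
#' \code{\link{ks_scenario}}, integrates piecewise between events
#' (noise injections and snapshot times are hard integration
#' breakpoints; step-size control restarts after each), and collects
#' snapshots and bookkeeping. Fully deterministic for a fixed seed.
#'
#' @param scenario a \code{\link{ks_scenario}}.
#' @param quiet suppress progress messages.
#' @return An object of class \code{"ks_result"}: list with
#'   \code{snapshots} (list of \code{\link{field_state}}s),
#'   \code{times}, \code{mass} (total worm number at each snapshot),
#'   \code{steps}, \code{rejected}, \code{grid}, \code{params},
#'   \code{scenario}, and \code{seed}.
#' @export
run_scenario <- function(scenario, quiet = TRUE) {
  stopifnot(inherits(scenario, "ks_scenario"))
  cfg <- scenario
  params <- cfg$params
  if (is.null(params))
    params <- ks_params(dim = cfg$dim, rho_bar = cfg$rho_bar,
                        repellent = cfg$repellent)
  grid <- periodic_grid(cfg$n, cfg$extent)
  controller <- cfg$controller
  if (is.null(controller))
    controller <- step_controller(rtol = 1e-4, atol = 1e-2, cfl = FALSE)
  schedule <- if (!is.null(cfg$tau)) slowdown_schedule(tau = cfg$tau)
  set.seed(cfg$seed)
  state <- if (cfg$ic == "center-sphere") {
    center_sphere_ic(grid, params, rho_bar = cfg$rho_bar,
                     noise_frac = cfg$noise_frac, seed = cfg$seed)
  } else {
    uniform_noisy_ic(cfg$rho_bar, cfg$noise_frac, cfg$seed, grid, params)
  }
  snap_times <- sort(unique(c(cfg$snapshot_times, cfg$t_end)))
  snap_times <- snap_times[snap_times > 0 & snap_times <= cfg$t_end]
  inj_times <- if (isTRUE(cfg$injections)) {
    tt <- noise_schedule()
    tt[tt < cfg$t_end]
  } else numeric(0)
  events <- sort(unique(c(snap_times, inj_times)))

  snapshots <- list(state)
  times <- 0
  mass <- total_mass(state$rho, grid)
  steps <- 0L
  rejected <- 0L
  last_inj <- 0
  for (te in events) {
    ctrl <- controller
    if (state$t > 0) ctrl$dt_init <- controller$dt_init / 10
    state <- advance(state, te, params, grid, schedule = schedule,
                     controller = ctrl)
    steps <- steps + attr(state, "steps")
    rejected <- rejected + attr(state, "rejected")
    if (te %in% inj_times) {
      state <- inject_noise(state, te - last_inj)
      last_inj <- te
    }
    if (te %in% snap_times) {
      snapshots <- c(snapshots, list(state))
      times <- c(times, te)
      mass <- c(mass, total_mass(state$rho, grid))
    }
    if (!quiet)
      message(sprintf("t = %g s (steps so far: %d)", te, steps))
  }
  structure(list(snapshots = snapshots, times = times, mass = mass,
                 steps = steps, rejected = rejected, grid = grid,
                 params = params, scenario = cfg, seed = cfg$seed),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Scenario '%s' (seed %d): %d snapshot(s), t in [0, %g] s\n",
              x$scenario$preset, x$seed, length(x$snapshots),
              max(x$times)))
  cat(sprintf("  %d accepted steps (%d rejected); mass drift %.3g relative\n",
              x$steps, x$rejected,
              max(abs(x$mass / x$mass[1] - 1))))
  invisible(x)
}
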