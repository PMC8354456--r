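#' Model parameters for the L1 aggregation model
#'
#' Constructs the full parameter set of the Keller-Segel L1 aggregation
#' model: the random-motility coefficient of the worms, the crowding
#' potential shape constants, and, per diffusible signal (attractant
#' \code{a}, repellent \code{r}), the Weber-law potential constants and the
#' reaction-diffusion rates. Defaults are the published calibration for
#' starved L1s on agar; all lengths are in cm, times in s, densities and
#' concentrations in cm^-d where \code{d} is the spatial dimension.
#'
#' The defaults encode two deliberate relations: signal secretion and decay
#' rates are numerically equal (\code{s_i == gamma_i}), so that at the
#' uniform steady state signal concentrations equal the worm density; and
#' \code{beta_a = 2 * sigma}, \code{beta_r = -beta_a}, which places the
#' attractant-only instability threshold at \code{alpha_a} = 1500 cm^-d.
#' A negative \code{beta} makes a signal repulsive.
#'
#' @param dim spatial dimension, 1 or 2.
#' @param rho_bar mean worm density (cm^-d).
#' @param sigma random-motility (diffusion) coefficient of the worms
#'   (cm^2/s).
#' @param rho_max crowding-potential midpoint: density at which the
#'   excluded-area potential reaches half its maximum (cm^-d).
#' @param cushion width of the crowding potential's tanh rise (cm^-d).
#' @param scale height of the crowding potential in units of \code{sigma}
#'   (dimensionless).
#' @param beta_a,beta_r signal coupling strengths (cm^2/s); negative values
#'   denote repellents.
#' @param alpha_a,alpha_r Weber-law concentration offsets (cm^-d).
#' @param gamma_a,gamma_r signal decay rates (1/s).
#' @param D_a,D_r signal diffusion constants (cm^2/s).
#' @param s_a,s_r per-worm signal secretion rates (cm^-d/s).
#' @param repellent logical; \code{FALSE} selects the attractant-only
#'   model, \code{TRUE} the attractant+repellent model.
#'
#' @return An object of class \code{"ks_params"} (a named list).
#' @examples
#' p <- ks_params()                      # published two-signal calibration
#' p1 <- ks_params(repellent = FALSE)    # attractant-only variant
#' @export
ks_params <- function(dim = 2,
                      rho_bar = 9000,
                      sigma = 5.555e-6,
                      rho_max = 28000,
                      cushion = 2000,
                      scale = 2,
                      beta_a = 1.111e-5,
                      alpha_a = 1500,
                      gamma_a = 0.01,
                      D_a = 1e-6,
                      s_a = 0.01,
                      beta_r = -1.111e-5,
                      alpha_r = 1500,
                      gamma_r = 0.001,
                      D_r = 1e-5,
                      s_r = 0.001,
                      repellent = TRUE) {
  if (!dim %in% c(1L, 2L))
    stop("`dim` must be 1 or 2", call. = FALSE)
  stopifnot(sigma > 0, rho_max > 0, cushion > 0, rho_bar >= 0,
            gamma_a > 0, D_a > 0, s_a > 0, alpha_a > 0,
            gamma_r > 0, D_r > 0, s_r > 0, alpha_r > 0)
  if (repellent && beta_r > 0)
    warning("repellent enabled but beta_r > 0: a positive coupling is ",
            "an attractant, not a repellent", call. = FALSE)
  p <- list(dim = as.integer(dim), rho_bar = rho_bar, sigma = sigma,
            rho_max = rho_max, cushion = cushion, scale = scale,
            beta_a = beta_a, alpha_a = alpha_a, gamma_a = gamma_a,
            D_a = D_a, s_a = s_a,
            beta_r = beta_r, alpha_r = alpha_r, gamma_r = gamma_r,
            D_r = D_r, s_r = s_r,
            repellent = isTRUE(repellent))
  class(p) <- "ks_params"
  p
}

#' @export
print.ks_params <- function(x, ...) {
  cat("Keller-Segel L1 aggregation parameters (",
      if (x$repellent) "attractant+repellent" else "attractant-only",
      ", d = ", x$dim, ")\n", sep = "")
  cat(sprintf("  sigma = %g cm^2/s, rho_bar = %g, rho_max = %g, cushion = %g, scale = %g\n",
              x$sigma, x$rho_bar, x$rho_max, x$cushion, x$scale))
  cat(sprintf("  attractant: beta = %g, alpha = %g, gamma = %g, D = %g, s = %g\n",
              x$beta_a, x$alpha_a, x$gamma_a, x$D_a, x$s_a))
  if (x$repellent)
    cat(sprintf("  repellent:  beta = %g, alpha = %g, gamma = %g, D = %g, s = %g\n",
                x$beta_r, x$alpha_r, x$gamma_r, x$D_r, x$s_r))
  invisible(x)
}

#' Movement-slowdown schedule
#'
#' Starved larvae slow down as they exhaust their reserves. The slowdown
#' variant of the model multiplies the movement parameters \code{sigma},
#' \code{beta_a} and \code{beta_r} by \code{exp(-t / tau)}; the chemical
#' fields' rates are untouched, so signal kinetics keep their own time
#' scales.
#'
#' @param tau decay time constant (s). Required when \code{enabled}.
#' @param enabled logical; a disabled schedule leaves all parameters
#'   time-independent.
#' @return An object of class \code{"ks_slowdown"}.
#' @export
slowdown_schedule <- function(tau = NULL, enabled = !is.null(tau)) {
  if (enabled) {
    if (is.null(tau) || !is.finite(tau) || tau <= 0)
      stop("`tau` must be a positive finite number when enabled",
           call. = FALSE)
  }
  structure(list(tau = tau, enabled = isTRUE(enabled)),
            class = "ks_slowdown")
}

#' Time-dependent slowdown multiplier
#'
#' @param t time (s), \code{t >= 0}; vectorized.
#' @param schedule a \code{\link{slowdown_schedule}} (or \code{NULL}, which
#'   means no slowdown).
#' @return \code{exp(-t / tau)} when the schedule is enabled, 1 otherwise.
#' @export
slowdown_factor <- function(t, schedule = NULL) {
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  if (is.null(schedule) || !schedule$enabled) return(rep(1, length(t)))
  exp(-t / schedule$tau)
}

#' Effective (possibly time-scaled) movement parameters
#'
#' Applies the slowdown multiplier to \code{sigma}, \code{beta_a},
#' \code{beta_r} at time \code{t}, leaving all chemical-field parameters
#' unchanged.
#'
#' @inheritParams slowdown_factor
#' @param params a \code{\link{ks_params}} object holding the t = 0 values.
#' @return A \code{ks_params} object with scaled movement parameters.
#' @export
effective_params <- function(params, t = 0, schedule = NULL) {
  f <- slowdown_factor(t, schedule)
  if (f == 1) return(params)
  params$sigma <- params$sigma * f
  params$beta_a <- params$beta_a * f
  params$beta_r <- params$beta_r * f
  params
}

#' Weber-law signal potential
#'
#' The worms' response to a diffusible signal of concentration \code{U} is
#' the logarithmic potential \code{V_U(U) = -beta * log(alpha + U)},
#' obtained by integrating a Weber-law just-noticeable-difference relation.
#' With \code{beta > 0} the potential decreases in \code{U} (an
#' attractant, since worms drift down-potential); \code{beta < 0} gives a
#' repellent. Concentrations are taken numerically in cm^-d before the
#' logarithm; only potential gradients enter the dynamics, so the additive
#' constant implied by that unit convention is dynamically irrelevant.
#'
#' @param U signal concentration (cm^-d), \code{U >= 0}; vectorized.
#' @param alpha concentration offset (cm^-d), \code{alpha > 0}.
#' @param beta coupling strength (cm^2/s).
#' @return Potential value(s) in cm^2/s.
#' @examples
#' signal_potential(0, 1500, 1.111e-5)   # boundary value -beta*log(alpha)
#' @export
signal_potential <- function(U, alpha, beta) {
  if (any(U < 0)) stop("`U` must be >= 0", call. = FALSE)
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  -beta * log(alpha + U)
}

#' Derivative of the signal potential
#'
#' @inheritParams signal_potential
#' @return \code{dV/dU = -beta / (alpha + U)} (cm^2 cm^d / s).
#' @export
signal_potential_deriv <- function(U, alpha, beta) {
  if (any(U < 0)) stop("`U` must be >= 0", call. = FALSE)
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  -beta / (alpha + U)
}

#' Crowding (excluded-area) potential
#'
#' A smoothed hard-core potential reflecting that a worm occupies area:
#' \code{V_rho(rho) = sigma * scale / 2 * (1 + tanh((rho - rho_max) /
#' cushion))}. It rises from ~0 well below \code{rho_max} to
#' \code{sigma * scale} above it, with midpoint (and steepest slope) at
#' \code{rho_max}.
#'
#' @param rho worm density (cm^-d), \code{rho >= 0}; vectorized.
#' @param params a \code{\link{ks_params}} object.
#' @return Potential value(s) in cm^2/s, bounded in (0, sigma * scale).
#' @export
crowding_potential <- function(rho, params) {
  if (any(rho < 0)) stop("`rho` must be >= 0", call. = FALSE)
  params$sigma * params$scale / 2 *
    (1 + tanh((rho - params$rho_max) / params$cushion))
}

#' Derivative of the crowding potential
#'
#' @inheritParams crowding_potential
#' @return \code{dV_rho/drho = sigma * scale / (2 * cushion) *
#'   sech((rho - rho_max)/cushion)^2}; strictly positive, maximal at
#'   \code{rho = rho_max}.
#' @export
crowding_potential_deriv <- function(rho, params) {
  if (any(rho < 0)) stop("`rho` must be >= 0", call. = FALSE)
  sech2 <- 1 / cosh((rho - params$rho_max) / params$cushion)^2
  params$sigma * params$scale / (2 * params$cushion) * sech2
}

#' Total movement potential
#'
#' Sum of the signal potentials and the crowding potential,
#' \code{V = V_Ua(U_a) + V_Ur(U_r) + V_rho(rho)}; the repellent term is
#' omitted in the attractant-only model. The worms' mean velocity is
#' \code{-grad V}.
#'
#' @param rho worm density field.
#' @param U_a attractant concentration field.
#' @param U_r repellent concentration field (ignored unless
#'   \code{params$repellent}).
#' @param params a \code{\link{ks_params}} object.
#' @return Potential field (same shape as inputs), cm^2/s.
#' @export
total_potential <- function(rho, U_a, U_r = NULL, params) {
  V <- signal_potential(U_a, params$alpha_a, params$beta_a) +
    crowding_potential(rho, params)
  if (params$repellent) {
    if (is.null(U_r))
      stop("repellent enabled but `U_r` missing", call. = FALSE)
    V <- V + signal_potential(U_r, params$alpha_r, params$beta_r)
  }
  V
}

#' Uniform steady-state signal concentrations
#'
#' At a spatially uniform density \code{rho_bar} the signal equations
#' equilibrate at \code{U_i = s_i * rho_bar / gamma_i}. With the default
#' calibration (\code{s_i == gamma_i} numerically) the steady
#' concentrations equal the worm density.
#'
#' @param rho_bar uniform worm density (cm^-d), \code{>= 0}.
#' @param params a \code{\link{ks_params}} object.
#' @return Named vector \code{c(U_a = ..., U_r = ...)} (\code{U_r} only
#'   when the repellent is enabled).
#' @export
uniform_steady_state <- function(rho_bar, params) {
  if (any(rho_bar < 0)) stop("`rho_bar` must be >= 0", call. = FALSE)
  out <- c(U_a = params$s_a * rho_bar / params$gamma_a)
  if (params$repellent)
    out <- c(out, U_r = params$s_r * rho_bar / params$gamma_r)
  out
}

#' Diffusive range of a signal
#'
#' The mean distance a signal molecule diffuses before decaying,
#' \code{sqrt(D / gamma)}. For the default attractant this is 100 um; for
#' the repellent, 1 mm.
#'
#' @param D diffusion constant (cm^2/s), \code{> 0}.
#' @param gamma decay rate (1/s), \code{> 0}.
#' @return Range in cm.
#' @export
signal_range <- function(D, gamma) {
  if (any(D <= 0) || any(gamma <= 0))
    stop("`D` and `gamma` must be > 0", call. = FALSE)
  sqrt(D / gamma)
}
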