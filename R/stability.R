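#' Marginal stability condition for the uniform state
#'
#' Linearizing the worm/signal system about the uniform steady state and
#' setting the growth rate to zero (which renders the signal equations
#' quasi-static) gives an exact marginal condition for a sinusoidal
#' perturbation of wavenumber \code{k}:
#' \deqn{g(k, \bar\rho) = \sigma + \bar\rho V_\rho'(\bar\rho) +
#'   \bar\rho \sum_i V_i'(U_i^*) \frac{s_i}{\gamma_i + D_i k^2}}
#' The mode is unstable exactly when \code{g < 0}. The crowding term
#' \code{rho_bar * V_rho'(rho_bar)} is kept for generality although it is
#' numerically negligible (< 1e-20 cm^2/s) at threshold densities.
#'
#' @param k wavenumber (radians/cm), \code{>= 0}; vectorized.
#' @param rho_bar uniform density (cm^-d), \code{> 0}.
#' @param params a \code{\link{ks_params}} object.
#' @return \code{g(k, rho_bar)} in cm^2/s; negative values mean
#'   instability.
#' @export
marginal_condition <- function(k, rho_bar, params) {
  if (any(rho_bar <= 0)) stop("`rho_bar` must be > 0", call. = FALSE)
  if (any(k < 0)) stop("`k` must be >= 0", call. = FALSE)
  uss <- uniform_steady_state(rho_bar, params)
  g <- params$sigma + rho_bar * crowding_potential_deriv(rho_bar, params) +
    rho_bar * signal_potential_deriv(uss["U_a"], params$alpha_a,
                                     params$beta_a) *
      params$s_a / (params$gamma_a + params$D_a * k^2)
  if (params$repellent)
    g <- g + rho_bar * signal_potential_deriv(uss["U_r"], params$alpha_r,
                                              params$beta_r) *
      params$s_r / (params$gamma_r + params$D_r * k^2)
  unname(g)
}

# Linearization matrix at wavenumber k about the uniform state.
# Row/column order: (rho, U_a[, U_r]).
linearization_matrix <- function(k, rho_bar, params) {
  uss <- uniform_steady_state(rho_bar, params)
  nch <- if (params$repellent) 2L else 1L
  M <- matrix(0, 1L + nch, 1L + nch)
  M[1, 1] <- -k^2 * (params$sigma +
                       rho_bar * crowding_potential_deriv(rho_bar, params))
  M[1, 2] <- -k^2 * rho_bar *
    signal_potential_deriv(uss["U_a"], params$alpha_a, params$beta_a)
  M[2, 1] <- params$s_a
  M[2, 2] <- -(params$gamma_a + params$D_a * k^2)
  if (params$repellent) {
    M[1, 3] <- -k^2 * rho_bar *
      signal_potential_deriv(uss["U_r"], params$alpha_r, params$beta_r)
    M[3, 1] <- params$s_r
    M[3, 3] <- -(params$gamma_r + params$D_r * k^2)
  }
  M
}

#' Dispersion relation of the uniform state
#'
#' For each wavenumber, assembles the linearization of the full coupled
#' system about the uniform steady state and returns the largest real
#' part of its eigenvalues: the growth rate of a sinusoidal perturbation.
#'
#' @param k wavenumbers (radians/cm), \code{>= 0}.
#' @param rho_bar uniform density (cm^-d), \code{> 0}.
#' @param params a \code{\link{ks_params}} object.
#' @return An object of class \code{"ks_dispersion"}: a data frame with
#'   columns \code{k} (radians/cm) and \code{growth_rate} (1/s), carrying
#'   \code{rho_bar} and the model variant as attributes.
#' @export
growth_rates <- function(k, rho_bar, params) {
  if (any(k < 0)) stop("`k` must be >= 0", call. = FALSE)
  if (rho_bar <= 0) stop("`rho_bar` must be > 0", call. = FALSE)
  gr <- vapply(k, function(ki) {
    ev <- eigen(linearization_matrix(ki, rho_bar, params),
                only.values = TRUE)$values
    max(Re(ev))
  }, 0)
  out <- data.frame(k = k, growth_rate = gr)
  attr(out, "rho_bar") <- rho_bar
  attr(out, "repellent") <- params$repellent
  class(out) <- c("ks_dispersion", "data.frame")
  out
}

# Minimum of the marginal condition over wavenumber at fixed density.
min_marginal <- function(rho_bar, params, k_max = 1000) {
  # minimize over log-spaced candidates, then polish with optimize()
  ks <- c(0, exp(seq(log(1e-2), log(k_max), length.out = 200)))
  gs <- marginal_condition(ks, rho_bar, params)
  i <- which.min(gs)
  lo <- ks[max(1L, i - 1L)]
  hi <- ks[min(length(ks), i + 1L)]
  if (hi > lo) {
    op <- stats::optimize(function(k) marginal_condition(k, rho_bar, params),
                          c(lo, hi), tol = 1e-10)
    if (op$objective < gs[i]) return(list(k = op$minimum, g = op$objective))
  }
  list(k = ks[i], g = gs[i])
}

#' Density threshold for the aggregation instability
#'
#' The smallest mean density at which some wavenumber becomes unstable,
#' found by bisection on the density with an inner minimization of
#' \code{\link{marginal_condition}} over wavenumber. With the default
#' calibration the attractant-only model gives 1500 cm^-d and the
#' attractant+repellent model 2357 cm^-d.
#'
#' @param params a \code{\link{ks_params}} object.
#' @param bracket density search interval (cm^-d).
#' @param tol relative tolerance on the threshold density.
#' @param k_max largest wavenumber searched (radians/cm).
#' @return An object of class \code{"ks_threshold"}: list with
#'   \code{rho_star} (threshold density), \code{k_c} (critical wavenumber
#'   at threshold, radians/cm), and \code{bracket}. If no threshold lies
#'   in the bracket, \code{rho_star} is \code{NA} and the bracket is
#'   reported.
#' @export
instability_threshold <- function(params, bracket = c(10, 1e6), tol = 1e-8,
                                  k_max = 1000) {
  f <- function(rho) min_marginal(rho, params, k_max)$g
  lo <- bracket[1]
  hi <- bracket[2]
  if (f(lo) < 0 || f(hi) > 0) {
    out <- list(rho_star = NA_real_, k_c = NA_real_, bracket = bracket)
    class(out) <- "ks_threshold"
    return(out)
  }
  while ((hi - lo) / hi > tol) {
    mid <- sqrt(lo * hi)
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  rho_star <- sqrt(lo * hi)
  out <- list(rho_star = rho_star,
              k_c = min_marginal(rho_star, params, k_max)$k,
              bracket = bracket)
  class(out) <- "ks_threshold"
  out
}

#' @export
print.ks_threshold <- function(x, ...) {
  if (is.na(x$rho_star)) {
    cat("No instability threshold found in bracket [",
        x$bracket[1], ", ", x$bracket[2], "] cm^-d\n", sep = "")
  } else {
    cat(sprintf("Instability threshold: rho* = %.2f cm^-d (k_c = %.3f rad/cm)\n",
                x$rho_star, x$k_c))
  }
  invisible(x)
}

#' Fastest-growing wavenumber
#'
#' The wavenumber maximizing the linear growth rate at a given density,
#' located by golden-section search on the continuous dispersion curve
#' (after a coarse scan to bracket the maximum). Below the instability
#' threshold there is no positively growing mode and an error is raised.
#'
#' @inheritParams growth_rates
#' @param k_max largest wavenumber searched (radians/cm).
#' @return Wavenumber \code{k*} in radians/cm (divide by \code{2*pi} for
#'   cycles/cm).
#' @export
fastest_growing_wavenumber <- function(rho_bar, params, k_max = 1000) {
  gr <- function(k) {
    max(Re(eigen(linearization_matrix(k, rho_bar, params),
                 only.values = TRUE)$values))
  }
  ks <- exp(seq(log(1e-2), log(k_max), length.out = 300))
  gs <- vapply(ks, gr, 0)
  i <- which.max(gs)
  if (gs[i] <= 0) {
    # near threshold the unstable band is narrow; look where the
    # marginal condition is most negative before giving up
    km <- min_marginal(rho_bar, params, k_max)
    if (km$g < 0) {
      ks <- c(ks, km$k)
      gs <- c(gs, gr(km$k))
      i <- which.max(gs)
    }
    if (gs[i] <= 0)
      stop(sprintf(
        "density %g is below the instability threshold: no growing mode",
        rho_bar), call. = FALSE)
  }
  o <- order(ks)
  ks <- ks[o]
  gs <- gs[o]
  i <- which.max(gs)
  lo <- ks[max(1L, i - 1L)]
  hi <- ks[min(length(ks), i + 1L)]
  op <- stats::optimize(gr, c(lo, hi), maximum = TRUE, tol = 1e-10)
  if (op$objective >= gs[i]) op$maximum else ks[i]
}

# nth positive zero of the Bessel function J1, by bisection from the
# asymptotic bracket (McMahon expansion locates them near (n + 1/4) pi).
besselj1_zero <- function(n) {
  vapply(n, function(m) {
    if (m < 1) stop("`n` must be >= 1", call. = FALSE)
    guess <- (m + 0.25) * pi
    stats::uniroot(function(x) besselJ(x, 1), c(guess - 1.2, guess + 1.2),
                   tol = 1e-12)$root
  }, 0)
}

#' Slowest diffusion eigenmode on a disk
#'
#' For pure diffusion on a disk of radius \code{R} with a no-flux
#' (Neumann) boundary, the circularly symmetric eigenmodes are
#' \code{J0(k r) exp(-sigma k^2 t)} with \code{k = j_{1,n}/R}, where
#' \code{j_{1,n}} is the nth nontrivial zero of \code{J1}. The slowest
#' mode (n = 1) sets the time scale on which worms spread over a petri
#' plate, which is how the random-motility coefficient was originally
#' calibrated (12 h spreading on a 3 cm radius plate).
#'
#' @param sigma diffusion coefficient (cm^2/s), \code{> 0}.
#' @param R disk radius (cm), \code{> 0}.
#' @param n mode index, \code{>= 1}.
#' @return List with \code{k} (radians/cm) and \code{tau} (the mode's
#'   decay time constant \code{1/(sigma k^2)}, s).
#' @export
disk_mode_time_constant <- function(sigma, R, n = 1) {
  if (sigma <= 0 || R <= 0) stop("`sigma` and `R` must be > 0", call. = FALSE)
  k <- besselj1_zero(n) / R
  list(k = k, tau = 1 / (sigma * k^2))
}
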