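#' Right-hand side of a signal reaction-diffusion equation
#'
#' \code{dU/dt = -gamma * U + D * laplacian(U) + s * rho}: first-order
#' decay, diffusion, and secretion by the worms.
#'
#' @param U signal concentration field.
#' @param rho worm density field.
#' @param gamma decay rate (1/s).
#' @param D diffusion constant (cm^2/s).
#' @param s per-worm secretion rate (cm^-d/s).
#' @param grid a \code{\link{periodic_grid}}.
#' @return Field of time derivatives.
#' @export
chemical_rhs <- function(U, rho, gamma, D, s, grid) {
  check_shape(U, grid); check_shape(rho, grid)
  -gamma * U + D * laplacian_op(U, grid) + s * rho
}

#' Right-hand side of the worm density equation
#'
#' The Fokker-Planck equation \code{drho/dt = div(rho * grad V + sigma *
#' grad rho)} with \code{V} the total movement potential. It is
#' discretized in flux form: the advective flux is the fourth-order face
#' interpolation of \code{rho} times the face gradient of \code{V}, the
#' diffusive flux is \code{sigma} times the face gradient of \code{rho},
#' and both are differenced with the conservative fourth-order face
#' divergence. The grid sum of the result is zero to rounding for any
#' state, so worm number is conserved exactly per evaluation.
#'
#' @param state a \code{\link{field_state}} with \code{rho > 0}
#'   everywhere.
#' @param params effective \code{\link{ks_params}} (already
#'   slowdown-scaled if applicable).
#' @param grid a \code{\link{periodic_grid}}.
#' @return Field \code{drho/dt}.
#' @export
worm_rhs <- function(state, params, grid) {
  if (any(state$rho <= 0)) stop("rho must be > 0 everywhere", call. = FALSE)
  worm_rhs_raw(state$rho, state$U_a, state$U_r, params, grid)
}

# Unchecked kernel shared with the stiff integrator, which may probe
# transiently nonpositive densities while estimating Jacobians or trial
# steps. Potential arguments are clamped at zero there; the flux itself
# uses the actual field values so the linear terms stay exact.
worm_rhs_raw <- function(rho, U_a, U_r, params, grid) {
  rc <- if (min(rho) < 0) pmax(rho, 0) else rho
  V <- -params$beta_a * log(params$alpha_a + pmax(U_a, 0)) +
    params$sigma * params$scale / 2 *
      (1 + tanh((rc - params$rho_max) / params$cushion))
  if (params$repellent)
    V <- V - params$beta_r * log(params$alpha_r + pmax(U_r, 0))
  out <- 0
  for (ax in seq_len(grid$dim)) {
    h <- grid$spacing[ax]
    flux <- face_interp(rho, ax) * face_gradient(V, h, ax) +
      params$sigma * face_gradient(rho, h, ax)
    out <- out + face_divergence(flux, h, ax)
  }
  out
}

#' Assembled right-hand side of the full PDE system
#'
#' Stacks the worm equation (with slowdown-scaled movement parameters at
#' time \code{t}) and the enabled signal equations.
#'
#' @param state a \code{\link{field_state}}.
#' @param params \code{\link{ks_params}} (t = 0 values).
#' @param grid a \code{\link{periodic_grid}}.
#' @param t time (s), used only by the slowdown schedule.
#' @param schedule optional \code{\link{slowdown_schedule}}.
#' @return List with fields \code{rho}, \code{U_a} and (if enabled)
#'   \code{U_r} holding the time derivatives.
#' @export
full_rhs <- function(state, params, grid, t = state$t, schedule = NULL) {
  pe <- effective_params(params, t, schedule)
  out <- list(rho = worm_rhs(state, pe, grid),
              U_a = chemical_rhs(state$U_a, state$rho, params$gamma_a,
                                 params$D_a, params$s_a, grid))
  if (params$repellent)
    out$U_r <- chemical_rhs(state$U_r, state$rho, params$gamma_r,
                            params$D_r, params$s_r, grid)
  out
}

#' Worm velocity field
#'
#' Mean worm velocity \code{v = -grad V} with \code{V} the total movement
#' potential, and its pointwise Euclidean magnitude. At a uniform
#' equilibrium the magnitude vanishes.
#'
#' @inheritParams worm_rhs
#' @return List with per-axis components (\code{vx}, and \code{vy} in 2D)
#'   and \code{speed}.
#' @export
velocity_field <- function(state, params, grid) {
  V <- total_potential(state$rho, state$U_a, state$U_r, params)
  vx <- -center_gradient(V, grid$spacing[1], 1L)
  if (grid$dim == 1L)
    return(list(vx = vx, speed = abs(vx)))
  vy <- -center_gradient(V, grid$spacing[2], 2L)
  list(vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2))
}

# --- state packing for the method-of-lines integrator ------------------

n_fields <- function(params) if (params$repellent) 3L else 2L

pack_state <- function(state, params) {
  if (params$repellent) c(state$rho, state$U_a, state$U_r)
  else c(state$rho, state$U_a)
}

unpack_state <- function(y, t, params, grid) {
  np <- prod(grid$n)
  as_field <- function(v) {
    if (grid$dim == 2L) matrix(v, grid$n[1], grid$n[2]) else v
  }
  rho <- as_field(y[seq_len(np)])
  U_a <- as_field(y[np + seq_len(np)])
  U_r <- if (params$repellent) as_field(y[2L * np + seq_len(np)]) else NULL
  structure(list(t = t, rho = rho, U_a = U_a, U_r = U_r),
            class = "ks_state")
}
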