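#' Adaptive step controller
#'
#' Settings for the implicit adaptive time integrator: local error
#' tolerances, step bounds, and whether the velocity-based (CFL-style)
#' step cap is applied.
#'
#' @param rtol relative local error tolerance per step.
#' @param atol absolute local error tolerance (field units).
#' @param dt_init initial step size (s).
#' @param dt_min smallest allowed step; going below it aborts the
#'   integration with a diagnostic error.
#' @param dt_max largest allowed step.
#' @param cfl logical; cap the step at \code{min(dx/|v_x|, dy/|v_y|)}
#'   over all grid points, so no worm advects further than one cell per
#'   step.
#' @return An object of class \code{"ks_controller"}.
#' @export
step_controller <- function(rtol = 1e-6, atol = 1e-9, dt_init = 1,
                            dt_min = 1e-10, dt_max = Inf, cfl = TRUE) {
  stopifnot(rtol > 0, atol > 0, dt_min > 0, dt_init >= dt_min,
            dt_max >= dt_init)
  structure(list(rtol = rtol, atol = atol, dt_init = dt_init,
                 dt_min = dt_min, dt_max = dt_max, cfl = isTRUE(cfl)),
            class = "ks_controller")
}

#' Velocity-based step-size cap
#'
#' The largest time step such that the mean worm velocity carries
#' material at most one grid cell: \code{min} over all points and axes of
#' \code{dx / |v_x|} (and \code{dy / |v_y|}). Returns \code{Inf} (no cap)
#' for an identically zero velocity field.
#'
#' @param state a \code{\link{field_state}}.
#' @param params effective \code{\link{ks_params}}.
#' @param grid a \code{\link{periodic_grid}}.
#' @return Maximum allowed step in seconds (possibly \code{Inf}).
#' @export
cfl_limit <- function(state, params, grid) {
  v <- velocity_field(state, params, grid)
  mx <- max(abs(v$vx))
  cap <- if (mx > 0) grid$spacing[1] / mx else Inf
  if (grid$dim == 2L) {
    my <- max(abs(v$vy))
    if (my > 0) cap <- min(cap, grid$spacing[2] / my)
  }
  cap
}

# Symbol (DFT eigenvalues) of the composed face-divergence(face-gradient)
# Laplacian along one axis. The face gradient and face divergence stencils
# are adjoint up to sign, so the symbol is -|G|^2: real and nonpositive,
# which makes the preconditioner solves unconditionally stable.
lap_symbol_axis <- function(n, h) {
  theta <- 2 * pi * (seq_len(n) - 1) / n
  G <- (exp(-1i * theta) - 27 + 27 * exp(1i * theta) - exp(2i * theta)) /
    (24 * h)
  -Mod(G)^2
}

lap_symbol <- function(grid) {
  Lx <- lap_symbol_axis(grid$n[1], grid$spacing[1])
  if (grid$dim == 1L) return(Lx)
  Ly <- lap_symbol_axis(grid$n[2], grid$spacing[2])
  outer(Lx, rep(1, grid$n[2])) + outer(rep(1, grid$n[1]), Ly)
}

# Full RHS through the compiled kernel; returns the packed derivative.
rhs_kernel <- function(y, params, grid) {
  ny <- if (grid$dim == 2L) grid$n[2] else 1L
  hy <- if (grid$dim == 2L) grid$spacing[2] else 1
  ks_rhs_cpp(y, params, grid$n[1], ny, grid$spacing[1], hy)
}

ifft_real <- function(uh) Re(stats::fft(uh, inverse = TRUE)) / length(uh)

# Right-preconditioned GMRES (modified Gram-Schmidt, single cycle).
gmres_solve <- function(Jv, b, prec1, tol = 0.05, maxit = 30L) {
  n <- length(b)
  bn <- sqrt(sum(b^2))
  if (bn == 0) return(list(x = numeric(n), it = 0L, ok = TRUE))
  V <- matrix(0, n, maxit + 1L)
  H <- matrix(0, maxit + 1L, maxit)
  cs <- sn <- numeric(maxit)
  gvec <- numeric(maxit + 1L)
  V[, 1] <- b / bn
  gvec[1] <- bn
  k_used <- 0L
  ok <- FALSE
  for (k in seq_len(maxit)) {
    w <- Jv(prec1(V[, k]))
    for (i in seq_len(k)) {
      H[i, k] <- sum(w * V[, i])
      w <- w - H[i, k] * V[, i]
    }
    H[k + 1L, k] <- sqrt(sum(w^2))
    if (H[k + 1L, k] > 0) V[, k + 1L] <- w / H[k + 1L, k]
    for (i in seq_len(k - 1L)) {
      tmp <- cs[i] * H[i, k] + sn[i] * H[i + 1L, k]
      H[i + 1L, k] <- -sn[i] * H[i, k] + cs[i] * H[i + 1L, k]
      H[i, k] <- tmp
    }
    d <- sqrt(H[k, k]^2 + H[k + 1L, k]^2)
    cs[k] <- H[k, k] / d
    sn[k] <- H[k + 1L, k] / d
    H[k, k] <- d
    gvec[k + 1L] <- -sn[k] * gvec[k]
    gvec[k] <- cs[k] * gvec[k]
    k_used <- k
    if (abs(gvec[k + 1L]) <= tol * bn) {
      ok <- TRUE
      break
    }
  }
  ysol <- backsolve(H[seq_len(k_used), seq_len(k_used), drop = FALSE],
                    gvec[seq_len(k_used)])
  list(x = prec1(V[, seq_len(k_used), drop = FALSE] %*% ysol),
       it = k_used, ok = ok)
}

#' Advance the PDE system in time
#'
#' Integrates the coupled worm/signal system from \code{state$t} to
#' \code{t_target} with a variable-step implicit backward-differentiation
#' scheme of order 2 (implicit Euler startup), A-stable and suited to the
#' stiffness of the crowding terms at sharp aggregate interfaces. The
#' nonlinear stage equations are solved by inexact Newton iteration with
#' matrix-free Jacobian-vector products and a preconditioned GMRES linear
#' solver; the preconditioner inverts, exactly and in Fourier space, the
#' constant-coefficient part of the linearization (signal decay and
#' diffusion, plus a worm-diffusion bound covering the crowding-enhanced
#' effective diffusivity).
#'
#' Local error is estimated from the discrepancy between the corrected
#' solution and a quadratic predictor extrapolated through the step
#' history, and kept below \code{atol + rtol * max|u|} per field. The step
#' is additionally capped by \code{\link{cfl_limit}} when enabled. After
#' each accepted step a density floor of \code{1e-6 * rho_bar} is imposed
#' (with global mass renormalization) so the state stays strictly
#' positive.
#'
#' @param state a \code{\link{field_state}}.
#' @param t_target time to integrate to (s), \code{> state$t}.
#' @param params \code{\link{ks_params}} (t = 0 values).
#' @param grid a \code{\link{periodic_grid}}.
#' @param schedule optional \code{\link{slowdown_schedule}}.
#' @param controller a \code{\link{step_controller}}.
#' @return The \code{\link{field_state}} at \code{t_target}, with
#'   attributes \code{steps} (accepted), \code{rejected}, \code{matvecs}
#'   and \code{dt_last}.
#' @export
advance <- function(state, t_target, params, grid, schedule = NULL,
                    controller = step_controller()) {
  if (t_target <= state$t)
    stop("`t_target` must exceed the state time", call. = FALSE)
  rep_on <- params$repellent
  if (rep_on && is.null(state$U_r))
    stop("repellent enabled but state has no U_r field", call. = FALSE)
  np <- prod(grid$n)
  nf <- if (rep_on) 3L else 2L
  sym <- lap_symbol(grid)
  # worm-diffusion bound: sigma + max over rho of rho * V_rho'(rho)
  A <- params$sigma *
    (1 + params$scale * params$rho_max / (2 * params$cushion))
  gam <- c(params$gamma_a, if (rep_on) params$gamma_r)
  Dd <- c(params$D_a, if (rep_on) params$D_r)
  lam <- vector("list", nf)
  lam[[1]] <- A * sym
  for (m in seq_len(nf - 1L)) lam[[m + 1L]] <- -gam[m] + Dd[m] * sym
  floor_rho <- 1e-6 * params$rho_bar
  as_field <- function(v) {
    if (grid$dim == 2L) matrix(v, grid$n[1], grid$n[2]) else v
  }
  fld <- function(y, m) y[(m - 1L) * np + seq_len(np)]

  frhs <- function(y, t) rhs_kernel(y, effective_params(params, t, schedule),
                                    grid)
  wts <- function(y) {
    vapply(seq_len(nf),
           function(m) controller$atol + controller$rtol * max(abs(fld(y, m))),
           0)
  }
  wnorm <- function(e, w) {
    s <- 0
    for (m in seq_len(nf)) s <- s + sum((fld(e, m) / w[m])^2)
    sqrt(s / length(e))
  }
  prec <- function(g, a0, dt) {
    out <- numeric(length(g))
    for (m in seq_len(nf)) {
      gh <- stats::fft(as_field(fld(g, m)))
      out[(m - 1L) * np + seq_len(np)] <-
        ifft_real(gh / (a0 - dt * lam[[m]]))
    }
    out
  }

  y <- c(state$rho, state$U_a, if (rep_on) state$U_r)
  t <- state$t
  hist_y <- list()
  hist_t <- numeric(0)
  n_acc <- 0L; n_rej <- 0L; n_mv <- 0L
  refresh_cap <- function(y, t) {
    if (!controller$cfl) return(Inf)
    st <- structure(list(t = t, rho = as_field(pmax(fld(y, 1), floor_rho)),
                         U_a = as_field(pmax(fld(y, 2), 0)),
                         U_r = if (rep_on) as_field(pmax(fld(y, 3), 0))),
                    class = "ks_state")
    cfl_limit(st, effective_params(params, t, schedule), grid)
  }
  cap <- refresh_cap(y, t)
  cap_age <- 0L
  dt <- min(controller$dt_init, controller$dt_max)

  while (t < t_target - 1e-9 * max(1, abs(t_target))) {
    dt <- min(dt, cap, controller$dt_max, t_target - t)
    if (dt < controller$dt_min)
      stop(sprintf(paste0("step size underflow at t = %g s (dt = %g): ",
                          "integration failure"), t, dt), call. = FALSE)
    tn1 <- t + dt
    nh <- length(hist_y)
    if (nh >= 1L) {
      r <- dt / (t - hist_t[nh])
      a0 <- (1 + 2 * r) / (1 + r)
      rhs_c <- (1 + r) * y - r^2 / (1 + r) * hist_y[[nh]]
      if (nh >= 2L) {
        tt <- c(hist_t[nh - 1L], hist_t[nh], t)
        L1 <- (tn1 - tt[2]) * (tn1 - tt[3]) / ((tt[1] - tt[2]) * (tt[1] - tt[3]))
        L2 <- (tn1 - tt[1]) * (tn1 - tt[3]) / ((tt[2] - tt[1]) * (tt[2] - tt[3]))
        L3 <- (tn1 - tt[1]) * (tn1 - tt[2]) / ((tt[3] - tt[1]) * (tt[3] - tt[2]))
        ypred <- L1 * hist_y[[nh - 1L]] + L2 * hist_y[[nh]] + L3 * y
      } else {
        ypred <- (1 + r) * y - r * hist_y[[nh]]
      }
    } else {
      # implicit Euler startup step
      a0 <- 1
      rhs_c <- y
      ypred <- y + dt * frhs(y, t)
    }
    w <- wts(y)
    u <- ypred
    ok <- FALSE
    for (it in 1:4) {
      fu <- frhs(u, tn1)
      G <- a0 * u - rhs_c - dt * fu
      Jv <- function(v) {
        eps <- 1e-7 * sqrt(sum(y^2)) / max(sqrt(sum(v^2)), 1e-300)
        n_mv <<- n_mv + 1L
        a0 * v - dt * (frhs(u + eps * v, tn1) - fu) / eps
      }
      sol <- gmres_solve(Jv, -G, function(g) prec(g, a0, dt),
                         tol = 0.05, maxit = 30L)
      u <- u + sol$x
      if (wnorm(sol$x, w) < 0.02) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      n_rej <- n_rej + 1L
      dt <- dt * 0.25
      next
    }
    err <- 0.35 * wnorm(u - ypred, w)
    if (nh < 2L) err <- min(err, 0.5) # startup steps are taken at dt_init
    if (err > 1) {
      n_rej <- n_rej + 1L
      dt <- dt * max(0.1, 0.9 * err^(-1 / 3))
      next
    }
    # accept: positivity floor with mass renormalization
    rho1 <- fld(u, 1)
    if (min(rho1) < floor_rho) {
      m0 <- sum(rho1)
      rho1 <- pmax(rho1, floor_rho)
      u[seq_len(np)] <- rho1 * (m0 / sum(rho1))
    }
    for (m in 2:nf) {
      um <- fld(u, m)
      if (min(um) < 0) u[(m - 1L) * np + seq_len(np)] <- pmax(um, 0)
    }
    hist_y <- c(hist_y, list(y))
    hist_t <- c(hist_t, t)
    if (length(hist_y) > 2L) {
      hist_y <- hist_y[-1]
      hist_t <- hist_t[-1]
    }
    y <- u
    t <- tn1
    n_acc <- n_acc + 1L
    cap_age <- cap_age + 1L
    if (controller$cfl && cap_age >= 5L) {
      cap <- refresh_cap(y, t)
      cap_age <- 0L
    }
    dt <- dt * min(3, max(0.3, 0.9 * max(err, 1e-4)^(-1 / 3)))
  }

  out <- field_state(t_target, as_field(fld(y, 1)), as_field(fld(y, 2)),
                     if (rep_on) as_field(fld(y, 3)), grid)
  attr(out, "steps") <- n_acc
  attr(out, "rejected") <- n_rej
  attr(out, "matvecs") <- n_mv
  attr(out, "dt_last") <- dt
  out
}
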