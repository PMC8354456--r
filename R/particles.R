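# --- particle-mesh helpers --------------------------------------------

# Cloud-in-cell (bilinear) deposition of unit-weight particles onto the
# periodic grid; returns a density field (cm^-d) given the mass carried
# by each particle. Cell centers sit at (i + 1/2) h.
deposit_density <- function(pos, grid, mass_per_particle = 1) {
  np <- prod(grid$n)
  if (grid$dim == 1L) {
    h <- grid$spacing[1]
    u <- pos[, 1] / h - 0.5
    i0 <- floor(u)
    f <- u - i0
    ia <- (i0 %% grid$n[1]) + 1L
    ib <- ((i0 + 1) %% grid$n[1]) + 1L
    dep <- numeric(grid$n[1])
    tab <- rowsum(c(1 - f, f), c(ia, ib))
    dep[as.integer(rownames(tab))] <- tab[, 1]
    return(dep * mass_per_particle / grid$cell_volume)
  }
  hx <- grid$spacing[1]
  hy <- grid$spacing[2]
  ux <- pos[, 1] / hx - 0.5
  uy <- pos[, 2] / hy - 0.5
  i0 <- floor(ux)
  j0 <- floor(uy)
  fx <- ux - i0
  fy <- uy - j0
  ia <- (i0 %% grid$n[1]) + 1L
  ib <- ((i0 + 1) %% grid$n[1]) + 1L
  ja <- (j0 %% grid$n[2]) + 1L
  jb <- ((j0 + 1) %% grid$n[2]) + 1L
  cell <- function(ii, jj) (jj - 1L) * grid$n[1] + ii
  idx <- c(cell(ia, ja), cell(ib, ja), cell(ia, jb), cell(ib, jb))
  wts <- c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  dep <- numeric(np)
  tab <- rowsum(wts, idx)
  dep[as.integer(rownames(tab))] <- tab[, 1]
  matrix(dep * mass_per_particle / grid$cell_volume, grid$n[1], grid$n[2])
}

# Bilinear interpolation of a cell-centered periodic field at particle
# positions (adjoint of the deposition stencil).
interp_field <- function(field, pos, grid) {
  if (grid$dim == 1L) {
    h <- grid$spacing[1]
    u <- pos[, 1] / h - 0.5
    i0 <- floor(u)
    f <- u - i0
    ia <- (i0 %% grid$n[1]) + 1L
    ib <- ((i0 + 1) %% grid$n[1]) + 1L
    return((1 - f) * field[ia] + f * field[ib])
  }
  hx <- grid$spacing[1]
  hy <- grid$spacing[2]
  ux <- pos[, 1] / hx - 0.5
  uy <- pos[, 2] / hy - 0.5
  i0 <- floor(ux)
  j0 <- floor(uy)
  fx <- ux - i0
  fy <- uy - j0
  ia <- (i0 %% grid$n[1]) + 1L
  ib <- ((i0 + 1) %% grid$n[1]) + 1L
  ja <- (j0 %% grid$n[2]) + 1L
  jb <- ((j0 + 1) %% grid$n[2]) + 1L
  (1 - fx) * (1 - fy) * field[cbind(ia, ja)] +
    fx * (1 - fy) * field[cbind(ib, ja)] +
    (1 - fx) * fy * field[cbind(ia, jb)] +
    fx * fy * field[cbind(ib, jb)]
}

#' Overdamped Langevin particle simulation
#'
#' Individual-based cross-check of the continuum model: N particles
#' follow the Euler-Maruyama discretization of the overdamped Langevin
#' equation \code{dX = -grad V dt + sqrt(2 sigma) dW} on the periodic
#' domain, whose population density evolves, in the large-N limit,
#' exactly according to the worm Fokker-Planck equation. The potential
#' is evaluated on the grid from the particles' own deposited density
#' (cloud-in-cell) and the signal fields, which are advanced on the grid
#' with the particle density as source (exact Fourier update of the
#' linear signal equations per step). With \code{frozen_V} the potential
#' is held fixed instead, for which the stationary particle density is
#' the Gibbs distribution \code{exp(-V / sigma)}.
#'
#' The slowdown schedule scales the drift by \code{exp(-t/tau)} and the
#' noise amplitude by its square root, matching the time-scaled
#' \code{sigma(t)} and \code{beta(t)} of the continuum model.
#'
#' @param n number of particles, \code{>= 100}.
#' @param params a \code{\link{ks_params}}; \code{rho_bar} sets the mass
#'   each particle carries (\code{rho_bar * area / n}).
#' @param grid a \code{\link{periodic_grid}}.
#' @param t_end end time (s).
#' @param dt time step (s); automatically sub-stepped (with a warning)
#'   if the drift would carry particles further than one cell.
#' @param seed RNG seed.
#' @param frozen_V optional fixed potential field on the grid; when
#'   given, signals are not evolved and \code{V} is constant in time.
#' @param schedule optional \code{\link{slowdown_schedule}}.
#' @param init \code{"uniform"} (uniform random positions) or a numeric
#'   matrix of initial positions (n rows, d columns).
#' @return An object of class \code{"ks_particles"}: list with
#'   \code{positions} (final n x d matrix), \code{density} (final
#'   deposited density field), \code{U_a}, \code{U_r} (final signal
#'   fields, unless frozen), \code{t}, \code{n}, \code{seed},
#'   \code{mass_per_particle}.
#' @export
simulate_particles <- function(n, params, grid, t_end, dt, seed = 1,
                               frozen_V = NULL, schedule = NULL,
                               init = "uniform") {
  if (n < 100) stop("`n` must be >= 100", call. = FALSE)
  if (dt <= 0 || t_end <= 0) stop("`dt` and `t_end` must be > 0",
                                  call. = FALSE)
  set.seed(seed)
  d <- grid$dim
  if (is.matrix(init)) {
    pos <- init
    stopifnot(nrow(pos) == n, ncol(pos) == d)
  } else {
    pos <- matrix(stats::runif(n * d), n, d)
    for (ax in seq_len(d)) pos[, ax] <- pos[, ax] * grid$extent[ax]
  }
  mpp <- params$rho_bar * prod(grid$extent) / n
  frozen <- !is.null(frozen_V)
  rep_on <- params$repellent && !frozen

  sym <- if (!frozen) lap_symbol(grid)
  U_a <- U_r <- NULL
  if (!frozen) {
    uss <- uniform_steady_state(params$rho_bar, params)
    as_field <- function(v) {
      if (d == 2L) matrix(v, grid$n[1], grid$n[2]) else v
    }
    U_a <- as_field(rep(uss["U_a"], prod(grid$n)))
    if (rep_on) U_r <- as_field(rep(uss["U_r"], prod(grid$n)))
  }

  chem_step <- function(U, gamma, D, s, rho_dep, dt) {
    lam <- -gamma + D * sym
    Uh <- stats::fft(U)
    rh <- stats::fft(rho_dep)
    phi <- (exp(lam * dt) - 1) / lam # lam < 0 everywhere: no 0/0
    ifft_real(exp(lam * dt) * Uh + phi * s * rh)
  }

  nt <- ceiling(t_end / dt)
  dt <- t_end / nt
  warned <- FALSE
  t <- 0
  for (it in seq_len(nt)) {
    f <- slowdown_factor(t, schedule)
    if (frozen) {
      V <- frozen_V
    } else {
      rho_dep <- deposit_density(pos, grid, mpp)
      V <- total_potential(pmax(rho_dep, 0), U_a, U_r,
                           effective_params(params, t, schedule))
    }
    gx <- center_gradient(V, grid$spacing[1], 1L)
    drift <- matrix(0, n, d)
    drift[, 1] <- -interp_field(gx, pos, grid)
    if (d == 2L) {
      gy <- center_gradient(V, grid$spacing[2], 2L)
      drift[, 2] <- -interp_field(gy, pos, grid)
    }
    if (frozen && !is.null(schedule)) drift <- drift * f
    vmax <- max(abs(drift))
    nsub <- 1L
    if (vmax * dt > min(grid$spacing)) {
      nsub <- ceiling(vmax * dt / min(grid$spacing))
      if (!warned) {
        warning(sprintf(paste0("dt = %g exceeds the velocity step cap; ",
                               "sub-stepping x%d"), dt, nsub),
                call. = FALSE)
        warned <- TRUE
      }
    }
    sdt <- dt / nsub
    sig_t <- params$sigma * f
    for (ss in seq_len(nsub)) {
      pos <- pos + drift * sdt +
        sqrt(2 * sig_t * sdt) * matrix(stats::rnorm(n * d), n, d)
      for (ax in seq_len(d)) pos[, ax] <- pos[, ax] %% grid$extent[ax]
    }
    if (!frozen) {
      rho_dep <- deposit_density(pos, grid, mpp)
      U_a <- chem_step(U_a, params$gamma_a, params$D_a, params$s_a,
                       rho_dep, dt)
      if (rep_on) U_r <- chem_step(U_r, params$gamma_r, params$D_r,
                                   params$s_r, rho_dep, dt)
    }
    t <- t + dt
  }
  structure(list(positions = pos,
                 density = deposit_density(pos, grid, mpp),
                 U_a = U_a, U_r = U_r, t = t, n = n, seed = seed,
                 mass_per_particle = mpp),
            class = "ks_particles")
}

#' Compare a particle density with a PDE density
#'
#' Side-by-side metrics for the individual-based cross-check: the
#' mass-normalized L1 distance \code{sum |rho1 - rho2| dA / M} (0 for
#' identical fields, 2 for equal masses on disjoint supports), each
#' field's dense-area fraction, and each field's aggregate count.
#'
#' @param rho_particles density field from
#'   \code{\link{simulate_particles}} (or any density).
#' @param rho_pde density field from the continuum solver, same grid.
#' @param grid a \code{\link{periodic_grid}}.
#' @param threshold density cut for the dense/aggregate metrics
#'   (default \code{rho_max/2} needs \code{params}).
#' @param params optional \code{\link{ks_params}} for the default
#'   threshold.
#' @return List with \code{l1}, \code{dense_fraction} (length-2 vector:
#'   particles, pde) and \code{count} (length-2 vector).
#' @export
compare_density <- function(rho_particles, rho_pde, grid,
                            threshold = NULL, params = NULL) {
  check_shape(rho_particles, grid)
  check_shape(rho_pde, grid)
  if (is.null(threshold)) {
    if (is.null(params))
      stop("supply `threshold` or `params`", call. = FALSE)
    threshold <- params$rho_max / 2
  }
  m <- sum(rho_pde) * grid$cell_volume
  l1 <- sum(abs(rho_particles - rho_pde)) * grid$cell_volume / m
  a1 <- aggregate_summary(rho_particles, grid, threshold = threshold)
  a2 <- aggregate_summary(rho_pde, grid, threshold = threshold)
  list(l1 = l1,
       dense_fraction = c(particles = a1$dense_fraction,
                          pde = a2$dense_fraction),
       count = c(particles = a1$count, pde = a2$count))
}
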