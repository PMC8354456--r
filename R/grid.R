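#' Uniform periodic grid
#'
#' Cell-centered uniform tensor grid on [0, w] (1D) or [0, w] x [0, h]
#' (2D) with periodic wraparound. Cell centers sit at \code{(i + 1/2) *
#' dx}, 0-based. Fields on the grid are numeric vectors (1D) or matrices
#' with rows indexing x and columns indexing y (2D).
#'
#' @param n points per axis: a single integer (1D) or length-2 integer
#'   vector \code{c(n_x, n_y)} (2D). At least 8 points per axis.
#' @param extent domain size per axis in cm, recycled to \code{length(n)}.
#' @return An object of class \code{"ks_grid"} with elements \code{dim},
#'   \code{n}, \code{extent}, \code{spacing}, \code{cell_volume} and
#'   coordinate vectors \code{x} (and \code{y}).
#' @examples
#' g <- periodic_grid(c(128, 128), extent = 1)
#' @export
periodic_grid <- function(n, extent = 1) {
  n <- as.integer(n)
  d <- length(n)
  if (!d %in% c(1L, 2L)) stop("`n` must have length 1 or 2", call. = FALSE)
  if (any(n < 8L)) stop("need at least 8 points per axis", call. = FALSE)
  extent <- rep_len(as.numeric(extent), d)
  if (any(extent <= 0)) stop("`extent` must be positive", call. = FALSE)
  spacing <- extent / n
  g <- list(dim = d, n = n, extent = extent, spacing = spacing,
            cell_volume = prod(spacing),
            x = (seq_len(n[1]) - 0.5) * spacing[1])
  if (d == 2L) g$y <- (seq_len(n[2]) - 0.5) * spacing[2]
  class(g) <- "ks_grid"
  g
}

#' @export
print.ks_grid <- function(x, ...) {
  cat("Periodic grid: ", paste(x$n, collapse = " x "), " points on ",
      paste(format(x$extent), collapse = " x "), " cm, spacing ",
      paste(format(x$spacing), collapse = " x "), " cm\n", sep = "")
  invisible(x)
}

#' Simulation field state
#'
#' Bundles the worm density and signal concentration fields with the
#' current time. Density must be strictly positive everywhere (the worm
#' equation contains log(rho)); the integrator maintains this with a
#' density floor.
#'
#' @param t current time (s).
#' @param rho worm density field (cm^-d), strictly positive.
#' @param U_a attractant concentration field (cm^-d), nonnegative.
#' @param U_r repellent concentration field, or \code{NULL} for the
#'   attractant-only model.
#' @param grid the \code{\link{periodic_grid}} the fields live on.
#' @return An object of class \code{"ks_state"}.
#' @export
field_state <- function(t, rho, U_a, U_r = NULL, grid) {
  chk <- function(f, name) {
    if (grid$dim == 1L) {
      if (!is.numeric(f) || length(f) != grid$n[1])
        stop(name, " has wrong shape for grid", call. = FALSE)
    } else {
      if (!is.matrix(f) || any(dim(f) != grid$n))
        stop(name, " has wrong shape for grid", call. = FALSE)
    }
  }
  chk(rho, "rho"); chk(U_a, "U_a")
  if (!is.null(U_r)) chk(U_r, "U_r")
  if (any(rho <= 0)) stop("rho must be > 0 everywhere", call. = FALSE)
  if (any(U_a < 0) || (!is.null(U_r) && any(U_r < 0)))
    stop("signal concentrations must be >= 0", call. = FALSE)
  structure(list(t = t, rho = unname(rho), U_a = unname(U_a),
                 U_r = if (!is.null(U_r)) unname(U_r)),
            class = "ks_state")
}

#' @export
print.ks_state <- function(x, ...) {
  cat(sprintf("Field state at t = %g s\n", x$t))
  cat(sprintf("  rho: [%g, %g]\n", min(x$rho), max(x$rho)))
  cat(sprintf("  U_a: [%g, %g]\n", min(x$U_a), max(x$U_a)))
  if (!is.null(x$U_r))
    cat(sprintf("  U_r: [%g, %g]\n", min(x$U_r), max(x$U_r)))
  invisible(x)
}

# Circular shift along an axis: result[i] = u[i + k] with periodic wrap.
shift_periodic <- function(u, k, axis = 1L) {
  if (is.matrix(u)) {
    n <- dim(u)[axis]
    idx <- ((seq_len(n) - 1L + k) %% n) + 1L
    if (axis == 1L) u[idx, , drop = FALSE] else u[, idx, drop = FALSE]
  } else {
    n <- length(u)
    u[((seq_len(n) - 1L + k) %% n) + 1L]
  }
}

# Fourth-order face-centered gradient along an axis. Element i of the
# result is the gradient at face i+1/2 (between cells i and i+1):
#   g = (27 (u_{i+1} - u_i) - (u_{i+2} - u_{i-1})) / (24 h)
face_gradient <- function(u, h, axis = 1L) {
  up1 <- shift_periodic(u, 1L, axis)
  (27 * (up1 - u) -
     (shift_periodic(u, 2L, axis) - shift_periodic(u, -1L, axis))) / (24 * h)
}

# Fourth-order interpolation of cell values to face i+1/2.
face_interp <- function(u, axis = 1L) {
  (9 * (u + shift_periodic(u, 1L, axis)) -
     (shift_periodic(u, -1L, axis) + shift_periodic(u, 2L, axis))) / 16
}

# Fourth-order divergence of a face-centered flux (element i = flux at
# face i+1/2):
#   div_i = (27 (F_{i+1/2} - F_{i-1/2}) - (F_{i+3/2} - F_{i-3/2})) / (24 h)
# Every stencil is a periodic circular convolution whose coefficients sum
# to zero, so the grid sum of the divergence vanishes to rounding: total
# mass is conserved exactly.
face_divergence <- function(F, h, axis = 1L) {
  Fm1 <- shift_periodic(F, -1L, axis)
  (27 * (F - Fm1) -
     (shift_periodic(F, 1L, axis) - shift_periodic(F, -2L, axis))) / (24 * h)
}

# Fourth-order cell-centered first derivative (used for velocity fields,
# not for the conservative flux divergence).
center_gradient <- function(u, h, axis = 1L) {
  (shift_periodic(u, -2L, axis) - 8 * shift_periodic(u, -1L, axis) +
     8 * shift_periodic(u, 1L, axis) - shift_periodic(u, 2L, axis)) / (12 * h)
}

#' Periodic spatial operators
#'
#' Fourth-order central-difference gradient and Laplacian with periodic
#' wraparound. The Laplacian is assembled as the face divergence of the
#' face gradient, so it is exactly conservative (its grid sum is zero to
#' rounding) and formally fourth-order accurate; both operators annihilate
#' constants exactly.
#'
#' @param field numeric vector (1D) or matrix (2D) matching the grid.
#' @param grid a \code{\link{periodic_grid}}.
#' @return List with \code{gradient} (list of per-axis arrays) and
#'   \code{laplacian}.
#' @export
spatial_operators <- function(field, grid) {
  check_shape(field, grid)
  grad <- vector("list", grid$dim)
  lap <- 0
  for (ax in seq_len(grid$dim)) {
    h <- grid$spacing[ax]
    grad[[ax]] <- center_gradient(field, h, ax)
    lap <- lap + face_divergence(face_gradient(field, h, ax), h, ax)
  }
  names(grad) <- c("x", "y")[seq_len(grid$dim)]
  list(gradient = grad, laplacian = lap)
}

check_shape <- function(field, grid) {
  ok <- if (grid$dim == 1L) {
    is.numeric(field) && !is.matrix(field) && length(field) == grid$n[1]
  } else {
    is.matrix(field) && all(dim(field) == grid$n)
  }
  if (!ok) stop("field shape does not match grid", call. = FALSE)
  invisible(TRUE)
}

# Laplacian only (avoids computing gradients when not needed).
laplacian_op <- function(field, grid) {
  lap <- 0
  for (ax in seq_len(grid$dim)) {
    h <- grid$spacing[ax]
    lap <- lap + face_divergence(face_gradient(field, h, ax), h, ax)
  }
  lap
}

#' Total worm number on the grid
#'
#' Cell-volume-weighted integral of a density field over the whole domain.
#'
#' @param rho density field.
#' @param grid a \code{\link{periodic_grid}}.
#' @return Total mass (number of worms).
#' @export
total_mass <- function(rho, grid) sum(rho) * grid$cell_volume
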