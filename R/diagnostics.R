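#' Expected worm count in a region
#'
#' The density field integrated over a region: because the continuum
#' density is best read as a measure, this is the expected number of
#' worms in the region (and, where it is much less than 1, the
#' probability of finding a single worm there).
#'
#' @param rho density field.
#' @param grid a \code{\link{periodic_grid}}.
#' @param mask logical field selecting the region; \code{NULL} means the
#'   whole domain.
#' @return Expected worm count (dimensionless).
#' @export
expected_count <- function(rho, grid, mask = NULL) {
  check_shape(rho, grid)
  if (is.null(mask)) return(sum(rho) * grid$cell_volume)
  sum(rho[mask]) * grid$cell_volume
}

#' Worm-weighted mean of a field
#'
#' The average of a field over worms rather than over area:
#' \code{integral(rho * field) / integral(rho)}. Applied to the density
#' itself this gives the worm-weighted mean density, which after
#' aggregation greatly exceeds the area-weighted mean (most worms sit in
#' dense aggregates; most area is nearly empty).
#'
#' @param field field to average (same shape as \code{rho}).
#' @param rho density field (the weight).
#' @param grid a \code{\link{periodic_grid}}.
#' @return Weighted mean in the field's units.
#' @export
worm_weighted_mean <- function(field, rho, grid) {
  check_shape(field, grid)
  check_shape(rho, grid)
  tot <- sum(rho)
  if (tot <= 0) stop("total mass must be > 0", call. = FALSE)
  sum(rho * field) / tot
}

#' Sphere of influence of a worm
#'
#' The expected number of worms within one attractant range
#' \code{r_a} of a point at local density \code{rho}:
#' \code{rho * pi * r_a^2}. At the full-scale mean density of
#' 2000 cm^-2 and the default attractant range of 0.01 cm this is 0.63
#' worms; evaluated at the worm-weighted mean density it quantifies how
#' many neighbors a typical worm actually interacts with.
#'
#' @param rho_value local density (cm^-2), \code{>= 0}.
#' @param attractant_range_cm interaction radius (cm), \code{>= 0}.
#' @return Expected worm count.
#' @export
sphere_of_influence <- function(rho_value, attractant_range_cm = 0.01) {
  if (any(rho_value < 0) || any(attractant_range_cm < 0))
    stop("inputs must be >= 0", call. = FALSE)
  rho_value * pi * attractant_range_cm^2
}

#' Elasticity of the Weber-law potential
#'
#' The relative sensitivity of the signal potential at concentration
#' \code{U}, measured against its total rise from zero concentration:
#' \code{E = U * V'(U) / (V(U) - V(0))}, which for the logarithmic
#' potential reduces to \code{U / ((alpha + U) * log(1 + U/alpha))} --
#' independent of the coupling strength \code{beta}. It lies in (0, 1),
#' tends to 1 as \code{U -> 0} (linear regime) and decreases as
#' saturation sets in; at the worm-weighted mean attractant
#' concentration of an aggregated full-scale run (11 600 cm^-2, with
#' \code{alpha} = 1500) it is about 0.41.
#'
#' @param U signal concentration (cm^-d), \code{> 0}; vectorized.
#' @param alpha Weber-law offset (cm^-d), \code{> 0}.
#' @return Elasticity (dimensionless, in (0, 1)).
#' @export
potential_elasticity <- function(U, alpha) {
  if (any(U <= 0)) stop("`U` must be > 0", call. = FALSE)
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  U / ((alpha + U) * log(1 + U / alpha))
}

# Periodic connected-component labeling (two-pass union-find).
# mask: logical vector (1D) or matrix (2D); connectivity 4 or 8 (2D).
label_periodic <- function(mask, connectivity = 4L) {
  if (!is.matrix(mask)) {
    n <- length(mask)
    if (!any(mask)) return(integer(n))
    lab <- integer(n)
    runs <- rle(mask)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    id <- 0L
    for (i in seq_along(runs$values)) {
      if (runs$values[i]) {
        id <- id + 1L
        lab[starts[i]:ends[i]] <- id
      }
    }
    # periodic seam: last run wraps onto the first
    if (mask[1] && mask[n] && lab[1] != lab[n])
      lab[lab == lab[n]] <- lab[1]
    # compact labels
    u <- sort(unique(lab[lab > 0L]))
    lab <- match(lab, u, nomatch = 0L)
    return(lab)
  }
  nx <- nrow(mask)
  ny <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(matrix(0L, nx, ny))
  parent <- seq_along(idx)
  pos <- integer(nx * ny)
  pos[idx] <- seq_along(idx)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  union2 <- function(a, b) {
    ra <- find(a)
    rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  i0 <- (idx - 1L) %% nx
  j0 <- (idx - 1L) %/% nx
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L)
    offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  for (o in offs) {
    nb <- ((i0 + o[1]) %% nx) + ((j0 + o[2]) %% ny) * nx + 1L
    hit <- which(pos[nb] > 0L)
    for (h in hit) union2(h, pos[nb[h]])
  }
  roots <- vapply(seq_along(idx), find, 0L)
  labs <- match(roots, sort(unique(roots)))
  out <- matrix(0L, nx, ny)
  out[idx] <- labs
  out
}

# Circular mean of coordinates on a periodic axis of extent w.
periodic_mean <- function(x, w) {
  ang <- 2 * pi * x / w
  m <- atan2(mean(sin(ang)), mean(cos(ang)))
  (m / (2 * pi) * w) %% w
}

# Minimal distance between two points on a periodic rectangle.
periodic_dist <- function(p, q, extent) {
  d <- abs(p - q)
  d <- pmin(d, extent - d)
  sqrt(sum(d^2))
}

#' Aggregate morphology summary
#'
#' Identifies aggregates as connected components of the region where the
#' density exceeds a threshold (default: half the crowding midpoint
#' \code{rho_max/2}, the natural plateau cut), with the labeling
#' wrapping across the periodic boundaries so a seam-crossing aggregate
#' is counted once. Reports per-aggregate mass, area and (circular-mean)
#' centroid, plus global summaries.
#'
#' @param rho density field.
#' @param grid a \code{\link{periodic_grid}}.
#' @param params a \code{\link{ks_params}} (supplies the default
#'   threshold).
#' @param threshold density cut for "dense" classification (cm^-d).
#' @param connectivity 4 (default) or 8; neighbor rule for the labeling.
#' @return An object of class \code{"ks_aggregates"}: list with
#'   \code{count}, \code{table} (data frame: label, mass, area_cm2,
#'   centroid coordinates), \code{dense_fraction} (dense area / domain
#'   area), and \code{spacing} (nearest-neighbor centroid distances
#'   under the periodic metric; \code{NULL} when count < 2).
#' @export
aggregate_summary <- function(rho, grid, params = NULL,
                              threshold = NULL, connectivity = 4L) {
  check_shape(rho, grid)
  if (is.null(threshold)) {
    if (is.null(params))
      stop("supply `threshold` or `params`", call. = FALSE)
    threshold <- params$rho_max / 2
  }
  mask <- rho > threshold
  lab <- label_periodic(mask, connectivity)
  n <- max(lab)
  if (n == 0L) {
    return(structure(list(count = 0L,
                          table = data.frame(label = integer(0),
                                             mass = numeric(0),
                                             area_cm2 = numeric(0)),
                          dense_fraction = 0, spacing = NULL,
                          threshold = threshold),
                     class = "ks_aggregates"))
  }
  cv <- grid$cell_volume
  tab <- data.frame(label = seq_len(n))
  tab$mass <- vapply(seq_len(n), function(l) sum(rho[lab == l]) * cv, 0)
  tab$area_cm2 <- vapply(seq_len(n), function(l) sum(lab == l) * cv, 0)
  if (grid$dim == 2L) {
    cx <- cy <- numeric(n)
    for (l in seq_len(n)) {
      cells <- which(lab == l)
      i0 <- (cells - 1L) %% grid$n[1]
      j0 <- (cells - 1L) %/% grid$n[1]
      cx[l] <- periodic_mean((i0 + 0.5) * grid$spacing[1], grid$extent[1])
      cy[l] <- periodic_mean((j0 + 0.5) * grid$spacing[2], grid$extent[2])
    }
    tab$x <- cx
    tab$y <- cy
  } else {
    tab$x <- vapply(seq_len(n), function(l) {
      periodic_mean(grid$x[lab == l], grid$extent[1])
    }, 0)
  }
  spacing <- NULL
  if (n >= 2L) {
    cen <- if (grid$dim == 2L) cbind(tab$x, tab$y) else cbind(tab$x)
    ext <- grid$extent
    spacing <- vapply(seq_len(n), function(i) {
      min(vapply(setdiff(seq_len(n), i), function(j) {
        periodic_dist(cen[i, ], cen[j, ], ext)
      }, 0))
    }, 0)
  }
  structure(list(count = n, table = tab,
                 dense_fraction = mean(mask),
                 spacing = spacing, threshold = threshold),
            class = "ks_aggregates")
}

#' @export
print.ks_aggregates <- function(x, ...) {
  cat(sprintf("%d aggregate(s) above %.0f cm^-d; dense-area fraction %.3f\n",
              x$count, x$threshold, x$dense_fraction))
  if (x$count > 0 && x$count <= 20) print(x$table, digits = 4)
  if (!is.null(x$spacing))
    cat(sprintf("  nearest-neighbor spacing: %.3g +/- %.2g cm\n",
                mean(x$spacing), stats::sd(x$spacing)))
  invisible(x)
}
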