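test_that("standardize_image maps any non-constant image onto [0, 1]", {
  set.seed(1)
  img <- matrix(stats::rnorm(64^2, 5, 3), 64, 64)
  s <- standardize_image(img)
  expect_equal(range(s), c(0, 1))
  # already standardized image is unchanged
  expect_equal(standardize_image(s), s)
  # negation flips the standardized image
  expect_equal(standardize_image(-img), 1 - s)
  expect_error(standardize_image(matrix(2, 8, 8)), "constant")
})

test_that("power spectrum concentrates a cosine's power and satisfies Parseval", {
  n <- 96
  w <- 1.5
  x <- (seq_len(n) - 0.5) / n
  m <- 7
  img <- outer(cos(2 * pi * m * x), rep(1, n))
  sp <- power_spectrum(img, w)
  # Parseval under the unitary normalization
  expect_equal(sum(sp$power), sum(img^2), tolerance = 1e-10)
  # symmetry p_{-k} = p_k for a real image
  pw <- sp$power
  idx <- function(i, n) ((i - 1) %% n) + 1
  for (q in list(c(2, 5), c(10, 3), c(40, 17))) {
    expect_equal(pw[q[1] + 1, q[2] + 1],
                 pw[idx(n - q[1] + 1, n), idx(n - q[2] + 1, n)],
                 tolerance = 1e-10)
  }
  # power concentrated at (±m, 0)
  tot <- sum(pw) - pw[1, 1]
  expect_gt((pw[m + 1, 1] + pw[n - m + 1, 1]) / tot, 0.999)
  expect_error(power_spectrum(matrix(1, 4, 6), 1), "square")
})

test_that("radial binning reproduces the fractional-weight worked example", {
  # a single unit of power at k = 2 pi (1, 2) / 1.93 lands at bin
  # coordinate j = 60.26: weight 0.74 to bin 60 and 0.26 to bin 61
  n <- 960
  w <- 1.93
  sp <- structure(list(power = matrix(0, n, n),
                       k_cyc_x = c(0:(n / 2 - 1), -(n / 2):-1) / w,
                       k_cyc_y = c(0:(n / 2 - 1), -(n / 2):-1) / w,
                       width_cm = w, n = n),
                  class = "ks_spectrum2d")
  sp$power[2, 3] <- 1 # (k_x, k_y) = (1, 2)/w cycles/cm
  rs <- radial_sum(sp, 1024, 20)
  j <- 1 + 1023 * (sqrt(5) / 1.93 / 20)
  expect_equal(j, 60.26, tolerance = 1e-3)
  expect_equal(rs$power[60], 61 - j)
  expect_equal(rs$power[61], j - 60)
  expect_equal(rs$power[60], 0.74, tolerance = 0.01)
  expect_equal(rs$power[61], 0.26, tolerance = 0.01)
  expect_equal(sum(rs$power), 1, tolerance = 1e-12)
})

test_that("radial binning conserves weight and sends integer landings to one bin", {
  set.seed(3)
  img <- matrix(stats::runif(64^2), 64, 64)
  sp <- power_spectrum(img, 1)
  rs <- radial_sum(sp, 1024, 50)  # wide enough to keep every mode
  expect_equal(rs$n_dropped, 0)
  expect_equal(sum(rs$power), sum(sp$power), tolerance = 1e-10)
  # integer landing: k_cyc = k_max puts full weight in the last bin
  sp0 <- structure(list(power = matrix(0, 16, 16),
                        k_cyc_x = c(0:7, -8:-1), k_cyc_y = c(0:7, -8:-1),
                        width_cm = 1, n = 16),
                   class = "ks_spectrum2d")
  sp0$power[5, 1] <- 2 # k_cyc = 4 exactly
  rs0 <- radial_sum(sp0, n_bins = 9, k_cyc_max = 8)
  # j = 1 + 8 * 4/8 = 5 exactly
  expect_equal(rs0$power[5], 2)
  expect_equal(sum(rs0$power != 0), 1)
})

test_that("radial spectrum of a pure cosine concentrates near its wavenumber", {
  n <- 128
  x <- (seq_len(n) - 0.5) / n
  img <- outer(cos(2 * pi * 9 * x), rep(1, n)) # 9 cycles/cm on 1 cm
  rs <- radial_sum(power_spectrum(img, 1), 1024, 20)
  binw <- 20 / 1023
  sel <- abs(rs$k_cyc - 9) <= binw
  non_dc <- rs$power
  non_dc[1] <- 0
  expect_gt(sum(non_dc[sel]) / sum(non_dc), 0.95)
})

test_that("Gaussian smoothing preserves power and kills the lattice period", {
  set.seed(5)
  rs <- radial_sum(power_spectrum(matrix(stats::runif(64^2), 64, 64), 1),
                   1024, 50)
  sm0 <- smooth_radial(rs, 0)
  expect_equal(sm0$power, rs$power)
  sm <- smooth_radial(rs, 18.7)
  expect_equal(sum(sm$power), sum(rs$power), tolerance = 0.01)
  # a sawtooth of period 26.5 bins is attenuated at least tenfold
  saw <- structure(list(power = (seq_len(1024) %% 26.5) / 26.5,
                        k_cyc = seq(0, 20, length.out = 1024),
                        n_dropped = 0, smoothed = FALSE),
                   class = "ks_radial_spectrum")
  saw$power <- saw$power - mean(saw$power)
  sms <- smooth_radial(saw, 18.7)
  core <- 100:900 # away from reflected boundaries
  expect_lt(max(abs(sms$power[core])), max(abs(saw$power)) / 10)
})

test_that("synthetic lattices put the dominant peak at the reciprocal ring", {
  # hexagonal lattice, spacing 1 mm: first ring at 2/(sqrt(3) a)
  img_h <- synthetic_pattern(0.1, 0.02, "hexagonal", jitter = 0,
                             width_cm = 1, n_px = 256)
  rs_h <- smooth_radial(radial_sum(power_spectrum(
    standardize_image(img_h), 1), 1024, 20), 5)
  pk_h <- dominant_peak(rs_h)
  expect_equal(pk_h, 2 / (sqrt(3) * 0.1), tolerance = 0.12)
  expect_gt(pk_h, 7)
  expect_lt(pk_h, 13)
  # square lattice, spacing a: peak at 1/a
  img_s <- synthetic_pattern(0.125, 0.025, "square", jitter = 0,
                             width_cm = 1, n_px = 256)
  rs_s <- smooth_radial(radial_sum(power_spectrum(
    standardize_image(img_s), 1), 1024, 20), 5)
  expect_equal(dominant_peak(rs_s), 8, tolerance = 0.1)
  # doubling the physical scale halves the peak wavenumber
  rs_s2 <- smooth_radial(radial_sum(power_spectrum(
    standardize_image(img_s), 2), 1024, 20), 5)
  expect_equal(dominant_peak(rs_s2), 4, tolerance = 0.1)
})

test_that("jitter broadens but does not move the lattice peak", {
  rs_of <- function(j) {
    img <- synthetic_pattern(0.1, 0.02, "hexagonal", jitter = j,
                             width_cm = 1, n_px = 192, seed = 9)
    smooth_radial(radial_sum(power_spectrum(standardize_image(img), 1),
                             1024, 20), 8)
  }
  rs0 <- rs_of(0)
  rs3 <- rs_of(0.3)
  p0 <- dominant_peak(rs0)
  p3 <- dominant_peak(rs3)
  expect_equal(p3, p0, tolerance = 0.15)
  fwhm <- function(rs) {
    sel <- rs$k_cyc >= 2
    pw <- rs$power[sel]
    sum(pw > max(pw) / 2)
  }
  expect_gt(fwhm(rs3), fwhm(rs0))
})

test_that("synthetic pattern spot count follows the lattice geometry", {
  img <- synthetic_pattern(0.1, 0.015, "hexagonal", jitter = 0,
                           width_cm = 1, n_px = 128)
  p <- ks_params()
  g <- periodic_grid(c(128, 128), 1)
  agg <- aggregate_summary(img, g, threshold = 0.5)
  cell_area <- 0.1^2 * sqrt(3) / 2
  expect_equal(agg$count, 1 / cell_area, tolerance = 0.1)
  # deterministic for a fixed seed
  a <- synthetic_pattern(0.1, 0.02, jitter = 0.2, seed = 4)
  b <- synthetic_pattern(0.1, 0.02, jitter = 0.2, seed = 4)
  expect_identical(a, b)
  expect_error(synthetic_pattern(0.1, 0.06), "spacing")
})
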