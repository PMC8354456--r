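# Shared fixtures: small grids and states built in code.

default_params <- function(...) ks_params(...)

small_grid_1d <- function(n = 64, w = 1) periodic_grid(n, w)
small_grid_2d <- function(n = 32, w = 1) periodic_grid(c(n, n), w)

uniform_state <- function(grid, params, rho_bar = params$rho_bar) {
  uss <- uniform_steady_state(rho_bar, params)
  as_field <- function(v) {
    if (grid$dim == 2L) matrix(v, grid$n[1], grid$n[2]) else v
  }
  np <- prod(grid$n)
  field_state(0, as_field(rep(rho_bar, np)),
              as_field(rep(uss["U_a"], np)),
              if (params$repellent) as_field(rep(uss["U_r"], np)),
              grid)
}

# central-difference oracle for derivative checks
central_diff <- function(f, x, h = x * 1e-6 + 1e-9) {
  (f(x + h) - f(x - h)) / (2 * h)
}
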