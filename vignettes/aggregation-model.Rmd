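---
title: "The wormKS aggregation model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The wormKS aggregation model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormKS)
```

## The model and its assumptions

Starved L1 larvae are modeled as a continuous density $\rho(t,
\mathbf{x})$ rather than as individuals. Their mean velocity is assumed
to be a conservative field, $\mathbf{v} = -\nabla V$, so the density
obeys a Fokker-Planck equation

$$\rho_t = \nabla\cdot\bigl(\rho\nabla V(\rho, U_a, U_r) +
\sigma\nabla\rho\bigr),$$

with random motility $\sigma$. The potential sums three terms:

* **Weber-law signal responses** $V_U(U) = -\beta\log(\alpha + U)$ for
  each diffusible signal. The logarithmic form follows from
  integrating a just-noticeable-difference law
  $\Delta\phi/(\phi+\alpha) = \mathrm{const}$; it is convex in $U$,
  which keeps velocities bounded on steep signal gradients. $\beta >
  0$ attracts (worms drift down-potential), $\beta < 0$ repels.
  Concentrations are taken numerically in cm$^{-d}$ before the
  logarithm; only gradients of $V$ act on the dynamics, so the
  additive constant from that unit convention is irrelevant.
* **Crowding** $V_\rho(\rho) = \tfrac{\sigma\,\mathrm{scale}}{2}(1 +
  \tanh\frac{\rho - \rho_{\max}}{\mathrm{cushion}})$, a differentiable
  stand-in for a hard-core potential: worms occupy area, so density
  saturates near $\rho_{\max}$.
* Each signal obeys $\dot U_i = -\gamma_i U_i + D_i\nabla^2 U_i +
  s_i\rho$.

The two-signal structure — an attractant with range
$\sqrt{D_a/\gamma_a} = 100\ \mu$m and a repellent with range 1 mm — is
the essential design: short-range attraction drives aggregation,
long-range repulsion selects a finite aggregate size and spacing.
Without the repellent the linearization has no nonzero minimum
wavenumber and aggregates coarsen without bound.

## Parameters

All defaults are in `ks_params()`; lengths in cm, times in s,
densities and concentrations in cm$^{-d}$ ($d$ = 1 or 2; the same
numbers are used in both dimensions so results can be compared).

| parameter | value | meaning |
|---|---|---|
| $\bar\rho$ | 9000 | working mean density (aggregates then cover about 9000/28000 ≈ 1/3 of the area) |
| $\sigma$ | 5.555e-6 cm²/s | random motility; calibrated against 12 h spreading on a 3 cm-radius plate (see `disk_mode_time_constant`) |
| $\rho_{\max}$ | 28 000 | inverse footprint of one L1 (15 × 240 µm) |
| cushion | 2000 | width of the crowding rise; purely numerical smoothing |
| scale | 2 | crowding height in units of $\sigma$; any value comfortably > 1 works |
| $\beta_a$ | $2\sigma$ | chosen so the attractant-only instability threshold sits at 1500 cm⁻² |
| $\alpha_a = \alpha_r$ | 1500 | Weber offset; makes $V_U$ linear near threshold and convex near $\rho_{\max}$ |
| $\gamma_a, D_a, s_a$ | 0.01, 1e-6, 0.01 | attractant: range 100 µm; $s_i = \gamma_i$ numerically, so steady signal = density |
| $\beta_r$ | $-2\sigma$ | equal-and-opposite repulsion |
| $\gamma_r, D_r, s_r$ | 0.001, 1e-5, 0.001 | repellent: range 1 mm |

With this calibration the marginal condition is exact and closed-form
testable: the attractant-only threshold is $\alpha_a = 1500$, the
two-signal threshold 2357.14 cm$^{-d}$ with critical wavenumber
$(\gamma_a\gamma_r/D_aD_r)^{1/4} = 31.62$ rad/cm.

The slowdown variant multiplies $\sigma, \beta_a, \beta_r$ by
$e^{-t/\tau}$ (worms running out of energy); signal kinetics keep
their own clocks. Only "30 min" is a documented arrest case, so the
`fig5` preset defaults to $\tau = 1800$ s and leaves $\tau$
configurable.

## Spatial discretization

Fields live on a uniform periodic grid, cell centers at
$(i+\tfrac12)h$. The worm equation is discretized in flux form: the
advective flux at each cell face is the fourth-order face
interpolation of $\rho$ times a fourth-order face gradient of $V$, the
diffusive flux is $\sigma$ times the face gradient of $\rho$, and
fluxes are differenced with a fourth-order face-to-center divergence.
Every stencil is a periodic circular convolution whose coefficients
sum to zero, so the grid sum of the divergence — total worm number —
is conserved to rounding at every evaluation, not merely to
discretization order. The Laplacian used for the signal equations is
the composition of the face gradient and face divergence; its DFT
symbol is $-|G(\theta)|^2$ (the two stencils are adjoint up to sign),
i.e. real, nonpositive, and damping at the Nyquist mode, which rules
out checkerboard artifacts. Observed convergence order on smooth
fields exceeds 3.8 over grid doublings.

Because the equation contains $\rho\nabla\log\rho$ in its derivation,
densities must stay positive: initial conditions and every accepted
time step apply a floor of $10^{-6}\bar\rho$ followed by a global mass
renormalization (the published initial conditions likewise add a small
uniform background "to avoid zero or negative densities").

## Time integration

The crowding term makes the system stiff exactly where it matters: at
aggregate interfaces the effective diffusivity $\sigma + \rho
V_\rho'(\rho)$ is ~15$\times$ the bare $\sigma$. `advance()` therefore
uses a fully implicit variable-step BDF2 (implicit Euler startup),
solving the stage equations by inexact Newton iteration with
matrix-free Jacobian-vector products and right-preconditioned GMRES.
The preconditioner inverts, exactly and per Fourier mode, the
constant-coefficient core of the Jacobian: signal decay + diffusion,
and a worm-diffusion bound $A = \sigma(1 +
\mathrm{scale}\,\rho_{\max}/2\,\mathrm{cushion})$ covering the largest
crowding-enhanced diffusivity. Local error is estimated as the
(scaled) gap between the BDF2 corrector and a quadratic extrapolation
through the step history and held below $\mathrm{atol} +
\mathrm{rtol}\,\max|u|$ per field; steps shrink by $0.9\,
\mathrm{err}^{-1/3}$ on rejection and may grow at most 3-fold. Newton
failure (no converged correction in 4 iterations) quarters the step.

A velocity-based cap `cfl_limit()` — the time for the fastest worm to
cross one cell, $\min(\Delta x/|v_x|, \Delta y/|v_y|)$ — can
additionally bound the step (`step_controller(cfl = TRUE)`, the
default for `advance()`). The scenario presets disable it: for this
A-stable solver it is not needed for stability, and at a saturated
pattern $\nabla V = -\sigma\nabla\log\rho \neq 0$ permanently at
interfaces, so the cap pins the step near ~10 s forever without
improving the solution. This was checked, not assumed: at $128^2$ the
aggregate count and spectral peak are identical across rtol
$10^{-6}$–$10^{-4}$, with and without the cap, and across $96^2$ vs
$128^2$ grids. Presets integrate at rtol $10^{-4}$, atol $10^{-2}$.

About tolerances and closed-form decay tests: an adaptive controller
bounds *local* error; global error of a long run is larger. The test
suite asserts the heat-kernel decay ratio at $10\times$ rtol over a
moderately decayed horizon, where that bound is honestly achievable,
and verifies that tightening rtol tightens the observed error.

Events — geometric Brownian noise injections and snapshot times — are
hard integration breakpoints: `run_scenario()` integrates between
them, applies the event, and restarts step-size control at
`dt_init/10` (injections deposit high-wavenumber noise that the next
few steps must resolve).

## Scenario presets and the synthetic study conditions

The presets encode the published numerical experiments: uniform
$\bar\rho = 9000$ with 1% multiplicative Gaussian initial noise on a
1×1 cm domain for the small-scale runs (`fig2-*` attractant-only,
`fig3-*` two-signal, `fig5` slowdown), and the full-scale design
(`fig6`): 6×6 cm, 72 000 worms of which 68 400 form a center bump
shaped like a collapsed 2 cm sphere ($\rho = b_\rho +
a_\rho\sqrt{\max(0, 1-r^2/R^2)}$, $a_\rho = 3(\bar\rho -
b_\rho)w^2/2\pi R^2$) over a 100 cm$^{-2}$ background, with noise
injections at $t = 10^{n/2}$ s, $n = 0..10$, of per-point log-variance
$10^{-6}\Delta t$, mass-renormalized. Initial noise is applied
multiplicatively after the bump/background superposition (the stated
per-point standard deviation is proportional to the local initial
density). `fig6` defaults to 64 points/cm — the published 384
points/cm (16 M unknowns) is configurable but not desk scale.

What the generator does *not* emulate: worm shape and the lumpy
granularity of real plates (the continuum is smooth by construction),
the debris-contaminated central region of real dispersal experiments,
and any oxygen- or surface-tension-mediated interaction. Passing
simulation tests therefore validates the model's mathematics and this
implementation, not the biological completeness of the model.

## Spectral pattern quantification

Images (or density fields) are standardized to [0, 1], transformed
with a unitary DFT ($p_\mathbf{k} = |\tilde b_\mathbf{k}|^2$, total
power = sum of squared pixels, an exactly tested Parseval identity),
and radially summed: each lattice wavenumber maps linearly to a
fractional position among 1024 bins spanning 0–20 cycles/cm and its
power splits between the two adjacent bins, conserving total power
exactly. Wavenumbers are reported in **cycles/cm** throughout (the
inverse of wavelength), converting from the rad/cm used internally by
the stability module. The raw radial spectrum is quasi-periodic at the
lattice spacing mapped into bins; a Gaussian filter (sd = radius/2,
reflected boundaries) removes it. The printed smoothing radius of the
source analysis is internally inconsistent (26.5/2 ≈ 13.25 yet stated
as ≈ 18.7, consistent with $26.5/\sqrt 2$ — a radical apparently lost
in typesetting); the default is 18.7 bins, which attenuates the
26.5-bin period more than tenfold, and the radius is a parameter.

`synthetic_pattern()` provides fixtures with analytically known peaks
(hexagonal lattice of spacing $a$: first reciprocal ring at
$2/\sqrt{3}a$ cycles/cm; square: $1/a$), used to validate the peak
finder against brute-force expectations.

## Aggregate morphology

Aggregates are connected components of $\{\rho > \rho_{\max}/2\}$ —
the sigmoid midpoint is the natural plateau cut — under 4-connectivity
(8 available) with periodic wraparound, so a cluster straddling the
domain seam counts once. Centroids use circular means; spacing is the
periodic nearest-neighbor distance. The threshold is exposed.

## The Langevin particle oracle

As an individual-based cross-check, N particles follow the
Euler-Maruyama discretization $X \leftarrow X - \nabla V\,dt +
\sqrt{2\sigma dt}\,\xi$, the exact microscopic counterpart of the worm
PDE (a cellular-lattice individual model would have no parameter
correspondence to calibrate against). Particles deposit density on the
grid by cloud-in-cell weighting (exactly mass-conserving); signals are
advanced on the grid with an exact per-step Fourier update of their
linear dynamics; $\nabla V$ is interpolated back bilinearly. Under
slowdown the drift scales with $e^{-t/\tau}$ and the noise amplitude
with its square root. With a frozen potential the stationary density
is the Gibbs form $\propto e^{-V/\sigma}$, which the tests verify via
relative entropy at $N = 10^5$.

One caveat the tests respect: even below the instability threshold a
*finite* ensemble shows attractant-mediated density correlations above
shot noise at small scales. The uniformity check against the stability
prediction is therefore made at quadrant scale, where the macroscopic
statement lives.

## Known limitations

* **Long-time pattern scale.** At the small-scale two-signal
  conditions ($\bar\rho = 9000$, 1 cm², 128², no injections) the
  pattern emerges near the fastest-growing linear mode (~7.7
  cycles/cm; measured 7.2 at $t = 5000$ s) and then coarsens to a
  stable array of ~30 aggregates by $t \sim 10^5$ s — a dominant
  spectral peak of ~5.9 cycles/cm (1.7 mm spacing), constant from
  $10^5$ to $2\times10^5$ s. This value is grid- and
  tolerance-converged here (identical at 96² and 128², rtol
  $10^{-6}$–$10^{-4}$). It is coarser than the ~10 cycles/cm ring
  reported for the *full-scale* dispersal experiment (different mean
  density, initial condition, and noise protocol), so comparisons of
  spectral peaks should be made against matching scenario conditions.
* Global error of long integrations is controlled indirectly through
  local tolerances; pattern *statistics* are robust to rtol across two
  orders of magnitude, but trajectories of individual aggregates are
  not bit-stable across tolerance choices.
* The particle oracle shares the model's potential and so is not an
  independent model of worm behavior — it cross-checks the continuum
  limit, nothing more.
* 1D and 2D share parameter values by design; 1D runs reach plateau
  densities but cannot exhibit hexagonal order or realistic
  coarsening geometry.
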