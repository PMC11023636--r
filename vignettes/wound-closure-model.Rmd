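---
title: "The woundsim model: stochastic continuum wound closure and migration statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The woundsim model: stochastic continuum wound closure and migration statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundsim)
```

# The scientific problem

When a scratch is made in a keratinocyte monolayer, the two wound edges
migrate towards each other until they meet (reepithelialization). The
collective dynamics mix several single-cell and multicellular ingredients:
random cellular locomotion, volume exclusion (cells cannot move into space
that is already at maximal density), cell--cell adhesion that hinders
rearrangement, a directional bias of migration towards the cell-free space
("coordinated directionality", transmitted from leader cells to followers),
and transient, spatially localized retraction events in which a stretch of
the wound edge pulls backwards.

`woundsim` implements a dimensionless continuum model of this process on the
unit square, together with the observables used to characterize wound
closure (wound area, interface length, closure proportion, parameter sweep
trends), a calibration path from single-cell measurements to model
parameters, and a self-contained migration-statistics suite (mean squared
displacement, velocity autocorrelation, von Mises direction fitting, angular
deviation, spatial velocity autocorrelation and its length constant) for
trajectory tables and PIV-style velocity fields.

# The governing equation

Cell density $\rho(\mathbf{x}, t) \in [0, 1]$ obeys a diffusion--advection
equation obtained as the continuum limit of a discrete hopping model:

$$\partial_t \rho = \nabla \cdot ( \mathbf{D} \nabla \rho ) -
  \nabla \cdot ( \mathbf{v}\, \rho ),$$

with monolayers along the bottom ($y = 0$) and top ($y = 1$) of the domain
and the wound in a central horizontal band.

**Diffusion.** The diffusivity factorizes into an anisotropic weight matrix
and a scalar density-dependent polynomial,
$\mathbf{D} = d \,(w_I \mathbf{I} + w_A \mathbf{A})\, \hat D_\alpha(\rho)$
with $\mathbf{A} = \mathrm{diag}(0, 1)$ (extra mobility towards the wound,
along $y$), so $\mathbf{D} = d\,\mathrm{diag}(1 - w_A,\, 1)\,\hat
D_\alpha(\rho)$. The convex weights derive from directed hopping magnitudes:
$d = d^\updownarrow$, $w_I = d^\leftrightarrow / d^\updownarrow$,
$w_A = 1 - w_I$ (`weights_from_motilities()`). The scalar part,

$$\hat D_\alpha(\rho) = 2\rho - (1 + 11\alpha)\rho^2 +
  (8\alpha + 16\alpha^2)\rho^3 - (13\alpha^2 + 7\alpha^3)\rho^4 +
  6\alpha^3\rho^5,$$

encodes volume filling and adhesion from the three non-target neighbours of
a hopping cell. It vanishes at $\rho = 0$ (fronts have compact support),
equals $(1-\alpha)^3$ at $\rho = 1$, and is positive on $(0, 1]$ only for
adhesion below a critical value: numerically the positivity bound is
$\alpha \lesssim 0.66$ (`alpha_max()`), which is why `model_params()`
refuses larger adhesion.

**Retraction.** Each wound edge carries an independent renewal process of
localized retraction events. Event $i$ has a band centre $c_i \sim U(0,1)$,
a duration $T^r_i$, an idle period to the next event $T^{nr}_i$, and a
strength $s_i$; durations and strengths are normal draws truncated to
positive values (non-physical draws are discarded and redrawn, so when
$\sigma$ is comparable to $\mu$ the realized means exceed the nominal ones;
`truncated_normal_mean()` gives the realized value the tests check against).
While an event is active, low-density material near that edge drifts with
velocity of magnitude
$H(\gamma - \rho)\,(1 - \rho)(1 - \alpha\rho)^3\, s_i$, split equally
between the two components ($s_i/\sqrt 2$ each, so the speed at $\rho = 0$
inside the band is exactly $s_i$). The vertical component points away from
the wound on the event's side (the edge recedes); the horizontal component
points outward from the band centre (the edge is pulled back and apart,
gouging a bay). The Heaviside gate $H(\gamma - \rho)$ localizes the drift to
the wound edge: it is off in the dense monolayer. The discontinuous gate and
indicator functions are smoothed: $H$ by a hyperbolic tangent of width
`width_h`, and the time window and spatial band by generalized bell
functions that equal $1$ at the centre, $0.5$ exactly at the window/band
edges, and sharpen to the discontinuous indicator as their widths shrink.

**Boundary and initial conditions.** The domain is a small neighbourhood of
the wound: cells flow in from the monolayer through time-dependent Dirichlet
values $g_0, g_1$ on the bottom/top rows (smooth low-frequency random
perturbations around density 1, clamped to $[0,1]$), while the left/right
sides carry no-flux conditions. The initial state is a banded monolayer with
a central cell-free band whose edges carry small random Fourier
perturbations, relaxed by a short retraction-free solve so the fronts are
smooth (`initial_condition()`).

**Units.** The solver is dimensionless. Physical units enter only through
the characteristic length $l$ (wound edge to maximal-density region) and
edge speed $v$, via the rate $\lambda = v / l$
(`nondimensionalization()` and its converters).

# Numerical scheme

* *Diffusion* is discretized directly from the discrete transitional
  probabilities of the hopping model (the natural discretization), assembled
  in interface-flux form so that mass is conserved exactly under all-Neumann
  boundaries. The suite verifies second-order convergence of this operator
  against the analytic continuum operator and against an independent
  conservative centred-difference oracle.
* *Advection* uses a second-order WENO reconstruction of the upwind density
  at each interface with the interface velocity, falling back to the
  monotone first-order upwind flux wherever the stencil is near vacuum
  ($\rho < 10^{-3}$), plus a donor-cell limiter that caps, per step and
  dimension, the advective outflow at 45% of a cell's mass and the inflow at
  45% of its free capacity $(1 - \rho)$. The limiter is inert in smooth
  regions; it enforces positivity and the volume-filling bound where the
  drift diverges or piles material against a nearly full cell.
* *Time stepping* is forward Euler at the combined stability bound
  `cfl_dt()`: the reciprocal sum of the diffusive rate
  $4 d \max_\rho \hat D_\alpha / h^2$ and the advective rate
  $v_{\max} / h$, times a safety factor of $0.5$. This is at least as strict
  as the smaller of the two single-mechanism limits. A step that still
  produces density outside $[-10^{-6}, 1 + 10^{-6}]$ aborts the run with an
  error naming the offending `dt` and `h`; round-off-scale overshoots are
  clipped.
* *Grid*: `(n+1) x (n+1)` points on the unit square, default `n = 128`
  (`h = 1/128`).

# Closure: two monitored events

The model's advection is conservative: a retraction event relocates mass, it
does not destroy it. Two distinct events therefore characterize "closure",
and the solver monitors both in every run:

* **contact** — the first time the wound set $\{\rho < \gamma\}$ stops
  spanning the domain from the left edge to the right edge (the interfaces
  have touched somewhere). This is the percolation criterion, and it is the
  default closure event for the per-run observables: normalized wound
  closure and the time at which the normalized edge length is read off.
* **healed** — the first time the wound set's area falls below 0.1% of its
  initial value: the wound has re-epithelialized along the entire scratch,
  and essentially no sub-threshold density remains for the edge-localized
  retraction to act on. `closure_proportion()` counts this event, because it
  is the healed-state time that grows with retraction strength: retraction
  keeps re-gouging low-density pockets and postpones complete healing. Under
  the package's base calibration the healed time rises from 0.265 (no
  retraction) to roughly 0.53 at strength 60, so at the reference horizon of
  0.5 the proportion of healed wounds stays near 1 through strength 40 and
  declines beyond it (about 0.9 / 0.45 / 0.25 at strengths 40 / 50 / 60 on a
  96-square grid with 20 replicates). The decline is genuine but not a full
  collapse: the smoothed Heaviside tail caps how high in density the drift
  can erode, so walls denser than about 0.5 are immune at any strength up to
  60 and every wound eventually heals. A variant in which wounds stay open
  indefinitely at high strength would need a mechanism that starves or
  re-opens consolidated regions more aggressively than this conservative
  advection does; the strength--proportion check in the test suite inherits
  that limitation — it verifies the decline but only approximates "almost
  none" at strength 60.

Both events must persist for a confirmation window (default: five mean
retraction cycles) before they count. A "contact" that the next retraction
event immediately re-opens, or a one-cell ridge of advected material that
transiently crosses the threshold and then diffuses away, is not touching
interfaces; without the confirmation window both artifacts systematically
bias closure times downward under strong retraction.

# Parameters, defaults, and how the base condition was fixed

| parameter | meaning | default |
|---|---|---|
| `d` | motility (vertical hopping magnitude) | 0.5 |
| `w_A` | coordinated directionality weight | 0.4 |
| `alpha` | cell--cell adhesion | 0.2 |
| `mu_r`, `sigma_r` | retraction duration mean/SD | 0.01, 0.0025 |
| `mu_nr`, `sigma_nr` | inter-retraction duration mean/SD | 0.003, 0.00075 |
| `mu_s`, `sigma_s` | retraction strength mean/SD | 20, 5 |
| `gamma` | edge-localization density threshold | 0.4 |
| `omega_r` | retraction band width | 0.2 |
| `width_h`, `width_x`, `width_t` | smoothing widths | 0.15, 0.02, 0.00125 |

The collective parameters carry their standard base values ($\alpha = 0.2$,
$w_A = 0.4$) and the localization constants their stated simulation values
($\gamma = 0.4$, $\omega_r = 0.2$). The remaining base values are the
package's own calibration, fixed once during development and not revisited:
`d`, the event process means/SDs, the initial wound half-width (0.30) and
the smoothing widths were chosen so that (i) the dimensionless front speed
is of order one, as the nondimensionalization by the measured edge speed
implies; (ii) many retraction cycles fit within one closure time, so the
renewal process is well sampled; (iii) the indicator smoothing widths are
small relative to the event duration (a time-smoothing width wider than the
event itself would smear neighbouring events together, which is why
`width_t` is far below the 0.02 one might pick for order-one durations); and
(iv) the closure-proportion knee of the strength sweep falls between
strengths 40 and 60, the anchor behaviour the model is known for. The
Heaviside width 0.15 sets the density range over which an event can erode
the front shoulder; much narrower gates make retraction act on the
(massless) front foot only, and the strength dependence of closure
disappears.

Two protocol choices deserve emphasis:

* *Directionality sweeps* vary `w_A` holding `d` (the vertical magnitude)
  fixed, the model's own parametrization. Increased directionality therefore
  does not change the vertical diffusivity; its accelerating effect on
  closure arises because weaker horizontal smoothing leaves the fronts
  rougher, and rougher fronts make first contact earlier. The same roughness
  lengthens the wound edge, which is why directionality is the only
  parameter whose closure and edge-length trends are both positive.
* *Horizons are analysis parameters.* Closure proportions are read at a
  horizon of 0.5 (just under twice the base-condition healed time of about
  0.27 without retraction, and placed between the healed-time distributions
  of the stable and slow strengths); sweep observables use shorter horizons
  placed inside the spread of contact times (e.g. 0.28 on a 64-square grid)
  so that the normalized closure retains resolution between conditions
  instead of saturating at 1.

# Condition calibration

`calibrate_condition()` maps an experimental condition onto parameters: the
measured fold changes (condition over control) multiply the retraction means
`mu_r`, `mu_nr`, `mu_s` and the motility `d` (SDs scaled proportionally),
while the two unmeasured collective parameters jump to their admissible
extrema — $w_A = 1$ (increased) or $0$ (decreased), $\alpha = 0.66$ or $0$ —
or stay at base values. Using extrema is justified by the monotonicity of
both observables in each parameter: if the extremum cannot reproduce an
experimental trend, no intermediate value can. The packaged fold-change
table (`synthetic_fold_changes()`) is a clearly labelled *synthetic*
stand-in whose signs follow the qualitative single-cell observations; it is
not measured data.

# Synthetic data generators

* `gen_trajectories()` emulates nuclei-tracking exports as correlated random
  walks: fixed step length `speed * dt`, wrapped-normal turning noise with
  SD $(1 - p)\pi$. The persistence dial `p` spans ballistic (`p = 1`,
  log-log MSD slope 2, velocity autocorrelation 1) to diffusive (`p = 0`,
  long-lag slope 1). Real trajectories have heterogeneous speeds, division
  and disappearance events, and interactions; none of these are emulated, so
  passing tests validate the statistics pipeline, not biological realism.
* `gen_vector_field()` emulates PIV output: von Mises directions about a
  mean with concentration `kappa`, optional Gaussian smoothing whose kernel
  SD is `corr_length / 2`, chosen so the spatial autocorrelation of the
  velocity decays to 0.37 at `corr_length`. Smoothing unit vectors and
  re-normalizing inflates the apparent concentration, so `kappa` round
  trips only approximately when `corr_length > 0` (the documented tolerance
  in the tests is wider there).
* `gen_scripted_field()` provides analytic density fields (flat band,
  sinusoidal interfaces with a closed-form arc length, closed monolayer)
  for exact metric tests.

# Migration statistics conventions

* MSD is the overlapping-window time average; lags are reported to a third
  of the trajectory length by default, where the average is well sampled.
* Velocity autocorrelation uses forward-difference velocities and averages
  over the pairs actually available at each lag, so `vac(0) = 1` exactly.
* Tracks with skipped frames are split at the gap on ingest, never
  interpolated.
* Angular deviation is reported as $1 - R$ ($R$ = mean resultant length), so
  0 means perfectly aligned vectors and values near 1 mean uniformly
  scattered directions; the raw resultant is available via
  `type = "resultant"`.
* The spatial autocorrelation correlates the wound-normal velocity component
  (a `component = "full"` switch uses full vector dot products), over all
  two-dimensional grid offsets binned isotropically by separation;
  `C(0) = 1` by construction and masked vectors are excluded from every
  pair.
* The length constant fits $\log C = a + b r + c r^2$ over separations with
  $C > 0.05$ and reports the smallest positive crossing of $C = 0.37$,
  falling back to a pure exponential fit if the quadratic never crosses and
  to `NA` if the crossing lies beyond twice the observed range.
* The von Mises fit minimizes the mean squared error between a 36-bin
  density histogram and the von Mises density, seeded by a coarse grid
  around the circular mean and refined with box constraints
  ($\kappa \ge 0$). For concentrated samples it agrees with the
  closed-form circular maximum-likelihood estimate; for small samples
  (below ~100 angles) it warns.

# Problem sizes used by the test suite

The acceptance checks run scaled-down versions of the full study: closure
proportions use a 96-square grid with 20 replicates per strength;
sign-matrix sweeps use a 64-square grid with 20 replicates over 5-point
grids; solver invariants use 32- to 128-square grids. These sizes were
chosen as the smallest at which the reported quantities are stable across
seeds; the full-scale protocol (the solver default `n = 128` with 100
replicates per condition) is available by raising `n` and `n_reps` in the
same calls.

# Known limitations

* The advection is conservative, so retraction redistributes mass; wound
  growth beyond the initial area is possible locally (bays) but the model
  cannot expel cells from the domain except through the Dirichlet rows.
* Percolation contact on a finite grid is a noisy functional of the front
  roughness; the confirmation window removes its worst artifacts but
  contact times retain a few-percent grid dependence.
* The model contains no proliferation, no mechanics (forces, stresses), and
  no explicit leader-cell agents; "leader-cell prevalence" is proxied
  entirely by the normalized edge length.
* The packaged fold-change table is synthetic; calibrated-condition results
  illustrate the machinery and are not predictions about any real
  perturbation.
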