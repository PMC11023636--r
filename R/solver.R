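#' Density field on the unit square
#'
#' A dense grid of dimensionless cell density `rho` in `[0, 1]` on
#' `[0, 1] x [0, 1]`. `values[i, j]` holds the density at
#' `x = (i - 1) h, y = (j - 1) h` with uniform spacing `h = 1 / n` for an
#' `(n + 1) x (n + 1)` grid.
#'
#' @param values Square numeric matrix with entries in `[0, 1]` (up to a
#'   small tolerance).
#' @param h Grid spacing; defaults to `1 / (nrow(values) - 1)`.
#' @param t Time stamp of the field.
#' @return An object of class `density_field`.
#' @export
density_field <- function(values, h = 1 / (nrow(values) - 1), t = 0) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (any(values < -1e-6) || any(values > 1 + 1e-6)) {
    rlang::abort("density values must lie in [0, 1] (tolerance 1e-6)")
  }
  structure(list(values = values, h = h, t = t), class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf("<density_field> %d x %d grid, h = %.5g, t = %.5g, range [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values), x$h, x$t, min(x$values),
              max(x$values)))
  invisible(x)
}

#' Total cell mass of a density field
#'
#' The discrete lattice mass `h^2 * sum(rho)`: every grid point is one cell
#' of the underlying discrete model, and this is the quantity the flux-form
#' discretization conserves exactly under all-Neumann boundaries.
#'
#' @param field A [density_field()].
#' @return Numeric scalar.
#' @export
total_mass <- function(field) {
  sum(field$values) * field$h^2
}

#' Directed transitional probabilities of the discrete model
#'
#' Assembles, for every grid point, the four directed transitional rates of
#' the discrete master equation, split into their diffusive part
#' (volume-filling and adhesion factors times `d_dir * rho / h^2`) and their
#' advective part (the same factors times the upwinded retraction drift
#' component over `h`). The semi-discrete right-hand side built from these
#' rates is the solver's diffusion discretization.
#'
#' @param field A [density_field()].
#' @param params A [model_params()] object.
#' @param advection Optional list with matrices `vx`, `vy` (e.g. from
#'   [retraction_velocity()]); `NULL` means no advection.
#' @return A list of matrices `diff_right`, `diff_left`, `diff_up`,
#'   `diff_down`, `adv_right`, `adv_left`, `adv_up`, `adv_down`.
#' @export
transitional_probabilities <- function(field, params, advection = NULL) {
  v <- field$values
  m <- nrow(v)
  h <- field$h
  a <- params$alpha
  dh <- params$d * (1 - params$w_A)
  dv <- params$d
  pad <- function(M, di, dj) {
    # neighbour value with mirror ghosts
    idx <- function(i, n) ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i))
    M[idx(seq_len(m) + di, m), idx(seq_len(m) + dj, m), drop = FALSE]
  }
  nb_r <- pad(v, 1, 0); nb_l <- pad(v, -1, 0)
  nb_u <- pad(v, 0, 1); nb_d <- pad(v, 0, -1)
  P4 <- (1 - a * nb_r) * (1 - a * nb_l) * (1 - a * nb_u) * (1 - a * nb_d)
  fac <- function(target) (1 - target) * P4 / (1 - a * target)
  out <- list(
    diff_right = fac(nb_r) * dh * v / h^2,
    diff_left  = fac(nb_l) * dh * v / h^2,
    diff_up    = fac(nb_u) * dv * v / h^2,
    diff_down  = fac(nb_d) * dv * v / h^2
  )
  zero <- matrix(0, m, m)
  if (is.null(advection)) {
    out$adv_right <- out$adv_left <- out$adv_up <- out$adv_down <- zero
  } else {
    out$adv_right <- fac(nb_r) * pmax(advection$vx, 0) / h
    out$adv_left  <- fac(nb_l) * pmax(-advection$vx, 0) / h
    out$adv_up    <- fac(nb_u) * pmax(advection$vy, 0) / h
    out$adv_down  <- fac(nb_d) * pmax(-advection$vy, 0) / h
  }
  out
}

#' Stable explicit time step
#'
#' Forward-Euler stability bound for the combined update: the reciprocal sum
#' of the diffusive rate `4 d max(Dhat) / h^2` and the advective rate
#' `v_max / h`, scaled by a safety factor. This is at least as strict as the
#' smaller of the two single-mechanism limits `h^2 / (4 d max Dhat)` and
#' `h / v_max`, and guards the positivity of the explicit step when both
#' mechanisms act in the same cell.
#'
#' @param params A [model_params()] object.
#' @param h Grid spacing (> 0).
#' @param safety Safety factor in `(0, 1]`.
#' @param max_speed Maximum advection speed; defaults to `mu_s + 3 sigma_s`.
#' @return Time step `dt`.
#' @export
cfl_dt <- function(params, h, safety = 0.5, max_speed = NULL) {
  stopifnot(h > 0, safety > 0, safety <= 1)
  if (is.null(max_speed)) max_speed <- params$mu_s + 3 * params$sigma_s
  dmax <- max(scalar_diffusion_coeff(seq(0, 1, length.out = 201),
                                     params$alpha))
  safety / (4 * params$d * dmax / h^2 + max_speed / h)
}

# draw Fourier coefficients of a boundary function (rows: a_k, k, phi, om, psi)
draw_g_coef <- function(n_modes = 3) {
  cbind(runif(n_modes, 0.5, 1), seq_len(n_modes),
        runif(n_modes, 0, 2 * pi), runif(n_modes, pi, 4 * pi),
        runif(n_modes, 0, 2 * pi))
}

#' Evaluate a Dirichlet boundary function
#'
#' The top/bottom boundary rows carry time-dependent Dirichlet values: smooth
#' random perturbations around the monolayer density 1, built from a few
#' low-frequency Fourier modes, always clamped to `[0, 1]`.
#'
#' @param x Positions in `[0, 1]`.
#' @param t Time.
#' @param coef Coefficient matrix as drawn by the simulator (one row per
#'   mode: amplitude, wavenumber, phase, temporal frequency, temporal phase).
#' @param amp Overall perturbation amplitude.
#' @return Numeric vector of boundary densities in `[0, 1]`.
#' @export
eval_boundary_g <- function(x, t, coef, amp = 0.05) {
  cpp_eval_g(x, t, coef, amp)
}

#' Apply boundary conditions to a density field
#'
#' Sets the Dirichlet rows `y = 0` and `y = 1` from the boundary functions;
#' the no-flux condition on the left/right sides is built into the flux-form
#' spatial discretization and needs no explicit action.
#'
#' @param field A [density_field()].
#' @param t Time.
#' @param g0,g1 Coefficient matrices for the bottom/top boundary functions.
#' @param amp Perturbation amplitude.
#' @return The updated `density_field`.
#' @export
apply_boundaries <- function(field, t, g0, g1, amp = 0.05) {
  m <- nrow(field$values)
  xs <- (seq_len(m) - 1) * field$h
  field$values[, 1] <- eval_boundary_g(xs, t, g0, amp)
  field$values[, m] <- eval_boundary_g(xs, t, g1, amp)
  field
}

#' Banded initial condition with an open central wound
#'
#' Builds the starting density: monolayers (`rho ~ 1`) along the bottom and
#' top of the domain and a cell-free band in the middle, with the band edges
#' perturbed by a few random Fourier modes, then relaxed by integrating the
#' retraction-free diffusion equation for a short time so the fronts are
#' smooth. Deterministic given the RNG state.
#'
#' @param params A [model_params()] object.
#' @param n Grid resolution (grid is `(n+1) x (n+1)`, `h = 1/n`).
#' @param wound_halfwidth Half-width of the initial cell-free band.
#' @param perturb Amplitude of the band-edge perturbation.
#' @param relax_time Duration of the retraction-free relaxation solve.
#' @return A [density_field()] at `t = 0`.
#' @export
initial_condition <- function(params, n = 128, wound_halfwidth = 0.3,
                              perturb = 0.02, relax_time = 0.001) {
  h <- 1 / n
  xs <- (0:n) * h
  modes <- function() {
    a <- runif(4, 0.25, 1) / (1:4)
    ph <- runif(4, 0, 2 * pi)
    s <- sapply(xs, function(x) sum(a * sin(2 * pi * (1:4) * x + ph)))
    perturb * s / sum(a)
  }
  ylo <- 0.5 - wound_halfwidth + modes()
  yhi <- 0.5 + wound_halfwidth + modes()
  delta <- 2 * h
  v <- matrix(0, n + 1, n + 1)
  for (i in 1:(n + 1)) {
    f <- 0.5 * (tanh((xs - ylo[i]) / delta) - tanh((xs - yhi[i]) / delta))
    v[i, ] <- pmin(pmax(1 - f, 0), 1)
  }
  if (relax_time > 0) {
    dt <- cfl_dt(params, h, max_speed = 0)
    empty <- matrix(numeric(0), ncol = 5)
    res <- cpp_simulate(v, h, dt, 0, relax_time, params$d, params$w_A,
                        params$alpha, empty, params$gamma, params$omega_r,
                        params$width_h, params$width_x, params$width_t, 0.02,
                        empty, empty, 0, 2L, 1000000L, 0L, 1000000L,
                        params$gamma, 1e-6, 0, 0L, 0)
    v <- res$final
  }
  density_field(v, h = h, t = 0)
}

#' Simulate wound closure
#'
#' Integrates the stochastic diffusion--advection model on the unit square
#' with an explicit finite-difference scheme: diffusion is discretized
#' directly from the discrete transitional probabilities (flux form) and the
#' retraction advection with a second-order WENO scheme, under forward-Euler
#' time stepping at the [cfl_dt()] bound. Dirichlet boundary rows at
#' `y = 0, 1` feed cells in from the monolayer; the left/right sides are
#' no-flux. The run stops at wound closure (when the low-density set no
#' longer spans the domain horizontally) or at `horizon`.
#'
#' @param params A [model_params()] object.
#' @param n Grid resolution (`h = 1/n`).
#' @param horizon Dimensionless end time.
#' @param seed Integer seed controlling the initial condition, the boundary
#'   functions and the retraction schedule.
#' @param schedule Optional pre-sampled `retraction_schedule`; `NULL` samples
#'   one (unless `mu_s = 0`, which runs retraction-free).
#' @param snapshots `"ends"` keeps the initial field, the last field at
#'   which the wound was still open, and the final field; `"all"` also
#'   stores a snapshot every `snap_every` steps.
#' @param bc `"standard"` (Dirichlet top/bottom + no-flux sides) or
#'   `"all_neumann"` (no-flux everywhere; conservation test variant).
#' @param init Optional [density_field()] starting state.
#' @param check_every Steps between closure/area checks.
#' @param snap_every Steps between stored snapshots when `snapshots = "all"`.
#' @param safety CFL safety factor.
#' @param dt Optional explicit time step (must satisfy the stability bound).
#' @param rho_wound Density threshold defining the wound set.
#' @param g_amp Amplitude of the Dirichlet boundary perturbations.
#' @param first_start Passed to [sample_retraction_schedule()].
#' @param clip_tol Overshoot tolerance before the step is declared unstable.
#' @param confirm_time How long the closure condition must persist before it
#'   counts: a contact that the next retraction event re-opens is not
#'   touching interfaces. Default: five mean retraction cycles
#'   (`5 (mu_r + mu_nr)`) when retraction is active, 0 otherwise.
#' @param closure Which monitored event defines `closed`/`closure_time` and
#'   stops the run: `"contact"` (default), the first confirmed time the wound
#'   set `{rho < rho_wound}` stops spanning the domain horizontally (the
#'   interfaces have touched somewhere); or `"healed"`, the first confirmed
#'   time the wound area drops below `area_frac` of its initial value (the
#'   wound has re-epithelialized along the whole scratch -- the state after
#'   which the edge-localized retraction can never act again). Both events
#'   are monitored in either mode; contact necessarily precedes healing.
#' @param area_frac Residual area fraction defining the `"healed"` event.
#' @return An object of class `wound_sim`; see [tidy.wound_sim()] and
#'   [glance.wound_sim()].
#' @examples
#' \donttest{
#' p <- model_params(mu_s = 0)
#' sim <- simulate_wound(p, n = 48, horizon = 0.05, seed = 1)
#' glance(sim)
#' }
#' @export
simulate_wound <- function(params, n = 128, horizon = 1, seed = 1,
                           schedule = NULL, snapshots = c("ends", "all"),
                           bc = c("standard", "all_neumann"), init = NULL,
                           check_every = 25, snap_every = 200, safety = 0.5,
                           dt = NULL, rho_wound = params$gamma, g_amp = 0.05,
                           first_start = NULL, clip_tol = 1e-6,
                           confirm_time = NULL,
                           closure = c("contact", "healed"),
                           area_frac = 0.001) {
  snapshots <- match.arg(snapshots)
  bc <- match.arg(bc)
  closure <- match.arg(closure)
  validate_model_params(params)
  set.seed(seed)
  h <- 1 / n
  if (is.null(init)) init <- initial_condition(params, n = n)
  stopifnot(inherits(init, "density_field"), nrow(init$values) == n + 1)
  g0 <- draw_g_coef(); g1 <- draw_g_coef()
  if (is.null(schedule)) {
    schedule <- if (params$mu_s > 0) {
      sample_retraction_schedule(params, horizon, first_start = first_start)
    } else {
      NULL
    }
  }
  smat <- schedule_matrix(schedule)
  max_s <- if (nrow(smat) > 0) max(smat[, 5]) else 0
  if (is.null(dt)) {
    # exact bound on a drift component: s * max_rho of the density factors
    rg <- seq(0, 1, length.out = 201)
    vfac <- max(smooth_heaviside(params$gamma - rg, params$width_h) *
                  (1 - rg) * (1 - params$alpha * rg)^3) / sqrt(2)
    dt <- cfl_dt(params, h, safety = safety, max_speed = max_s * vfac)
  }
  if (is.null(confirm_time)) {
    # closure must outlast a few retraction cycles to count as contact
    confirm_time <- if (max_s > 0) 5 * (params$mu_r + params$mu_nr) else 0
  }
  res <- cpp_simulate(init$values, h, dt, init$t, horizon, params$d,
                      params$w_A, params$alpha, smat, params$gamma,
                      params$omega_r, params$width_h, params$width_x,
                      params$width_t, 0.02, g0, g1, g_amp,
                      if (bc == "all_neumann") 1L else 0L,
                      as.integer(check_every),
                      if (snapshots == "all") 1L else 0L,
                      as.integer(snap_every), rho_wound, clip_tol,
                      confirm_time, if (closure == "healed") 1L else 0L,
                      area_frac)
  if (isTRUE(res$blown)) {
    rlang::abort(sprintf(
      "solver instability: density reached %.4g with dt = %.3g, h = %.3g; reduce dt or the safety factor",
      res$bad_value, dt, h))
  }
  structure(list(
    params = params, n = n, h = h, seed = seed, horizon = horizon, dt = dt,
    bc = bc, rho_wound = rho_wound,
    times = res$check_times, areas = res$areas,
    closed = res$closed, closure_time = res$closure_time,
    closure_event = closure,
    contact = res$contact, contact_time = res$contact_time,
    initial = density_field(res$initial, h, 0),
    final = density_field(res$final, h, res$t_end),
    last_open = density_field(res$last_open, h, res$last_open_time),
    pre_contact = density_field(res$pre_contact, h, res$pre_contact_time),
    snapshots = res$snapshots, snapshot_times = res$snapshot_times,
    schedule = schedule, steps = res$steps
  ), class = "wound_sim")
}

#' @export
print.wound_sim <- function(x, ...) {
  cat(sprintf("<wound_sim> %d x %d grid, horizon %g, seed %d\n",
              x$n + 1, x$n + 1, x$horizon, x$seed))
  if (x$closed) {
    cat(sprintf("  wound closed at t = %.4g\n", x$closure_time))
  } else {
    cat("  wound open at end of horizon\n")
  }
  invisible(x)
}

#' Does the wound set span the domain horizontally?
#'
#' The wound is considered open while the set `{rho < thr}` contains a
#' 4-connected component touching both the left and right domain edges.
#'
#' @param field A [density_field()].
#' @param thr Density threshold.
#' @return Logical scalar.
#' @export
wound_spans <- function(field, thr) {
  cpp_wound_spans(field$values, thr)
}

#' Wound closure time of a simulation
#'
#' The first recorded time at which the low-density set no longer spans the
#' domain from left to right (interfaces have touched), or `NA` if the wound
#' stayed open through the horizon. With `rho_wound` supplied and snapshots
#' stored, the time is recomputed from the snapshots at that threshold.
#'
#' @param sim A `wound_sim` object.
#' @param rho_wound Optional alternative threshold (requires
#'   `snapshots = "all"`).
#' @return Closure time, or `NA_real_`.
#' @export
closure_time <- function(sim, rho_wound = NULL) {
  if (is.null(rho_wound)) {
    return(if (isTRUE(sim$closed)) sim$closure_time else NA_real_)
  }
  if (length(sim$snapshots) == 0) {
    rlang::abort("recomputing closure at a new threshold requires snapshots = \"all\"")
  }
  for (k in seq_along(sim$snapshots)) {
    f <- density_field(sim$snapshots[[k]], sim$h, sim$snapshot_times[k])
    if (!wound_spans(f, rho_wound)) return(sim$snapshot_times[k])
  }
  NA_real_
}

#' Advance a density field by one explicit step
#'
#' Single forward-Euler update used by the low-level tests: assembles the
#' master-equation diffusion right-hand side and (if a schedule is active)
#' the WENO advection term, then clips round-off overshoots.
#'
#' @param field A [density_field()].
#' @param dt Time step.
#' @param params A [model_params()] object.
#' @param schedule Optional `retraction_schedule`.
#' @param dirichlet Keep the `y = 0, 1` rows fixed (TRUE) or let them evolve
#'   under no-flux conditions (FALSE).
#' @return The advanced [density_field()].
#' @export
step_density <- function(field, dt, params, schedule = NULL,
                         dirichlet = FALSE) {
  v <- field$values
  m <- nrow(v)
  rhs <- cpp_diffusion_rhs(v, field$h, params$d * (1 - params$w_A), params$d,
                           params$alpha)
  if (!is.null(schedule) && nrow(schedule) > 0) {
    vel <- retraction_velocity(field, field$t, schedule, params)
    rhs <- rhs + cpp_advection_rhs(v, vel$vx, vel$vy, field$h)
  }
  out <- v + dt * rhs
  if (dirichlet) {
    out[, 1] <- v[, 1]
    out[, m] <- v[, m]
  }
  out <- pmin(pmax(out, 0), 1)
  density_field(out, field$h, field$t + dt)
}
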