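# analytic pieces of the continuum operator, used as the convergence oracle
dhat_prime <- function(r, a) {
  2 - 2 * (1 + 11 * a) * r + 3 * (8 * a + 16 * a^2) * r^2 -
    4 * (13 * a^2 + 7 * a^3) * r^3 + 30 * a^3 * r^4
}

# independent conservative centred-difference discretization of
# div(D grad rho) with D = diag(dh, dv) * Dhat(rho): interface diffusivity
# from the midpoint density
centered_oracle <- function(rho, h, dh, dv, a) {
  m <- nrow(rho)
  out <- matrix(0, m, m)
  Dmid <- function(r1, r2) scalar_diffusion_coeff((r1 + r2) / 2, a)
  for (i in 1:(m - 1)) {
    f <- dh * Dmid(rho[i, ], rho[i + 1, ]) * (rho[i + 1, ] - rho[i, ]) / h^2
    out[i, ] <- out[i, ] + f
    out[i + 1, ] <- out[i + 1, ] - f
  }
  for (j in 1:(m - 1)) {
    f <- dv * Dmid(rho[, j], rho[, j + 1]) * (rho[, j + 1] - rho[, j]) / h^2
    out[, j] <- out[, j] + f
    out[, j + 1] <- out[, j + 1] - f
  }
  out
}

smooth_test_field <- function(n) {
  g <- (0:n) / n
  X <- outer(g, rep(1, n + 1))
  Y <- t(X)
  list(rho = 0.3 + 0.15 * sin(2 * pi * X) * cos(2 * pi * Y), X = X, Y = Y)
}

test_that("transitional probabilities obey volume filling and symmetry", {
  p <- test_params()
  full <- uniform_field(1)
  tp <- transitional_probabilities(full, p)
  expect_equal(max(abs(tp$diff_right)), 0)
  expect_equal(max(abs(tp$diff_up)), 0)
  # isotropic weights, uniform density: all four diffusive rates equal
  iso <- test_params(w_A = 0)
  tp2 <- transitional_probabilities(uniform_field(0.4), iso)
  expect_equal(tp2$diff_right, tp2$diff_left)
  expect_equal(tp2$diff_right, tp2$diff_up)
  expect_equal(tp2$diff_right, tp2$diff_down)
  # advective parts split the drift by direction
  f <- uniform_field(0.2)
  adv <- list(vx = matrix(1, 33, 33), vy = matrix(-2, 33, 33))
  tp3 <- transitional_probabilities(f, p, advection = adv)
  expect_true(all(tp3$adv_right > 0))
  expect_equal(max(abs(tp3$adv_left)), 0)
  expect_true(all(tp3$adv_down > 0))
  expect_equal(max(abs(tp3$adv_up)), 0)
})

test_that("master-equation assembly matches the compiled diffusion kernel", {
  p <- test_params()
  fl <- smooth_test_field(24)
  f <- density_field(pmin(pmax(fl$rho, 0), 1), h = 1 / 24)
  tp <- transitional_probabilities(f, p)
  m <- 25
  shift <- function(M, di, dj) {
    idx <- function(i) ifelse(i < 1, 2 - i, ifelse(i > m, 2 * m - i, i))
    M[idx(seq_len(m) + di), idx(seq_len(m) + dj)]
  }
  v <- f$values
  rhs_master <- shift(tp$diff_right * v, -1, 0) + shift(tp$diff_left * v, 1, 0) +
    shift(tp$diff_up * v, 0, -1) + shift(tp$diff_down * v, 0, 1) -
    (tp$diff_right + tp$diff_left + tp$diff_up + tp$diff_down) * v
  got <- cpp_diffusion_rhs(v, f$h, p$d * (1 - p$w_A), p$d, p$alpha)
  # interior only: the flux form zeroes boundary-crossing fluxes while the
  # naive mirrored assembly does not
  idx <- 3:(m - 2)
  expect_equal(got[idx, idx], rhs_master[idx, idx], tolerance = 1e-12)
})

test_that("diffusion discretization is second-order against the analytic operator", {
  a <- 0.2; dh <- 0.3; dv <- 0.5
  err_at <- function(n) {
    fl <- smooth_test_field(n)
    rho <- fl$rho
    rx <- 0.15 * 2 * pi * cos(2 * pi * fl$X) * cos(2 * pi * fl$Y)
    rxx <- -0.15 * (2 * pi)^2 * sin(2 * pi * fl$X) * cos(2 * pi * fl$Y)
    ry <- -0.15 * 2 * pi * sin(2 * pi * fl$X) * sin(2 * pi * fl$Y)
    ryy <- rxx
    exact <- dh * (dhat_prime(rho, a) * rx^2 +
                     scalar_diffusion_coeff(rho, a) * rxx) +
      dv * (dhat_prime(rho, a) * ry^2 + scalar_diffusion_coeff(rho, a) * ryy)
    got <- cpp_diffusion_rhs(rho, 1 / n, dh, dv, a)
    oracle <- centered_oracle(rho, 1 / n, dh, dv, a)
    idx <- 4:(n - 2)
    c(master = max(abs(got[idx, idx] - exact[idx, idx])),
      oracle = max(abs(oracle[idx, idx] - exact[idx, idx])),
      pair = max(abs(got[idx, idx] - oracle[idx, idx])))
  }
  e32 <- err_at(32)
  e64 <- err_at(64)
  # both discretizations converge at order >= 1.9, and so does their gap
  expect_gte(log2(e32["master"] / e64["master"]), 1.9)
  expect_gte(log2(e32["oracle"] / e64["oracle"]), 1.9)
  expect_gte(log2(e32["pair"] / e64["pair"]), 1.9)
})

test_that("stable time step obeys the stated bounds and scalings", {
  p <- test_params(d = 1, alpha = 0, mu_s = 0, sigma_s = 0)
  h <- 1 / 64
  # max of 2 rho - rho^2 on [0, 1] is 1, so the diffusive bound is h^2 / 8
  expect_equal(cfl_dt(p, h, max_speed = 0), h^2 / 8, tolerance = 1e-9)
  # with mu_s = 0 the default is governed by diffusion alone
  expect_equal(cfl_dt(p, h), cfl_dt(p, h, max_speed = 0))
  # doubling resolution quarters dt in the diffusion-limited regime
  expect_equal(cfl_dt(p, h / 2, max_speed = 0) / cfl_dt(p, h, max_speed = 0),
               0.25, tolerance = 1e-9)
  # adding advection strictly tightens the step
  expect_lt(cfl_dt(p, h, max_speed = 10), cfl_dt(p, h, max_speed = 0))
})

test_that("uniform density is a fixed point of the explicit step", {
  p <- test_params(mu_s = 0)
  f <- uniform_field(0.6)
  out <- step_density(f, cfl_dt(p, f$h, max_speed = 0), p)
  expect_equal(out$values, f$values, tolerance = 1e-14)
})

test_that("all-Neumann retraction-free dynamics conserve mass over 1000 steps", {
  p <- test_params(mu_s = 0, sigma_s = 0)
  n <- 48
  dt <- cfl_dt(p, 1 / n, max_speed = 0)
  sim <- simulate_wound(p, n = n, horizon = 1000 * dt, seed = 2,
                        bc = "all_neumann", check_every = 100)
  drift <- abs(total_mass(sim$final) - total_mass(sim$initial)) /
    total_mass(sim$initial)
  expect_lt(drift, 1e-8)
})

test_that("density stays within [0, 1] for base-condition runs", {
  sim <- simulate_wound(test_params(), n = 64, horizon = 0.2, seed = 3,
                        snapshots = "all", snap_every = 500)
  for (v in sim$snapshots) {
    expect_gte(min(v), -1e-6)
    expect_lte(max(v), 1 + 1e-6)
  }
  expect_gte(min(sim$final$values), 0)
  expect_lte(max(sim$final$values), 1)
})

test_that("initial condition is banded, open in the middle, and reproducible", {
  p <- test_params()
  set.seed(9)
  f <- initial_condition(p, n = 64)
  m <- 65
  # wound open along the central row
  expect_true(all(f$values[, round(m / 2)] < p$gamma))
  # monolayer rows at the boundaries
  expect_true(all(f$values[, 1] > 0.95))
  expect_true(all(f$values[, m] > 0.95))
  set.seed(9)
  f2 <- initial_condition(p, n = 64)
  expect_identical(f$values, f2$values)
})

test_that("Dirichlet boundary functions stay within [0, 1]", {
  set.seed(4)
  coef <- woundsim:::draw_g_coef()
  for (t in c(0, 0.1, 0.7, 3)) {
    g <- eval_boundary_g(seq(0, 1, length.out = 101), t, coef, amp = 0.05)
    expect_true(all(g >= 0 & g <= 1))
    expect_true(all(g >= 0.9)) # perturbations around monolayer density
  }
})

test_that("solution is mirror symmetric under y -> 1 - y with mirrored schedules", {
  p <- test_params(sigma_r = 0, sigma_nr = 0, sigma_s = 0)
  sched <- tibble::tibble(side = c("bottom", "top"), c = c(0.3, 0.7),
                          tau = 0, T_r = 0.05, s = 20)
  mirrored <- tibble::tibble(side = c("top", "bottom"), c = c(0.3, 0.7),
                             tau = 0, T_r = 0.05, s = 20)
  n <- 48
  set.seed(5)
  init <- initial_condition(p, n = n, perturb = 0)
  run <- function(sc) {
    simulate_wound(p, n = n, horizon = 0.05, seed = 5, schedule = sc,
                   init = init, g_amp = 0, check_every = 1e6)
  }
  a <- run(sched)$final$values
  b <- run(mirrored)$final$values
  expect_equal(a, b[, (n + 1):1], tolerance = 1e-10)
})

test_that("x-independent problems stay x-independent (translation invariance)", {
  p <- test_params(mu_s = 0)
  n <- 48
  set.seed(6)
  init <- initial_condition(p, n = n, perturb = 0)
  sim <- simulate_wound(p, n = n, horizon = 0.05, seed = 6, init = init,
                        g_amp = 0)
  spread <- apply(sim$final$values, 2, function(row) diff(range(row)))
  expect_lt(max(spread), 1e-10)
})

test_that("closure detection has the right trivial limits", {
  p <- test_params(mu_s = 0)
  # already-closed field: closure at t = 0
  closed0 <- simulate_wound(p, n = 32, horizon = 0.01, seed = 1,
                            init = uniform_field(1), g_amp = 0)
  expect_true(closed0$closed)
  expect_equal(closure_time(closed0), 0)
  # static open band within a tiny horizon: no closure
  slow <- test_params(d = 1e-3, mu_s = 0)
  set.seed(2)
  open_sim <- simulate_wound(slow, n = 32, horizon = 1e-4, seed = 2)
  expect_false(open_sim$closed)
  expect_true(is.na(closure_time(open_sim)))
  # wound_spans is the underlying predicate
  expect_false(wound_spans(uniform_field(1), 0.4))
  expect_true(wound_spans(gen_scripted_field("flat", n = 32), 0.4))
})

test_that("wound area is non-increasing without retraction", {
  sim <- simulate_wound(test_params(mu_s = 0), n = 48, horizon = 0.15,
                        seed = 7)
  areas <- tidy(sim)$wound_area
  expect_true(all(diff(areas) <= 1e-4))
})

test_that("isotropic runs spread equally in x and y", {
  p <- test_params(w_A = 0, mu_s = 0)
  n <- 64
  g <- (0:n) / n
  X <- outer(g, rep(1, n + 1)); Y <- t(X)
  R <- sqrt((X - 0.5)^2 + (Y - 0.5)^2)
  disc <- density_field(pmin(pmax(0.5 + 0.5 * tanh((R - 0.25) / 0.03), 0), 1),
                        h = 1 / n)
  sim <- simulate_wound(p, n = n, horizon = 0.02, seed = 8, init = disc,
                        bc = "all_neumann")
  w <- 1 - sim$final$values
  sx <- sum(w * (X - 0.5)^2) / sum(w)
  sy <- sum(w * (Y - 0.5)^2) / sum(w)
  expect_lt(abs(sx - sy) / sx, 0.01)
})

test_that("deterministic closure time is grid-converged within 2%", {
  p <- test_params(sigma_r = 0, sigma_nr = 0, sigma_s = 0)
  sched <- tibble::tibble(side = rep(c("bottom", "top"), 12),
                          c = rep(c(0.25, 0.75), 12),
                          tau = rep(seq(0, 0.143, by = 0.013), each = 2),
                          T_r = 0.01, s = 20)
  ct <- vapply(c(64, 128), function(n) {
    set.seed(11)
    init <- initial_condition(p, n = n, perturb = 0)
    sim <- simulate_wound(p, n = n, horizon = 0.4, seed = 11, init = init,
                          schedule = sched, g_amp = 0)
    sim$closure_time
  }, numeric(1))
  expect_false(any(is.na(ct)))
  expect_lt(abs(ct[1] - ct[2]) / ct[2], 0.02)
})

test_that("an oversized time step is rejected with a clear error", {
  p <- test_params(mu_s = 0)
  expect_error(
    simulate_wound(p, n = 32, horizon = 0.05, seed = 1,
                   dt = 100 * cfl_dt(p, 1 / 32, max_speed = 0)),
    "instability"
  )
})

test_that("repeated runs with one seed are identical end to end", {
  a <- simulate_wound(test_params(), n = 32, horizon = 0.05, seed = 13)
  b <- simulate_wound(test_params(), n = 32, horizon = 0.05, seed = 13)
  expect_identical(a$final$values, b$final$values)
  expect_identical(a$schedule, b$schedule)
  expect_identical(a$areas, b$areas)
})
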