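# brute-force oracles, written independently of the package implementations
msd_oracle <- function(xy, m) {
  n <- nrow(xy)
  if (m == 0) return(0)
  acc <- 0
  for (k in 0:(n - m - 1)) {
    acc <- acc + sum((xy[k + m + 1, ] - xy[k + 1, ])^2)
  }
  acc / (n - m)
}

vac_oracle <- function(xy, n_lag, dt) {
  v <- (xy[-1, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE]) / dt
  nv <- nrow(v)
  norm <- mean(v[, 1]^2 + v[, 2]^2)
  acc <- 0
  for (i in 1:(nv - n_lag)) {
    acc <- acc + sum(v[i, ] * v[i + n_lag, ])
  }
  acc / (nv - n_lag) / norm
}

tracks_from_xy <- function(xy, id = "t1") {
  tibble::tibble(track_id = id, frame = seq_len(nrow(xy)) - 1,
                 x_um = xy[, 1], y_um = xy[, 2])
}

test_that("MSD matches the stated closed forms and the brute-force oracle", {
  # stationary trajectory
  still <- tracks_from_xy(cbind(rep(1, 8), rep(2, 8)))
  expect_true(all(msd(still, dt = 5)$msd == 0))
  # ballistic motion: MSD(m) = (v m dt)^2
  v_um_min <- 0.3
  dt <- 5
  line <- tracks_from_xy(cbind((0:9) * v_um_min * dt, 0))
  out <- msd(line, dt = dt, max_lag = Inf)
  expect_equal(out$msd, (v_um_min * out$lag * dt)^2, tolerance = 1e-12)
  # random trajectory equals the double-loop oracle to 1e-12
  set.seed(1)
  xy <- cbind(cumsum(rnorm(10)), cumsum(rnorm(10)))
  got <- msd(tracks_from_xy(xy), dt = 5, max_lag = Inf)
  want <- vapply(0:9, function(m) msd_oracle(xy, m), numeric(1))
  expect_equal(got$msd, want, tolerance = 1e-12)
  expect_error(msd(tracks_from_xy(xy), max_lag = Inf)[0, ], NA)
})

test_that("velocity autocorrelation matches hand-evaluated and oracle values", {
  # constant velocity: 1 at every lag
  line <- tracks_from_xy(cbind(0:9, 2 * (0:9)))
  out <- velocity_autocorrelation(line, dt = 5, max_lag = Inf)
  expect_true(all(abs(out$vac - 1) < 1e-12))
  expect_equal(out$vac[out$lag == 0], 1)
  # perfect back-and-forth: -1 at lag 1
  zig <- tracks_from_xy(cbind(rep(c(0, 1), 3), 0))
  out2 <- velocity_autocorrelation(zig, dt = 5, max_lag = 1)
  expect_equal(out2$vac[out2$lag == 1], -1, tolerance = 1e-12)
  # random trajectory equals the independent oracle to 1e-12
  set.seed(2)
  xy <- cbind(cumsum(rnorm(10)), cumsum(rnorm(10)))
  got <- velocity_autocorrelation(tracks_from_xy(xy), dt = 5, max_lag = Inf)
  want <- vapply(0:(nrow(xy) - 2), function(n) vac_oracle(xy, n, 5),
                 numeric(1))
  expect_equal(got$vac, want, tolerance = 1e-12)
  # all-zero velocities are undefined
  expect_error(velocity_autocorrelation(tracks_from_xy(cbind(rep(0, 5), 0))),
               "undefined|zero")
})

test_that("instantaneous speed scales correctly", {
  still <- tracks_from_xy(cbind(rep(0, 5), 0))
  expect_equal(instantaneous_speed(still, dt = 5)$speed_um_min, 0)
  line <- tracks_from_xy(cbind((0:5) * 1, 0)) # 1 um per frame
  expect_equal(instantaneous_speed(line, dt = 5)$speed_um_min, 0.2)
  doubled <- tracks_from_xy(cbind((0:5) * 2, 0))
  expect_equal(instantaneous_speed(doubled, dt = 5)$speed_um_min, 0.4)
})

test_that("ensemble average reduces to the n = 2 formulas", {
  xy <- cbind(0:9, 0)
  two <- dplyr::bind_rows(tracks_from_xy(xy, "a"),
                          tracks_from_xy(2 * xy, "b"))
  curves <- msd(two, dt = 5, max_lag = Inf)
  avg <- ensemble_average(curves, "msd")
  c1 <- curves$msd[curves$track_id == "a"]
  c2 <- curves$msd[curves$track_id == "b"]
  expect_equal(avg$mean, (c1 + c2) / 2, tolerance = 1e-12)
  expect_equal(avg$sem, abs(c1 - c2) / 2, tolerance = 1e-12)
  # identical trajectories: SEM identically zero
  same <- dplyr::bind_rows(tracks_from_xy(xy, "a"), tracks_from_xy(xy, "b"))
  expect_true(all(ensemble_average(msd(same, dt = 5), "msd")$sem == 0))
})

test_that("correlated-walk MSD exponents bracket the ballistic and diffusive limits", {
  tr1 <- gen_trajectories(n_tracks = 40, n_frames = 40, speed = 1,
                          persistence = 1, dt = 5, seed = 10)
  m1 <- ensemble_average(msd(tr1, dt = 5), "msd")
  fit1 <- lm(log(mean) ~ log(tau_min), data = m1[m1$lag > 0, ])
  expect_equal(unname(coef(fit1)[2]), 2, tolerance = 0.01)
  tr0 <- gen_trajectories(n_tracks = 250, n_frames = 60, speed = 1,
                          persistence = 0, dt = 5, seed = 11)
  m0 <- ensemble_average(msd(tr0, dt = 5), "msd")
  # diffusive limit over long lags
  sub <- m0[m0$lag >= 5, ]
  fit0 <- lm(log(mean) ~ log(tau_min), data = sub)
  expect_equal(unname(coef(fit0)[2]), 1, tolerance = 0.15)
})

test_that("velocity autocorrelation decays faster for less persistent walks", {
  rate <- function(p, seed) {
    tr <- gen_trajectories(n_tracks = 120, n_frames = 30, speed = 1,
                           persistence = p, dt = 5, seed = seed)
    v <- ensemble_average(velocity_autocorrelation(tr, dt = 5), "vac")
    # lag-1 autocorrelation as decay proxy
    v$mean[v$lag == 1]
  }
  expect_gt(rate(0.8, 21), rate(0.2, 22))
})
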