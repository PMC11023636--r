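test_that("deterministic schedule places events at exact multiples of the cycle", {
  p <- test_params(mu_r = 1, sigma_r = 0, mu_nr = 2, sigma_nr = 0,
                   mu_s = 5, sigma_s = 0)
  set.seed(1)
  sched <- sample_retraction_schedule(p, horizon = 10, first_start = 0)
  for (side in c("bottom", "top")) {
    ev <- sched[sched$side == side, ]
    expect_equal(ev$tau, seq(0, 9, by = 3))
    expect_true(all(ev$T_r == 1))
    expect_true(all(ev$s == 5))
  }
})

test_that("long-horizon mean event count approaches horizon / (mu_r + mu_nr)", {
  p <- test_params(mu_r = 0.5, sigma_r = 0.1, mu_nr = 0.5, sigma_nr = 0.1,
                   mu_s = 1, sigma_s = 0.2)
  set.seed(42)
  horizon <- 50
  counts <- replicate(300, {
    sum(sample_retraction_schedule(p, horizon)$side == "bottom")
  })
  # rejection sampling leaves the means essentially unchanged here
  # (sigma / mu = 0.2), so the renewal rate is ~ 1 / (mu_r + mu_nr)
  expected <- horizon / (p$mu_r + p$mu_nr)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1)
})

test_that("rejection sampling keeps all durations and strengths positive", {
  p <- test_params(mu_s = 0.5, sigma_s = 10, mu_r = 0.2, sigma_r = 2,
                   mu_nr = 0.2, sigma_nr = 2)
  set.seed(7)
  sched <- sample_retraction_schedule(p, horizon = 20)
  expect_true(all(sched$s > 0))
  expect_true(all(sched$T_r > 0))
  expect_true(all(sched$c >= 0 & sched$c <= 1))
  # events on one side never overlap
  for (side in c("bottom", "top")) {
    ev <- sched[sched$side == side, ]
    expect_true(all(diff(ev$tau) >= ev$T_r[-nrow(ev)]))
  }
})

test_that("realized event durations match the truncated-normal mean", {
  p <- test_params(mu_r = 0.3, sigma_r = 0.6, mu_nr = 0.5, sigma_nr = 0.1,
                   mu_s = 1, sigma_s = 0)
  set.seed(11)
  sched <- sample_retraction_schedule(p, horizon = 400)
  target <- truncated_normal_mean(p$mu_r, p$sigma_r)
  expect_gt(target, p$mu_r) # rejection inflates the mean when sigma >> mu
  se <- sd(sched$T_r) / sqrt(nrow(sched))
  expect_lt(abs(mean(sched$T_r) - target), 4 * se)
})

test_that("retraction velocity is localized in density, time and space", {
  p <- test_params(width_h = 0.02, width_x = 0.005, width_t = 0.001)
  sched <- tibble::tibble(side = "bottom", c = 0.5, tau = 1, T_r = 1, s = 4)
  # well above the threshold: Heaviside off
  f_high <- uniform_field(0.9)
  v <- retraction_velocity(f_high, t = 1.5, sched, p)
  expect_equal(max(abs(v$vx)), 0, tolerance = 1e-10)
  expect_equal(max(abs(v$vy)), 0, tolerance = 1e-10)
  # between events: time indicator off
  f_low <- uniform_field(0)
  v2 <- retraction_velocity(f_low, t = 5, sched, p)
  expect_equal(max(abs(v2$vy)), 0, tolerance = 1e-10)
  # inside the band at rho = 0 in the sharp limit the speed equals s
  v3 <- retraction_velocity(f_low, t = 1.5, sched, p)
  m <- nrow(f_low$values)
  speed <- sqrt(v3$vx^2 + v3$vy^2)
  # band centre column, deep in the lower half
  expect_equal(speed[round(0.5 * m), round(0.2 * m)], 4, tolerance = 1e-3)
  # outside the band: off
  expect_lt(speed[round(0.9 * m), round(0.2 * m)], 1e-6)
  # bottom-side event pushes towards y = 0 in the lower half
  expect_lt(v3$vy[round(0.5 * m), round(0.2 * m)], 0)
})

test_that("compiled retraction velocity matches the pure-R reference", {
  p <- test_params()
  set.seed(3)
  sched <- sample_retraction_schedule(p, horizon = 0.1)
  f <- gen_scripted_field("sine", n = 48, halfwidth = 0.3)
  tq <- sched$tau[1] + sched$T_r[1] / 2
  a <- retraction_velocity(f, tq, sched, p)
  b <- retraction_velocity_ref(f, tq, sched, p)
  expect_equal(a$vx, b$vx, tolerance = 1e-12)
  expect_equal(a$vy, b$vy, tolerance = 1e-12)
})

test_that("zero mean strength disables the retraction field entirely", {
  p <- test_params(mu_s = 0, sigma_s = 0)
  set.seed(5)
  sched <- sample_retraction_schedule(p, horizon = 1)
  expect_true(all(sched$s == 0))
  f <- uniform_field(0.1)
  v <- retraction_velocity(f, t = sched$tau[1] + 1e-3, sched, p)
  expect_equal(max(abs(v$vx)) + max(abs(v$vy)), 0)
})
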