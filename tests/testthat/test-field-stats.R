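# circular-MLE oracle: invert the Bessel ratio A(kappa) = R
kappa_mle <- function(angles) {
  R <- sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
  if (R < 1e-8) return(0)
  A <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  stats::uniroot(function(k) A(k) - R, c(1e-8, 500))$root
}

test_that("von Mises density integrates to one and has the uniform limit", {
  expect_equal(von_mises_pdf(0.7, 0, 0), 1 / (2 * pi))
  expect_equal(von_mises_pdf(1, 1 + 0.3, 2), von_mises_pdf(1 + 0.6, 1 + 0.3, 2))
  for (k in c(0.5, 1, 5)) {
    q <- stats::integrate(von_mises_pdf, -pi, pi, mu = 0.4, kappa = k,
                          rel.tol = 1e-10)
    expect_equal(q$value, 1, tolerance = 1e-8)
  }
})

test_that("histogram-MSE von Mises fit recovers known parameters", {
  set.seed(100)
  a <- rvon_mises(1e5, mu = 0, kappa = 2)
  fit <- fit_von_mises(a)
  expect_lt(abs(fit$kappa - 2) / 2, 0.05)
  expect_lt(abs(fit$mu), 0.05)
  # uniform angles give near-zero concentration
  set.seed(101)
  u <- runif(1e5, -pi, pi)
  expect_lt(fit_von_mises(u)$kappa, 0.05)
  # agreement with the closed-form circular MLE within 10%
  for (k in c(0.3, 1, 3)) {
    set.seed(200 + k * 10)
    x <- rvon_mises(2e4, mu = 0.5, kappa = k)
    expect_lt(abs(fit_von_mises(x)$kappa - kappa_mle(x)) / kappa_mle(x), 0.1)
  }
  expect_error(fit_von_mises(numeric(0)), "no angles")
})

test_that("wound-oriented angles are equivariant under joint rotation", {
  f <- tibble::tibble(x_um = c(0, 10), y_um = c(0, 10),
                      u = c(0, 0), v = c(1, -1))
  a <- orient_angles(f, normal = c(0, 1))
  expect_equal(a, c(0, pi))
  # rotate field and normal together by 40 degrees
  th <- 40 * pi / 180
  rot <- function(u, v) cbind(cos(th) * u - sin(th) * v,
                              sin(th) * u + cos(th) * v)
  uv <- rot(f$u, f$v)
  f2 <- tibble::tibble(x_um = f$x_um, y_um = f$y_um, u = uv[, 1], v = uv[, 2])
  a2 <- orient_angles(f2, normal = c(-sin(th), cos(th)))
  expect_equal(a2, a, tolerance = 1e-12)
})

test_that("angular deviation has the stated endpoints", {
  expect_equal(angular_deviation(rep(0.3, 50)), 0)
  expect_equal(angular_deviation(c(0, pi / 2, pi, 3 * pi / 2)), 1,
               tolerance = 1e-12)
  set.seed(9)
  expect_equal(angular_deviation(runif(1e5, -pi, pi)), 1, tolerance = 0.01)
  # the printed resultant form is available as an option
  expect_equal(angular_deviation(rep(1, 10), type = "resultant"), 1)
})

test_that("spatial autocorrelation is exact on constant and noise fields", {
  const <- gen_vector_field(nx = 24, ny = 24, kappa = 50, corr_length = 0,
                            mag_cv = 0, seed = 1)
  const$u <- 0; const$v <- 1
  cc <- spatial_autocorrelation(const)
  expect_true(all(abs(cc$C - 1) < 1e-12))
  expect_equal(cc$C[cc$r == 0], 1)
  # iid noise: near-zero correlation beyond zero separation
  set.seed(12)
  vals <- replicate(5, {
    f <- gen_vector_field(nx = 64, ny = 64, kappa = 0, corr_length = 0,
                          seed = sample.int(1e6, 1))
    cc <- spatial_autocorrelation(f)
    max(abs(cc$C[cc$r > 0 & cc$r < 300]))
  })
  expect_lt(median(vals), 0.05)
})

test_that("spatial autocorrelation is invariant to sign flip and rescaling", {
  f <- gen_vector_field(nx = 32, ny = 32, kappa = 0.5, corr_length = 40,
                        seed = 4)
  c1 <- spatial_autocorrelation(f)
  f2 <- f; f2$u <- -3 * f$u; f2$v <- -3 * f$v
  c2 <- spatial_autocorrelation(f2)
  expect_equal(c1$C, c2$C, tolerance = 1e-12)
})

test_that("masked vectors are excluded from the statistics", {
  f <- gen_vector_field(nx = 16, ny = 16, kappa = 1, seed = 6)
  f$mask[1:50] <- FALSE
  a <- orient_angles(f)
  expect_length(a, nrow(f) - 50)
  cc <- spatial_autocorrelation(f)
  full <- spatial_autocorrelation(dplyr::mutate(f, mask = TRUE))
  expect_lt(max(cc$n_pairs), max(full$n_pairs))
})

test_that("length constant solves the fitted exponential crossing", {
  r <- seq(0, 300, by = 10)
  curve <- tibble::tibble(r = r, C = exp(-r / 50))
  # quadratic-exponent fit at the literal 0.37 threshold
  expect_equal(length_constant(curve), 50 * log(1 / 0.37), tolerance = 1e-6)
  # pure exponential at threshold exp(-1) gives the definition of the constant
  expect_equal(length_constant(curve, threshold = exp(-1)), 50,
               tolerance = 1e-6)
  # added downward curvature lowers the crossing distance
  bent <- tibble::tibble(r = r, C = exp(-r / 50 - (r / 300)^2))
  expect_lt(length_constant(bent), length_constant(curve))
  # a flat curve never reaches the threshold
  flat <- tibble::tibble(r = r, C = rep(0.9, length(r)))
  expect_true(is.na(length_constant(flat)))
})

test_that("local autocorrelation interpolates the binned curve", {
  curve <- tibble::tibble(r = c(0, 100, 200), C = c(1, 0.5, 0.2))
  expect_equal(local_autocorrelation(curve, 100), 0.5)
  expect_equal(local_autocorrelation(curve, 150), 0.35)
  const <- tibble::tibble(r = c(0, 150, 300), C = c(1, 1, 1))
  expect_equal(local_autocorrelation(const, 150), 1)
  expect_error(local_autocorrelation(curve, 500), "range")
})

test_that("generator round trip recovers direction concentration and correlation length", {
  f <- gen_vector_field(nx = 64, ny = 64, kappa = 5, corr_length = 0,
                        mean_direction = pi / 2, seed = 31)
  fit <- fit_von_mises(orient_angles(f, normal = c(0, 1)))
  expect_gt(fit$kappa, 3.5)
  expect_lt(fit$kappa, 6.5)
  expect_lt(abs(fit$mu), 0.1)
  # uniform limit
  f0 <- gen_vector_field(nx = 96, ny = 96, kappa = 0, corr_length = 0,
                         seed = 32)
  expect_lt(fit_von_mises(orient_angles(f0))$kappa, 0.05)
  expect_gt(angular_deviation(f0), 0.95)
  # imposed correlation length recovered within 30% (median of 3 fields on
  # the PIV-sized 64 x 64 grid)
  lc <- median(vapply(33:35, function(sd) {
    fL <- gen_vector_field(nx = 64, ny = 64, kappa = 0, corr_length = 100,
                           spacing = 13.8, seed = sd)
    length_constant(spatial_autocorrelation(fL))
  }, numeric(1)))
  expect_lt(abs(lc - 100) / 100, 0.3)
})

test_that("higher direction concentration means lower angular deviation", {
  kappas <- c(0.3, 0.7, 1.5, 4)
  devs <- vapply(seq_along(kappas), function(i) {
    f <- gen_vector_field(nx = 48, ny = 48, kappa = kappas[i], seed = 40 + i)
    angular_deviation(f)
  }, numeric(1))
  expect_equal(stats::cor(kappas, devs, method = "spearman"), -1)
})
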