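# von Mises sampler (Best & Fisher 1979 rejection scheme); kappa = 0 falls
# back to the circular uniform
rvon_mises <- function(n, mu, kappa) {
  if (kappa == 0) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0
  while (got < n) {
    todo <- n - got
    u1 <- runif(todo); u2 <- runif(todo); u3 <- runif(todo)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3 - 0.5)[ok] * acos(f[ok])
    take <- min(length(th), todo)
    if (take > 0) out[got + seq_len(take)] <- th[seq_len(take)]
    got <- got + take
  }
  wrap_angle(out + mu)
}

#' Generate correlated-random-walk trajectories
#'
#' Emulates nuclei-tracking exports: each track starts at a random position,
#' moves with fixed step length `speed * dt` per frame, and turns by wrapped
#' normal noise with standard deviation `(1 - persistence) * pi`, so
#' `persistence = 1` gives straight lines and `persistence = 0` an isotropic
#' random walk. Deterministic given `seed`.
#'
#' @param n_tracks Number of trajectories.
#' @param n_frames Time points per trajectory.
#' @param speed Speed in micrometres per minute.
#' @param persistence Directional persistence in `[0, 1]`.
#' @param dt Frame interval in minutes.
#' @param seed Integer seed.
#' @param spread Spatial spread of starting positions (micrometres).
#' @return A tibble with columns `track_id`, `frame`, `x_um`, `y_um`.
#' @examples
#' tr <- gen_trajectories(n_tracks = 3, n_frames = 10, seed = 1)
#' @export
gen_trajectories <- function(n_tracks = 50, n_frames = 60, speed = 0.5,
                             persistence = 0.5, dt = 5, seed = 1,
                             spread = 500) {
  stopifnot(persistence >= 0, persistence <= 1, speed >= 0, n_frames >= 2)
  set.seed(seed)
  step <- speed * dt
  sd_turn <- (1 - persistence) * pi
  purrr::map_dfr(seq_len(n_tracks), function(k) {
    heading <- runif(1, -pi, pi)
    turns <- rnorm(n_frames - 2, 0, sd_turn)
    headings <- heading + c(0, cumsum(turns))
    dx <- c(0, step * cos(headings))
    dy <- c(0, step * sin(headings))
    tibble::tibble(track_id = sprintf("track_%04d", k),
                   frame = 0:(n_frames - 1),
                   x_um = runif(1, 0, spread) + cumsum(dx),
                   y_um = runif(1, 0, spread) + cumsum(dy))
  })
}

# separable Gaussian blur with edge renormalization (kernel rows re-scaled
# so smoothing does not damp values near the grid border)
gauss_blur <- function(M, sigma_cells) {
  if (sigma_cells <= 0) return(M)
  half <- max(1, ceiling(3 * sigma_cells))
  k <- dnorm(-half:half, sd = sigma_cells)
  smooth_dim <- function(A) {
    n <- nrow(A)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - half):(i + half)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- k[ok] / sum(k[ok])
    }
    K %*% A
  }
  t(smooth_dim(t(smooth_dim(M))))
}

#' Generate a direction-concentrated, spatially correlated vector field
#'
#' Emulates PIV output: directions are drawn from a von Mises distribution
#' about `mean_direction` with concentration `kappa`, converted to unit
#' vectors, optionally smoothed with a Gaussian kernel so that the spatial
#' autocorrelation of the velocity decays to 0.37 at separation
#' `corr_length`, re-normalized to unit length and scaled by positive
#' magnitudes. Re-normalizing the smoothed unit vectors shrinks their
#' correlations, so the kernel SD is set to `0.6 * corr_length` (calibrated
#' once on large grids so the realized 0.37-crossing matches `corr_length`);
#' the same re-normalization inflates the apparent direction concentration,
#' so round-trip recovery of `kappa` is only approximate when
#' `corr_length > 0`. Deterministic given `seed`.
#'
#' @param nx,ny Grid dimensions.
#' @param spacing Grid spacing in micrometres.
#' @param mean_direction Mean direction (radians; default `pi/2`, towards
#'   the wound along `+y`).
#' @param kappa Von Mises concentration (>= 0; 0 = uniform directions).
#' @param corr_length Imposed correlation length in micrometres (0 = none).
#' @param magnitude Mean speed magnitude.
#' @param mag_cv Coefficient of variation of the (lognormal) magnitudes.
#' @param seed Integer seed.
#' @return A tibble with columns `x_um`, `y_um`, `u`, `v`, `mask`.
#' @export
gen_vector_field <- function(nx = 64, ny = 64, spacing = 13.8,
                             mean_direction = pi / 2, kappa = 0,
                             corr_length = 0, magnitude = 1, mag_cv = 0.1,
                             seed = 1) {
  stopifnot(kappa >= 0, corr_length >= 0, magnitude > 0)
  set.seed(seed)
  th <- matrix(rvon_mises(nx * ny, mean_direction, kappa), nx, ny)
  U <- cos(th); V <- sin(th)
  if (corr_length > 0) {
    sc <- (0.6 * corr_length) / spacing
    U <- gauss_blur(U, sc); V <- gauss_blur(V, sc)
    nrm <- sqrt(U^2 + V^2)
    nrm[nrm < 1e-12] <- 1
    U <- U / nrm; V <- V / nrm
  }
  mag <- matrix(magnitude * exp(rnorm(nx * ny, 0, mag_cv) - mag_cv^2 / 2),
                nx, ny)
  tibble::tibble(
    x_um = rep((seq_len(nx) - 1) * spacing, times = ny),
    y_um = rep((seq_len(ny) - 1) * spacing, each = nx),
    u = as.vector(U * mag), v = as.vector(V * mag), mask = TRUE
  )
}

#' Scripted density fields for metric tests
#'
#' Analytic density fields on the unit square: `"flat"` gives two straight
#' interfaces bounding a central cell-free band, `"sine"` modulates both
#' interfaces sinusoidally, `"closed"` is a uniform monolayer with no wound.
#' Interfaces are tanh-smoothed over a few grid cells (or sharp when
#' `delta = 0`).
#'
#' @param kind One of `"flat"`, `"sine"`, `"closed"`.
#' @param amplitude Sine amplitude (interface `y = 0.5 +/- halfwidth +
#'   amplitude * sin(2 pi x)`).
#' @param n Grid resolution.
#' @param halfwidth Half-width of the cell-free band.
#' @param delta Interface smoothing width; `NULL` uses `1.5 / n`, `0` gives
#'   a sharp step.
#' @return A [density_field()].
#' @export
gen_scripted_field <- function(kind = c("flat", "sine", "closed"),
                               amplitude = 0.05, n = 128, halfwidth = 0.2,
                               delta = NULL) {
  kind <- match.arg(kind)
  h <- 1 / n
  xs <- (0:n) * h
  if (is.null(delta)) delta <- 1.5 * h
  v <- matrix(1, n + 1, n + 1)
  if (kind != "closed") {
    amp <- if (kind == "sine") amplitude else 0
    for (i in 1:(n + 1)) {
      off <- amp * sin(2 * pi * xs[i])
      ylo <- 0.5 - halfwidth + off
      yhi <- 0.5 + halfwidth + off
      f <- if (delta > 0) {
        0.5 * (tanh((xs - ylo) / delta) - tanh((xs - yhi) / delta))
      } else {
        as.numeric(xs >= ylo & xs <= yhi)
      }
      v[i, ] <- pmin(pmax(1 - f, 0), 1)
    }
  }
  density_field(v, h = h, t = 0)
}
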