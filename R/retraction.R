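# draw from N(mu, sigma^2) conditioned on positivity (non-physical draws
# are discarded and redrawn); sigma = 0 returns mu
rtrunc_pos <- function(n, mu, sigma) {
  if (sigma == 0) return(rep(mu, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- rnorm(length(need), mu, sigma)
    ok <- draw > 0
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# mean of N(mu, sigma^2) truncated to (0, Inf); used by tests to state the
# realized mean under rejection sampling
truncated_normal_mean <- function(mu, sigma) {
  if (sigma == 0) return(mu)
  a <- -mu / sigma
  mu + sigma * dnorm(a) / (1 - pnorm(a))
}

#' Sample a retraction event schedule
#'
#' Draws, independently for the two wound edges (the bottom and top
#' monolayers), a chronological sequence of localized retraction events
#' covering `[0, horizon]`. Each event has a band centre `c ~ U(0, 1)`, a
#' duration and a strength drawn from normal distributions truncated to
#' positive values (non-physical draws are discarded and redrawn), and the
#' next event starts after an idle period drawn the same way, so events on
#' one side never overlap. When `mu_s = 0` the strengths are identically
#' zero and the schedule exerts no advection.
#'
#' @param params A [model_params()] object.
#' @param horizon Simulation end time (> 0).
#' @param first_start Start time of the first event on each side; `NULL`
#'   (default) draws it uniformly on `[0, mu_r + mu_nr]` so the two sides are
#'   not synchronized. A numeric value (e.g. `0`) fixes it on both sides.
#' @return A tibble of class `retraction_schedule` with columns `side`
#'   (`"bottom"`/`"top"`), `c`, `tau`, `T_r`, `s`, ordered by side then start
#'   time, with attribute `horizon`.
#' @examples
#' p <- model_params(sigma_r = 0, sigma_nr = 0, sigma_s = 0)
#' set.seed(1)
#' sample_retraction_schedule(p, horizon = 0.5)
#' @export
sample_retraction_schedule <- function(params, horizon, first_start = NULL) {
  if (!is.numeric(horizon) || horizon <= 0) {
    rlang::abort("'horizon' must be > 0")
  }
  if (params$mu_r <= 0 || params$mu_nr <= 0) {
    rlang::abort("mean durations must be > 0 to sample a schedule")
  }
  one_side <- function(side) {
    tau <- if (is.null(first_start)) {
      runif(1, 0, params$mu_r + params$mu_nr)
    } else {
      first_start
    }
    cs <- taus <- trs <- ss <- numeric(0)
    while (tau < horizon) {
      T_r <- rtrunc_pos(1, params$mu_r, params$sigma_r)
      s <- if (params$mu_s == 0) 0 else rtrunc_pos(1, params$mu_s, params$sigma_s)
      cs <- c(cs, runif(1))
      taus <- c(taus, tau)
      trs <- c(trs, T_r)
      ss <- c(ss, s)
      tau <- tau + T_r + rtrunc_pos(1, params$mu_nr, params$sigma_nr)
    }
    tibble::tibble(side = side, c = cs, tau = taus, T_r = trs, s = ss)
  }
  out <- dplyr::bind_rows(one_side("bottom"), one_side("top"))
  attr(out, "horizon") <- horizon
  class(out) <- c("retraction_schedule", class(out))
  out
}

# schedule tibble -> numeric matrix (side01, c, tau, T_r, s) for the C++ core
schedule_matrix <- function(schedule) {
  if (is.null(schedule) || nrow(schedule) == 0) {
    return(matrix(numeric(0), ncol = 5))
  }
  cbind(as.numeric(schedule$side == "top"), schedule$c, schedule$tau,
        schedule$T_r, schedule$s)
}

#' Retraction drift velocity
#'
#' Evaluates the retraction advection velocity at grid points for a density
#' field and an event schedule. The drift is
#' `H(gamma - rho) * (1 - rho) * (1 - alpha rho)^3 * s` in magnitude (with
#' the smoothed Heaviside and bell indicators localizing it to the wound
#' edge, the active time window and the active band), split equally between
#' the horizontal and vertical components (`s / sqrt(2)` each) and directed
#' away from the wound: events on the bottom monolayer push density towards
#' `y = 0`, events on the top towards `y = 1`.
#'
#' @param field A [density_field()].
#' @param t Time at which to evaluate.
#' @param schedule A `retraction_schedule`.
#' @param params A [model_params()] object.
#' @param ramp_w Width of the logistic ramp assigning grid rows to the two
#'   sides about `y = 1/2`.
#' @return A list with matrices `vx` and `vy` matching `field$values`.
#' @export
retraction_velocity <- function(field, t, schedule, params, ramp_w = 0.02) {
  res <- cpp_retraction_velocity(field$values, field$h, t,
                                 schedule_matrix(schedule),
                                 params$alpha, params$gamma, params$omega_r,
                                 params$width_h, params$width_x,
                                 params$width_t, ramp_w)
  res
}

# pure-R reference implementation used to cross-check the compiled kernel
retraction_velocity_ref <- function(field, t, schedule, params,
                                    ramp_w = 0.02) {
  m <- nrow(field$values)
  xs <- (seq_len(m) - 1) * field$h
  ys <- xs
  vx <- vy <- matrix(0, m, m)
  if (is.null(schedule) || nrow(schedule) == 0) return(list(vx = vx, vy = vy))
  base <- smooth_heaviside(params$gamma - field$values, params$width_h) *
    (1 - field$values) * (1 - params$alpha * field$values)^3 / sqrt(2)
  rb <- 1 / (1 + exp((ys - 0.5) / ramp_w))
  cw_b <- cw_t <- cwx_b <- cwx_t <- numeric(m)
  for (e in seq_len(nrow(schedule))) {
    s <- schedule$s[e]
    if (s <= 0) next
    bt <- smooth_indicator_time(t, schedule$tau[e], schedule$T_r[e],
                                params$width_t)
    if (bt < 1e-8) next
    bx <- smooth_indicator_space(xs, schedule$c[e], params$omega_r,
                                 params$width_x)
    bx[bx < 1e-10] <- 0
    sgn <- sign(xs - schedule$c[e])
    if (schedule$side[e] == "bottom") {
      cw_b <- cw_b + s * bt * bx
      cwx_b <- cwx_b + s * bt * bx * sgn
    } else {
      cw_t <- cw_t + s * bt * bx
      cwx_t <- cwx_t + s * bt * bx * sgn
    }
  }
  for (j in seq_len(m)) {
    vx[, j] <- base[, j] * (cwx_b * rb[j] + cwx_t * (1 - rb[j]))
    vy[, j] <- base[, j] * (cw_t * (1 - rb[j]) - cw_b * rb[j])
  }
  list(vx = vx, vy = vy)
}
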