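# split a tracks table into a list of per-trajectory coordinate matrices,
# ordered by frame; assumes gap-free tracks (read_tracks() splits gaps)
track_list <- function(tracks) {
  stopifnot(is.data.frame(tracks),
            all(c("track_id", "frame", "x_um", "y_um") %in% names(tracks)))
  tracks <- dplyr::arrange(tracks, .data$track_id, .data$frame)
  idx <- split(seq_len(nrow(tracks)), tracks$track_id)
  lapply(idx, function(ii) cbind(tracks$x_um[ii], tracks$y_um[ii]))
}

msd_single <- function(xy, lags) {
  n <- nrow(xy)
  vapply(lags, function(m) {
    if (m == 0) return(0)
    d <- xy[(m + 1):n, , drop = FALSE] - xy[1:(n - m), , drop = FALSE]
    sum(d^2) / (n - m)
  }, numeric(1))
}

#' Time-averaged mean squared displacement
#'
#' Overlapping-window time average per trajectory:
#' \deqn{\Delta^2(m) = \frac{1}{N_t - m} \sum_{k=0}^{N_t-m-1}
#'   [r(k+m) - r(k)]^2,} with `MSD(0) = 0`. Lags are reported up to
#' `max_lag` (default: a third of the trajectory length, the range over
#' which the time average is well sampled).
#'
#' @param tracks A data frame with columns `track_id`, `frame`, `x_um`,
#'   `y_um` (uniform frame interval, no gaps).
#' @param dt Frame interval in minutes.
#' @param max_lag Largest lag (frames); `NULL` uses `floor((N_t - 1) / 3)`
#'   per track, `Inf` uses all available lags.
#' @return A tibble with columns `track_id`, `lag`, `tau_min`, `msd`
#'   (square micrometres).
#' @export
msd <- function(tracks, dt = 5, max_lag = NULL) {
  tl <- track_list(tracks)
  purrr::imap_dfr(tl, function(xy, id) {
    n <- nrow(xy)
    if (n < 2) rlang::abort("each trajectory needs at least 2 points")
    top <- if (is.null(max_lag)) {
      max(1, floor((n - 1) / 3))
    } else {
      min(n - 1, max_lag)
    }
    lags <- 0:top
    tibble::tibble(track_id = id, lag = lags, tau_min = lags * dt,
                   msd = msd_single(xy, lags))
  })
}

vac_single <- function(xy, lags, dt) {
  v <- diff(xy) / dt # forward-difference velocities, one per interval
  nv <- nrow(v)
  norm <- mean(rowSums(v^2))
  if (norm == 0) rlang::abort("trajectory has zero net motion everywhere; velocity autocorrelation undefined")
  vapply(lags, function(n) {
    idx <- 1:(nv - n)
    sum(v[idx, 1] * v[idx + n, 1] + v[idx, 2] * v[idx + n, 2]) /
      (nv - n) / norm
  }, numeric(1))
}

#' Velocity autocorrelation of a trajectory
#'
#' Frame-difference velocities are correlated at increasing lags and
#' normalized by the mean squared speed, so `vac(0) = 1` exactly (pairs are
#' averaged over the lags actually available, the DiPer convention) and a
#' straight constant-velocity path gives 1 at every lag.
#'
#' @inheritParams msd
#' @return A tibble with columns `track_id`, `lag`, `tau_min`, `vac`.
#' @export
velocity_autocorrelation <- function(tracks, dt = 5, max_lag = NULL) {
  tl <- track_list(tracks)
  purrr::imap_dfr(tl, function(xy, id) {
    n <- nrow(xy)
    if (n < 3) rlang::abort("velocity autocorrelation needs at least 3 points")
    nv <- n - 1
    top <- if (is.null(max_lag)) max(1, floor(nv / 3)) else min(nv - 1, max_lag)
    lags <- 0:top
    tibble::tibble(track_id = id, lag = lags, tau_min = lags * dt,
                   vac = vac_single(xy, lags, dt))
  })
}

#' Average instantaneous speed per trajectory
#'
#' Mean over frames of the frame-to-frame displacement divided by the frame
#' interval.
#'
#' @inheritParams msd
#' @return A tibble with columns `track_id`, `speed_um_min`.
#' @export
instantaneous_speed <- function(tracks, dt = 5) {
  tl <- track_list(tracks)
  purrr::imap_dfr(tl, function(xy, id) {
    step <- sqrt(rowSums(diff(xy)^2))
    tibble::tibble(track_id = id, speed_um_min = mean(step) / dt)
  })
}

#' Ensemble mean and SEM of per-trajectory curves
#'
#' Pointwise mean and standard error across trajectories at each lag,
#' truncated to the lag range common to every trajectory.
#'
#' @param curves A tibble as returned by [msd()] or
#'   [velocity_autocorrelation()].
#' @param value Name of the value column (`"msd"` or `"vac"`).
#' @return A tibble with columns `lag`, `tau_min`, `mean`, `sem`, `n`.
#' @export
ensemble_average <- function(curves, value = c("msd", "vac")) {
  value <- match.arg(value)
  n_tracks <- dplyr::n_distinct(curves$track_id)
  common <- curves |>
    dplyr::count(.data$track_id) |>
    dplyr::summarise(m = min(.data$n)) |>
    dplyr::pull(.data$m)
  curves |>
    dplyr::filter(.data$lag < common) |>
    dplyr::group_by(.data$lag, .data$tau_min) |>
    dplyr::summarise(
      mean = mean(.data[[value]]),
      sem = if (dplyr::n() > 1) sd(.data[[value]]) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$lag)
}
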