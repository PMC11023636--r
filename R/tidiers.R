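#' Tidy a wound simulation
#'
#' @param x A `wound_sim` object.
#' @param ... Unused.
#' @return A tibble with one row per recorded check: `time`, `wound_area`
#'   (point-count fraction of the grid below the wound threshold).
#' @export
tidy.wound_sim <- function(x, ...) {
  tibble::tibble(time = x$times, wound_area = x$areas)
}

#' One-row summary of a wound simulation
#'
#' @param x A `wound_sim` object.
#' @param ... Unused.
#' @return A tibble with closure status and the two wound observables.
#' @export
glance.wound_sim <- function(x, ...) {
  tibble::tibble(
    closed = x$closed,
    closure_event = x$closure_event,
    closure_time = if (x$closed) x$closure_time else NA_real_,
    contact = x$contact,
    contact_time = if (isTRUE(x$contact)) x$contact_time else NA_real_,
    closure = normalized_wound_closure(x),
    edge_length = normalized_edge_length(x),
    horizon = x$horizon, n = x$n, seed = x$seed, steps = x$steps
  )
}

#' @export
tidy.von_mises_fit <- function(x, ...) {
  tibble::tibble(term = c("mu", "kappa"), estimate = c(x$mu, x$kappa))
}

#' @export
glance.von_mises_fit <- function(x, ...) {
  tibble::tibble(mu = x$mu, kappa = x$kappa, mse = x$mse, n = x$n)
}

#' @export
tidy.retraction_schedule <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Summarise a parameter sweep by parameter value
#'
#' @param x A `sweep_result` from [parameter_sweep()].
#' @param ... Unused.
#' @return A tibble with one row per swept value: means and standard errors
#'   of normalized wound closure and normalized edge length, and the closure
#'   proportion.
#' @export
tidy.sweep_result <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$parameter, .data$value) |>
    dplyr::summarise(
      closure_mean = mean(.data$closure),
      closure_sem = sd(.data$closure) / sqrt(dplyr::n()),
      edge_length_mean = mean(.data$edge_length, na.rm = TRUE),
      edge_length_sem = sd(.data$edge_length, na.rm = TRUE) /
        sqrt(sum(is.finite(.data$edge_length))),
      closed_proportion = mean(.data$closed),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$value)
}

#' Trend signs of a parameter sweep
#'
#' Spearman sign of the mean normalized wound closure and mean normalized
#' edge length against the swept parameter values; the signatures compared
#' against the model's characteristic sign pattern (only coordinated
#' directionality yields `+,+`).
#'
#' @param x A `sweep_result`.
#' @return A tibble with `parameter`, `closure_sign`, `edge_length_sign`
#'   (each `-1`, `0` or `1`).
#' @export
sweep_trend_signs <- function(x) {
  s <- tidy.sweep_result(x)
  spearman_sign <- function(v, y) {
    ok <- is.finite(y)
    sign(stats::cor(v[ok], y[ok], method = "spearman"))
  }
  tibble::tibble(
    parameter = s$parameter[1],
    closure_sign = spearman_sign(s$value, s$closure_mean),
    edge_length_sign = spearman_sign(s$value, s$edge_length_mean)
  )
}

#' @export
glance.correlation_curve <- function(x, ...) {
  tibble::tibble(
    length_constant = length_constant(x),
    C_at_150 = if (max(x$r) >= 150 && min(x$r) <= 150) {
      local_autocorrelation(x, 150)
    } else {
      NA_real_
    },
    n_bins = nrow(x)
  )
}
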