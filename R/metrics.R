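#' Wound area fraction
#'
#' Area of the low-density set `{rho < rho_wound}` as a fraction of the unit
#' square. Within each grid column the extent of the wound in `y` is measured
#' with linear sub-cell interpolation at threshold crossings; the column
#' measures are then integrated over `x` by the trapezoid rule.
#'
#' @param field A [density_field()].
#' @param rho_wound Density threshold.
#' @return Area fraction in `[0, 1]`.
#' @export
wound_area <- function(field, rho_wound) {
  v <- field$values
  m <- nrow(v)
  h <- field$h
  col_measure <- function(col) {
    below <- col < rho_wound
    len <- 0
    for (j in 1:(m - 1)) {
      a <- col[j]; b <- col[j + 1]
      if (below[j] && below[j + 1]) {
        len <- len + h
      } else if (below[j] != below[j + 1]) {
        frac <- (rho_wound - a) / (b - a) # crossing point within the cell
        len <- len + h * (if (below[j]) frac else 1 - frac)
      }
    }
    len
  }
  ms <- apply(v, 1, col_measure)
  w <- rep(h, m); w[c(1, m)] <- h / 2
  min(max(sum(w * ms), 0), 1)
}

#' Wound edge length
#'
#' Total length of the iso-density contour at `rho_edge`, extracted with
#' marching squares ([grDevices::contourLines()]) and summed over both
#' interfaces. Dimensionless (the domain width is 1); two perfectly flat
#' interfaces give 2.
#'
#' @param field A [density_field()].
#' @param rho_edge Contour level (default 0.5, the front's mid-density).
#' @return Total contour length.
#' @export
edge_length <- function(field, rho_edge = 0.5) {
  m <- nrow(field$values)
  g <- (seq_len(m) - 1) * field$h
  if (min(field$values) >= rho_edge || max(field$values) <= rho_edge) {
    return(0)
  }
  cl <- grDevices::contourLines(g, g, field$values, levels = rho_edge)
  sum(vapply(cl, function(seg) {
    sum(sqrt(diff(seg$x)^2 + diff(seg$y)^2))
  }, numeric(1)))
}

#' Edge-length time series and normalized edge length
#'
#' Edge length of every stored snapshot of a simulation (requires
#' `snapshots = "all"`), and the normalized edge length: the length at the
#' final time (the last snapshot at which the wound was still open, if it
#' closed) divided by the starting length.
#'
#' @param sim A `wound_sim` object.
#' @param rho_edge Contour level.
#' @return A tibble with columns `time` and `edge_length`.
#' @export
edge_length_series <- function(sim, rho_edge = 0.5) {
  if (length(sim$snapshots) == 0) {
    rlang::abort("edge_length_series requires snapshots = \"all\"")
  }
  tibble::tibble(
    time = sim$snapshot_times,
    edge_length = vapply(sim$snapshots, function(v) {
      edge_length(density_field(v, sim$h), rho_edge)
    }, numeric(1))
  )
}

#' @rdname edge_length_series
#' @export
normalized_edge_length <- function(sim, rho_edge = 0.5) {
  # evaluated when the interfaces first touch (the last stored field before
  # confirmed contact), or at the end of the horizon if they never do
  end <- if (isTRUE(sim$contact)) sim$pre_contact else sim$final
  e0 <- edge_length(sim$initial, rho_edge)
  if (e0 == 0) return(NA_real_)
  edge_length(end, rho_edge) / e0
}

#' Normalized wound closure
#'
#' Raw closure of one run: the fraction of the initial wound area closed by
#' `t_end = min(closure_time, horizon)`; a run that reached closure scores 1,
#' an untouched wound scores 0. Cross-condition normalization (dividing by
#' the mean raw closure of a control condition) is available through
#' `normalize_to_control()`.
#'
#' @param sim A `wound_sim` object.
#' @param rho_wound Threshold for the wound set (defaults to the run's).
#' @return Raw closure in `[0, 1]` (can be slightly negative if retraction
#'   enlarged the wound).
#' @export
normalized_wound_closure <- function(sim, rho_wound = NULL) {
  if (is.null(rho_wound)) rho_wound <- sim$rho_wound
  if (isTRUE(sim$closed)) return(1)
  a0 <- wound_area(sim$initial, rho_wound)
  if (a0 == 0) return(1)
  (a0 - wound_area(sim$final, rho_wound)) / a0
}

#' @rdname normalized_wound_closure
#' @param x Numeric vector of per-run metric values for a condition.
#' @param control Numeric vector of the same metric for the control
#'   condition.
#' @export
normalize_to_control <- function(x, control) {
  mc <- mean(control)
  if (mc == 0) rlang::abort("control mean is zero; cannot normalize")
  x / mc
}

#' Proportion of runs reaching closure
#'
#' Fraction of `n_reps` independently seeded simulations whose wound closed
#' within the horizon.
#'
#' @param params A [model_params()] object.
#' @param n_reps Number of replicate runs.
#' @param horizon Dimensionless end time per run.
#' @param seed Base seed; replicate `k` runs with `seed + k - 1`.
#' @param n Grid resolution.
#' @param event Closure event counted: `"healed"` (default; the wound has
#'   re-epithelialized along the whole scratch, the absorbing state after
#'   which retraction can no longer act) or `"contact"` (first confirmed
#'   touch of the interfaces).
#' @param ... Further arguments passed to [simulate_wound()].
#' @return Fraction in `[0, 1]`.
#' @export
closure_proportion <- function(params, n_reps = 20, horizon = 0.55, seed = 1,
                               n = 96, event = c("healed", "contact"), ...) {
  event <- match.arg(event)
  closed <- vapply(seq_len(n_reps), function(k) {
    sim <- simulate_wound(params, n = n, horizon = horizon,
                          seed = seed + k - 1, closure = event, ...)
    isTRUE(sim$closed)
  }, logical(1))
  mean(closed)
}

#' Parameter sweep of wound observables
#'
#' Runs `n_reps` seeded replicates at each value of one model parameter and
#' records, per run, the raw normalized wound closure, the normalized edge
#' length, and whether the wound closed. These are the two observables whose
#' monotone trends against the six model parameters characterize the model
#' (retraction strength/duration and adhesion slow closure and lengthen the
#' edge; inter-retraction duration and motility do the opposite; coordinated
#' directionality is the only parameter that speeds closure *and* lengthens
#' the edge).
#'
#' @param base A [model_params()] object giving the base condition.
#' @param name Name of the parameter to sweep (a field of `model_params`).
#' @param values Numeric vector of parameter values.
#' @param n_reps Replicates per value.
#' @param seed Base seed.
#' @param n Grid resolution.
#' @param horizon End time per run.
#' @param ... Further arguments passed to [simulate_wound()].
#' @return A tibble of class `sweep_result` with one row per run: `parameter`,
#'   `value`, `rep`, `seed`, `closure`, `edge_length`, `closed`,
#'   `closure_time`.
#' @export
parameter_sweep <- function(base, name, values, n_reps = 20, seed = 1,
                            n = 64, horizon = 0.3, ...) {
  if (!name %in% names(base)) {
    rlang::abort(paste0("unknown model parameter: '", name, "'"))
  }
  rows <- purrr::map_dfr(seq_along(values), function(iv) {
    p <- base
    p[[name]] <- values[iv]
    # keep SDs proportional when sweeping a retraction mean
    if (name %in% c("mu_r", "mu_nr", "mu_s") && base[[name]] > 0) {
      sd_name <- sub("mu", "sigma", name)
      p[[sd_name]] <- base[[sd_name]] * values[iv] / base[[name]]
    }
    validate_model_params(p)
    purrr::map_dfr(seq_len(n_reps), function(k) {
      s <- seed + (iv - 1) * n_reps + k - 1
      sim <- simulate_wound(p, n = n, horizon = horizon, seed = s, ...)
      tibble::tibble(parameter = name, value = values[iv], rep = k, seed = s,
                     closure = normalized_wound_closure(sim),
                     edge_length = normalized_edge_length(sim),
                     closed = isTRUE(sim$closed),
                     closure_time = closure_time(sim))
    })
  })
  class(rows) <- c("sweep_result", class(rows))
  rows
}

#' Calibrate parameters to an experimental condition
#'
#' Adjusts a base parameter set to a perturbed condition: the retraction
#' means (`mu_r`, `mu_nr`, `mu_s`) and the motility `d` are multiplied by
#' their measured fold changes (condition over control), with their SDs
#' scaled proportionally; the unmeasured collective parameters are set to
#' their admissible extrema -- directionality `w_A` to 1 (increased) or 0
#' (decreased), adhesion `alpha` to 0.66 (increased) or 0 (decreased) --
#' or kept at their base values (0.4 and 0.2) when unchanged.
#'
#' @param base A [model_params()] object for the control condition.
#' @param fold_changes A data frame with columns `parameter` (among
#'   `"mu_r"`, `"mu_nr"`, `"mu_s"`, `"d"`) and `fold` (positive ratios).
#' @param directionality_mode One of `"same"`, `"increase"`, `"decrease"`.
#' @param adhesion_mode One of `"same"`, `"increase"`, `"decrease"`.
#' @return A [model_params()] object for the perturbed condition.
#' @examples
#' folds <- tibble::tibble(parameter = c("mu_r", "d"), fold = c(1.5, 1.2))
#' calibrate_condition(model_params(), folds, "increase", "same")
#' @export
calibrate_condition <- function(base, fold_changes,
                                directionality_mode = c("same", "increase",
                                                        "decrease"),
                                adhesion_mode = c("same", "increase",
                                                  "decrease")) {
  directionality_mode <- match.arg(directionality_mode)
  adhesion_mode <- match.arg(adhesion_mode)
  stopifnot(is.data.frame(fold_changes),
            all(c("parameter", "fold") %in% names(fold_changes)))
  allowed <- c("mu_r", "mu_nr", "mu_s", "d")
  bad <- setdiff(fold_changes$parameter, allowed)
  if (length(bad) > 0) {
    rlang::abort(paste0("fold changes allowed only for ",
                        paste(allowed, collapse = ", "), "; got: ",
                        paste(bad, collapse = ", ")))
  }
  if (any(fold_changes$fold <= 0)) rlang::abort("fold changes must be > 0")
  p <- unclass(base)
  for (k in seq_len(nrow(fold_changes))) {
    nm <- fold_changes$parameter[k]
    p[[nm]] <- p[[nm]] * fold_changes$fold[k]
    if (nm %in% c("mu_r", "mu_nr", "mu_s")) {
      sd_name <- sub("mu", "sigma", nm)
      p[[sd_name]] <- p[[sd_name]] * fold_changes$fold[k]
    }
  }
  p$w_A <- switch(directionality_mode, same = p$w_A, increase = 1,
                  decrease = 0)
  p$alpha <- switch(adhesion_mode, same = p$alpha, increase = ALPHA_UPPER,
                    decrease = 0)
  validate_model_params(p)
  structure(p, class = "model_params")
}
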