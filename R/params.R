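#' Model parameters for the wound-closure continuum model
#'
#' Bundles every coefficient of the dimensionless diffusion--advection model
#' of collective keratinocyte migration: cell motility `d`, the coordinated
#' directionality weight `w_A` (the anisotropic share of diffusion; the
#' isotropic share is `w_I = 1 - w_A`), the cell--cell adhesion coefficient
#' `alpha`, the normal-distributed retraction event process (mean/SD of event
#' duration, inter-event duration and strength), the edge-localization
#' density threshold `gamma`, the retraction band width `omega_r`, and the
#' smoothing widths used to regularize the Heaviside and indicator functions.
#'
#' Defaults reproduce the model's base condition: `alpha = 0.2`,
#' `w_A = 0.4`, `gamma = 0.4`, `omega_r = 0.2`, with the retraction process
#' and motility set to the package's calibrated base values (see the methods
#' vignette for how these were fixed).
#'
#' @param d Cell motility coefficient (dimensionless, > 0).
#' @param w_A Coordinated-directionality weight in `[0, 1]`.
#' @param alpha Cell--cell adhesion coefficient in `[0, 0.66]`; the upper
#'   bound keeps the scalar diffusion polynomial positive on `(0, 1]`.
#' @param mu_r,sigma_r Mean and SD of retraction event duration
#'   (dimensionless time).
#' @param mu_nr,sigma_nr Mean and SD of the idle duration between successive
#'   retraction events.
#' @param mu_s,sigma_s Mean and SD of retraction strength (advection speed);
#'   `mu_s = 0` disables retraction.
#' @param gamma Edge-localization density threshold in `(0, 1)`: retraction
#'   acts only where density is below `gamma`.
#' @param omega_r Width of the retraction band in `(0, 1)`.
#' @param width_h Smoothing width (in density units) of the tanh Heaviside.
#' @param width_x,width_t Smoothing widths of the generalized-bell space and
#'   time indicators.
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params()
#' p$alpha
#' @export
model_params <- function(d = 0.5, w_A = 0.4, alpha = 0.2,
                         mu_r = 0.01, sigma_r = 0.0025,
                         mu_nr = 0.003, sigma_nr = 0.00075,
                         mu_s = 20, sigma_s = 5,
                         gamma = 0.4, omega_r = 0.2,
                         width_h = 0.15, width_x = 0.02,
                         width_t = 0.00125) {
  p <- list(d = d, w_A = w_A, alpha = alpha,
            mu_r = mu_r, sigma_r = sigma_r,
            mu_nr = mu_nr, sigma_nr = sigma_nr,
            mu_s = mu_s, sigma_s = sigma_s,
            gamma = gamma, omega_r = omega_r,
            width_h = width_h, width_x = width_x, width_t = width_t)
  validate_model_params(p)
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  motility d = %g, directionality w_A = %g, adhesion alpha = %g\n",
              x$d, x$w_A, x$alpha))
  cat(sprintf("  retraction: duration N(%g, %g^2), idle N(%g, %g^2), strength N(%g, %g^2)\n",
              x$mu_r, x$sigma_r, x$mu_nr, x$sigma_nr, x$mu_s, x$sigma_s))
  cat(sprintf("  localization: gamma = %g, omega_r = %g; widths (H, x, t) = (%g, %g, %g)\n",
              x$gamma, x$omega_r, x$width_h, x$width_x, x$width_t))
  invisible(x)
}

# upper bound on alpha keeping the scalar diffusion polynomial positive
ALPHA_UPPER <- 0.66

validate_model_params <- function(p) {
  stopifnot(is.list(p))
  req <- c("d", "w_A", "alpha", "mu_r", "sigma_r", "mu_nr", "sigma_nr",
           "mu_s", "sigma_s", "gamma", "omega_r", "width_h", "width_x",
           "width_t")
  miss <- setdiff(req, names(p))
  if (length(miss) > 0) {
    rlang::abort(paste0("missing model parameter(s): ",
                        paste(miss, collapse = ", ")))
  }
  num1 <- function(v) {
    if (!is.numeric(p[[v]]) || length(p[[v]]) != 1 || !is.finite(p[[v]])) {
      rlang::abort(paste0("parameter '", v, "' must be a finite number"))
    }
  }
  for (v in req) num1(v)
  if (p$d <= 0) rlang::abort("motility 'd' must be > 0")
  if (p$w_A < 0 || p$w_A > 1) rlang::abort("'w_A' must lie in [0, 1]")
  if (p$alpha < 0 || p$alpha > ALPHA_UPPER) {
    rlang::abort(paste0(
      "'alpha' must lie in [0, ", ALPHA_UPPER, "]: larger adhesion makes the ",
      "scalar diffusion polynomial negative at high density (positivity bound)"))
  }
  if (p$mu_r <= 0 || p$mu_nr <= 0) {
    rlang::abort("mean durations 'mu_r' and 'mu_nr' must be > 0")
  }
  if (p$mu_s < 0) rlang::abort("'mu_s' must be >= 0")
  if (p$sigma_r < 0 || p$sigma_nr < 0 || p$sigma_s < 0) {
    rlang::abort("standard deviations must be >= 0")
  }
  if (p$gamma <= 0 || p$gamma >= 1) rlang::abort("'gamma' must lie in (0, 1)")
  if (p$omega_r <= 0 || p$omega_r >= 1) {
    rlang::abort("'omega_r' must lie in (0, 1)")
  }
  if (p$width_h <= 0 || p$width_x <= 0 || p$width_t <= 0) {
    rlang::abort("smoothing widths must be > 0")
  }
  invisible(p)
}

#' Continuum motility and directionality weights from directed magnitudes
#'
#' Converts the discrete-model magnitudes of movement in the horizontal
#' (`d_h`, along the wound) and vertical (`d_v`, towards the wound)
#' directions into the continuum coefficients: motility `d = d_v`, isotropic
#' weight `w_I = d_h / d_v` and coordinated-directionality weight
#' `w_A = (d_v - d_h) / d_v`, so that `w_I + w_A = 1`.
#'
#' @param d_h Horizontal magnitude of movement, `0 <= d_h <= d_v`.
#' @param d_v Vertical magnitude of movement, `> 0`.
#' @return A tibble with columns `d`, `w_I`, `w_A`.
#' @examples
#' weights_from_motilities(1, 2)
#' @export
weights_from_motilities <- function(d_h, d_v) {
  if (!is.numeric(d_h) || !is.numeric(d_v) || length(d_h) != 1 ||
      length(d_v) != 1) {
    rlang::abort("'d_h' and 'd_v' must be single numbers")
  }
  if (d_v <= 0) rlang::abort("'d_v' must be > 0")
  if (d_h < 0) rlang::abort("'d_h' must be >= 0")
  if (d_h > d_v) {
    rlang::abort(paste0(
      "directionality assumption violated: requires d_h <= d_v (movement ",
      "towards the wound at least as large as along it)"))
  }
  tibble::tibble(d = d_v, w_I = d_h / d_v, w_A = (d_v - d_h) / d_v)
}

#' Nondimensionalization constants
#'
#' The model is dimensionless; physical units enter only through the
#' characteristic length `l` (distance from the wound edge to the
#' maximal-density region, in micrometres) and the characteristic wound-edge
#' speed `v` (micrometres per minute), giving the rate
#' `lambda = v / l` (per minute). Helper columns convert between physical
#' and dimensionless quantities.
#'
#' @param l Characteristic length in micrometres (> 0).
#' @param v Characteristic edge speed in micrometres per minute (> 0).
#' @return An object of class `nondimensionalization` with fields `l`, `v`,
#'   `lambda`.
#' @examples
#' nd <- nondimensionalization(l = 250, v = 0.5)
#' nd$lambda
#' to_dimless_length(nd, 125)
#' @export
nondimensionalization <- function(l, v) {
  stopifnot(is.numeric(l), is.numeric(v), l > 0, v > 0)
  structure(list(l = l, v = v, lambda = v / l),
            class = "nondimensionalization")
}

#' @rdname nondimensionalization
#' @param nd A `nondimensionalization` object.
#' @param x_um Length in micrometres.
#' @export
to_dimless_length <- function(nd, x_um) x_um / nd$l

#' @rdname nondimensionalization
#' @param t_min Time in minutes.
#' @export
to_dimless_time <- function(nd, t_min) t_min * nd$lambda

#' @rdname nondimensionalization
#' @param x Dimensionless length.
#' @export
to_um <- function(nd, x) x * nd$l

#' @rdname nondimensionalization
#' @param t Dimensionless time.
#' @export
to_minutes <- function(nd, t) t / nd$lambda
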