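#' Scalar diffusion polynomial
#'
#' The density-dependent scalar part of the diffusivity,
#' \deqn{\hat D_\alpha(\rho) = 2\rho - (1 + 11\alpha)\rho^2 +
#'   (8\alpha + 16\alpha^2)\rho^3 - (13\alpha^2 + 7\alpha^3)\rho^4 +
#'   6\alpha^3\rho^5,}
#' obtained by upscaling the discrete transitional probabilities: the
#' leading `2rho` comes from the density-dependent hopping rate, the
#' higher-order terms from volume filling and the three-neighbour cell--cell
#' adhesion factors. At full density it simplifies to
#' \eqn{\hat D_\alpha(1) = (1-\alpha)^3}. It is positive on `(0, 1]` only
#' for adhesion below about 0.66 (see [alpha_max()]).
#'
#' @param rho Cell density values in `[0, 1]` (vectorized).
#' @param alpha Adhesion coefficient in `[0, 1]`.
#' @return Numeric vector of the same length as `rho`.
#' @examples
#' scalar_diffusion_coeff(1, 0.2) # (1 - 0.2)^3 = 0.512
#' @export
scalar_diffusion_coeff <- function(rho, alpha) {
  if (!is.numeric(rho) || any(!is.finite(rho)) || any(rho < 0) ||
      any(rho > 1)) {
    rlang::abort("'rho' must be numeric in [0, 1]")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1) {
    rlang::abort("'alpha' must be a single number in [0, 1]")
  }
  2 * rho - (1 + 11 * alpha) * rho^2 + (8 * alpha + 16 * alpha^2) * rho^3 -
    (13 * alpha^2 + 7 * alpha^3) * rho^4 + 6 * alpha^3 * rho^5
}

#' Largest admissible adhesion coefficient
#'
#' Scans `alpha` on a uniform grid and reports the largest value for which
#' the scalar diffusion polynomial stays strictly positive for every density
#' on a fine grid over `(0, 1]`. Densities at which the polynomial first
#' turns negative sit near `rho = 1`, where the polynomial equals
#' `(1 - alpha)^3 > 0`; the loss of positivity happens in the interior,
#' which is why a grid search (rather than the endpoint value) is needed.
#'
#' @param n_rho Number of density grid points over `(0, 1]`.
#' @param alpha_step Spacing of the `alpha` grid on `[0, 1]`.
#' @return The largest admissible `alpha` on the grid (numeric scalar).
#' @examples
#' round(alpha_max(n_rho = 1000, alpha_step = 0.01), 2)
#' @export
alpha_max <- function(n_rho = 1e4, alpha_step = 1e-3) {
  rho <- seq_len(n_rho) / n_rho
  alphas <- seq(0, 1, by = alpha_step)
  ok <- vapply(alphas, function(a) {
    min(scalar_diffusion_coeff(rho, a)) > 0
  }, logical(1))
  if (!any(ok)) rlang::abort("no admissible alpha found on the grid")
  # positivity is monotone in alpha; take the last TRUE
  max(alphas[ok])
}

#' Diffusivity tensor
#'
#' The 2x2 diffusivity `D = d * (w_I I + w_A A) * Dhat_alpha(rho)` with
#' anisotropy matrix `A = diag(0, 1)` (extra mobility towards the wound,
#' taken along y), i.e. `D = d * diag(1 - w_A, 1) * Dhat_alpha(rho)`.
#' Positive definite whenever `Dhat_alpha(rho) > 0` and `w_A < 1`.
#'
#' @param rho Single density value in `[0, 1]`.
#' @param params A [model_params()] object (or any list with `d`, `w_A`,
#'   `alpha`).
#' @return A 2x2 numeric matrix.
#' @examples
#' diffusivity_tensor(1, model_params(d = 1, w_A = 0.4, alpha = 0.2))
#' @export
diffusivity_tensor <- function(rho, params) {
  stopifnot(length(rho) == 1)
  dh <- scalar_diffusion_coeff(rho, params$alpha)
  params$d * diag(c(1 - params$w_A, 1)) * dh
}

#' Smoothed localization functions
#'
#' Differentiable stand-ins for the discontinuous localizers of the
#' retraction term: a hyperbolic-tangent Heaviside and generalized
#' bell-shaped indicators for the event's time window and spatial band.
#' All three take the value 0.5 exactly at the threshold/edges and converge
#' to the sharp step/box as `width -> 0`.
#'
#' @param u Argument of the Heaviside (e.g. `gamma - rho`).
#' @param width Smoothing width (> 0).
#' @return Values in `[0, 1]`.
#' @examples
#' smooth_heaviside(0, 0.05) # 0.5 at the threshold
#' @export
smooth_heaviside <- function(u, width) {
  stopifnot(width > 0)
  0.5 * (1 + tanh(u / width))
}

# generalized bell centred at `centre` with half-width `a`; equals 0.5 at
# |x - centre| = a and sharpens to the box indicator as width -> 0
gbell <- function(x, centre, a, width) {
  b <- max(1, a / width)
  u <- abs((x - centre) / a)
  out <- 1 / (1 + u^(2 * b))
  out[u > 6] <- 0
  out
}

#' @rdname smooth_heaviside
#' @param t Time.
#' @param tau Event start time.
#' @param T_r Event duration (> 0).
#' @export
smooth_indicator_time <- function(t, tau, T_r, width) {
  stopifnot(width > 0, T_r > 0)
  gbell(t, tau + T_r / 2, T_r / 2, width)
}

#' @rdname smooth_heaviside
#' @param x Position in `[0, 1]`.
#' @param centre Centre of the retraction band.
#' @param omega_r Band width (> 0).
#' @export
smooth_indicator_space <- function(x, centre, omega_r, width) {
  stopifnot(width > 0, omega_r > 0)
  gbell(x, centre, omega_r / 2, width)
}
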