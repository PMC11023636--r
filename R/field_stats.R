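wrap_angle <- function(a) {
  out <- (a + pi) %% (2 * pi) - pi
  # keep pi rather than -pi so the range is (-pi, pi]
  out[out == -pi] <- pi
  out
}

# validate a PIV vector-field table and drop masked/incomplete rows
field_table <- function(field) {
  stopifnot(is.data.frame(field),
            all(c("x_um", "y_um", "u", "v") %in% names(field)))
  if ("mask" %in% names(field)) field <- field[as.logical(field$mask), ]
  field[complete.cases(field[, c("x_um", "y_um", "u", "v")]), ]
}

#' Wound-oriented vector angles
#'
#' Angle of each velocity vector measured relative to the wound normal (the
#' unit direction pointing into the cell-free region), so 0 means "towards
#' the wound". Rotating the field and the normal together leaves the angles
#' unchanged.
#'
#' @param field A data frame with columns `x_um`, `y_um`, `u`, `v` and an
#'   optional logical `mask` (masked-out rows are dropped).
#' @param normal Unit 2-vector of the wound normal (defaults to `+y`).
#' @return Numeric vector of angles in `(-pi, pi]`.
#' @export
orient_angles <- function(field, normal = c(0, 1)) {
  f <- field_table(field)
  wrap_angle(atan2(f$v, f$u) - atan2(normal[2], normal[1]))
}

#' Von Mises probability density
#'
#' \deqn{f(x \mid \mu, \kappa) = \frac{e^{\kappa\cos(x - \mu)}}{2\pi
#' I_0(\kappa)},} the circular analogue of the normal distribution;
#' `kappa = 0` is the uniform density `1/(2 pi)`. Evaluated with the
#' exponentially scaled Bessel function so large `kappa` does not overflow.
#'
#' @param x Angles (radians).
#' @param mu Mean direction.
#' @param kappa Concentration (>= 0).
#' @return Density values.
#' @export
von_mises_pdf <- function(x, mu, kappa) {
  stopifnot(kappa >= 0)
  exp(kappa * (cos(x - mu) - 1)) / (2 * pi * besselI(kappa, 0,
                                                    expon.scaled = TRUE))
}

#' Fit a von Mises distribution to angles by histogram MSE
#'
#' Bins the angles into a density-normalized histogram over `(-pi, pi]` and
#' minimizes the mean squared error between the bin densities and the von
#' Mises density, first on a coarse `(mu, kappa)` grid and then with
#' box-constrained local refinement. `kappa` is clipped at 0.
#'
#' @param angles Numeric vector of angles (radians); at least 100 for a
#'   stable fit (a warning is raised below that).
#' @param bins Number of histogram bins.
#' @return An object of class `von_mises_fit` with fields `mu`, `kappa`,
#'   `mse`, `n`, plus the binned histogram.
#' @export
fit_von_mises <- function(angles, bins = 36) {
  angles <- angles[is.finite(angles)]
  if (length(angles) == 0) rlang::abort("no angles to fit")
  if (length(angles) < 100) {
    rlang::warn("fewer than 100 angles; von Mises fit may be unstable")
  }
  a <- wrap_angle(angles)
  breaks <- seq(-pi, pi, length.out = bins + 1)
  counts <- table(cut(a, breaks, include.lowest = TRUE))
  dens <- as.numeric(counts) / length(a) / diff(breaks)
  mids <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  obj <- function(par) {
    mean((dens - von_mises_pdf(mids, par[1], max(par[2], 0)))^2)
  }
  # coarse grid: circular mean as mu seed plus offsets, log-spaced kappa
  mu0 <- atan2(mean(sin(a)), mean(cos(a)))
  mu_grid <- wrap_angle(mu0 + seq(-pi / 2, pi / 2, length.out = 5))
  kappa_grid <- c(0, 0.1, 0.25, 0.5, 1, 2, 4, 8, 16)
  grid <- expand.grid(mu = mu_grid, kappa = kappa_grid)
  vals <- apply(grid, 1, obj)
  start <- as.numeric(grid[which.min(vals), ])
  fit <- optim(start, obj, method = "L-BFGS-B",
               lower = c(start[1] - pi, 0), upper = c(start[1] + pi, 500))
  structure(list(mu = wrap_angle(fit$par[1]), kappa = max(fit$par[2], 0),
                 mse = fit$value, n = length(a),
                 histogram = tibble::tibble(mid = mids, density = dens)),
            class = "von_mises_fit")
}

#' @export
print.von_mises_fit <- function(x, ...) {
  cat(sprintf("<von_mises_fit> mu = %.4f rad, kappa = %.4f (n = %d, MSE = %.3g)\n",
              x$mu, x$kappa, x$n, x$mse))
  invisible(x)
}

#' Angular deviation of vector directions
#'
#' Variability of directions within a flow field, defined as `1 - R` where
#' `R` is the mean resultant length
#' \eqn{R = \frac{1}{N}\sqrt{(\sum\cos\theta)^2 + (\sum\sin\theta)^2}}:
#' 0 for perfectly aligned vectors, approaching 1 for uniformly scattered
#' directions. `type = "resultant"` returns `R` itself.
#'
#' @param x Either a numeric vector of angles or a vector-field data frame
#'   (see [orient_angles()]).
#' @param type `"one_minus_R"` (default) or `"resultant"`.
#' @param normal Wound normal, used only when `x` is a data frame.
#' @return Scalar in `[0, 1]`.
#' @export
angular_deviation <- function(x, type = c("one_minus_R", "resultant"),
                              normal = c(0, 1)) {
  type <- match.arg(type)
  theta <- if (is.data.frame(x)) orient_angles(x, normal) else x
  if (length(theta) == 0) rlang::abort("no angles")
  R <- sqrt(sum(cos(theta))^2 + sum(sin(theta))^2) / length(theta)
  if (type == "resultant") R else 1 - R
}

#' Spatial autocorrelation of the wound-normal velocity
#'
#' For the scalar field `v` (the component of each velocity along the wound
#' normal, or the full vector dot product), computes
#' \deqn{C(\Delta r) = \frac{\sum_i v(r_i) v(r_i + \Delta r)}
#'   {\sqrt{\sum_i v^2(r_i)\, \sum_i v^2(r_i + \Delta r)}}}
#' for every grid offset, then bins offsets isotropically by their Euclidean
#' separation. `C(0) = 1` by construction; masked vectors are excluded from
#' every pair.
#'
#' @param field Vector-field data frame on a regular grid (`x_um`, `y_um`,
#'   `u`, `v`, optional `mask`).
#' @param bin_width Bin width in micrometres (default: the grid spacing).
#' @param component `"normal"` correlates the wound-normal component;
#'   `"full"` uses the full vector dot products.
#' @param normal Wound normal direction.
#' @param max_r Largest separation (default: half the domain extent).
#' @return A tibble of class `correlation_curve` with columns `r`, `C`,
#'   `n_pairs`.
#' @export
spatial_autocorrelation <- function(field, bin_width = NULL,
                                    component = c("normal", "full"),
                                    normal = c(0, 1), max_r = NULL) {
  component <- match.arg(component)
  stopifnot(is.data.frame(field),
            all(c("x_um", "y_um", "u", "v") %in% names(field)))
  xs <- sort(unique(field$x_um))
  ys <- sort(unique(field$y_um))
  if (length(xs) < 2 || length(ys) < 2) {
    rlang::abort("need at least 2 grid rows and columns")
  }
  sp <- c(diff(xs), diff(ys))
  spacing <- min(sp)
  if (max(abs(sp - mean(sp))) > 1e-6 * spacing) {
    rlang::abort("vector field must sit on a regular grid")
  }
  if (is.null(bin_width)) bin_width <- spacing
  if (is.null(max_r)) {
    max_r <- 0.5 * max(diff(range(xs)), diff(range(ys)))
  }
  nx <- length(xs); ny <- length(ys)
  ix <- match(field$x_um, xs); iy <- match(field$y_um, ys)
  nrm <- normal / sqrt(sum(normal^2))
  keep <- if ("mask" %in% names(field)) as.logical(field$mask) else
    rep(TRUE, nrow(field))
  pts <- cbind(ix, iy)[keep, , drop = FALSE]
  V <- matrix(NA_real_, nx, ny)
  V[pts] <- (field$u * nrm[1] + field$v * nrm[2])[keep]
  U1 <- W1 <- NULL
  if (component == "full") {
    U1 <- matrix(NA_real_, nx, ny); W1 <- matrix(NA_real_, nx, ny)
    U1[pts] <- field$u[keep]
    W1[pts] <- field$v[keep]
  }
  K <- floor(max_r / spacing)
  offs <- expand.grid(dx = -K:K, dy = 0:K)
  offs <- offs[offs$dy > 0 | (offs$dy == 0 & offs$dx >= 0), ]
  offs$r <- spacing * sqrt(offs$dx^2 + offs$dy^2)
  offs <- offs[offs$r <= max_r, ]
  corr_at <- function(dx, dy) {
    xa <- seq_len(nx - abs(dx)); ya <- seq_len(ny - dy)
    if (dx < 0) xa <- xa + abs(dx)
    xb <- xa + dx; yb <- ya + dy
    if (component == "full") {
      A1 <- U1[xa, ya, drop = FALSE]; A2 <- W1[xa, ya, drop = FALSE]
      B1 <- U1[xb, yb, drop = FALSE]; B2 <- W1[xb, yb, drop = FALSE]
      ok <- is.finite(A1) & is.finite(B1)
      num <- sum((A1 * B1 + A2 * B2)[ok])
      den <- sqrt(sum((A1^2 + A2^2)[ok]) * sum((B1^2 + B2^2)[ok]))
    } else {
      A <- V[xa, ya, drop = FALSE]; B <- V[xb, yb, drop = FALSE]
      ok <- is.finite(A) & is.finite(B)
      num <- sum((A * B)[ok])
      den <- sqrt(sum(A[ok]^2) * sum(B[ok]^2))
    }
    c(if (den > 0) num / den else NA_real_, sum(ok))
  }
  vals <- t(mapply(corr_at, offs$dx, offs$dy))
  offs$C <- vals[, 1]
  offs$n <- vals[, 2]
  offs <- offs[is.finite(offs$C) & offs$n > 0, ]
  offs$bin <- round(offs$r / bin_width)
  curve <- offs |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(r = sum(.data$r * .data$n) / sum(.data$n),
                     C = sum(.data$C * .data$n) / sum(.data$n),
                     n_pairs = sum(.data$n), .groups = "drop") |>
    dplyr::arrange(.data$r) |>
    dplyr::select(-"bin")
  class(curve) <- c("correlation_curve", class(curve))
  curve
}

#' Correlation length constant
#'
#' Fits `log C = a + b r + c r^2` over the separations where `C > 0.05`
#' (an exponential with quadratic exponent) and returns the smallest positive
#' distance at which the fit crosses `C = 0.37`, the length constant of
#' coordinated motion. If the quadratic never crosses, a pure exponential
#' (`c = 0`) refit is used; if the crossing lies beyond twice the observed
#' separation range (or does not exist), the length constant is reported as
#' `NA`.
#'
#' @param curve A `correlation_curve` (or data frame with `r`, `C`).
#' @param threshold Crossing level (default 0.37).
#' @return Length constant in the units of `r`, or `NA_real_`.
#' @export
length_constant <- function(curve, threshold = 0.37) {
  d <- curve[is.finite(curve$C) & curve$C > 0.05, ]
  if (nrow(d) < 3) return(NA_real_)
  r_max <- 2 * max(curve$r)
  root_of <- function(a, b, cc) {
    if (abs(cc) > 1e-14) {
      disc <- b^2 - 4 * cc * (a - log(threshold))
      if (disc < 0) return(NA_real_)
      roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * cc)
      roots <- roots[roots > 0]
      if (length(roots) == 0) return(NA_real_)
      min(roots)
    } else {
      if (b >= 0) return(NA_real_)
      (log(threshold) - a) / b
    }
  }
  fit2 <- lm(log(C) ~ r + I(r^2), data = d)
  x <- root_of(coef(fit2)[1], coef(fit2)[2], coef(fit2)[3])
  if (!is.finite(x) || x > r_max) {
    fit1 <- lm(log(C) ~ r, data = d)
    x <- root_of(coef(fit1)[1], coef(fit1)[2], 0)
  }
  if (!is.finite(x) || x > r_max) return(NA_real_)
  unname(x)
}

#' Local spatial coordination
#'
#' The spatial autocorrelation linearly interpolated at a reference
#' separation (150 micrometres by default, a few cell lengths), measuring
#' how coordinated a cell's motion is with its neighbours.
#'
#' @param curve A `correlation_curve`.
#' @param r0 Reference separation (micrometres).
#' @return Interpolated correlation value.
#' @export
local_autocorrelation <- function(curve, r0 = 150) {
  if (r0 < min(curve$r) || r0 > max(curve$r)) {
    rlang::abort("r0 lies outside the observed separation range")
  }
  approx(curve$r, curve$C, xout = r0)$y
}
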