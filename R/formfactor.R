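# Broken-rod form-factor model in Kratky space.
#
# The local structure of an ionotropic polysaccharide gel is modelled as a
# mixture of locally cylindrical scatterers ("broken rods"): thin single
# chains plus thicker multi-chain junction zones.  In Kratky representation
# (q^2 I(q) vs q) each rod component of cross-sectional radius rc contributes
#
#     q * k * [J1(q*rc) / (q*rc)]^2
#
# and a flat Kratky-space constant absorbs residual incoherent background.

#' Construct and validate a broken-rod parameter set
#'
#' Parameters of the one- or two-component broken-rod Kratky model
#' \deqn{q^2 I(q) = q k_1 [J_1(q R_{c1})/(q R_{c1})]^2 +
#'                  q k_2 [J_1(q R_{c2})/(q R_{c2})]^2 + const.}
#' The component ordering `rc1 < rc2` is part of the definition (thin chains
#' first, junction zones second); it prevents label switching during fitting.
#'
#' @param rc1 Cross-sectional radius of the thin component, nm. Must lie in
#'   `(0, 50]`; radii above 50 nm are outside the physically meaningful range
#'   for polysaccharide chains and junction zones and are rejected.
#' @param rc2 Cross-sectional radius of the thick component, nm; required to
#'   exceed `rc1` when `n_components = 2`, ignored (may be `NA`) otherwise.
#' @param k1,k2 Non-negative component amplitudes (arbitrary intensity units
#'   times nm); `k2` must be 0 when `n_components = 1`.
#' @param const Non-negative additive constant in Kratky space.
#' @param n_components 1 or 2.
#' @return An object of class `"broken_rod_params"`.
#' @examples
#' p <- broken_rod_params(rc1 = 0.9, rc2 = 2.9, k1 = 0.2, k2 = 0.8)
#' p
#' @export
broken_rod_params <- function(rc1, rc2 = NA_real_, k1 = 1, k2 = 0,
                              const = 0, n_components = if (k2 > 0) 2L else 1L) {
  n_components <- as.integer(n_components)
  if (!n_components %in% c(1L, 2L))
    stop("n_components must be 1 or 2", call. = FALSE)
  if (n_components == 1L) {
    if (!isTRUE(k2 == 0)) stop("k2 must be 0 for a one-component model", call. = FALSE)
    rc2 <- NA_real_
  }
  p <- structure(list(rc1 = as.numeric(rc1), rc2 = as.numeric(rc2),
                      k1 = as.numeric(k1), k2 = as.numeric(k2),
                      const = as.numeric(const), n_components = n_components),
                 class = "broken_rod_params")
  validate_broken_rod_params(p)
  p
}

#' @rdname broken_rod_params
#' @param p A `broken_rod_params` object to validate.
#' @export
validate_broken_rod_params <- function(p) {
  stopifnot(inherits(p, "broken_rod_params"))
  num_ok <- function(x) length(x) == 1L && is.finite(x)
  if (!num_ok(p$rc1) || p$rc1 <= 0 || p$rc1 > 50)
    stop("rc1 must be finite, > 0 and <= 50 nm", call. = FALSE)
  if (!num_ok(p$k1) || p$k1 < 0) stop("k1 must be finite and >= 0", call. = FALSE)
  if (!num_ok(p$k2) || p$k2 < 0) stop("k2 must be finite and >= 0", call. = FALSE)
  if (!num_ok(p$const) || p$const < 0) stop("const must be finite and >= 0", call. = FALSE)
  if (p$n_components == 2L) {
    if (!num_ok(p$rc2) || p$rc2 <= 0 || p$rc2 > 50)
      stop("rc2 must be finite, > 0 and <= 50 nm", call. = FALSE)
    if (p$rc2 <= p$rc1)
      stop("component ordering requires rc2 > rc1", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.broken_rod_params <- function(x, ...) {
  if (x$n_components == 1L) {
    cat(sprintf("broken-rod model, 1 component\n  rc1 = %.4g nm, k1 = %.4g, const = %.4g\n",
                x$rc1, x$k1, x$const))
  } else {
    cat(sprintf(paste0("broken-rod model, 2 components\n",
                       "  rc1 = %.4g nm (k1 = %.4g), rc2 = %.4g nm (k2 = %.4g), const = %.4g\n"),
                x$rc1, x$k1, x$rc2, x$k2, x$const))
  }
  invisible(x)
}

#' First-order Bessel function of the first kind
#'
#' Thin wrapper around [base::besselJ()] extending it to negative arguments
#' through the odd symmetry J1(-x) = -J1(x).
#'
#' @param x Numeric vector, finite.
#' @return J1(x), same length as `x`.
#' @examples
#' bessel_j1(c(0, 1e-6, 3.8317))
#' @export
bessel_j1 <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("x must be finite numeric", call. = FALSE)
  sign(x) * besselJ(abs(x), 1)
}

# J1(x)/x, analytically continued through x = 0 (limit 1/2).
# Near zero the power series 1/2 - x^2/16 + x^4/384 avoids 0/0; truncation
# error of the cubic term at |x| < 1e-4 is ~ (1e-4)^6/18432 << eps.
j1_over_x <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  xs <- x[small]
  out[small] <- 0.5 - xs^2 / 16 + xs^4 / 384
  xl <- x[!small]
  out[!small] <- besselJ(abs(xl), 1) / abs(xl)
  out
}

#' Single-rod Kratky term
#'
#' The unit-amplitude contribution of one rod of cross-sectional radius `rc`
#' to the Kratky curve: `q * (J1(q*rc)/(q*rc))^2`.  The q = 0 value is the
#' analytic limit 0 (the curve leaves the origin with slope 1/4).  The term
#' obeys the scaling identity `term(q, rc) = phi(q*rc)/rc` for a fixed shape
#' function, so its peak sits at `q = xstar/rc` with `xstar` the universal
#' Kratky-peak constant (see [kratky_peak_constant()]).
#'
#' @param q Scattering-vector magnitudes, nm^-1, each >= 0.
#' @param rc Cross-sectional radius, nm, > 0.
#' @return Kratky ordinates, arbitrary units.
#' @examples
#' q <- seq(0.103, 3.26, length.out = 5)
#' rod_kratky_term(q, rc = 2.7)
#' @export
rod_kratky_term <- function(q, rc) {
  if (!is.numeric(rc) || length(rc) != 1L || !is.finite(rc) || rc <= 0)
    stop("rc must be a single finite value > 0", call. = FALSE)
  if (!is.numeric(q) || any(!is.finite(q)) || any(q < 0))
    stop("q must be finite and >= 0", call. = FALSE)
  q * j1_over_x(q * rc)^2
}

#' Evaluate the broken-rod Kratky model
#'
#' Sum of the one or two rod terms, weighted by the amplitudes, plus the
#' Kratky-space constant.  At q = 0 the value is `const`; the initial slope
#' is `(k1 + k2)/4`.
#'
#' @param q Strictly increasing grid of scattering-vector magnitudes, nm^-1,
#'   all >= 0.
#' @param params A [broken_rod_params()] object.
#' @return Kratky ordinates q^2 I(q), same length as `q`.
#' @examples
#' p <- broken_rod_params(rc1 = 0.9, rc2 = 2.9, k1 = 0.2, k2 = 0.8, const = 0.002)
#' kratky_model(seq(0.103, 3.26, length.out = 5), p)
#' @export
kratky_model <- function(q, params) {
  validate_broken_rod_params(params)
  if (is.unsorted(q, strictly = TRUE))
    stop("q grid must be strictly increasing", call. = FALSE)
  y <- params$k1 * rod_kratky_term(q, params$rc1) + params$const
  if (params$n_components == 2L)
    y <- y + params$k2 * rod_kratky_term(q, params$rc2)
  y
}

#' Scattered intensity implied by the broken-rod model
#'
#' Inverts the Kratky transform: `I(q) = kratky_model(q)/q^2`.  Requires a
#' strictly positive grid (the 1/q^2 envelope diverges at q = 0).
#'
#' @inheritParams kratky_model
#' @return Intensities, arbitrary units.
#' @export
intensity_model <- function(q, params) {
  if (any(q <= 0)) stop("intensity_model requires q > 0", call. = FALSE)
  kratky_model(q, params) / q^2
}

#' Universal Kratky-peak constant for a single rod
#'
#' For one rod term the product `q_peak * rc` is a dimensionless constant
#' `xstar`, the positive root of `2 x J0(x) = 3 J1(x)` (stationarity of
#' `x (J1(x)/x)^2`), approximately 1.3566.
#'
#' @return The constant `xstar`.
#' @export
kratky_peak_constant <- function() {
  stats::uniroot(function(x) 2 * x * besselJ(x, 0) - 3 * besselJ(x, 1),
                 c(1, 2), tol = 1e-12)$root
}

#' Locate the Kratky peak of a broken-rod model within a q window
#'
#' Finds the global maximum of `kratky_model - const` on `[q_min, q_max]` by
#' a dense grid scan (default 4001 points) followed by golden-section
#' refinement to an absolute tolerance of 1e-4 nm^-1.  Returns `NA` when the
#' curve is non-decreasing across the window, i.e. the peak lies beyond
#' `q_max` (thin rods push the peak to high q since `q_peak = xstar/rc`).
#'
#' @param params A [broken_rod_params()] object.
#' @param q_min,q_max Window bounds, nm^-1, `0 < q_min < q_max`.
#' @param n_scan Number of grid-scan points, >= 2000.
#' @return Peak position in nm^-1, or `NA_real_` if no interior maximum.
#' @examples
#' kratky_peak(broken_rod_params(rc1 = 2.7), 0.103, 3.26)
#' @export
kratky_peak <- function(params, q_min, q_max, n_scan = 4001L) {
  validate_broken_rod_params(params)
  if (!is.finite(q_min) || !is.finite(q_max) || q_min <= 0 || q_min >= q_max)
    stop("require 0 < q_min < q_max", call. = FALSE)
  n_scan <- max(as.integer(n_scan), 2000L)
  grid <- seq(q_min, q_max, length.out = n_scan)
  f <- function(q) kratky_model(q, params) - params$const
  y <- f(grid)
  i <- which.max(y)
  # non-decreasing across the window: maximum pinned to the upper edge
  if (i == n_scan && all(diff(y) >= -.Machine$double.eps * max(abs(y))))
    return(NA_real_)
  if (i == 1L) return(NA_real_)   # decreasing from the edge: peak below q_min
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, n_scan)]
  opt <- stats::optimize(function(q) f(q), lower = lo, upper = hi,
                         maximum = TRUE, tol = 1e-6)
  if (abs(opt$maximum - q_min) < 1e-3 || abs(opt$maximum - q_max) < 1e-3)
    return(NA_real_)
  opt$maximum
}
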