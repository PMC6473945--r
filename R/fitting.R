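# Per-frame broken-rod fits and time-course assembly.
#
# Each Kratky profile is fitted by bounded weighted least squares
# (Levenberg-Marquardt, minpack.lm).  One- and two-component models compete
# by BIC with a parsimony tie-break; a frame series is fitted sequentially
# with warm starts, since a 5 s acquisition cadence makes consecutive frames
# nearly continuous in parameter space.

#' Fitting configuration
#'
#' @param q_min,q_max Fit window in nm^-1; the default is the full instrument
#'   range 0.103-3.26 nm^-1. Setting `q_max = 2` excludes the high-q region
#'   where a broader distribution of lateral association modes makes the
#'   two-component model deviate at long reaction times.
#' @param use_sigma Weight residuals by 1/sigma^2 when the profile carries
#'   uncertainties (default `TRUE`); otherwise unweighted.
#' @param ftol Relative convergence tolerance on the cost.
#' @param maxiter Maximum Levenberg-Marquardt iterations.
#' @param delta_bic Parsimony margin: the two-component model must beat the
#'   one-component model by more than this much BIC to be selected.
#' @param wf_mode How amplitudes map to weight fractions: `"amplitude"`
#'   (w_i = k_i / (k1 + k2), default) or `"mass"` (w_i proportional to
#'   k_i * rc_i^2, a mass-per-length reweighting).
#' @param rc_bounds Lower/upper bounds on the radii, nm.
#' @return A list of class `"rod_fit_config"`.
#' @export
fit_config <- function(q_min = 0.103, q_max = 3.26, use_sigma = TRUE,
                       ftol = 1e-10, maxiter = 400L, delta_bic = 2,
                       wf_mode = c("amplitude", "mass"),
                       rc_bounds = c(0.05, 50)) {
  stopifnot(q_min < q_max, ftol > 0, maxiter >= 1, delta_bic >= 0,
            length(rc_bounds) == 2L, rc_bounds[1] > 0,
            rc_bounds[1] < rc_bounds[2])
  structure(list(q_min = q_min, q_max = q_max, use_sigma = use_sigma,
                 ftol = ftol, maxiter = as.integer(maxiter),
                 delta_bic = delta_bic, wf_mode = match.arg(wf_mode),
                 rc_bounds = rc_bounds),
            class = "rod_fit_config")
}

#' Weight fractions from component amplitudes
#'
#' The amplitude k_i of each rod term is proportional to the weight fraction
#' of that component; normalising by the amplitude sum gives
#' `w_i = k_i / (k1 + k2)`.  The `"mass"` mode instead reweights each
#' amplitude by the cross-sectional area (mass per unit length of a rod
#' scales as rc^2) before normalising.
#'
#' @param k1,k2 Non-negative amplitudes, not both zero.
#' @param rc1,rc2 Radii, required only for `mode = "mass"`.
#' @param mode `"amplitude"` (default) or `"mass"`.
#' @return Numeric `c(w1, w2)` summing to 1.
#' @examples
#' weight_fractions(2, 8)
#' @export
weight_fractions <- function(k1, k2, rc1 = NULL, rc2 = NULL,
                             mode = c("amplitude", "mass")) {
  mode <- match.arg(mode)
  if (!is.finite(k1) || !is.finite(k2) || k1 < 0 || k2 < 0)
    stop("amplitudes must be finite and >= 0", call. = FALSE)
  if (k1 + k2 <= 0)
    stop("weight fractions undefined: both amplitudes are zero", call. = FALSE)
  if (mode == "mass") {
    if (is.null(rc1) || is.null(rc2))
      stop("mass mode requires rc1 and rc2", call. = FALSE)
    m <- c(k1 * rc1^2, k2 * rc2^2)
  } else {
    m <- c(k1, k2)
  }
  m / sum(m)
}

#' Initial parameter guess from the shape of a Kratky profile
#'
#' If the profile has an interior maximum at `q_pk`, the thick component is
#' placed at `rc2 = xstar / q_pk` (the universal single-rod peak relation)
#' with `rc1 = rc2 / 3`; the total amplitude comes from the low-q slope
#' (slope of the model at the origin is `(k1 + k2) / 4`) split evenly, and
#' the constant from the high-q tail median.  Without an interior maximum a
#' one-component guess is made, with `rc1` from the low-q curvature of
#' `y/q` against `q^2`.
#'
#' @param profile A `"kratky_profile"` (see [kratky_transform()]) of length
#'   >= 8.
#' @return A [broken_rod_params()] object.
#' @export
initial_guess <- function(profile) {
  stopifnot(inherits(profile, "kratky_profile"))
  q <- profile$q; y <- profile$y
  n <- length(q)
  if (n < 8L) stop("need at least 8 points for an initial guess", call. = FALSE)
  xstar <- 1.356602
  tail_const <- max(stats::median(y[q >= stats::quantile(q, 0.85)]), 0)
  # light smoothing so a noisy point is not mistaken for a peak
  k_run <- max(3L, 2L * (n %/% 40L) + 1L)
  run_mean <- function(v) {
    out <- stats::filter(v, rep(1 / k_run, k_run), sides = 2)
    out[is.na(out)] <- v[is.na(out)]
    as.numeric(out)
  }
  ys <- run_mean(y)
  if (!is.null(profile$sigma_y)) {
    # Kratky-space noise grows as q^2 sigma, so the raw argmax is dominated
    # by the high-q tail; score peak candidates by their significance
    se <- sqrt(run_mean(profile$sigma_y^2) / k_run)
    score <- (ys - tail_const) / se
    i_pk <- which.max(score)
    interior <- i_pk > 2L && i_pk < n - 1L && score[i_pk] > 3
  } else {
    i_pk <- which.max(ys)
    interior <- i_pk > 2L && i_pk < n - 1L &&
      ys[i_pk] > 1.05 * max(ys[2], tail_const)
  }
  # low-q linearisation y ~ const + (k/4) q; the intercept absorbs the
  # constant so flat profiles yield near-zero amplitude
  lowq <- q <= stats::quantile(q, 0.25)
  slope <- max(stats::coef(stats::lm(y[lowq] ~ q[lowq]))[[2]], 1e-8)
  k_tot <- 4 * slope
  if (interior) {
    rc2 <- xstar / q[i_pk]
    p <- broken_rod_params(rc1 = rc2 / 3, rc2 = rc2, k1 = k_tot / 2,
                           k2 = k_tot / 2, const = tail_const,
                           n_components = 2L)
  } else {
    # y/q ~ (k/4) (1 - (q rc)^2 / 4) at low q: slope/intercept gives rc
    z <- y[lowq] / q[lowq]
    co <- stats::coef(stats::lm(z ~ I(q[lowq]^2)))
    rc1 <- if (is.finite(co[2]) && co[2] < 0 && co[1] > 0)
      min(2 * sqrt(-co[2] / co[1]), 45) else 0.2
    p <- broken_rod_params(rc1 = max(rc1, 0.06), k1 = max(k_tot, 0),
                           const = tail_const, n_components = 1L)
  }
  p
}

# raw model evaluation used inside the optimiser (no ordering constraint)
.rod_model_raw <- function(q, theta, n_comp) {
  if (n_comp == 1L) {
    theta[["k1"]] * rod_kratky_term(q, theta[["rc1"]]) + theta[["const"]]
  } else {
    theta[["k1"]] * rod_kratky_term(q, theta[["rc1"]]) +
      theta[["k2"]] * rod_kratky_term(q, theta[["rc2"]]) + theta[["const"]]
  }
}

#' Fit the broken-rod model to a single Kratky profile
#'
#' Bounded weighted least squares in Kratky space, minimising
#' `sum(w * (y - model)^2)` with `w = 1/sigma_y^2` where uncertainties exist
#' (and `use_sigma` is on), else `w = 1`.  Radii are bounded to
#' `config$rc_bounds`, amplitudes and the constant to `>= 0`.  After the fit
#' the components are swapped if needed so `rc1 < rc2` always holds.
#' Non-convergence is reported through the `converged` flag, never as an
#' error, so series fits keep a fixed length.
#'
#' @param profile A `"kratky_profile"` with >= 8 points (mask first if
#'   needed).
#' @param init A [broken_rod_params()] starting point; its `n_components`
#'   decides the model order fitted.
#' @param config A [fit_config()].
#' @return An object of class `"rod_fit"`: fields `params`,
#'   `weight_fractions` (`c(w1, w2)`), `cost`, `dof`, `bic`, `converged`,
#'   `message`, `frame_time`.
#' @export
fit_frame <- function(profile, init, config = fit_config()) {
  stopifnot(inherits(profile, "kratky_profile"),
            inherits(config, "rod_fit_config"))
  validate_broken_rod_params(init)
  q <- profile$q; y <- profile$y
  n <- length(q)
  if (n < 8L) stop("need at least 8 points to fit", call. = FALSE)
  w <- if (config$use_sigma && !is.null(profile$sigma_y))
    1 / profile$sigma_y^2 else rep(1, n)
  sw <- sqrt(w)
  n_comp <- init$n_components
  rb <- config$rc_bounds
  if (n_comp == 1L) {
    theta0 <- c(rc1 = min(max(init$rc1, rb[1]), rb[2]), k1 = init$k1,
                const = init$const)
    lower <- c(rb[1], 0, 0); upper <- c(rb[2], Inf, Inf)
  } else {
    theta0 <- c(rc1 = min(max(init$rc1, rb[1]), rb[2]),
                rc2 = min(max(init$rc2, rb[1]), rb[2]),
                k1 = init$k1, k2 = init$k2, const = init$const)
    lower <- c(rb[1], rb[1], 0, 0, 0); upper <- c(rb[2], rb[2], Inf, Inf, Inf)
  }
  resid_fn <- function(theta) {
    names(theta) <- names(theta0)
    sw * (y - .rod_model_raw(q, theta, n_comp))
  }
  # non-convergence is reported through the `converged` flag, so the
  # optimiser's own warnings (e.g. maxiter reached) are redundant here
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = theta0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = config$ftol, ptol = 1e-12,
                           maxiter = config$maxiter, maxfev = 100000L))),
    error = function(e) e)
  p_free <- length(theta0)
  if (inherits(fit, "error")) {
    return(structure(list(params = init,
                          weight_fractions = .wf_of(init, config$wf_mode),
                          cost = NA_real_, dof = n - p_free, bic = Inf,
                          converged = FALSE,
                          message = conditionMessage(fit),
                          frame_time = profile$time),
                     class = "rod_fit"))
  }
  th <- fit$par
  if (n_comp == 2L && th[["rc2"]] < th[["rc1"]]) {
    th[c("rc1", "rc2", "k1", "k2")] <- th[c("rc2", "rc1", "k2", "k1")]
  }
  if (n_comp == 2L && th[["rc2"]] <= th[["rc1"]]) {
    # degenerate coincident radii: keep ordering valid by an infinitesimal split
    th[["rc2"]] <- th[["rc1"]] * (1 + 1e-9)
    if (th[["rc2"]] > rb[2]) {
      th[["rc2"]] <- rb[2]
      th[["rc1"]] <- rb[2] * (1 - 1e-9)
    }
  }
  params <- if (n_comp == 1L) {
    broken_rod_params(rc1 = th[["rc1"]], k1 = th[["k1"]],
                      const = th[["const"]], n_components = 1L)
  } else {
    broken_rod_params(rc1 = th[["rc1"]], rc2 = th[["rc2"]], k1 = th[["k1"]],
                      k2 = th[["k2"]], const = th[["const"]],
                      n_components = 2L)
  }
  cost <- max(fit$deviance, 1e-300)
  # nls.lm info codes 1-4 indicate convergence in f, p, both, or gradient
  converged <- fit$info %in% 1:4
  structure(list(params = params,
                 weight_fractions = .wf_of(params, config$wf_mode),
                 cost = cost, dof = n - p_free,
                 bic = n * log(cost / n) + p_free * log(n),
                 converged = converged, message = fit$message,
                 frame_time = profile$time),
            class = "rod_fit")
}

.wf_of <- function(params, wf_mode) {
  if (params$n_components == 1L) return(c(w1 = 1, w2 = 0))
  if (params$k1 + params$k2 <= 0) return(c(w1 = NA_real_, w2 = NA_real_))
  w <- weight_fractions(params$k1, params$k2, params$rc1, params$rc2,
                        mode = wf_mode)
  c(w1 = w[1], w2 = w[2])
}

#' @export
print.rod_fit <- function(x, ...) {
  cat(sprintf("broken-rod fit at t = %g s (%s)\n", x$frame_time,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  print(x$params)
  cat(sprintf("  w = (%.3f, %.3f), cost = %.4g, dof = %d, BIC = %.2f\n",
              x$weight_fractions[1], x$weight_fractions[2], x$cost, x$dof,
              x$bic))
  invisible(x)
}

#' Choose between one and two rod components by BIC
#'
#' Fits both model orders and returns the lower-BIC fit;
#' `BIC = n log(cost/n) + p log(n)`.  Ties (|dBIC| < `config$delta_bic`,
#' default 2) resolve to the one-component model — early frames of a gelation
#' series are single-population and the extra component must earn its two
#' parameters.
#'
#' Each model order is fitted from several deterministic starting points —
#' the warm start (when given), the data-driven [initial_guess()], and a
#' wider-split variant of the guess — and the lowest-cost converged fit
#' represents that order; the broken-rod cost surface has local minima when
#' the two radii start close together, and a single start is not reliable.
#'
#' @inheritParams fit_frame
#' @param init Optional [broken_rod_params()] warm start (e.g. the previous
#'   frame's fit in a series).
#' @return A `"rod_fit"`, with attribute `"delta_bic"` = BIC(2) - BIC(1).
#' @export
select_components <- function(profile, config = fit_config(), init = NULL) {
  guess <- initial_guess(profile)
  rb <- config$rc_bounds
  cands1 <- list(.as_ncomp(guess, 1L))
  cands2 <- list(.as_ncomp(guess, 2L, rc_bounds = rb))
  amp <- guess$k1 + guess$k2
  if (guess$n_components == 2L) {
    # the interior peak may belong to either component: try both readings
    cands2 <- c(cands2, list(broken_rod_params(
      rc1 = max(guess$rc2 / 6, rb[1] * 1.2), rc2 = guess$rc2, k1 = 0.3 * amp,
      k2 = 0.7 * amp, const = guess$const, n_components = 2L)))
    rc2_swap <- min(3 * guess$rc2, rb[2] * 0.999)
    if (rc2_swap > guess$rc2) {
      cands2 <- c(cands2, list(broken_rod_params(
        rc1 = guess$rc2, rc2 = rc2_swap, k1 = amp / 2, k2 = amp / 2,
        const = guess$const, n_components = 2L)))
    }
  }
  # window-scale start: a thick component whose peak sits mid-window
  rc_win <- min(max(1.356602 / sqrt(min(profile$q) * max(profile$q)),
                    3 * rb[1]), 0.9 * rb[2])
  cands2 <- c(cands2, list(broken_rod_params(
    rc1 = rc_win / 3, rc2 = rc_win, k1 = amp / 2, k2 = amp / 2,
    const = guess$const, n_components = 2L)))
  if (!is.null(init)) {
    cands1 <- c(list(.as_ncomp(init, 1L)), cands1)
    cands2 <- c(list(.as_ncomp(init, 2L, rc_bounds = config$rc_bounds)),
                cands2)
  }
  f1 <- .fit_best(profile, cands1, config)
  f2 <- .fit_best(profile, cands2, config)
  if (!f1$converged && !f2$converged) {
    out <- f1
    out$message <- paste("neither model order converged:", out$message)
    attr(out, "delta_bic") <- f2$bic - f1$bic
    return(out)
  }
  if (!f2$converged) { attr(f1, "delta_bic") <- Inf; return(f1) }
  if (!f1$converged) { attr(f2, "delta_bic") <- -Inf; return(f2) }
  dbic <- f2$bic - f1$bic
  out <- if (dbic < -config$delta_bic) f2 else f1
  attr(out, "delta_bic") <- dbic
  out
}

# fit from every candidate start; best = lowest cost among converged fits
# (or lowest cost overall when none converged)
.fit_best <- function(profile, inits, config) {
  fits <- lapply(inits, function(i) fit_frame(profile, i, config))
  conv <- vapply(fits, `[[`, logical(1), "converged")
  pool <- if (any(conv)) fits[conv] else fits
  costs <- vapply(pool, `[[`, numeric(1), "cost")
  costs[is.na(costs)] <- Inf
  pool[[which.min(costs)]]
}

# coerce a params object to a given component count for warm starts
.as_ncomp <- function(p, n_comp, rc_bounds = c(0.05, 50)) {
  if (p$n_components == n_comp) return(p)
  if (n_comp == 1L) {
    broken_rod_params(rc1 = p$rc1, k1 = p$k1 + p$k2, const = p$const,
                      n_components = 1L)
  } else {
    rc2 <- min(max(3 * p$rc1, p$rc1 + 0.5), rc_bounds[2])
    broken_rod_params(rc1 = p$rc1, rc2 = rc2, k1 = p$k1 * 0.7,
                      k2 = max(p$k1 * 0.3, 1e-6), const = p$const,
                      n_components = 2L)
  }
}

#' Fit a frame series into a time course of radii and weight fractions
#'
#' Sequential per-frame [select_components()] with warm starts: each frame is
#' seeded from the previous frame's converged parameters (the first frame
#' uses [initial_guess()]).  Non-convergent frames carry forward the previous
#' parameters and are flagged in the `converged` column; frames are never
#' dropped, so the time course has one row per frame.
#'
#' @param frames List of [scattering_frame()] (already buffer-subtracted),
#'   in any order; they are processed sorted by time.
#' @param config A [fit_config()]; frames are masked to
#'   `[config$q_min, config$q_max]` and Kratky-transformed before fitting.
#' @return A data.frame of class `"rod_timecourse"` with columns
#'   `time_s, n_comp, rc1_nm, rc2_nm, w2, cost, bic, converged`
#'   (`rc2_nm`/`w2` are `NA`/0 where one component was chosen).
#' @export
fit_series <- function(frames, config = fit_config()) {
  if (!length(frames)) stop("empty frame list", call. = FALSE)
  stopifnot(all(vapply(frames, inherits, logical(1), "scattering_frame")))
  times <- vapply(frames, `[[`, numeric(1), "time")
  frames <- frames[order(times)]
  prev <- NULL
  rows <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    prof <- kratky_transform(mask_q(frames[[i]], config$q_min, config$q_max))
    fit <- select_components(prof, config, init = prev)
    if (!fit$converged && !is.null(prev)) {
      fit$params <- prev
      fit$weight_fractions <- .wf_of(prev, config$wf_mode)
    }
    if (fit$converged) prev <- fit$params
    p <- fit$params
    rows[[i]] <- data.frame(
      time_s = prof$time, n_comp = p$n_components, rc1_nm = p$rc1,
      rc2_nm = if (p$n_components == 2L) p$rc2 else NA_real_,
      w2 = unname(fit$weight_fractions[2]), cost = fit$cost, bic = fit$bic,
      converged = fit$converged, k1 = p$k1, k2 = p$k2, const = p$const)
  }
  tc <- do.call(rbind, rows)
  class(tc) <- c("rod_timecourse", "data.frame")
  tc
}

#' Average two replicate time courses
#'
#' Aligns frames of replicate `b` to the nearest time in `a` (the two
#' replicates must share a time base to within one frame interval) and
#' averages pointwise over the overlap.  Where either replicate chose one
#' component, `rc2_nm` and `w2` take the value of whichever replicate
#' defined them (or stay `NA`).
#'
#' @param a,b `"rod_timecourse"` objects.
#' @return A `"rod_timecourse"` over the overlapping time range.
#' @export
average_timecourses <- function(a, b) {
  stopifnot(inherits(a, "rod_timecourse"), inherits(b, "rod_timecourse"))
  if (max(a$time_s) < min(b$time_s) || max(b$time_s) < min(a$time_s))
    stop("time ranges do not overlap", call. = FALSE)
  if (nrow(a) != nrow(b))
    warning("replicates differ in length; averaging over the overlap",
            call. = FALSE)
  interval <- stats::median(diff(a$time_s))
  if (!is.finite(interval) || interval <= 0) interval <- Inf
  j <- vapply(a$time_s, function(t) which.min(abs(b$time_s - t)), integer(1))
  # a frame further than half an interval away belongs to a different exposure
  ok <- abs(b$time_s[j] - a$time_s) <= interval / 2
  if (!any(ok)) stop("no frames align within one frame interval", call. = FALSE)
  aa <- a[ok, , drop = FALSE]; bb <- b[j[ok], , drop = FALSE]
  mean2 <- function(x, y) {
    out <- (x + y) / 2
    out[is.na(x)] <- y[is.na(x)]
    out[is.na(y)] <- x[is.na(y)]
    out
  }
  out <- data.frame(
    time_s = (aa$time_s + bb$time_s) / 2,
    n_comp = pmax(aa$n_comp, bb$n_comp),
    rc1_nm = mean2(aa$rc1_nm, bb$rc1_nm),
    rc2_nm = mean2(aa$rc2_nm, bb$rc2_nm),
    w2 = mean2(aa$w2, bb$w2),
    cost = mean2(aa$cost, bb$cost),
    bic = mean2(aa$bic, bb$bic),
    converged = aa$converged & bb$converged)
  class(out) <- c("rod_timecourse", "data.frame")
  out
}

#' Write a time course as CSV
#'
#' Columns `time_s, n_comp, rc1_nm, rc2_nm, w2, cost, bic, converged`; full
#' decimal precision.
#'
#' @param tc A `"rod_timecourse"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "rod_timecourse"))
  keep <- c("time_s", "n_comp", "rc1_nm", "rc2_nm", "w2", "cost", "bic",
            "converged")
  df <- as.data.frame(tc)[, intersect(keep, names(tc)), drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
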