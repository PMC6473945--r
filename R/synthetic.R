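# Synthetic time-resolved SAXS frame series.
#
# Ground-truth broken-rod parameters follow saturating-exponential
# trajectories through the anchor values reported for CLEX alginate gelation
# at pH 7.0, 7.4 and 8.0 (single 0.2 nm chains initially; ~0.9 nm chains plus
# 2.5-3.0 nm junction zones at equilibrium, with pH-dependent final weight
# fractions).  Frames are rendered with Gaussian photon-counting-like noise
# on top of a smooth buffer background, fully seeded.

#' Construct a ground-truth parameter trajectory
#'
#' @param rc1,rc2,w2,amplitude,const Functions of time (s) returning the
#'   thin-component radius (nm), thick-component radius (nm), thick-component
#'   weight fraction, overall Kratky amplitude `k1 + k2`, and Kratky-space
#'   constant.
#' @param switch_time Time (s) at which the second component appears; `w2`
#'   must be 0 before it.
#' @param name Label.
#' @return An object of class `"param_trajectory"`.
#' @export
param_trajectory <- function(rc1, rc2, w2, amplitude, const, switch_time,
                             name = "custom") {
  stopifnot(is.function(rc1), is.function(rc2), is.function(w2),
            is.function(amplitude), is.function(const))
  structure(list(rc1 = rc1, rc2 = rc2, w2 = w2, amplitude = amplitude,
                 const = const, switch_time = switch_time, name = name),
            class = "param_trajectory")
}

# saturating exponential a + (b - a) * (1 - exp(-(t - t0)/tau)) clipped at t0
.satexp <- function(a, b, tau, t0 = 0) {
  function(t) ifelse(t <= t0, a, a + (b - a) * (1 - exp(-(t - t0) / tau)))
}

#' Preset gelation scenarios
#'
#' Deterministic parameter trajectories through the anchor values reported
#' for each pH condition:
#' \describe{
#'   \item{`"pH7.0"`}{rc1 0.2 -> 0.9 nm; rc2 2.6 -> 2.9 nm from 10 s; w2
#'     0 -> ~0.6 within two minutes -> ~0.8 at 10 h (complete exchange).}
#'   \item{`"pH7.4"`}{rc1 -> 0.93 nm, rc2 -> 2.9 nm; w2 plateaus at ~0.6 and
#'     does not increase further by 10 h; slightly slower rise and weaker
#'     amplitude.}
#'   \item{`"pH8.0"`}{weak amplitude, rc2 = 2.5 nm; w2 rises to ~0.5 by
#'     180 s then halves to ~0.25 by 10 h (the reading in which the
#'     junction-zone fraction halves on reorganisation).}
#'   \item{`"pH8.0-alt"`}{as `"pH8.0"` but with the alternative reading of
#'     the late-time fractions: the thin-chain fraction falls to 25%, i.e.
#'     w2 -> 0.75 at 10 h.}
#'   \item{`"GDL-control"`}{identical trajectory to `"pH7.0"`: the slow
#'     acidification control reaches an almost identical end state.}
#' }
#'
#' @param name Preset id.
#' @return A [param_trajectory()].
#' @examples
#' traj <- scenario("pH7.0")
#' trajectory_params(traj, c(0, 120, 36000))
#' @export
scenario <- function(name = c("pH7.0", "pH7.4", "pH8.0", "pH8.0-alt",
                              "GDL-control")) {
  name <- match.arg(name)
  ts <- 10   # s; the thick component is discernible from 10 s onwards
  zero <- function(t) rep(0, length(t))
  base_const <- function(t) rep(0.002, length(t))
  traj <- switch(
    name,
    "pH7.0" = ,
    "GDL-control" = param_trajectory(
      rc1 = .satexp(0.2, 0.9, 60),
      rc2 = .satexp(2.6, 2.9, 7200, t0 = ts),
      w2 = function(t) ifelse(t <= ts, 0,
        0.6 * (1 - exp(-(t - ts) / 30)) + 0.2 * (1 - exp(-(t - ts) / 7200))),
      amplitude = function(t) rep(1, length(t)),
      const = base_const, switch_time = ts, name = name),
    "pH7.4" = param_trajectory(
      rc1 = .satexp(0.2, 0.93, 70),
      rc2 = .satexp(2.6, 2.9, 7200, t0 = ts),
      w2 = function(t) ifelse(t <= ts, 0,
        0.6 * (1 - exp(-(t - ts) / 45))),
      amplitude = function(t) rep(0.8, length(t)),
      const = base_const, switch_time = ts, name = name),
    "pH8.0" = param_trajectory(
      rc1 = .satexp(0.2, 0.9, 90),
      rc2 = function(t) rep(2.5, length(t)),
      w2 = function(t) {
        rise <- 0.5 * (1 - exp(-(pmin(t, 180) - ts) / 60))
        w180 <- 0.5 * (1 - exp(-170 / 60))
        ifelse(t <= ts, 0,
               ifelse(t <= 180, rise,
                      0.25 + (w180 - 0.25) * exp(-(t - 180) / 7200)))
      },
      amplitude = function(t) rep(0.4, length(t)),
      const = base_const, switch_time = ts, name = name),
    "pH8.0-alt" = param_trajectory(
      rc1 = .satexp(0.2, 0.9, 90),
      rc2 = function(t) rep(2.5, length(t)),
      w2 = function(t) ifelse(t <= ts, 0,
        0.5 * (1 - exp(-(t - ts) / 60)) + 0.25 * (1 - exp(-(t - ts) / 7200))),
      amplitude = function(t) rep(0.4, length(t)),
      const = base_const, switch_time = ts, name = name))
  traj
}

#' Evaluate a trajectory at given times
#'
#' @param traj A [param_trajectory()].
#' @param times Times, s.
#' @return A data.frame with columns `time_s, n_comp, rc1_nm, rc2_nm, w2,
#'   amplitude, const` (one row per time; `rc2_nm` is `NA` where the second
#'   component is absent).
#' @export
trajectory_params <- function(traj, times) {
  stopifnot(inherits(traj, "param_trajectory"))
  w2 <- traj$w2(times)
  if (any(w2 < 0 | w2 > 1)) stop("trajectory w2 outside [0, 1]", call. = FALSE)
  two <- w2 > 0
  data.frame(time_s = times, n_comp = ifelse(two, 2L, 1L),
             rc1_nm = traj$rc1(times),
             rc2_nm = ifelse(two, traj$rc2(times), NA_real_), w2 = w2,
             amplitude = traj$amplitude(times), const = traj$const(times))
}

# broken_rod_params for one trajectory row
.params_at <- function(row) {
  if (row$n_comp == 2L) {
    broken_rod_params(rc1 = row$rc1_nm, rc2 = row$rc2_nm,
                      k1 = (1 - row$w2) * row$amplitude,
                      k2 = row$w2 * row$amplitude, const = row$const,
                      n_components = 2L)
  } else {
    broken_rod_params(rc1 = row$rc1_nm, k1 = row$amplitude,
                      const = row$const, n_components = 1L)
  }
}

#' Smooth synthetic buffer background
#'
#' Low-q power law plus a constant, `0.02 q^-1.3 + 0.05` (arbitrary units);
#' a plausible stand-in for an unpublished buffer curve so that buffer
#' subtraction is a meaningful pipeline step.
#'
#' @param q Scattering-vector magnitudes, nm^-1, > 0.
#' @return Background intensities.
#' @export
buffer_background <- function(q) 0.02 * q^(-1.3) + 0.05

# run code with a private, seeded RNG stream; caller's RNG state untouched
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

#' Render a noisy synthetic frame series
#'
#' For each time the broken-rod intensity (with trajectory parameters) is
#' added to the buffer background; independent Gaussian noise with standard
#' deviation `noise_level * sqrt(intensity + background)` emulates photon
#' counting statistics (the exposure time is folded into `noise_level`).
#' The `sigma` column carries the true per-point standard deviation.  At the
#' default `noise_level = 0.015` a buffer-subtracted full-gel frame has a
#' Kratky-peak signal-to-noise ratio of about 30.  A matched buffer frame is
#' returned for subtraction; following the usual beamline practice of
#' recording the buffer once as an average over many exposures, its noise is
#' that of `buffer_averages` averaged frames, so subtraction adds little
#' variance.
#'
#' @param traj A [param_trajectory()].
#' @param times Frame times, s; default one frame every 5 s over 145 s.
#' @param q_grid Strictly increasing q grid, nm^-1; default 200 points over
#'   the instrument window 0.103-3.26 nm^-1.
#' @param noise_level Noise amplitude, >= 0; 0 gives exact model frames with
#'   no `sigma` column.
#' @param buffer_averages Number of exposures averaged into the buffer frame
#'   (>= 1); its per-point standard deviation shrinks by the square root of
#'   this count.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A list: `frames` (list of [scattering_frame()]), `buffer`
#'   (a [scattering_frame()]), `truth` (the [trajectory_params()] table).
#' @export
render_frames <- function(traj, times = seq(0, by = 5, length.out = 30),
                          q_grid = seq(0.103, 3.26, length.out = 200),
                          noise_level = 0.015, buffer_averages = 16L,
                          seed = 1L) {
  stopifnot(inherits(traj, "param_trajectory"))
  if (!is.finite(noise_level) || noise_level < 0)
    stop("noise_level must be >= 0", call. = FALSE)
  if (buffer_averages < 1) stop("buffer_averages must be >= 1", call. = FALSE)
  truth <- trajectory_params(traj, times)
  bg <- buffer_background(q_grid)
  meta <- list(wavelength_nm = 0.1, label = traj$name)
  .with_seed(seed, {
    frames <- lapply(seq_along(times), function(i) {
      p <- .params_at(truth[i, ])
      mu <- intensity_model(q_grid, p) + bg
      if (noise_level == 0) {
        scattering_frame(q_grid, mu, time = times[i], meta = meta)
      } else {
        sig <- noise_level * sqrt(mu)
        scattering_frame(q_grid, mu + stats::rnorm(length(mu), sd = sig),
                         sigma = sig, time = times[i], meta = meta)
      }
    })
    buffer <- if (noise_level == 0) {
      scattering_frame(q_grid, bg, time = 0, meta = list(label = "buffer"))
    } else {
      sigb <- noise_level * sqrt(bg) / sqrt(buffer_averages)
      scattering_frame(q_grid, bg + stats::rnorm(length(bg), sd = sigb),
                       sigma = sigb, time = 0, meta = list(label = "buffer"))
    }
    list(frames = frames, buffer = buffer, truth = truth)
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Lays out `profiles/*.dat` (3-column ASCII), `buffer.dat`, `manifest.csv`
#' (`time_s,path`) and `truth.csv` (the ground-truth trajectory table, for
#' recovery scoring).  The default time base is 30 frames at 5 s spacing
#' plus a fully equilibrated frame at 10 h.
#'
#' @param dir Output directory (created if needed).
#' @param scenario_name Preset id for [scenario()], or a
#'   [param_trajectory()].
#' @param seed Integer seed.
#' @param times,q_grid,noise_level Passed to [render_frames()].
#' @return The manifest path, invisibly.
#' @export
write_fixture <- function(dir, scenario_name = "pH7.0", seed = 1L,
                          times = c(seq(0, by = 5, length.out = 30), 36000),
                          q_grid = seq(0.103, 3.26, length.out = 200),
                          noise_level = 0.015) {
  traj <- if (inherits(scenario_name, "param_trajectory")) scenario_name
          else scenario(scenario_name)
  sim <- render_frames(traj, times = times, q_grid = q_grid,
                       noise_level = noise_level, seed = seed)
  dir.create(file.path(dir, "profiles"), recursive = TRUE, showWarnings = FALSE)
  rel <- sprintf("profiles/frame_%04d.dat", seq_along(sim$frames))
  for (i in seq_along(sim$frames))
    write_profile(sim$frames[[i]], file.path(dir, rel[i]))
  write_profile(sim$buffer, file.path(dir, "buffer.dat"))
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(time_s = sim$truth$time_s, path = rel),
                   manifest, row.names = FALSE, quote = FALSE)
  truth_out <- sim$truth
  num <- vapply(truth_out, is.numeric, logical(1))
  truth_out[num] <- lapply(truth_out[num], fmt_num)
  utils::write.csv(truth_out, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
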