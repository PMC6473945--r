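# Plain-text 1D SAXS profile I/O, frame series, buffer subtraction and the
# Kratky transform.
#
# Profiles are 2- or 3-column ASCII (q, I[, sigma]); '#' starts a comment.
# A frame series is described by a manifest CSV with header `time_s,path`.
# No interpolation is performed anywhere: sample and buffer must share the
# same q grid, so subtraction never correlates noise across points.

# repr-level decimal formatting for CSV/ASCII output (no padding, NA as "NA")
fmt_num <- function(x) trimws(formatC(x, digits = 17, format = "g"))

#' Construct a 1D scattering frame
#'
#' @param q Strictly increasing scattering-vector magnitudes, nm^-1, all > 0.
#' @param intensity Intensities, arbitrary units, same length as `q`.
#' @param sigma Optional per-point uncertainties (> 0), same length as `q`.
#' @param time Acquisition time in seconds since first injection, >= 0.
#' @param meta Named list of metadata; conventional entries are
#'   `wavelength_nm` (the incident wavelength in q = (4 pi / lambda) sin
#'   theta, with 2 theta the scattering angle), `detector_distance_m`, and
#'   `label`.
#' @return An object of class `"scattering_frame"`.
#' @export
scattering_frame <- function(q, intensity, sigma = NULL, time = 0,
                             meta = list()) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) == 0L) stop("empty frame", call. = FALSE)
  if (any(!is.finite(q)) || any(q <= 0))
    stop("q must be finite and > 0", call. = FALSE)
  if (is.unsorted(q, strictly = TRUE))
    stop("q must be strictly increasing", call. = FALSE)
  if (length(intensity) != length(q))
    stop("intensity length must match q", call. = FALSE)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q) || any(!is.finite(sigma)) || any(sigma <= 0))
      stop("sigma must match q in length and be > 0", call. = FALSE)
  }
  if (!is.finite(time) || time < 0) stop("time must be >= 0", call. = FALSE)
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 time = as.numeric(time), meta = meta),
            class = "scattering_frame")
}

#' @export
print.scattering_frame <- function(x, ...) {
  cat(sprintf("scattering frame: %d points, q in [%.4g, %.4g] nm^-1, t = %g s%s\n",
              length(x$q), min(x$q), max(x$q), x$time,
              if (is.null(x$sigma)) "" else ", with uncertainties"))
  invisible(x)
}

#' Read a 1D SAXS profile from a plain-text file
#'
#' Accepts 2 or 3 whitespace- or comma-separated numeric columns
#' (q, intensity\[, sigma\]); lines starting with `#` are skipped.  The
#' delimiter is sniffed (comma vs whitespace); units are never guessed and
#' must be declared through `dialect`.
#'
#' @param path File path.
#' @param dialect Unit of the q column: `"nm"` (nm^-1, default) or
#'   `"angstrom"` (A^-1, converted to nm^-1 by multiplying by 10).
#' @param time Timestamp to attach, seconds.
#' @param meta Metadata list, as in [scattering_frame()].
#' @return A [scattering_frame()].
#' @export
read_profile <- function(path, dialect = c("nm", "angstrom"), time = 0,
                         meta = list()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  if (length(body) == 0L) stop("no data lines in ", path, call. = FALSE)
  sep <- if (any(grepl(",", body))) "," else ""
  tab <- utils::read.table(text = body, sep = sep, header = FALSE,
                           strip.white = TRUE)
  if (ncol(tab) < 2L)
    stop("format error in ", path, ": need at least 2 numeric columns",
         call. = FALSE)
  if (!all(vapply(tab[, 1:min(3L, ncol(tab))], is.numeric, logical(1))))
    stop("format error in ", path, ": non-numeric column", call. = FALSE)
  q <- tab[[1L]]
  if (dialect == "angstrom") q <- q * 10
  bad <- which(diff(q) <= 0)
  if (length(bad))
    stop(sprintf("format error in %s: q not strictly increasing at data line %d",
                 path, bad[1L] + 1L), call. = FALSE)
  sigma <- if (ncol(tab) >= 3L) tab[[3L]] else NULL
  scattering_frame(q, tab[[2L]], sigma = sigma, time = time, meta = meta)
}

#' Write a profile as 3-column (or 2-column) ASCII
#'
#' Floats are written with full `repr`-level precision (17 significant
#' digits) so a read/write round trip is exact in decimal form.
#'
#' @param frame A [scattering_frame()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(frame, path) {
  stopifnot(inherits(frame, "scattering_frame"))
  hdr <- sprintf("# q_nm^-1 intensity%s  t=%s s",
                 if (is.null(frame$sigma)) "" else " sigma",
                 fmt_num(frame$time))
  cols <- if (is.null(frame$sigma)) {
    paste(fmt_num(frame$q), fmt_num(frame$intensity))
  } else {
    paste(fmt_num(frame$q), fmt_num(frame$intensity), fmt_num(frame$sigma))
  }
  writeLines(c(hdr, cols), path)
  invisible(path)
}

#' Read an ordered frame series from a manifest
#'
#' The manifest is a CSV with header `time_s,path`; relative paths are
#' resolved against the manifest's directory.  Frames are returned sorted by
#' time.  A warning is issued when the frame spacing deviates more than 10%
#' from the modal interval (acquisition programs are expected to be uniform,
#' e.g. one exposure every 5 s).
#'
#' @param manifest Path to the manifest CSV.
#' @param dialect Passed to [read_profile()].
#' @return List of [scattering_frame()] sorted by time.
#' @export
read_series <- function(manifest, dialect = "nm") {
  if (!file.exists(manifest)) stop("no such file: ", manifest, call. = FALSE)
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("time_s", "path") %in% names(tab)))
    stop("manifest must have columns time_s,path", call. = FALSE)
  if (anyDuplicated(tab$time_s))
    stop("duplicate timestamps in manifest", call. = FALSE)
  tab <- tab[order(tab$time_s), , drop = FALSE]
  dir <- dirname(manifest)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", tab$path), tab$path,
                  file.path(dir, tab$path))
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing profile file(s): ", paste(paths[missing], collapse = ", "),
         call. = FALSE)
  frames <- Map(function(p, t) read_profile(p, dialect = dialect, time = t),
                paths, tab$time_s)
  names(frames) <- NULL
  if (length(frames) > 2L) {
    dt <- diff(tab$time_s)
    modal <- as.numeric(names(sort(table(signif(dt, 6)), decreasing = TRUE))[1L])
    if (any(abs(dt - modal) > 0.1 * modal))
      warning(sprintf("frame spacing deviates > 10%% from modal interval %g s",
                      modal), call. = FALSE)
  }
  frames
}

#' Subtract a buffer profile from a sample profile
#'
#' `intensity_out = intensity_sample - scale * intensity_buffer`.  The two
#' frames must share the q grid to within 1e-9 relative — no interpolation is
#' ever applied.  Uncertainties combine in quadrature when both frames carry
#' them.  Negative differences are retained (clipping would bias the flat
#' Kratky-space constant of a later fit); their count is reported via a
#' message.
#'
#' @param sample,buffer [scattering_frame()] objects on identical q grids.
#' @param scale Buffer scale factor (e.g. a transmission ratio), > 0 allowed
#'   as well as 0; default 1.
#' @return A [scattering_frame()] with the buffer-subtracted intensity.
#' @export
subtract_buffer <- function(sample, buffer, scale = 1.0) {
  stopifnot(inherits(sample, "scattering_frame"),
            inherits(buffer, "scattering_frame"))
  if (!is.finite(scale) || scale < 0)
    stop("scale must be finite and >= 0", call. = FALSE)
  if (length(sample$q) != length(buffer$q) ||
      any(abs(sample$q - buffer$q) > 1e-9 * pmax(abs(sample$q), 1e-300)))
    stop("q grids differ: buffer subtraction requires identical grids",
         call. = FALSE)
  intensity <- sample$intensity - scale * buffer$intensity
  sigma <- NULL
  if (!is.null(sample$sigma) && !is.null(buffer$sigma)) {
    sigma <- sqrt(sample$sigma^2 + (scale * buffer$sigma)^2)
  } else if (!is.null(sample$sigma)) {
    sigma <- sample$sigma
  }
  nneg <- sum(intensity < 0)
  if (nneg > 0)
    message(sprintf("subtract_buffer: %d negative intensities retained", nneg))
  scattering_frame(sample$q, intensity, sigma = sigma, time = sample$time,
                   meta = sample$meta)
}

#' Restrict a frame to a q window
#'
#' Retains points with `q_min <= q <= q_max`; the default window is the
#' instrument range 0.103-3.26 nm^-1.
#'
#' @param frame A [scattering_frame()].
#' @param q_min,q_max Window bounds, nm^-1.
#' @return The masked [scattering_frame()].
#' @export
mask_q <- function(frame, q_min = 0.103, q_max = 3.26) {
  stopifnot(inherits(frame, "scattering_frame"))
  if (!is.finite(q_min) || !is.finite(q_max) || q_min >= q_max)
    stop("require q_min < q_max", call. = FALSE)
  keep <- frame$q >= q_min & frame$q <= q_max
  if (!any(keep))
    stop("q window does not intersect the frame's grid", call. = FALSE)
  scattering_frame(frame$q[keep], frame$intensity[keep],
                   sigma = if (is.null(frame$sigma)) NULL else frame$sigma[keep],
                   time = frame$time, meta = frame$meta)
}

#' Kratky transform of a frame
#'
#' Maps intensity to `y = q^2 I(q)` (and `sigma_y = q^2 sigma`); the inverse
#' transform recovers the frame exactly.
#'
#' @param frame A [scattering_frame()].
#' @return An object of class `"kratky_profile"` with fields `q`, `y`,
#'   `sigma_y`, `time`.
#' @export
kratky_transform <- function(frame) {
  stopifnot(inherits(frame, "scattering_frame"))
  structure(list(q = frame$q, y = frame$q^2 * frame$intensity,
                 sigma_y = if (is.null(frame$sigma)) NULL else frame$q^2 * frame$sigma,
                 time = frame$time),
            class = "kratky_profile")
}

#' @rdname kratky_transform
#' @param profile A `"kratky_profile"`.
#' @param meta Metadata to attach to the reconstructed frame.
#' @export
kratky_inverse <- function(profile, meta = list()) {
  stopifnot(inherits(profile, "kratky_profile"))
  scattering_frame(profile$q, profile$y / profile$q^2,
                   sigma = if (is.null(profile$sigma_y)) NULL else
                     profile$sigma_y / profile$q^2,
                   time = profile$time, meta = meta)
}
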