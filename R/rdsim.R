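# 1D reaction-diffusion model of CLEX Ca2+ release coupled to alginate
# gelation.
#
# Two chelate solutions meet at x = 0: CaEDTA (C1) diffuses from the left,
# ZnEDDA (C2) from the right.  Their second-order exchange reaction
# (rate constant kappa) liberates free Ca2+ (C3):
#
#   dC1/dt = D1 d2C1/dx2 - kappa C1 C2
#   dC2/dt = D2 d2C2/dx2 - kappa C1 C2
#   dC3/dt = D3 d2C3/dx2 + kappa C1 C2 - r_bind k_bind C3 A
#   dG/dt  = k_bind C3 A,  A = alg0 - G   (alginate immobile)
#
# with A the ungelled alginate monomer concentration and G the gel in
# monomer units; r_bind Ca2+ ions are consumed per monomer gelled.  The
# aggregate exchange products (ZnEDTA + EDDA) are tracked as a bookkeeping
# field feeding no kinetics.  Finite-volume method of lines on a uniform
# cell-centred grid, zero-flux boundaries, stiff integration via
# deSolve::ode.1D (lsoda).

#' Reaction-diffusion configuration
#'
#' Defaults reproduce the published simulation conditions: equal chelate
#' diffusivities of 0.78e-9 m^2 s^-1, exchange rate constant 1e4 M^-1 s^-1
#' (large enough that the exchange is not rate limiting), 60 mM chelate on
#' each side, 1% w/v alginate (0.0505 M monomer at 198 g/mol), and output
#' every 12 s over the first 120 s.
#'
#' @param D1,D2 Diffusion constants of CaEDTA and ZnEDDA, m^2 s^-1.
#' @param D_ca Diffusion constant of free Ca2+, m^2 s^-1 (default `D1`).
#' @param kappa Exchange rate constant, M^-1 s^-1.
#' @param c1_0,c2_0 Initial chelate concentrations on their respective
#'   sides, M.
#' @param alg_monomer_0 Ungelled alginate monomer concentration, M.
#' @param r_bind Ca2+ ions consumed per monomer gelled (dimensionless).
#' @param k_bind Gelation rate constant, M^-1 s^-1 ("fast" regime by
#'   default).
#' @param half_length Half box size, m; the box is `[-half_length,
#'   half_length]` with the solution interface at 0.  Must be large enough
#'   that boundary concentrations stay at their initial values over the run.
#' @param n_grid Number of finite-volume cells (>= 101).
#' @param t_out Output times, s, increasing, starting at 0.
#' @param rtol,atol Solver tolerances.
#' @return A list of class `"rd_config"`.
#' @export
rd_config <- function(D1 = 0.78e-9, D2 = 0.78e-9, D_ca = D1, kappa = 1e4,
                      c1_0 = 0.06, c2_0 = 0.06, alg_monomer_0 = 0.0505,
                      r_bind = 0.5, k_bind = 1e4, half_length = 2.5e-3,
                      n_grid = 400L, t_out = seq(0, 120, by = 12),
                      rtol = 1e-8, atol = 1e-12) {
  n_grid <- as.integer(n_grid)
  if (n_grid < 101L) stop("n_grid must be >= 101", call. = FALSE)
  pos <- c(D1 = D1, D2 = D2, D_ca = D_ca, c1_0 = c1_0, c2_0 = c2_0,
           alg_monomer_0 = alg_monomer_0, half_length = half_length)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("diffusivities, concentrations and half_length must be > 0",
         call. = FALSE)
  if (kappa < 0 || k_bind < 0 || r_bind < 0)
    stop("rates must be >= 0", call. = FALSE)
  t_out <- as.numeric(t_out)
  if (length(t_out) < 2L || is.unsorted(t_out, strictly = TRUE) || t_out[1] < 0)
    stop("t_out must be increasing and non-negative", call. = FALSE)
  structure(list(D1 = D1, D2 = D2, D_ca = D_ca, kappa = kappa, c1_0 = c1_0,
                 c2_0 = c2_0, alg_monomer_0 = alg_monomer_0, r_bind = r_bind,
                 k_bind = k_bind, half_length = half_length, n_grid = n_grid,
                 t_out = t_out, rtol = rtol, atol = atol),
            class = "rd_config")
}

# second difference with zero-flux (reflecting) boundaries, uniform grid
.lap0 <- function(c, dx2) {
  n <- length(c)
  (c[c(1L, 1:(n - 1L))] - 2 * c + c[c(2:n, n)]) / dx2
}

#' Simulate CLEX Ca2+ release and gelation
#'
#' Integrates the coupled reaction-diffusion system from a step initial
#' condition (CaEDTA filling x < 0, ZnEDDA filling x > 0, ungelled alginate
#' everywhere) with zero-flux boundaries.  The run aborts with an error if
#' either chelate is depleted by more than 0.1% of its initial value at its
#' own boundary — the box is then too small to emulate an effectively
#' infinite reservoir.
#'
#' @param config An [rd_config()].
#' @return An object of class `"rd_result"`: `x` (cell centres, m), `t`
#'   (output times, s), and `n_times x n_grid` matrices `c1`, `c2`, `c3`
#'   (free Ca2+), `products` (aggregate ZnEDTA + EDDA, bookkeeping),
#'   `alg_free` and `gel` (both in M monomer).
#' @examples
#' \donttest{
#' res <- rd_simulate(rd_config(n_grid = 101, t_out = c(0, 30, 60)))
#' }
#' @export
rd_simulate <- function(config = rd_config()) {
  stopifnot(inherits(config, "rd_config"))
  n <- config$n_grid
  L <- config$half_length
  dx <- 2 * L / n
  x <- seq(-L + dx / 2, L - dx / 2, length.out = n)
  dx2 <- dx^2
  y0 <- c(ifelse(x < 0, config$c1_0, 0),     # c1: CaEDTA
          ifelse(x > 0, config$c2_0, 0),     # c2: ZnEDDA
          rep(0, n),                         # c3: free Ca2+
          rep(0, n),                         # g : gel (monomer units)
          rep(0, n))                         # p : exchange products
  kappa <- config$kappa; kb <- config$k_bind; rb <- config$r_bind
  alg0 <- config$alg_monomer_0
  D1 <- config$D1; D2 <- config$D2; D3 <- config$D_ca
  rhs <- function(t, y, parms) {
    c1 <- y[1:n]; c2 <- y[(n + 1):(2 * n)]; c3 <- y[(2 * n + 1):(3 * n)]
    g <- y[(3 * n + 1):(4 * n)]
    ex <- kappa * c1 * c2
    gel_rate <- kb * c3 * pmax(alg0 - g, 0)
    list(c(D1 * .lap0(c1, dx2) - ex,
           D2 * .lap0(c2, dx2) - ex,
           D3 * .lap0(c3, dx2) + ex - rb * gel_rate,
           gel_rate,
           ex))
  }
  sol <- deSolve::ode.1D(y = y0, times = config$t_out, func = rhs,
                         parms = NULL, nspec = 5L, dimens = n,
                         method = "lsoda", rtol = config$rtol,
                         atol = config$atol)
  if (attr(sol, "istate")[1] < 0)
    stop("stiff integrator failed; see deSolve diagnostics", call. = FALSE)
  take <- function(k) unname(sol[, (1 + (k - 1) * n + 1):(1 + k * n),
                                 drop = FALSE])
  c1 <- take(1); c2 <- take(2); c3 <- take(3); g <- take(4); p <- take(5)
  # reservoir check: each chelate must remain at its initial value at its
  # own boundary (left for CaEDTA, right for ZnEDDA)
  if (max(abs(c1[, 1] - config$c1_0)) > 1e-3 * config$c1_0 ||
      max(abs(c2[, n] - config$c2_0)) > 1e-3 * config$c2_0)
    stop("boundary depletion exceeds 0.1% of the initial concentration: ",
         "increase half_length", call. = FALSE)
  structure(list(x = x, t = config$t_out, c1 = c1, c2 = c2, c3 = c3,
                 products = p, alg_free = alg0 - g, gel = g,
                 config = config),
            class = "rd_result")
}

#' @export
print.rd_result <- function(x, ...) {
  cat(sprintf(paste0("reaction-diffusion result: %d times x %d cells, ",
                     "box [%.3g, %.3g] m\n  final max gel %.4g M monomer\n"),
              length(x$t), length(x$x), min(x$x), max(x$x),
              max(x$gel[nrow(x$gel), ])))
  invisible(x)
}

#' ROI-averaged gel concentration vs time
#'
#' Spatial mean of the gel field over the window
#' `[center - width/2, center + width/2]` at each output time, by trapezoidal
#' integration with linearly interpolated window edges.  When the window is
#' narrower than one grid cell the value reduces to linear interpolation at
#' the centre (the nearest-node value when the centre sits on a node).
#'
#' @param result An [rd_result()][rd_simulate()].
#' @param center ROI centre, m (0 = solution interface).
#' @param width ROI width, m (the published regions are 50 um across, at the
#'   interface and 200 um off-centre).
#' @return Numeric vector of mean gel concentration (M monomer) per output
#'   time.
#' @export
roi_mean_gel <- function(result, center = 0, width = 50e-6) {
  stopifnot(inherits(result, "rd_result"))
  lo <- center - width / 2; hi <- center + width / 2
  x <- result$x
  if (lo < min(x) || hi > max(x))
    stop("ROI extends outside the simulated grid", call. = FALSE)
  apply(result$gel, 1L, function(g) {
    inner <- x[x > lo & x < hi]
    xs <- c(lo, inner, hi)
    gs <- stats::approx(x, g, xout = xs)$y
    if (length(xs) < 2L || hi - lo < .Machine$double.eps)
      return(stats::approx(x, g, xout = center)$y)
    sum(diff(xs) * (head_(gs) + tail_(gs)) / 2) / (hi - lo)
  })
}

head_ <- function(v) v[-length(v)]
tail_ <- function(v) v[-1L]

#' Mass-balance diagnostics for a simulation
#'
#' Box integrals (midpoint rule, exact for the finite-volume fields) of the
#' conserved totals vs time: total calcium `c1 + c3 + r_bind * gel`, total
#' zinc-chelate partners `c2 + products`, and total alginate monomer
#' `alg_free + gel`.  Reports the maximum relative drift of each from its
#' initial value.
#'
#' @param result An [rd_result()][rd_simulate()].
#' @return A list with the per-time totals (`ca`, `zn`, `alg`) and their max
#'   relative drifts (`drift_ca`, `drift_zn`, `drift_alg`).
#' @export
mass_balance <- function(result) {
  stopifnot(inherits(result, "rd_result"))
  dx <- diff(result$x[1:2])
  tot <- function(m) rowSums(m) * dx
  ca <- tot(result$c1 + result$c3 + result$config$r_bind * result$gel)
  zn <- tot(result$c2 + result$products)
  alg <- tot(result$alg_free + result$gel)
  drift <- function(v) max(abs(v - v[1])) / abs(v[1])
  list(ca = ca, zn = zn, alg = alg,
       drift_ca = drift(ca), drift_zn = drift(zn), drift_alg = drift(alg))
}

#' Write simulation fields and ROI series as CSV
#'
#' `fields_path` receives long format `t_s, x_m, species, conc_M` for the six
#' fields; `roi_path` receives `t_s, roi_label, gel_M` for the interface ROI
#' and a 200 um-offset ROI (both 50 um across).
#'
#' @param result An [rd_result()][rd_simulate()].
#' @param fields_path,roi_path Output CSV paths (`NULL` to skip either).
#' @param roi_width,roi_offset ROI geometry, m.
#' @return Invisibly, a list with the two data frames.
#' @export
write_rd_result <- function(result, fields_path = NULL, roi_path = NULL,
                            roi_width = 50e-6, roi_offset = 200e-6) {
  stopifnot(inherits(result, "rd_result"))
  species <- c("c1", "c2", "c3", "products", "alg_free", "gel")
  long <- do.call(rbind, lapply(species, function(s) {
    m <- result[[s]]
    data.frame(t_s = rep(result$t, each = length(result$x)),
               x_m = rep(result$x, times = length(result$t)),
               species = s, conc_M = as.vector(t(m)))
  }))
  roi <- rbind(
    data.frame(t_s = result$t, roi_label = "centre",
               gel_M = roi_mean_gel(result, 0, roi_width)),
    data.frame(t_s = result$t, roi_label = "offset",
               gel_M = roi_mean_gel(result, roi_offset, roi_width)))
  if (!is.null(fields_path)) {
    out <- long
    out$conc_M <- fmt_num(out$conc_M)
    out$x_m <- fmt_num(out$x_m)
    utils::write.csv(out, fields_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(roi_path)) {
    out <- roi
    out$gel_M <- fmt_num(out$gel_M)
    utils::write.csv(out, roi_path, row.names = FALSE, quote = FALSE)
  }
  invisible(list(fields = long, roi = roi))
}
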