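# Shared oracles and fixture builders.  Oracles are deliberately independent
# of the package internals they check.

# truncated power series for J1: sum (-1)^m / (m! (m+1)!) (x/2)^(2m+1);
# terms are added until they fall below 1e-18 of the running magnitude
j1_series <- function(x) {
  vapply(x, function(xi) {
    term <- xi / 2
    total <- term
    m <- 0
    while (abs(term) > 1e-18 * max(1, abs(total)) && m < 60) {
      m <- m + 1
      term <- -term * (xi / 2)^2 / (m * (m + 1))
      total <- total + term
    }
    total
  }, numeric(1))
}

# bisection root finder on a function (for oracle roots)
bisect <- function(f, lo, hi, tol = 1e-12) {
  flo <- f(lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (hi - lo < tol) break
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

# brute-force Kratky peak of a single rod by dense grid scan (independent of
# kratky_peak): returns the q of the maximum of q*(J1(q rc)/(q rc))^2
scan_peak <- function(rc, q_min, q_max, n = 200001L) {
  q <- seq(q_min, q_max, length.out = n)
  x <- q * rc
  y <- q * (besselJ(x, 1) / x)^2
  q[which.max(y)]
}

# complementary error function via the normal CDF (closed-form oracle for
# step-profile diffusion)
erfc_exact <- function(z) 2 * stats::pnorm(-z * sqrt(2))

# noiseless Kratky profile from known parameters
synth_profile <- function(params, q = seq(0.103, 3.26, length.out = 200),
                          time = 0) {
  kratky_transform(scattering_frame(q, intensity_model(q, params),
                                    time = time))
}

# one noisy buffer-subtracted frame at a trajectory time, as the fitting
# pipeline would see it
noisy_subtracted_frame <- function(scenario_name, t, seed,
                                   noise_level = 0.015) {
  sim <- render_frames(scenario(scenario_name), times = c(t, t + 5),
                       noise_level = noise_level, seed = seed)
  suppressMessages(subtract_buffer(sim$frames[[1]], sim$buffer))
}

full_gel_truth <- function(scenario_name = "pH7.0", t = 36000) {
  trajectory_params(scenario(scenario_name), t)
}
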