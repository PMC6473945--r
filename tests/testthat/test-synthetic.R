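test_that("scenario presets pass through their anchor values", {
  tr <- trajectory_params(scenario("pH7.0"), c(0, 120, 36000))
  # initial state: 0.2 nm single chains, no second component
  expect_equal(tr$rc1_nm[1], 0.2)
  expect_equal(tr$w2[1], 0)
  expect_equal(tr$n_comp[1], 1L)
  # two minutes in: junction zones carry ~60% of the weight
  expect_equal(tr$w2[2], 0.6, tolerance = 0.05)
  # 10 h endpoint: 0.9 / 2.9 nm with ~80% junction zones
  expect_equal(tr$rc1_nm[3], 0.9, tolerance = 0.01)
  expect_equal(tr$rc2_nm[3], 2.9, tolerance = 0.01)
  expect_equal(tr$w2[3], 0.8, tolerance = 0.01)
  # pH 7.4 endpoint radii are 0.93 and 2.9 nm, w2 plateaus near 0.6
  t74 <- trajectory_params(scenario("pH7.4"), 36000)
  expect_equal(t74$rc1_nm, 0.93, tolerance = 0.01)
  expect_equal(t74$rc2_nm, 2.9, tolerance = 0.01)
  expect_equal(t74$w2, 0.6, tolerance = 0.01)
  # pH 8.0: thinner junction zones (2.5 nm), non-monotone fractions
  t80 <- trajectory_params(scenario("pH8.0"), c(180, 36000))
  expect_equal(t80$rc2_nm[1], 2.5)
  expect_equal(t80$w2[1], 0.5, tolerance = 0.1)
  expect_equal(t80$w2[2], 0.25, tolerance = 0.01)
  expect_gt(t80$w2[1], t80$w2[2])
  # the alternative late-time reading rises instead
  t80a <- trajectory_params(scenario("pH8.0-alt"), 36000)
  expect_equal(t80a$w2, 0.75, tolerance = 0.01)
  # the slow-acidification control shares the pH 7.0 end state
  tg <- trajectory_params(scenario("GDL-control"), 36000)
  expect_equal(tg$rc1_nm, tr$rc1_nm[3])
  expect_equal(tg$w2, tr$w2[3])
  expect_error(scenario("pH9"), "arg")
})

test_that("trajectories keep the component ordering invariant", {
  for (name in c("pH7.0", "pH7.4", "pH8.0", "pH8.0-alt")) {
    tr <- trajectory_params(scenario(name), c(0, 5, 11, 60, 180, 3600, 36000))
    expect_true(all(tr$w2 >= 0 & tr$w2 <= 1))
    two <- tr$n_comp == 2L
    expect_true(all(tr$rc1_nm[two] < tr$rc2_nm[two]))
    expect_true(all(is.finite(tr$rc1_nm) & tr$rc1_nm > 0))
  }
})

test_that("rendering is exact at zero noise and reproducible under a seed", {
  traj <- scenario("pH7.0")
  q <- seq(0.103, 3.26, length.out = 50)
  clean <- render_frames(traj, times = c(0, 60), q_grid = q,
                         noise_level = 0, seed = 1)
  p <- trajectory_params(traj, 60)
  want <- intensity_model(q, broken_rod_params(
    rc1 = p$rc1_nm, rc2 = p$rc2_nm, k1 = (1 - p$w2) * p$amplitude,
    k2 = p$w2 * p$amplitude, const = p$const, n_components = 2L)) +
    buffer_background(q)
  expect_equal(clean$frames[[2]]$intensity, want)
  expect_null(clean$frames[[1]]$sigma)
  # same seed twice: bit-identical; different seed: different noise, same truth
  a <- render_frames(traj, times = c(0, 60), q_grid = q, seed = 33)
  b <- render_frames(traj, times = c(0, 60), q_grid = q, seed = 33)
  d <- render_frames(traj, times = c(0, 60), q_grid = q, seed = 34)
  expect_identical(a$frames[[1]]$intensity, b$frames[[1]]$intensity)
  expect_identical(a$buffer$intensity, b$buffer$intensity)
  expect_false(identical(a$frames[[1]]$intensity, d$frames[[1]]$intensity))
  expect_identical(a$truth, d$truth)
  expect_error(render_frames(traj, noise_level = -1), "noise_level")
})

test_that("the noise model is calibrated: seeded replicates centre on the model", {
  traj <- scenario("pH7.0")
  q <- seq(0.4, 0.6, length.out = 16)
  p <- trajectory_params(traj, 36000)
  mu <- intensity_model(q, broken_rod_params(
    rc1 = p$rc1_nm, rc2 = p$rc2_nm, k1 = (1 - p$w2) * p$amplitude,
    k2 = p$w2 * p$amplitude, const = p$const, n_components = 2L))[8] +
    buffer_background(q)[8]
  draws <- vapply(1:500, function(s) {
    render_frames(traj, times = 36000, q_grid = q,
                  seed = s)$frames[[1]]$intensity[8]
  }, numeric(1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mu), 3 * se)
})

test_that("reduced chi-square of the true model against noisy fixtures is near 1", {
  traj <- scenario("pH7.0")
  q <- seq(0.103, 3.26, length.out = 200)
  times <- seq(15, by = 5, length.out = 30)  # all after the switch time
  bg <- buffer_background(q)
  # pooled over a whole fixture so the statistic's own sd (~sqrt(2/n)) is
  # small against the asserted band
  chisq <- vapply(1:20, function(s) {
    sim <- render_frames(traj, times = times, q_grid = q, seed = 100 + s)
    z2 <- vapply(seq_along(times), function(i) {
      p <- sim$truth[i, ]
      mu <- intensity_model(q, broken_rod_params(
        rc1 = p$rc1_nm, rc2 = p$rc2_nm, k1 = (1 - p$w2) * p$amplitude,
        k2 = p$w2 * p$amplitude, const = p$const, n_components = 2L)) + bg
      mean(((sim$frames[[i]]$intensity - mu) / sim$frames[[i]]$sigma)^2)
    }, numeric(1))
    mean(z2)
  }, numeric(1))
  expect_true(all(chisq > 0.8 & chisq < 1.2))
})

test_that("fixtures round-trip through the I/O layer", {
  dir <- tempfile()
  man <- write_fixture(dir, "pH7.0", seed = 2)
  expect_true(file.exists(man))
  expect_true(file.exists(file.path(dir, "buffer.dat")))
  truth <- read.csv(file.path(dir, "truth.csv"))
  # 30 frames at 5 s spacing plus the 10 h full-gel frame
  expect_equal(nrow(truth), 31)
  expect_equal(diff(truth$time_s[1:30]), rep(5, 29))
  expect_equal(truth$time_s[31], 36000)
  frames <- suppressWarnings(read_series(man))  # the 10 h gap is irregular
  expect_length(frames, 31)
  expect_equal(vapply(frames, `[[`, numeric(1), "time"), truth$time_s)
  # two seeds: different intensities, identical ground truth
  dir2 <- tempfile()
  write_fixture(dir2, "pH7.0", seed = 3)
  expect_identical(readLines(file.path(dir, "truth.csv")),
                   readLines(file.path(dir2, "truth.csv")))
  expect_false(identical(
    readLines(file.path(dir, "profiles", "frame_0001.dat")),
    readLines(file.path(dir2, "profiles", "frame_0001.dat"))))
})

test_that("fitting a zero-noise fixture recovers the trajectory anchors", {
  dir <- tempfile()
  man <- write_fixture(dir, "pH7.0", seed = 1, noise_level = 0,
                       times = c(0, 120, 36000))
  frames <- suppressWarnings(read_series(man))
  buffer <- read_profile(file.path(dir, "buffer.dat"))
  frames <- suppressMessages(lapply(frames, subtract_buffer, buffer = buffer))
  tc <- fit_series(frames)
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(tc$rc1_nm, truth$rc1_nm, tolerance = 1e-4)
  expect_equal(tc$rc2_nm[-1], truth$rc2_nm[-1], tolerance = 1e-4)
  expect_equal(tc$w2[-1], truth$w2[-1], tolerance = 1e-4)
  expect_equal(tc$n_comp, truth$n_comp)
})
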