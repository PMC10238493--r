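test_that("pearson correlation handles exact and degenerate cases", {
  x <- seq(-2, 5, length.out = 50)
  expect_equal(pearson_correlation(x, 2 * x), 1.0)
  expect_equal(pearson_correlation(x, -x + 7), -1.0)
  t <- seq(0, 10, by = 1 / 200)[-1]
  expect_close(pearson_correlation(sin(2 * pi * t), cos(2 * pi * t)), 0,
               tol = 1e-3)
  expect_error(pearson_correlation(x, rep(1, 50)), "zero-variance")
  expect_error(pearson_correlation(x, x[-1]), "equal length")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("cycle peaks land on the known maxima of a sinusoid", {
  f <- 0.5
  t <- seq(0, 6, by = 1 / 60)
  pk <- cycle_peaks(sin(2 * pi * f * t), t, f)
  expect_equal(length(pk), 3)
  expect_close(as.numeric(pk), c(0.5, 2.5, 4.5), tol = 1 / 60)

  # time-shift equivariance
  pk2 <- cycle_peaks(sin(2 * pi * f * (t - 0.3)), t, f)
  expect_close(as.numeric(pk2), c(0.8, 2.8, 4.8), tol = 1 / 60)

  # noisy sinusoid: peak times recovered within 2% of the period
  set.seed(31)
  y <- sin(2 * pi * f * t) + stats::rnorm(length(t), 0, 0.05)
  pk3 <- cycle_peaks(y, t, f)
  truth <- 0.5 + (seq_along(pk3) - 1) * 2
  expect_true(all(abs(as.numeric(pk3) - truth) < 0.02 / f))

  expect_error(cycle_peaks(sin(t), t[1:30], 0.5))
  expect_error(cycle_peaks(sin(2 * pi * t[1:40]), t[1:40], 0.5), "2 cycles")
})

test_that("relative phase follows |t0 - t1| * f * pi with a conventional sidecar", {
  expect_equal(as.numeric(relative_phase(1.2, 1.2, 0.7)), 0)
  rp <- relative_phase(1.0, 1.5, 1.0)
  expect_close(as.numeric(rp), pi / 2, tol = 1e-12)
  expect_close(attr(rp, "conventional"), pi, tol = 1e-12)
  expect_true(all(as.numeric(relative_phase(c(0, 1), c(2, 0.4), 0.3)) >= 0))
})

test_that("energy cost equals the brute-force work sum and ignores signs", {
  expect_equal(energy_cost(matrix(10, 6000, 1), matrix(0.5, 6000, 1), 1 / 60),
               500)
  expect_equal(energy_cost(matrix(0, 10, 2), matrix(3, 10, 2), 0.1), 0)
  set.seed(17)
  tau <- matrix(stats::rnorm(200), 100, 2)
  om <- matrix(stats::rnorm(200), 100, 2)
  brute <- 0
  for (i in 1:100) for (j in 1:2) brute <- brute + abs(tau[i, j] * om[i, j]) * 0.02
  expect_close(energy_cost(tau, om, 0.02), brute, tol = 1e-10)
  expect_equal(energy_cost(-tau, om, 0.02), energy_cost(tau, om, 0.02))
  expect_equal(energy_cost(tau, -om, 0.02), energy_cost(tau, om, 0.02))
  expect_error(energy_cost(tau, om[1:50, ], 0.02), "aligned")
})

test_that("windowed correlation is consistent with the global coefficient", {
  set.seed(23)
  t <- seq(0, 20, by = 1 / 30)
  x <- sin(2 * pi * 0.5 * t) + stats::rnorm(length(t), 0, 0.05)
  y <- sin(2 * pi * 0.5 * t + 0.3) + stats::rnorm(length(t), 0, 0.05)
  wc <- windowed_correlation(x, y, window = 120, stride = 15, times = t)
  expect_true(all(wc$correlation > 0))
  single <- windowed_correlation(x, y, window = length(x), times = t)
  expect_equal(nrow(single), 1L)
  expect_close(single$correlation, pearson_correlation(x, y), tol = 1e-12)

  # constant window is flagged missing, not NaN
  xc <- c(rep(0, 200), sin(2 * pi * t))
  yc <- c(rep(0, 200), sin(2 * pi * t))
  wc2 <- windowed_correlation(xc, yc, window = 100, stride = 50)
  expect_true(any(is.na(wc2$correlation)))
  expect_false(any(is.nan(wc2$correlation)))

  expect_error(windowed_correlation(x, y, window = 5), "at least 10")
  expect_error(windowed_correlation(x[1:50], y[1:50], window = 100), "shorter")
})

test_that("transition frequency interpolates the first zero crossing", {
  expect_close(transition_frequency(c(0.5, 0.1, -0.3), c(0.4, 0.6, 0.8)),
               0.65, tol = 1e-12)
  no_t <- transition_frequency(c(0.5, 0.4, 0.2), c(0.4, 0.6, 0.8))
  expect_true(is.na(no_t))
  expect_true(attr(no_t, "no_transition"))
  # NA windows are skipped, crossing still found
  expect_close(transition_frequency(c(0.5, NA, -0.5), c(0.4, 0.6, 0.8)),
               0.6, tol = 1e-12)
})

test_that("summaries classify constructed in-phase and anti-phase logs", {
  fs_in <- fixture_spec(frequency = 0.5, ankle_amplitude = 0.06,
                        hip_amplitude = 0.04, lag = 0, noise_sigma = 0,
                        duration = 20, seed = 4)
  sm_in <- summarize_episode(gen_coordination_pair(fs_in))
  expect_gt(sm_in$hip_ankle_correlation, 0.99)
  expect_equal(sm_in$mode_label, "in_phase")
  expect_lt(sm_in$relative_phase, 0.05)

  fs_anti <- fs_in; fs_anti$lag <- 1  # half of the 2 s period
  sm_anti <- summarize_episode(gen_coordination_pair(fs_anti))
  expect_lt(sm_anti$hip_ankle_correlation, -0.99)
  expect_equal(sm_anti$mode_label, "anti_phase")

  # head following the target law exactly: mean |velocity| = 4 f a
  f <- 0.4; a <- 0.08
  t <- seq(0, 30, by = 1 / 60)
  head_x <- -a * cos(2 * pi * f * t) + a
  df <- data.frame(time = t, theta_ankle = sin(2 * pi * f * t) * 0.05,
                   theta_hip = sin(2 * pi * f * t) * 0.03,
                   omega_ankle = cos(2 * pi * f * t),
                   omega_hip = cos(2 * pi * f * t),
                   torque_ankle = 0 * t + 1, torque_hip = 0 * t + 1,
                   head_x = head_x,
                   head_vx = a * sin(2 * pi * f * t) * 2 * pi * f,
                   target_x = head_x, cop_x = 0.8 * sin(2 * pi * f * t) * 0.05,
                   fallen = FALSE)
  log <- trajectory_log(df, spec = task_spec(amplitude_A = a, frequency_f = f))
  sm <- summarize_episode(log)
  expect_close(sm$mean_head_velocity, 4 * f * a, tol = 1e-3)
  expect_close(sm$head_amplitude, a, tol = 0.03 * a)
  expect_equal(unname(sm$cop_quartiles[3]), stats::fivenum(df$cop_x)[3])

  # guard rails
  short <- trajectory_log(df[df$time < 8, ],
                          spec = task_spec(amplitude_A = a, frequency_f = f))
  expect_error(summarize_episode(short), "5 target periods")
  dff <- df; dff$fallen[100] <- TRUE
  expect_error(summarize_episode(trajectory_log(
    dff, spec = task_spec(amplitude_A = a, frequency_f = f))), "fall")
})

test_that("fixture parameters are recovered across a seeded grid", {
  # correlation sign always right; lag within 5%; amplitudes within 3%
  grid <- expand.grid(f = c(0.3, 0.6, 1.0), lag_frac = c(0.05, 0.2, 0.45),
                      seed = c(101, 202))
  for (i in seq_len(nrow(grid))) {
    f <- grid$f[i]
    lag <- grid$lag_frac[i] / f
    fs <- fixture_spec(frequency = f, ankle_amplitude = 0.07,
                       hip_amplitude = 0.05, lag = lag, noise_sigma = 0.05,
                       duration = max(20, 8 / f), seed = grid$seed[i])
    sm <- summarize_episode(gen_coordination_pair(fs))
    expected_sign <- sign(cos(2 * pi * f * lag))
    expect_equal(sign(sm$hip_ankle_correlation), expected_sign,
                 label = sprintf("sign at f=%.2f lag=%.3f", f, lag))
    expect_lt(abs(sm$relative_phase - lag * f * pi) / (lag * f * pi), 0.05)
    expect_lt(abs(sm$peak_to_peak_ankle / 2 - 0.07) / 0.07, 0.03)
    expect_lt(abs(sm$peak_to_peak_hip / 2 - 0.05) / 0.05, 0.03)
  }
})
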