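#' Synthetic coordination fixture specification
#'
#' Describes a joint-angle time-series fixture with prescribed frequency,
#' amplitudes, hip-ankle lag and additive noise, used to exercise the
#' metrics and experiment plumbing without any training run.
#'
#' @param frequency Oscillation frequency (Hz); start frequency when
#'   `chirp_rate > 0`.
#' @param ankle_amplitude,hip_amplitude Angle amplitudes (rad).
#' @param lag Hip peak time minus ankle peak time (s).
#' @param noise_sigma Gaussian noise standard deviation as a fraction of
#'   each amplitude, < 0.2.
#' @param duration Length of the series (s); for fixed-frequency phase
#'   fixtures at least 5 cycles are required.
#' @param sample_rate Sampling rate (Hz). Default 60.
#' @param chirp_rate Linear frequency growth (Hz/s). Default 0.
#' @param seed RNG seed; identical seeds give identical fixtures.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(frequency, ankle_amplitude = 0.05,
                         hip_amplitude = 0.05, lag = 0, noise_sigma = 0.02,
                         duration = 30, sample_rate = 60, chirp_rate = 0,
                         seed = 1L) {
  stopifnot(frequency > 0, ankle_amplitude > 0, hip_amplitude > 0,
            noise_sigma >= 0, duration > 0, sample_rate > 0, chirp_rate >= 0)
  if (noise_sigma >= 0.2) stop("noise_sigma must be below 0.2")
  if (chirp_rate == 0 && duration * frequency < 5)
    stop("fixed-frequency fixtures must cover at least 5 cycles")
  structure(list(frequency = frequency, ankle_amplitude = ankle_amplitude,
                 hip_amplitude = hip_amplitude, lag = lag,
                 noise_sigma = noise_sigma, duration = duration,
                 sample_rate = sample_rate, chirp_rate = chirp_rate,
                 seed = as.integer(seed)), class = "fixture_spec")
}

# Shared assembly of a fixture trajectory log from noiseless angle signals
# and their analytic derivatives. Torques are passive-stiffness proxies
# (-k * theta), not solutions of the dynamics; head position is computed
# through the plant's forward kinematics so fixtures stay geometrically
# consistent. The target channel mirrors the head (perfect-tracking proxy).
fixture_log <- function(fs, th1, th2, om1, om2, times, params) {
  n <- length(times)
  th1n <- th1 + stats::rnorm(n, 0, fs$noise_sigma * fs$ankle_amplitude)
  th2n <- th2 + stats::rnorm(n, 0, fs$noise_sigma * fs$hip_amplitude)
  st <- list(theta_ankle = th1n, theta_hip = th2n,
             omega_ankle = om1, omega_hip = om2)
  fk <- forward_kinematics(st, params)
  tau1 <- -params$ankle_stiffness * th1n
  tau2 <- -params$hip_stiffness * th2n
  df <- data.frame(time = times, theta_ankle = th1n, theta_hip = th2n,
                   omega_ankle = om1, omega_hip = om2,
                   torque_ankle = tau1, torque_hip = tau2,
                   head_x = fk$head_x, head_vx = fk$head_vx,
                   target_x = fk$head_x, cop_x = fk$com_x,
                   r_stay = NA_real_, r_target = NA_real_,
                   r_energy = NA_real_, r_torque = NA_real_,
                   r_total = NA_real_, fallen = FALSE)
  trajectory_log(df,
                 spec = task_spec(amplitude_A = max(diff(range(fk$head_x)) / 2,
                                                    1e-6),
                                  frequency_f = fs$frequency,
                                  chirp_rate = fs$chirp_rate,
                                  episode_duration = fs$duration),
                 params = params, seed = fs$seed,
                 control_dt = 1 / fs$sample_rate)
}

#' Generate a hip-ankle coordination fixture
#'
#' Produces a trajectory log whose joint angles are noisy sinusoids with a
#' prescribed hip-ankle lag: `ankle = a sin(2 pi f t)`,
#' `hip = b sin(2 pi f (t - lag))`, plus seeded Gaussian noise on the
#' angles. Velocities are the analytic derivatives of the noiseless
#' signals; torque channels are passive-stiffness proxies (clearly
#' non-dynamic); the head trace comes from the plant's forward kinematics.
#' The generator's parameters are the ground truth that the metrics layer
#' must recover.
#'
#' @param fs A [fixture_spec()] with `chirp_rate = 0`.
#' @param params Plant parameters (defaults to the standard subject).
#' @return A `trajectory_log`.
#' @export
gen_coordination_pair <- function(fs, params = derive_segment_parameters()) {
  stopifnot(inherits(fs, "fixture_spec"), fs$chirp_rate == 0)
  set.seed(fs$seed)
  times <- seq(0, fs$duration, by = 1 / fs$sample_rate)
  w <- 2 * pi * fs$frequency
  th1 <- fs$ankle_amplitude * sin(w * times)
  th2 <- fs$hip_amplitude * sin(w * (times - fs$lag))
  om1 <- fs$ankle_amplitude * w * cos(w * times)
  om2 <- fs$hip_amplitude * w * cos(w * (times - fs$lag))
  fixture_log(fs, th1, th2, om1, om2, times, params)
}

#' Generate a chirp fixture with a programmed mode switch
#'
#' Emulates an in-phase to anti-phase transition under a frequency chirp:
#' both joints follow the accumulated chirp phase, and the hip flips to a
#' half-period lag (phase `-pi`) once the instantaneous frequency crosses
#' `flip_frequency`. Used to validate the windowed-correlation transition
#' detector against a known transition point.
#'
#' @param f_start Chirp start frequency (Hz).
#' @param rate Chirp rate (Hz/s), > 0.
#' @param flip_frequency Frequency (Hz) at which the hip lag flips to half a
#'   period.
#' @param fs A [fixture_spec()] providing amplitudes, noise, duration,
#'   sample rate and seed (its `frequency`/`chirp_rate` are overridden by
#'   `f_start`/`rate`).
#' @param params Plant parameters.
#' @return A `trajectory_log` whose attached spec carries the chirp.
#' @export
gen_mode_switch_series <- function(f_start, rate, flip_frequency, fs,
                                   params = derive_segment_parameters()) {
  stopifnot(inherits(fs, "fixture_spec"), rate > 0)
  fs$frequency <- f_start
  fs$chirp_rate <- rate
  set.seed(fs$seed)
  times <- seq(0, fs$duration, by = 1 / fs$sample_rate)
  phase <- 2 * pi * (f_start * times + rate * times^2 / 2)
  finst <- f_start + rate * times
  flipped <- finst >= flip_frequency
  th1 <- fs$ankle_amplitude * sin(phase)
  th2 <- fs$hip_amplitude * sin(phase - pi * flipped)
  om1 <- fs$ankle_amplitude * cos(phase) * 2 * pi * finst
  om2 <- fs$hip_amplitude * cos(phase - pi * flipped) * 2 * pi * finst
  fixture_log(fs, th1, th2, om1, om2, times, params)
}
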