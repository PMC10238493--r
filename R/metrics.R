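#' Pearson correlation with degenerate-input guard
#'
#' Standard Pearson r between two equal-length series, erroring (rather than
#' returning NaN) when either series is constant. The sign of the hip-ankle
#' joint-angle correlation is the primary classifier of the postural
#' coordination mode: positive = in-phase, negative = anti-phase.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 3) stop("need at least 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero-variance series")
  stats::cor(x, y)
}

# Centered moving average used to stabilize peak/amplitude extraction on
# noisy angle traces; width is forced odd, ends padded by replication.
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) return(x)
  half <- (w - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[
    (half + 1L):(half + length(x))]
}

#' Per-cycle peak times of an oscillating series
#'
#' Finds one maximum per target cycle `[k/f, (k+1)/f)` covered by the
#' series. The raw argmax is refined by a least-squares quadratic fit over a
#' neighbourhood of one-eighth of a cycle, which makes the peak time robust
#' to sampling and measurement noise. Cycles whose excursion is below
#' `flat_tol` times the overall series range are skipped; the number of
#' skipped cycles is attached as attribute `"skipped"`.
#'
#' @param series Numeric series (e.g. a joint angle in rad).
#' @param times Sample times (s), same length, increasing.
#' @param f Cycle frequency (Hz); the series must span at least 2 cycles.
#' @param smooth Moving-average pre-smoothing width in samples; `NULL`
#'   (default) picks one-tenth of a cycle.
#' @param flat_tol Relative excursion below which a cycle is deemed flat.
#' @return Numeric vector of peak times with attributes `"cycles"` (the
#'   integer cycle index of each peak) and `"skipped"`.
#' @export
cycle_peaks <- function(series, times, f, smooth = NULL, flat_tol = 1e-6) {
  stopifnot(length(series) == length(times), f > 0)
  span <- diff(range(times))
  if (span * f < 2) stop("series must span at least 2 cycles")
  n_per_cycle <- 1 / f / stats::median(diff(times))
  if (is.null(smooth)) smooth <- round(n_per_cycle / 10)
  sm <- moving_average(series, smooth)
  rng <- diff(range(sm))
  if (rng == 0) stop("degenerate input: constant series")

  k0 <- ceiling(min(times) * f - 1e-9)
  k1 <- floor((max(times) + 1e-9) * f) - 1L
  peaks <- numeric(0); cyc <- integer(0); skipped <- 0L
  half_fit <- max(2L, round(n_per_cycle / 8))
  for (k in k0:k1) {
    sel <- which(times >= k / f & times < (k + 1) / f)
    if (length(sel) < 3) next
    if (diff(range(sm[sel])) < flat_tol * rng) { skipped <- skipped + 1L; next }
    i <- sel[which.max(sm[sel])]
    lo <- max(sel[1], i - half_fit); hi <- min(sel[length(sel)], i + half_fit)
    idx <- lo:hi
    tp <- times[i]
    if (length(idx) >= 5) {
      tt <- times[idx] - times[i]
      fit <- stats::lm.fit(cbind(1, tt, tt^2), sm[idx])
      c2 <- fit$coefficients[3]; c1 <- fit$coefficients[2]
      if (is.finite(c2) && c2 < 0) {
        cand <- times[i] - c1 / (2 * c2)
        if (cand >= times[lo] && cand <= times[hi]) tp <- cand
      }
    }
    peaks <- c(peaks, tp); cyc <- c(cyc, k)
  }
  structure(peaks, cycles = cyc, skipped = skipped)
}

#' Relative phase from per-cycle peak times
#'
#' The study's cycle-based relative phase between ankle and hip:
#' `|t0 - t1| * f * pi`, where `t0` and `t1` are the times of the maximum
#' ankle and hip angles in a cycle. Note the formula yields `pi/2` (not
#' `pi`) for a half-period lag; the conventional phase lag
#' `2 pi f |t0 - t1|` is attached as attribute `"conventional"`.
#'
#' @param t0,t1 Peak times (s) of the two signals, vectorized (e.g. one pair
#'   per cycle).
#' @param f Cycle frequency (Hz), > 0.
#' @return Relative phase(s) in radians (non-negative), with attribute
#'   `"conventional"`.
#' @export
relative_phase <- function(t0, t1, f) {
  stopifnot(f > 0)
  dt <- abs(t0 - t1)
  structure(dt * f * pi, conventional = 2 * pi * f * dt)
}

#' Cumulative mechanical energy cost
#'
#' `sum_t sum_j |tau_j(t) * omega_j(t)| * dt` in joules over the evaluation
#' window — the (unsigned) mechanical work rate integrated over time, the
#' quantity penalized per-step by the reward's energy term.
#'
#' @param torques Matrix (or list of equal-length vectors), one column per
#'   joint (Nm).
#' @param omegas Matching angular velocities (rad/s).
#' @param dt Sampling interval (s).
#' @return Energy cost in joules (>= 0).
#' @export
energy_cost <- function(torques, omegas, dt) {
  if (is.list(torques)) torques <- do.call(cbind, torques)
  if (is.list(omegas)) omegas <- do.call(cbind, omegas)
  if (!all(dim(torques) == dim(omegas)))
    stop("torque and velocity series must be aligned")
  sum(abs(torques * omegas)) * dt
}

#' Sliding-window hip-ankle correlation
#'
#' Pearson correlation between two series in sliding windows, reported at
#' centered timestamps; used to track the coordination mode through time
#' (e.g. under a frequency chirp). Windows in which either series is
#' constant yield `NA` (flagged missing, not NaN).
#'
#' @param x,y Equal-length numeric series.
#' @param window Window length in samples (>= 10).
#' @param stride Step between window starts in samples. Default 1.
#' @param times Optional sample times; window centers are reported on this
#'   axis (defaults to the sample index).
#' @return A data frame with `center` (time or index of the window center)
#'   and `correlation`.
#' @export
windowed_correlation <- function(x, y, window, stride = 1L, times = NULL) {
  stopifnot(length(x) == length(y))
  window <- as.integer(window); stride <- as.integer(stride)
  if (window < 10) stop("window must be at least 10 samples")
  if (length(x) < window) stop("series shorter than the window")
  if (is.null(times)) times <- seq_along(x)
  starts <- seq.int(1L, length(x) - window + 1L, by = stride)
  r <- vapply(starts, function(s) {
    xi <- x[s:(s + window - 1L)]; yi <- y[s:(s + window - 1L)]
    if (stats::sd(xi) == 0 || stats::sd(yi) == 0) NA_real_
    else stats::cor(xi, yi)
  }, numeric(1))
  centers <- times[starts] + (times[starts + window - 1L] - times[starts]) / 2
  data.frame(center = centers, correlation = r)
}

#' Mode-transition frequency from a windowed correlation series
#'
#' The target frequency at which the hip-ankle correlation first changes
#' sign (in-phase to anti-phase, or vice versa), linearly interpolated
#' between the bracketing windows.
#'
#' @param correlation Windowed correlation series (NA windows are dropped).
#' @param frequency Target frequency (Hz) at each window center, same
#'   length.
#' @return The interpolated transition frequency (Hz), or `NA` with
#'   attribute `no_transition = TRUE` when the correlation never changes
#'   sign.
#' @export
transition_frequency <- function(correlation, frequency) {
  stopifnot(length(correlation) == length(frequency))
  keep <- !is.na(correlation)
  correlation <- correlation[keep]; frequency <- frequency[keep]
  if (length(correlation) < 2)
    return(structure(NA_real_, no_transition = TRUE))
  s <- sign(correlation)
  flip <- which(s[-1] * s[-length(s)] < 0)
  if (length(flip) == 0) return(structure(NA_real_, no_transition = TRUE))
  i <- flip[1]
  c0 <- correlation[i]; c1 <- correlation[i + 1]
  frequency[i] + (frequency[i + 1] - frequency[i]) * c0 / (c0 - c1)
}

#' Coordination summary of one evaluation episode
#'
#' Aggregates a trajectory log over the steady-state window (the first
#' `discard_periods` target periods are dropped as transient) into the
#' study's evaluation indices: hip-ankle Pearson correlation and the mode
#' label it implies, cycle-based relative phase, per-cycle joint and torque
#' amplitudes, head amplitude and mean head speed, target-head tracking
#' correlation, cumulative energy cost and CoP five-number summary.
#'
#' @param log A `trajectory_log` (from [run_episode()] or the synthetic
#'   generators), covering at least 5 target periods without a fall.
#' @param spec The [task_spec()] (defaults to the log's attached spec).
#' @param mode_threshold Dead-band on |r| below which the mode is labelled
#'   `"ambiguous"`. Default 0.1.
#' @param discard_periods Leading periods dropped as transient. Default 2.
#' @return An object of class `coordination_summary` (named list).
#' @export
summarize_episode <- function(log, spec = attr(log, "spec"),
                              mode_threshold = 0.1, discard_periods = 2) {
  if (is.null(spec)) stop("no task_spec available: pass spec explicitly")
  f <- spec$frequency_f
  stopifnot(f > 0)
  dt <- attr(log, "control_dt")
  if (is.null(dt)) dt <- stats::median(diff(log$time))
  span <- diff(range(log$time))
  if (span * f < 5) stop("log must cover at least 5 target periods")
  if (any(log$fallen)) stop("fall inside the evaluation window; shorten the window")

  t_start <- min(log$time) + discard_periods / f
  win <- log[log$time >= t_start, , drop = FALSE]

  r <- pearson_correlation(win$theta_ankle, win$theta_hip)
  mode <- if (r > mode_threshold) "in_phase"
  else if (r < -mode_threshold) "anti_phase"
  else "ambiguous"

  pk_a <- cycle_peaks(win$theta_ankle, win$time, f)
  pk_h <- cycle_peaks(win$theta_hip, win$time, f)
  common <- intersect(attr(pk_a, "cycles"), attr(pk_h, "cycles"))
  if (length(common) == 0) {
    rp <- NA_real_; rp_conv <- NA_real_
  } else {
    t0 <- pk_a[match(common, attr(pk_a, "cycles"))]
    t1 <- pk_h[match(common, attr(pk_h, "cycles"))]
    ph <- relative_phase(t0, t1, f)
    rp <- mean(ph); rp_conv <- mean(attr(ph, "conventional"))
  }

  n_per_cycle <- 1 / f / dt
  sm_w <- round(n_per_cycle / 10)
  cycle_range <- function(x) {
    xs <- moving_average(x, sm_w)
    ks <- ceiling(min(win$time) * f - 1e-9):(floor(max(win$time) * f + 1e-9) - 1L)
    rng <- vapply(ks, function(k) {
      sel <- win$time >= k / f & win$time < (k + 1) / f
      if (sum(sel) < 3) NA_real_ else diff(range(xs[sel]))
    }, numeric(1))
    mean(rng, na.rm = TRUE)
  }

  head_vx <- if ("head_vx" %in% names(win)) win$head_vx
  else c(diff(win$head_x) / diff(win$time), NA)

  cop <- win$cop_x[is.finite(win$cop_x)]

  structure(list(
    hip_ankle_correlation = r,
    relative_phase = rp,
    relative_phase_conventional = rp_conv,
    mode_label = mode,
    peak_to_peak_ankle = cycle_range(win$theta_ankle),
    peak_to_peak_hip = cycle_range(win$theta_hip),
    torque_amplitude_ankle = cycle_range(win$torque_ankle) / 2,
    torque_amplitude_hip = cycle_range(win$torque_hip) / 2,
    target_head_correlation_r = pearson_correlation(win$target_x, win$head_x),
    head_amplitude = cycle_range(win$head_x) / 2,
    mean_head_velocity = mean(abs(head_vx), na.rm = TRUE),
    energy_cost = energy_cost(cbind(win$torque_ankle, win$torque_hip),
                              cbind(win$omega_ankle, win$omega_hip), dt),
    cop_quartiles = if (length(cop) >= 5) stats::fivenum(cop)
    else rep(NA_real_, 5),
    frequency = f,
    n_cycles = length(common),
    window_duration = diff(range(win$time))
  ), class = "coordination_summary")
}

#' @export
print.coordination_summary <- function(x, ...) {
  cat(sprintf("Coordination summary (f = %.3g Hz, %.1f s window, %d cycles)\n",
              x$frequency, x$window_duration, x$n_cycles))
  cat(sprintf("  hip-ankle r = %+.4f  [%s],  relative phase = %.3f rad (conventional %.3f)\n",
              x$hip_ankle_correlation, x$mode_label, x$relative_phase,
              x$relative_phase_conventional))
  cat(sprintf("  p2p ankle/hip = %.4f / %.4f rad,  torque amp = %.2f / %.2f Nm\n",
              x$peak_to_peak_ankle, x$peak_to_peak_hip,
              x$torque_amplitude_ankle, x$torque_amplitude_hip))
  cat(sprintf("  tracking r = %.4f,  head amplitude = %.4f m,  mean |head vel| = %.4f m/s\n",
              x$target_head_correlation_r, x$head_amplitude,
              x$mean_head_velocity))
  cat(sprintf("  energy cost = %.1f J,  CoP quartiles [m]: %s\n",
              x$energy_cost,
              paste(signif(x$cop_quartiles, 3), collapse = " ")))
  invisible(x)
}

#' Flatten a coordination summary to a one-row data frame
#'
#' @param x A `coordination_summary`.
#' @param ... Unused.
#' @return One-row data frame (CoP quartiles as five columns), suitable for
#'   binding into sweep tables.
#' @export
as.data.frame.coordination_summary <- function(x, ...) {
  q <- x$cop_quartiles
  data.frame(hip_ankle_correlation = x$hip_ankle_correlation,
             relative_phase = x$relative_phase,
             relative_phase_conventional = x$relative_phase_conventional,
             mode_label = x$mode_label,
             peak_to_peak_ankle = x$peak_to_peak_ankle,
             peak_to_peak_hip = x$peak_to_peak_hip,
             torque_amplitude_ankle = x$torque_amplitude_ankle,
             torque_amplitude_hip = x$torque_amplitude_hip,
             target_head_correlation_r = x$target_head_correlation_r,
             head_amplitude = x$head_amplitude,
             mean_head_velocity = x$mean_head_velocity,
             energy_cost = x$energy_cost,
             cop_min = q[1], cop_q1 = q[2], cop_median = q[3],
             cop_q3 = q[4], cop_max = q[5],
             frequency = x$frequency, n_cycles = x$n_cycles,
             stringsAsFactors = FALSE)
}
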