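#' Head-tracking task specification
#'
#' The supra-postural task: the head must track a point moving sinusoidally
#' along the x-axis, `x(t) = -A cos(2 pi f t) + A`, so the target sweeps the
#' range `[0, 2A]` starting from 0. In chirp mode the instantaneous frequency
#' grows linearly, `f(t) = f0 + chirp_rate * t`, and the target uses the
#' accumulated phase `phi(t) = 2 pi (f0 t + chirp_rate t^2 / 2)`.
#'
#' @param amplitude_A Target half-range A (m). Default 0.1.
#' @param frequency_f Target frequency (Hz); start frequency in chirp mode.
#' @param chirp_rate Linear frequency growth rate (Hz/s); 0 for fixed
#'   frequency. Default 0.
#' @param episode_duration Episode length (s). Default 20.
#' @param target_height Visual height of the target (m); display only.
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(amplitude_A = 0.1, frequency_f = 0.4, chirp_rate = 0,
                      episode_duration = 20, target_height = 1.7) {
  stopifnot(amplitude_A > 0, frequency_f >= 0, chirp_rate >= 0,
            episode_duration > 0)
  structure(list(amplitude_A = amplitude_A, frequency_f = frequency_f,
                 chirp_rate = chirp_rate, episode_duration = episode_duration,
                 target_height = target_height), class = "task_spec")
}

#' Target position and velocity at time t
#'
#' @param spec A [task_spec()].
#' @param t Time(s) in seconds, vectorized, `t >= 0`.
#' @return `target_position()` returns the x-position (m);
#'   `target_velocity()` its analytic time derivative (m/s).
#' @export
target_position <- function(spec, t) {
  stopifnot(all(t >= 0))
  A <- spec$amplitude_A
  phase <- 2 * pi * (spec$frequency_f * t + spec$chirp_rate * t^2 / 2)
  -A * cos(phase) + A
}

#' @rdname target_position
#' @export
target_velocity <- function(spec, t) {
  stopifnot(all(t >= 0))
  A <- spec$amplitude_A
  phase <- 2 * pi * (spec$frequency_f * t + spec$chirp_rate * t^2 / 2)
  finst <- spec$frequency_f + spec$chirp_rate * t
  A * sin(phase) * 2 * pi * finst
}

#' Reward weights
#'
#' Coefficients of the composite reward
#' `R_total = alpha R_stay + beta R_target + gamma R_energy + gamma R_torque`
#' (a single `gamma` multiplies both the energy and the torque penalty).
#' `R_stay = (1 + ||Pf0 - Pft||^2)^-1` keeps the feet in place,
#' `R_target = (1 + ||x_target - x_head||^2)^-1` rewards tracking,
#' `R_energy = -sum_j |tau_j omega_j| dt` penalises mechanical work and
#' `R_torque = -sum_j tau_j^2` penalises torque magnitude. When the HAT CoM
#' height drops below the fall threshold the total reward is overridden
#' to -1.
#'
#' `torque_scale` divides the joint torques before the energy/torque penalty
#' terms (only): with the default 1 the formulas act on raw Nm torques
#' exactly as written; the training configuration sets it to the torque limit
#' so the penalties act on normalized torques in \[-1, 1\], keeping them
#' commensurate with the O(1) stay/tracking terms.
#'
#' @param alpha Weight of the stay-in-place term. Default 1.
#' @param beta Weight of the tracking term. Default 5.
#' @param gamma Weight of both energy and torque penalties. Default 20.
#' @param torque_scale Torque normalization (Nm) for the penalty terms.
#' @return An object of class `reward_weights`.
#' @export
reward_weights <- function(alpha = 1, beta = 5, gamma = 20, torque_scale = 1) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, torque_scale > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 torque_scale = torque_scale), class = "reward_weights")
}

#' Per-step reward breakdown
#'
#' Evaluates the composite tracking/balance reward for one control step; see
#' [reward_weights()] for the term definitions. All arguments are vectorized
#' over a batch of environments.
#'
#' @param mech Mechanics output of the step ([forward_kinematics()] /
#'   [step_dynamics()]), used for `head_x` and the `fallen` flag.
#' @param foot_displacement Displacement of the foot from its initial
#'   position (m); identically 0 for the pinned-ankle plant.
#' @param target_x Target x-position (m) at the step time.
#' @param torques Applied joint torques (Nm): length-2 numeric or list of two
#'   vectors (ankle, hip).
#' @param omegas Joint angular velocities (rad/s), same shape as `torques`.
#' @param dt Control step duration (s), > 0.
#' @param w A [reward_weights()] object.
#' @return A list (class `reward_breakdown`) with `r_stay`, `r_target`,
#'   `r_energy`, `r_torque`, `r_total` and `fallen`; `r_total` is -1
#'   wherever `fallen` is true.
#' @export
compute_reward <- function(mech, foot_displacement, target_x, torques, omegas,
                           dt, w) {
  stopifnot(dt > 0)
  if (is.list(torques)) { tau1 <- torques[[1]]; tau2 <- torques[[2]] }
  else { tau1 <- torques[1]; tau2 <- torques[2] }
  if (is.list(omegas)) { om1 <- omegas[[1]]; om2 <- omegas[[2]] }
  else { om1 <- omegas[1]; om2 <- omegas[2] }

  r_stay <- 1 / (1 + foot_displacement^2)
  err <- target_x - mech$head_x
  r_target <- 1 / (1 + err^2)
  ts1 <- tau1 / w$torque_scale; ts2 <- tau2 / w$torque_scale
  r_energy <- -(abs(ts1 * om1) + abs(ts2 * om2)) * dt
  r_torque <- -(ts1^2 + ts2^2)
  r_total <- w$alpha * r_stay + w$beta * r_target +
    w$gamma * r_energy + w$gamma * r_torque
  fallen <- mech$fallen
  r_total[fallen] <- -1
  structure(list(r_stay = r_stay, r_target = r_target, r_energy = r_energy,
                 r_torque = r_torque, r_total = r_total, fallen = fallen),
            class = "reward_breakdown")
}

#' Observation vector fed to the policy
#'
#' Fixed-order observation: ankle angle, hip angle, ankle velocity, hip
#' velocity (rad, rad/s), head x-position and velocity (m, m/s), tracking
#' error `target_x - head_x` (m), and target velocity (m/s). Length 8 for
#' every state.
#'
#' @param state A `plant_state` (scalar or batch).
#' @param mech Matching mechanics output with `head_x` and `head_vx`.
#' @param spec A [task_spec()].
#' @param t Time (s), scalar or batch vector.
#' @return A numeric vector of length 8 for a scalar state, otherwise an
#'   n x 8 matrix (rows = environments).
#' @export
build_observation <- function(state, mech, spec, t) {
  obs <- cbind(theta_ankle = state$theta_ankle,
               theta_hip = state$theta_hip,
               omega_ankle = state$omega_ankle,
               omega_hip = state$omega_hip,
               head_x = mech$head_x,
               head_vx = mech$head_vx,
               target_err = target_position(spec, t) - mech$head_x,
               target_vx = rep_len(target_velocity(spec, t), length(mech$head_x)))
  if (nrow(obs) == 1L) obs[1L, ] else obs
}

#' Run one evaluation episode
#'
#' Steps the plant under a policy at the control rate (default 60 Hz, four
#' RK4 physics substeps per control step) until the episode duration elapses
#' or the model falls, recording a full per-step trajectory log.
#'
#' @param policy A policy object: anything with a [policy_action()] method
#'   (a trained [ppo_train()] policy or a scripted policy such as
#'   [sine_policy()]).
#' @param spec A [task_spec()].
#' @param params A [derive_segment_parameters()] plant.
#' @param w A [reward_weights()] object.
#' @param seed Integer seed for any policy stochasticity (and the initial
#'   state perturbation if `init_sd > 0`). Same seed, same policy: identical
#'   logs.
#' @param control_dt Control period (s). Default 1/60.
#' @param physics_substeps RK4 substeps per control step. Default 4
#'   (physics at 240 Hz).
#' @param deterministic If true (default) stochastic policies act on their
#'   mean action.
#' @param init_sd Standard deviation (rad) of the initial joint-angle
#'   perturbation. Default 0.
#' @return A `trajectory_log`: a data frame with one row per control step
#'   (time, joint angles/velocities, applied torques, head and target
#'   positions, CoP, reward breakdown, fall flag) and attributes recording
#'   the configuration and seed.
#' @export
run_episode <- function(policy, spec, params, w = reward_weights(),
                        seed = 1L, control_dt = 1 / 60, physics_substeps = 4L,
                        deterministic = TRUE, init_sd = 0) {
  set.seed(seed)
  n_steps <- floor(spec$episode_duration / control_dt + 1e-9)
  state <- plant_state(theta_ankle = stats::rnorm(1, 0, init_sd),
                       theta_hip = stats::rnorm(1, 0, init_sd))
  mech <- plant_mechanics(state, c(0, 0), params)
  lim <- params$torque_limit
  sub_dt <- control_dt / physics_substeps

  cols <- c("time", "theta_ankle", "theta_hip", "omega_ankle", "omega_hip",
            "torque_ankle", "torque_hip", "head_x", "head_vx", "target_x",
            "cop_x", "r_stay", "r_target", "r_energy", "r_torque", "r_total",
            "fallen")
  log <- matrix(NA_real_, n_steps, length(cols), dimnames = list(NULL, cols))

  t <- 0
  for (i in seq_len(n_steps)) {
    obs <- build_observation(state, mech, spec, t)
    a <- policy_action(policy, matrix(obs, nrow = 1),
                       deterministic = deterministic, t = t)
    a <- pmin(pmax(as.numeric(a), -1), 1)
    tau <- a * lim
    for (j in seq_len(physics_substeps)) {
      res <- step_dynamics(state, tau, params, sub_dt)
      state <- res$state
    }
    mech <- res$mechanics
    t <- t + control_dt
    rb <- compute_reward(mech, 0, target_position(spec, t),
                         c(mech$ankle_torque_applied, mech$hip_torque_applied),
                         c(state$omega_ankle, state$omega_hip), control_dt, w)
    log[i, ] <- c(t, state$theta_ankle, state$theta_hip, state$omega_ankle,
                  state$omega_hip, mech$ankle_torque_applied,
                  mech$hip_torque_applied, mech$head_x, mech$head_vx,
                  target_position(spec, t), mech$cop_x, rb$r_stay, rb$r_target,
                  rb$r_energy, rb$r_torque, rb$r_total, as.numeric(rb$fallen))
    if (rb$fallen) { log <- log[seq_len(i), , drop = FALSE]; break }
  }

  out <- as.data.frame(log)
  out$fallen <- as.logical(out$fallen)
  trajectory_log(out, spec = spec, params = params, weights = w, seed = seed,
                 control_dt = control_dt)
}

#' Construct a trajectory log
#'
#' Wraps a per-control-step record as a classed data frame carrying the task
#' configuration, plant parameters, reward weights, seed and control period
#' as attributes. Most users obtain these from [run_episode()] or
#' [gen_coordination_pair()].
#'
#' @param df Data frame with the per-step columns (see [run_episode()]).
#' @param spec,params,weights,seed,control_dt Configuration to attach.
#' @return The data frame with class `trajectory_log`.
#' @export
trajectory_log <- function(df, spec, params = NULL, weights = NULL, seed = NA,
                           control_dt = NULL) {
  stopifnot(is.data.frame(df), "time" %in% names(df))
  if (is.null(control_dt)) control_dt <- stats::median(diff(df$time))
  structure(df, class = c("trajectory_log", "data.frame"),
            spec = spec, params = params, weights = weights, seed = seed,
            control_dt = control_dt)
}

#' @export
print.trajectory_log <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Trajectory log: %d control steps (%.1f s at dt = %.4g s)%s\n",
              nrow(x), nrow(x) * attr(x, "control_dt"), attr(x, "control_dt"),
              if (isTRUE(x$fallen[nrow(x)])) ", ended by fall" else ""))
  if (!is.null(spec))
    cat(sprintf("  target: A = %.3g m, f = %.3g Hz%s\n", spec$amplitude_A,
                spec$frequency_f,
                if (spec$chirp_rate > 0)
                  sprintf(" + %.3g Hz/s chirp", spec$chirp_rate) else ""))
  utils::str(as.data.frame(utils::head(x, 3)))
  invisible(x)
}
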