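# Vectorized training environments. An environment factory is a function
# (n_envs, seed) -> env, where env is a list with fields
#   reset()        : n x obs_dim observation matrix (resets every env)
#   step(actions)  : list(obs, reward, done, finished_returns) for an
#                    n x act_dim matrix of normalized actions in [-1, 1]
#   obs_dim, act_dim, obs_scale
# Batch plants are stepped with vectorized arithmetic, so stepping 64
# environments costs little more than stepping one.

#' Environment factory for the head-tracking task
#'
#' Returns a factory producing vectorized tracking-balance environments:
#' each environment is an independent copy of the planar standing plant
#' driven at the control rate (default 60 Hz; four RK4 substeps at 240 Hz),
#' rewarded per [compute_reward()], reset on fall or episode end.
#'
#' @param spec A [task_spec()] (its `episode_duration` is the training
#'   episode length).
#' @param params A plant from [derive_segment_parameters()].
#' @param w A [reward_weights()]; for training, construct it with
#'   `torque_scale = params$torque_limit` so the energy/torque penalties act
#'   on normalized torques.
#' @param control_dt Control period (s). Default 1/60.
#' @param physics_substeps RK4 substeps per control step. Default 4.
#' @param init_sd Standard deviation (rad) of the initial joint-angle
#'   perturbation at reset. Default 0.02.
#' @param frequency_sampler Optional function(n) returning a target
#'   frequency (Hz) per environment episode, used for the multi-frequency
#'   curriculum; overrides `spec$frequency_f` at each reset.
#' @return A function `(n_envs, seed) -> env` as described above.
#' @export
make_tracking_env <- function(spec, params, w = reward_weights(torque_scale = params$torque_limit),
                              control_dt = 1 / 60, physics_substeps = 4L,
                              init_sd = 0.02, frequency_sampler = NULL) {
  force(spec); force(params); force(w); force(control_dt)
  force(physics_substeps); force(init_sd); force(frequency_sampler)

  function(n_envs, seed = NULL) {
    k <- plant_coefficients(params)
    lim <- params$torque_limit
    sub_dt <- control_dt / physics_substeps
    ar <- params$ankle_angle_range; hr <- params$hip_angle_range
    n_steps_max <- floor(spec$episode_duration / control_dt + 1e-9)

    e <- new.env(parent = emptyenv())
    e$th1 <- e$th2 <- e$om1 <- e$om2 <- numeric(n_envs)
    e$tt <- numeric(n_envs)          # within-episode time
    e$freq <- rep(spec$frequency_f, n_envs)
    e$ep_ret <- numeric(n_envs)

    reset_idx <- function(idx) {
      n <- length(idx)
      if (n == 0) return(invisible())
      e$th1[idx] <- stats::rnorm(n, 0, init_sd)
      e$th2[idx] <- stats::rnorm(n, 0, init_sd)
      e$om1[idx] <- 0; e$om2[idx] <- 0
      e$tt[idx] <- 0
      e$ep_ret[idx] <- 0
      if (!is.null(frequency_sampler)) e$freq[idx] <- frequency_sampler(n)
      invisible()
    }

    target_at <- function(tt, freq) {
      A <- spec$amplitude_A
      ph <- 2 * pi * (freq * tt + spec$chirp_rate * tt^2 / 2)
      list(x = -A * cos(ph) + A,
           v = A * sin(ph) * 2 * pi * (freq + spec$chirp_rate * tt))
    }

    obs_now <- function() {
      st <- list(theta_ankle = e$th1, theta_hip = e$th2,
                 omega_ankle = e$om1, omega_hip = e$om2)
      t1 <- e$th1; t12 <- e$th1 + e$th2
      head_x <- params$leg_length * sin(t1) + params$head_distance * sin(t12)
      head_vx <- params$leg_length * cos(t1) * e$om1 +
        params$head_distance * cos(t12) * (e$om1 + e$om2)
      tg <- target_at(e$tt, e$freq)
      cbind(e$th1, e$th2, e$om1, e$om2, head_x, head_vx,
            tg$x - head_x, tg$v, deparse.level = 0)
    }

    list(
      obs_dim = 8L, act_dim = 2L,
      obs_scale = c(3, 3, 0.5, 0.5, 3, 1, 5, 1),
      reset = function() {
        reset_idx(seq_len(n_envs))
        obs_now()
      },
      step = function(actions) {
        a1 <- pmin(pmax(actions[, 1], -1), 1)
        a2 <- pmin(pmax(actions[, 2], -1), 1)
        tau1 <- a1 * lim; tau2 <- a2 * lim
        th1 <- e$th1; th2 <- e$th2; om1 <- e$om1; om2 <- e$om2
        for (j in seq_len(physics_substeps)) {
          s <- rk4_substep(k, params, th1, th2, om1, om2, tau1, tau2, sub_dt)
          hit1 <- s$th1 < ar[1] | s$th1 > ar[2]
          hit2 <- s$th2 < hr[1] | s$th2 > hr[2]
          th1 <- pmin(pmax(s$th1, ar[1]), ar[2])
          th2 <- pmin(pmax(s$th2, hr[1]), hr[2])
          om1 <- s$om1; om2 <- s$om2
          om1[hit1] <- 0; om2[hit2] <- 0
        }
        if (!all(is.finite(th1)) || !all(is.finite(om1)) ||
            !all(is.finite(th2)) || !all(is.finite(om2)))
          stop("integration failure: non-finite state in training rollout")
        e$th1 <- th1; e$th2 <- th2; e$om1 <- om1; e$om2 <- om2
        e$tt <- e$tt + control_dt

        t12 <- th1 + th2
        head_x <- params$leg_length * sin(th1) + params$head_distance * sin(t12)
        trunk_z <- params$leg_length * cos(th1) +
          params$trunk_com_distance * cos(t12)
        fallen <- trunk_z < params$fall_height_threshold
        tg <- target_at(e$tt, e$freq)
        rb <- compute_reward(list(head_x = head_x, fallen = fallen), 0, tg$x,
                             list(tau1, tau2), list(om1, om2), control_dt, w)
        done <- fallen | e$tt >= spec$episode_duration - 1e-9
        e$ep_ret <- e$ep_ret + rb$r_total
        finished <- e$ep_ret[done]
        reset_idx(which(done))
        list(obs = obs_now(), reward = rb$r_total, done = done,
             finished_returns = finished)
      }
    )
  }
}

#' Deterministic 1-D double-integrator toy environment
#'
#' A small LQR-like regulation problem (position/velocity state, one bounded
#' action, quadratic cost) used as a smoke benchmark for the PPO learner:
#' returns must improve within a few dozen updates.
#'
#' @param episode_steps Episode length in steps. Default 50.
#' @return An environment factory `(n_envs, seed) -> env`.
#' @export
make_toy_env <- function(episode_steps = 50L) {
  force(episode_steps)
  function(n_envs, seed = NULL) {
    e <- new.env(parent = emptyenv())
    e$x <- e$v <- numeric(n_envs)
    e$step_i <- integer(n_envs)
    e$ep_ret <- numeric(n_envs)
    reset_idx <- function(idx) {
      n <- length(idx)
      if (n == 0) return(invisible())
      e$x[idx] <- stats::runif(n, -1, 1)
      e$v[idx] <- stats::runif(n, -1, 1)
      e$step_i[idx] <- 0L
      e$ep_ret[idx] <- 0
      invisible()
    }
    list(
      obs_dim = 2L, act_dim = 1L, obs_scale = c(1, 1),
      reset = function() {
        reset_idx(seq_len(n_envs))
        cbind(e$x, e$v, deparse.level = 0)
      },
      step = function(actions) {
        a <- pmin(pmax(actions[, 1], -1), 1)
        e$x <- e$x + 0.1 * e$v
        e$v <- e$v + 0.3 * a
        e$step_i <- e$step_i + 1L
        r <- -(e$x^2 + 0.1 * e$v^2 + 0.01 * a^2)
        done <- e$step_i >= episode_steps
        e$ep_ret <- e$ep_ret + r
        finished <- e$ep_ret[done]
        reset_idx(which(done))
        list(obs = cbind(e$x, e$v, deparse.level = 0), reward = r,
             done = done, finished_returns = finished)
      }
    )
  }
}

#' Uniform frequency-curriculum sampler
#'
#' Returns a sampler drawing one target frequency per episode uniformly from
#' a fixed set of values — the multi-frequency training curriculum used
#' before chirp and added-mass transfer evaluations (the policy experiences
#' each frequency only as a fixed per-episode setting, never a continuous
#' variation). Pass the result as `frequency_sampler` to
#' [make_tracking_env()].
#'
#' @param values Frequencies (Hz) to sample from; defaults to the ten fixed
#'   frequencies of the frequency sweep.
#' @return A function `(n)` returning `n` sampled frequencies.
#' @export
frequency_curriculum_sampler <- function(values = sweep_values("frequency")) {
  force(values)
  function(n) values[sample.int(length(values), n, replace = TRUE)]
}
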