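# Policy objects. All policies act through policy_action(): observations in,
# normalized actions in [-1, 1] out (scaled to torques by the environment).

#' Compute a policy's action for a batch of observations
#'
#' @param policy A policy object (`ppo_policy`, [zero_policy()],
#'   [sine_policy()], [scripted_policy()], ...).
#' @param obs Numeric matrix, one row per environment.
#' @param deterministic For stochastic policies, act on the mean instead of
#'   sampling.
#' @param ... Method-specific arguments.
#' @return Action matrix (rows = environments), normalized to `[-1, 1]`
#'   torque units.
#' @export
policy_action <- function(policy, obs, deterministic = FALSE, ...) {
  UseMethod("policy_action")
}

#' Scripted policies
#'
#' Simple open-loop or rule-based policies used for testing and for
#' fixture-driven evaluations that bypass learning. `zero_policy()` outputs
#' zero torque; `sine_policy()` drives the ankle (and optionally the hip)
#' sinusoidally; `scripted_policy(f)` wraps an arbitrary function
#' `f(obs, t)` returning normalized actions.
#'
#' @param ankle_amp,hip_amp Normalized torque amplitudes in `[0, 1]`.
#' @param frequency_f Drive frequency (Hz).
#' @param hip_lag Time lag (s) of the hip drive relative to the ankle.
#' @return A policy object usable with [policy_action()] and
#'   [run_episode()].
#' @export
zero_policy <- function() structure(list(), class = c("zero_policy", "postcoord_policy"))

#' @export
policy_action.zero_policy <- function(policy, obs, deterministic = FALSE, ...) {
  matrix(0, nrow(obs), 2)
}

#' @rdname zero_policy
#' @export
sine_policy <- function(ankle_amp = 0.2, frequency_f = 0.5, hip_amp = 0,
                        hip_lag = 0) {
  structure(list(ankle_amp = ankle_amp, frequency_f = frequency_f,
                 hip_amp = hip_amp, hip_lag = hip_lag),
            class = c("sine_policy", "postcoord_policy"))
}

# Scripted policies receive time through the policy_action `t` argument when
# the caller tracks it; otherwise they fall back to an internal step counter.
#' @export
policy_action.sine_policy <- function(policy, obs, deterministic = FALSE,
                                      t = NULL, ...) {
  if (is.null(t)) stop("sine_policy requires the time argument t")
  cbind(policy$ankle_amp * sin(2 * pi * policy$frequency_f * t),
        policy$hip_amp * sin(2 * pi * policy$frequency_f * (t - policy$hip_lag)))[
          rep(1, nrow(obs)), , drop = FALSE]
}

#' @rdname zero_policy
#' @param f Function `(obs, t)` returning a normalized action vector/matrix.
#' @export
scripted_policy <- function(f) {
  structure(list(f = f), class = c("scripted_policy", "postcoord_policy"))
}

#' @export
policy_action.scripted_policy <- function(policy, obs, deterministic = FALSE,
                                          t = NULL, ...) {
  a <- policy$f(obs, t)
  if (is.null(dim(a))) a <- matrix(a, nrow = nrow(obs), byrow = nrow(obs) > 1)
  a
}
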