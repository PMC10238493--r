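# Shared builders for the test suite. Everything is generated in code;
# no stored fixtures.

default_params <- function(...) derive_segment_parameters(...)

# A conservatively stabilized plant (stiff springs, no damping) whose
# upright equilibrium is Lyapunov-stable, for conservation/oscillation tests
# that need bounded trajectories away from the joint limits.
stiff_params <- function(k = 2000, damping = 0) {
  derive_segment_parameters(ankle_stiffness = k, hip_stiffness = k,
                            ankle_damping = damping, hip_damping = damping)
}

# Hand-tuned PD tracking controller; balances the default plant and tracks
# the target well enough to exercise evaluation plumbing without training.
pd_policy <- function(kp_a = 6, kd_a = 1.5, k_err = 2, kp_h = 1, kd_h = 0.3) {
  scripted_policy(function(obs, t) {
    cbind(-(kp_a * obs[, 1] + kd_a * obs[, 3]) + k_err * obs[, 7],
          -(kp_h * obs[, 2] + kd_h * obs[, 4]))
  })
}

expect_close <- function(object, expected, tol = 1e-8) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("max abs diff %g > tol %g",
                              max(abs(object - expected)), tol))
}
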