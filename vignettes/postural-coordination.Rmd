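---
title: "Self-organizing hip-ankle postural coordination: model, learner and metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-organizing hip-ankle postural coordination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(postcoord)
```

## The scientific question

Standing humans tracking a moving visual target with the head recruit two
distinct hip-ankle coordination modes: *in-phase* (hip and ankle joint angles
oscillate together; the whole body leans as one inverted pendulum) at low
target frequencies, and *anti-phase* (hip counter-rotates against the ankle)
at high frequencies, where trunk inertia must be compensated to keep the
centre of mass over the feet. The transition between the modes is a
self-organized phenomenon: nobody instructs the switch, it emerges from the
interplay of task demand, body mechanics and effort.

This package reproduces that emergence *without a body model*: a planar
standing plant learns the head-tracking task by model-free deep reinforcement
learning (PPO), and the coordination mode is read off the learned behaviour
with the same indices used in the human-movement literature (joint-angle
correlation, cycle-based relative phase, centre-of-pressure statistics,
energy cost).

## The plant

The standing body is reduced to a planar two-link inverted pendulum in the
sagittal plane: a lumped leg segment pinned to the ground at the ankle, and a
head-arms-trunk (HAT) segment articulated at the hip. This is the effective
system of the mirrored-leg humanoid the study design calls for: with both
legs receiving identical commands, the lateral degrees of freedom are inert
and the sagittal dynamics are those of a double inverted pendulum.

`derive_segment_parameters()` builds the plant from three aggregate subject
measurements (default: mass 40.15 kg, height 1.57 m, upright CoM height
0.814 m). Segment masses and lengths follow fixed anthropometric fractions
(legs 32 % of body mass, HAT 68 %, leg length 53 % of stature, leg CoM at
45 % of leg length, segment radii of gyration 30 % of segment length); the
HAT CoM offset above the hip is then *solved* so the upright whole-body CoM
height matches the subject value exactly. Only aggregates are published for
the reference subject, so the split is a modelling choice; any error it
introduces moves segment inertias by a few percent, far below the behavioural
effects studied.

Dynamics are the standard two-link manipulator equations
`M(q) q'' + C(q, q') q' + G(q) = tau_active + tau_passive` with passive
spring-dampers at both joints (`tau_passive = -K (q - q_neutral) - D q'`),
defaults 25 Nm/rad (ankle) and 125 Nm/rad (hip) stiffness and 2 Nm s/rad
damping. Damping is unreported in the source setting; 2 Nm s/rad is a small,
physiologically plausible value that keeps passive oscillations realistic,
and it is exposed in the configuration. Active torques saturate at
±100 Nm. Joint excursions are limited to (−50°, 50°) at the ankle and
(−120°, 45°) at the hip by a soft clamp (angle pinned to the bound, velocity
zeroed, occurrence flagged) — a deliberate simplification of joint-stop
contact. A fall is declared when the HAT CoM height drops below 1 m, and the
per-step reward is then overridden to −1.

Integration is fixed-step RK4 at 240 Hz with the controller acting at 60 Hz
(decimation 4). The integrator conserves mechanical energy to better than
1e-6 relative over 10 s in the undamped, unactuated case (checked in the
test suite, which also verifies the mass-matrix symmetry/positive
definiteness and the `dM/dt - 2C` skew-symmetry identity).

The centre of pressure is computed from a free-body balance of the massless
foot: the total ankle torque required by inverse dynamics at the current
accelerations divided by the vertical ground reaction (weight plus segment
vertical inertia forces), reported in metres relative to the ankle (the
natural reference for a pinned-ankle plant; the static limit is the CoM
ground projection). Because the ankle is pinned, the stay-in-place reward
term is identically at its maximum; it is retained in the reward so the
formula keeps its published four-term shape and generalizes to a
sliding-foot plant.

## Task and reward

The head tracks `x(t) = -A cos(2 pi f t) + A` (amplitude default
A = 0.1 m, so the target sweeps [0, 0.2] m); in chirp mode the frequency
grows linearly and the target follows the accumulated phase. The per-step
reward is

    R = alpha R_stay + beta R_target + gamma R_energy + gamma R_torque
    R_stay   = (1 + ||Pf0 - Pft||^2)^-1
    R_target = (1 + (x_target - x_head)^2)^-1
    R_energy = -sum_j |tau_j omega_j| dt
    R_torque = -sum_j tau_j^2

with the fall override to −1 described above. One deliberate reading: the
energy term is dt-scaled while the torque term is not, exactly as printed in
the source formulas; the asymmetry is preserved.

Two reward constants are not published and had to be fixed here:

* **Torque units in the penalties.** Taken literally in newton-metres, the
  torque penalty at the published weights (`gamma` up to 40) reaches
  thousands of reward units per step against a tracking term bounded by
  `beta`; falling immediately (−1) would then dominate any tracking policy,
  contradicting the successful tracking the study reports. The penalties
  must act on torques commensurate with O(1) — i.e. normalized actuator
  commands. `reward_weights()` therefore carries a `torque_scale` divisor
  applied to the two penalty terms only: 1 by default (the printed formulas,
  used by all worked examples) and set to the 100 Nm torque limit for
  training, so penalties act on normalized torques in [−1, 1].
* **alpha and beta.** With the pinned ankle, `R_stay` is constant, so only
  `beta/gamma` matters. `alpha = 1, beta = 5` makes the tracking term
  dominate the stay term while keeping the energy penalty influential over
  the published `gamma` range — which is essential: the mode *selection*
  (Experiment 2's gamma sweep) works precisely because the energy terms can
  out-compete the mode-indifferent part of the tracking reward. Raising
  `beta` by an order of magnitude improves tracking amplitude but was found
  to destroy the energy-driven mode selection at low frequency; the default
  keeps the published phenomenology at the cost of under-tracked amplitude
  at desk scale (see Limitations).

The observation fed to the policy is the 8-vector
`(theta_ankle, theta_hip, omega_ankle, omega_hip, head_x, head_vx,
x_target - head_x, v_target)`; the published work does not document its
state vector, so this is the minimal proprioceptive + task-error choice.

## The PPO learner

`ppo_train()` is a from-scratch actor-critic PPO implementation (dense tanh
networks, manual backpropagation, Adam): the clipped surrogate
`min(w A, clip(w, 1-eps, 1+eps) A)` with probability ratio
`w = pi_new/pi_old`, a squared-error critic loss, and generalized advantage
estimation (discount 0.99, lambda 0.95 — the estimator is not specified in
the source and GAE is the field default). The action distribution is a
diagonal Gaussian with a learned state-independent log-std (initial std 0.2,
bounded in [e^-4, e], with a small entropy bonus, coefficient 1e-3); actions live in [−1, 1] and are scaled by the torque
limit in the environment. The learning rate adapts to hold the per-update
analytic Gaussian KL near the 0.002 threshold (halve above 2×, grow 1.5×
below 0.5×, bounds [1e-6, 1e-2]) — the published configuration names only
the threshold, so the rule follows common adaptive-KL practice. Advantages
are normalized per update; rewards are scaled by 0.01 inside the learner so
critic targets are O(1) (reported returns are unscaled). Gradients are
clipped at global norm 1. Training is bit-reproducible per seed.

Two profiles bundle the scale-dependent settings:

| setting | `paper` | `desk` (default) |
|---|---|---|
| environments | 8192 | 64 |
| minibatch | 8192 | 2048 |
| hidden layers | 256, 256 | 64, 64 |
| total steps | 5,000,000 | 300,000 |
| horizon / epochs / KL threshold | 32 / 5 / 0.002 | same |

The desk profile exists so the full pipeline (training included) runs on a
single CPU in tens of seconds per condition; the published scale is
selectable but not the default. The desk network is also narrowed — an
8-dimensional observation does not need 256-unit layers, and the smaller
network trains faster and more stably at small batch sizes.

## Coordination metrics

All indices are computed on the steady-state window after discarding the
first 2 target periods (whether the source removed transients is unstated;
discarding 2 periods is conservative and configurable):

* **Hip-ankle correlation**: Pearson r between the two joint-angle series;
  positive = in-phase, negative = anti-phase. A dead band of |r| < 0.1
  labels the mode "ambiguous" rather than letting noise pick a sign.
* **Relative phase**: per cycle, the times of the maximum ankle and hip
  angles are found (one argmax per target cycle, refined by a least-squares
  parabola over ±1/8 cycle, after light moving-average smoothing — raw
  argmax times on noisy angles are biased by the flat sinusoid peak) and
  combined as `|t0 - t1| * f * pi`, the study's printed formula, averaged
  over cycles. Note this yields pi/2, not pi, for a half-period lag; the
  conventional `2 pi f |t0 - t1|` is reported alongside. The formula is
  dimensionally consistent only if the peak times are in seconds, so seconds
  are used.
* **Amplitudes**: head amplitude is the mean per-cycle half range of the
  head trace (consistent with published amplitudes of ~0.078-0.083 m against
  A = 0.1 m); joint excursions are reported peak-to-peak; torque amplitudes
  as per-cycle half ranges.
* **Energy cost**: `sum |tau omega| dt` in joules over the window.
* **CoP statistics**: five-number (Tukey) summary for box plots.
* **Windowed correlation and transition frequency**: sliding Pearson r
  (default window 300 control steps = 5 s) against the instantaneous chirp
  frequency; the transition frequency is the first zero crossing, linearly
  interpolated between bracketing windows.

## The synthetic fixture generator

`gen_coordination_pair()` emits joint-angle logs with *prescribed* frequency,
amplitudes, hip-ankle lag and noise: `ankle = a sin(2 pi f t)`,
`hip = b sin(2 pi f (t - lag))` plus seeded Gaussian angle noise, velocities
as analytic derivatives, torques as passive-stiffness proxies (`-k theta`,
explicitly non-dynamic), and the head position through the plant's true
forward kinematics. `gen_mode_switch_series()` adds a chirp whose hip lag
flips to half a period at a programmed frequency. The generator's parameters
are the ground truth for the metrics layer: the test suite demands the
correlation sign always, the lag within 5 % and the amplitudes within 3 %
back from noisy fixtures (noise up to 5 % of amplitude), and the programmed
transition frequency within one window stride. What the fixtures do *not*
emulate: learned-policy idiosyncrasies such as transients, asymmetric cycles
or amplitude drift — passing the recovery suite shows the metrics are
correct, not that trained policies are well-behaved.

## Experiment drivers

`run_sweep()` reproduces the four study designs as configuration-driven
sweeps: target frequency (0.15-1.50 Hz), energy weight gamma (0-40), hip
stiffness (25-200 Nm/rad, at f = 0.5 Hz, gamma = 20, retrained per
stiffness), and added upper-body mass (0-4 kg, *evaluation-only* transfer of
one policy trained across the ten fixed frequencies — no retraining, mirroring
the transfer design). `sweep_values()` exposes the full published condition
lists; desk-scale work uses subsets. Each (condition, seed) row trains,
evaluates one deterministic episode (50 s desk / 100 s paper) and stores the
full coordination summary; failures are recorded rather than dropped, and
completed rows are cached by configuration hash. `run_chirp_eval()` runs the
continuous-frequency probe (0.036 Hz/s over 25 s by default) and reports the
windowed-correlation transition frequency. `make_report()` renders the
standard tables, correlation/phase curves, CoP box plots and the stiffness ×
frequency correlation heat map.

Sign claims (in-phase at low frequency, anti-phase at high frequency; energy
decreasing in gamma) are made per condition by majority over 3 seeds — the
source reports single runs, but a desk-scale stochastic learner needs
replication for a defensible claim.

## Problem sizes and what the tests show

The test suite trains desk-profile policies (64 environments, 300k-600k
steps — roughly 30-60 s per run on one CPU core) at two frequencies and two
energy weights, three seeds each. At this scale the published *phenomenology*
reproduces: positive hip-ankle correlation at 0.2 Hz, negative at 1.2 Hz,
high target-head correlation in converged runs, and lower energy cost at
gamma = 20 than gamma = 0. The published *numbers* (e.g. r = 0.9984 at
0.15 Hz, transition at 0.69 Hz, energy 1632 J to 287 J) belong to the
5M-step, 8192-environment profile and are reproduced here only in sign and
order of magnitude.

## Known limitations

* Desk-scale policies under-track at high frequency: head amplitude
  ~0.02-0.04 m at 1.2 Hz against the published ~0.08 m. The mode signs are
  robust to this, the amplitude numbers are not.
* The plant is planar with a pinned ankle: no foot lift-off, no ground
  friction or gripping limits, no knee/neck, no lateral dynamics.
* The reward's torque normalization and alpha/beta are reconstructions (see
  above); absolute reward magnitudes are therefore not comparable with the
  source, only the induced behaviour is.
* Relative phase uses the study's printed formula; compare its values with
  the conventional phase lag via the `relative_phase_conventional` field,
  not across conventions.
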