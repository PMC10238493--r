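# postcoord

Self-organizing hip–ankle postural coordination through deep reinforcement
learning, in R.

## The problem

A standing person tracking a moving target with the head coordinates the hip
and ankle in one of two modes: **in-phase** (both joints swing together — the
"ankle strategy") at low target frequencies, and **anti-phase** (the hip
counter-rotates against the ankle — the "hip strategy") at high frequencies,
where trunk inertia must be cancelled to keep the centre of mass over the
feet. The switch between modes is self-organized: it emerges from task
demand, body mechanics and effort, not from an explicit instruction.

`postcoord` reproduces this emergence with no prior body model. It provides:

* a **planar two-link standing plant** (lumped legs pinned at the ankle +
  head-arms-trunk segment at the hip) with passive joint stiffness/damping,
  ±100 Nm torque saturation, joint limits, RK4 dynamics at 240 Hz,
  centre-of-pressure output and a 1 m trunk-height fall rule;
* a **head-tracking task**: the target moves as
  `x(t) = −A·cos(2πft) + A` (A = 0.1 m), and the per-step reward is
  `α·R_stay + β·R_target + γ·R_energy + γ·R_torque`, with
  `R_target = (1 + (x_target − x_head)²)⁻¹`,
  `R_energy = −Σ|τ_j ω_j|Δt`, `R_torque = −Σ τ_j²`, and the total overridden
  to −1 on a fall;
* a **from-scratch PPO learner** (clipped surrogate
  `min(ωÂ, clip(ω, 1−ε, 1+ε)Â)`, GAE, adaptive-KL learning rate at the 0.002
  threshold, Table-style hyper-parameters: horizon 32, 5 epochs) written in
  base R with hand-derived backpropagation — no deep-learning dependency;
* the **coordination metrics** of the motor-control literature: hip–ankle
  Pearson correlation (sign = mode), cycle-based relative phase
  `|t0 − t1|·f·π`, per-cycle amplitudes, energy cost, CoP box statistics,
  sliding-window correlation and the chirp transition frequency;
* **experiment drivers** for the four study designs (frequency sweep, energy
  weight γ sweep, hip-stiffness sweep, added-mass transfer) plus the
  stiffness × frequency grid, and a **synthetic fixture generator** that lets
  the whole analysis layer be tested with zero training.

## Worked example

Train a desk-scale policy at a low tracking frequency, evaluate it, and read
off the coordination mode (about a minute on one CPU core):

```r
library(postcoord)

params <- derive_segment_parameters()        # 40.15 kg, 1.57 m subject
task   <- task_spec(frequency_f = 0.2)       # 0.2 Hz target, A = 0.1 m
w      <- reward_weights(alpha = 1, beta = 5, gamma = 20,
                         torque_scale = params$torque_limit)

fit <- ppo_train(make_tracking_env(task, params, w),
                 ppo_config(profile = "desk", total_steps = 6e5, seed = 1))
log <- run_episode(fit, task_spec(frequency_f = 0.2, episode_duration = 50),
                   params, w, seed = 1, deterministic = TRUE)
summarize_episode(log, attr(log, "spec"))
```

```
Coordination summary (f = 0.2 Hz, 40.0 s window, 7 cycles)
  hip-ankle r = +0.9865  [in_phase],  relative phase = 0.084 rad (conventional 0.168)
  p2p ankle/hip = 0.0450 / 0.0673 rad,  torque amp = 9.84 / 1.08 Nm
  tracking r = 0.9849,  head amplitude = 0.0600 m,  mean |head vel| = 0.0488 m/s
  energy cost = 4.3 J,  CoP quartiles [m]: -0.029 -0.0211 -0.0021 0.0169 0.0248
```

Reading the summary: the hip–ankle correlation of +0.99 classifies the
learned behaviour as in-phase (the ankle-strategy whole-body lean humans use
at 0.2 Hz), the tracking correlation of 0.98 confirms the head follows the
target, and the tiny hip torque amplitude (1.1 Nm against 9.8 Nm at the
ankle) shows the ankle doing the work. Retraining with `frequency_f = 1.2`
flips the correlation negative (anti-phase), with larger hip excursions and
torques. No metrics require training: the same summary
runs on synthetic fixtures from `gen_coordination_pair()`, and
`run_sweep()` / `run_chirp_eval()` / `make_report()` drive the full
experiment tables and figures.

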