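test_that("segment derivation reproduces the subject aggregates", {
  p <- derive_segment_parameters(40.15, 1.57, 0.814)
  com <- (p$leg_mass * p$leg_com_distance +
            p$trunk_mass * (p$leg_length + p$trunk_com_distance)) / p$total_mass
  expect_close(com, 0.814, tol = 1e-6)
  expect_close(p$leg_mass + p$trunk_mass, 40.15, tol = 1e-12)
  expect_equal(p$head_distance + p$leg_length, 1.57)
  expect_equal(p$torque_limit, 100)
  expect_equal(p$ankle_angle_range, c(-50, 50) * pi / 180)
  expect_equal(p$hip_angle_range, c(-120, 45) * pi / 180)

  # masses scale linearly with total mass, lengths are untouched
  p2 <- derive_segment_parameters(80.30, 1.57, 0.814)
  expect_close(p2$leg_mass, 2 * p$leg_mass, tol = 1e-12)
  expect_close(p2$trunk_mass, 2 * p$trunk_mass, tol = 1e-12)
  expect_equal(p2$leg_length, p$leg_length)
  expect_equal(p2$trunk_com_distance, p$trunk_com_distance)

  expect_error(derive_segment_parameters(40.15, 1.57, 1.56),
               "infeasible geometry")
  expect_error(derive_segment_parameters(40.15, 1.57, 0.30),
               "infeasible geometry")
})

test_that("forward kinematics matches direct trigonometry", {
  p <- default_params()
  up <- forward_kinematics(plant_state(0, 0), p)
  expect_close(up$head_x, 0, tol = 1e-15)
  expect_close(up$head_z, p$total_height, tol = 1e-12)
  expect_false(up$fallen)

  quarter <- forward_kinematics(plant_state(pi / 2, 0), p)
  expect_close(quarter$head_z, 0, tol = 1e-12)
  expect_close(quarter$head_x, p$total_height, tol = 1e-12)
  expect_true(quarter$fallen)

  # independent symbolic-geometry recomputation on random small angles
  set.seed(42)
  for (i in 1:20) {
    t1 <- stats::runif(1, -0.3, 0.3); t2 <- stats::runif(1, -0.5, 0.3)
    fk <- forward_kinematics(plant_state(t1, t2), p)
    hx <- p$leg_length * sin(t1) + (p$total_height - p$leg_length) * sin(t1 + t2)
    hz <- p$leg_length * cos(t1) + (p$total_height - p$leg_length) * cos(t1 + t2)
    m2 <- p$trunk_mass
    cx <- (p$leg_mass * p$leg_com_distance * sin(t1) +
             m2 * (p$leg_length * sin(t1) + p$trunk_com_distance * sin(t1 + t2))) /
      (p$leg_mass + m2)
    expect_close(fk$head_x, hx, tol = 1e-12)
    expect_close(fk$head_z, hz, tol = 1e-12)
    expect_close(fk$com_x, cx, tol = 1e-12)
  }
})

test_that("upright neutral state with zero torque is an equilibrium", {
  p <- default_params()
  s <- plant_state(0, 0, 0, 0)
  out <- step_dynamics(s, c(0, 0), p, 1 / 240)
  expect_close(out$state$theta_ankle, 0, tol = 1e-14)
  expect_close(out$state$theta_hip, 0, tol = 1e-14)
  expect_close(out$state$omega_ankle, 0, tol = 1e-14)
  expect_close(out$state$omega_hip, 0, tol = 1e-14)
})

test_that("commanded torques are saturated at the +/-100 Nm limit", {
  p <- default_params()
  s <- plant_state(0.01, -0.01)
  out <- step_dynamics(s, c(250, -250), p, 1 / 240)
  expect_equal(out$mechanics$ankle_torque_applied, 100)
  expect_equal(out$mechanics$hip_torque_applied, -100)
  out2 <- step_dynamics(s, c(-3000, 42), p, 1 / 240)
  expect_equal(out2$mechanics$ankle_torque_applied, -100)
  expect_equal(out2$mechanics$hip_torque_applied, 42)
})

test_that("undamped unactuated dynamics conserve mechanical energy", {
  p <- stiff_params()   # stable upright equilibrium, bounded oscillation
  s <- plant_state(0.05, -0.03)
  e0 <- plant_energy(s, p)
  for (i in 1:10000) s <- step_dynamics(s, c(0, 0), p, 1e-3)$state
  expect_lt(abs(plant_energy(s, p) - e0) / abs(e0), 1e-6)
})

test_that("damping strictly dissipates energy", {
  p <- stiff_params(damping = 5)
  s <- plant_state(0.05, -0.03)
  e <- plant_energy(s, p)
  for (i in 1:10) {
    for (j in 1:100) s <- step_dynamics(s, c(0, 0), p, 1e-3)$state
    e_new <- plant_energy(s, p)
    expect_lt(e_new, e)
    e <- e_new
  }
})

test_that("mass matrix is symmetric positive definite; dM/dt - 2C is skew", {
  p <- default_params()
  set.seed(7)
  for (i in 1:25) {
    s <- plant_state(stats::runif(1, -0.8, 0.8), stats::runif(1, -2, 0.7),
                     stats::runif(1, -3, 3), stats::runif(1, -3, 3))
    M <- mass_matrix(s, p)
    expect_equal(M[1, 2], M[2, 1])
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))

    # dM/dt by finite difference of the configuration along the velocity
    h <- 1e-7
    s2 <- plant_state(s$theta_ankle + h * s$omega_ankle,
                      s$theta_hip + h * s$omega_hip,
                      s$omega_ankle, s$omega_hip)
    Mdot <- (mass_matrix(s2, p) - M) / h
    N <- Mdot - 2 * coriolis_matrix(s, p)
    expect_close(N + t(N), matrix(0, 2, 2), tol = 1e-5)
  }
})

test_that("hip-locked hanging small oscillation matches the compound-pendulum frequency", {
  p <- derive_segment_parameters(ankle_stiffness = 25, hip_stiffness = 1e4,
                                 ankle_damping = 0, hip_damping = 0)
  p$gravity <- -9.81   # hang the chain below the pivot: stable configuration
  m2t <- p$trunk_mass
  I_total <- p$leg_mass * p$leg_com_distance^2 + p$leg_inertia +
    m2t * (p$leg_length^2 + p$trunk_com_distance^2 +
             2 * p$leg_length * p$trunk_com_distance) + p$trunk_inertia
  restoring <- 9.81 * (p$leg_mass * p$leg_com_distance +
                         m2t * (p$leg_length + p$trunk_com_distance)) +
    p$ankle_stiffness
  f_expected <- sqrt(restoring / I_total) / (2 * pi)

  s <- plant_state(0.02, 0)
  dt <- 1 / 240
  th <- numeric(4800)
  for (i in seq_along(th)) {
    s <- step_dynamics(s, c(0, 0), p, dt)$state
    th[i] <- s$theta_ankle
  }
  crossings <- which(th[-1] > 0 & th[-length(th)] <= 0)
  periods <- diff(crossings) * dt
  f_measured <- 1 / mean(periods)
  expect_lt(abs(f_measured - f_expected) / f_expected, 0.01)
})

test_that("static CoP equals the CoM projection and its small-angle form", {
  p <- default_params()
  s <- plant_state(0.1, 0)
  cop <- compute_cop(s, c(0, 0), p)
  expect_close(cop, forward_kinematics(s, p)$com_x, tol = 1e-12)
  s2 <- plant_state(0.02, 0)
  expect_close(compute_cop(s2, c(0, 0), p),
               p$standing_com_height * 0.02, tol = 1e-4)
})

test_that("dynamic CoP matches an independent Newton-Euler free-body oracle", {
  p <- default_params()
  set.seed(11)
  for (i in 1:15) {
    s <- plant_state(stats::runif(1, -0.4, 0.4), stats::runif(1, -0.8, 0.4),
                     stats::runif(1, -2, 2), stats::runif(1, -2, 2))
    tau <- stats::runif(2, -80, 80)
    spring <- c(-p$ankle_stiffness * s$theta_ankle - p$ankle_damping * s$omega_ankle,
                -p$hip_stiffness * s$theta_hip - p$hip_damping * s$omega_hip)
    qdd <- solve(mass_matrix(s, p),
                 tau + spring - coriolis_matrix(s, p) %*%
                   c(s$omega_ankle, s$omega_hip) - gravity_torque(s, p))

    # Oracle: rate of change of angular momentum about the ankle.
    t1 <- s$theta_ankle; t12 <- t1 + s$theta_hip
    o1 <- s$omega_ankle; o12 <- o1 + s$omega_hip
    a1 <- qdd[1]; a12 <- qdd[1] + qdd[2]
    seg <- function(m, x, z, xdd, zdd, I, alpha) {
      list(dL = m * (z * xdd - x * zdd) + I * alpha,
           fz = m * (p$gravity + zdd), mg_x = m * p$gravity * x)
    }
    l1 <- p$leg_length; lc1 <- p$leg_com_distance; lc2 <- p$trunk_com_distance
    leg <- seg(p$leg_mass, lc1 * sin(t1), lc1 * cos(t1),
               lc1 * (cos(t1) * a1 - sin(t1) * o1^2),
               -lc1 * (sin(t1) * a1 + cos(t1) * o1^2),
               p$leg_inertia, a1)
    trk <- seg(p$trunk_mass,
               l1 * sin(t1) + lc2 * sin(t12),
               l1 * cos(t1) + lc2 * cos(t12),
               l1 * (cos(t1) * a1 - sin(t1) * o1^2) +
                 lc2 * (cos(t12) * a12 - sin(t12) * o12^2),
               -l1 * (sin(t1) * a1 + cos(t1) * o1^2) -
                 lc2 * (sin(t12) * a12 + cos(t12) * o12^2),
               p$trunk_inertia, a12)
    tau_ankle_total <- (leg$dL + trk$dL) - (leg$mg_x + trk$mg_x)
    fz <- leg$fz + trk$fz
    cop_oracle <- -tau_ankle_total / fz

    expect_close(compute_cop(s, qdd, p), cop_oracle, tol = 1e-9)
  }
})

test_that("degenerate inputs raise explicit errors", {
  p <- default_params()
  s <- plant_state(0, 0)
  expect_error(step_dynamics(s, c(0, 0), p, 0.1), "dt")
  expect_error(step_dynamics(s, c(NaN, 0), p, 1 / 240), "finite")
  # airborne/invalid: acceleration pattern that unloads the feet
  expect_error(compute_cop(plant_state(0.3, 0), c(500, 0), p), "ground reaction")
})

test_that("joint-limit clamp zeroes velocity at the bound and flags it", {
  p <- default_params()
  s <- plant_state(p$ankle_angle_range[2] - 1e-4, 0, 5, 0)
  out <- step_dynamics(s, c(100, 0), p, 1 / 240)
  expect_equal(out$state$theta_ankle, p$ankle_angle_range[2])
  expect_equal(out$state$omega_ankle, 0)
  expect_true(out$mechanics$clamped)
})
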