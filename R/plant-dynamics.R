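# Two-link manipulator dynamics of the planar standing model.
#
# Generalized coordinates q = (theta_ankle, theta_hip): absolute leg angle
# from vertical and relative HAT angle at the hip. Equations of motion
#   M(q) qdd + C(q, qd) qd + G(q) = tau_active + tau_passive,
# with tau_passive = -K (q - q_neutral) - D qd, the ankle pinned to the
# ground, and gravity destabilizing (G is the gradient of the gravitational
# potential of the inverted configuration). All internal routines are
# elementwise-vectorized over a batch of states.

# Constant dynamic coefficients; m2t includes any added payload at the HAT CoM.
plant_coefficients <- function(params) {
  m2t <- params$trunk_mass + params$added_mass
  l1 <- params$leg_length
  lc1 <- params$leg_com_distance
  lc2 <- params$trunk_com_distance
  list(
    a1 = params$leg_mass * lc1^2 + params$leg_inertia + m2t * l1^2,
    a2 = m2t * lc2^2 + params$trunk_inertia,
    a3 = m2t * l1 * lc2,
    g1 = (params$leg_mass * lc1 + m2t * l1) * params$gravity,
    g2 = m2t * lc2 * params$gravity,
    m2t = m2t
  )
}

#' Mass matrix of the two-link model
#'
#' @param state A `plant_state` (single configuration).
#' @param params A `plant_params` object.
#' @return The symmetric positive-definite 2x2 inertia matrix (kg m^2).
#' @export
mass_matrix <- function(state, params) {
  k <- plant_coefficients(params)
  c2 <- cos(state$theta_hip[1])
  matrix(c(k$a1 + k$a2 + 2 * k$a3 * c2, k$a2 + k$a3 * c2,
           k$a2 + k$a3 * c2, k$a2), 2, 2)
}

#' Coriolis/centrifugal matrix of the two-link model
#'
#' Christoffel form, so that `d(M)/dt - 2 C` is skew-symmetric.
#'
#' @inheritParams mass_matrix
#' @return The 2x2 Coriolis matrix (kg m^2 / s).
#' @export
coriolis_matrix <- function(state, params) {
  k <- plant_coefficients(params)
  h <- -k$a3 * sin(state$theta_hip[1])
  o1 <- state$omega_ankle[1]; o2 <- state$omega_hip[1]
  matrix(c(h * o2, -h * o1,
           h * (o1 + o2), 0), 2, 2)
}

#' Gravity torque vector of the two-link model
#'
#' Gradient of the gravitational potential with respect to the joint angles;
#' negative for forward lean (gravity topples the inverted pendulum).
#'
#' @inheritParams mass_matrix
#' @return Length-2 numeric (Nm), to be placed on the left-hand side of the
#'   equations of motion.
#' @export
gravity_torque <- function(state, params) {
  k <- plant_coefficients(params)
  t1 <- state$theta_ankle[1]; t12 <- t1 + state$theta_hip[1]
  c(-k$g1 * sin(t1) - k$g2 * sin(t12), -k$g2 * sin(t12))
}

# Vectorized joint accelerations given TOTAL applied torques (active+passive
# already summed). th/om/tau are equal-length numeric vectors.
plant_accel <- function(k, th1, th2, om1, om2, tau1, tau2) {
  c2 <- cos(th2); s2 <- sin(th2)
  m11 <- k$a1 + k$a2 + 2 * k$a3 * c2
  m12 <- k$a2 + k$a3 * c2
  m22 <- k$a2
  h <- -k$a3 * s2
  s1 <- sin(th1); s12 <- sin(th1 + th2)
  rhs1 <- tau1 - (h * om2 * om1 + h * (om1 + om2) * om2) - (-k$g1 * s1 - k$g2 * s12)
  rhs2 <- tau2 - (-h * om1 * om1) - (-k$g2 * s12)
  det <- m11 * m22 - m12 * m12
  list(a1 = (m22 * rhs1 - m12 * rhs2) / det,
       a2 = (m11 * rhs2 - m12 * rhs1) / det)
}

# Passive spring-damper torques (vectorized).
passive_torque <- function(params, th1, th2, om1, om2) {
  list(p1 = -params$ankle_stiffness * (th1 - params$neutral_angles[1]) -
         params$ankle_damping * om1,
       p2 = -params$hip_stiffness * (th2 - params$neutral_angles[2]) -
         params$hip_damping * om2)
}

# One fixed-step RK4 integration of the batch state under constant active
# torques; passive torques are re-evaluated at every stage.
rk4_substep <- function(k, params, th1, th2, om1, om2, act1, act2, dt) {
  deriv <- function(th1, th2, om1, om2) {
    p <- passive_torque(params, th1, th2, om1, om2)
    a <- plant_accel(k, th1, th2, om1, om2, act1 + p$p1, act2 + p$p2)
    list(d1 = om1, d2 = om2, d3 = a$a1, d4 = a$a2)
  }
  k1 <- deriv(th1, th2, om1, om2)
  k2 <- deriv(th1 + dt / 2 * k1$d1, th2 + dt / 2 * k1$d2,
              om1 + dt / 2 * k1$d3, om2 + dt / 2 * k1$d4)
  k3 <- deriv(th1 + dt / 2 * k2$d1, th2 + dt / 2 * k2$d2,
              om1 + dt / 2 * k2$d3, om2 + dt / 2 * k2$d4)
  k4 <- deriv(th1 + dt * k3$d1, th2 + dt * k3$d2,
              om1 + dt * k3$d3, om2 + dt * k3$d4)
  list(th1 = th1 + dt / 6 * (k1$d1 + 2 * k2$d1 + 2 * k3$d1 + k4$d1),
       th2 = th2 + dt / 6 * (k1$d2 + 2 * k2$d2 + 2 * k3$d2 + k4$d2),
       om1 = om1 + dt / 6 * (k1$d3 + 2 * k2$d3 + 2 * k3$d3 + k4$d3),
       om2 = om2 + dt / 6 * (k1$d4 + 2 * k2$d4 + 2 * k3$d4 + k4$d4))
}

#' Advance the plant by one integration step
#'
#' Integrates the two-link equations of motion with a fixed-step fourth-order
#' Runge-Kutta scheme under constant active torques. Commanded torques are
#' saturated to `+/- torque_limit` before use; after the step, joint angles
#' are softly clamped to their configured ranges (velocity zeroed at the
#' bound, occurrence flagged).
#'
#' @param state A `plant_state` (scalar or batch).
#' @param active_torques Commanded ankle/hip torques (Nm). For a scalar state
#'   a length-2 numeric; for a batch, a list/matrix with ankle and hip
#'   components of the batch length.
#' @param params A `plant_params` object.
#' @param dt Integration step (s), in (0, 0.05].
#' @return A list with `state` (the new `plant_state`) and `mechanics` (the
#'   [forward_kinematics()] output augmented with applied torques, centre of
#'   pressure and fall flag; see [compute_cop()]).
#' @export
step_dynamics <- function(state, active_torques, params, dt) {
  if (!(dt > 0 && dt <= 0.05)) stop("dt must be in (0, 0.05]")
  if (is.list(active_torques)) {
    act1 <- active_torques[[1]]; act2 <- active_torques[[2]]
  } else {
    act1 <- active_torques[1]; act2 <- active_torques[2]
  }
  if (!all(is.finite(act1)) || !all(is.finite(act2)))
    stop("active torques must be finite")
  lim <- params$torque_limit
  act1 <- pmin(pmax(act1, -lim), lim)
  act2 <- pmin(pmax(act2, -lim), lim)

  k <- plant_coefficients(params)
  s <- rk4_substep(k, params, state$theta_ankle, state$theta_hip,
                   state$omega_ankle, state$omega_hip, act1, act2, dt)

  if (!all(is.finite(s$th1)) || !all(is.finite(s$th2)) ||
      !all(is.finite(s$om1)) || !all(is.finite(s$om2)))
    stop("integration failure: non-finite state after step at t = ",
         state$time[1])

  # Soft joint-limit clamp: angle to bound, velocity zeroed there.
  ar <- params$ankle_angle_range; hr <- params$hip_angle_range
  hit1 <- s$th1 < ar[1] | s$th1 > ar[2]
  hit2 <- s$th2 < hr[1] | s$th2 > hr[2]
  s$th1 <- pmin(pmax(s$th1, ar[1]), ar[2])
  s$th2 <- pmin(pmax(s$th2, hr[1]), hr[2])
  s$om1[hit1] <- 0
  s$om2[hit2] <- 0

  new_state <- structure(list(theta_ankle = s$th1, theta_hip = s$th2,
                              omega_ankle = s$om1, omega_hip = s$om2,
                              time = state$time + dt), class = "plant_state")
  mech <- plant_mechanics(new_state, c(act1[1], act2[1]), params,
                          act1 = act1, act2 = act2)
  mech$clamped <- hit1 | hit2
  list(state = new_state, mechanics = mech)
}

# Full mechanics output for a (possibly batch) state under applied torques:
# forward kinematics, CoP from inverse dynamics at the consistent
# accelerations, and the fall flag.
plant_mechanics <- function(state, active_torques, params, act1 = NULL, act2 = NULL) {
  if (is.null(act1)) { act1 <- active_torques[1]; act2 <- active_torques[2] }
  k <- plant_coefficients(params)
  p <- passive_torque(params, state$theta_ankle, state$theta_hip,
                      state$omega_ankle, state$omega_hip)
  acc <- plant_accel(k, state$theta_ankle, state$theta_hip,
                     state$omega_ankle, state$omega_hip,
                     act1 + p$p1, act2 + p$p2)
  mech <- forward_kinematics(state, params)
  mech$ankle_torque_applied <- act1
  mech$hip_torque_applied <- act2
  mech$accel_ankle <- acc$a1
  mech$accel_hip <- acc$a2
  mech$cop_x <- cop_from_accel(state, acc$a1, acc$a2, params, k, strict = FALSE)
  mech
}

#' Forward kinematics of the standing model
#'
#' Positions of the head, whole-body CoM and HAT CoM for a given joint
#' configuration, with the ankle at the origin and z vertical.
#'
#' @inheritParams mass_matrix
#' @return A list (class `plant_mechanics`) with `head_x`, `head_z`,
#'   `head_vx`, `com_x`, `com_z`, `trunk_com_z` and the fall flag `fallen`
#'   (true iff the HAT CoM height is below `fall_height_threshold`). Each
#'   entry is a vector for batch states.
#' @export
forward_kinematics <- function(state, params) {
  t1 <- state$theta_ankle; t12 <- t1 + state$theta_hip
  o1 <- state$omega_ankle; o12 <- o1 + state$omega_hip
  l1 <- params$leg_length; lc1 <- params$leg_com_distance
  lc2 <- params$trunk_com_distance; dh <- params$head_distance
  m1 <- params$leg_mass; m2t <- params$trunk_mass + params$added_mass
  mt <- m1 + m2t

  head_x <- l1 * sin(t1) + dh * sin(t12)
  head_z <- l1 * cos(t1) + dh * cos(t12)
  head_vx <- l1 * cos(t1) * o1 + dh * cos(t12) * o12
  leg_x <- lc1 * sin(t1); leg_z <- lc1 * cos(t1)
  trk_x <- l1 * sin(t1) + lc2 * sin(t12)
  trk_z <- l1 * cos(t1) + lc2 * cos(t12)

  structure(list(
    head_x = head_x, head_z = head_z, head_vx = head_vx,
    com_x = (m1 * leg_x + m2t * trk_x) / mt,
    com_z = (m1 * leg_z + m2t * trk_z) / mt,
    trunk_com_z = trk_z,
    fallen = trk_z < params$fall_height_threshold,
    cop_x = NA_real_,
    ankle_torque_applied = NA_real_,
    hip_torque_applied = NA_real_
  ), class = "plant_mechanics")
}

# CoP from inverse dynamics (vectorized): total ankle torque required for the
# given accelerations, and vertical ground reaction from segment CoM vertical
# accelerations. cop_x = -tau_ankle_total / Fz (ankle at the ground origin).
cop_from_accel <- function(state, a1, a2, params, k = plant_coefficients(params),
                           strict = TRUE) {
  t1 <- state$theta_ankle; t2 <- state$theta_hip; t12 <- t1 + t2
  o1 <- state$omega_ankle; o2 <- state$omega_hip
  c2 <- cos(t2)
  m11 <- k$a1 + k$a2 + 2 * k$a3 * c2
  m12 <- k$a2 + k$a3 * c2
  h <- -k$a3 * sin(t2)
  tau1 <- m11 * a1 + m12 * a2 +
    h * o2 * o1 + h * (o1 + o2) * o2 +
    (-k$g1 * sin(t1) - k$g2 * sin(t12))

  l1 <- params$leg_length; lc1 <- params$leg_com_distance
  lc2 <- params$trunk_com_distance
  m1 <- params$leg_mass; m2t <- k$m2t
  o12 <- o1 + o2; a12 <- a1 + a2
  zdd_leg <- -lc1 * (cos(t1) * o1^2 + sin(t1) * a1)
  zdd_trk <- -l1 * (cos(t1) * o1^2 + sin(t1) * a1) -
    lc2 * (cos(t12) * o12^2 + sin(t12) * a12)
  fz <- (m1 + m2t) * params$gravity + m1 * zdd_leg + m2t * zdd_trk
  if (any(fz <= 0)) {
    if (strict)
      stop("vertical ground reaction force is non-positive (airborne or invalid state)")
    tau1[fz <= 0] <- NA_real_
    fz[fz <= 0] <- 1
  }
  -tau1 / fz
}

#' Centre of pressure under the feet
#'
#' Location (m, relative to the ankle, positive forward) of the resultant
#' ground-reaction force, from a free-body balance of the massless foot: the
#' total ankle torque required by inverse dynamics at the supplied joint
#' accelerations, divided by the vertical ground-reaction force (weight plus
#' segment vertical inertia forces). In the static limit the CoP equals the
#' horizontal projection of the whole-body CoM.
#'
#' @param state A `plant_state`.
#' @param accelerations Joint angular accelerations (rad/s^2): length-2
#'   numeric (ankle, hip), or a list of two vectors for batch states.
#' @param params A `plant_params` object.
#' @return CoP x-position(s) in metres. Errors if the vertical ground
#'   reaction is non-positive.
#' @export
compute_cop <- function(state, accelerations, params) {
  if (is.list(accelerations)) {
    a1 <- accelerations[[1]]; a2 <- accelerations[[2]]
  } else {
    a1 <- accelerations[1]; a2 <- accelerations[2]
  }
  cop_from_accel(state, a1, a2, params)
}

#' Total mechanical energy of the plant
#'
#' Kinetic energy plus gravitational potential (referenced to the ankle
#' plane) plus elastic energy stored in the passive joint springs. Used by
#' the integrator-accuracy checks: with zero damping and zero active torque
#' this quantity is conserved.
#'
#' @inheritParams mass_matrix
#' @return Energy in joules (vectorized over batch states).
#' @export
plant_energy <- function(state, params) {
  k <- plant_coefficients(params)
  t1 <- state$theta_ankle; t2 <- state$theta_hip
  o1 <- state$omega_ankle; o2 <- state$omega_hip
  c2 <- cos(t2)
  m11 <- k$a1 + k$a2 + 2 * k$a3 * c2
  m12 <- k$a2 + k$a3 * c2
  kin <- 0.5 * (m11 * o1^2 + 2 * m12 * o1 * o2 + k$a2 * o2^2)
  pot <- k$g1 * cos(t1) + k$g2 * cos(t1 + t2)
  ela <- 0.5 * params$ankle_stiffness * (t1 - params$neutral_angles[1])^2 +
    0.5 * params$hip_stiffness * (t2 - params$neutral_angles[2])^2
  kin + pot + ela
}
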