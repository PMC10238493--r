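#' Physical parameters of the planar standing model
#'
#' The standing humanoid is reduced to a planar two-link inverted pendulum in
#' the sagittal plane: a leg segment (both legs lumped, ankle pinned to the
#' ground) and a head-arms-trunk (HAT) segment articulated at the hip. Both
#' joints carry passive rotational stiffness toward a neutral upright posture
#' and viscous damping; active torques are saturated at `torque_limit`.
#'
#' `derive_segment_parameters()` builds a full parameter set from the three
#' aggregate quantities usually reported for a subject: total mass, total
#' height and upright whole-body centre-of-mass (CoM) height. Segment masses
#' and lengths follow fixed anthropometric fractions (legs 32% of mass, HAT
#' 68%; leg length, ankle to hip, 53% of height; leg CoM at 45% of leg length
#' above the ankle), and the HAT CoM position above the hip is then solved so
#' the upright whole-body CoM height matches `standing_com_height` exactly.
#' The head sits at `total_height`.
#'
#' @param total_mass Total body mass (kg). Default 40.15.
#' @param total_height Standing height, ankle to head (m). Default 1.57.
#' @param standing_com_height Upright whole-body CoM height above the ankle
#'   (m). Default 0.814.
#' @param added_mass Extra payload attached at the HAT CoM (kg), e.g. a
#'   backpack; not part of `total_mass`. Default 0.
#' @param ankle_stiffness,hip_stiffness Passive joint stiffness (Nm/rad).
#'   Defaults 25 and 125.
#' @param ankle_damping,hip_damping Passive joint damping (Nm s/rad).
#'   Default 2 each.
#' @param torque_limit Saturation bound on each active joint torque (Nm).
#'   Default 100.
#' @param ankle_angle_range,hip_angle_range Allowed joint excursions (rad),
#'   length-2 numeric. Defaults c(-50, 50) deg for the ankle and
#'   c(-120, 45) deg for the hip.
#' @param neutral_angles Joint angles (rad) at which the passive springs are
#'   unloaded. Default c(0, 0) = upright.
#' @param gravity Gravitational acceleration (m/s^2). Default 9.81.
#' @param fall_height_threshold HAT-CoM height (m) below which the model is
#'   judged to have fallen. Default 1.
#' @return An object of class `plant_params`: a named list with the segment
#'   decomposition (`leg_mass`, `trunk_mass`, `leg_length`,
#'   `leg_com_distance`, `trunk_com_distance`, `head_distance`,
#'   `leg_inertia`, `trunk_inertia`) alongside the arguments above.
#' @examples
#' p <- derive_segment_parameters(40.15, 1.57, 0.814)
#' p$leg_mass + p$trunk_mass  # == total mass
#' @export
derive_segment_parameters <- function(total_mass = 40.15,
                                      total_height = 1.57,
                                      standing_com_height = 0.814,
                                      added_mass = 0,
                                      ankle_stiffness = 25,
                                      hip_stiffness = 125,
                                      ankle_damping = 2,
                                      hip_damping = 2,
                                      torque_limit = 100,
                                      ankle_angle_range = c(-50, 50) * pi / 180,
                                      hip_angle_range = c(-120, 45) * pi / 180,
                                      neutral_angles = c(0, 0),
                                      gravity = 9.81,
                                      fall_height_threshold = 1) {
  stopifnot(total_mass > 0, total_height > 0, standing_com_height > 0,
            standing_com_height < total_height, added_mass >= 0)

  leg_mass_frac <- 0.32
  leg_len_frac  <- 0.53
  leg_com_frac  <- 0.45   # leg CoM position, fraction of leg length above ankle
  rog_frac      <- 0.30   # radius of gyration about segment CoM / segment length

  m1 <- leg_mass_frac * total_mass
  m2 <- (1 - leg_mass_frac) * total_mass
  l1 <- leg_len_frac * total_height
  lc1 <- leg_com_frac * l1
  head_distance <- total_height - l1

  # Solve HAT CoM distance above the hip so the upright whole-body CoM height
  # equals standing_com_height: (m1*lc1 + m2*(l1 + lc2)) / M = h_com.
  lc2 <- (total_mass * standing_com_height - m1 * lc1 - m2 * l1) / m2
  if (!is.finite(lc2) || lc2 <= 0 || lc2 >= head_distance) {
    stop("infeasible geometry: standing_com_height ", standing_com_height,
         " m cannot be realized with the anthropometric fractions ",
         "(HAT CoM would sit ", signif(lc2, 4), " m above the hip, outside (0, ",
         signif(head_distance, 4), "))")
  }

  params <- structure(list(
    total_mass = total_mass,
    total_height = total_height,
    standing_com_height = standing_com_height,
    leg_mass = m1,
    trunk_mass = m2,
    added_mass = added_mass,
    leg_length = l1,
    leg_com_distance = lc1,
    trunk_com_distance = lc2,
    head_distance = head_distance,
    leg_inertia = m1 * (rog_frac * l1)^2,
    trunk_inertia = m2 * (rog_frac * head_distance)^2,
    ankle_stiffness = ankle_stiffness,
    hip_stiffness = hip_stiffness,
    ankle_damping = ankle_damping,
    hip_damping = hip_damping,
    torque_limit = torque_limit,
    ankle_angle_range = ankle_angle_range,
    hip_angle_range = hip_angle_range,
    neutral_angles = neutral_angles,
    gravity = gravity,
    fall_height_threshold = fall_height_threshold
  ), class = "plant_params")

  validate_plant_params(params)

  # Self-check: recomputed upright CoM height must match to 1e-6 m.
  com0 <- with(params, (leg_mass * leg_com_distance +
                          trunk_mass * (leg_length + trunk_com_distance)) /
                 (leg_mass + trunk_mass))
  if (abs(com0 - standing_com_height) > 1e-6) {
    stop("internal error: recomputed upright CoM height ", com0,
         " does not match requested ", standing_com_height)
  }
  params
}

#' Validate a plant parameter set
#'
#' Checks positivity of masses, lengths, stiffness and damping, mass
#' conservation (leg + HAT mass equals total mass; `added_mass` is extra), and
#' that each joint range contains its neutral angle.
#'
#' @param params A `plant_params` object.
#' @return `params`, invisibly; errors describe the first violated constraint.
#' @export
validate_plant_params <- function(params) {
  with(params, {
    if (abs(leg_mass + trunk_mass - total_mass) > 1e-9)
      stop("segment masses must sum to total_mass (added_mass is extra)")
    pos <- c(leg_mass = leg_mass, trunk_mass = trunk_mass,
             leg_length = leg_length, leg_com_distance = leg_com_distance,
             trunk_com_distance = trunk_com_distance,
             head_distance = head_distance,
             ankle_stiffness = ankle_stiffness, hip_stiffness = hip_stiffness,
             torque_limit = torque_limit, gravity = gravity)
    if (any(pos <= 0))
      stop("non-positive parameter: ",
           paste(names(pos)[pos <= 0], collapse = ", "))
    if (ankle_damping < 0 || hip_damping < 0)
      stop("damping must be non-negative")
    if (!(neutral_angles[1] >= ankle_angle_range[1] &&
          neutral_angles[1] <= ankle_angle_range[2]))
      stop("ankle_angle_range must contain the ankle neutral angle")
    if (!(neutral_angles[2] >= hip_angle_range[1] &&
          neutral_angles[2] <= hip_angle_range[2]))
      stop("hip_angle_range must contain the hip neutral angle")
  })
  invisible(params)
}

#' @export
print.plant_params <- function(x, ...) {
  cat("Planar two-link standing model\n")
  cat(sprintf("  total mass %.2f kg (+%.2f kg payload), height %.2f m, CoM %.3f m\n",
              x$total_mass, x$added_mass, x$total_height, x$standing_com_height))
  cat(sprintf("  leg: %.2f kg, %.3f m (CoM at %.3f m); HAT: %.2f kg (CoM %.3f m above hip)\n",
              x$leg_mass, x$leg_length, x$leg_com_distance,
              x$trunk_mass, x$trunk_com_distance))
  cat(sprintf("  stiffness ankle/hip %.0f/%.0f Nm/rad, damping %.1f/%.1f Nm s/rad, torque limit %.0f Nm\n",
              x$ankle_stiffness, x$hip_stiffness,
              x$ankle_damping, x$hip_damping, x$torque_limit))
  invisible(x)
}

#' Instantaneous mechanical state of the plant
#'
#' Angles are measured from the upright neutral (rad): the ankle angle is the
#' absolute lean of the leg from vertical (positive toward +x, the tracking
#' direction); the hip angle is the HAT segment's rotation relative to the
#' leg.
#'
#' @param theta_ankle,theta_hip Joint angles (rad).
#' @param omega_ankle,omega_hip Joint angular velocities (rad/s).
#' @param time Simulation time (s).
#' @return An object of class `plant_state`. All fields may be equal-length
#'   vectors, in which case the state describes a batch of independent plants
#'   (used internally for parallel-environment training).
#' @export
plant_state <- function(theta_ankle = 0, theta_hip = 0,
                        omega_ankle = 0, omega_hip = 0, time = 0) {
  n <- max(length(theta_ankle), length(theta_hip),
           length(omega_ankle), length(omega_hip), length(time))
  s <- structure(list(
    theta_ankle = rep_len(as.numeric(theta_ankle), n),
    theta_hip = rep_len(as.numeric(theta_hip), n),
    omega_ankle = rep_len(as.numeric(omega_ankle), n),
    omega_hip = rep_len(as.numeric(omega_hip), n),
    time = rep_len(as.numeric(time), n)
  ), class = "plant_state")
  if (!all(vapply(s, function(v) all(is.finite(v)), logical(1))))
    stop("plant_state fields must be finite")
  s
}
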