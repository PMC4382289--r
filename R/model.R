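#' Construct the planar walking model
#'
#' Builds the 7-segment, 9 degree-of-freedom sagittal-plane skeleton: a lumped
#' trunk+head+arms segment (HAT) and, per leg, a thigh, shank, and foot,
#' connected by pin joints at hip, knee, and ankle. Generalized coordinates are
#' hip-point x/y, trunk pitch (positive = forward lean), then hip flexion,
#' knee flexion, and ankle dorsiflexion for the right and left legs (all
#' positive in the flexion/dorsiflexion direction).
#'
#' Segment inertial parameters default to an anthropometric reconstruction for
#' an 80 kg, 1.88 m adult (HAT 53.5 kg, thigh 8.5 kg, shank 3.5 kg, foot
#' 1.25 kg per side). The ankle is raised above the sole: the heel and ball
#' contact spheres sit 5 cm below the ankle joint in the foot frame. Joint
#' limits are one-sided nonlinear spring-dampers that engage only beyond the
#' limit angle.
#'
#' @param file optional YAML model definition; fields override the defaults.
#' @param ... named overrides applied after the file (e.g. `gravity = c(0, 0)`).
#' @return an object of class `walker_model` (a validated named list).
#' @export
walker_model <- function(file = NULL, ...) {
  m <- list(
    # trunk + head + arms (HAT); distances measured from the hip point
    m_hat = 53.5, I_hat = 3.0, d_hat = 0.35, l_hat = 0.8,
    m_thigh = 8.5, I_thigh = 0.15, d_thigh = 0.2, l_thigh = 0.5,
    m_shank = 3.5, I_shank = 0.05, d_shank = 0.2, l_shank = 0.5,
    m_foot = 1.25, I_foot = 0.005,
    foot_com = c(0.05, -0.03),
    # contact spheres in the foot frame (ankle at origin, x toward the toe)
    heel_offset = c(-0.06, -0.05), ball_offset = c(0.13, -0.05),
    sphere_radius = 0.01,
    # backpack load (attach_load fills these in)
    m_back = 0, I_back = 0, back_dx = -0.1,
    gravity = c(0, -9.80665),
    # hip, knee, ankle one-sided limits (rad); identical left/right
    limit_lower = c(-0.35, 0.0, -0.9),
    limit_upper = c(2.0, 2.5, 0.7),
    limit_stiffness = 300, limit_damping = 30,
    fall_height = 0.7
  )
  if (!is.null(file)) {
    cfg <- yaml::read_yaml(file)
    for (nm in names(cfg)) m[[nm]] <- cfg[[nm]]
  }
  dots <- list(...)
  for (nm in names(dots)) m[[nm]] <- dots[[nm]]
  m$gravity <- as.numeric(m$gravity)
  validate_walker_model(m)
  structure(m, class = "walker_model")
}

validate_walker_model <- function(m) {
  masses <- c(m$m_hat, m$m_thigh, m$m_shank, m$m_foot)
  if (any(masses <= 0)) stop("segment masses must be positive")
  if (any(c(m$I_hat, m$I_thigh, m$I_shank, m$I_foot) <= 0))
    stop("segment inertias must be positive")
  if (any(c(m$l_hat, m$l_thigh, m$l_shank) <= 0))
    stop("segment lengths must be positive")
  if (m$m_back < 0) stop("backpack mass cannot be negative")
  if (length(m$gravity) != 2) stop("gravity must be a 2-vector")
  if (any(m$limit_upper < m$limit_lower)) stop("malformed joint limits")
  invisible(m)
}

#' @export
print.walker_model <- function(x, ...) {
  cat("<walker_model> planar 7-segment, 9-DOF skeleton\n")
  cat(sprintf("  body mass %.1f kg (+ backpack %.1f kg), gravity (%.3f, %.3f) m/s^2\n",
              total_body_mass(x) - x$m_back, x$m_back,
              x$gravity[1], x$gravity[2]))
  invisible(x)
}

#' Total model mass (body plus any attached backpack load)
#' @param model a `walker_model`.
#' @return mass in kg.
#' @export
total_body_mass <- function(model) {
  model$m_hat + 2 * (model$m_thigh + model$m_shank + model$m_foot) + model$m_back
}

#' Model state constructor
#'
#' @param q 9-vector of generalized coordinates (hip x, hip y, trunk pitch,
#'   right hip/knee/ankle, left hip/knee/ankle).
#' @param qdot 9-vector of generalized velocities.
#' @param t time in seconds.
#' @return a `walker_state` list.
#' @export
walker_state <- function(q, qdot = numeric(9), t = 0) {
  q <- as.numeric(q); qdot <- as.numeric(qdot)
  if (length(q) != 9 || length(qdot) != 9) stop("q and qdot must have length 9")
  if (!all(is.finite(q)) || !all(is.finite(qdot))) stop("state must be finite")
  structure(list(q = q, qdot = qdot, t = t), class = "walker_state")
}

#' Forward dynamics of the skeleton
#'
#' Solves the planar equations of motion `M(q) qdd = Q + Q_gravity - c(q, qd)`
#' for the generalized accelerations. `generalized_forces` carries everything
#' outside gravity: muscle joint torques, contact generalized forces, and
#' joint-limit torques.
#'
#' @param model a `walker_model`.
#' @param state a `walker_state`.
#' @param generalized_forces 9-vector of applied generalized forces
#'   (N for the two translations, N m for the angles).
#' @return list with `qdd` (9-vector), `mass_matrix` (9 x 9), `bias`, and
#'   `gravity_force`.
#' @export
forward_dynamics <- function(model, state, generalized_forces = numeric(9)) {
  stopifnot(inherits(model, "walker_model"), inherits(state, "walker_state"))
  f <- as.numeric(generalized_forces)
  if (length(f) != 9) stop("generalized_forces must have length 9")
  rg_dynamics_cpp(unclass(model), state$q, state$qdot, f)
}

#' Joint-limit torques and the hyperextension penalty
#'
#' One-sided nonlinear spring-damper torques that engage beyond the configured
#' joint limits, plus the instantaneous hyperextension penalty HPE: the sum of
#' squared limit torques across the six leg joints.
#'
#' @inheritParams forward_dynamics
#' @return list with `torques` (6-vector: right hip/knee/ankle then left) and
#'   `hpe` ((N m)^2).
#' @export
joint_limit_torque <- function(model, state) {
  stopifnot(inherits(model, "walker_model"), inherits(state, "walker_state"))
  rg_joint_limits_cpp(unclass(model), state$q, state$qdot)
}

#' Whole-body center of mass kinematics
#'
#' Mass-weighted average of the segment centers of mass (including any
#' attached backpack load).
#'
#' @inheritParams forward_dynamics
#' @return list with `com_position` and `com_velocity` (2-vectors, m and m/s).
#' @export
com_kinematics <- function(model, state) {
  stopifnot(inherits(model, "walker_model"), inherits(state, "walker_state"))
  k <- rg_kinematics_cpp(unclass(model), state$q, state$qdot)
  list(com_position = k$com, com_velocity = k$com_vel)
}

#' Full point kinematics of the model
#'
#' Segment centers of mass, head point (top of the trunk segment), ankle
#' joint centers, and the four contact-sphere centers.
#'
#' @inheritParams forward_dynamics
#' @return list of positions and velocities.
#' @export
walker_kinematics <- function(model, state) {
  stopifnot(inherits(model, "walker_model"), inherits(state, "walker_state"))
  rg_kinematics_cpp(unclass(model), state$q, state$qdot)
}

#' Write a model definition to YAML
#' @param model a `walker_model`.
#' @param file output path.
#' @export
write_walker_model <- function(model, file) {
  yaml::write_yaml(lapply(unclass(model), function(x) unname(x)), file)
  invisible(file)
}
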