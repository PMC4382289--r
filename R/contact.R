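#' Contact parameter set
#'
#' Hunt-Crossley compliant normal contact with smooth Stribeck friction at two
#' spheres per foot. Defaults: stiffness `k = 9.4281e5` N m^-1.5, dissipation
#' `c = 2` (m/s)^-1, transition speed `v_t = 0.1` m/s, static and dynamic
#' friction 0.8, viscous friction 0.5 per unit slip speed.
#'
#' @param k contact stiffness (N m^-1.5).
#' @param c dissipation coefficient ((m/s)^-1).
#' @param mu_s,mu_d,mu_v static, dynamic, and viscous friction coefficients.
#' @param v_t friction transition speed (m/s).
#' @param plane_angle ground-plane tilt (rad) for the tilted-plane incline
#'   representation; the default keeps the plane level.
#' @return a `contact_params` list.
#' @export
contact_params <- function(k = 9.4281e5, c = 2, mu_s = 0.8, mu_d = 0.8,
                           mu_v = 0.5, v_t = 0.1, plane_angle = 0) {
  if (k <= 0) stop("k must be positive")
  if (c < 0) stop("c cannot be negative")
  if (!(mu_s >= mu_d && mu_d >= 0)) stop("need mu_s >= mu_d >= 0")
  if (v_t <= 0) stop("v_t must be positive")
  structure(list(k = k, c = c, mu_s = mu_s, mu_d = mu_d, mu_v = mu_v,
                 v_t = v_t, plane_angle = plane_angle),
            class = "contact_params")
}

#' Hunt-Crossley normal force
#'
#' `GRF_y = k h^1.5 (1 + 1.5 c hdot)` for penetration `h > 0`, clamped below
#' at zero (fast retraction would otherwise produce unphysical adhesion), and
#' identically zero without penetration.
#'
#' @param h penetration depth (m); non-positive means no contact.
#' @param hdot penetration rate (m/s, positive = penetrating deeper).
#' @param params a `contact_params`.
#' @return normal force (N), vectorized over `h`/`hdot`.
#' @export
normal_force <- function(h, hdot, params = contact_params()) {
  mapply(function(hi, hdi) rg_normal_force_cpp(hi, hdi, params$k, params$c),
         h, hdot)
}

#' Slip-velocity-dependent friction force
#'
#' Tangential force `-mu(xdot) * N` where `mu` is a smooth, odd Stribeck
#' blend: a `tanh` dynamic-friction branch, a static-friction hump around the
#' transition speed, and a viscous term `mu_v * xdot`. For
#' `|xdot| >> v_t` the magnitude approaches `(mu_d + mu_v |xdot|) N`.
#'
#' @param xdot tangential slip velocity of the contact point (m/s).
#' @param normal normal load (N, non-negative).
#' @param params a `contact_params`.
#' @return friction force (N), opposing slip.
#' @export
friction_force <- function(xdot, normal, params = contact_params()) {
  if (any(normal < 0)) stop("normal load cannot be negative")
  mapply(function(v, n) {
    -rg_friction_mu_cpp(v, params$mu_s, params$mu_d, params$mu_v, params$v_t) * n
  }, xdot, normal)
}

#' Friction coefficient curve
#'
#' The smooth Stribeck `mu(xdot)` used by [friction_force()], exposed for
#' inspection and testing.
#'
#' @inheritParams friction_force
#' @return dimensionless friction coefficient (odd in `xdot`).
#' @export
friction_mu <- function(xdot, params = contact_params()) {
  vapply(xdot, function(v)
    rg_friction_mu_cpp(v, params$mu_s, params$mu_d, params$mu_v, params$v_t),
    numeric(1))
}

#' Foot-ground contact forces
#'
#' Evaluates the two contact spheres of each foot against the ground plane and
#' reports, per foot, the total ground reaction force, the center of pressure,
#' the per-sphere normal forces, and the projection onto the generalized
#' coordinates.
#'
#' @param model a `walker_model`.
#' @param state a `walker_state`.
#' @param params a `contact_params`.
#' @return list with `grf_r`, `grf_l` (named vectors: `grf_x`, `grf_y`,
#'   `cop_x`, `heel_n`, `ball_n`) and `generalized_forces` (9-vector).
#' @export
foot_contact_forces <- function(model, state, params = contact_params()) {
  stopifnot(inherits(model, "walker_model"), inherits(state, "walker_state"))
  rg_foot_contact_cpp(unclass(model), unclass(params), state$q, state$qdot)
}
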