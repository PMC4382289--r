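#' Default musculotendon parameter table
#'
#' One row per muscle of a leg: ILPSO (iliopsoas), GMAX (gluteus maximus),
#' HAMS (biarticular hamstrings), RF (rectus femoris), VAS (vasti), GAS
#' (gastrocnemius), SOL (soleus), TA (tibialis anterior). HAMS, RF, and GAS
#' span two joints; the others one. Values are a documented reconstruction of
#' the reflex-walking literature's parameter set (maximum isometric forces,
#' optimal fiber lengths, maximum shortening velocities, tendon slack
#' lengths); the RF row is an assumption since the source model family does
#' not include it. Reflex transmission delays are fixed per muscle group:
#' 5 ms (ILPSO, GMAX, HAMS, RF), 10 ms (VAS), 20 ms (GAS, SOL, TA).
#'
#' Moment arms are parametric: constant (`arm_type = 0`) or cosine-shaped
#' (`arm_type = 1`, arm `= sign * r0 * cos(theta - theta_m)`), and the
#' musculotendon path length is the consistent integral, so
#' `d l_mtu / d theta = -arm(theta)` exactly. `theta_ref` is the joint angle
#' at which the path length equals `l_slack + l_opt`.
#'
#' @param file optional CSV with the same columns, overriding the defaults.
#' @return data.frame with one row per muscle.
#' @export
mtu_table <- function(file = NULL) {
  if (!is.null(file)) {
    tab <- read.csv(file, stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(
      name = c("ILPSO", "GMAX", "HAMS", "RF", "VAS", "GAS", "SOL", "TA"),
      F_max = c(2000, 1500, 3000, 1200, 6000, 1500, 4000, 800),
      l_opt = c(0.11, 0.11, 0.10, 0.08, 0.08, 0.05, 0.04, 0.06),
      v_max = c(12, 12, 12, 12, 12, 12, 6, 12),
      l_slack = c(0.10, 0.13, 0.31, 0.35, 0.23, 0.40, 0.26, 0.24),
      tau_act = rep(0.01, 8),
      u0 = rep(0.01, 8),
      fast_twitch = c(0.5, 0.45, 0.4, 0.55, 0.5, 0.5, 0.2, 0.7),
      delay = c(0.005, 0.005, 0.005, 0.005, 0.010, 0.020, 0.020, 0.020),
      n_joint = c(1L, 1L, 2L, 2L, 1L, 2L, 1L, 1L),
      # joint: 0 hip, 1 knee, 2 ankle; sign: torque direction about the
      # flexion/dorsiflexion-positive coordinate
      joint1 = c(0L, 0L, 0L, 0L, 1L, 1L, 2L, 2L),
      arm_type1 = c(0L, 0L, 0L, 0L, 1L, 0L, 1L, 1L),
      r0_1 = c(0.10, 0.10, 0.08, 0.08, 0.06, 0.04, 0.05, 0.04),
      theta_m1 = c(0, 0, 0, 0, 0.8, 0, -0.15, 0.25),
      theta_ref1 = c(0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.0, 0.0),
      sign1 = c(1, -1, -1, 1, -1, 1, -1, 1),
      joint2 = c(0L, 0L, 1L, 1L, 0L, 2L, 0L, 0L),
      arm_type2 = c(0L, 0L, 0L, 1L, 0L, 1L, 0L, 0L),
      r0_2 = c(0, 0, 0.05, 0.045, 0, 0.05, 0, 0),
      theta_m2 = c(0, 0, 0, 0.8, 0, -0.15, 0, 0),
      theta_ref2 = c(0, 0, 0.3, 0.3, 0, 0.0, 0, 0),
      sign2 = c(1, 1, 1, -1, 1, -1, 1, 1),
      stringsAsFactors = FALSE
    )
  }
  validate_mtu_table(tab)
  tab
}

validate_mtu_table <- function(tab) {
  req <- c("name", "F_max", "l_opt", "v_max", "l_slack", "tau_act", "u0",
           "fast_twitch", "delay", "n_joint", "joint1", "arm_type1", "r0_1",
           "theta_m1", "theta_ref1", "sign1", "joint2", "arm_type2", "r0_2",
           "theta_m2", "theta_ref2", "sign2")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("mtu table missing columns: ", paste(miss, collapse = ", "))
  if (any(tab$F_max <= 0) || any(tab$l_opt <= 0) || any(tab$v_max <= 0))
    stop("F_max, l_opt, v_max must be positive")
  invisible(tab)
}

#' First-order activation dynamics
#'
#' Exact discrete update of `da/dt = (u - a) / tau`: activation approaches the
#' (clipped) excitation with time constant `tau`. Output always stays in
#' `[0, 1]`.
#'
#' @param a current activation in `[0, 1]`.
#' @param u neural excitation; clipped to `[0, 1]`.
#' @param dt time step (s).
#' @param tau activation time constant (s).
#' @return updated activation.
#' @export
activation_dynamics <- function(a, u, dt, tau = 0.01) {
  u <- pmin(pmax(u, 0), 1)
  a + (u - a) * (1 - exp(-dt / tau))
}

#' Hill-type muscle curves
#'
#' Normalized active force-length (Gaussian bell peaking at 1 at the optimal
#' fiber length), force-velocity (hyperbolic on shortening, reaching 0 at the
#' maximum shortening velocity; smooth saturating branch at 1.5 on
#' lengthening), and passive exponential force-length (zero at or below
#' optimal length, rising with stretch).
#'
#' @param l_norm fiber length / optimal fiber length.
#' @param v_norm fiber velocity / maximum shortening velocity (negative =
#'   shortening).
#' @return named vector `f_l`, `f_v`, `f_pe`.
#' @export
hill_curves <- function(l_norm, v_norm = 0) {
  rg_hill_curves_cpp(l_norm, v_norm)
}

#' Normalized series-elastic tendon force
#'
#' Quadratic toe curve: zero when slack, reaching the maximum isometric force
#' at 4 percent tendon strain.
#'
#' @param l_t tendon length (m).
#' @param l_slack tendon slack length (m).
#' @return tendon force normalized by `F_max`.
#' @export
tendon_force_norm <- function(l_t, l_slack) {
  vapply(l_t, rg_tendon_force_norm_cpp, numeric(1), l_slack = l_slack)
}

#' Musculotendon force and fiber-length rate
#'
#' Tendon-equilibrium formulation: the series-elastic tendon force at the
#' current fiber length is matched against the contractile element by
#' inverting the force-velocity curve, yielding the fiber-length rate that the
#' integrator advances. The returned force is the tendon (= musculotendon)
#' force. A slack path (`l_mtu` near or below `l_slack + l_ce`) gives
#' near-zero force.
#'
#' @param params one row of [mtu_table()] (data.frame row or named list).
#' @param state list with `a` (activation) and `l_ce` (fiber length, m).
#' @param l_mtu musculotendon path length (m).
#' @param v_mtu path lengthening rate (m/s); carried for interface
#'   completeness, the fiber rate follows from the equilibrium inversion.
#' @return list with `force` (N), `force_norm`, and `l_ce_rate` (m/s).
#' @export
mtu_force <- function(params, state, l_mtu, v_mtu = 0) {
  if (!is.finite(l_mtu)) stop("non-finite musculotendon path length")
  params <- as.list(params)
  rg_mtu_equilibrium_cpp(params, state$a, state$l_ce, l_mtu)
}

#' Musculotendon path lengths and moment arms for one leg
#'
#' @param tab a [mtu_table()].
#' @param q_leg 3-vector of (hip flexion, knee flexion, ankle dorsiflexion)
#'   angles (rad).
#' @return list with `path_length` (m, per muscle) and `moment_arms`
#'   (muscle x joint matrix, m).
#' @export
muscle_geometry <- function(tab, q_leg) {
  if (!all(is.finite(q_leg))) stop("non-finite joint angles")
  g <- rg_muscle_geometry_cpp(as.list(tab), as.numeric(q_leg),
                              numeric(nrow(tab)))
  list(path_length = setNames(g$path_length, tab$name),
       moment_arms = `dimnames<-`(g$moment_arms,
                                  list(tab$name, c("hip", "knee", "ankle"))))
}

#' Joint torques produced by a set of muscle forces
#'
#' Per-joint torque `sum(arm(q) * force)` over the muscles of one leg;
#' biarticular muscles contribute to both spanned joints.
#'
#' @param tab a [mtu_table()].
#' @param forces per-muscle tendon forces (N), in table order.
#' @param q_leg 3-vector of joint angles (rad).
#' @return named 3-vector of torques (N m) about hip, knee, ankle.
#' @export
muscle_joint_torques <- function(tab, forces, q_leg) {
  if (length(forces) != nrow(tab)) stop("one force per muscle required")
  g <- rg_muscle_geometry_cpp(as.list(tab), as.numeric(q_leg),
                              as.numeric(forces))
  setNames(g$torques, c("hip", "knee", "ankle"))
}
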