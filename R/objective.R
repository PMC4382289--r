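#' Objective weights and thresholds
#'
#' Defaults: `w_fail = 500000`, `w_vel = 50`, `w_head = 25`, `w_effort = 1`;
#' velocity deadband 0.05 m/s around the 1.5 m/s target, head-stability
#' deadband 0.2 m/s, hyperextension-penalty coefficient 0.005, fall height
#' 0.7 m. The same weights are used for every scenario.
#'
#' @param w_fail,w_vel,w_head,w_effort term weights (dimensionless).
#' @param target_speed target forward speed (m/s).
#' @param vel_epsilon,head_epsilon deadband half-widths (m/s).
#' @param hpe_coeff weight of the hyperextension penalty inside the effort
#'   term.
#' @param fall_height center-of-mass height (m) below which the model is
#'   considered fallen.
#' @return an `objective_weights` list.
#' @export
objective_weights <- function(w_fail = 500000, w_vel = 50, w_head = 25,
                              w_effort = 1, target_speed = 1.5,
                              vel_epsilon = 0.05, head_epsilon = 0.2,
                              hpe_coeff = 0.005, fall_height = 0.7) {
  w <- list(w_fail = w_fail, w_vel = w_vel, w_head = w_head,
            w_effort = w_effort, target_speed = target_speed,
            vel_epsilon = vel_epsilon, head_epsilon = head_epsilon,
            hpe_coeff = hpe_coeff, fall_height = fall_height)
  if (any(unlist(w[1:4]) < 0)) stop("weights must be non-negative")
  structure(w, class = "objective_weights")
}

#' Deadband quadratic penalty
#'
#' `Q(d, eps) = d^2` when `|d| > eps`, and 0 otherwise.
#'
#' @param d deviation.
#' @param eps deadband half-width (non-negative).
#' @return the penalty, vectorized over `d`.
#' @export
q_penalty <- function(d, eps) {
  if (any(eps < 0)) stop("eps must be non-negative")
  ifelse(abs(d) > eps, d^2, 0)
}

#' Fall penalty term
#'
#' `J_fail = (1 / T_fall) (T_total - T_fall)` where `T_fall` is the first
#' time the center-of-mass height drops below the fall height; 0 when the
#' model never falls within the simulation horizon.
#'
#' @param trajectory a `walker_trajectory`.
#' @return non-negative cost, decreasing in the time survived.
#' @export
j_fail <- function(trajectory) {
  if (!isTRUE(trajectory$fell)) return(0)
  T_fall <- trajectory$T_fall
  if (T_fall <= 0) stop("fall at t = 0: initial COM must start above the fall height")
  (1 / T_fall) * (trajectory$duration - T_fall)
}

#' Velocity tracking term
#'
#' At each heel-strike, the average forward center-of-mass velocity over the
#' previous step (the interval since the preceding heel-strike of either leg)
#' is compared to the target inside a deadband: the mean of
#' `Q(step_speed - target, eps)` over heel-strikes. The first heel-strike has
#' no preceding step and is skipped. With no usable steps the term is 0 (a
#' falling rollout is dominated by the fall term anyway).
#'
#' @param trajectory a `walker_trajectory` with heel-strike events carrying
#'   `com_x`.
#' @param target_speed target speed (m/s).
#' @param eps deadband half-width (m/s).
#' @return non-negative cost.
#' @export
j_vel <- function(trajectory, target_speed = 1.5, eps = 0.05) {
  ev <- trajectory$events
  if (is.null(ev) || nrow(ev) < 2) {
    if (is.null(ev) || nrow(ev) == 0)
      warning("no heel-strikes in trajectory; J_vel set to 0")
    return(0)
  }
  ev <- ev[order(ev$time), ]
  v <- diff(ev$com_x) / diff(ev$time)
  mean(q_penalty(v - target_speed, eps))
}

#' Head stability term
#'
#' Mean of `Q(head_vel, eps)` over the 100 Hz sample set, where `head_vel` is
#' the relative forward velocity between the head (top of the trunk segment)
#' and the center of mass.
#'
#' @param trajectory a `walker_trajectory`.
#' @param eps deadband half-width (m/s).
#' @return non-negative cost.
#' @export
j_head <- function(trajectory, eps = 0.2) {
  s <- at_100hz(trajectory$samples)
  mean(q_penalty(s$head_vel_rel, eps))
}

#' Effort term
#'
#' Mass-normalized mean over the 100 Hz sample set of the total muscle
#' metabolic power (including the basal rate) plus the weighted
#' hyperextension penalty:
#' `J_effort = (1 / ((M_body + M_back) |S|)) * sum(Metabolics_t +
#' hpe_coeff * HPE_t)`.
#'
#' @param trajectory a `walker_trajectory`.
#' @param hpe_coeff weight of the squared-joint-limit-torque penalty.
#' @return cost in W/kg.
#' @export
j_effort <- function(trajectory, hpe_coeff = 0.005) {
  s <- at_100hz(trajectory$samples)
  mass <- trajectory$m_body + trajectory$m_back
  sum(s$met_total + hpe_coeff * s$hpe) / (mass * nrow(s))
}

# restrict samples to the exact 100 Hz objective grid (0, 0.01, 0.02, ... s)
at_100hz <- function(samples) {
  on_grid <- abs(samples$t * 100 - round(samples$t * 100)) < 1e-6
  samples[on_grid, , drop = FALSE]
}

#' Total objective
#'
#' `R = w_fail J_fail + w_vel J_vel + w_head J_head + w_effort J_effort`,
#' reported with the per-term breakdown.
#'
#' @param trajectory a `walker_trajectory`.
#' @param weights an [objective_weights()].
#' @return list with `R` and `terms` (named vector of the four J values).
#' @export
total_objective <- function(trajectory, weights = objective_weights()) {
  terms <- c(J_fail = j_fail(trajectory),
             J_vel = j_vel(trajectory, weights$target_speed, weights$vel_epsilon),
             J_head = j_head(trajectory, weights$head_epsilon),
             J_effort = j_effort(trajectory, weights$hpe_coeff))
  R <- weights$w_fail * terms["J_fail"] + weights$w_vel * terms["J_vel"] +
    weights$w_head * terms["J_head"] + weights$w_effort * terms["J_effort"]
  list(R = unname(R), terms = terms, weights = weights)
}

#' Write an objective report as JSON
#' @param report result of [total_objective()].
#' @param file output path.
#' @export
write_objective_report <- function(report, file) {
  jsonlite::write_json(list(R = report$R, terms = as.list(report$terms),
                            weights = unclass(report$weights)),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
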