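MUSCLES <- c("ILPSO", "GMAX", "HAMS", "RF", "VAS", "GAS", "SOL", "TA")
MODES <- c("stance", "early_swing", "late_swing")
PD_CHANNELS <- c("trunk", "hip", "knee", "ankle")

#' Reflex feedback laws
#'
#' The three scalar control laws combined into muscle excitations:
#' force feedback `u = G_F * F(t - D)` on the muscle's own delayed normalized
#' force; stretch feedback `u = G_L * [l(t - D) - H]+` on the delayed
#' normalized fiber length beyond a threshold; and rectified
#' proportional-derivative control
#' `u = [K_p (theta(t - D) - theta_des) + K_d thetadot(t - D)]+` on a delayed
#' angular feature. `[x]+` is zero for negative `x`.
#'
#' @param G_F,G_L,K_p,K_d feedback gains (dimensionless, dimensionless,
#'   per rad, per rad/s).
#' @param F_delayed delayed normalized musculotendon force (non-negative).
#' @param l_delayed delayed normalized fiber length.
#' @param H stretch threshold (normalized length).
#' @param theta_delayed,thetadot_delayed delayed angle (rad) and rate (rad/s).
#' @param theta_desired PD target angle (rad).
#' @return excitation contribution (non-negative).
#' @name reflex_laws
NULL

#' @rdname reflex_laws
#' @export
force_feedback <- function(G_F, F_delayed) {
  if (any(F_delayed < 0)) stop("normalized force must be non-negative")
  G_F * F_delayed
}

#' @rdname reflex_laws
#' @export
stretch_feedback <- function(G_L, l_delayed, H) {
  G_L * pmax(l_delayed - H, 0)
}

#' @rdname reflex_laws
#' @export
pd_feedback <- function(K_p, K_d, theta_delayed, thetadot_delayed,
                        theta_desired) {
  pmax(K_p * (theta_delayed - theta_desired) + K_d * thetadot_delayed, 0)
}

#' Compose law outputs into a muscle excitation
#'
#' Sum of the baseline excitation and the enabled law outputs (inhibitory
#' contributions enter negatively), clipped to `[0, 1]`.
#'
#' @param law_outputs numeric vector of law contributions.
#' @param u0 baseline excitation.
#' @return excitation in `[0, 1]`.
#' @export
compose_excitation <- function(law_outputs, u0 = 0.01) {
  min(max(u0 + sum(law_outputs), 0), 1)
}

#' Gait-mode state machine for one leg
#'
#' Three modes: STANCE while the foot is in contact; on breaking contact the
#' leg enters EARLY_SWING; EARLY_SWING becomes LATE_SWING once the ankle joint
#' center moves more than `d_swing` ahead of the whole-body center of mass in
#' the sagittal plane; making contact returns the leg to STANCE from either
#' swing mode.
#'
#' @param mode current mode: `"stance"`, `"early_swing"`, or `"late_swing"`.
#' @param foot_in_contact logical contact state of the foot.
#' @param ankle_x,com_x world-frame forward positions (m) of the ankle joint
#'   center and the center of mass.
#' @param d_swing swing threshold distance (m).
#' @return the updated mode.
#' @export
update_gait_mode <- function(mode, foot_in_contact, ankle_x, com_x, d_swing) {
  mode <- match.arg(mode, MODES)
  if (foot_in_contact) return("stance")
  if (mode == "stance") return("early_swing")
  if (mode == "early_swing" && (ankle_x - com_x) > d_swing)
    return("late_swing")
  mode
}

#' Fixed-delay signal buffer
#'
#' Ring buffer over uniformly sampled signals: a query at delay `D` returns
#' the sample recorded exactly `D` seconds earlier when `D` is a multiple of
#' the sampling step (the simulation uses steps that divide every reflex
#' delay, so delayed lookups are exact).
#'
#' @param initial value the buffer is pre-filled with.
#' @param dt sampling step (s).
#' @param capacity number of retained samples.
#' @return a `delay_buffer` object with `$push(x)` and `$get(delay)` methods.
#' @export
delay_buffer <- function(initial = 0, dt = 5e-4, capacity = 64) {
  buf <- rep(as.numeric(initial), capacity)
  head <- 1L
  push <- function(x) {
    head <<- if (head == capacity) 1L else head + 1L
    buf[head] <<- x
    invisible(x)
  }
  get <- function(delay) {
    steps <- delay / dt
    if (abs(steps - round(steps)) > 1e-9)
      stop("delay must be a multiple of the sampling step")
    steps <- as.integer(round(steps))
    if (steps >= capacity) stop("delay exceeds buffer capacity")
    idx <- ((head - 1L - steps) %% capacity) + 1L
    buf[idx]
  }
  structure(list(push = push, get = get, dt = dt), class = "delay_buffer")
}

# ---------------------------------------------------------------- wiring ----

wiring_param <- function(name, lower, upper, default) {
  data.frame(name = name, lower = lower, upper = upper, default = default,
             stringsAsFactors = FALSE)
}

law_row <- function(target, mode, type, source, sign, neg, p1, p2 = NA, p3 = NA) {
  data.frame(target = target, mode = mode, type = type, source = source,
             sign = sign, neg = neg, p1 = p1, p2 = p2, p3 = p3,
             stringsAsFactors = FALSE)
}

#' Default reflex wiring table
#'
#' The declarative per-muscle, per-gait-mode assignment of control laws,
#' following the reflex-walking control scheme the model family is built on:
#' in stance, positive force feedback on the plantarflexors and vasti (the
#' vasti additionally carry a rectified knee-overextension inhibition),
#' stretch feedback with soleus force inhibition on tibialis anterior, and a
#' shared trunk-orientation PD driving gluteus maximus and iliopsoas as an
#' antagonist pair with a scaled hamstrings contribution; in early swing,
#' iliopsoas stretch feedback drives swing initiation with tibialis anterior
#' stretch for foot clearance; in late swing ("stance preparation"), PD
#' controllers place the hip and knee for landing while hamstrings force
#' feedback decelerates the limb. Each gait mode also carries small constant
#' excitation offsets. Both legs share the same laws (left/right symmetry).
#'
#' The table defines 55 free controller parameters; with the swing threshold
#' distance `d_swing` and 18 initial conditions the optimization design
#' vector has exactly 74 entries, which is asserted.
#'
#' @return list with `laws` (data.frame), `params` (name/lower/upper/default),
#'   and `extra` (bounds for `d_swing` and the 18 initial conditions).
#' @export
default_wiring <- function() {
  params <- rbind(
    wiring_param("st_sol_gf", 0, 3, 1.2),
    wiring_param("st_gas_gf", 0, 3, 1.1),
    wiring_param("st_vas_gf", 0, 3, 1.0),
    wiring_param("st_vas_kp", 0, 8, 2.0),
    wiring_param("st_vas_koff", 0, 0.4, 0.15),
    wiring_param("st_vas_kd", 0, 1, 0.1),
    wiring_param("st_ta_gl", 0, 4, 1.1),
    wiring_param("st_ta_h", 0.4, 1.4, 0.72),
    wiring_param("st_ta_gfi", 0, 2, 0.3),
    wiring_param("st_trunk_kp", 0, 6, 1.5),
    wiring_param("st_trunk_kd", 0, 2, 0.3),
    wiring_param("st_trunk_des", -0.2, 0.5, 0.1),
    wiring_param("st_hams_kp", 0, 6, 1.0),
    wiring_param("st_hams_kd", 0, 2, 0.2),
    wiring_param("st_gmax_gf", 0, 2, 0.1),
    wiring_param("st_hams_gf", 0, 2, 0.1),
    wiring_param("st_ilpso_gl", 0, 4, 0.5),
    wiring_param("st_ilpso_h", 0.4, 1.4, 0.9),
    wiring_param("st_rf_gf", 0, 2, 0.1),
    wiring_param(paste0("st_c_", tolower(MUSCLES)), 0, 0.4,
                 c(0.01, 0.01, 0.01, 0.01, 0.08, 0.01, 0.01, 0.01)),
    wiring_param("sw_ilpso_gl", 0, 4, 1.0),
    wiring_param("sw_ilpso_h", 0.4, 1.4, 0.85),
    wiring_param("sw_hams_gf", 0, 2, 0.25),
    wiring_param("sw_ta_gl", 0, 4, 1.1),
    wiring_param("sw_ta_h", 0.4, 1.4, 0.72),
    wiring_param(paste0("sw_c_", tolower(MUSCLES)), 0, 0.4,
                 c(0.15, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01)),
    wiring_param("ls_hip_kp", 0, 6, 1.5),
    wiring_param("ls_hip_kd", 0, 2, 0.3),
    wiring_param("ls_hip_des", -0.2, 1.0, 0.35),
    wiring_param("ls_knee_kp", 0, 6, 1.5),
    wiring_param("ls_knee_kd", 0, 2, 0.3),
    wiring_param("ls_knee_des", 0, 1.2, 0.25),
    wiring_param("ls_ta_gl", 0, 4, 1.1),
    wiring_param("ls_ta_h", 0.4, 1.4, 0.72),
    wiring_param("ls_hams_gf", 0, 2, 0.4),
    wiring_param(paste0("ls_c_", tolower(MUSCLES[c(1:5, 8)])), 0, 0.4, 0.01)
  )

  st_const <- do.call(rbind, lapply(MUSCLES, function(m)
    law_row(m, "stance", "const", m, 1, 0, paste0("st_c_", tolower(m)))))
  sw_const <- do.call(rbind, lapply(MUSCLES, function(m)
    law_row(m, "early_swing", "const", m, 1, 0, paste0("sw_c_", tolower(m)))))
  ls_const <- do.call(rbind, lapply(MUSCLES[c(1:5, 8)], function(m)
    law_row(m, "late_swing", "const", m, 1, 0, paste0("ls_c_", tolower(m)))))

  laws <- rbind(
    law_row("SOL", "stance", "force", "SOL", 1, 0, "st_sol_gf"),
    law_row("GAS", "stance", "force", "GAS", 1, 0, "st_gas_gf"),
    law_row("VAS", "stance", "force", "VAS", 1, 0, "st_vas_gf"),
    law_row("VAS", "stance", "pd", "knee", -1, 1,
            "st_vas_kp", "st_vas_koff", "st_vas_kd"),
    law_row("TA", "stance", "stretch", "TA", 1, 0, "st_ta_gl", "st_ta_h"),
    law_row("TA", "stance", "force", "SOL", 1, 1, "st_ta_gfi"),
    law_row("GMAX", "stance", "pd", "trunk", 1, 0,
            "st_trunk_kp", "st_trunk_des", "st_trunk_kd"),
    law_row("ILPSO", "stance", "pd", "trunk", -1, 0,
            "st_trunk_kp", "st_trunk_des", "st_trunk_kd"),
    law_row("HAMS", "stance", "pd", "trunk", 1, 0,
            "st_hams_kp", "st_trunk_des", "st_hams_kd"),
    law_row("GMAX", "stance", "force", "GMAX", 1, 0, "st_gmax_gf"),
    law_row("HAMS", "stance", "force", "HAMS", 1, 0, "st_hams_gf"),
    law_row("ILPSO", "stance", "stretch", "ILPSO", 1, 0,
            "st_ilpso_gl", "st_ilpso_h"),
    law_row("RF", "stance", "force", "RF", 1, 0, "st_rf_gf"),
    st_const,
    law_row("ILPSO", "early_swing", "stretch", "ILPSO", 1, 0,
            "sw_ilpso_gl", "sw_ilpso_h"),
    law_row("HAMS", "early_swing", "force", "HAMS", 1, 0, "sw_hams_gf"),
    law_row("TA", "early_swing", "stretch", "TA", 1, 0, "sw_ta_gl", "sw_ta_h"),
    sw_const,
    law_row("ILPSO", "late_swing", "pd", "hip", -1, 0,
            "ls_hip_kp", "ls_hip_des", "ls_hip_kd"),
    law_row("GMAX", "late_swing", "pd", "hip", 1, 0,
            "ls_hip_kp", "ls_hip_des", "ls_hip_kd"),
    law_row("VAS", "late_swing", "pd", "knee", 1, 0,
            "ls_knee_kp", "ls_knee_des", "ls_knee_kd"),
    law_row("HAMS", "late_swing", "pd", "knee", -1, 0,
            "ls_knee_kp", "ls_knee_des", "ls_knee_kd"),
    law_row("TA", "late_swing", "stretch", "TA", 1, 0, "ls_ta_gl", "ls_ta_h"),
    law_row("HAMS", "late_swing", "force", "HAMS", 1, 0, "ls_hams_gf"),
    ls_const
  )

  extra <- rbind(
    wiring_param("d_swing", 0, 0.45, 0.15),
    wiring_param("q_x", -0.5, 0.5, 0),
    wiring_param("q_y", 0.9, 1.12, 1.02),
    wiring_param("q_pitch", -0.2, 0.5, 0.08),
    wiring_param("q_hip_r", -0.6, 1.2, 0.4),
    wiring_param("q_knee_r", 0, 1.6, 0.1),
    wiring_param("q_ankle_r", -0.6, 0.6, 0),
    wiring_param("q_hip_l", -0.6, 1.2, -0.1),
    wiring_param("q_knee_l", 0, 1.6, 0.15),
    wiring_param("q_ankle_l", -0.6, 0.6, 0),
    wiring_param("qd_x", 0, 2.5, 1.3),
    wiring_param("qd_y", -1, 1, -0.1),
    wiring_param("qd_pitch", -2, 2, 0),
    wiring_param("qd_hip_r", -5, 5, 0),
    wiring_param("qd_knee_r", -5, 5, 0),
    wiring_param("qd_ankle_r", -5, 5, 0),
    wiring_param("qd_hip_l", -5, 5, 0),
    wiring_param("qd_knee_l", -5, 5, 0),
    wiring_param("qd_ankle_l", -5, 5, 0)
  )

  w <- list(laws = laws, params = params, extra = extra)
  stopifnot(design_length(w) == 74)
  validate_wiring(w)
  w
}

validate_wiring <- function(w) {
  used <- stats::na.omit(unlist(w$laws[, c("p1", "p2", "p3")]))
  unknown <- setdiff(used, w$params$name)
  if (length(unknown))
    stop("laws reference unknown parameters: ", paste(unknown, collapse = ", "))
  bad_t <- setdiff(w$laws$target, MUSCLES)
  if (length(bad_t)) stop("unknown target muscle: ", paste(bad_t, collapse = ", "))
  bad_m <- setdiff(w$laws$mode, MODES)
  if (length(bad_m)) stop("unknown gait mode: ", paste(bad_m, collapse = ", "))
  fs <- w$laws$type %in% c("force", "stretch")
  bad_s <- setdiff(w$laws$source[fs], MUSCLES)
  if (length(bad_s)) stop("unknown source muscle: ", paste(bad_s, collapse = ", "))
  bad_c <- setdiff(w$laws$source[w$laws$type == "pd"], PD_CHANNELS)
  if (length(bad_c)) stop("unknown PD channel: ", paste(bad_c, collapse = ", "))
  invisible(w)
}

#' Number of free design variables defined by a wiring table
#' @param wiring a [default_wiring()]-style list.
#' @return integer count (controller parameters + d_swing + 18 initial
#'   conditions).
#' @export
design_length <- function(wiring = default_wiring()) {
  nrow(wiring$params) + nrow(wiring$extra)
}

#' Design-vector bounds
#' @param wiring a wiring list.
#' @return data.frame with `name`, `lower`, `upper`, `default` for every
#'   design variable, in design-vector order (controller parameters, then
#'   d_swing, then 9 initial coordinates, then 9 initial velocities).
#' @export
design_bounds <- function(wiring = default_wiring()) {
  rbind(wiring$params, wiring$extra)
}

# integer law matrix + sign vector for the compiled rollout
laws_to_matrix <- function(wiring) {
  laws <- wiring$laws
  pidx <- function(p) ifelse(is.na(p), 0L, match(p, wiring$params$name) - 1L)
  type_id <- c(const = 0L, force = 1L, stretch = 2L, pd = 3L)
  src <- ifelse(laws$type == "pd",
                match(laws$source, PD_CHANNELS) - 1L,
                match(laws$source, MUSCLES) - 1L)
  m <- cbind(target = match(laws$target, MUSCLES) - 1L,
             mode = match(laws$mode, MODES) - 1L,
             type = type_id[laws$type],
             source = as.integer(src),
             p1 = pidx(laws$p1), p2 = pidx(laws$p2), p3 = pidx(laws$p3),
             neg = as.integer(laws$neg))
  storage.mode(m) <- "integer"
  list(matrix = m, signs = as.numeric(laws$sign))
}

#' Decode a normalized design vector
#'
#' The optimizer works on a normalized design space: a raw vector `z` of
#' length 74 is mapped affinely onto the configured bounds,
#' `x = lower + z * (upper - lower)`, so an all-zeros raw vector decodes to
#' the lower bounds. Raw values outside `[0, 1]` are clipped (the number of
#' clipped entries is reported).
#'
#' @param z numeric vector of length [design_length()].
#' @param wiring a wiring list.
#' @return list with `cparams` (named controller parameters), `d_swing`,
#'   `q0`, `qd0` (9-vectors), and `n_clipped`.
#' @export
decode_design <- function(z, wiring = default_wiring()) {
  b <- design_bounds(wiring)
  if (length(z) != nrow(b))
    stop("design vector must have length ", nrow(b))
  zc <- pmin(pmax(z, 0), 1)
  x <- b$lower + zc * (b$upper - b$lower)
  names(x) <- b$name
  np <- nrow(wiring$params)
  list(cparams = x[seq_len(np)],
       d_swing = unname(x[np + 1]),
       q0 = unname(x[np + 1 + 1:9]),
       qd0 = unname(x[np + 10 + 1:9]),
       n_clipped = sum(z != zc))
}

#' Encode physical parameters into a normalized design vector
#'
#' Inverse of [decode_design()]: lossless for in-bounds values.
#'
#' @param cparams named controller parameter vector (wiring order).
#' @param d_swing swing threshold distance (m).
#' @param q0,qd0 initial coordinates and velocities (9-vectors).
#' @param wiring a wiring list.
#' @return normalized design vector of length [design_length()].
#' @export
encode_design <- function(cparams, d_swing, q0, qd0, wiring = default_wiring()) {
  b <- design_bounds(wiring)
  x <- c(cparams, d_swing, q0, qd0)
  if (length(x) != nrow(b)) stop("wrong number of parameters")
  (x - b$lower) / (b$upper - b$lower)
}

#' Read a wiring table from YAML
#'
#' The YAML layout mirrors [default_wiring()]: `laws`, `params`, and `extra`
#' sections, each a list of records. The shipped default lives at
#' `system.file("extdata", "wiring_default.yaml", package = "reflexgait")`.
#'
#' @param file path to a wiring YAML file.
#' @return a validated wiring list.
#' @export
read_wiring <- function(file) {
  y <- yaml::read_yaml(file)
  tod <- function(recs) do.call(rbind, lapply(recs, function(r) {
    r[vapply(r, is.null, logical(1))] <- NA
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  w <- list(laws = tod(y$laws), params = tod(y$params), extra = tod(y$extra))
  validate_wiring(w)
  w
}

#' Default design vector (normalized)
#' @param wiring a wiring list.
#' @return the wiring defaults encoded as a normalized vector.
#' @export
default_design <- function(wiring = default_wiring()) {
  b <- design_bounds(wiring)
  (b$default - b$lower) / (b$upper - b$lower)
}
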