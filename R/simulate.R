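#' Walking scenario descriptor
#'
#' @param load_fraction backpack load as a fraction of body mass (0 to 0.4 in
#'   the study conditions).
#' @param incline_deg uphill slope angle in degrees (0 to 20).
#' @param target_speed target forward speed (m/s), measured along the slope.
#' @param duration simulation horizon (s).
#' @return a `walking_scenario` list.
#' @export
walking_scenario <- function(load_fraction = 0, incline_deg = 0,
                             target_speed = 1.5, duration = 10) {
  if (load_fraction < 0) stop("load_fraction cannot be negative")
  if (duration <= 0) stop("duration must be positive")
  if (incline_deg < 0 || incline_deg > 30) stop("incline must be in [0, 30] degrees")
  structure(list(load_fraction = load_fraction, incline_deg = incline_deg,
                 target_speed = target_speed, duration = duration),
            class = "walking_scenario")
}

#' Attach a backpack load to the trunk
#'
#' The load is a point mass `M_back = load_fraction * M_body` fixed to the
#' trunk 0.1 m posterior to the trunk center of mass, with an additional
#' rotational inertia of `0.15 * M_back` kg m^2.
#'
#' @param model a `walker_model`.
#' @param load_fraction load as a fraction of the unloaded body mass.
#' @return the model with the load attached.
#' @export
attach_load <- function(model, load_fraction) {
  stopifnot(inherits(model, "walker_model"))
  if (load_fraction < 0 || load_fraction > 1)
    stop("load_fraction must be in [0, 1]")
  m_body <- total_body_mass(model) - model$m_back
  model$m_back <- load_fraction * m_body
  model$I_back <- 0.15 * model$m_back
  model$back_dx <- -0.1
  model
}

#' Incline environment
#'
#' Walking up a slope of angle `incline_deg` is realized by rotating the
#' gravity vector while the contact plane stays fixed; the simulation frame is
#' then the slope frame (x along the slope, y perpendicular to it), which is
#' dynamically equivalent to tilting the plane. Forward velocity is measured
#' along the slope.
#'
#' @param scenario a `walking_scenario`.
#' @param g gravitational acceleration magnitude (m/s^2).
#' @return list with `gravity` (2-vector in the slope frame), `grade`
#'   (dimensionless, `tan(incline)`), and `incline_rad`.
#' @export
apply_incline <- function(scenario, g = 9.80665) {
  gam <- scenario$incline_deg * pi / 180
  list(gravity = c(-g * sin(gam), -g * cos(gam)),
       grade = tan(gam), incline_rad = gam)
}

#' Closed-loop rollout of the reflex-controlled walker
#'
#' Integrates the coupled skeletal, muscle, and controller dynamics with a
#' fixed-step semi-implicit Euler scheme (default 0.5 ms, which divides every
#' reflex delay and the 100 Hz output sampling exactly, keeping delayed
#' lookups and the recorded grid exact). The rollout runs for the scenario
#' duration or until a fall (center of mass height below the configured fall
#' height, measured perpendicular to the contact plane), and is deterministic
#' given identical inputs.
#'
#' @param design normalized design vector of length [design_length()], or a
#'   decoded list from [decode_design()].
#' @param scenario a [walking_scenario()].
#' @param model a [walker_model()] (load and incline from the scenario are
#'   applied on top).
#' @param contact a [contact_params()].
#' @param muscles a [mtu_table()].
#' @param wiring a [default_wiring()]-style wiring list.
#' @param dt integration step (s); must divide every reflex delay.
#' @param record_hz output sampling rate (Hz; at least 100).
#' @param basal_rate_per_kg basal metabolic rate (W per kg unloaded body mass).
#' @param contact_on,contact_off per-foot contact detection thresholds (N):
#'   a foot is considered on the ground once its total normal force exceeds
#'   `contact_on` and off again below `contact_off` (hysteresis).
#' @return a `walker_trajectory`: uniformly sampled channels (`$samples`),
#'   heel-strike events (`$events`), fall information, and metadata.
#' @export
simulate_walker <- function(design, scenario = walking_scenario(),
                            model = walker_model(),
                            contact = contact_params(),
                            muscles = mtu_table(),
                            wiring = default_wiring(),
                            dt = 5e-4, record_hz = 100,
                            basal_rate_per_kg = 1.2,
                            contact_on = 20, contact_off = 5) {
  if (is.numeric(design)) design <- decode_design(design, wiring)
  if (record_hz < 100) stop("record_hz must be at least 100")
  m_body <- total_body_mass(model) - model$m_back
  model <- attach_load(model, scenario$load_fraction)
  env <- apply_incline(scenario)
  model$gravity <- env$gravity

  lm <- laws_to_matrix(wiring)
  raw <- rg_rollout_cpp(unclass(model), unclass(contact), as.list(muscles),
                        lm$matrix, lm$signs,
                        as.numeric(design$cparams), design$d_swing,
                        design$q0, design$qd0,
                        scenario$duration, dt, 1 / record_hz,
                        contact_on, contact_off)

  samples <- as.data.frame(raw$samples)
  names(samples) <- trajectory_columns()
  basal <- basal_rate_per_kg * m_body
  samples$met_total <- samples$met_muscle + basal
  events <- data.frame(time = raw$hs_time,
                       leg = c("r", "l")[raw$hs_leg],
                       com_x = raw$hs_com_x)
  structure(list(samples = samples, events = events,
                 fell = raw$fell, T_fall = raw$T_fall, t_end = raw$t_end,
                 duration = scenario$duration, dt = dt,
                 record_hz = record_hz, scenario = scenario,
                 m_body = m_body, m_back = model$m_back,
                 basal = basal),
            class = "walker_trajectory")
}

#' @rdname simulate_walker
#' @param ... passed to [simulate_walker()].
#' @export
rollout <- function(design, scenario = walking_scenario(), ...) {
  simulate_walker(design, scenario, ...)
}

trajectory_columns <- function() {
  mus <- tolower(MUSCLES)
  c("t",
    paste0("q_", c("x", "y", "pitch", "hip_r", "knee_r", "ankle_r",
                   "hip_l", "knee_l", "ankle_l")),
    paste0("qd_", c("x", "y", "pitch", "hip_r", "knee_r", "ankle_r",
                    "hip_l", "knee_l", "ankle_l")),
    paste0("u_", mus, "_r"), paste0("u_", mus, "_l"),
    paste0("act_", mus, "_r"), paste0("act_", mus, "_l"),
    paste0("f_", mus, "_r"), paste0("f_", mus, "_l"),
    paste0("lce_", mus, "_r"), paste0("lce_", mus, "_l"),
    paste0("tau_", c("hip_r", "knee_r", "ankle_r", "hip_l", "knee_l", "ankle_l")),
    paste0("lim_", c("hip_r", "knee_r", "ankle_r", "hip_l", "knee_l", "ankle_l")),
    "grf_x_r", "grf_y_r", "cop_x_r", "grf_x_l", "grf_y_l", "cop_x_l",
    "com_x", "com_y", "com_vx", "com_vy", "head_vel_rel",
    "met_muscle", "hpe", "mode_r", "mode_l")
}

#' @export
print.walker_trajectory <- function(x, ...) {
  cat(sprintf("<walker_trajectory> %.2f s simulated at %g Hz output (%d samples)\n",
              x$t_end, x$record_hz, nrow(x$samples)))
  if (x$fell) cat(sprintf("  model FELL at t = %.3f s\n", x$T_fall))
  else cat("  no fall\n")
  cat(sprintf("  heel strikes: %d (R %d / L %d)\n", nrow(x$events),
              sum(x$events$leg == "r"), sum(x$events$leg == "l")))
  invisible(x)
}

#' Heel-strike event times
#'
#' One event per swing-to-stance transition per leg. When the trajectory
#' carries engine-recorded events those are returned (exact event times);
#' otherwise events are detected from the sampled gait-mode channels.
#'
#' @param trajectory a `walker_trajectory`.
#' @param use_events use engine-recorded events when available.
#' @return data.frame with `time` and `leg` (`"r"`/`"l"`), ordered by time
#'   (plus `com_x` when engine events are available).
#' @export
detect_heelstrikes <- function(trajectory, use_events = TRUE) {
  if (use_events && !is.null(trajectory$events) && nrow(trajectory$events) > 0)
    return(trajectory$events[order(trajectory$events$time), , drop = FALSE])
  s <- trajectory$samples
  out <- list()
  for (leg in c("r", "l")) {
    m <- s[[paste0("mode_", leg)]]
    hs <- which(diff(m == 0) == 1) + 1
    if (length(hs))
      out[[leg]] <- data.frame(time = s$t[hs], leg = leg)
  }
  if (!length(out)) return(data.frame(time = numeric(0), leg = character(0)))
  res <- do.call(rbind, out)
  res[order(res$time), , drop = FALSE]
}

#' Write a trajectory as an OpenSim-style storage (.sto) file
#'
#' Tab-delimited time series with the storage-dialect header (name, rows,
#' columns, `endheader`).
#'
#' @param trajectory a `walker_trajectory`.
#' @param file output path.
#' @param name dataset name written into the header.
#' @export
write_trajectory_sto <- function(trajectory, file, name = "reflexgait") {
  s <- trajectory$samples
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(name,
               sprintf("nRows=%d", nrow(s)),
               sprintf("nColumns=%d", ncol(s)),
               "inDegrees=no", "endheader",
               paste(names(s), collapse = "\t")), con)
  utils::write.table(s, con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Write trajectory samples as CSV with a JSON event sidecar
#'
#' @param trajectory a `walker_trajectory`.
#' @param file CSV output path; events go to `<file>.events.json`.
#' @export
write_trajectory_csv <- function(trajectory, file) {
  write.csv(trajectory$samples, file, row.names = FALSE)
  side <- paste0(file, ".events.json")
  jsonlite::write_json(list(events = trajectory$events,
                            fell = trajectory$fell,
                            T_fall = trajectory$T_fall,
                            t_end = trajectory$t_end),
                       side, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(file)
}

#' Read a storage (.sto) time-series file
#' @param file path to a tab-delimited storage file.
#' @return data.frame of the sampled channels.
#' @export
read_trajectory_sto <- function(file) {
  lines <- readLines(file, n = 50)
  hdr <- which(lines == "endheader")
  if (!length(hdr)) stop("not a storage file: no endheader line")
  read.delim(file, skip = hdr[1], check.names = FALSE)
}
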