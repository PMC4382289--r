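#' Mean stride cycle extraction
#'
#' Segments a trajectory into strides at heel-strikes of the reference leg,
#' drops the first `n_skip` strides (so the control excitation cycles have
#' stabilized), time-normalizes each remaining stride onto a 101-point
#' 0-100 percent gait-cycle grid, and averages per channel.
#'
#' @param trajectory a `walker_trajectory`.
#' @param leg reference leg, `"r"` or `"l"`; strides start at its heel-strike.
#' @param n_skip strides dropped from the start (default 2).
#' @param channels channels to average (default: all numeric sample columns).
#' @return a `gait_cycles` list: `curves` (101 x channels matrix on the
#'   0-100 percent grid), `pct` (grid), `n_strides` (averaged count),
#'   `stride_time` (s, mean over included strides), `stride_length`
#'   (m, mean forward COM travel per stride).
#' @export
extract_mean_stride <- function(trajectory, leg = "r", n_skip = 2,
                                channels = NULL) {
  hs <- detect_heelstrikes(trajectory)
  hs <- hs$time[hs$leg == leg]
  n_str <- length(hs) - 1
  if (n_str < n_skip + 1)
    stop(sprintf("need at least %d complete strides, found %d",
                 n_skip + 1, max(n_str, 0)))
  s <- trajectory$samples
  if (is.null(channels))
    channels <- setdiff(names(s), "t")
  pct <- seq(0, 100, length.out = 101)
  keep <- seq(n_skip + 1, n_str)
  curves <- array(0, c(101, length(channels)),
                  dimnames = list(NULL, channels))
  stride_times <- numeric(length(keep))
  stride_lengths <- numeric(length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    t0 <- hs[i]; t1 <- hs[i + 1]
    stride_times[j] <- t1 - t0
    tt <- t0 + (pct / 100) * (t1 - t0)
    for (ch in channels)
      curves[, ch] <- curves[, ch] + approx(s$t, s[[ch]], tt, rule = 2)$y
    stride_lengths[j] <- approx(s$t, s$com_x, t1, rule = 2)$y -
      approx(s$t, s$com_x, t0, rule = 2)$y
  }
  curves <- curves / length(keep)
  structure(list(curves = curves, pct = pct, n_strides = length(keep),
                 stride_time = mean(stride_times),
                 stride_length = mean(stride_lengths)),
            class = "gait_cycles")
}

#' Reference band constructor
#'
#' Mean and standard-deviation curves of a channel over the gait cycle on the
#' common 101-point grid, as used for band-coverage scoring against
#' experimental data.
#'
#' @param mean_curve,sd_curve numeric vectors on the same grid; `sd_curve`
#'   must be non-negative.
#' @param pct grid (percent of gait cycle).
#' @param label provenance label.
#' @return a `reference_band` list.
#' @export
reference_band <- function(mean_curve, sd_curve, pct = seq(0, 100, length.out = 101),
                           label = "synthetic") {
  if (length(mean_curve) != length(pct) || length(sd_curve) != length(pct))
    stop("mean and sd curves must match the grid")
  if (any(sd_curve < 0)) stop("sd curve must be non-negative")
  structure(list(mean = mean_curve, sd = sd_curve, pct = pct, label = label),
            class = "reference_band")
}

#' Fraction of the gait cycle inside a reference band
#'
#' Percentage of grid points where `|curve - mean| <= sd` (the boundary
#' counts as inside).
#'
#' @param curve numeric vector on the band's grid.
#' @param band a [reference_band()].
#' @return coverage in percent (0-100).
#' @export
band_coverage <- function(curve, band) {
  if (length(curve) != length(band$mean))
    stop("curve and band are on different grids")
  100 * mean(abs(curve - band$mean) <= band$sd)
}

#' Teager-Kaiser EMG onset/offset detection
#'
#' Computes the discrete Teager-Kaiser energy
#' `psi[n] = x[n]^2 - x[n-1] x[n+1]`, rectifies and smooths it with a moving
#' average, estimates the baseline noise distribution from an "off" region
#' (supplied as an index range, or auto-selected as the lowest-energy quarter
#' of the samples), and thresholds at `baseline mean + n_sd * baseline SD`.
#' Brief gaps are merged and brief detections dropped (`min_duration`).
#'
#' @param emg raw EMG samples.
#' @param fs sampling rate (Hz), e.g. 1500 for surface EMG.
#' @param n_sd detection threshold in baseline standard deviations (default
#'   6).
#' @param baseline optional integer indices of a known "off" region.
#' @param smooth_ms moving-average window (ms) applied to the rectified
#'   energy.
#' @param min_duration minimal on/off interval length (s); brief detections are treated as noise.
#' @return data.frame with `onset` and `offset` times (s), possibly empty.
#' @export
teager_kaiser_onsets <- function(emg, fs, n_sd = 6, baseline = NULL,
                                 smooth_ms = 20, min_duration = 0.03) {
  x <- as.numeric(emg)
  n <- length(x)
  if (n < 3) stop("signal must have at least 3 samples")
  psi <- c(0, x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n], 0)
  e <- abs(psi)
  w <- max(1L, as.integer(round(smooth_ms / 1000 * fs)))
  e <- as.numeric(stats::filter(e, rep(1 / w, w), sides = 2))
  e[is.na(e)] <- 0
  if (is.null(baseline))
    baseline <- order(e)[seq_len(max(3L, n %/% 4))]
  thr <- mean(e[baseline]) + n_sd * sd(e[baseline])
  on <- e > thr
  # merge sub-threshold gaps shorter than min_duration, then drop short bursts
  r <- rle(on)
  gap <- as.integer(round(min_duration * fs))
  idx_end <- cumsum(r$lengths)
  for (k in seq_along(r$values))
    if (!r$values[k] && r$lengths[k] < gap && k > 1 && k < length(r$values))
      on[(idx_end[k] - r$lengths[k] + 1):idx_end[k]] <- TRUE
  r <- rle(on)
  idx_end <- cumsum(r$lengths)
  out <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= gap) {
      i0 <- idx_end[k] - r$lengths[k] + 1
      out[[length(out) + 1]] <- data.frame(onset = (i0 - 1) / fs,
                                           offset = (idx_end[k] - 1) / fs)
    }
  }
  if (!length(out)) return(data.frame(onset = numeric(0), offset = numeric(0)))
  do.call(rbind, out)
}

#' Metabolic summary of a walking trial
#'
#' Mean total metabolic power over the steady strides (first two strides
#' ignored), normalized to the unloaded body mass regardless of any carried
#' load, with an optional percent change against a reference value.
#'
#' @param trajectory a `walker_trajectory`.
#' @param reference optional reference power (W/kg) for the percent change.
#' @param n_skip strides ignored at the start.
#' @return list with `power_per_kg` (W/kg of unloaded body mass),
#'   `pct_change` (percent, or NA without a reference), and the averaging
#'   window `t_window`.
#' @export
metabolic_summary <- function(trajectory, reference = NULL, n_skip = 2) {
  hs <- detect_heelstrikes(trajectory)
  s <- trajectory$samples
  if (nrow(hs) > n_skip + 1) {
    hs_r <- hs$time[hs$leg == "r"]
    t0 <- if (length(hs_r) > n_skip) hs_r[n_skip + 1] else hs$time[n_skip + 1]
    t1 <- max(hs$time)
  } else {
    t0 <- min(s$t); t1 <- max(s$t)
  }
  win <- s$t >= t0 & s$t <= t1
  p <- mean(s$met_total[win]) / trajectory$m_body
  pct <- if (is.null(reference)) NA_real_ else 100 * (p - reference) / reference
  list(power_per_kg = p, pct_change = pct, t_window = c(t0, t1))
}

#' Synthetic evaluation fixtures
#'
#' Deterministic synthetic inputs for the analysis pipeline, standing in for
#' experimental gait data (which this package does not ship): smooth periodic
#' reference bands with SD envelopes for hip/knee/ankle angles, a synthetic
#' EMG trace (Gaussian baseline noise with amplified bursts at known on/off
#' times), and an analytically periodic walking trajectory with gait-mode,
#' COM, and metabolic channels so every analysis operation can run without
#' external data.
#'
#' @param seed integer seed; identical seeds give identical fixtures.
#' @param stride_time stride period of the synthetic trajectory (s).
#' @param n_strides number of strides in the synthetic trajectory.
#' @param emg_fs EMG sampling rate (Hz).
#' @return list with `bands` (named list of [reference_band()]), `emg`
#'   (list: `signal`, `fs`, `bursts`), and `trajectory` (a synthetic
#'   `walker_trajectory`).
#' @export
generate_fixtures <- function(seed = 1, stride_time = 1.1, n_strides = 8,
                              emg_fs = 1500) {
  set.seed(seed)
  pct <- seq(0, 100, length.out = 101)
  ph <- 2 * pi * pct / 100
  bands <- list(
    hip = reference_band(30 * sin(ph + 0.3) + 5, 6 + 2 * abs(cos(ph)), pct),
    knee = reference_band(35 * (1 - cos(ph)) / 2 + 25 * pmax(sin(2 * ph), 0) / 2,
                          5 + 1.5 * abs(sin(ph)), pct),
    ankle = reference_band(12 * sin(2 * ph + 1), 4 + abs(sin(ph)), pct)
  )

  dur_emg <- 2
  n_emg <- dur_emg * emg_fs
  emg <- rnorm(n_emg, 0, 0.01)
  bursts <- data.frame(on = c(0.3, 1.2), off = c(0.6, 1.5))
  for (b in seq_len(nrow(bursts))) {
    i0 <- round(bursts$on[b] * emg_fs) + 1
    i1 <- round(bursts$off[b] * emg_fs)
    emg[i0:i1] <- rnorm(i1 - i0 + 1, 0, 0.15)
  }

  fs <- 100
  tt <- seq(0, n_strides * stride_time, by = 1 / fs)
  ph_t <- 2 * pi * (tt %% stride_time) / stride_time
  speed <- 1.5
  samples <- data.frame(t = tt)
  samples$q_hip_r <- (30 * sin(ph_t + 0.3) + 5) * pi / 180
  samples$q_knee_r <- (35 * (1 - cos(ph_t)) / 2) * pi / 180
  samples$q_ankle_r <- (12 * sin(2 * ph_t + 1)) * pi / 180
  samples$com_x <- speed * tt
  samples$com_y <- 0.9 + 0.02 * sin(2 * ph_t)
  samples$com_vx <- speed + 0.05 * sin(ph_t)
  samples$com_vy <- 0.02 * (4 * pi / stride_time) * cos(2 * ph_t)
  samples$head_vel_rel <- 0.05 * sin(ph_t)
  samples$met_muscle <- 220 + 40 * sin(ph_t)^2
  samples$met_total <- samples$met_muscle + 96
  samples$hpe <- 0
  # stance for the first 60 percent of each stride, then early/late swing
  frac <- (tt %% stride_time) / stride_time
  samples$mode_r <- ifelse(frac < 0.6, 0, ifelse(frac < 0.8, 1, 2))
  frac_l <- ((tt + stride_time / 2) %% stride_time) / stride_time
  samples$mode_l <- ifelse(frac_l < 0.6, 0, ifelse(frac_l < 0.8, 1, 2))
  hs_r <- stride_time * seq(0, n_strides - 1)
  hs_l <- stride_time * (seq(0, n_strides - 1) + 0.5)
  ev <- rbind(data.frame(time = hs_r, leg = "r"),
              data.frame(time = hs_l, leg = "l"))
  ev <- ev[ev$time > 0 & ev$time <= max(tt), ]
  ev$com_x <- speed * ev$time
  ev <- ev[order(ev$time), ]
  traj <- structure(list(samples = samples, events = ev, fell = FALSE,
                         T_fall = NA_real_, t_end = max(tt),
                         duration = max(tt), dt = 1 / fs, record_hz = fs,
                         scenario = walking_scenario(duration = max(tt)),
                         m_body = 80, m_back = 0, basal = 96),
                    class = "walker_trajectory")
  list(bands = bands, emg = list(signal = emg, fs = emg_fs, bursts = bursts),
       trajectory = traj)
}
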