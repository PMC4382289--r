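test_that("load attachment follows the printed rule", {
  m <- walker_model()
  expect_equal(attach_load(m, 0), m)              # no-op at zero load
  m20 <- attach_load(m, 0.2)
  expect_equal(m20$m_back, 16)                    # 0.2 * 80 kg
  expect_equal(m20$I_back, 2.4)                   # 0.15 * M_back
  expect_equal(m20$back_dx, -0.1)                 # 0.1 m posterior
  expect_equal(total_body_mass(m20), 96)
  expect_error(attach_load(m, 1.5), "load_fraction")
  # composite trunk+load COM shifts posterior by M_back * 0.1 / (m_hat + M_back)
  st <- walker_state(q = c(0, 1, 0, 0, 0, 0, 0, 0, 0))
  k0 <- walker_kinematics(m, st)
  k1 <- walker_kinematics(m20, st)
  trunk0 <- k0$segments[1, 1:2]
  comp <- (m$m_hat * k1$segments[1, 1:2] + 16 * k1$segments[2, 1:2]) /
    (m$m_hat + 16)
  expect_equal(comp[1] - trunk0[1], -16 * 0.1 / (m$m_hat + 16),
               tolerance = 1e-12)
})

test_that("incline environments have the stated grades", {
  expect_equal(apply_incline(walking_scenario())$grade, 0)
  expect_equal(apply_incline(walking_scenario(incline_deg = 5))$grade,
               0.087, tolerance = 0.01)
  expect_equal(apply_incline(walking_scenario(incline_deg = 20))$grade,
               0.364, tolerance = 0.01)
  g <- apply_incline(walking_scenario(incline_deg = 10))$gravity
  expect_equal(sqrt(sum(g^2)), 9.80665)            # magnitude preserved
  expect_lt(g[1], 0)                               # pulls back down the slope
})

test_that("rollouts are deterministic and record all channels", {
  w <- default_wiring()
  z <- default_design(w)
  t1 <- simulate_walker(z, walking_scenario(duration = 2))
  t2 <- simulate_walker(z, walking_scenario(duration = 2))
  expect_identical(t1$samples, t2$samples)
  expect_identical(t1$events, t2$events)
  expect_true(all(diff(t1$samples$t) > 0))
  expect_equal(t1$record_hz, 100)
  need <- c("t", "q_x", "qd_x", "u_sol_r", "act_ta_l", "f_gas_r",
            "lce_vas_l", "tau_hip_r", "lim_knee_l", "grf_y_r", "cop_x_l",
            "com_x", "com_vy", "head_vel_rel", "met_total", "hpe",
            "mode_r", "mode_l")
  expect_true(all(need %in% names(t1$samples)))
})

test_that("an unactuated model released standing falls and is flagged", {
  w <- default_wiring()
  d <- decode_design(default_design(w), w)
  d$cparams[] <- 0
  d$q0 <- c(0, 1.0, 0, 0.05, 0.05, 0, 0.05, 0.05, 0)
  d$q0[2] <- settle_height(walker_model(), d$q0)
  d$qd0 <- rep(0, 9)
  mus <- mtu_table(); mus$u0 <- 0
  tr <- simulate_walker(d, walking_scenario(duration = 10), muscles = mus)
  expect_true(tr$fell)
  expect_lt(tr$T_fall, 10)
  expect_equal(tr$t_end, tr$T_fall)
})

test_that("heel strikes are detected from engine events and mode channels", {
  # constructed fixture: synthetic mode signal with known transitions
  tt <- seq(0, 5.99, by = 0.01)
  mode_r <- rep(c(0, 0, 0, 1, 1, 2), each = 100)[seq_along(tt)]
  mode_l <- rep(c(1, 2, 0, 0, 0, 1), each = 100)[seq_along(tt)]
  s <- data.frame(t = tt, mode_r = mode_r, mode_l = mode_l)
  traj <- make_traj(s, events = NULL, duration = 6)
  hs <- detect_heelstrikes(traj)
  expect_equal(nrow(hs), 1)                  # one swing->stance per leg here
  expect_equal(hs$time[hs$leg == "l"], 2.0)
  # six constructed transitions are all recovered
  m6 <- rep(c(0, 1, 0, 2, 0, 1, 0, 2, 0, 1, 0, 2, 0), each = 46)[seq_along(tt)]
  s2 <- data.frame(t = tt, mode_r = m6, mode_l = rep(1, length(tt)))
  hs2 <- detect_heelstrikes(make_traj(s2, duration = 6))
  expect_equal(sum(hs2$leg == "r"), 6)
  # no transitions: empty result
  s3 <- data.frame(t = tt, mode_r = rep(0, length(tt)),
                   mode_l = rep(1, length(tt)))
  expect_equal(nrow(detect_heelstrikes(make_traj(s3, duration = 6))), 0)
})

test_that("tilted-plane and rotated-gravity inclines agree dynamically", {
  # the controller is held passive (zero gains) because its trunk-PD target
  # and swing threshold are deliberately frame-referenced; the passive plant
  # must be exactly equivalent between the two incline representations.
  # Stiff bouncing contact amplifies rounding differences chaotically, so
  # tight agreement is asserted on a short horizon and coarse agreement on a
  # longer one.
  gam <- 10 * pi / 180
  w <- default_wiring()
  d <- decode_design(default_design(w), w)
  d$cparams[] <- 0
  d$q0 <- c(0, 1.0, 0.05, 0.1, 0.15, 0.02, -0.05, 0.1, 0)
  d$q0[2] <- settle_height(walker_model(), d$q0, penetration = 0.001)
  d$qd0 <- c(0.5, 0, 0, 0, 0, 0, 0, 0, 0)
  R <- matrix(c(cos(gam), sin(gam), -sin(gam), cos(gam)), 2, 2)
  dB <- d
  dB$q0[1:2] <- R %*% d$q0[1:2]
  dB$q0[3] <- d$q0[3] - gam
  dB$qd0[1:2] <- R %*% d$qd0[1:2]
  # representation A: slope frame (gravity rotated, level plane)
  # representation B: world frame (vertical gravity, tilted plane)
  trA <- simulate_walker(d, walking_scenario(duration = 0.05, incline_deg = 10))
  trB <- simulate_walker(dB, walking_scenario(duration = 0.05),
                         contact = contact_params(plane_angle = gam))
  for (ch in c("q_hip_r", "q_knee_r", "q_ankle_r", "q_hip_l", "q_knee_l",
               "q_ankle_l"))
    expect_equal(trA$samples[[ch]], trB$samples[[ch]], tolerance = 1e-7)
  # frame-dependent pitch differs by exactly the plane angle
  expect_equal(trA$samples$q_pitch, trB$samples$q_pitch + gam,
               tolerance = 1e-8)
  trA4 <- simulate_walker(d, walking_scenario(duration = 0.4, incline_deg = 10))
  trB4 <- simulate_walker(dB, walking_scenario(duration = 0.4),
                          contact = contact_params(plane_angle = gam))
  expect_equal(trA4$samples$q_knee_r, trB4$samples$q_knee_r, tolerance = 5e-3)
})

test_that("steady strides satisfy the impulse-momentum balance", {
  # over a settled stride the net vertical GRF impulse must equal
  # weight * stride time (no net vertical momentum change)
  z <- shipped_warmstart()
  tr <- simulate_walker(z, walking_scenario(duration = 10))
  expect_false(tr$fell)
  hs <- detect_heelstrikes(tr)
  hr <- hs$time[hs$leg == "r"]
  expect_gte(length(hr), 8)
  s <- tr$samples
  weight <- 80 * 9.80665
  steady <- 6:(length(hr) - 1)       # early strides still carry transients
  rel <- vapply(steady, function(i) {
    win <- s$t >= hr[i] & s$t < hr[i + 1]
    mean(s$grf_y_r[win] + s$grf_y_l[win]) / weight - 1
  }, numeric(1))
  expect_lt(max(abs(rel)), 0.025)
  expect_lt(abs(mean(rel)), 0.02)
})

test_that("storage and CSV writers round-trip the sampled channels", {
  w <- default_wiring()
  tr <- simulate_walker(default_design(w), walking_scenario(duration = 1))
  f <- tempfile(fileext = ".sto")
  write_trajectory_sto(tr, f)
  back <- read_trajectory_sto(f)
  expect_equal(dim(back), dim(tr$samples))
  expect_equal(back$com_x, tr$samples$com_x, tolerance = 1e-12)
  fcsv <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, fcsv)
  expect_true(file.exists(paste0(fcsv, ".events.json")))
  ev <- jsonlite::read_json(paste0(fcsv, ".events.json"), simplifyVector = TRUE)
  expect_equal(ev$fell, tr$fell)
})
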