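test_that("reflex law algebra matches the control-law definitions", {
  # force feedback: u = G_F * F(t - D)
  expect_equal(force_feedback(1.2, 0.5), 0.6)
  expect_equal(force_feedback(2, 0), 0)
  expect_error(force_feedback(1, -0.1), "non-negative")
  # stretch feedback: zero at and below the threshold, linear above
  expect_equal(stretch_feedback(2, 1.0, 1.0), 0)
  expect_equal(stretch_feedback(2, 1.1, 1.0), 0.2)
  expect_equal(stretch_feedback(2, 0.8, 1.0), 0)
  # PD: rectified at zero
  expect_equal(pd_feedback(10, 0, 0.5, 0, 0.5), 0)
  expect_equal(pd_feedback(10, 0, 0.6, 0, 0.5), 1.0)
  expect_equal(pd_feedback(10, 1, 0.4, -0.5, 0.5), 0)   # negative bracket
  expect_equal(pd_feedback(10, 2, 0.5, 0.3, 0.5), 0.6)  # derivative term
})

test_that("excitation composition adds the baseline and saturates", {
  expect_equal(compose_excitation(numeric(0), u0 = 0.01), 0.01)
  expect_equal(compose_excitation(c(0.3, 0.2), u0 = 0.01), 0.51)
  expect_equal(compose_excitation(c(1.0, 0.7), u0 = 0.01), 1)   # clipped
  expect_equal(compose_excitation(c(-0.5), u0 = 0.01), 0)       # floor
})

test_that("the gait-mode machine follows the contact-driven transitions", {
  # stance foot leaving the ground enters early swing
  expect_equal(update_gait_mode("stance", FALSE, 0, 0, 0.15), "early_swing")
  # early swing becomes late swing once the ankle passes d_swing ahead of COM
  expect_equal(update_gait_mode("early_swing", FALSE, 0.20, 0, 0.15),
               "late_swing")
  expect_equal(update_gait_mode("early_swing", FALSE, 0.10, 0, 0.15),
               "early_swing")
  # foot strike returns to stance from either swing mode
  expect_equal(update_gait_mode("late_swing", TRUE, 0.3, 0, 0.15), "stance")
  expect_equal(update_gait_mode("early_swing", TRUE, 0.1, 0, 0.15), "stance")
  # stance persists while in contact
  expect_equal(update_gait_mode("stance", TRUE, -0.2, 0, 0.15), "stance")
})

test_that("delay buffers return samples recorded exactly D seconds earlier", {
  dt <- 5e-4
  for (D in c(0.005, 0.010, 0.020)) {
    buf <- delay_buffer(initial = 0, dt = dt)
    n <- 100
    sig <- sin(seq_len(n))
    got <- numeric(n)
    for (i in seq_len(n)) {
      buf$push(sig[i])
      got[i] <- buf$get(D)
    }
    k <- as.integer(D / dt)
    expect_identical(got[(k + 1):n], sig[seq_len(n - k)])
    expect_identical(got[seq_len(k)], rep(0, k))  # pre-filled history
  }
  expect_error(delay_buffer(dt = 5e-4)$get(0.0012), "multiple")
})

test_that("the default wiring defines exactly 74 design variables", {
  w <- default_wiring()
  expect_equal(design_length(w), 74)
  expect_equal(nrow(w$params), 55)       # free controller parameters
  expect_equal(nrow(w$extra), 19)        # d_swing + 18 initial conditions
  # left/right symmetry is structural: laws carry no leg index
  expect_false("leg" %in% names(w$laws))
  expect_error(validate_wiring(list(laws = data.frame(
    target = "XYZ", mode = "stance", type = "const", source = "XYZ",
    sign = 1, neg = 0, p1 = "st_sol_gf", p2 = NA, p3 = NA),
    params = default_wiring()$params)), "unknown target")
})

test_that("the shipped wiring YAML reloads to the default wiring", {
  f <- system.file("extdata", "wiring_default.yaml", package = "reflexgait")
  w <- read_wiring(f)
  w0 <- default_wiring()
  expect_equal(w$laws$target, w0$laws$target)
  expect_equal(w$laws$p1, w0$laws$p1)
  expect_equal(w$params$name, w0$params$name)
  expect_equal(w$params$lower, w0$params$lower)
  expect_equal(w$params$upper, w0$params$upper)
  expect_equal(design_length(w), 74)
})

test_that("with all gains zero every excitation stays at the baseline", {
  w <- default_wiring()
  d <- decode_design(default_design(w), w)
  d$cparams[] <- 0
  d$q0 <- c(0, 1.0, 0.05, 0.1, 0.1, 0.05, -0.1, 0.2, 0)
  d$q0[2] <- settle_height(walker_model(), d$q0)
  d$qd0 <- rep(0, 9)
  tr <- simulate_walker(d, walking_scenario(duration = 3))
  u_cols <- grep("^u_", names(tr$samples), value = TRUE)
  for (cc in u_cols) expect_true(all(tr$samples[[cc]] == 0.01))
})

test_that("rollout excitations obey the exact per-muscle reflex delay", {
  # wire only force feedback on one muscle per delay group; during continuous
  # stance the excitation must equal u0 + G * F delayed by exactly D, i.e.
  # shifted by D * 200 Hz samples on a 200 Hz recording grid
  w <- default_wiring()
  d0 <- decode_design(default_design(w), w)
  d0$cparams[] <- 0
  d0$q0 <- c(0, 1.0, 0.02, 0.05, 0.08, 0.05, 0.05, 0.08, 0.05)
  d0$q0[2] <- settle_height(walker_model(), d0$q0)
  d0$qd0 <- rep(0, 9)
  cases <- list(list(gain = "st_sol_gf", u = "u_sol_r", f = "f_sol_r", D = 0.020),
                list(gain = "st_vas_gf", u = "u_vas_r", f = "f_vas_r", D = 0.010),
                list(gain = "st_hams_gf", u = "u_hams_r", f = "f_hams_r", D = 0.005))
  for (cs in cases) {
    d <- d0
    d$cparams[cs$gain] <- 0.8
    tr <- simulate_walker(d, walking_scenario(duration = 2), record_hz = 200)
    s <- tr$samples
    k <- as.integer(cs$D * 200)
    stance <- s$mode_r == 0
    lagged_stance <- c(rep(FALSE, k), stance[seq_len(nrow(s) - k)])
    idx <- which(stance & lagged_stance)
    idx <- idx[idx > k + 2 & s[[cs$u]][idx] < 1]
    expect_gt(length(idx), 20)
    expect_equal(s[[cs$u]][idx], 0.01 + 0.8 * s[[cs$f]][idx - k],
                 tolerance = 1e-10)
    # the excitation must NOT match the undelayed signal
    expect_false(isTRUE(all.equal(s[[cs$u]][idx], 0.01 + 0.8 * s[[cs$f]][idx],
                                  tolerance = 1e-6)))
  }
})

test_that("rollouts are invariant under left-right exchange", {
  # the controller and model are structurally symmetric; trajectories of a
  # mirrored start match to floating-point accumulation accuracy over a
  # short horizon (summation order differs between the legs)
  w <- default_wiring()
  z <- default_design(w)
  d <- decode_design(z, w)
  d$q0[2] <- settle_height(walker_model(), d$q0)
  dm <- d
  dm$q0 <- mirror_q(d$q0); dm$qd0 <- mirror_q(d$qd0)
  t1 <- simulate_walker(d, walking_scenario(duration = 0.3))
  t2 <- simulate_walker(dm, walking_scenario(duration = 0.3))
  # excitations mirror exactly at the start (no accumulated rounding yet)
  expect_identical(t1$samples$u_sol_r[1], t2$samples$u_sol_l[1])
  expect_identical(t1$samples$u_ilpso_l[1], t2$samples$u_ilpso_r[1])
  expect_equal(t1$samples$q_hip_r, t2$samples$q_hip_l, tolerance = 1e-3)
  expect_equal(t1$samples$q_knee_r, t2$samples$q_knee_l, tolerance = 1e-3)
  expect_equal(t1$samples$act_sol_r, t2$samples$act_sol_l, tolerance = 1e-3)
  expect_equal(t1$samples$com_x, t2$samples$com_x, tolerance = 1e-4)
  expect_identical(t1$fell, t2$fell)
})
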