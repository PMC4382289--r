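test_that("model construction validates and reports nominal mass", {
  m <- walker_model()
  expect_s3_class(m, "walker_model")
  expect_equal(total_body_mass(m), 80)
  expect_error(walker_model(m_thigh = -1), "positive")
  expect_error(walker_state(q = rep(0, 8)), "length 9")
  expect_error(walker_state(q = c(NA, rep(0, 8))), "finite")
})

test_that("equilibrium without gravity or forces gives zero accelerations", {
  m <- walker_model(gravity = c(0, 0))
  st <- walker_state(q = c(0, 1.06, 0, 0.2, 0.1, -0.1, -0.3, 0.4, 0.2))
  fd <- forward_dynamics(m, st)
  expect_equal(fd$qdd, rep(0, 9), tolerance = 1e-12)
})

test_that("mass matrix is symmetric positive definite", {
  m <- walker_model()
  set.seed(3)
  for (i in 1:5) {
    st <- walker_state(q = c(runif(2), runif(7, -1, 1)),
                       qdot = runif(9, -2, 2))
    fd <- forward_dynamics(m, st)
    expect_equal(fd$mass_matrix, t(fd$mass_matrix))
    expect_gt(min(eigen(fd$mass_matrix, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
})

test_that("singular inertia is rejected as a hard error", {
  m <- walker_model()
  m$m_foot <- 0; m$I_foot <- 0   # bypass constructor validation on purpose
  st <- walker_state(q = c(0, 1, rep(0, 7)))
  expect_error(rg_dynamics_cpp(unclass(m), st$q, st$qdot, numeric(9)),
               "singular")
})

test_that("forward dynamics matches the independent Lagrangian oracle", {
  m <- walker_model(m_back = 8, I_back = 1.2)
  set.seed(42)
  for (i in 1:6) {
    q <- c(runif(1, -1, 1), runif(1, 0.8, 1.2), runif(7, -0.5, 0.5))
    qd <- runif(9, -1, 1)
    tau <- runif(9, -20, 20)
    fd <- forward_dynamics(m, walker_state(q, qd), tau)
    expected <- oracle_qdd(m, q, qd, tau)
    expect_equal(fd$qdd, expected, tolerance = 1e-6)
  }
})

test_that("heavy-trunk reduction reproduces the closed-form pendulum", {
  # a very heavy trunk held by a vertical support force at the hip acts as a
  # near-inertial pivot; the one remaining massive segment (a thigh) then
  # swings as a rigid pendulum: qdd = -(m g d / I_pivot) sin(theta)
  m <- walker_model(m_hat = 1e5, I_hat = 1e5,
                    m_shank = 1e-4, I_shank = 1e-5,
                    m_foot = 1e-4, I_foot = 1e-5)
  g <- 9.80665
  support <- c(0, (m$m_hat + m$m_thigh * 2 + 2e-4 * 2) * g, rep(0, 7))
  for (th in c(0.3, -0.7, 1.2)) {
    st <- walker_state(q = c(0, 1, 0, th, 0, 0, 0, 0, 0))
    fd <- forward_dynamics(m, st, support)
    I_pivot <- m$I_thigh + m$m_thigh * m$d_thigh^2
    expected <- -(m$m_thigh * g * m$d_thigh / I_pivot) * sin(th)
    expect_equal(fd$qdd[4], expected, tolerance = 1e-3)
  }
})

test_that("passive contact-free dynamics conserve mechanical energy", {
  m <- walker_model()
  q <- c(0, 1.0, 0.1, 0.3, 0.2, -0.1, -0.2, 0.4, 0.1)
  qd <- c(0.3, 0.1, -0.2, 0.5, -0.3, 0.2, 0.1, -0.4, 0.3)
  E0 <- oracle_energy(m, q, qd)
  dt <- 1e-4
  for (i in 1:10000) {    # 1 s of free fall and swing
    qdd <- forward_dynamics(m, walker_state(q, qd))$qdd
    qd <- qd + dt * qdd
    q <- q + dt * qd
  }
  expect_lt(abs(oracle_energy(m, q, qd) - E0) / abs(E0), 1e-3)
})

test_that("mirroring a state mirrors the dynamics exactly", {
  m <- walker_model()
  set.seed(7)
  for (i in 1:4) {
    q <- c(0, runif(1, 0.9, 1.1), runif(7, -0.6, 0.6))
    qd <- runif(9, -2, 2)
    tau <- c(runif(3, -10, 10), runif(6, -30, 30))
    a1 <- forward_dynamics(m, walker_state(q, qd), tau)$qdd
    a2 <- forward_dynamics(m, walker_state(mirror_q(q), mirror_q(qd)),
                           mirror_q(tau))$qdd
    expect_equal(a1, mirror_q(a2), tolerance = 1e-12)
  }
})

test_that("joint limit torques vanish mid-range and follow the limit law", {
  m <- walker_model()
  st <- walker_state(q = c(0, 1, 0, 0.5, 0.5, 0, 0.5, 0.5, 0))
  jl <- joint_limit_torque(m, st)
  expect_equal(jl$torques, rep(0, 6))
  expect_equal(jl$hpe, 0)

  # knee hyperextended by delta beyond its lower limit, no damping
  m2 <- walker_model(limit_damping = 0)
  delta <- 0.1
  q <- c(0, 1, 0, 0.5, m2$limit_lower[2] - delta, 0, 0.5, 0.5, 0)
  jl2 <- joint_limit_torque(m2, walker_state(q))
  expect_equal(jl2$torques[2], m2$limit_stiffness * delta)
  expect_equal(jl2$hpe, (m2$limit_stiffness * delta)^2)

  # two joints violating: hpe sums the squares
  q3 <- q; q3[6] <- m2$limit_upper[3] + 0.2
  jl3 <- joint_limit_torque(m2, walker_state(q3))
  expect_equal(jl3$hpe, sum(jl3$torques^2))
  expect_equal(sum(jl3$torques != 0), 2)
})

test_that("COM kinematics are the mass-weighted segment average", {
  m <- walker_model(m_back = 10, I_back = 1.5)
  set.seed(11)
  q <- c(0.3, 1.0, runif(7, -0.5, 0.5))
  qd <- runif(9, -1, 1)
  ck <- com_kinematics(m, walker_state(q, qd))
  s <- oracle_segments(m, q)
  mm <- oracle_masses(m)
  expect_equal(ck$com_position,
               c(sum(mm$m * Re(s$P[, 1])), sum(mm$m * Re(s$P[, 2]))) / sum(mm$m),
               tolerance = 1e-12)
  # stationary model: zero COM velocity; rigid translation: COM moves at v
  expect_equal(com_kinematics(m, walker_state(q))$com_velocity, c(0, 0))
  v <- c(1.3, -0.4)
  ck2 <- com_kinematics(m, walker_state(q, c(v, rep(0, 7))))
  expect_equal(ck2$com_velocity, v, tolerance = 1e-12)
})

test_that("model YAML round-trips", {
  m <- walker_model(m_back = 4, I_back = 0.6)
  f <- tempfile(fileext = ".yaml")
  write_walker_model(m, f)
  m2 <- walker_model(file = f)
  expect_equal(total_body_mass(m2), total_body_mass(m))
  expect_equal(m2$gravity, m$gravity)
})
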