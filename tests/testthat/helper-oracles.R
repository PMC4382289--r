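# Independent oracles used across the suite.
#
# The dynamics oracle re-derives the planar equations of motion from scratch:
# segment positions are written as independent R expressions, differentiated
# by complex-step (machine precision), the mass matrix is assembled from
# kinetic energy, the Coriolis/centrifugal bias from Christoffel symbols of
# finite-differenced mass matrices, and gravity from the potential gradient.
# Nothing is shared with the compiled implementation.

oracle_segments <- function(m, q) {
  # returns complex-capable positions (8 x 2) and orientation angles (8)
  tau <- q[3]
  R2 <- function(p, vx, vy) c(cos(p) * vx - sin(p) * vy,
                              sin(p) * vx + cos(p) * vy)
  dvec <- function(p) c(sin(p), -cos(p))
  P <- matrix(0 + 0i, 8, 2); A <- rep(0 + 0i, 8)
  hip <- c(q[1], q[2])
  P[1, ] <- hip + m$d_hat * c(sin(tau), cos(tau)); A[1] <- -tau
  P[2, ] <- hip + R2(-tau, m$back_dx, m$d_hat);    A[2] <- -tau
  for (s in 0:1) {
    h <- q[4 + 3 * s]; k <- q[5 + 3 * s]; a <- q[6 + 3 * s]
    phth <- h - tau; phsh <- phth - k; gam <- phsh + a
    knee <- hip + m$l_thigh * dvec(phth)
    ank <- knee + m$l_shank * dvec(phsh)
    P[3 + 3 * s, ] <- hip + m$d_thigh * dvec(phth); A[3 + 3 * s] <- phth
    P[4 + 3 * s, ] <- knee + m$d_shank * dvec(phsh); A[4 + 3 * s] <- phsh
    P[5 + 3 * s, ] <- ank + R2(gam, m$foot_com[1], m$foot_com[2])
    A[5 + 3 * s] <- gam
  }
  list(P = P, A = A)
}

oracle_masses <- function(m) {
  list(m = c(m$m_hat, m$m_back, rep(c(m$m_thigh, m$m_shank, m$m_foot), 2)),
       I = c(m$I_hat, m$I_back, rep(c(m$I_thigh, m$I_shank, m$I_foot), 2)))
}

oracle_jacobian <- function(m, q) {
  h <- 1e-20
  Jx <- matrix(0, 8, 9); Jy <- matrix(0, 8, 9); Ja <- matrix(0, 8, 9)
  for (j in 1:9) {
    qc <- as.complex(q); qc[j] <- qc[j] + h * 1i
    s <- oracle_segments(m, qc)
    Jx[, j] <- Im(s$P[, 1]) / h
    Jy[, j] <- Im(s$P[, 2]) / h
    Ja[, j] <- Im(s$A) / h
  }
  list(Jx = Jx, Jy = Jy, Ja = Ja)
}

oracle_mass_matrix <- function(m, q) {
  J <- oracle_jacobian(m, q)
  mm <- oracle_masses(m)
  M <- matrix(0, 9, 9)
  for (i in 1:8) {
    if (mm$m[i] > 0)
      M <- M + mm$m[i] * (outer(J$Jx[i, ], J$Jx[i, ]) +
                          outer(J$Jy[i, ], J$Jy[i, ]))
    M <- M + mm$I[i] * outer(J$Ja[i, ], J$Ja[i, ])
  }
  M
}

oracle_qdd <- function(m, q, qd, tau_applied = numeric(9)) {
  M <- oracle_mass_matrix(m, q)
  h <- 1e-6
  dM <- array(0, c(9, 9, 9))
  for (k in 1:9) {
    qp <- q; qp[k] <- qp[k] + h
    qm <- q; qm[k] <- qm[k] - h
    dM[, , k] <- (oracle_mass_matrix(m, qp) - oracle_mass_matrix(m, qm)) / (2 * h)
  }
  bias <- numeric(9)
  for (i in 1:9) for (j in 1:9) for (k in 1:9)
    bias[i] <- bias[i] +
      0.5 * (dM[i, j, k] + dM[i, k, j] - dM[j, k, i]) * qd[j] * qd[k]
  mm <- oracle_masses(m)
  Qg <- numeric(9)
  for (j in 1:9) {
    qc <- as.complex(q); qc[j] <- qc[j] + 1e-20i
    s <- oracle_segments(m, qc)
    Qg[j] <- sum(mm$m * (Im(s$P[, 1]) / 1e-20 * m$gravity[1] +
                         Im(s$P[, 2]) / 1e-20 * m$gravity[2]))
  }
  solve(M, tau_applied + Qg - bias)
}

oracle_energy <- function(m, q, qd) {
  M <- oracle_mass_matrix(m, q)
  s <- oracle_segments(m, q)
  mm <- oracle_masses(m)
  V <- -sum(mm$m * (Re(s$P[, 1]) * m$gravity[1] + Re(s$P[, 2]) * m$gravity[2]))
  0.5 * drop(t(qd) %*% M %*% qd) + V
}

# independent Stribeck friction coefficient (mirrors the documented blend)
oracle_mu <- function(v, mu_s, mu_d, mu_v, v_t) {
  s <- v / v_t
  mu_d * tanh(4 * s) + (mu_s - mu_d) * s / (0.25 * s^2 + 0.75)^2 + mu_v * v
}

# independent Hill curve evaluations (documented formulation)
oracle_f_l <- function(x) exp(-(x - 1)^2 / 0.45)
oracle_f_pe <- function(x) ifelse(x <= 1, 0,
                                  (exp(4 * (x - 1) / 0.6) - 1) / (exp(4) - 1))
oracle_f_v <- function(v) ifelse(v <= 0,
                                 ifelse(v <= -1, 0, (1 + v) / (1 - 4 * v)),
                                 1.5 - 0.5 / (1 + 10 * v))

# mirror a state/design left-right
mirror_q <- function(q) q[c(1, 2, 3, 7, 8, 9, 4, 5, 6)]

# hip height that puts the lowest contact sphere at a given penetration
settle_height <- function(model, q, penetration = 0) {
  kin <- walker_kinematics(model, walker_state(q))
  q[2] - (min(kin$spheres[, 2]) - model$sphere_radius) + penetration
}

# minimal synthetic trajectory for objective-term tests
make_traj <- function(samples, events = NULL, fell = FALSE, T_fall = NA,
                      duration = 10, m_body = 80, m_back = 0) {
  structure(list(samples = samples, events = events, fell = fell,
                 T_fall = T_fall,
                 t_end = if (fell) T_fall else duration,
                 duration = duration, dt = 0.01, record_hz = 100,
                 scenario = walking_scenario(duration = duration),
                 m_body = m_body, m_back = m_back, basal = 1.2 * m_body),
            class = "walker_trajectory")
}
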