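// Planar 7-segment, 9-DOF neuromusculoskeletal walker: rigid-body dynamics,
// Hunt-Crossley sphere contact, Hill-type musculotendon units with delayed
// reflex excitation, and the fixed-step closed-loop rollout engine.
//
// Coordinate conventions (x forward, y up, rotations about z):
//   q[0] hip x (m), q[1] hip y (m), q[2] trunk pitch (rad, + = forward lean),
//   q[3..5] right hip flexion / knee flexion / ankle dorsiflexion (rad, +),
//   q[6..8] same for the left leg.
// Segment orientation forms (counter-clockwise rates):
//   trunk  -q2 ; thigh  q3-q2 ; shank q3-q2-q4 ; foot q3-q2-q4+q5 (per leg).

#include <RcppArmadillo.h>
using namespace Rcpp;

static const int NQ = 9;
static const int NMUS = 16;   // 8 per leg, right then left
static const int NMUS_LEG = 8;

// ---------------------------------------------------------------- model ----

struct Model {
  // segment inertial / geometric parameters
  double m_hat, I_hat, d_hat, l_hat;
  double m_th, I_th, d_th, l_th;
  double m_sh, I_sh, d_sh, l_sh;
  double m_ft, I_ft, fcx, fcy;
  double heel_x, heel_y, ball_x, ball_y, r_sphere;
  double m_back, I_back, back_dx;       // backpack point mass on the trunk
  double gx, gy;                        // gravity vector (rotated on inclines)
  // one-sided joint limits (hip, knee, ankle; identical left/right)
  double lim_lo[3], lim_hi[3], k_lim, d_lim;
  double fall_height;
};

static Model parseModel(const List& m) {
  Model M;
  M.m_hat = m["m_hat"]; M.I_hat = m["I_hat"]; M.d_hat = m["d_hat"]; M.l_hat = m["l_hat"];
  M.m_th = m["m_thigh"]; M.I_th = m["I_thigh"]; M.d_th = m["d_thigh"]; M.l_th = m["l_thigh"];
  M.m_sh = m["m_shank"]; M.I_sh = m["I_shank"]; M.d_sh = m["d_shank"]; M.l_sh = m["l_shank"];
  M.m_ft = m["m_foot"]; M.I_ft = m["I_foot"];
  NumericVector fc = m["foot_com"]; M.fcx = fc[0]; M.fcy = fc[1];
  NumericVector he = m["heel_offset"]; M.heel_x = he[0]; M.heel_y = he[1];
  NumericVector ba = m["ball_offset"]; M.ball_x = ba[0]; M.ball_y = ba[1];
  M.r_sphere = m["sphere_radius"];
  M.m_back = m["m_back"]; M.I_back = m["I_back"]; M.back_dx = m["back_dx"];
  NumericVector g = m["gravity"]; M.gx = g[0]; M.gy = g[1];
  NumericVector lo = m["limit_lower"], hi = m["limit_upper"];
  for (int j = 0; j < 3; ++j) { M.lim_lo[j] = lo[j]; M.lim_hi[j] = hi[j]; }
  M.k_lim = m["limit_stiffness"]; M.d_lim = m["limit_damping"];
  M.fall_height = m["fall_height"];
  return M;
}

// ----------------------------------------------------------- kinematics ----

// A chain point: world position, velocity, 2x9 Jacobian, velocity-product
// acceleration (Jdot * qdot).
struct PointKin {
  double p[2], v[2], J[2][NQ], avp[2];
  void reset() {
    p[0] = p[1] = v[0] = v[1] = avp[0] = avp[1] = 0.0;
    for (int j = 0; j < NQ; ++j) { J[0][j] = 0.0; J[1][j] = 0.0; }
  }
  void baseHip(const double* q, const double* qd) {
    reset();
    p[0] = q[0]; p[1] = q[1]; v[0] = qd[0]; v[1] = qd[1];
    J[0][0] = 1.0; J[1][1] = 1.0;
  }
  // add a rotational term R(omega) * (vx, vy); the angle form omega has
  // sparse gradient {cols[i]: coefs[i]} over q, rate omdot.
  void addTerm(double omega, double omdot, double vx, double vy,
               const int* cols, const double* coefs, int nc) {
    double co = std::cos(omega), si = std::sin(omega);
    double Tx = co * vx - si * vy, Ty = si * vx + co * vy;
    double Px = -Ty, Py = Tx;                     // z x T
    p[0] += Tx; p[1] += Ty;
    v[0] += omdot * Px; v[1] += omdot * Py;
    avp[0] -= omdot * omdot * Tx; avp[1] -= omdot * omdot * Ty;
    for (int i = 0; i < nc; ++i) {
      J[0][cols[i]] += coefs[i] * Px;
      J[1][cols[i]] += coefs[i] * Py;
    }
  }
};

struct BodyKin {
  PointKin pt;          // COM
  double m, I;
  double c[NQ];         // angular-velocity coefficient row (ccw)
  double omdot;
};

struct Kin {
  BodyKin body[8];      // trunk, backpack, thighR, shankR, footR, thighL, shankL, footL
  int nbody;
  PointKin head, ankle[2], sphere[4];  // spheres: heelR, ballR, heelL, ballL
  double foot_omega[2];                // ccw angular rate of each foot
  double foot_c[2][NQ];
  double com[2], comv[2];
  double mass_total;
};

static void legKinematics(const Model& M, const double* q, const double* qd,
                          int side, Kin& K, int body0) {
  // side 0 = right (cols 3,4,5), 1 = left (cols 6,7,8)
  int ch = 3 + 3 * side, ck = ch + 1, ca = ch + 2;
  double tau = q[2], h = q[ch], k = q[ck], a = q[ca];
  double taud = qd[2], hd = qd[ch], kd = qd[ck], ad = qd[ca];

  double A2 = h - tau,          A2d = hd - taud;
  double A3 = h - tau - k,      A3d = hd - taud - kd;
  double A4 = h - tau - k + a,  A4d = hd - taud - kd + ad;
  int c2[2] = {2, ch};            double s2[2] = {-1.0, 1.0};
  int c3[3] = {2, ch, ck};        double s3[3] = {-1.0, 1.0, -1.0};
  int c4[4] = {2, ch, ck, ca};    double s4[4] = {-1.0, 1.0, -1.0, 1.0};

  BodyKin& thigh = K.body[body0];
  thigh.pt.baseHip(q, qd);
  thigh.pt.addTerm(A2, A2d, 0.0, -M.d_th, c2, s2, 2);
  thigh.m = M.m_th; thigh.I = M.I_th; thigh.omdot = A2d;
  for (int j = 0; j < NQ; ++j) thigh.c[j] = 0.0;
  thigh.c[2] = -1.0; thigh.c[ch] = 1.0;

  BodyKin& shank = K.body[body0 + 1];
  shank.pt.baseHip(q, qd);
  shank.pt.addTerm(A2, A2d, 0.0, -M.l_th, c2, s2, 2);
  shank.pt.addTerm(A3, A3d, 0.0, -M.d_sh, c3, s3, 3);
  shank.m = M.m_sh; shank.I = M.I_sh; shank.omdot = A3d;
  for (int j = 0; j < NQ; ++j) shank.c[j] = 0.0;
  shank.c[2] = -1.0; shank.c[ch] = 1.0; shank.c[ck] = -1.0;

  BodyKin& foot = K.body[body0 + 2];
  foot.pt.baseHip(q, qd);
  foot.pt.addTerm(A2, A2d, 0.0, -M.l_th, c2, s2, 2);
  foot.pt.addTerm(A3, A3d, 0.0, -M.l_sh, c3, s3, 3);
  foot.pt.addTerm(A4, A4d, M.fcx, M.fcy, c4, s4, 4);
  foot.m = M.m_ft; foot.I = M.I_ft; foot.omdot = A4d;
  for (int j = 0; j < NQ; ++j) foot.c[j] = 0.0;
  foot.c[2] = -1.0; foot.c[ch] = 1.0; foot.c[ck] = -1.0; foot.c[ca] = 1.0;

  PointKin& ank = K.ankle[side];
  ank.baseHip(q, qd);
  ank.addTerm(A2, A2d, 0.0, -M.l_th, c2, s2, 2);
  ank.addTerm(A3, A3d, 0.0, -M.l_sh, c3, s3, 3);

  for (int s = 0; s < 2; ++s) {
    PointKin& sp = K.sphere[2 * side + s];
    sp = ank;
    double ox = (s == 0) ? M.heel_x : M.ball_x;
    double oy = (s == 0) ? M.heel_y : M.ball_y;
    sp.addTerm(A4, A4d, ox, oy, c4, s4, 4);
  }
  K.foot_omega[side] = A4d;
  for (int j = 0; j < NQ; ++j) K.foot_c[side][j] = foot.c[j];
}

static void computeKin(const Model& M, const double* q, const double* qd, Kin& K) {
  double tau = q[2], taud = qd[2];
  int ct[1] = {2}; double st[1] = {-1.0};

  BodyKin& trunk = K.body[0];
  trunk.pt.baseHip(q, qd);
  trunk.pt.addTerm(-tau, -taud, 0.0, M.d_hat, ct, st, 1);
  trunk.m = M.m_hat; trunk.I = M.I_hat; trunk.omdot = -taud;
  for (int j = 0; j < NQ; ++j) trunk.c[j] = 0.0;
  trunk.c[2] = -1.0;

  BodyKin& back = K.body[1];
  back.pt.baseHip(q, qd);
  back.pt.addTerm(-tau, -taud, M.back_dx, M.d_hat, ct, st, 1);
  back.m = M.m_back; back.I = M.I_back; back.omdot = -taud;
  for (int j = 0; j < NQ; ++j) back.c[j] = 0.0;
  back.c[2] = -1.0;

  K.head.baseHip(q, qd);
  K.head.addTerm(-tau, -taud, 0.0, M.l_hat, ct, st, 1);

  legKinematics(M, q, qd, 0, K, 2);
  legKinematics(M, q, qd, 1, K, 5);
  K.nbody = 8;

  double mt = 0.0, cx = 0.0, cy = 0.0, cvx = 0.0, cvy = 0.0;
  for (int b = 0; b < K.nbody; ++b) {
    const BodyKin& B = K.body[b];
    if (B.m <= 0.0) continue;
    mt += B.m;
    cx += B.m * B.pt.p[0]; cy += B.m * B.pt.p[1];
    cvx += B.m * B.pt.v[0]; cvy += B.m * B.pt.v[1];
  }
  K.mass_total = mt;
  K.com[0] = cx / mt; K.com[1] = cy / mt;
  K.comv[0] = cvx / mt; K.comv[1] = cvy / mt;
}

// ------------------------------------------------------------- dynamics ----

// Mass matrix, bias (Coriolis/centrifugal), and generalized gravity force.
static void assembleDynamics(const Model& M, const Kin& K,
                             arma::mat& Mass, arma::vec& bias, arma::vec& Qg) {
  Mass.zeros(NQ, NQ); bias.zeros(NQ); Qg.zeros(NQ);
  for (int b = 0; b < K.nbody; ++b) {
    const BodyKin& B = K.body[b];
    if (B.m <= 0.0 && B.I <= 0.0) continue;
    for (int i = 0; i < NQ; ++i) {
      double Jxi = B.pt.J[0][i], Jyi = B.pt.J[1][i];
      if (B.m > 0.0) {
        for (int j = i; j < NQ; ++j)
          Mass(i, j) += B.m * (Jxi * B.pt.J[0][j] + Jyi * B.pt.J[1][j]);
        bias(i) += B.m * (Jxi * B.pt.avp[0] + Jyi * B.pt.avp[1]);
        Qg(i) += B.m * (Jxi * M.gx + Jyi * M.gy);
      }
      if (B.I > 0.0 && B.c[i] != 0.0)
        for (int j = i; j < NQ; ++j)
          if (B.c[j] != 0.0) Mass(i, j) += B.I * B.c[i] * B.c[j];
    }
  }
  for (int i = 1; i < NQ; ++i)
    for (int j = 0; j < i; ++j) Mass(i, j) = Mass(j, i);
}

// Fixed-size Cholesky solve for the 9x9 mass matrix (hot path).
static bool cholSolve9(const arma::mat& A, const arma::vec& b, double* x) {
  double L[NQ][NQ];
  for (int i = 0; i < NQ; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A(i, j);
      for (int k = 0; k < j; ++k) s -= L[i][k] * L[j][k];
      if (i == j) {
        if (s <= 0.0) return false;
        L[i][i] = std::sqrt(s);
      } else L[i][j] = s / L[j][j];
    }
  }
  double y[NQ];
  for (int i = 0; i < NQ; ++i) {
    double s = b(i);
    for (int k = 0; k < i; ++k) s -= L[i][k] * y[k];
    y[i] = s / L[i][i];
  }
  for (int i = NQ - 1; i >= 0; --i) {
    double s = y[i];
    for (int k = i + 1; k < NQ; ++k) s -= L[k][i] * x[k];
    x[i] = s / L[i][i];
  }
  return true;
}

// One-sided nonlinear spring-damper joint limits; returns instantaneous HPE.
static double jointLimitTorques(const Model& M, const double* q, const double* qd,
                                double* tau6) {
  double hpe = 0.0;
  for (int leg = 0; leg < 2; ++leg) {
    for (int j = 0; j < 3; ++j) {
      int idx = 3 + 3 * leg + j;
      double th = q[idx], thd = qd[idx], t = 0.0;
      if (th > M.lim_hi[j]) {
        t = -M.k_lim * (th - M.lim_hi[j]) - M.d_lim * thd;
        if (t > 0.0) t = 0.0;                     // limit never attracts
      } else if (th < M.lim_lo[j]) {
        t = -M.k_lim * (th - M.lim_lo[j]) - M.d_lim * thd;
        if (t < 0.0) t = 0.0;
      }
      tau6[3 * leg + j] = t;
      hpe += t * t;
    }
  }
  return hpe;
}

// -------------------------------------------------------------- contact ----

// Smooth Stribeck friction coefficient (odd in v): dynamic tanh branch,
// static hump, viscous term. v_t scales the transition region.
static double frictionMu(double v, double mu_s, double mu_d, double mu_v, double v_t) {
  double s = v / v_t;
  double hump = (mu_s - mu_d) * s / std::pow(0.25 * s * s + 0.75, 2);
  return mu_d * std::tanh(4.0 * s) + hump + mu_v * v;
}

static double huntCrossley(double h, double hdot, double k, double c) {
  if (h <= 0.0) return 0.0;
  double f = k * std::pow(h, 1.5) * (1.0 + 1.5 * c * hdot);
  return f > 0.0 ? f : 0.0;
}

struct ContactParams {
  double k, c, mu_s, mu_d, mu_v, v_t;
  double plane_angle;   // ground plane tilt (rad); normal = (-sin, cos)
};

static ContactParams parseContact(const List& cp) {
  ContactParams C;
  C.k = cp["k"]; C.c = cp["c"]; C.mu_s = cp["mu_s"]; C.mu_d = cp["mu_d"];
  C.mu_v = cp["mu_v"]; C.v_t = cp["v_t"];
  C.plane_angle = cp.containsElementNamed("plane_angle") ?
    double(cp["plane_angle"]) : 0.0;
  return C;
}

struct FootContact {
  double grf_x, grf_y, cop_x;     // plane-frame tangential/normal, COP along plane
  double sphere_n[2];             // per-sphere normal force
};

// Contact for one foot (2 spheres); accumulates generalized forces into Q.
// When Dmat is given, the velocity-derivative of the contact force (friction
// slope and Hunt-Crossley dissipation) is accumulated as a generalized
// damping matrix for implicit (first-order) treatment by the integrator:
// the steep friction transition around zero slip is far too stiff for a
// 0.5 ms explicit step on the light foot segment.
static void footContact(const Model& M, const ContactParams& C, const Kin& K,
                        int side, arma::vec& Q, FootContact& out,
                        arma::mat* Dmat = 0) {
  double nb_x = -std::sin(C.plane_angle), nb_y = std::cos(C.plane_angle);
  double tg_x = std::cos(C.plane_angle), tg_y = std::sin(C.plane_angle);
  out.grf_x = out.grf_y = 0.0;
  double cop_num = 0.0;
  for (int s = 0; s < 2; ++s) {
    const PointKin& sp = K.sphere[2 * side + s];
    double dist = sp.p[0] * nb_x + sp.p[1] * nb_y;     // center to plane
    double h = M.r_sphere - dist;
    out.sphere_n[s] = 0.0;
    if (h <= 0.0) continue;
    // contact point: sphere center advanced to the surface along -normal
    double off_x = -M.r_sphere * nb_x, off_y = -M.r_sphere * nb_y;
    double om = K.foot_omega[side];
    double vpx = sp.v[0] - om * off_y, vpy = sp.v[1] + om * off_x;
    double hdot = -(vpx * nb_x + vpy * nb_y);
    double N = huntCrossley(h, hdot, C.k, C.c);
    double vslip = vpx * tg_x + vpy * tg_y;
    double Ft = -frictionMu(vslip, C.mu_s, C.mu_d, C.mu_v, C.v_t) * N;
    double Fx = N * nb_x + Ft * tg_x, Fy = N * nb_y + Ft * tg_y;
    out.sphere_n[s] = N;
    out.grf_y += N; out.grf_x += Ft;
    cop_num += N * ((sp.p[0] + off_x) * tg_x + (sp.p[1] + off_y) * tg_y);
    // contact-point Jacobian rows (translation + rotation of the offset)
    double Jt[NQ], Jn[NQ];
    for (int j = 0; j < NQ; ++j) {
      double cj = K.foot_c[side][j];
      double Jpx = sp.J[0][j] - cj * off_y;
      double Jpy = sp.J[1][j] + cj * off_x;
      Jt[j] = Jpx * tg_x + Jpy * tg_y;
      Jn[j] = Jpx * nb_x + Jpy * nb_y;
      Q(j) += Jpx * Fx + Jpy * Fy;
    }
    if (Dmat) {
      double ss = vslip / C.v_t, ch = std::cosh(4.0 * ss);
      double dmu = C.mu_d * 4.0 / C.v_t / (ch * ch) + C.mu_v;
      double c_t = N * dmu;                              // friction slope
      double c_n = C.k * std::pow(h, 1.5) * 1.5 * C.c;   // HC dissipation
      for (int i = 0; i < NQ; ++i)
        for (int j = 0; j < NQ; ++j)
          (*Dmat)(i, j) += c_t * Jt[i] * Jt[j] + c_n * Jn[i] * Jn[j];
    }
  }
  out.cop_x = out.grf_y > 0.0 ? cop_num / out.grf_y : NA_REAL;
}

// ------------------------------------------------------------------ MTU ----

struct MTU {
  double F_max, l_opt, v_max, l_slack, tau_act, u0, fast_twitch;
  // up to two spanned joints: local joint id within leg (0 hip, 1 knee,
  // 2 ankle), arm type (0 constant, 1 cosine), r0, theta_m, theta_ref, sign
  int njoint;
  int joint[2], arm_type[2];
  double r0[2], theta_m[2], theta_ref[2], sgn[2];
  int delay_steps;
};

static std::vector<MTU> parseMTU(const List& tab, double dt) {
  NumericVector F_max = tab["F_max"], l_opt = tab["l_opt"], v_max = tab["v_max"],
    l_slack = tab["l_slack"], tau_act = tab["tau_act"], u0 = tab["u0"],
    ft = tab["fast_twitch"], delay = tab["delay"];
  IntegerVector njoint = tab["n_joint"];
  IntegerVector j1 = tab["joint1"], at1 = tab["arm_type1"];
  NumericVector r01 = tab["r0_1"], tm1 = tab["theta_m1"], tr1 = tab["theta_ref1"],
    sg1 = tab["sign1"];
  IntegerVector j2 = tab["joint2"], at2 = tab["arm_type2"];
  NumericVector r02 = tab["r0_2"], tm2 = tab["theta_m2"], tr2 = tab["theta_ref2"],
    sg2 = tab["sign2"];
  int n = F_max.size();
  std::vector<MTU> mus(n);
  for (int i = 0; i < n; ++i) {
    MTU& m = mus[i];
    m.F_max = F_max[i]; m.l_opt = l_opt[i]; m.v_max = v_max[i];
    m.l_slack = l_slack[i]; m.tau_act = tau_act[i]; m.u0 = u0[i];
    m.fast_twitch = ft[i];
    m.njoint = njoint[i];
    m.joint[0] = j1[i]; m.arm_type[0] = at1[i]; m.r0[0] = r01[i];
    m.theta_m[0] = tm1[i]; m.theta_ref[0] = tr1[i]; m.sgn[0] = sg1[i];
    m.joint[1] = j2[i]; m.arm_type[1] = at2[i]; m.r0[1] = r02[i];
    m.theta_m[1] = tm2[i]; m.theta_ref[1] = tr2[i]; m.sgn[1] = sg2[i];
    m.delay_steps = (int) std::lround(delay[i] / dt);
    if (std::fabs(m.delay_steps * dt - delay[i]) > 1e-12)
      stop("integration step must divide the reflex delay exactly");
  }
  return mus;
}

// moment arm about a spanned joint; dl_mtu/dtheta = -arm
static inline double momentArm(const MTU& m, int k, double theta) {
  if (m.arm_type[k] == 0) return m.sgn[k] * m.r0[k];
  return m.sgn[k] * m.r0[k] * std::cos(theta - m.theta_m[k]);
}

static inline double pathTerm(const MTU& m, int k, double theta) {
  if (m.arm_type[k] == 0) return -m.sgn[k] * m.r0[k] * (theta - m.theta_ref[k]);
  return -m.sgn[k] * m.r0[k] *
    (std::sin(theta - m.theta_m[k]) - std::sin(m.theta_ref[k] - m.theta_m[k]));
}

static double pathLength(const MTU& m, const double* qleg) {
  double l = m.l_slack + m.l_opt;
  for (int k = 0; k < m.njoint; ++k) l += pathTerm(m, k, qleg[m.joint[k]]);
  return l;
}

// Hill curves (shared with the R-level oracles through exported wrappers)
static inline double fL(double lnorm) {
  double d = lnorm - 1.0;
  return std::exp(-d * d / 0.45);
}
static inline double fPE(double lnorm) {
  if (lnorm <= 1.0) return 0.0;
  return (std::exp(4.0 * (lnorm - 1.0) / 0.6) - 1.0) / (std::exp(4.0) - 1.0);
}
static inline double fV(double vnorm) {      // vnorm = v_ce / v_max, - shortening
  if (vnorm <= 0.0) {
    if (vnorm <= -1.0) return 0.0;
    return (1.0 + vnorm) / (1.0 - 4.0 * vnorm);
  }
  return 1.5 - 0.5 / (1.0 + 10.0 * vnorm);
}
static inline double fVinv(double f) {       // inverse of fV, f in [0, 1.45]
  if (f <= 1.0) return (f - 1.0) / (1.0 + 4.0 * f);
  return (0.5 / (1.5 - f) - 1.0) / 10.0;
}
static inline double tendonForceNorm(double l_t, double l_slack) {
  double eps = (l_t - l_slack) / l_slack;
  if (eps <= 0.0) return 0.0;
  double r = eps / 0.04;
  return r * r;
}

// Tendon-equilibrium fiber velocity: invert the force-velocity curve so the
// contractile element force matches the series-elastic tendon force.
static double fiberVelocity(const MTU& m, double a, double l_ce, double l_mtu,
                            double& F_norm_out) {
  double lnorm = l_ce / m.l_opt;
  double F_se = tendonForceNorm(l_mtu - l_ce, m.l_slack);
  double fv_req = (F_se - fPE(lnorm)) / (a * fL(lnorm) + 0.01);
  if (fv_req < 0.0) fv_req = 0.0;
  if (fv_req > 1.45) fv_req = 1.45;
  F_norm_out = F_se;
  return fVinv(fv_req) * m.v_max * m.l_opt;
}

// ------------------------------------------------------------ metabolics ---

// Per-muscle metabolic power: activation/maintenance heat proportional to
// estimated muscle mass and twitch composition, shortening heat, and positive
// mechanical work, in the Anderson-Pandy heat-rate tradition.
static const double MUSCLE_DENSITY = 1059.7;   // kg/m^3
static const double SPECIFIC_TENSION = 0.25e6; // Pa

static inline double muscleMass(const MTU& m) {
  return m.F_max * m.l_opt * MUSCLE_DENSITY / SPECIFIC_TENSION;
}
static inline double heatRateAM(const MTU& m, double a) {
  return muscleMass(m) * (25.0 + 128.0 * m.fast_twitch) * a;
}
static double metabolicMuscle(const MTU& m, double a, double v_ce, double F) {
  double p = heatRateAM(m, a);
  if (v_ce < 0.0) {
    p += 0.25 * F * (-v_ce);          // shortening heat
    p += F * (-v_ce);                 // positive mechanical work
  }
  return p;
}

// ----------------------------------------------------------- controller ----

// Declarative wiring law: target muscle gets a contribution in one gait mode.
// type: 0 constant, 1 force feedback, 2 stretch feedback, 3 PD.
// source: muscle index within leg (force/stretch) or PD channel
//   (0 trunk pitch, 1 hip, 2 knee, 3 ankle).
// p1,p2,p3: indices into the controller parameter vector (-1 = unused).
// sign multiplies the signal inside the rectification bracket; neg = 1 turns
// the (rectified) law output into an inhibitory contribution.
struct Law { int target, mode, type, source, p1, p2, p3, neg; double sign; };

static std::vector<Law> parseLaws(const IntegerMatrix& lm, const NumericVector& sg) {
  int n = lm.nrow();
  std::vector<Law> laws(n);
  for (int i = 0; i < n; ++i) {
    laws[i].target = lm(i, 0); laws[i].mode = lm(i, 1); laws[i].type = lm(i, 2);
    laws[i].source = lm(i, 3); laws[i].p1 = lm(i, 4); laws[i].p2 = lm(i, 5);
    laws[i].p3 = lm(i, 6); laws[i].neg = lm(i, 7); laws[i].sign = sg[i];
  }
  return laws;
}

// ------------------------------------------------------------- exports -----

// [[Rcpp::export]]
List rg_dynamics_cpp(List model, NumericVector q, NumericVector qd,
                     NumericVector forces) {
  Model M = parseModel(model);
  Kin K;
  computeKin(M, q.begin(), qd.begin(), K);
  arma::mat Mass; arma::vec bias, Qg;
  assembleDynamics(M, K, Mass, bias, Qg);
  arma::vec rhs = Qg - bias;
  for (int j = 0; j < NQ; ++j) rhs(j) += forces[j];
  arma::vec qdd;
  bool ok = arma::solve(qdd, Mass, rhs, arma::solve_opts::no_approx);
  if (!ok || arma::rcond(Mass) < 1e-14)
    stop("singular mass matrix: check segment inertial parameters");
  return List::create(_["qdd"] = NumericVector(qdd.begin(), qdd.end()),
                      _["mass_matrix"] = Mass,
                      _["bias"] = NumericVector(bias.begin(), bias.end()),
                      _["gravity_force"] = NumericVector(Qg.begin(), Qg.end()));
}

// [[Rcpp::export]]
List rg_kinematics_cpp(List model, NumericVector q, NumericVector qd) {
  Model M = parseModel(model);
  Kin K;
  computeKin(M, q.begin(), qd.begin(), K);
  NumericMatrix seg(K.nbody, 4);
  for (int b = 0; b < K.nbody; ++b) {
    seg(b, 0) = K.body[b].pt.p[0]; seg(b, 1) = K.body[b].pt.p[1];
    seg(b, 2) = K.body[b].pt.v[0]; seg(b, 3) = K.body[b].pt.v[1];
  }
  NumericMatrix sph(4, 4);
  for (int s = 0; s < 4; ++s) {
    sph(s, 0) = K.sphere[s].p[0]; sph(s, 1) = K.sphere[s].p[1];
    sph(s, 2) = K.sphere[s].v[0]; sph(s, 3) = K.sphere[s].v[1];
  }
  return List::create(
    _["com"] = NumericVector::create(K.com[0], K.com[1]),
    _["com_vel"] = NumericVector::create(K.comv[0], K.comv[1]),
    _["head"] = NumericVector::create(K.head.p[0], K.head.p[1]),
    _["head_vel"] = NumericVector::create(K.head.v[0], K.head.v[1]),
    _["ankle_r"] = NumericVector::create(K.ankle[0].p[0], K.ankle[0].p[1]),
    _["ankle_l"] = NumericVector::create(K.ankle[1].p[0], K.ankle[1].p[1]),
    _["segments"] = seg, _["spheres"] = sph,
    _["mass_total"] = K.mass_total);
}

// [[Rcpp::export]]
List rg_joint_limits_cpp(List model, NumericVector q, NumericVector qd) {
  Model M = parseModel(model);
  double tau6[6];
  double hpe = jointLimitTorques(M, q.begin(), qd.begin(), tau6);
  return List::create(_["torques"] = NumericVector(tau6, tau6 + 6),
                      _["hpe"] = hpe);
}

// [[Rcpp::export]]
double rg_normal_force_cpp(double h, double hdot, double k, double c) {
  return huntCrossley(h, hdot, k, c);
}

// [[Rcpp::export]]
double rg_friction_mu_cpp(double v, double mu_s, double mu_d, double mu_v,
                          double v_t) {
  return frictionMu(v, mu_s, mu_d, mu_v, v_t);
}

// [[Rcpp::export]]
List rg_foot_contact_cpp(List model, List contact, NumericVector q,
                         NumericVector qd) {
  Model M = parseModel(model);
  ContactParams C = parseContact(contact);
  Kin K;
  computeKin(M, q.begin(), qd.begin(), K);
  arma::vec Q(NQ, arma::fill::zeros);
  FootContact fr, fl;
  footContact(M, C, K, 0, Q, fr);
  footContact(M, C, K, 1, Q, fl);
  return List::create(
    _["grf_r"] = NumericVector::create(_["grf_x"] = fr.grf_x,
      _["grf_y"] = fr.grf_y, _["cop_x"] = fr.cop_x,
      _["heel_n"] = fr.sphere_n[0], _["ball_n"] = fr.sphere_n[1]),
    _["grf_l"] = NumericVector::create(_["grf_x"] = fl.grf_x,
      _["grf_y"] = fl.grf_y, _["cop_x"] = fl.cop_x,
      _["heel_n"] = fl.sphere_n[0], _["ball_n"] = fl.sphere_n[1]),
    _["generalized_forces"] = NumericVector(Q.begin(), Q.end()));
}

// [[Rcpp::export]]
NumericVector rg_hill_curves_cpp(double lnorm, double vnorm) {
  return NumericVector::create(_["f_l"] = fL(lnorm), _["f_v"] = fV(vnorm),
                               _["f_pe"] = fPE(lnorm));
}

// [[Rcpp::export]]
double rg_tendon_force_norm_cpp(double l_t, double l_slack) {
  return tendonForceNorm(l_t, l_slack);
}

// [[Rcpp::export]]
List rg_mtu_equilibrium_cpp(List mtu_row, double a, double l_ce, double l_mtu) {
  MTU m;
  m.F_max = mtu_row["F_max"]; m.l_opt = mtu_row["l_opt"];
  m.v_max = mtu_row["v_max"]; m.l_slack = mtu_row["l_slack"];
  double F_norm;
  double v_ce = fiberVelocity(m, a, l_ce, l_mtu, F_norm);
  return List::create(_["force"] = F_norm * m.F_max,
                      _["force_norm"] = F_norm,
                      _["l_ce_rate"] = v_ce);
}

// Path lengths and joint torques for a full muscle table at one leg pose.
// qleg = (hip, knee, ankle) angles.
// [[Rcpp::export]]
List rg_muscle_geometry_cpp(List mtu_table, NumericVector qleg,
                            NumericVector forces) {
  std::vector<MTU> mus = parseMTU(mtu_table, 5e-4);
  int n = mus.size();
  NumericVector len(n);
  NumericMatrix arms(n, 3);
  NumericVector tau(3);
  for (int i = 0; i < n; ++i) {
    len[i] = pathLength(mus[i], qleg.begin());
    for (int k = 0; k < mus[i].njoint; ++k) {
      double r = momentArm(mus[i], k, qleg[mus[i].joint[k]]);
      arms(i, mus[i].joint[k]) = r;
      tau[mus[i].joint[k]] += r * forces[i];
    }
  }
  return List::create(_["path_length"] = len, _["moment_arms"] = arms,
                      _["torques"] = tau);
}

// [[Rcpp::export]]
NumericVector rg_metabolic_cpp(List mtu_table, NumericVector a,
                               NumericVector v_ce, NumericVector F) {
  std::vector<MTU> mus = parseMTU(mtu_table, 5e-4);
  int n = mus.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = metabolicMuscle(mus[i], a[i], v_ce[i], F[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector rg_heat_am_cpp(List mtu_table, NumericVector a) {
  std::vector<MTU> mus = parseMTU(mtu_table, 5e-4);
  int n = mus.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = heatRateAM(mus[i], a[i]);
  return out;
}

// ------------------------------------------------------------- rollout -----

static const int MODE_STANCE = 0, MODE_EARLY = 1, MODE_LATE = 2;

struct DelayHistory {
  // fixed-capacity ring; capacity a power of two >= max delay steps + 1
  static const int CAP = 64, MASK = 63;
  std::vector<double> buf;   // nchan x CAP
  int nchan, head;
  void init(int nc, const double* init_vals) {
    nchan = nc; head = 0;
    buf.assign((size_t) nc * CAP, 0.0);
    for (int c = 0; c < nc; ++c)
      for (int s = 0; s < CAP; ++s) buf[(size_t) c * CAP + s] = init_vals[c];
  }
  void push(const double* vals) {
    head = (head + 1) & MASK;
    for (int c = 0; c < nchan; ++c) buf[(size_t) c * CAP + head] = vals[c];
  }
  double get(int chan, int delay_steps) const {
    return buf[(size_t) chan * CAP + ((head - delay_steps) & MASK)];
  }
};

// [[Rcpp::export]]
List rg_rollout_cpp(List model, List contact, List mtu_table,
                    IntegerMatrix law_matrix, NumericVector law_signs,
                    NumericVector cparams, double d_swing,
                    NumericVector q0, NumericVector qd0,
                    double duration, double dt, double record_dt,
                    double contact_on, double contact_off) {
  Model M = parseModel(model);
  ContactParams C = parseContact(contact);
  std::vector<MTU> mus = parseMTU(mtu_table, dt);
  if ((int) mus.size() != NMUS_LEG) stop("expected 8 muscles per leg");
  std::vector<Law> laws = parseLaws(law_matrix, law_signs);

  int nstep = (int) std::lround(duration / dt);
  int rec_every = (int) std::lround(record_dt / dt);
  int nrec_max = nstep / rec_every + 2;

  // state
  double q[NQ], qd[NQ];
  for (int j = 0; j < NQ; ++j) { q[j] = q0[j]; qd[j] = qd0[j]; }
  double act[NMUS], l_ce[NMUS], u_exc[NMUS], F_norm[NMUS], v_ce[NMUS];
  int mode[2];
  bool in_contact[2];

  Kin K;
  computeKin(M, q, qd, K);

  // initial fiber lengths: tendon at slack (zero force) where possible
  for (int leg = 0; leg < 2; ++leg) {
    const double* qleg = q + 3 + 3 * leg;
    for (int i = 0; i < NMUS_LEG; ++i) {
      int gi = leg * NMUS_LEG + i;
      double lm = pathLength(mus[i], qleg);
      double lc = lm - mus[i].l_slack;
      double lo = mus[i].l_opt;
      if (lc < 0.5 * lo) lc = 0.5 * lo;
      if (lc > 1.5 * lo) lc = 1.5 * lo;
      l_ce[gi] = lc;
      act[gi] = mus[i].u0;
      u_exc[gi] = mus[i].u0;
      F_norm[gi] = tendonForceNorm(lm - lc, mus[i].l_slack);
      v_ce[gi] = 0.0;
    }
  }

  // delay history channels, per leg: F_norm(8), l_ce_norm(8), trunk pitch,
  // trunk rate, hip, hip rate, knee, knee rate, ankle, ankle rate  -> 24
  const int NCH = 24;
  DelayHistory hist[2];
  for (int leg = 0; leg < 2; ++leg) {
    double init_vals[NCH];
    const double* qleg = q + 3 + 3 * leg;
    const double* qdleg = qd + 3 + 3 * leg;
    for (int i = 0; i < NMUS_LEG; ++i) {
      init_vals[i] = F_norm[leg * NMUS_LEG + i];
      init_vals[NMUS_LEG + i] = l_ce[leg * NMUS_LEG + i] / mus[i].l_opt;
    }
    init_vals[16] = q[2]; init_vals[17] = qd[2];
    for (int j = 0; j < 3; ++j) {
      init_vals[18 + 2 * j] = qleg[j];
      init_vals[19 + 2 * j] = qdleg[j];
    }
    hist[leg].init(NCH, init_vals);
  }

  // initial contact / gait modes
  {
    arma::vec Qtmp(NQ, arma::fill::zeros);
    FootContact fc[2];
    footContact(M, C, K, 0, Qtmp, fc[0]);
    footContact(M, C, K, 1, Qtmp, fc[1]);
    for (int leg = 0; leg < 2; ++leg) {
      in_contact[leg] = fc[leg].grf_y > contact_on;
      if (in_contact[leg]) mode[leg] = MODE_STANCE;
      else {
        double dx = K.ankle[leg].p[0] - K.com[0];
        mode[leg] = dx > d_swing ? MODE_LATE : MODE_EARLY;
      }
    }
  }

  // recording: t, q(9), qd(9), u/act/F/lce (4x16), muscle + limit torques
  // (6+6), GRF r/l (3+3), COM (4), head rel. vel., muscle metabolic power,
  // HPE, modes (2)
  int ncol = 110;
  NumericMatrix rec(nrec_max, ncol);
  int nrec = 0;
  std::vector<double> ev_time; std::vector<int> ev_leg; std::vector<double> ev_comx;
  double t = 0.0, T_fall = -1.0;
  bool fell = false;

  arma::mat::fixed<NQ, NQ> Mass, Dmat; arma::vec::fixed<NQ> bias, Qg, Q, rhs9;
  double nb_x0 = -std::sin(C.plane_angle), nb_y0 = std::cos(C.plane_angle);

  for (int step = 0; step <= nstep; ++step) {
    computeKin(M, q, qd, K);

    // contact forces + gait-mode machine
    Q.zeros(); Dmat.zeros();
    FootContact fc[2];
    footContact(M, C, K, 0, Q, fc[0], &Dmat);
    footContact(M, C, K, 1, Q, fc[1], &Dmat);
    for (int leg = 0; leg < 2; ++leg) {
      if (in_contact[leg]) {
        if (fc[leg].grf_y < contact_off) in_contact[leg] = false;
      } else if (fc[leg].grf_y > contact_on) in_contact[leg] = true;
      int prev = mode[leg];
      if (in_contact[leg]) mode[leg] = MODE_STANCE;
      else if (prev == MODE_STANCE) mode[leg] = MODE_EARLY;
      else if (prev == MODE_EARLY &&
               (K.ankle[leg].p[0] - K.com[0]) > d_swing) mode[leg] = MODE_LATE;
      if (prev != MODE_STANCE && mode[leg] == MODE_STANCE && step > 0) {
        ev_time.push_back(t); ev_leg.push_back(leg + 1);
        ev_comx.push_back(K.com[0]);
      }
    }

    // reflex excitations from the delayed sensor history: the history was
    // last pushed at the end of step k-1, so a lookup of (delay_steps - 1)
    // pushes back returns the signal at exactly t - D
    for (int leg = 0; leg < 2; ++leg) {
      for (int i = 0; i < NMUS_LEG; ++i) u_exc[leg * NMUS_LEG + i] = mus[i].u0;
      for (size_t li = 0; li < laws.size(); ++li) {
        const Law& L = laws[li];
        if (L.mode != mode[leg]) continue;
        const MTU& tm = mus[L.target];
        int D = tm.delay_steps - 1;
        double out = 0.0;
        if (L.type == 0) {
          out = L.sign * cparams[L.p1];
        } else if (L.type == 1) {
          out = L.sign * cparams[L.p1] * hist[leg].get(L.source, D);
        } else if (L.type == 2) {
          double l = hist[leg].get(NMUS_LEG + L.source, D);
          double ex = l - cparams[L.p2];
          out = ex > 0.0 ? L.sign * cparams[L.p1] * ex : 0.0;
        } else {
          double th, thd;
          if (L.source == 0) { th = hist[leg].get(16, D); thd = hist[leg].get(17, D); }
          else { th = hist[leg].get(18 + 2 * (L.source - 1), D);
                 thd = hist[leg].get(19 + 2 * (L.source - 1), D); }
          double pd = cparams[L.p1] * (th - cparams[L.p2]) + cparams[L.p3] * thd;
          pd *= L.sign;
          out = pd > 0.0 ? pd : 0.0;
        }
        if (L.neg) out = -out;
        u_exc[leg * NMUS_LEG + L.target] += out;
      }
      for (int i = 0; i < NMUS_LEG; ++i) {
        int gi = leg * NMUS_LEG + i;
        if (u_exc[gi] < 0.0) u_exc[gi] = 0.0;
        if (u_exc[gi] > 1.0) u_exc[gi] = 1.0;
      }
    }

    // muscle dynamics and joint torques
    double mtau[6] = {0, 0, 0, 0, 0, 0};
    for (int leg = 0; leg < 2; ++leg) {
      const double* qleg = q + 3 + 3 * leg;
      for (int i = 0; i < NMUS_LEG; ++i) {
        int gi = leg * NMUS_LEG + i;
        const MTU& m = mus[i];
        double decay = 1.0 - std::exp(-dt / m.tau_act);
        act[gi] += (u_exc[gi] - act[gi]) * decay;
        double lm = pathLength(m, qleg);
        double Fn;
        double vce = fiberVelocity(m, act[gi], l_ce[gi], lm, Fn);
        F_norm[gi] = Fn; v_ce[gi] = vce;
        double F = Fn * m.F_max;
        for (int k = 0; k < m.njoint; ++k)
          mtau[3 * leg + m.joint[k]] += momentArm(m, k, qleg[m.joint[k]]) * F;
        l_ce[gi] += vce * dt;
        double lo = m.l_opt;
        if (l_ce[gi] < 0.4 * lo) l_ce[gi] = 0.4 * lo;
        if (l_ce[gi] > 1.6 * lo) l_ce[gi] = 1.6 * lo;
      }
    }

    // joint limits: spring + damping at the old velocity applied explicitly,
    // with the damping coefficient also entering the implicit damping matrix
    // (the light foot segment makes explicit limit damping unstable at dt)
    // record this step's sensor values for future delayed lookups
    for (int leg = 0; leg < 2; ++leg) {
      double vals[NCH];
      const double* qleg = q + 3 + 3 * leg;
      const double* qdleg = qd + 3 + 3 * leg;
      for (int i = 0; i < NMUS_LEG; ++i) {
        vals[i] = F_norm[leg * NMUS_LEG + i];
        vals[NMUS_LEG + i] = l_ce[leg * NMUS_LEG + i] / mus[i].l_opt;
      }
      vals[16] = q[2]; vals[17] = qd[2];
      for (int j = 0; j < 3; ++j) {
        vals[18 + 2 * j] = qleg[j];
        vals[19 + 2 * j] = qdleg[j];
      }
      hist[leg].push(vals);
    }

    double ltau[6], hpe = 0.0;
    for (int leg = 0; leg < 2; ++leg) {
      for (int j = 0; j < 3; ++j) {
        int idx = 3 + 3 * leg + j;
        double th = q[idx], thd = qd[idx], tl = 0.0;
        bool engaged = false;
        if (th > M.lim_hi[j]) { tl = -M.k_lim * (th - M.lim_hi[j]); engaged = true; }
        else if (th < M.lim_lo[j]) { tl = -M.k_lim * (th - M.lim_lo[j]); engaged = true; }
        if (engaged) {
          tl -= M.d_lim * thd;
          Dmat(idx, idx) += M.d_lim;
        }
        ltau[3 * leg + j] = tl;
        hpe += tl * tl;
      }
    }
    for (int j = 0; j < 6; ++j) Q(3 + j) += mtau[j] + ltau[j];

    // record
    if (step % rec_every == 0 && nrec < nrec_max) {
      int c = 0;
      rec(nrec, c++) = t;
      for (int j = 0; j < NQ; ++j) rec(nrec, c++) = q[j];
      for (int j = 0; j < NQ; ++j) rec(nrec, c++) = qd[j];
      for (int i = 0; i < NMUS; ++i) rec(nrec, c++) = u_exc[i];
      for (int i = 0; i < NMUS; ++i) rec(nrec, c++) = act[i];
      for (int i = 0; i < NMUS; ++i) rec(nrec, c++) = F_norm[i];
      for (int i = 0; i < NMUS; ++i)
        rec(nrec, c++) = l_ce[i] / mus[i % NMUS_LEG].l_opt;
      for (int j = 0; j < 6; ++j) rec(nrec, c++) = mtau[j];
      for (int j = 0; j < 6; ++j) rec(nrec, c++) = ltau[j];
      rec(nrec, c++) = fc[0].grf_x; rec(nrec, c++) = fc[0].grf_y;
      rec(nrec, c++) = fc[0].cop_x;
      rec(nrec, c++) = fc[1].grf_x; rec(nrec, c++) = fc[1].grf_y;
      rec(nrec, c++) = fc[1].cop_x;
      rec(nrec, c++) = K.com[0]; rec(nrec, c++) = K.com[1];
      rec(nrec, c++) = K.comv[0]; rec(nrec, c++) = K.comv[1];
      rec(nrec, c++) = K.head.v[0] - K.comv[0];
      double met = 0.0;
      for (int i = 0; i < NMUS; ++i)
        met += metabolicMuscle(mus[i % NMUS_LEG], act[i], v_ce[i],
                               F_norm[i] * mus[i % NMUS_LEG].F_max);
      rec(nrec, c++) = met;               // muscle-only power; basal added in R
      rec(nrec, c++) = hpe;
      rec(nrec, c++) = mode[0]; rec(nrec, c++) = mode[1];
      ++nrec;
    }

    // fall test: COM height above the contact plane
    double com_h = K.com[0] * nb_x0 + K.com[1] * nb_y0;
    if (com_h < M.fall_height) { fell = true; T_fall = t; break; }

    if (step == nstep) break;

    // integrate (semi-implicit Euler with implicit velocity-damping terms)
    assembleDynamics(M, K, Mass, bias, Qg);
    Mass += dt * Dmat;
    for (int j = 0; j < NQ; ++j) rhs9(j) = Qg(j) - bias(j) + Q(j);
    double acc[NQ];
    if (!cholSolve9(Mass, rhs9, acc)) { fell = true; T_fall = t; break; }
    bool finite = true;
    for (int j = 0; j < NQ; ++j) {
      qd[j] += dt * acc[j];
      q[j] += dt * qd[j];
      if (!std::isfinite(q[j]) || !std::isfinite(qd[j])) finite = false;
    }
    if (!finite) { fell = true; T_fall = t; break; }
    t += dt;
  }

  NumericMatrix out(nrec, ncol);
  for (int r = 0; r < nrec; ++r)
    for (int c2 = 0; c2 < ncol; ++c2) out(r, c2) = rec(r, c2);
  return List::create(
    _["samples"] = out,
    _["fell"] = fell,
    _["T_fall"] = fell ? T_fall : NA_REAL,
    _["t_end"] = fell ? T_fall : duration,
    _["hs_time"] = NumericVector(ev_time.begin(), ev_time.end()),
    _["hs_leg"] = IntegerVector(ev_leg.begin(), ev_leg.end()),
    _["hs_com_x"] = NumericVector(ev_comx.begin(), ev_comx.end()));
}
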