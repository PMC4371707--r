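// Compiled core: arm geometry kernel, 4-DOF rigid-body dynamics, the
// closed-loop reach simulation (equilibrium-point controller + inferior
// olive + cerebellar store), and the idealized point-mass model.
//
// Conventions: SI units (m, s, rad, N) throughout; the shoulder sits at the
// origin and the resting arm hangs along -z.  Shoulder orientation uses
// intrinsic ZXZ Euler angles (alpha, beta, gamma); delta is elbow flexion
// (0 = fully extended, bending toward +y).  Muscle tensions are nonnegative
// and shorten the muscle, so generalized torques are -J^T f with
// J = d(lengths)/d(angles).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>

using namespace Rcpp;
using arma::vec;
using arma::mat;

static const double REFRACTORY_S = 0.200;   // per-cell complex-spike refractory
static const double STORE_WINDOW_S = 0.250; // max spike-to-storage latency

// ---------------------------------------------------------------------------
// rotations

static mat rot_zxz(double a, double b, double g) {
  double ca = std::cos(a), sa = std::sin(a);
  double cb = std::cos(b), sb = std::sin(b);
  double cg = std::cos(g), sg = std::sin(g);
  mat R(3, 3);
  R(0, 0) = ca * cg - sa * cb * sg; R(0, 1) = -ca * sg - sa * cb * cg; R(0, 2) = sa * sb;
  R(1, 0) = sa * cg + ca * cb * sg; R(1, 1) = -sa * sg + ca * cb * cg; R(1, 2) = -ca * sb;
  R(2, 0) = sb * sg;                R(2, 1) = sb * cg;                 R(2, 2) = cb;
  return R;
}

static mat rot_x(double d) {
  double c = std::cos(d), s = std::sin(d);
  mat R(3, 3, arma::fill::eye);
  R(1, 1) = c; R(1, 2) = -s;
  R(2, 1) = s; R(2, 2) = c;
  return R;
}

static mat skew(const vec& v) {
  mat S(3, 3, arma::fill::zeros);
  S(0, 1) = -v(2); S(0, 2) = v(1);
  S(1, 0) = v(2);  S(1, 2) = -v(0);
  S(2, 0) = -v(1); S(2, 1) = v(0);
  return S;
}

// ZXZ Euler -> unit quaternion (w, x, y, z), canonicalized to w >= 0
static vec quat_zxz(double a, double b, double g) {
  double cb = std::cos(b / 2.0), sb = std::sin(b / 2.0);
  double cp = std::cos((a + g) / 2.0), sp = std::sin((a + g) / 2.0);
  double cm = std::cos((a - g) / 2.0), sm = std::sin((a - g) / 2.0);
  vec q = { cb * cp, sb * cm, sb * sm, cb * sp };
  if (q(0) < 0) q = -q;
  return q;
}

// ---------------------------------------------------------------------------
// geometry

struct Geometry {
  double La, Lf;       // upper arm, forearm+hand lengths
  double m1, m2;       // segment masses
  double r1, r2;       // cylinder radii (inertia)
  double eps_inertia;  // articulation inertia regularizing the ZXZ chart
  int nm;
  mat orig, ins;                  // 3 x nm, rest coordinates
  arma::ivec orig_frame, ins_frame; // 0 torso, 1 upper arm, 2 forearm
  arma::ivec has_bend, bend_frame;
  mat bendA, bendB, bendN;        // 3 x nm, rest coordinates
  // Hill parameters
  vec Fmax, tau_a, k_p, b_p, vmax, l_rest;
  // elbow soft limits
  double delta_min, delta_max, K_lim, b_lim;
  double gravity_g;
};

static Geometry parse_geometry(const List& g) {
  Geometry G;
  G.La = as<double>(g["L_arm"]);   G.Lf = as<double>(g["L_farm"]);
  G.m1 = as<double>(g["m_arm"]);   G.m2 = as<double>(g["m_farm"]);
  G.r1 = as<double>(g["r_arm"]);   G.r2 = as<double>(g["r_farm"]);
  G.eps_inertia = as<double>(g["eps_inertia"]);
  G.orig = as<mat>(g["orig"]);     G.ins = as<mat>(g["ins"]);
  G.orig_frame = as<arma::ivec>(g["orig_frame"]);
  G.ins_frame = as<arma::ivec>(g["ins_frame"]);
  G.has_bend = as<arma::ivec>(g["has_bend"]);
  G.bend_frame = as<arma::ivec>(g["bend_frame"]);
  G.bendA = as<mat>(g["bendA"]); G.bendB = as<mat>(g["bendB"]);
  G.bendN = as<mat>(g["bendN"]);
  G.nm = G.orig.n_cols;
  G.Fmax = as<vec>(g["F_max"]);   G.tau_a = as<vec>(g["tau_act"]);
  G.k_p = as<vec>(g["k_passive"]); G.b_p = as<vec>(g["b_passive"]);
  G.vmax = as<vec>(g["v_max"]);   G.l_rest = as<vec>(g["l_rest"]);
  G.delta_min = as<double>(g["delta_min"]);
  G.delta_max = as<double>(g["delta_max"]);
  G.K_lim = as<double>(g["K_limit"]);
  G.b_lim = as<double>(g["b_limit"]);
  G.gravity_g = as<double>(g["gravity_g"]);
  return G;
}

struct Frames {
  mat R1;     // shoulder rotation
  mat R1Rx;   // forearm rotation (about the elbow, in rest coords)
  vec e_rest; // elbow in rest coordinates
};

static Frames make_frames(const vec& q, const Geometry& G) {
  Frames F;
  F.R1 = rot_zxz(q(0), q(1), q(2));
  F.R1Rx = F.R1 * rot_x(q(3));
  F.e_rest = { 0.0, 0.0, -G.La };
  return F;
}

static vec world_point(const vec& p, int frame, const Frames& F) {
  if (frame == 0) return p;
  if (frame == 1) return F.R1 * p;
  // forearm: rotate rest coordinates about the elbow, then the shoulder
  return F.R1 * F.e_rest + F.R1Rx * (p - F.e_rest);
}

static vec world_dir(const vec& n, int frame, const Frames& F) {
  if (frame == 0) return n;
  if (frame == 1) return F.R1 * n;
  return F.R1Rx * n;
}

// Shortest path p1 -> (point on segment a-b) -> p2; exact mirror solution
// of the convex 1-D problem, clamped to the segment.
static double via_path_length(const vec& p1, const vec& p2,
                              const vec& a, const vec& b, vec* via) {
  vec u = b - a;
  double L = arma::norm(u);
  if (L < 1e-12) stop("degenerate bending line");
  u /= L;
  double s1 = arma::dot(p1 - a, u), s2 = arma::dot(p2 - a, u);
  double r1 = arma::norm(p1 - (a + s1 * u));
  double r2 = arma::norm(p2 - (a + s2 * u));
  double t;
  if (r1 + r2 < 1e-12) t = 0.5 * (s1 + s2);
  else t = s1 + r1 * (s2 - s1) / (r1 + r2);
  t = std::min(std::max(t, 0.0), L);
  vec v = a + t * u;
  if (via) *via = v;
  return arma::norm(p1 - v) + arma::norm(v - p2);
}

// length of muscle i at the pose held in F; wraps over its bending line when
// the straight path crosses the plane through the line with the stored normal
static double muscle_length_i(int i, const Geometry& G, const Frames& F) {
  vec p1 = world_point(G.orig.col(i), G.orig_frame(i), F);
  vec p2 = world_point(G.ins.col(i), G.ins_frame(i), F);
  double straight = arma::norm(p1 - p2);
  if (!G.has_bend(i)) return straight;
  vec a = world_point(G.bendA.col(i), G.bend_frame(i), F);
  vec b = world_point(G.bendB.col(i), G.bend_frame(i), F);
  vec n = world_dir(G.bendN.col(i), G.bend_frame(i), F);
  double s1 = arma::dot(n, p1 - a), s2 = arma::dot(n, p2 - a);
  if (s1 * s2 >= 0.0) return straight; // same side: no wrapping
  double wrapped = via_path_length(p1, p2, a, b, nullptr);
  return std::max(wrapped, straight);
}

static vec all_lengths(const vec& q, const Geometry& G) {
  Frames F = make_frames(q, G);
  vec l(G.nm);
  for (int i = 0; i < G.nm; ++i) l(i) = muscle_length_i(i, G, F);
  return l;
}

static vec hand_pos(const vec& q, const Geometry& G) {
  Frames F = make_frames(q, G);
  vec hand_rest = { 0.0, 0.0, -(G.La + G.Lf) };
  return world_point(hand_rest, 2, F);
}

// J = d(lengths)/dq, central differences
static mat length_jacobian(const vec& q, const Geometry& G) {
  const double h = 1e-6;
  mat J(G.nm, 4);
  for (int k = 0; k < 4; ++k) {
    vec qp = q, qm = q;
    qp(k) += h; qm(k) -= h;
    J.col(k) = (all_lengths(qp, G) - all_lengths(qm, G)) / (2.0 * h);
  }
  return J;
}

// ---------------------------------------------------------------------------
// dynamics

static void body_jacobians(const vec& q, const Geometry& G,
                           mat& A1, mat& A2, mat& B1, mat& B2,
                           vec& c1, vec& c2, mat& R1, mat& R2w) {
  double a = q(0), b = q(1);
  R1 = rot_zxz(a, b, q(2));
  R2w = R1 * rot_x(q(3));
  vec zhat = { 0.0, 0.0, 1.0 };
  vec ax_b = { std::cos(a), std::sin(a), 0.0 };                    // Rz(a) x
  vec ax_g = { std::sin(a) * std::sin(b), -std::cos(a) * std::sin(b), std::cos(b) };
  vec ax_d = R1.col(0);                                            // elbow axis
  A1.zeros(3, 4); A2.zeros(3, 4);
  A1.col(0) = zhat; A1.col(1) = ax_b; A1.col(2) = ax_g;
  A2 = A1; A2.col(3) = ax_d;
  vec half1 = { 0.0, 0.0, -G.La / 2.0 };
  c1 = R1 * half1;
  vec e = R1 * vec({ 0.0, 0.0, -G.La });
  vec half2 = { 0.0, 0.0, -G.Lf / 2.0 };
  vec c2e = R2w * half2;
  c2 = e + c2e;
  B1 = -skew(c1) * A1;
  B2 = -skew(e) * A1 - skew(c2e) * A2;
}

static mat mass_matrix(const vec& q, const Geometry& G) {
  mat A1, A2, B1, B2, R1, R2w;
  vec c1, c2;
  body_jacobians(q, G, A1, A2, B1, B2, c1, c2, R1, R2w);
  auto cyl = [](double m, double r, double L) {
    mat I(3, 3, arma::fill::zeros);
    I(0, 0) = I(1, 1) = m * (3.0 * r * r + L * L) / 12.0;
    I(2, 2) = m * r * r / 2.0;
    return I;
  };
  mat I1w = R1 * cyl(G.m1, G.r1, G.La) * R1.t();
  mat I2w = R2w * cyl(G.m2, G.r2, G.Lf) * R2w.t();
  mat M = G.m1 * B1.t() * B1 + G.m2 * B2.t() * B2 +
          A1.t() * I1w * A1 + A2.t() * I2w * A2;
  M.diag() += G.eps_inertia;
  return M;
}

static double potential_energy(const vec& q, const Geometry& G, bool gravity) {
  if (!gravity) return 0.0;
  mat A1, A2, B1, B2, R1, R2w;
  vec c1, c2;
  body_jacobians(q, G, A1, A2, B1, B2, c1, c2, R1, R2w);
  return G.gravity_g * (G.m1 * c1(2) + G.m2 * c2(2));
}

// Coriolis/centrifugal generalized forces from numerical Christoffel symbols
static vec coriolis(const vec& q, const vec& qd, const Geometry& G) {
  const double h = 1e-5;
  arma::cube dM(4, 4, 4);
  for (int i = 0; i < 4; ++i) {
    vec qp = q, qm = q;
    qp(i) += h; qm(i) -= h;
    dM.slice(i) = (mass_matrix(qp, G) - mass_matrix(qm, G)) / (2.0 * h);
  }
  vec c(4, arma::fill::zeros);
  for (int k = 0; k < 4; ++k) {
    double s = 0.0;
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j)
        s += (dM.slice(i)(k, j) - 0.5 * dM.slice(k)(i, j)) * qd(i) * qd(j);
    c(k) = s;
  }
  return c;
}

static vec gravity_force(const vec& q, const Geometry& G, bool gravity) {
  if (!gravity) return vec(4, arma::fill::zeros);
  const double h = 1e-6;
  vec gq(4);
  for (int k = 0; k < 4; ++k) {
    vec qp = q, qm = q;
    qp(k) += h; qm(k) -= h;
    gq(k) = -(potential_energy(qp, G, true) - potential_energy(qm, G, true)) / (2.0 * h);
  }
  return gq;
}

static vec limit_torque(const vec& q, const vec& qd, const Geometry& G) {
  vec tau(4, arma::fill::zeros);
  double d = q(3);
  if (d < G.delta_min) tau(3) += G.K_lim * (G.delta_min - d) - G.b_lim * qd(3);
  if (d > G.delta_max) tau(3) += -G.K_lim * (d - G.delta_max) - G.b_lim * qd(3);
  return tau;
}

// force-velocity factor: Hill hyperbola while shortening (v < 0), linear
// eccentric rise capped at 1.5; continuous with slope 5/vmax at v = 0
static double fv_curve(double v, double vmax) {
  if (v < 0) {
    double x = v / vmax;
    if (x <= -1.0) return 0.0;
    return (1.0 + x) / (1.0 - 4.0 * x);
  }
  return std::min(1.5, 1.0 + 5.0 * v / vmax);
}

static double tension_i(int i, double act, double l, double v, const Geometry& G) {
  double active = G.Fmax(i) * act * fv_curve(v, G.vmax(i));
  double passive = G.k_p(i) * (l - G.l_rest(i)) + G.b_p(i) * v;
  if (passive < 0) passive = 0;
  double f = active + passive;
  return f < 0 ? 0 : f;
}

// ---------------------------------------------------------------------------
// exported geometry / dynamics kernels

// [[Rcpp::export]]
arma::vec cpp_muscle_lengths(const arma::vec& q, const List& geom) {
  Geometry G = parse_geometry(geom);
  return all_lengths(q, G);
}

// [[Rcpp::export]]
arma::vec cpp_hand_position(const arma::vec& q, const List& geom) {
  Geometry G = parse_geometry(geom);
  return hand_pos(q, G);
}

// [[Rcpp::export]]
List cpp_path_length(const arma::vec& p1, const arma::vec& p2,
                     const arma::vec& a, const arma::vec& b,
                     const arma::vec& n, bool has_bend) {
  double straight = arma::norm(p1 - p2);
  if (!has_bend)
    return List::create(_["length"] = straight, _["via"] = R_NilValue);
  if (arma::norm(b - a) < 1e-12) stop("degenerate bending line");
  double s1 = arma::dot(n, p1 - a), s2 = arma::dot(n, p2 - a);
  if (s1 * s2 >= 0.0)
    return List::create(_["length"] = straight, _["via"] = R_NilValue);
  vec via;
  double len = via_path_length(p1, p2, a, b, &via);
  if (len <= straight + 1e-12)
    return List::create(_["length"] = straight, _["via"] = R_NilValue);
  return List::create(_["length"] = len, _["via"] = via);
}

// [[Rcpp::export]]
arma::mat cpp_length_jacobian(const arma::vec& q, const List& geom) {
  Geometry G = parse_geometry(geom);
  return length_jacobian(q, G);
}

// [[Rcpp::export]]
arma::vec cpp_joint_torques(const arma::vec& q, const arma::vec& tensions,
                            const List& geom) {
  Geometry G = parse_geometry(geom);
  mat J = length_jacobian(q, G);
  return -J.t() * tensions;
}

// [[Rcpp::export]]
arma::mat cpp_mass_matrix(const arma::vec& q, const List& geom) {
  Geometry G = parse_geometry(geom);
  return mass_matrix(q, G);
}

// [[Rcpp::export]]
double cpp_energy(const arma::vec& q, const arma::vec& qd, const List& geom,
                  bool gravity) {
  Geometry G = parse_geometry(geom);
  mat M = mass_matrix(q, G);
  return 0.5 * arma::dot(qd, M * qd) + potential_energy(q, G, gravity);
}

// [[Rcpp::export]]
arma::vec cpp_muscle_force(const arma::vec& u, const arma::vec& l,
                           const arma::vec& v, const List& geom) {
  Geometry G = parse_geometry(geom);
  if (!u.is_finite() || !l.is_finite() || !v.is_finite())
    stop("non-finite muscle state");
  vec f(G.nm);
  for (int i = 0; i < G.nm; ++i)
    f(i) = tension_i(i, std::max(u(i), 0.0), l(i), v(i), G);
  return f;
}

static vec qdd_free(const vec& q, const vec& qd, const vec& tau,
                    const Geometry& G, bool gravity) {
  vec rhs = tau + gravity_force(q, G, gravity) + limit_torque(q, qd, G) -
            coriolis(q, qd, G);
  return arma::solve(mass_matrix(q, G), rhs, arma::solve_opts::likely_sympd);
}

// Explicit-midpoint (second-order) integration under constant generalized
// torque; returns the state and an instability flag (joint speed exceeding
// qd_max, clamped rather than fatal).
// [[Rcpp::export]]
List cpp_step_dynamics(const arma::vec& q0, const arma::vec& qd0,
                       const arma::vec& tau, double dt, int n_steps,
                       const List& geom, bool gravity, double qd_max) {
  Geometry G = parse_geometry(geom);
  vec q = q0, qd = qd0;
  bool unstable = false;
  for (int s = 0; s < n_steps; ++s) {
    vec a1 = qdd_free(q, qd, tau, G, gravity);
    vec qm = q + 0.5 * dt * qd;
    vec qdm = qd + 0.5 * dt * a1;
    vec a2 = qdd_free(qm, qdm, tau, G, gravity);
    q += dt * qdm;
    qd += dt * a2;
    if (!qd.is_finite() || arma::abs(qd).max() > qd_max) {
      unstable = true;
      for (int k = 0; k < 4; ++k) {
        if (!std::isfinite(qd(k))) qd(k) = 0.0;
        qd(k) = std::min(std::max(qd(k), -qd_max), qd_max);
      }
    }
    if (!q.is_finite()) { unstable = true; q = qm; qd.zeros(); }
  }
  return List::create(_["q"] = q, _["qd"] = qd, _["unstable"] = unstable);
}

// ---------------------------------------------------------------------------
// cerebellar store kernels (shared between the R API and the reach loop)

struct Store {
  mat F;  // entries x context
  mat W;  // entries x muscles
};

static double scaled_dist(const arma::rowvec& f1, const arma::rowvec& f2,
                          const vec& scales) {
  double s = 0.0;
  for (arma::uword k = 0; k < scales.n_elem; ++k) {
    double d = scales(k) * (f1(k) - f2(k));
    s += d * d;
  }
  return std::sqrt(s);
}

static vec recall_kernel(const Store& S, const vec& v, const vec& scales,
                         double gamma, int MF, int nm) {
  vec out(nm, arma::fill::zeros);
  int n = S.F.n_rows;
  if (n == 0) return out;
  vec D(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (arma::uword k = 0; k < scales.n_elem; ++k) {
      double d = scales(k) * (S.F(i, k) - v(k));
      s += d * d;
    }
    D(i) = s;
  }
  double nD = arma::norm(D);
  vec DN = (nD > 0) ? vec(double(MF) / nD * D) : vec(n, arma::fill::zeros);
  for (int i = 0; i < n; ++i)
    out += std::exp(gamma * DN(i)) * S.W.row(i).t();
  return out;
}

// insert with fusion: when the store is full or the new entry lies within
// fuse_thresh (scaled units) of its nearest neighbor, parent and newcomer
// are replaced by their midpoint
static void store_add(Store& S, const arma::rowvec& f, const arma::rowvec& w,
                      const vec& scales, int MF, double fuse_thresh) {
  int n = S.F.n_rows;
  if (n > 0) {
    int best = -1;
    double bd = std::numeric_limits<double>::infinity();
    for (int i = 0; i < n; ++i) {
      double d = scaled_dist(S.F.row(i), f, scales);
      if (d < bd) { bd = d; best = i; }
    }
    if (n >= MF || bd < fuse_thresh) {
      S.F.row(best) = 0.5 * (S.F.row(best) + f);
      S.W.row(best) = 0.5 * (S.W.row(best) + w);
      return;
    }
  }
  S.F.insert_rows(n, f);
  S.W.insert_rows(n, w);
}

// [[Rcpp::export]]
arma::vec cpp_recall(const arma::mat& F, const arma::mat& W,
                     const arma::vec& v, const arma::vec& scales,
                     double gamma, int MF) {
  Store S{F, W};
  int nm = W.n_cols > 0 ? W.n_cols : 11;
  return recall_kernel(S, v, scales, gamma, MF, nm);
}

// [[Rcpp::export]]
List cpp_store_add(const arma::mat& F, const arma::mat& W,
                   const arma::vec& f, const arma::vec& w,
                   const arma::vec& scales, int MF, double fuse_thresh) {
  Store S{F, W};
  store_add(S, f.t(), w.t(), scales, MF, fuse_thresh);
  return List::create(_["F"] = S.F, _["W"] = S.W);
}

// ---------------------------------------------------------------------------
// Eq.-7 spike probability (E and its derivative in gating units, i.e. cm)

static double spike_probability(double E, double Edot_pos, double freq_hz,
                                double phase_s, double t, double p,
                                bool product_parse) {
  double ang = 2.0 * M_PI * freq_hz;
  double osc = p * std::cos(ang * (t - phase_s)) + 1.0;
  double gate = (1.0 + std::exp(5.0 - E)) * (1.0 + std::exp(30.0 - 15.0 * Edot_pos));
  double P = product_parse ? osc / gate : (p * std::cos(ang * (t - phase_s)) + 1.0 / gate);
  if (P < 0) P = 0;
  if (P > 1) P = 1;
  return P;
}

// [[Rcpp::export]]
double cpp_spike_probability(double E, double Edot_pos, double freq_hz,
                             double phase_s, double t, double p,
                             bool product_parse) {
  return spike_probability(E, Edot_pos, freq_hz, phase_s, t, p, product_parse);
}

// ---------------------------------------------------------------------------
// closed-loop reach simulation

// model: 0 none, 1..4 cerebellar variants
// [[Rcpp::export]]
List cpp_sim_reach(const arma::vec& q0, const arma::vec& qd0,
                   const arma::vec& target, const List& geom,
                   const arma::vec& lambda, const arma::vec& qdes,
                   double delta_des, const List& ctl, const List& olive,
                   const List& cb, const List& sim, int model,
                   const arma::mat& store_F, const arma::mat& store_W,
                   int seed) {
  Geometry G = parse_geometry(geom);
  const int nm = G.nm;

  // controller parameters
  double g_l = as<double>(ctl["g_l"]), g_v = as<double>(ctl["g_v"]);
  double tau_f = as<double>(ctl["tau_filter"]);
  double k_i = as<double>(ctl["k_integral"]);
  double tau_p = as<double>(ctl["tau_p"]), tau_v = as<double>(ctl["tau_v"]);

  // olive parameters
  vec ol_freq = as<vec>(olive["freq"]);     // Hz per cell
  vec ol_phase = as<vec>(olive["phase"]);   // s per cell
  double ol_p = as<double>(olive["p"]);
  bool product_parse = as<bool>(olive["product_parse"]);
  int ncell = ol_freq.n_elem;

  // cerebellum parameters
  vec scales = as<vec>(cb["scales"]);
  double gamma = as<double>(cb["gamma"]);
  int MF = as<int>(cb["M_F"]);
  double fuse_thresh = as<double>(cb["fuse_thresh"]);
  double gain = as<double>(cb["gain"]);
  bool output_enabled = as<bool>(cb["output_enabled"]);

  // simulation parameters
  double T = as<double>(sim["T"]);
  double dt = as<double>(sim["dt_ctrl"]);
  double dtp = as<double>(sim["dt_phys"]);
  bool gravity = as<bool>(sim["gravity"]);
  double qd_max = as<double>(sim["qd_max"]);
  int n_steps = (int)std::lround(T / dt);
  int n_sub = std::max(1, (int)std::lround(dt / dtp));
  int d_p = (int)std::lround(tau_p / dt);  // proprioceptive delay in steps
  int d_v = (int)std::lround(tau_v / dt);  // visual delay in steps
  int d_w = (int)std::lround((tau_v - tau_p) / dt); // efference window shift
  int ctx_len = 17 + nm; // E, Edot, qs(4), qsd(4), th, thd, ev(nm), qdes(4), delta

  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  Store S{store_F, store_W};
  if (S.F.n_rows == 0) { S.F.set_size(0, ctx_len); S.W.set_size(0, nm); }

  // histories at control resolution
  mat h_l(n_steps, nm), h_v(n_steps, nm), h_quat(n_steps, 4);
  vec h_E(n_steps), h_Edot(n_steps), h_th(n_steps), h_thd(n_steps);
  mat h_eff(n_steps, nm);    // efferent command [e_v]+
  mat h_ctx(n_steps, ctx_len);
  mat h_ld(n_steps, nm), h_vd(n_steps, nm); // proprio-delayed copies

  // spike bookkeeping
  vec last_spike(ncell); last_spike.fill(-1e9);
  vec last_musc(nm); last_musc.fill(-1e9);
  struct Pending { int step; int source; };
  std::vector<Pending> pending;
  std::vector<double> ev_t, ev_src;              // spike log
  std::vector<double> st_tcs, st_t, st_src;      // storage log

  // output trajectory
  mat traj(n_steps, 1 + 3 + 4 + 1 + 2 * nm);
  vec recall_norm(n_steps, arma::fill::zeros);

  vec q = q0, qd = qd0;
  vec act(nm, arma::fill::zeros);
  vec fs(nm, arma::fill::zeros);   // low-pass state
  vec Sint(nm, arma::fill::zeros); // integral state
  bool unstable = false;
  double E_prev = 0.0;

  for (int n = 0; n < n_steps; ++n) {
    double t = n * dt;
    vec l = all_lengths(q, G);
    mat J = length_jacobian(q, G);
    vec vmus = J * qd;
    vec hp = hand_pos(q, G);
    double E = arma::norm(hp - target);
    double Edot = (n == 0) ? 0.0 : (E - E_prev) / dt;
    E_prev = E;

    h_l.row(n) = l.t();
    h_v.row(n) = vmus.t();
    h_quat.row(n) = quat_zxz(q(0), q(1), q(2)).t();
    h_E(n) = E; h_Edot(n) = Edot;
    h_th(n) = q(3); h_thd(n) = qd(3);

    // delayed reads (initial sample before the delay has elapsed)
    int ip = std::max(0, n - d_p), iv = std::max(0, n - d_v);
    vec l_d = h_l.row(ip).t(), v_d = h_v.row(ip).t();
    vec qs_d = h_quat.row(ip).t();
    vec qsd_d(4, arma::fill::zeros);
    if (ip > 0) qsd_d = (h_quat.row(ip) - h_quat.row(ip - 1)).t() / dt;
    double th_d = h_th(ip), thd_d = h_thd(ip);
    double E_d = h_E(iv), Edot_d = h_Edot(iv);
    h_ld.row(n) = l_d.t(); h_vd.row(n) = v_d.t();

    // central controller (Eq. 6 + low-pass + integral)
    vec e_l = g_l * (l_d - lambda);
    vec e_v = g_v * (v_d + e_l);
    vec u_raw = arma::clamp(e_v, 0.0, arma::datum::inf);
    fs += (dt / tau_f) * (u_raw - fs);
    Sint += fs * dt;
    vec u_ctl = fs + k_i * Sint;
    h_eff.row(n) = u_raw.t();

    // context as perceived now
    arma::rowvec ctx(ctx_len);
    ctx(0) = E_d; ctx(1) = Edot_d;
    for (int k = 0; k < 4; ++k) { ctx(2 + k) = qs_d(k); ctx(6 + k) = qsd_d(k); }
    ctx(10) = th_d; ctx(11) = thd_d;
    for (int i = 0; i < nm; ++i) ctx(12 + i) = u_raw(i);
    for (int k = 0; k < 4; ++k) ctx(12 + nm + k) = qdes(k);
    ctx(16 + nm) = delta_des;
    h_ctx.row(n) = ctx;

    // complex spikes
    if (model == 1 || model == 4) {
      double E_cm = 100.0 * E_d;
      double Ed_cm = 100.0 * std::max(Edot_d, 0.0);
      for (int i = 0; i < ncell; ++i) {
        double P = spike_probability(E_cm, Ed_cm, ol_freq(i), ol_phase(i), t,
                                     ol_p, product_parse);
        double r = unif(rng);
        if (r < P && t - last_spike(i) >= REFRACTORY_S) {
          last_spike(i) = t;
          pending.push_back({ n, -1 });
          ev_t.push_back(t); ev_src.push_back(-1);
        }
      }
    } else if (model == 2 || model == 3) {
      for (int i = 0; i < nm; ++i) {
        bool cond = v_d(i) > 0 && l_d(i) > lambda(i) &&
                    (t - last_musc(i) >= REFRACTORY_S);
        if (model == 3) cond = cond && Edot_d > 0;
        if (cond) {
          last_musc(i) = t;
          pending.push_back({ n, i });
          ev_t.push_back(t); ev_src.push_back(i);
        }
      }
    }

    // handle pending spikes: store once the error episode has ended,
    // discard if it outlasts the storage window
    if (model > 0 && !pending.empty()) {
      std::vector<Pending> keep;
      for (const Pending& pd : pending) {
        double age = (n - pd.step) * dt;
        bool over = (pd.source < 0) ? (Edot_d <= 0) : (v_d(pd.source) <= 0);
        if (over && age <= STORE_WINDOW_S + 1e-12) {
          // context lookback: tau_v - tau_p + (t - t_cs)/2 before the spike
          double look = (pd.source < 0 ? (tau_v - tau_p) : 0.0) + age / 2.0;
          int nf = std::max(0, pd.step - (int)std::lround(look / dt));
          arma::rowvec f = h_ctx.row(nf);
          arma::rowvec w(nm, arma::fill::zeros);
          if (model == 1) {
            int a = std::max(0, pd.step - d_w);
            int b = std::max(a, n - d_w);
            w = gain * arma::mean(h_eff.rows(a, b), 0);
          } else if (model == 2 || model == 3) {
            w(pd.source) = gain;
          } else { // model 4: [<l> - lambda]+ [ldot]+ per muscle
            int a = std::max(0, pd.step - d_w);
            int b = std::max(a, n - d_w);
            arma::rowvec lavg = arma::mean(h_ld.rows(a, b), 0);
            arma::rowvec vavg = arma::mean(arma::clamp(h_vd.rows(a, b), 0.0,
                                            arma::datum::inf), 0);
            for (int i = 0; i < nm; ++i)
              w(i) = gain * std::max(lavg(i) - lambda(i), 0.0) * vavg(i);
          }
          store_add(S, f, w, scales, MF, fuse_thresh);
          st_tcs.push_back(pd.step * dt); st_t.push_back(t);
          st_src.push_back(pd.source);
        } else if (age <= STORE_WINDOW_S + 1e-12) {
          keep.push_back(pd); // episode still running
        } // else: discard
      }
      pending.swap(keep);
    }

    // cerebellar recall added at the muscle input
    vec u = u_ctl;
    if (model > 0 && output_enabled) {
      vec crec = recall_kernel(S, ctx.t(), scales, gamma, MF, nm);
      recall_norm(n) = arma::norm(crec);
      u += crec;
    }
    u = arma::clamp(u, 0.0, arma::datum::inf);

    // plant substeps (explicit midpoint; muscle lengths linearized around
    // the control-step pose through the Jacobian)
    vec q_at_J = q;
    auto qdd_muscle = [&](const vec& q_, const vec& qd_) -> vec {
      vec l_lin = l + J * (q_ - q_at_J);
      vec v_lin = J * qd_;
      vec f(nm);
      for (int i = 0; i < nm; ++i)
        f(i) = tension_i(i, act(i), l_lin(i), v_lin(i), G);
      vec rhs = -J.t() * f + gravity_force(q_, G, gravity) +
                limit_torque(q_, qd_, G) - coriolis(q_, qd_, G);
      return arma::solve(mass_matrix(q_, G), rhs,
                         arma::solve_opts::likely_sympd);
    };
    for (int s = 0; s < n_sub; ++s) {
      for (int i = 0; i < nm; ++i)
        act(i) += dtp * (u(i) - act(i)) / G.tau_a(i);
      vec a1 = qdd_muscle(q, qd);
      vec qm = q + 0.5 * dtp * qd;
      vec qdm = qd + 0.5 * dtp * a1;
      vec a2 = qdd_muscle(qm, qdm);
      q += dtp * qdm;
      qd += dtp * a2;
      if (!qd.is_finite() || arma::abs(qd).max() > qd_max) {
        unstable = true;
        for (int k = 0; k < 4; ++k) {
          if (!std::isfinite(qd(k))) qd(k) = 0.0;
          qd(k) = std::min(std::max(qd(k), -qd_max), qd_max);
        }
      }
      if (!q.is_finite()) { unstable = true; q = q_at_J; qd.zeros(); }
    }

    traj(n, 0) = t;
    for (int k = 0; k < 3; ++k) traj(n, 1 + k) = hp(k);
    for (int k = 0; k < 4; ++k) traj(n, 4 + k) = q(k);
    traj(n, 8) = E;
    for (int i = 0; i < nm; ++i) traj(n, 9 + i) = l(i);
    for (int i = 0; i < nm; ++i) traj(n, 9 + nm + i) = u(i);
  }

  return List::create(
    _["traj"] = traj,
    _["store_F"] = S.F, _["store_W"] = S.W,
    _["spike_t"] = ev_t, _["spike_source"] = ev_src,
    _["storage_tcs"] = st_tcs, _["storage_t"] = st_t,
    _["storage_source"] = st_src,
    _["unstable"] = unstable, _["recall_norm"] = recall_norm,
    _["q_final"] = q, _["qd_final"] = qd);
}

// ---------------------------------------------------------------------------
// idealized point-mass model: central force, impulsive corrections

// [[Rcpp::export]]
List cpp_sim_ideal(const arma::vec& r0, const arma::vec& v0, double k,
                   double m, double dt, double T_max, double v_thr,
                   double d_thr, double gain, double ball_radius,
                   double reentry_refract, int record_stride) {
  vec r = r0, v = v0;
  double omega = std::sqrt(k / m);
  double period = 2.0 * M_PI / omega;
  int n_steps = (int)std::lround(T_max / dt);

  std::vector<arma::rowvec> entries;  // [r(3), v(3)*vel_scale]
  std::vector<vec> impulses;
  std::vector<double> entry_last_applied;
  double vel_scale = 1.0 / omega;

  bool in_episode = false;
  vec Jacc(3, arma::fill::zeros);
  double theta_acc = 0.0;
  vec r_onset(3), v_onset(3);
  bool episode_valid = false;

  std::vector<double> cor_t, cor_r, cor_Lbefore, cor_Lafter, cor_imp;
  std::vector<double> cor_entry, cor_dist, cor_cosv;
  std::vector<double> seg_L_dev; // |L| relative deviation within segments
  double segL_ref = arma::norm(arma::cross(r, m * v));
  double segL_maxdev = 0.0;

  std::vector<double> rec_t, rec_x, rec_y, rec_z, rec_rad, rec_L;
  std::string termination = "time_limit";
  double t_end = T_max;

  // sliding window for the near-circular test
  int win = std::max(1, (int)std::lround(period / dt));
  std::vector<double> raddot_hist(win, 1e9);
  int hist_i = 0, steps_since_cor = win + 1;

  auto finalize_episode = [&](double /*t*/) {
    if (!in_episode) return;
    in_episode = false;
    if (!episode_valid || arma::norm(Jacc) == 0) return;
    // deduplicate: skip entries inside an existing ball
    arma::rowvec e(6);
    for (int i = 0; i < 3; ++i) { e(i) = r_onset(i); e(3 + i) = v_onset(i) * vel_scale; }
    for (size_t j = 0; j < entries.size(); ++j)
      if (arma::norm(entries[j] - e) < ball_radius) return;
    entries.push_back(e);
    impulses.push_back(gain * Jacc);
    entry_last_applied.push_back(-1e9);
  };

  int n = 0;
  for (; n < n_steps; ++n) {
    double t = n * dt;
    double rad = arma::norm(r);
    double raddot = (rad > 1e-12) ? arma::dot(r, v) / rad : 0.0;

    if (record_stride > 0 && n % record_stride == 0) {
      rec_t.push_back(t); rec_x.push_back(r(0)); rec_y.push_back(r(1));
      rec_z.push_back(r(2)); rec_rad.push_back(rad);
      rec_L.push_back(arma::norm(arma::cross(r, m * v)));
    }

    // termination checks
    if (rad < d_thr) { termination = "reached"; t_end = t; break; }
    raddot_hist[hist_i] = std::fabs(raddot);
    hist_i = (hist_i + 1) % win;
    ++steps_since_cor;
    if (n >= win && steps_since_cor > win) {
      double mx = 0.0;
      for (double x : raddot_hist) mx = std::max(mx, x);
      if (mx < v_thr) { termination = "circular"; t_end = t; break; }
    }

    // event detection / episode integration
    if (!in_episode) {
      if (raddot > v_thr && rad > d_thr) {
        in_episode = true;
        Jacc.zeros(); theta_acc = 0.0;
        r_onset = r; v_onset = v;
        episode_valid = true;
      }
    }
    if (in_episode) {
      bool stop_now = false;
      if (raddot <= v_thr) stop_now = true;              // (1)
      if (theta_acc > M_PI / 2.0) stop_now = true;       // (2)
      vec F = -k * r;
      vec Jnew = Jacc + F * dt;
      if (!stop_now && rad > 1e-12) {
        double rv_after = arma::dot(v + gain * Jnew / m, r) / rad;
        if (rv_after < 0) stop_now = true;               // (3)
      }
      if (stop_now) finalize_episode(t);
      else Jacc = Jnew;
    }

    // re-entry of stored regions: apply the stored impulse
    arma::rowvec state(6);
    for (int i = 0; i < 3; ++i) { state(i) = r(i); state(3 + i) = v(i) * vel_scale; }
    for (size_t j = 0; j < entries.size(); ++j) {
      if (t - entry_last_applied[j] < reentry_refract) continue;
      if (arma::norm(entries[j] - state) < ball_radius) {
        if (raddot <= 0) continue; // stored onsets have outward radial velocity
        vec dv = impulses[j] / m;
        double rhat_dv = (rad > 1e-12) ? arma::dot(dv, r) / rad : 0.0;
        double rv = raddot;
        // never reverse the radial velocity (condition 3 at application)
        double s = 1.0;
        if (rhat_dv < 0 && rv + rhat_dv < 0)
          s = std::min(1.0, std::max(0.0, -rv / rhat_dv));
        double Lb = arma::norm(arma::cross(r, m * v));
        vec v_pre = v;
        v += s * dv;
        double La = arma::norm(arma::cross(r, m * v));
        entry_last_applied[j] = t;
        cor_t.push_back(t); cor_r.push_back(rad);
        cor_Lbefore.push_back(Lb); cor_Lafter.push_back(La);
        cor_imp.push_back(arma::norm(s * impulses[j]));
        cor_entry.push_back((double)j);
        cor_dist.push_back(arma::norm(entries[j] - state));
        double nv = arma::norm(v_pre), nd = arma::norm(dv);
        cor_cosv.push_back((nv > 0 && nd > 0) ? arma::dot(v_pre, dv) / (nv * nd) : 0.0);
        seg_L_dev.push_back(segL_maxdev / std::max(segL_ref, 1e-300));
        segL_ref = La; segL_maxdev = 0.0;
        steps_since_cor = 0;
        if (in_episode) { in_episode = false; episode_valid = false; }
        break; // at most one impulse per step
      }
    }

    // rotation bookkeeping + velocity Verlet
    vec a1 = -(k / m) * r;
    vec r_new = r + v * dt + 0.5 * a1 * dt * dt;
    vec a2 = -(k / m) * r_new;
    vec v_new = v + 0.5 * (a1 + a2) * dt;
    if (in_episode) {
      double cr = arma::norm(arma::cross(r, r_new));
      double dn = arma::norm(r) * arma::norm(r_new);
      if (dn > 1e-300) theta_acc += std::asin(std::min(1.0, cr / dn));
    }
    r = r_new; v = v_new;
    double Lnow = arma::norm(arma::cross(r, m * v));
    segL_maxdev = std::max(segL_maxdev, std::fabs(Lnow - segL_ref));
  }
  if (n >= n_steps) t_end = T_max;
  seg_L_dev.push_back(segL_maxdev / std::max(segL_ref, 1e-300));

  return List::create(
    _["termination"] = termination, _["t_end"] = t_end,
    _["r_final"] = r, _["v_final"] = v,
    _["n_entries"] = (int)entries.size(),
    _["cor_t"] = cor_t, _["cor_r"] = cor_r,
    _["cor_L_before"] = cor_Lbefore, _["cor_L_after"] = cor_Lafter,
    _["cor_impulse"] = cor_imp,
    _["cor_entry"] = cor_entry, _["cor_dist"] = cor_dist,
    _["cor_cosv"] = cor_cosv,
    _["segment_L_reldev"] = seg_L_dev,
    _["rec_t"] = rec_t, _["rec_x"] = rec_x, _["rec_y"] = rec_y,
    _["rec_z"] = rec_z, _["rec_rad"] = rec_rad, _["rec_L"] = rec_L);
}
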