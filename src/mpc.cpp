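// Receding-horizon firing-rate inference for the calcium/indicator ODE.
//
// The finite-horizon subproblem minimizes
//   sum_{k=0..n-1} (z_k - m_k)^2 + r (s_k - s_{k-1})^2
//     + tw * (z_n - m_n)^2
// over nonnegative rate sequences s, subject to RK4-discretized dynamics
// (single shooting). Gradients are exact: forward sensitivities are
// propagated through the RK4 stages in tangent mode. The solver is a
// projected Levenberg-Marquardt Gauss-Newton iteration; bounds are handled
// by clamping trial points and zeroing bound-active gradient components.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

struct CellPar {
  double kf, kr, L, alpha, gamma;
};

static CellPar as_par(const Rcpp::List& p) {
  CellPar q;
  q.kf = Rcpp::as<double>(p["k_f"]);
  q.kr = Rcpp::as<double>(p["k_r"]);
  q.L = Rcpp::as<double>(p["L"]);
  q.alpha = Rcpp::as<double>(p["alpha"]);
  q.gamma = Rcpp::as<double>(p["gamma"]);
  return q;
}

struct Hcfg {
  int n;
  double r, dt;
  int substeps;
  double smin, smax, tw, tol;
  int max_iter;
  bool reset_state;
};

static Hcfg as_cfg(const Rcpp::List& c) {
  Hcfg h;
  h.n = Rcpp::as<int>(c["n"]);
  h.r = Rcpp::as<double>(c["r"]);
  h.dt = Rcpp::as<double>(c["dt"]);
  h.substeps = Rcpp::as<int>(c["substeps"]);
  h.smin = Rcpp::as<double>(c["s_min"]);
  h.smax = Rcpp::as<double>(c["s_max"]);
  h.tw = Rcpp::as<double>(c["terminal_weight"]);
  h.tol = Rcpp::as<double>(c["solver_tol"]);
  h.max_iter = Rcpp::as<int>(c["max_iter"]);
  h.reset_state = Rcpp::as<bool>(c["reset_state"]);
  return h;
}

static inline void frhs(const CellPar& p, double x, double z, double s,
                        double& dx, double& dz) {
  const double bind = p.kf * x * (p.L - z);
  dx = p.alpha * s - p.gamma * x + p.kr * z - bind;
  dz = bind - p.kr * z;
}

static void rk4_step(const CellPar& p, double h, double s,
                     double& x, double& z) {
  double k1x, k1z, k2x, k2z, k3x, k3z, k4x, k4z;
  frhs(p, x, z, s, k1x, k1z);
  frhs(p, x + 0.5 * h * k1x, z + 0.5 * h * k1z, s, k2x, k2z);
  frhs(p, x + 0.5 * h * k2x, z + 0.5 * h * k2z, s, k3x, k3z);
  frhs(p, x + h * k3x, z + h * k3z, s, k4x, k4z);
  x += h / 6.0 * (k1x + 2.0 * k2x + 2.0 * k3x + k4x);
  z += h / 6.0 * (k1z + 2.0 * k2z + 2.0 * k3z + k4z);
}

// The binding term k_f*x*(L-z) makes the system stiff when large inputs
// push free calcium high; keep h * (fastest local rate) below a safe
// explicit-RK4 stability margin by refining the substep count.
static int stable_substeps(const CellPar& p, double x, double dt,
                           int base) {
  const double lam =
      p.gamma + p.kr + p.kf * (std::max(x, 0.0) + p.L);
  const int need = (int)std::ceil(dt * lam / 0.8);
  const int m = std::max(base, need);
  return std::min(m, 100000);
}

// One RK4 substep with tangent propagation of sensitivities dstate/ds_j for
// columns 0..ncols-1 of S; column jcol is the control active on this step.
static void rk4_step_tan(const CellPar& p, double h, double s,
                         double& x, double& z, arma::mat& S,
                         int ncols, int jcol) {
  double k1x, k1z;
  frhs(p, x, z, s, k1x, k1z);
  const double x2 = x + 0.5 * h * k1x, z2 = z + 0.5 * h * k1z;
  double k2x, k2z;
  frhs(p, x2, z2, s, k2x, k2z);
  const double x3 = x + 0.5 * h * k2x, z3 = z + 0.5 * h * k2z;
  double k3x, k3z;
  frhs(p, x3, z3, s, k3x, k3z);
  const double x4 = x + h * k3x, z4 = z + h * k3z;
  double k4x, k4z;
  frhs(p, x4, z4, s, k4x, k4z);

  auto jac = [&p](double xx, double zz, double J[4]) {
    J[0] = -p.gamma - p.kf * (p.L - zz);
    J[1] = p.kr + p.kf * xx;
    J[2] = p.kf * (p.L - zz);
    J[3] = -(p.kr + p.kf * xx);
  };
  double J1[4], J2[4], J3[4], J4[4];
  jac(x, z, J1);
  jac(x2, z2, J2);
  jac(x3, z3, J3);
  jac(x4, z4, J4);
  const double bx = p.alpha;

  for (int j = 0; j < ncols; ++j) {
    const double ds = (j == jcol) ? 1.0 : 0.0;
    const double ux = S(0, j), uz = S(1, j);
    const double d1x = J1[0] * ux + J1[1] * uz + bx * ds;
    const double d1z = J1[2] * ux + J1[3] * uz;
    const double u2x = ux + 0.5 * h * d1x, u2z = uz + 0.5 * h * d1z;
    const double d2x = J2[0] * u2x + J2[1] * u2z + bx * ds;
    const double d2z = J2[2] * u2x + J2[3] * u2z;
    const double u3x = ux + 0.5 * h * d2x, u3z = uz + 0.5 * h * d2z;
    const double d3x = J3[0] * u3x + J3[1] * u3z + bx * ds;
    const double d3z = J3[2] * u3x + J3[3] * u3z;
    const double u4x = ux + h * d3x, u4z = uz + h * d3z;
    const double d4x = J4[0] * u4x + J4[1] * u4z + bx * ds;
    const double d4z = J4[2] * u4x + J4[3] * u4z;
    S(0, j) = ux + h / 6.0 * (d1x + 2.0 * d2x + 2.0 * d3x + d4x);
    S(1, j) = uz + h / 6.0 * (d1z + 2.0 * d2z + 2.0 * d3z + d4z);
  }
  x += h / 6.0 * (k1x + 2.0 * k2x + 2.0 * k3x + k4x);
  z += h / 6.0 * (k1z + 2.0 * k2z + 2.0 * k3z + k4z);
}

// Evaluate the horizon cost; optionally fill weighted residuals, their
// Jacobian, and the predicted trajectory. meas has length n+1 (current
// sample plus n lookahead samples).
static double horizon_eval(const CellPar& p, const Hcfg& c,
                           const arma::vec& s, double x0, double z0,
                           const arma::vec& meas, double sprev,
                           arma::vec* res, arma::mat* Jout,
                           arma::vec* zpred, arma::vec* xpred) {
  const int n = c.n;
  double x = x0, z = z0;
  arma::mat S(2, n, arma::fill::zeros);
  double cost = (z0 - meas[0]) * (z0 - meas[0]);
  const double sr = std::sqrt(c.r);
  if (res) res->zeros(2 * n);
  if (Jout) Jout->zeros(2 * n, n);
  for (int k = 0; k < n; ++k) {
    const double x_end = x + p.alpha * s[k] * c.dt;  // influx upper bound
    const int ms = stable_substeps(p, std::max(x, x_end), c.dt,
                                   c.substeps);
    const double h = c.dt / ms;
    for (int m = 0; m < ms; ++m)
      rk4_step_tan(p, h, s[k], x, z, S, k + 1, k);
    if (zpred) (*zpred)[k] = z;
    if (xpred) (*xpred)[k] = x;
    const double w = (k == n - 1) ? c.tw : 1.0;
    const double sw = std::sqrt(w);
    const double e = z - meas[k + 1];
    cost += w * e * e;
    if (res) (*res)[k] = sw * e;
    if (Jout)
      for (int j = 0; j <= k; ++j) (*Jout)(k, j) = sw * S(1, j);
    const double prev = (k == 0) ? sprev : s[k - 1];
    const double de = s[k] - prev;
    cost += c.r * de * de;
    if (res) (*res)[n + k] = sr * de;
    if (Jout) {
      (*Jout)(n + k, k) = sr;
      if (k > 0) (*Jout)(n + k, k - 1) = -sr;
    }
  }
  return cost;
}

// Projected LM Gauss-Newton from the given start; returns best cost found.
static double solve_gn(const CellPar& p, const Hcfg& c, arma::vec& s,
                       double x0, double z0, const arma::vec& meas,
                       double sprev, int& iters, bool& converged) {
  const int n = c.n;
  arma::vec res(2 * n);
  arma::mat J(2 * n, n);
  double cost = horizon_eval(p, c, s, x0, z0, meas, sprev, &res, &J,
                             nullptr, nullptr);
  double lambda = 1e-4;
  converged = false;
  int it = 0;
  for (; it < c.max_iter; ++it) {
    arma::vec g = 2.0 * (J.t() * res);
    double pg = 0.0;
    for (int j = 0; j < n; ++j) {
      double gj = g[j];
      if (s[j] <= c.smin + 1e-12 && gj > 0) gj = 0.0;
      if (s[j] >= c.smax - 1e-12 && gj < 0) gj = 0.0;
      pg += gj * gj;
    }
    if (std::sqrt(pg) < 1e-14) {  // exactly stationary
      converged = true;
      break;
    }
    const arma::mat H = J.t() * J;
    const arma::vec rhs = -(J.t() * res);
    bool accepted = false;
    for (int inner = 0; inner < 12; ++inner) {
      arma::mat Hd = H;
      Hd.diag() += lambda * (H.diag() + 1e-12);
      arma::vec d;
      const bool ok = arma::solve(d, Hd, rhs,
                                  arma::solve_opts::likely_sympd +
                                      arma::solve_opts::no_approx);
      if (!ok) {
        lambda *= 10.0;
        continue;
      }
      arma::vec st = arma::clamp(s + d, c.smin, c.smax);
      arma::vec rest(2 * n);
      arma::mat Jt(2 * n, n);
      const double ct = horizon_eval(p, c, st, x0, z0, meas, sprev, &rest,
                                     &Jt, nullptr, nullptr);
      if (ct < cost - 1e-15) {
        const double step = arma::abs(st - s).max();
        s = st;
        cost = ct;
        res = rest;
        J = Jt;
        lambda = std::max(lambda / 3.0, 1e-10);
        accepted = true;
        // convergence in rate units: the accepted step moved no component
        // by more than tol * (1 + scale of s)
        if (step < c.tol * (1.0 + arma::abs(s).max())) converged = true;
        break;
      }
      lambda *= 5.0;
    }
    if (converged) {
      ++it;
      break;
    }
    if (!accepted) break;  // stalled: keep best feasible iterate
  }
  iters = it;
  return cost;
}

// Warm-started solve with one restart from s = smin on non-convergence and
// a zero-input candidate guard (guarantees cost <= cost of zero input).
static double solve_full(const CellPar& p, const Hcfg& c, arma::vec& s,
                         double x0, double z0, const arma::vec& meas,
                         double sprev, int& iters, bool& converged) {
  int it1 = 0;
  bool cv1 = false;
  double best = solve_gn(p, c, s, x0, z0, meas, sprev, it1, cv1);
  int itb = it1;
  if (!cv1) {
    arma::vec s0(c.n);
    s0.fill(std::max(0.0, c.smin));
    int it2 = 0;
    bool cv2 = false;
    const double c2 = solve_gn(p, c, s0, x0, z0, meas, sprev, it2, cv2);
    itb += it2;
    if (c2 < best) {
      best = c2;
      s = s0;
      cv1 = cv2;
    }
  }
  arma::vec sz(c.n);
  sz.fill(std::max(0.0, c.smin));
  const double cz = horizon_eval(p, c, sz, x0, z0, meas, sprev, nullptr,
                                 nullptr, nullptr, nullptr);
  if (cz < best) {
    best = cz;
    s = sz;
  }
  iters = itb;
  converged = cv1;
  return best;
}

// [[Rcpp::export]]
Rcpp::List mpc_horizon_cost_cpp(arma::vec s, double x0, double z0,
                                arma::vec meas, double sprev,
                                Rcpp::List par, Rcpp::List cfg) {
  const CellPar p = as_par(par);
  Hcfg c = as_cfg(cfg);
  c.n = s.n_elem;
  if ((int)meas.n_elem != c.n + 1)
    Rcpp::stop("`meas` must have length n + 1");
  arma::vec res(2 * c.n), zp(c.n), xp(c.n);
  arma::mat J(2 * c.n, c.n);
  const double cost = horizon_eval(p, c, s, x0, z0, meas, sprev, &res, &J,
                                   &zp, &xp);
  const arma::vec grad = 2.0 * (J.t() * res);
  return Rcpp::List::create(Rcpp::Named("cost") = cost,
                            Rcpp::Named("grad") = grad,
                            Rcpp::Named("z_pred") = zp,
                            Rcpp::Named("x_pred") = xp);
}

// [[Rcpp::export]]
Rcpp::List mpc_solve_horizon_cpp(arma::vec warm, double x0, double z0,
                                 arma::vec meas, double sprev,
                                 Rcpp::List par, Rcpp::List cfg) {
  const CellPar p = as_par(par);
  Hcfg c = as_cfg(cfg);
  c.n = warm.n_elem;
  if ((int)meas.n_elem != c.n + 1)
    Rcpp::stop("`meas` must have length n + 1");
  int iters = 0;
  bool converged = false;
  arma::vec s = warm;
  const double cost =
      solve_full(p, c, s, x0, z0, meas, sprev, iters, converged);
  arma::vec zp(c.n), xp(c.n);
  horizon_eval(p, c, s, x0, z0, meas, sprev, nullptr, nullptr, &zp, &xp);
  return Rcpp::List::create(
      Rcpp::Named("s") = s, Rcpp::Named("cost") = cost,
      Rcpp::Named("iterations") = iters,
      Rcpp::Named("converged") = converged, Rcpp::Named("z_pred") = zp,
      Rcpp::Named("x_pred") = xp);
}

// [[Rcpp::export]]
Rcpp::List mpc_infer_cpp(arma::vec meas, double x0, double z0,
                         Rcpp::List par, Rcpp::List cfg) {
  const CellPar p = as_par(par);
  const Hcfg c = as_cfg(cfg);
  const int N = meas.n_elem;
  const int n = c.n;
  if (N < n) Rcpp::stop("measurement shorter than the horizon");
  const int K = N - n;  // index of the last solved horizon
  arma::vec s_hat(N, arma::fill::zeros);
  arma::vec zsim(N), xsim(N);
  arma::vec cost(K + 1), iters(K + 1);
  Rcpp::LogicalVector conv(K + 1);
  double x = x0, z = z0;
  zsim[0] = z0;
  xsim[0] = x0;
  arma::vec warm(n, arma::fill::zeros), last_sol(n, arma::fill::zeros);
  double sprev = 0.0;
  auto advance = [&](double s_apply) {
    const double x_end = x + p.alpha * s_apply * c.dt;
    const int ms = stable_substeps(p, std::max(x, x_end), c.dt,
                                   c.substeps);
    const double h = c.dt / ms;
    for (int m = 0; m < ms; ++m) rk4_step(p, h, s_apply, x, z);
  };
  for (int k = 0; k <= K; ++k) {
    if (c.reset_state && k > 0) {
      const double eps = 1e-9 * p.L;
      z = std::min(std::max(meas[k], eps), p.L - eps);
    }
    arma::vec w(n + 1);
    for (int j = 0; j <= n; ++j) w[j] = meas[std::min(k + j, N - 1)];
    int it = 0;
    bool cv = false;
    cost[k] = solve_full(p, c, warm, x, z, w, sprev, it, cv);
    iters[k] = it;
    conv[k] = cv;
    last_sol = warm;
    s_hat[k] = warm[0];
    advance(s_hat[k]);
    if (k + 1 < N) {
      zsim[k + 1] = z;
      xsim[k + 1] = x;
    }
    sprev = s_hat[k];
    // shift for warm start of the next horizon
    for (int j = 0; j + 1 < n; ++j) warm[j] = last_sol[j + 1];
    warm[n - 1] = last_sol[n - 1];
  }
  // tail: the final n-1 controls come from the last solved horizon
  for (int j = 1; j < n && K + j < N; ++j) {
    s_hat[K + j] = last_sol[j];
    advance(s_hat[K + j]);
    if (K + j + 1 < N) {
      zsim[K + j + 1] = z;
      xsim[K + j + 1] = x;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("s_hat") = s_hat, Rcpp::Named("z_sim") = zsim,
      Rcpp::Named("x_sim") = xsim, Rcpp::Named("cost") = cost,
      Rcpp::Named("iterations") = iters, Rcpp::Named("converged") = conv);
}

// Fixed-step RK4 rollout with piecewise-constant drive; states returned at
// every grid point (length(s_steps) + 1).
// [[Rcpp::export]]
Rcpp::List crn_rk4_path_cpp(arma::vec s_steps, double x0, double z0,
                            double dt, int substeps, Rcpp::List par) {
  const CellPar p = as_par(par);
  const int M = s_steps.n_elem;
  arma::vec xs(M + 1), zs(M + 1);
  double x = x0, z = z0;
  xs[0] = x;
  zs[0] = z;
  for (int k = 0; k < M; ++k) {
    const double x_end = x + p.alpha * s_steps[k] * dt;
    const int ms = stable_substeps(p, std::max(x, x_end), dt, substeps);
    const double h = dt / ms;
    for (int m = 0; m < ms; ++m) rk4_step(p, h, s_steps[k], x, z);
    xs[k + 1] = x;
    zs[k + 1] = z;
  }
  return Rcpp::List::create(Rcpp::Named("x") = xs, Rcpp::Named("z") = zs);
}
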