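#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Analytic model potentials are sums of (possibly rotated) Gaussians plus
// harmonic terms and one-sided quadratic walls.  The same parameterisation is
// evaluated from R (R/potentials.R); the C++ copy exists because the Langevin
// integrator calls it every step.

struct Potential {
  int dim;
  std::vector<bool> periodic;
  std::vector<double> period;
  double offset;
  // gaussians: G components, each with center (dim), precision (dim*dim), height
  int G;
  std::vector<double> gc;    // G x dim, row-major
  std::vector<double> gp;    // G x dim x dim
  std::vector<double> gh;    // G
  // quadratic terms: Q components, each 0.5 * sum_i k_i * d_i^2
  int Q;
  std::vector<double> qk;    // Q x dim
  std::vector<double> qc;    // Q x dim
  // walls
  bool has_walls;
  std::vector<double> wlo, whi;
  double wk;
  // valley tube (2D): polyline + piecewise-cosine depth profile
  bool has_tube;
  int TN;
  std::vector<double> tp;    // TN x 2 polyline points
  std::vector<double> tarc;  // TN cumulative arclength
  std::vector<double> tsb, tfb;
  double tsigma, tplateau;
  // 1D piecewise-cosine profile
  bool has_profile;
  std::vector<double> psb, pfb;
};

// piecewise-cosine through (sb, fb), zero slope at knots; val + derivative
static void pw_cosine(const std::vector<double> &sb, const std::vector<double> &fb,
                      double s, double &v, double &dv) {
  int n = sb.size();
  if (s <= sb[0]) { v = fb[0]; dv = 0.0; return; }
  if (s >= sb[n - 1]) { v = fb[n - 1]; dv = 0.0; return; }
  int i = 0;
  while (i < n - 1 && sb[i + 1] < s) ++i;
  double d = sb[i + 1] - sb[i], u = (s - sb[i]) / d;
  v = fb[i] + (fb[i + 1] - fb[i]) * (1.0 - std::cos(M_PI * u)) / 2.0;
  dv = (fb[i + 1] - fb[i]) * M_PI * std::sin(M_PI * u) / (2.0 * d);
}

static double wrap_diff(double d, bool per, double L) {
  if (!per) return d;
  return d - L * std::floor(d / L + 0.5);   // minimum image, [-L/2, L/2)
}

static Potential parse_potential(List pot) {
  Potential P;
  P.dim = as<int>(pot["dim"]);
  LogicalVector per = pot["periodic"];
  NumericVector pl = pot["period"];
  for (int i = 0; i < P.dim; ++i) {
    P.periodic.push_back(per[i]);
    P.period.push_back(per[i] ? pl[i] : 0.0);
  }
  P.offset = as<double>(pot["offset"]);
  P.G = 0;
  if (pot.containsElementNamed("gauss") && !Rf_isNull(pot["gauss"])) {
    List g = pot["gauss"];
    NumericMatrix centers = g["centers"];
    NumericVector heights = g["heights"];
    List prec = g["prec"];
    P.G = centers.nrow();
    for (int k = 0; k < P.G; ++k) {
      for (int i = 0; i < P.dim; ++i) P.gc.push_back(centers(k, i));
      NumericMatrix pm = prec[k];
      for (int i = 0; i < P.dim; ++i)
        for (int j = 0; j < P.dim; ++j) P.gp.push_back(pm(i, j));
      P.gh.push_back(heights[k]);
    }
  }
  P.Q = 0;
  if (pot.containsElementNamed("quads") && !Rf_isNull(pot["quads"])) {
    List q = pot["quads"];
    P.Q = q.size();
    for (int k = 0; k < P.Q; ++k) {
      List qq = q[k];
      NumericVector kk = qq["k"], cc = qq["center"];
      for (int i = 0; i < P.dim; ++i) { P.qk.push_back(kk[i]); P.qc.push_back(cc[i]); }
    }
  }
  P.has_walls = pot.containsElementNamed("walls") && !Rf_isNull(pot["walls"]);
  if (P.has_walls) {
    List w = pot["walls"];
    NumericVector lo = w["lo"], hi = w["hi"];
    P.wk = as<double>(w["k"]);
    for (int i = 0; i < P.dim; ++i) { P.wlo.push_back(lo[i]); P.whi.push_back(hi[i]); }
  }
  P.has_tube = pot.containsElementNamed("tube") && !Rf_isNull(pot["tube"]);
  if (P.has_tube) {
    List tb = pot["tube"];
    NumericMatrix pts = tb["points"];
    NumericVector arc = tb["arc"], sb = tb["sb"], fb = tb["fb"];
    P.TN = pts.nrow();
    for (int k = 0; k < P.TN; ++k) {
      P.tp.push_back(pts(k, 0));
      P.tp.push_back(pts(k, 1));
      P.tarc.push_back(arc[k]);
    }
    P.tsb.assign(sb.begin(), sb.end());
    P.tfb.assign(fb.begin(), fb.end());
    P.tsigma = as<double>(tb["sigma"]);
    P.tplateau = as<double>(tb["plateau"]);
  }
  P.has_profile = pot.containsElementNamed("profile") && !Rf_isNull(pot["profile"]);
  if (P.has_profile) {
    List pr = pot["profile"];
    NumericVector sb = pr["sb"], fb = pr["fb"];
    P.psb.assign(sb.begin(), sb.end());
    P.pfb.assign(fb.begin(), fb.end());
  }
  return P;
}

// energy and force (force overwritten); returns energy
static double pot_force(const Potential &P, const double *x, double *f) {
  const int d = P.dim;
  double V = P.offset;
  for (int i = 0; i < d; ++i) f[i] = 0.0;
  std::vector<double> dx(d), pd(d);
  for (int k = 0; k < P.G; ++k) {
    for (int i = 0; i < d; ++i)
      dx[i] = wrap_diff(x[i] - P.gc[k * d + i], P.periodic[i], P.period[i]);
    double q = 0.0;
    for (int i = 0; i < d; ++i) {
      double s = 0.0;
      for (int j = 0; j < d; ++j) s += P.gp[(k * d + i) * d + j] * dx[j];
      pd[i] = s;
      q += s * dx[i];
    }
    if (q < 120.0) {
      double e = P.gh[k] * std::exp(-0.5 * q);
      V += e;
      for (int i = 0; i < d; ++i) f[i] += e * pd[i];
    }
  }
  for (int k = 0; k < P.Q; ++k) {
    for (int i = 0; i < d; ++i) {
      double di = wrap_diff(x[i] - P.qc[k * d + i], P.periodic[i], P.period[i]);
      double ki = P.qk[k * d + i];
      V += 0.5 * ki * di * di;
      f[i] -= ki * di;
    }
  }
  if (P.has_tube) {
    // nearest point on the polyline
    double best_d2 = R_PosInf, best_s = 0.0, best_tx = 1.0, best_ty = 0.0;
    double best_px = 0.0, best_py = 0.0;
    bool best_clamped = false;
    for (int k = 0; k < P.TN - 1; ++k) {
      double ax = P.tp[2 * k], ay = P.tp[2 * k + 1];
      double bx = P.tp[2 * k + 2], by = P.tp[2 * k + 3];
      double sx = bx - ax, sy = by - ay;
      double l2 = sx * sx + sy * sy;
      double tt = ((x[0] - ax) * sx + (x[1] - ay) * sy) / l2;
      bool cl = false;
      if (tt <= 0.0) { tt = 0.0; cl = true; }
      if (tt >= 1.0) { tt = 1.0; cl = true; }
      double px = ax + tt * sx, py = ay + tt * sy;
      double dd = (x[0] - px) * (x[0] - px) + (x[1] - py) * (x[1] - py);
      if (dd < best_d2) {
        best_d2 = dd;
        double l = std::sqrt(l2);
        best_s = P.tarc[k] + tt * l;
        best_tx = sx / l; best_ty = sy / l;
        best_px = px; best_py = py;
        best_clamped = cl;
      }
    }
    double dist = std::sqrt(best_d2);
    double fv, fdv;
    pw_cosine(P.tsb, P.tfb, best_s, fv, fdv);
    if (best_clamped) fdv = 0.0;   // s locally constant in vertex wedges
    double e = std::exp(-best_d2 / (2.0 * P.tsigma * P.tsigma));
    double A = P.tplateau - fv;
    V += -A * e;
    // grad V = f'(s) e t_hat + A e (d/sigma^2) n_hat; force = -grad
    f[0] -= fdv * e * best_tx;
    f[1] -= fdv * e * best_ty;
    if (dist > 1e-12) {
      double nx = (x[0] - best_px) / dist, ny = (x[1] - best_py) / dist;
      double c = A * e * dist / (P.tsigma * P.tsigma);
      f[0] -= c * nx;
      f[1] -= c * ny;
    }
  }
  if (P.has_profile) {
    double fv, fdv;
    pw_cosine(P.psb, P.pfb, x[0], fv, fdv);
    V += fv;
    f[0] -= fdv;
  }
  if (P.has_walls) {
    for (int i = 0; i < d; ++i) {
      if (P.periodic[i]) continue;
      if (x[i] > P.whi[i]) {
        double e = x[i] - P.whi[i];
        V += P.wk * e * e;
        f[i] -= 2.0 * P.wk * e;
      } else if (x[i] < P.wlo[i]) {
        double e = x[i] - P.wlo[i];
        V += P.wk * e * e;
        f[i] -= 2.0 * P.wk * e;
      }
    }
  }
  return V;
}

// bias energy and (optionally) force of deposited axis-aligned Gaussian hills
static double bias_eval(const std::vector<double> &hc, const std::vector<double> &hh,
                        const double *sigma, int nh, int d,
                        const std::vector<bool> &periodic, const std::vector<double> &period,
                        const double *x, double *f) {
  double V = 0.0;
  if (f) for (int i = 0; i < d; ++i) f[i] = 0.0;
  std::vector<double> dx(d);
  for (int k = 0; k < nh; ++k) {
    double q = 0.0;
    for (int i = 0; i < d; ++i) {
      double di = wrap_diff(x[i] - hc[k * d + i], periodic[i], period[i]);
      dx[i] = di;
      q += di * di / (sigma[i] * sigma[i]);
    }
    if (q < 120.0) {
      double e = hh[k] * std::exp(-0.5 * q);
      V += e;
      if (f) for (int i = 0; i < d; ++i) f[i] += e * dx[i] / (sigma[i] * sigma[i]);
    }
  }
  return V;
}

// [[Rcpp::export]]
double cpp_potential_energy_point(List pot, NumericVector x) {
  Potential P = parse_potential(pot);
  std::vector<double> f(P.dim);
  return pot_force(P, x.begin(), f.data());
}

// Gridded bias accumulator (PLUMED-style): hills are stamped onto a regular
// grid holding the bias and its gradient; per-step evaluation is a
// multilinear interpolation, so the cost per step is independent of the
// number of deposited hills.
struct BiasGrid {
  int d;
  std::vector<int> n;
  std::vector<double> lo, hi, h;     // spacing h per dim
  std::vector<bool> periodic;
  std::vector<double> period;
  std::vector<double> V;             // bias
  std::vector<double> G;             // gradient, d * ncell
  int ncell;

  void init(int d_, const std::vector<double> &lo_, const std::vector<double> &hi_,
            const std::vector<int> &n_, const std::vector<bool> &per,
            const std::vector<double> &pl) {
    d = d_; lo = lo_; hi = hi_; n = n_; periodic = per; period = pl;
    ncell = 1;
    h.resize(d);
    for (int i = 0; i < d; ++i) {
      // periodic dims wrap: n cells cover one full period
      h[i] = periodic[i] ? (hi[i] - lo[i]) / n[i] : (hi[i] - lo[i]) / (n[i] - 1);
      ncell *= n[i];
    }
    V.assign(ncell, 0.0);
    G.assign((size_t)ncell * d, 0.0);
  }

  // stamp one Gaussian hill (height hh, widths sigma) centred at c
  void add_hill(const double *c, const double *sigma, double hh) {
    double cut = 6.0;
    int i0[2] = {0, 0}, i1[2] = {0, 0};
    for (int i = 0; i < d; ++i) {
      double r = cut * sigma[i];
      i0[i] = (int)std::floor((c[i] - r - lo[i]) / h[i]);
      i1[i] = (int)std::ceil((c[i] + r - lo[i]) / h[i]);
      if (!periodic[i]) {
        if (i0[i] < 0) i0[i] = 0;
        if (i1[i] > n[i] - 1) i1[i] = n[i] - 1;
      }
    }
    if (d == 1) {
      for (int a = i0[0]; a <= i1[0]; ++a) {
        int ia = a;
        if (periodic[0]) ia = ((a % n[0]) + n[0]) % n[0];
        double dx = wrap_diff(lo[0] + a * h[0] - c[0], periodic[0], period[0]);
        double q = dx * dx / (sigma[0] * sigma[0]);
        if (q > 120.0) continue;
        double e = hh * std::exp(-0.5 * q);
        V[ia] += e;
        G[ia] += e * dx / (sigma[0] * sigma[0]);
      }
    } else {
      for (int a = i0[0]; a <= i1[0]; ++a) {
        int ia = a;
        if (periodic[0]) ia = ((a % n[0]) + n[0]) % n[0];
        double dx = wrap_diff(lo[0] + a * h[0] - c[0], periodic[0], period[0]);
        double qx = dx * dx / (sigma[0] * sigma[0]);
        if (qx > 120.0) continue;
        for (int b = i0[1]; b <= i1[1]; ++b) {
          int ib = b;
          if (periodic[1]) ib = ((b % n[1]) + n[1]) % n[1];
          double dy = wrap_diff(lo[1] + b * h[1] - c[1], periodic[1], period[1]);
          double q = qx + dy * dy / (sigma[1] * sigma[1]);
          if (q > 120.0) continue;
          double e = hh * std::exp(-0.5 * q);
          size_t id = (size_t)ia + (size_t)ib * n[0];
          V[id] += e;
          G[id * 2] += e * dx / (sigma[0] * sigma[0]);
          G[id * 2 + 1] += e * dy / (sigma[1] * sigma[1]);
        }
      }
    }
  }

  // multilinear interpolation of V (and force += -grad interp)
  double eval(const double *x, double *force) const {
    int idx[2] = {0, 0};
    double w[2] = {0.0, 0.0};
    for (int i = 0; i < d; ++i) {
      double xi = x[i];
      if (periodic[i]) xi = lo[i] + (xi - lo[i]) -
        period[i] * std::floor((xi - lo[i]) / period[i]);
      double u = (xi - lo[i]) / h[i];
      int k = (int)std::floor(u);
      if (!periodic[i]) {
        if (k < 0) { k = 0; u = 0.0; }
        if (k > n[i] - 2) { k = n[i] - 2; u = n[i] - 1; }
      }
      idx[i] = k;
      w[i] = u - k;
    }
    double v = 0.0, g0 = 0.0, g1 = 0.0;
    if (d == 1) {
      int k0 = idx[0], k1 = k0 + 1;
      if (periodic[0]) { k0 %= n[0]; k1 %= n[0]; }
      v = (1 - w[0]) * V[k0] + w[0] * V[k1];
      g0 = (1 - w[0]) * G[k0] + w[0] * G[k1];
      if (force) force[0] += g0;
    } else {
      int a0 = idx[0], a1 = a0 + 1, b0 = idx[1], b1 = b0 + 1;
      if (periodic[0]) { a0 %= n[0]; a1 %= n[0]; }
      if (periodic[1]) { b0 %= n[1]; b1 %= n[1]; }
      size_t c00 = (size_t)a0 + (size_t)b0 * n[0], c10 = (size_t)a1 + (size_t)b0 * n[0];
      size_t c01 = (size_t)a0 + (size_t)b1 * n[0], c11 = (size_t)a1 + (size_t)b1 * n[0];
      double w00 = (1 - w[0]) * (1 - w[1]), w10 = w[0] * (1 - w[1]);
      double w01 = (1 - w[0]) * w[1], w11 = w[0] * w[1];
      v = w00 * V[c00] + w10 * V[c10] + w01 * V[c01] + w11 * V[c11];
      g0 = w00 * G[c00 * 2] + w10 * G[c10 * 2] + w01 * G[c01 * 2] + w11 * G[c11 * 2];
      g1 = w00 * G[c00 * 2 + 1] + w10 * G[c10 * 2 + 1] + w01 * G[c01 * 2 + 1] +
        w11 * G[c11 * 2 + 1];
      if (force) { force[0] += g0; force[1] += g1; }
    }
    return v;
  }
};

// BAOAB Langevin integrator with optional well-tempered hill deposition.
// Uses R's RNG so set.seed() at the R level makes runs bitwise reproducible.
// `bias_grid_spec` (list with lo, hi, n) switches the bias bookkeeping from
// exact hill summation to the gridded accumulator.
// [[Rcpp::export]]
List cpp_sample(List pot, NumericVector x0, int n_steps, double dt,
                double friction, double temperature, double mass, double kB,
                int hill_stride, NumericVector hill_sigma, double hill_h0,
                double hill_deltaT, int traj_stride,
                Nullable<List> bias_grid_spec = R_NilValue) {
  Potential P = parse_potential(pot);
  const int d = P.dim;
  if ((int)x0.size() != d) stop("x0 has wrong dimensionality");

  std::vector<double> x(x0.begin(), x0.end()), v(d), f(d), bf(d);
  const double kT = kB * temperature;
  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt((1.0 - c1 * c1) * kT / mass);
  const double sv = std::sqrt(kT / mass);
  for (int i = 0; i < d; ++i) v[i] = (temperature > 0.0) ? sv * norm_rand() : 0.0;

  std::vector<double> hc, hh;
  std::vector<int> hstep;
  int nh = 0;
  const bool metad = hill_stride > 0;

  BiasGrid grid;
  bool use_grid = false;
  if (metad && bias_grid_spec.isNotNull()) {
    List gs(bias_grid_spec);
    NumericVector glo = gs["lo"], ghi = gs["hi"];
    IntegerVector gn = gs["n"];
    std::vector<double> lo(glo.begin(), glo.end()), hi(ghi.begin(), ghi.end());
    std::vector<int> nn(gn.begin(), gn.end());
    grid.init(d, lo, hi, nn, P.periodic, P.period);
    use_grid = true;
  }

  int nsave = n_steps / traj_stride;
  NumericMatrix traj(nsave, d);
  int isave = 0;

  pot_force(P, x.data(), f.data());
  if (metad) {
    if (use_grid) grid.eval(x.data(), f.data());
    else {
      bias_eval(hc, hh, hill_sigma.begin(), nh, d, P.periodic, P.period, x.data(), bf.data());
      for (int i = 0; i < d; ++i) f[i] += bf[i];
    }
  }

  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < d; ++i) v[i] += 0.5 * dt * f[i] / mass;
    for (int i = 0; i < d; ++i) x[i] += 0.5 * dt * v[i];
    for (int i = 0; i < d; ++i) v[i] = c1 * v[i] + c2 * norm_rand();
    for (int i = 0; i < d; ++i) {
      x[i] += 0.5 * dt * v[i];
      if (P.periodic[i])
        x[i] -= P.period[i] * std::floor(x[i] / P.period[i]);
      if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e8)
        stop("unstable integration (coordinate overflow); reduce dt = %f", dt);
    }

    if (metad && step % hill_stride == 0) {
      double vb = use_grid ? grid.eval(x.data(), (double *)0)
                           : bias_eval(hc, hh, hill_sigma.begin(), nh, d,
                                       P.periodic, P.period, x.data(), (double *)0);
      double h = hill_h0 * std::exp(-vb / hill_deltaT);
      for (int i = 0; i < d; ++i) hc.push_back(x[i]);
      hh.push_back(h);
      hstep.push_back(step);
      ++nh;
      if (use_grid) grid.add_hill(&hc[(size_t)(nh - 1) * d], hill_sigma.begin(), h);
    }

    pot_force(P, x.data(), f.data());
    if (metad) {
      if (use_grid) grid.eval(x.data(), f.data());
      else {
        bias_eval(hc, hh, hill_sigma.begin(), nh, d, P.periodic, P.period, x.data(), bf.data());
        for (int i = 0; i < d; ++i) f[i] += bf[i];
      }
    }
    for (int i = 0; i < d; ++i) v[i] += 0.5 * dt * f[i] / mass;

    if (step % traj_stride == 0 && isave < nsave) {
      for (int i = 0; i < d; ++i) traj(isave, i) = x[i];
      ++isave;
    }
  }

  NumericMatrix centers(nh, d);
  NumericVector heights(nh);
  IntegerVector steps(nh);
  for (int k = 0; k < nh; ++k) {
    for (int i = 0; i < d; ++i) centers(k, i) = hc[k * d + i];
    heights[k] = hh[k];
    steps[k] = hstep[k];
  }
  return List::create(_["trajectory"] = traj, _["centers"] = centers,
                      _["heights"] = heights, _["steps"] = steps,
                      _["final"] = NumericVector(x.begin(), x.end()));
}

// Exact sum-of-hills bias evaluated at arbitrary points (rows of `at`).
// [[Rcpp::export]]
NumericVector cpp_bias_energy(NumericMatrix centers, NumericVector heights,
                              NumericMatrix sigma, LogicalVector periodic,
                              NumericVector period, NumericMatrix at) {
  const int nh = centers.nrow(), d = centers.ncol(), n = at.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double V = 0.0;
    for (int k = 0; k < nh; ++k) {
      double q = 0.0;
      for (int i = 0; i < d; ++i) {
        double di = at(p, i) - centers(k, i);
        if (periodic[i]) {
          double L = period[i];
          di -= L * std::floor(di / L + 0.5);
        }
        q += di * di / (sigma(k, i) * sigma(k, i));
      }
      if (q < 120.0) V += heights[k] * std::exp(-0.5 * q);
    }
    out[p] = V;
  }
  return out;
}
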