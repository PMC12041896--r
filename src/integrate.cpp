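// Adaptive Dormand-Prince (RK45) integration of the replicator (genotypic)
// and multi-replicator (allelic) fields of a common-interests game.
//
// The flow is integrated in log-frequency coordinates: writing u = log x
// (per simplex block, up to a common shift absorbed by normalization), the
// replicator dynamics becomes du_g/dt = w_g and the multi-replicator
// du^i_j/dt = w^i_j(q) — bounded, smooth fields with no stiffness near the
// simplex boundary. Frequencies many hundreds of orders of magnitude below
// one are carried faithfully (they matter: a transiently suppressed allele
// can later sweep), exact zeros are invariant (u = -Inf), and each block is
// renormalized by subtracting its running maximum.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct GameSpec {
  int ng;                       // number of genotypes
  int m;                        // number of loci
  std::vector<double> w;        // fitness, enumeration order
  std::vector<int> gidx;        // ng x m, 0-based allele index (column-major)
  std::vector<int> nall;        // alleles per locus
  std::vector<int> off;         // offset of each locus block in the q vector
  int dim_sex;                  // total allelic coordinates
};

// frequencies from log coordinates: per-block softmax
void freqs_from_log(const GameSpec& G, bool sexual,
                    const std::vector<double>& u, std::vector<double>& x) {
  if (sexual) {
    for (int i = 0; i < G.m; ++i) {
      double mx = -INFINITY;
      for (int j = 0; j < G.nall[i]; ++j)
        mx = std::max(mx, u[G.off[i] + j]);
      double s = 0.0;
      for (int j = 0; j < G.nall[i]; ++j) {
        x[G.off[i] + j] = std::exp(u[G.off[i] + j] - mx);
        s += x[G.off[i] + j];
      }
      for (int j = 0; j < G.nall[i]; ++j) x[G.off[i] + j] /= s;
    }
  } else {
    double mx = -INFINITY;
    for (int g = 0; g < G.ng; ++g) mx = std::max(mx, u[g]);
    double s = 0.0;
    for (int g = 0; g < G.ng; ++g) { x[g] = std::exp(u[g] - mx); s += x[g]; }
    for (int g = 0; g < G.ng; ++g) x[g] /= s;
  }
}

struct Deriv {
  const GameSpec& G;
  bool sexual;
  std::vector<double> x, qv;
  explicit Deriv(const GameSpec& g, bool sex)
      : G(g), sexual(sex), x(sex ? g.dim_sex : g.ng, 0.0), qv(g.m, 0.0) {}
  // du/dt at u; returns mean fitness
  double operator()(const std::vector<double>& u, std::vector<double>& du) {
    freqs_from_log(G, sexual, u, x);
    double wbar = 0.0;
    if (sexual) {
      std::fill(du.begin(), du.end(), 0.0);
      for (int g = 0; g < G.ng; ++g) {
        double prod = 1.0;
        for (int j = 0; j < G.m; ++j) {
          qv[j] = x[G.off[j] + G.gidx[g + (size_t)j * G.ng]];
          prod *= qv[j];
        }
        wbar += G.w[g] * prod;
        for (int j = 0; j < G.m; ++j) {
          double pe = 1.0;
          for (int l = 0; l < G.m; ++l) if (l != j) pe *= qv[l];
          du[G.off[j] + G.gidx[g + (size_t)j * G.ng]] += G.w[g] * pe;
        }
      }
    } else {
      for (int g = 0; g < G.ng; ++g) { du[g] = G.w[g]; wbar += G.w[g] * x[g]; }
    }
    return wbar;
  }
  // velocity of the frequencies themselves (for the stopping criterion)
  double velocity_norm(const std::vector<double>& du, double wbar) const {
    double mv = 0.0;
    for (size_t k = 0; k < x.size(); ++k)
      mv = std::max(mv, std::fabs(x[k] * (du[k] - wbar)));
    return mv;
  }
};

// subtract each block's maximum so log coordinates stay bounded above
void recenter(const GameSpec& G, bool sexual, std::vector<double>& u) {
  if (sexual) {
    for (int i = 0; i < G.m; ++i) {
      double mx = -INFINITY;
      for (int j = 0; j < G.nall[i]; ++j)
        mx = std::max(mx, u[G.off[i] + j]);
      for (int j = 0; j < G.nall[i]; ++j) u[G.off[i] + j] -= mx;
    }
  } else {
    double mx = -INFINITY;
    for (int g = 0; g < G.ng; ++g) mx = std::max(mx, u[g]);
    for (int g = 0; g < G.ng; ++g) u[g] -= mx;
  }
}

// leading mass criterion: every simplex block concentrated above 1 - tol_m
bool mass_converged(const GameSpec& G, bool sexual,
                    const std::vector<double>& x, double tol_m) {
  if (sexual) {
    for (int i = 0; i < G.m; ++i) {
      double mx = 0.0;
      for (int j = 0; j < G.nall[i]; ++j)
        mx = std::max(mx, x[G.off[i] + j]);
      if (mx <= 1.0 - tol_m) return false;
    }
    return true;
  }
  double mx = 0.0;
  for (int g = 0; g < G.ng; ++g) mx = std::max(mx, x[g]);
  return mx > 1.0 - tol_m;
}

// The modal vertex must be a genuine attractor before a stop is accepted:
// near an unstable vertex both the velocity and the leading-mass criteria
// would fire spuriously while an escape direction still carries
// (astronomically small but positive) mass. For the sexual flow the modal
// genotype must be a strict pure Nash equilibrium; for the asexual flow it
// must be fitness-maximal within the positive support (exact zeros are
// invariant under the replicator).
bool vertex_ok(const GameSpec& G, bool sexual, const std::vector<double>& x,
               const std::vector<int>& is_nash) {
  if (sexual) {
    long row = 0;
    long stride = 1;
    std::vector<long> strides(G.m);
    for (int i = G.m - 1; i >= 0; --i) { strides[i] = stride; stride *= G.nall[i]; }
    for (int i = 0; i < G.m; ++i) {
      int arg = 0;
      double mx = -1.0;
      for (int j = 0; j < G.nall[i]; ++j)
        if (x[G.off[i] + j] > mx) { mx = x[G.off[i] + j]; arg = j; }
      row += arg * strides[i];
    }
    return is_nash[row] != 0;
  }
  int arg = 0;
  double mx = -1.0;
  for (int g = 0; g < G.ng; ++g) if (x[g] > mx) { mx = x[g]; arg = g; }
  for (int g = 0; g < G.ng; ++g)
    if (x[g] > 0.0 && G.w[g] > G.w[arg]) return false;
  return true;
}

} // namespace

// Integrate the selected field from grid[0] to grid[end], recording the
// state at every grid time. Stops early once the velocity max-norm drops
// below tol_v or every simplex block has leading mass above 1 - tol_m,
// provided the modal vertex is a genuine attractor (see vertex_ok).
// rtol/atol control the local error of the log-frequencies, i.e. the
// relative error of the frequencies.
// [[Rcpp::export]]
List cpp_integrate(NumericVector w, IntegerMatrix gidx, IntegerVector nall,
                   NumericVector x0, bool sexual, NumericVector grid,
                   double tol_v, double tol_m, double rtol, double atol,
                   IntegerVector strict_nash) {
  GameSpec G;
  G.ng = gidx.nrow();
  G.m = gidx.ncol();
  G.w.assign(w.begin(), w.end());
  G.gidx.resize((size_t)G.ng * G.m);
  for (int j = 0; j < G.m; ++j)
    for (int g = 0; g < G.ng; ++g)
      G.gidx[g + (size_t)j * G.ng] = gidx(g, j) - 1;  // to 0-based
  G.nall.assign(nall.begin(), nall.end());
  G.off.resize(G.m);
  int acc = 0;
  for (int i = 0; i < G.m; ++i) { G.off[i] = acc; acc += G.nall[i]; }
  G.dim_sex = acc;

  const int dim = sexual ? G.dim_sex : G.ng;
  if (x0.size() != dim) stop("state has wrong dimension for this mode");
  if (strict_nash.size() != G.ng) stop("strict_nash has wrong length");
  std::vector<int> is_nash(strict_nash.begin(), strict_nash.end());
  const int ngrid = grid.size();

  std::vector<double> u(dim);
  for (int d = 0; d < dim; ++d) {
    double v = x0[d];
    if (!std::isfinite(v) || v < 0)
      stop("initial state must be finite and non-negative");
    u[d] = v > 0 ? std::log(v) : -INFINITY;
  }
  recenter(G, sexual, u);

  Deriv f(G, sexual);
  std::vector<double> k1(dim), k2(dim), k3(dim), k4(dim), k5(dim), k6(dim),
      k7(dim), ut(dim), un(dim);

  // Dormand-Prince 5(4) coefficients
  const double a21 = 1.0 / 5;
  const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
               a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
               a64 = 49.0 / 176, a65 = -5103.0 / 18656;
  const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
               b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
               e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

  NumericMatrix states(ngrid, dim);
  NumericVector wbars(ngrid), times(ngrid);
  int nrec = 0;

  double t = grid[0];
  double wbar = f(u, k1);
  double vel = f.velocity_norm(k1, wbar);
  times[nrec] = t;
  for (int d = 0; d < dim; ++d) states(nrec, d) = f.x[d];
  wbars[nrec] = wbar;
  ++nrec;

  bool converged = false;
  std::string reason = "horizon";
  if (vertex_ok(G, sexual, f.x, is_nash)) {
    if (vel < tol_v) { converged = true; reason = "velocity"; }
    else if (mass_converged(G, sexual, f.x, tol_m)) {
      converged = true; reason = "mass";
    }
  }

  long max_steps = 20000000L;
  long steps = 0;
  double h = 0.01;
  const double hmax = 1e6;

  for (int gi = 1; gi < ngrid && !converged; ++gi) {
    double tg = grid[gi];
    while (t < tg) {
      if (++steps > max_steps) stop("integration exceeded step budget");
      double hs = std::min(h, tg - t);
      f(u, k1);
      for (int d = 0; d < dim; ++d) ut[d] = u[d] + hs * a21 * k1[d];
      f(ut, k2);
      for (int d = 0; d < dim; ++d)
        ut[d] = u[d] + hs * (a31 * k1[d] + a32 * k2[d]);
      f(ut, k3);
      for (int d = 0; d < dim; ++d)
        ut[d] = u[d] + hs * (a41 * k1[d] + a42 * k2[d] + a43 * k3[d]);
      f(ut, k4);
      for (int d = 0; d < dim; ++d)
        ut[d] = u[d] + hs * (a51 * k1[d] + a52 * k2[d] + a53 * k3[d] +
                             a54 * k4[d]);
      f(ut, k5);
      for (int d = 0; d < dim; ++d)
        ut[d] = u[d] + hs * (a61 * k1[d] + a62 * k2[d] + a63 * k3[d] +
                             a64 * k4[d] + a65 * k5[d]);
      f(ut, k6);
      for (int d = 0; d < dim; ++d)
        un[d] = u[d] + hs * (b1 * k1[d] + b3 * k3[d] + b4 * k4[d] +
                             b5 * k5[d] + b6 * k6[d]);
      f(un, k7);
      // embedded error estimate on the log-frequencies; -Inf coordinates
      // (exact zeros) have infinite scale, hence no error contribution
      double errnorm = 0.0;
      for (int d = 0; d < dim; ++d) {
        double err = hs * (e1 * k1[d] + e3 * k3[d] + e4 * k4[d] +
                           e5 * k5[d] + e6 * k6[d] + e7 * k7[d]);
        double sc = atol + rtol * (1.0 + std::fabs(u[d]));
        double r = err / sc;
        errnorm += r * r;
      }
      errnorm = std::sqrt(errnorm / dim);
      if (errnorm <= 1.0) {
        u = un;
        recenter(G, sexual, u);
        t += hs;
      }
      double fac = errnorm > 0 ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
      fac = std::min(5.0, std::max(0.2, fac));
      h = std::min(hmax, std::max(1e-12, hs * fac));
    }
    wbar = f(u, k1);
    vel = f.velocity_norm(k1, wbar);
    times[nrec] = t;
    for (int d = 0; d < dim; ++d) states(nrec, d) = f.x[d];
    wbars[nrec] = wbar;
    ++nrec;
    if (vertex_ok(G, sexual, f.x, is_nash)) {
      if (vel < tol_v) { converged = true; reason = "velocity"; }
      else if (mass_converged(G, sexual, f.x, tol_m)) {
        converged = true; reason = "mass";
      }
    }
  }

  NumericMatrix st(nrec, dim);
  NumericVector tv(nrec), wv(nrec);
  for (int r = 0; r < nrec; ++r) {
    tv[r] = times[r];
    wv[r] = wbars[r];
    for (int d = 0; d < dim; ++d) st(r, d) = states(r, d);
  }
  return List::create(_["times"] = tv, _["states"] = st,
                      _["mean_fitness"] = wv, _["converged"] = converged,
                      _["reason"] = reason, _["velocity_norm"] = vel);
}
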