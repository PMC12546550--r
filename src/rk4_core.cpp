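// Fixed-step RK4 integration of the semi-discrete five-field angiogenesis
// system. Mirrors the reference R implementation (.rhs_matrix / rk4_step)
// stencil for stencil: central differences with second-order one-sided
// boundary rows for the gradient, ghost-reflection Neumann rows for the
// Laplacian. Used for the physical (source-free) model only; manufactured
// forcing runs through the R path.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Params {
  double dC, dP, dI, dO;
  double a1, a2, a3;
  double k1, k2, k3, k4, k5, k6;
  double g1, g2, KO, Omax, beta;
};

typedef std::vector<double> Vec;

inline void apply_dx(const double* u, double* out, int n, double inv2dx) {
  out[0] = (-3.0 * u[0] + 4.0 * u[1] - u[2]) * inv2dx;
  for (int j = 1; j < n - 1; ++j) out[j] = (u[j + 1] - u[j - 1]) * inv2dx;
  out[n - 1] = (u[n - 3] - 4.0 * u[n - 2] + 3.0 * u[n - 1]) * inv2dx;
}

inline void apply_dxx(const double* u, double* out, int n, double invdx2) {
  out[0] = (-2.0 * u[0] + 2.0 * u[1]) * invdx2;
  for (int j = 1; j < n - 1; ++j)
    out[j] = (u[j - 1] - 2.0 * u[j] + u[j + 1]) * invdx2;
  out[n - 1] = (2.0 * u[n - 2] - 2.0 * u[n - 1]) * invdx2;
}

// State layout: five contiguous fields of length n in the order C, P, I, F, O.
struct Work {
  Vec dxF, dxI, flux, dxflux, lap;
  explicit Work(int n)
      : dxF(n), dxI(n), flux(n), dxflux(n), lap(n) {}
};

void rhs(const Vec& U, Vec& K, int n, const Params& p,
         const Vec& Tv, const Vec& dphi, double inv2dx, double invdx2,
         Work& w) {
  const double* C = &U[0];
  const double* P = &U[n];
  const double* I = &U[2 * n];
  const double* F = &U[3 * n];
  const double* O = &U[4 * n];

  // taxis flux divergence for the endothelial equation
  apply_dx(F, w.dxF.data(), n, inv2dx);
  apply_dx(I, w.dxI.data(), n, inv2dx);
  for (int j = 0; j < n; ++j) {
    double v = p.a1 * w.dxF[j] - p.a2 * w.dxI[j] + p.a3 * dphi[j];
    w.flux[j] = C[j] * v;
  }
  apply_dx(w.flux.data(), w.dxflux.data(), n, inv2dx);

  apply_dxx(C, w.lap.data(), n, invdx2);
  for (int j = 0; j < n; ++j) {
    double H = O[j] / (p.KO + O[j]);
    K[j] = p.dC * w.lap[j] - w.dxflux[j] + p.k1 * C[j] * (1.0 - C[j]) * H;
  }

  apply_dxx(P, w.lap.data(), n, invdx2);
  for (int j = 0; j < n; ++j)
    K[n + j] = p.dP * w.lap[j] - p.k3 * P[j] * I[j] + p.k4 * Tv[j] * C[j] +
               p.k5 * Tv[j] - p.k6 * P[j];

  apply_dxx(I, w.lap.data(), n, invdx2);
  for (int j = 0; j < n; ++j)
    K[2 * n + j] = p.dI * w.lap[j] - p.k3 * P[j] * I[j];

  for (int j = 0; j < n; ++j) K[3 * n + j] = -p.k2 * P[j] * F[j];

  apply_dxx(O, w.lap.data(), n, invdx2);
  for (int j = 0; j < n; ++j)
    K[4 * n + j] = p.dO * w.lap[j] - p.g1 * C[j] * O[j] / (p.KO + O[j]) +
                   p.g2 * (p.Omax - O[j]) * p.beta * C[j];
}

NumericMatrix as_matrix(const Vec& U, int n) {
  NumericMatrix m(n, 5);
  for (int k = 0; k < 5; ++k)
    for (int j = 0; j < n; ++j) m(j, k) = U[k * n + j];
  colnames(m) = CharacterVector::create("C", "P", "I", "F", "O");
  return m;
}

double energy_of(const Vec& U, int n, double dx, double ow) {
  double s = 0.0;
  for (int j = 0; j < n; ++j) {
    double q = U[j] * U[j] + U[n + j] * U[n + j] + U[2 * n + j] * U[2 * n + j] +
               U[3 * n + j] * U[3 * n + j] + ow * U[4 * n + j] * U[4 * n + j];
    s += (j == 0 || j == n - 1) ? 0.5 * q : q;
  }
  return 0.5 * dx * s;
}

}  // namespace

// [[Rcpp::export]]
List rk4_core(NumericMatrix U0, double dx, double dt,
              int n_full, double dt_last,
              NumericVector par, NumericVector Tv, NumericVector dphi,
              int monitor_every, IntegerVector snap_steps,
              int front_idx, double front_threshold, double energy_w) {
  const int n = U0.nrow();
  if (U0.ncol() != 5) stop("state matrix must have 5 columns");
  if (par.size() != 18) stop("expected 18 parameters");
  Params p;
  p.dC = par[0]; p.dP = par[1]; p.dI = par[2]; p.dO = par[3];
  p.a1 = par[4]; p.a2 = par[5]; p.a3 = par[6];
  p.k1 = par[7]; p.k2 = par[8]; p.k3 = par[9];
  p.k4 = par[10]; p.k5 = par[11]; p.k6 = par[12];
  p.g1 = par[13]; p.g2 = par[14]; p.KO = par[15]; p.Omax = par[16];
  p.beta = par[17];

  const double inv2dx = 1.0 / (2.0 * dx);
  const double invdx2 = 1.0 / (dx * dx);
  const int n_total = n_full + (dt_last > 0.0 ? 1 : 0);
  const double t_final = n_full * dt + dt_last;

  Vec U(5 * n), Y(5 * n), s1(5 * n), s2(5 * n), s3(5 * n), s4(5 * n);
  Vec Tvec(Tv.begin(), Tv.end()), dphiv(dphi.begin(), dphi.end());
  for (int k = 0; k < 5; ++k)
    for (int j = 0; j < n; ++j) U[k * n + j] = U0(j, k);
  Work w(n);

  std::vector<double> ext_min(5), ext_max(5);
  const char* comp_names = "CPIFO";
  for (int k = 0; k < 5; ++k) {
    double mn = U[k * n], mx = U[k * n];
    for (int j = 1; j < n; ++j) {
      double v = U[k * n + j];
      if (v < mn) mn = v;
      if (v > mx) mx = v;
    }
    ext_min[k] = mn;
    ext_max[k] = mx;
  }

  std::vector<double> mon_times, mon_energy;
  std::vector<double> mon_minmax;  // row-major records of 10 values
  List snapshots;
  int snap_ptr = 0;
  double front_arrival = -1.0;

  auto record_monitor = [&](double t, const double* mn, const double* mx) {
    mon_times.push_back(t);
    for (int k = 0; k < 5; ++k) {
      mon_minmax.push_back(mn[k]);
      mon_minmax.push_back(mx[k]);
    }
    mon_energy.push_back(energy_of(U, n, dx, energy_w));
  };
  auto check_front = [&](double t) {
    if (front_idx >= 0 && front_arrival < 0.0) {
      for (int j = front_idx; j < n; ++j) {
        if (U[j] > front_threshold) {
          front_arrival = t;
          break;
        }
      }
    }
  };

  if (snap_ptr < snap_steps.size() && snap_steps[snap_ptr] == 0) {
    snapshots.push_back(as_matrix(U, n));
    ++snap_ptr;
  }
  if (monitor_every > 0) record_monitor(0.0, ext_min.data(), ext_max.data());
  check_front(0.0);

  double step_min[5], step_max[5];
  for (int step = 1; step <= n_total; ++step) {
    const double h = (step <= n_full) ? dt : dt_last;
    rhs(U, s1, n, p, Tvec, dphiv, inv2dx, invdx2, w);
    for (int i = 0; i < 5 * n; ++i) Y[i] = U[i] + 0.5 * h * s1[i];
    rhs(Y, s2, n, p, Tvec, dphiv, inv2dx, invdx2, w);
    for (int i = 0; i < 5 * n; ++i) Y[i] = U[i] + 0.5 * h * s2[i];
    rhs(Y, s3, n, p, Tvec, dphiv, inv2dx, invdx2, w);
    for (int i = 0; i < 5 * n; ++i) Y[i] = U[i] + h * s3[i];
    rhs(Y, s4, n, p, Tvec, dphiv, inv2dx, invdx2, w);
    for (int i = 0; i < 5 * n; ++i)
      U[i] += (h / 6.0) * (s1[i] + 2.0 * s2[i] + 2.0 * s3[i] + s4[i]);
    const double t = (step <= n_full) ? step * dt : t_final;

    for (int k = 0; k < 5; ++k) {
      double mn = U[k * n], mx = U[k * n];
      for (int j = 0; j < n; ++j) {
        double v = U[k * n + j];
        if (!std::isfinite(v))
          stop("non-finite state in component %s at t = %g",
               std::string(1, comp_names[k]), t);
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      step_min[k] = mn;
      step_max[k] = mx;
      if (mn < ext_min[k]) ext_min[k] = mn;
      if (mx > ext_max[k]) ext_max[k] = mx;
    }

    if (monitor_every > 0 && step % monitor_every == 0)
      record_monitor(t, step_min, step_max);
    if (snap_ptr < snap_steps.size() && snap_steps[snap_ptr] == step) {
      snapshots.push_back(as_matrix(U, n));
      ++snap_ptr;
    }
    check_front(t);
    if (step % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  const int n_rec = static_cast<int>(mon_times.size());
  NumericMatrix mon_mat(n_rec, 10);
  for (int r = 0; r < n_rec; ++r)
    for (int c = 0; c < 10; ++c) mon_mat(r, c) = mon_minmax[r * 10 + c];

  return List::create(
      _["snapshots"] = snapshots,
      _["ext_min"] = NumericVector(ext_min.begin(), ext_min.end()),
      _["ext_max"] = NumericVector(ext_max.begin(), ext_max.end()),
      _["monitor_times"] = NumericVector(mon_times.begin(), mon_times.end()),
      _["monitor_minmax"] = mon_mat,
      _["monitor_energy"] = NumericVector(mon_energy.begin(), mon_energy.end()),
      _["front_arrival"] = front_arrival);
}
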