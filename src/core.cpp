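#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Ordered-pair template match counts for sample entropy.
// Templates i, j run over 1..N-m (0-based 0..N-m-1) so that the m-match and
// (m+1)-match counts share the same index range and their ratio is a valid
// conditional probability. Matches use the Chebyshev norm with a strict
// "< r" tolerance.
// [[Rcpp::export]]
NumericVector cpp_sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int n_templates = n - m; // both dimensions m and m+1 fit here
  double b = 0.0, a = 0.0;       // unordered counts, doubled at the end
  for (int i = 0; i < n_templates - 1; ++i) {
    for (int j = i + 1; j < n_templates; ++j) {
      bool match_m = true;
      for (int l = 0; l < m; ++l) {
        if (std::fabs(x[i + l] - x[j + l]) >= r) { match_m = false; break; }
      }
      if (!match_m) continue;
      b += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) < r) a += 1.0;
    }
  }
  return NumericVector::create(2.0 * b, 2.0 * a);
}

// Conditional mutual information I(y; x | z) in nats, estimated with the
// k-nearest-neighbour (Kraskov/Frenzel-Pompe) scheme under the Chebyshev
// metric: psi(k) - < psi(n_xz+1) + psi(n_yz+1) - psi(n_z+1) >, where the
// n_* are the numbers of points strictly within the distance to the k-th
// joint-space neighbour in each marginal subspace.
// y: n vector; xe: n x dx matrix; ze: n x dz matrix.
// [[Rcpp::export]]
double cpp_cmi_knn(NumericVector y, NumericMatrix xe, NumericMatrix ze, int k) {
  const int n = y.size();
  const int dx = xe.ncol();
  const int dz = ze.ncol();
  if (xe.nrow() != n || ze.nrow() != n)
    stop("embedding row count does not match target length");
  if (k >= n) stop("k must be smaller than the number of points");

  // pack each point's coordinates contiguously: z dims, then x dims, then y
  const int dim = dz + dx + 1;
  std::vector<double> pts((size_t)n * dim);
  for (int i = 0; i < n; ++i) {
    double *p = &pts[(size_t)i * dim];
    for (int l = 0; l < dz; ++l) p[l] = ze(i, l);
    for (int l = 0; l < dx; ++l) p[dz + l] = xe(i, l);
    p[dz + dx] = y[i];
  }

  std::vector<double> d_z(n), d_xz(n), d_yz(n), d_joint(n), scratch(n);
  double acc = 0.0;
  const double psi_k = R::digamma((double)k);

  for (int i = 0; i < n; ++i) {
    const double *pi = &pts[(size_t)i * dim];
    for (int j = 0; j < n; ++j) {
      if (j == i) {
        d_z[j] = d_xz[j] = d_yz[j] = d_joint[j] = R_PosInf;
        continue;
      }
      const double *pj = &pts[(size_t)j * dim];
      double dzv = 0.0;
      for (int l = 0; l < dz; ++l) {
        double d = std::fabs(pi[l] - pj[l]);
        if (d > dzv) dzv = d;
      }
      double dxzv = dzv;
      for (int l = dz; l < dz + dx; ++l) {
        double d = std::fabs(pi[l] - pj[l]);
        if (d > dxzv) dxzv = d;
      }
      double dy = std::fabs(pi[dz + dx] - pj[dz + dx]);
      double dyzv = (dy > dzv) ? dy : dzv;
      d_z[j] = dzv;
      d_xz[j] = dxzv;
      d_yz[j] = dyzv;
      d_joint[j] = (dxzv > dyzv) ? dxzv : dyzv;
    }
    std::copy(d_joint.begin(), d_joint.end(), scratch.begin());
    std::nth_element(scratch.begin(), scratch.begin() + (k - 1), scratch.end());
    const double eps = scratch[k - 1];

    int n_z = 0, n_xz = 0, n_yz = 0;
    for (int j = 0; j < n; ++j) {
      if (d_z[j] < eps) ++n_z;
      if (d_xz[j] < eps) ++n_xz;
      if (d_yz[j] < eps) ++n_yz;
    }
    // eps is an attained distance, so every marginal count is >= k >= 1
    acc += psi_k - R::digamma((double)(n_xz + 1)) -
           R::digamma((double)(n_yz + 1)) + R::digamma((double)(n_z + 1));
  }
  return acc / n;
}

// Fixed-step RK4 integration of two diffusively coupled Lorenz systems:
//   dX_i/dt = a (Y_i - X_i) + J (X_j - X_i)
//   dY_i/dt = c X_i - X_i Z_i - Y_i
//   dZ_i/dt = X_i Y_i - b Z_i
// State is recorded every `sample_every` steps (including t = 0).
// Returns a matrix with columns t, X1, Y1, Z1, X2, Y2, Z2.
static inline void lorenz_deriv(const double *s, double *ds, double a,
                                double b, double c, double J) {
  // sides: s[0..2] = X1,Y1,Z1; s[3..5] = X2,Y2,Z2
  ds[0] = a * (s[1] - s[0]) + J * (s[3] - s[0]);
  ds[1] = c * s[0] - s[0] * s[2] - s[1];
  ds[2] = s[0] * s[1] - b * s[2];
  ds[3] = a * (s[4] - s[3]) + J * (s[0] - s[3]);
  ds[4] = c * s[3] - s[3] * s[5] - s[4];
  ds[5] = s[3] * s[4] - b * s[5];
}

// [[Rcpp::export]]
NumericMatrix cpp_coupled_lorenz_rk4(double a, double b, double c, double J,
                                     NumericVector init1, NumericVector init2,
                                     double t_end, double dt,
                                     int sample_every) {
  const long n_steps = (long)std::lround(t_end / dt);
  const long n_out = n_steps / sample_every + 1;
  NumericMatrix out(n_out, 7);
  double s[6] = {init1[0], init1[1], init1[2], init2[0], init2[1], init2[2]};
  double k1[6], k2[6], k3[6], k4[6], tmp[6];

  long row = 0;
  out(row, 0) = 0.0;
  for (int d = 0; d < 6; ++d) out(row, d + 1) = s[d];
  ++row;

  for (long step = 1; step <= n_steps; ++step) {
    lorenz_deriv(s, k1, a, b, c, J);
    for (int d = 0; d < 6; ++d) tmp[d] = s[d] + 0.5 * dt * k1[d];
    lorenz_deriv(tmp, k2, a, b, c, J);
    for (int d = 0; d < 6; ++d) tmp[d] = s[d] + 0.5 * dt * k2[d];
    lorenz_deriv(tmp, k3, a, b, c, J);
    for (int d = 0; d < 6; ++d) tmp[d] = s[d] + dt * k3[d];
    lorenz_deriv(tmp, k4, a, b, c, J);
    for (int d = 0; d < 6; ++d)
      s[d] += dt / 6.0 * (k1[d] + 2.0 * k2[d] + 2.0 * k3[d] + k4[d]);
    for (int d = 0; d < 6; ++d) {
      if (!R_finite(s[d]))
        stop("coupled Lorenz integration diverged at t = %f", step * dt);
    }
    if (step % sample_every == 0) {
      out(row, 0) = step * dt;
      for (int d = 0; d < 6; ++d) out(row, d + 1) = s[d];
      ++row;
    }
  }
  return out;
}
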