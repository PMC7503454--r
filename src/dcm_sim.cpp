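#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Bilinear neural state equation with a balloon-type hemodynamic stage and
// blood-volume (contrast-agent) readout.
//
// Neural:        dz/dt = (A + sum_j u_j B_j) z + C u
// Hemodynamic:   ds/dt = z - kappa s - gamma (f - 1)
//                df/dt = s
//            tau dv/dt = f - v^(1/alpha)
//            tau dq/dt = f E(f)/E0 - v^(1/alpha) q / v,
//                E(f) = 1 - (1 - E0)^(1/f)
// Readout:       y = -eps (v - 1)  (activation increases blood volume,
//                                   which darkens the MION signal)
//
// Inputs are zero-order-held over each TR; integration is fixed-step
// classical Runge-Kutta (4th order) with `substeps` steps per TR.
// [[Rcpp::export]]
NumericMatrix dcm_simulate_cpp(NumericMatrix A, List B, NumericMatrix C,
                               NumericMatrix U, double tr, int substeps,
                               double eps, NumericVector hemo,
                               bool track_q = true) {
  const int k = A.nrow();
  const int m = U.nrow();
  const int T = U.ncol();
  const double kappa = hemo[0], gamma = hemo[1], tau = hemo[2],
               alpha = hemo[3], E0 = hemo[4];
  const double ia = 1.0 / alpha;
  const double l1mE0 = std::log(1.0 - E0);
  const double dt = tr / substeps;

  std::vector<const double*> Bp(m);
  for (int j = 0; j < m; ++j) {
    NumericMatrix Bj = B[j];
    Bp[j] = REAL(Bj);
  }
  const double* Ap = REAL(A);
  const double* Cp = REAL(C);

  std::vector<double> z(k, 0.0), s(k, 0.0), f(k, 1.0), v(k, 1.0), q(k, 1.0);
  std::vector<double> M(k * k), cu(k);
  std::vector<double> kz(4 * k), ks(4 * k), kf(4 * k), kv(4 * k), kq(4 * k);
  std::vector<double> zt(k), st(k), ft(k), vt(k), qt(k);

  NumericMatrix Y(k, T);

  for (int t = 0; t < T; ++t) {
    // effective connectivity and drive for this TR
    for (int a = 0; a < k * k; ++a) M[a] = Ap[a];
    for (int i = 0; i < k; ++i) cu[i] = 0.0;
    for (int j = 0; j < m; ++j) {
      const double uj = U(j, t);
      if (uj != 0.0) {
        const double* Bj = Bp[j];
        for (int a = 0; a < k * k; ++a) M[a] += uj * Bj[a];
        for (int i = 0; i < k; ++i) cu[i] += Cp[i + j * k] * uj;
      }
    }

    for (int step = 0; step < substeps; ++step) {
      for (int stage = 0; stage < 4; ++stage) {
        const double w = (stage == 0) ? 0.0 : (stage == 3 ? dt : 0.5 * dt);
        for (int i = 0; i < k; ++i) {
          zt[i] = z[i] + (stage ? w * kz[(stage - 1) * k + i] : 0.0);
          st[i] = s[i] + (stage ? w * ks[(stage - 1) * k + i] : 0.0);
          ft[i] = f[i] + (stage ? w * kf[(stage - 1) * k + i] : 0.0);
          vt[i] = v[i] + (stage ? w * kv[(stage - 1) * k + i] : 0.0);
          qt[i] = q[i] + (stage ? w * kq[(stage - 1) * k + i] : 0.0);
        }
        for (int i = 0; i < k; ++i) {
          double dz = cu[i];
          for (int jj = 0; jj < k; ++jj) dz += M[i + jj * k] * zt[jj];
          kz[stage * k + i] = dz;
          ks[stage * k + i] = zt[i] - kappa * st[i] - gamma * (ft[i] - 1.0);
          kf[stage * k + i] = st[i];
          const double vi = vt[i] > 1e-6 ? vt[i] : 1e-6;
          const double fi = ft[i] > 1e-6 ? ft[i] : 1e-6;
          const double vpow = std::exp(ia * std::log(vi));
          kv[stage * k + i] = (fi - vpow) / tau;
          if (track_q) {
            const double Ef = 1.0 - std::exp(l1mE0 / fi);
            kq[stage * k + i] = (fi * Ef / E0 - vpow * qt[i] / vi) / tau;
          } else {
            kq[stage * k + i] = 0.0;
          }
        }
      }
      const double h6 = dt / 6.0;
      for (int i = 0; i < k; ++i) {
        z[i] += h6 * (kz[i] + 2 * kz[k + i] + 2 * kz[2 * k + i] + kz[3 * k + i]);
        s[i] += h6 * (ks[i] + 2 * ks[k + i] + 2 * ks[2 * k + i] + ks[3 * k + i]);
        f[i] += h6 * (kf[i] + 2 * kf[k + i] + 2 * kf[2 * k + i] + kf[3 * k + i]);
        v[i] += h6 * (kv[i] + 2 * kv[k + i] + 2 * kv[2 * k + i] + kv[3 * k + i]);
        q[i] += h6 * (kq[i] + 2 * kq[k + i] + 2 * kq[2 * k + i] + kq[3 * k + i]);
      }
    }
    for (int i = 0; i < k; ++i) Y(i, t) = -eps * (v[i] - 1.0);
  }
  return Y;
}
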