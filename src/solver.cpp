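#include <Rcpp.h>
using namespace Rcpp;

// 5-point Laplacian with mirrored (no-flux) ghost nodes, in place into lap
static void laplacian(const std::vector<double>& m, std::vector<double>& lap,
                      int nr, int nc, double inv_dx2) {
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int i = c * nr + r;
      double up    = m[c * nr + (r == 0 ? 0 : r - 1)];
      double down  = m[c * nr + (r == nr - 1 ? nr - 1 : r + 1)];
      double left  = m[(c == 0 ? 0 : c - 1) * nr + r];
      double right = m[(c == nc - 1 ? nc - 1 : c + 1) * nr + r];
      lap[i] = (up + down + left + right - 4.0 * m[i]) * inv_dx2;
    }
  }
}

// Explicit forward-Euler run of the post-treatment two-phenotype model.
// All parameter fields are full matrices (nr x nc). Records Ntot (column
// per requested time, pixels column-major) at steps listed in `snapped`.
// [[Rcpp::export]]
NumericMatrix cpp_post_sim(NumericMatrix Ns0, NumericMatrix Nd0,
                           NumericMatrix gs, NumericMatrix gd,
                           NumericMatrix kd, NumericMatrix gamma_d,
                           NumericMatrix th_pix, double Ds, double Dd,
                           double dx_mm, double dt, int n_steps,
                           IntegerVector snapped, double drug_age0,
                           bool clip) {
  int nr = Ns0.nrow(), nc = Ns0.ncol(), np = nr * nc;
  int nt = snapped.size();
  std::vector<double> ns(Ns0.begin(), Ns0.end());
  std::vector<double> nd(Nd0.begin(), Nd0.end());
  std::vector<double> lns(np), lnd(np);
  NumericMatrix out(np, nt);
  double inv_dx2 = 1.0 / (dx_mm * dx_mm);
  for (int k = 0; k <= n_steps; ++k) {
    for (int j = 0; j < nt; ++j) {
      if (snapped[j] == k) {
        for (int i = 0; i < np; ++i) out(i, j) = ns[i] + nd[i];
      }
    }
    if (k == n_steps) break;
    laplacian(ns, lns, nr, nc, inv_dx2);
    laplacian(nd, lnd, nr, nc, inv_dx2);
    double age = drug_age0 + k * dt;
    for (int i = 0; i < np; ++i) {
      double ntot = ns[i] + nd[i];
      double crowd = 1.0 - ntot / th_pix[i];
      double rate_d = gd[i] + kd[i] * std::exp(-gamma_d[i] * age) - kd[i];
      double ns2 = ns[i] + dt * (Ds * lns[i] + gs[i] * ns[i] * crowd);
      double nd2 = nd[i] + dt * (Dd * lnd[i] + rate_d * nd[i] * crowd);
      if (clip) {
        if (ns2 < 0) ns2 = 0;
        if (nd2 < 0) nd2 = 0;
      }
      ns[i] = ns2;
      nd[i] = nd2;
    }
  }
  return out;
}

// Pre-treatment exponential reaction-diffusion run; records the map
// (pixels column-major) at steps listed in `snapped`.
// [[Rcpp::export]]
NumericMatrix cpp_pre_sim(NumericMatrix N0, double g0, double D0,
                          double dx_mm, double dt, int n_steps,
                          IntegerVector snapped, bool clip) {
  int nr = N0.nrow(), nc = N0.ncol(), np = nr * nc;
  int nt = snapped.size();
  std::vector<double> n(N0.begin(), N0.end());
  std::vector<double> lap(np);
  NumericMatrix out(np, nt);
  double inv_dx2 = 1.0 / (dx_mm * dx_mm);
  for (int k = 0; k <= n_steps; ++k) {
    for (int j = 0; j < nt; ++j) {
      if (snapped[j] == k) {
        for (int i = 0; i < np; ++i) out(i, j) = n[i];
      }
    }
    if (k == n_steps) break;
    laplacian(n, lap, nr, nc, inv_dx2);
    for (int i = 0; i < np; ++i) {
      double v = n[i] + dt * (D0 * lap[i] + g0 * n[i]);
      n[i] = (clip && v < 0) ? 0 : v;
    }
  }
  return out;
}
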