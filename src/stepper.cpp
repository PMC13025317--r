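#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Explicit-Euler kernel for the electrodiffusive model
//   d psi/dt = lap(psi) - kappa^2 sinh(psi) + w(x) * A sin(2 pi f t)
// with first-order mirror (zero-flux) ghosts: the value outside the border
// equals the adjacent border value, so border neighbours outside the domain
// contribute the centre value itself. Matches the R reference euler_step()
// bit-for-bit in exact arithmetic ordering: psi + dt*(lap - sink + force),
// then optional zero-mean normalization, then t += dt.
//
// psi is nx x ny with rows indexing x (R column-major), so x-neighbours are
// +-1 in memory and y-neighbours are +-nx.
// [[Rcpp::export]]
List cpp_run_model(NumericMatrix psi_in, double h, double kappa, double dt,
                   double amplitude, double frequency, NumericVector w,
                   double t0, int n_steps, bool zero_mean, bool record) {
  const int nx = psi_in.nrow(), ny = psi_in.ncol();
  const double inv_h2 = 1.0 / (h * h);
  const double k2 = kappa * kappa;
  const double two_pi_f = 2.0 * M_PI * frequency;
  const double guard = 30.0;

  std::vector<double> psi(psi_in.begin(), psi_in.end());
  std::vector<double> nxt(static_cast<size_t>(nx) * ny);
  NumericVector edge(record ? n_steps : 0);
  double t = t0;
  double max_abs = 0.0;

  for (int step = 0; step < n_steps; ++step) {
    const double s_t = amplitude * std::sin(two_pi_f * t);
    double sum = 0.0;
    for (int j = 0; j < ny; ++j) {
      const int jm = (j == 0) ? 0 : j - 1;
      const int jp = (j == ny - 1) ? ny - 1 : j + 1;
      const double *col = &psi[static_cast<size_t>(j) * nx];
      const double *colS = &psi[static_cast<size_t>(jm) * nx];
      const double *colN = &psi[static_cast<size_t>(jp) * nx];
      double *out = &nxt[static_cast<size_t>(j) * nx];
      for (int i = 0; i < nx; ++i) {
        const double c = col[i];
        const double wv = (i == 0) ? c : col[i - 1];
        const double ev = (i == nx - 1) ? c : col[i + 1];
        const double lap = (ev + wv + colN[i] + colS[i] - 4.0 * c) * inv_h2;
        const double v = c + dt * (lap - k2 * std::sinh(c) + w[i] * s_t);
        out[i] = v;
        sum += v;
      }
    }
    if (zero_mean) {
      const double mu = sum / (static_cast<double>(nx) * ny);
      for (size_t k = 0; k < nxt.size(); ++k) nxt[k] -= mu;
    }
    double step_max = 0.0;
    for (size_t k = 0; k < nxt.size(); ++k) {
      const double a = std::fabs(nxt[k]);
      if (a > step_max) step_max = a;
    }
    if (!std::isfinite(step_max) || step_max > guard)
      stop("field blew up: max |psi| reached %g at dt = %g (step %d)",
           step_max, dt, step + 1);
    if (step_max > max_abs) max_abs = step_max;
    psi.swap(nxt);
    t = t0 + (step + 1) * dt;
    if (record) {
      double esum = 0.0;
      for (int j = 0; j < ny; ++j) esum += psi[static_cast<size_t>(j) * nx + nx - 1];
      edge[step] = esum / ny;
    }
  }

  NumericMatrix out(nx, ny);
  std::copy(psi.begin(), psi.end(), out.begin());
  return List::create(_["psi"] = out, _["t"] = t, _["edge"] = edge,
                      _["max_abs_psi"] = max_abs);
}
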