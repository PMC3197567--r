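#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Thomas solve for a tridiagonal system with constant sub/super diagonal
// `off` except that row 0 has super-diagonal `off0` (ghost-node symmetry),
// and constant main diagonal `d`. Overwrites rhs with the solution.
static void thomas_const(std::vector<double> &cp, std::vector<double> &rhs,
                         double d, double off, double off0) {
  const int n = static_cast<int>(rhs.size());
  cp[0] = off0 / d;
  rhs[0] = rhs[0] / d;
  for (int i = 1; i < n; ++i) {
    double m = d - off * cp[i - 1];
    cp[i] = off / m;
    rhs[i] = (rhs[i] - off * rhs[i - 1]) / m;
  }
  for (int i = n - 2; i >= 0; --i) rhs[i] -= cp[i] * rhs[i + 1];
}

// One IMEX step for one species: implicit diffusion (coefficient `diff`)
// and implicit linear self-decay (`decay`), explicit source `src`
// (already includes any cross-species and bilinear terms). u has N+1
// nodes; node N is Dirichlet (value 1). Writes the new values into out.
static void imex_species(const std::vector<double> &u, const NumericVector &src,
                         double diff, double decay, double dx, double dt,
                         std::vector<double> &rhs, std::vector<double> &cp,
                         std::vector<double> &out) {
  const int N = static_cast<int>(u.size()) - 1; // unknowns 0..N-1
  const double ih2 = diff / (dx * dx);
  const double d = 1.0 / dt + 2.0 * ih2 + decay;
  rhs.resize(N);
  for (int i = 0; i < N; ++i) rhs[i] = u[i] / dt + src[i];
  rhs[N - 1] += ih2 * 1.0; // Dirichlet neighbour u_N = 1
  cp.resize(N);
  thomas_const(cp, rhs, d, -ih2, -2.0 * ih2);
  for (int i = 0; i < N; ++i) out[i] = rhs[i];
  out[N] = 1.0;
}

// Advance the full system `max_steps` IMEX steps (or until the steady-state
// criterion max|du|/dt < steady_tol is met when steady_tol > 0).
// Order per step: C first (bilinear source lagged at step n), then A and B
// using the fresh C. Returns the state plus convergence diagnostics.
// [[Rcpp::export]]
List imex_run_cpp(NumericVector A, NumericVector B, NumericVector C,
                  double lambda1, double lambda2, double lambda3,
                  double lambda4, double lambda5,
                  double delta_A, double delta_B, double mu_A, double mu_B,
                  double dx, double dt, double steady_tol, int max_steps,
                  int report_every) {
  const int n = A.size();
  std::vector<double> a(A.begin(), A.end());
  std::vector<double> b(B.begin(), B.end());
  std::vector<double> c(C.begin(), C.end());
  std::vector<double> an(n), bn(n), cn(n), rhs, cp;
  NumericVector src(n - 1);

  double rateA = R_PosInf, rateB = R_PosInf, rateC = R_PosInf;
  bool converged = false;
  int step = 0;
  for (step = 1; step <= max_steps; ++step) {
    // complex: dC/dt = D2 C + lambda1 A B - lambda2 C
    for (int i = 0; i < n - 1; ++i) src[i] = lambda1 * a[i] * b[i];
    imex_species(c, src, 1.0, lambda2, dx, dt, rhs, cp, cn);
    // free chemical: dA/dt = dA D2 A - l1 muA A B + l2 muA C - l3 A
    for (int i = 0; i < n - 1; ++i)
      src[i] = -lambda1 * mu_A * a[i] * b[i] + lambda2 * mu_A * cn[i];
    imex_species(a, src, delta_A, lambda3, dx, dt, rhs, cp, an);
    // binding partner: dB/dt = dB D2 B - l1 muB A B - l4 B + l5 C
    for (int i = 0; i < n - 1; ++i)
      src[i] = -lambda1 * mu_B * a[i] * b[i] + lambda5 * cn[i];
    imex_species(b, src, delta_B, lambda4, dx, dt, rhs, cp, bn);

    rateA = rateB = rateC = 0.0;
    for (int i = 0; i < n; ++i) {
      rateA = std::max(rateA, std::fabs(an[i] - a[i]));
      rateB = std::max(rateB, std::fabs(bn[i] - b[i]));
      rateC = std::max(rateC, std::fabs(cn[i] - c[i]));
    }
    rateA /= dt; rateB /= dt; rateC /= dt;
    if (!(std::isfinite(rateA) && std::isfinite(rateB) && std::isfinite(rateC))) {
      stop("non-finite values at step %d: the time step is unstable for "
           "these parameters; reduce dt", step);
    }
    a.swap(an); b.swap(bn); c.swap(cn);
    if (report_every > 0 && step % report_every == 0) {
      Rcpp::Rcout << "step " << step << " max|du|/dt A=" << rateA
                  << " B=" << rateB << " C=" << rateC << "\n";
    }
    if (steady_tol > 0 && rateA < steady_tol && rateB < steady_tol &&
        rateC < steady_tol) {
      converged = true;
      break;
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  if (step > max_steps) step = max_steps;
  return List::create(
      _["A"] = NumericVector(a.begin(), a.end()),
      _["B"] = NumericVector(b.begin(), b.end()),
      _["C"] = NumericVector(c.begin(), c.end()),
      _["steps"] = step, _["converged"] = converged,
      _["max_rate"] = NumericVector::create(_["A"] = rateA, _["B"] = rateB,
                                            _["C"] = rateC));
}
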