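// Fixed-step RK4 integration of the bilinear neuronal model coupled to the
// Balloon-Windkessel hemodynamics, with BOLD read-out at volume times.
// The input u is piecewise-constant on the microtime grid (value at the
// start of a step is held through the step). The four-region system is
// small, so the inner loop uses fixed-size arrays rather than matrix
// temporaries; dcm_integrate_batch_cpp amortizes call overhead across the
// many perturbed simulations needed for finite-difference Jacobians.
#include <RcppArmadillo.h>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

constexpr int NR = 4;

struct State {
  double z[NR], s[NR], f[NR], v[NR], q[NR];
};

struct Model {
  double A[NR][NR], B[NR][NR], C[NR];
  double kappa[NR], gamma[NR], inv_tau[NR], inv_alpha[NR], E0[NR], one_minus_E0[NR];
  double V0;
};

// ub drives the bilinear (modulatory) term, uc the direct input; they
// coincide unless the caller centers the modulatory input
inline void drift(const State &x, double ub, double uc, const Model &m,
                  State &d) {
  for (int i = 0; i < NR; ++i) {
    double acc = m.C[i] * uc;
    if (ub != 0.0)
      for (int j = 0; j < NR; ++j)
        acc += (m.A[i][j] + ub * m.B[i][j]) * x.z[j];
    else
      for (int j = 0; j < NR; ++j)
        acc += m.A[i][j] * x.z[j];
    d.z[i] = acc;
    double fr = x.f[i] > 1e-8 ? x.f[i] : 1e-8;
    double vr = x.v[i] > 1e-8 ? x.v[i] : 1e-8;
    double qr = x.q[i] > 1e-8 ? x.q[i] : 1e-8;
    d.s[i] = x.z[i] - m.kappa[i] * x.s[i] - m.gamma[i] * (x.f[i] - 1.0);
    d.f[i] = x.s[i];
    double fv = std::pow(vr, m.inv_alpha[i]);
    double ef = 1.0 - std::pow(m.one_minus_E0[i], 1.0 / fr);
    d.v[i] = (fr - fv) * m.inv_tau[i];
    d.q[i] = (fr * ef / m.E0[i] - fv * qr / vr) * m.inv_tau[i];
  }
}

inline void axpy(State &y, const State &x, double a) {
  for (int i = 0; i < NR; ++i) {
    y.z[i] += a * x.z[i]; y.s[i] += a * x.s[i]; y.f[i] += a * x.f[i];
    y.v[i] += a * x.v[i]; y.q[i] += a * x.q[i];
  }
}

inline void comb(State &y, const State &x, const State &k, double a) {
  for (int i = 0; i < NR; ++i) {
    y.z[i] = x.z[i] + a * k.z[i]; y.s[i] = x.s[i] + a * k.s[i];
    y.f[i] = x.f[i] + a * k.f[i]; y.v[i] = x.v[i] + a * k.v[i];
    y.q[i] = x.q[i] + a * k.q[i];
  }
}

// returns false if the state became non-finite
bool integrate_one(const Model &m, const arma::vec &ub, const arma::vec &uc,
                   double dt, const arma::uvec &sample_steps,
                   double *bold_out, double *z_out) {
  State x;
  for (int i = 0; i < NR; ++i) {
    x.z[i] = 0.0; x.s[i] = 0.0; x.f[i] = 1.0; x.v[i] = 1.0; x.q[i] = 1.0;
  }
  State k1, k2, k3, k4, tmp;
  const arma::uword n_steps = ub.n_elem, n_out = sample_steps.n_elem;
  arma::uword next = 0;
  for (arma::uword step = 0; step < n_steps; ++step) {
    const double ui = ub(step), uci = uc(step);
    drift(x, ui, uci, m, k1);
    comb(tmp, x, k1, 0.5 * dt); drift(tmp, ui, uci, m, k2);
    comb(tmp, x, k2, 0.5 * dt); drift(tmp, ui, uci, m, k3);
    comb(tmp, x, k3, dt);       drift(tmp, ui, uci, m, k4);
    axpy(x, k1, dt / 6.0); axpy(x, k2, dt / 3.0);
    axpy(x, k3, dt / 3.0); axpy(x, k4, dt / 6.0);
    for (int i = 0; i < NR; ++i)
      if (!std::isfinite(x.z[i])) return false;
    while (next < n_out && sample_steps(next) == step + 1) {
      for (int i = 0; i < NR; ++i) {
        const double kk1 = 7.0 * m.E0[i], kk2 = 2.0,
                     kk3 = 2.0 * m.E0[i] - 0.2;
        bold_out[next + n_out * i] =
            m.V0 * (kk1 * (1.0 - x.q[i]) + kk2 * (1.0 - x.q[i] / x.v[i]) +
                    kk3 * (1.0 - x.v[i]));
        if (z_out) z_out[next + n_out * i] = x.z[i];
      }
      ++next;
    }
  }
  return true;
}

Model make_model(const arma::mat &A, const arma::mat &B, const arma::vec &C,
                 const arma::vec &kappa, const arma::vec &gamma,
                 const arma::vec &tau, const arma::vec &alpha,
                 const arma::vec &E0, double V0) {
  Model m;
  for (int i = 0; i < NR; ++i) {
    for (int j = 0; j < NR; ++j) {
      m.A[i][j] = A(i, j);
      m.B[i][j] = B(i, j);
    }
    m.C[i] = C(i);
    m.kappa[i] = kappa(i); m.gamma[i] = gamma(i);
    m.inv_tau[i] = 1.0 / tau(i); m.inv_alpha[i] = 1.0 / alpha(i);
    m.E0[i] = E0(i); m.one_minus_E0[i] = 1.0 - E0(i);
  }
  m.V0 = V0;
  return m;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List dcm_integrate_cpp(const arma::mat &A, const arma::mat &B,
                             const arma::vec &C, const arma::vec &u,
                             double dt, const arma::uvec &sample_steps,
                             const arma::vec &kappa, const arma::vec &gamma,
                             const arma::vec &tau, const arma::vec &alpha,
                             const arma::vec &E0, double V0) {
  Model m = make_model(A, B, C, kappa, gamma, tau, alpha, E0, V0);
  const arma::uword n_out = sample_steps.n_elem;
  arma::mat bold(n_out, NR), zsamp(n_out, NR);
  if (!integrate_one(m, u, u, dt, sample_steps, bold.memptr(),
                     zsamp.memptr()))
    Rcpp::stop("neural state became non-finite during integration (unstable parameters?)");
  return Rcpp::List::create(Rcpp::Named("bold") = bold,
                            Rcpp::Named("z") = zsamp);
}

// Batched variant: each column set of (A, B, C, hemo scale) comes from a
// list of parameter sets; returns a (n_out*R) x n_models matrix of BOLD
// predictions for ONE session input. Non-finite runs give NaN columns.
// [[Rcpp::export]]
arma::mat dcm_integrate_batch_cpp(const Rcpp::List &models,
                                  const arma::vec &ub, const arma::vec &uc,
                                  double dt, const arma::uvec &sample_steps) {
  const arma::uword n_out = sample_steps.n_elem;
  const int n_models = models.size();
  arma::mat out(n_out * NR, n_models);
  for (int k = 0; k < n_models; ++k) {
    Rcpp::List mk = models[k];
    Model m = make_model(Rcpp::as<arma::mat>(mk["A"]),
                         Rcpp::as<arma::mat>(mk["B"]),
                         Rcpp::as<arma::vec>(mk["C"]),
                         Rcpp::as<arma::vec>(mk["kappa"]),
                         Rcpp::as<arma::vec>(mk["gamma"]),
                         Rcpp::as<arma::vec>(mk["tau"]),
                         Rcpp::as<arma::vec>(mk["alpha"]),
                         Rcpp::as<arma::vec>(mk["E0"]),
                         Rcpp::as<double>(mk["V0"]));
    if (!integrate_one(m, ub, uc, dt, sample_steps, out.colptr(k), nullptr))
      out.col(k).fill(arma::datum::nan);
  }
  return out;
}
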