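#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Fixed-step RK4 integration of the n-region bilinear neural model with a
// balloon-type hemodynamic observation model. Inputs are zero-order-held
// within each microtime step. States per region: z (neural), s (vasodilatory
// signal), f (inflow), v (blood volume), q (deoxyhemoglobin). The inner loop
// is allocation-free: all work happens in small preallocated buffers.

struct HemoConst { double kappa, gam, tau, alpha, E0, V0, k1, k2, k3; };

// One evaluation of the full state derivative. st layout per region r:
// st[5*r + 0..4] = z, s, f, v, q.
static inline void deriv(const double* st, const double* Aeff,
                         const double* cu, int n, const HemoConst& hc,
                         double* d) {
  for (int i = 0; i < n; ++i) {
    double zd = cu[i];
    for (int j = 0; j < n; ++j) zd += Aeff[i + n * j] * st[5 * j];
    const double* x = st + 5 * i;
    double s = x[1];
    double f = x[2] > 1e-6 ? x[2] : 1e-6;
    double v = x[3] > 1e-6 ? x[3] : 1e-6;
    double q = x[4] > 1e-6 ? x[4] : 1e-6;
    double fout = std::pow(v, 1.0 / hc.alpha);
    double E = 1.0 - std::pow(1.0 - hc.E0, 1.0 / f);
    double* y = d + 5 * i;
    y[0] = zd;
    y[1] = x[0] - hc.kappa * s - hc.gam * (f - 1.0);
    y[2] = s;
    y[3] = (f - fout) / hc.tau;
    y[4] = (f * E / hc.E0 - fout * q / v) / hc.tau;
  }
}

// [[Rcpp::export]]
Rcpp::List dcm_integrate_cpp(const arma::mat& A, const arma::cube& B,
                             const arma::mat& C, const arma::mat& Umod,
                             const arma::mat& Udrive, double dt,
                             const arma::uvec& sample_idx,
                             const arma::vec& hemo_const,
                             bool return_neural = false) {
  const int n = (int)A.n_rows;
  const int nt = (int)Umod.n_rows;
  const int M = (int)B.n_slices;
  const int K = (int)C.n_cols;
  if ((int)Udrive.n_rows != nt) Rcpp::stop("input streams must share a clock");
  HemoConst hc;
  hc.kappa = hemo_const(0); hc.gam = hemo_const(1); hc.tau = hemo_const(2);
  hc.alpha = hemo_const(3); hc.E0 = hemo_const(4); hc.V0 = hemo_const(5);
  hc.k1 = 7.0 * hc.E0; hc.k2 = 2.0; hc.k3 = 2.0 * hc.E0 - 0.2;

  std::vector<double> st(5 * n, 0.0);
  for (int r = 0; r < n; ++r) { st[5 * r + 2] = 1.0; st[5 * r + 3] = 1.0; st[5 * r + 4] = 1.0; }

  mat bold(nt, n, fill::zeros);
  mat neural;
  if (return_neural) neural.set_size(nt, n);

  std::vector<double> Aeff(n * n), cu(n),
      k1v(5 * n), k2v(5 * n), k3v(5 * n), k4v(5 * n), tmp(5 * n);

  for (int t = 0; t < nt; ++t) {
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) Aeff[i + n * j] = A(i, j);
    for (int m = 0; m < M; ++m) {
      double u = Umod(t, m);
      if (u != 0.0)
        for (int j = 0; j < n; ++j)
          for (int i = 0; i < n; ++i) Aeff[i + n * j] += u * B(i, j, m);
    }
    for (int i = 0; i < n; ++i) cu[i] = 0.0;
    for (int k = 0; k < K; ++k) {
      double u = Udrive(t, k);
      if (u != 0.0) for (int i = 0; i < n; ++i) cu[i] += u * C(i, k);
    }

    deriv(st.data(), Aeff.data(), cu.data(), n, hc, k1v.data());
    for (int i = 0; i < 5 * n; ++i) tmp[i] = st[i] + 0.5 * dt * k1v[i];
    deriv(tmp.data(), Aeff.data(), cu.data(), n, hc, k2v.data());
    for (int i = 0; i < 5 * n; ++i) tmp[i] = st[i] + 0.5 * dt * k2v[i];
    deriv(tmp.data(), Aeff.data(), cu.data(), n, hc, k3v.data());
    for (int i = 0; i < 5 * n; ++i) tmp[i] = st[i] + dt * k3v[i];
    deriv(tmp.data(), Aeff.data(), cu.data(), n, hc, k4v.data());
    bool finite = true;
    for (int i = 0; i < 5 * n; ++i) {
      st[i] += dt / 6.0 * (k1v[i] + 2.0 * k2v[i] + 2.0 * k3v[i] + k4v[i]);
      if (!std::isfinite(st[i])) finite = false;
    }
    if (!finite)
      Rcpp::stop("DCM integration diverged at t = %f s (non-physical parameters?)", t * dt);

    for (int r = 0; r < n; ++r) {
      double v = st[5 * r + 3] > 1e-6 ? st[5 * r + 3] : 1e-6;
      double q = st[5 * r + 4] > 1e-6 ? st[5 * r + 4] : 1e-6;
      bold(t, r) = hc.V0 * (hc.k1 * (1.0 - q) + hc.k2 * (1.0 - q / v) +
                            hc.k3 * (1.0 - v)) * 100.0;
      if (return_neural) neural(t, r) = st[5 * r];
    }
  }

  mat y(sample_idx.n_elem, n);
  for (uword i = 0; i < sample_idx.n_elem; ++i)
    y.row(i) = bold.row(sample_idx(i) - 1);

  if (return_neural)
    return Rcpp::List::create(Rcpp::Named("bold") = y,
                              Rcpp::Named("neural") = neural);
  return Rcpp::List::create(Rcpp::Named("bold") = y);
}
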