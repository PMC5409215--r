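#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Binomial-likelihood admixture EM.
// g: n x m dosage matrix with -1 for missing; q0: n x K; f0: K x m.
// Returns q, f, the log-likelihood trace and the iteration count.
//
// The E-step expected allele-origin counts factorise so that both M-step
// updates reduce to matrix products: with GP = g/p and GQ = (2-g)/(1-p)
// (missing entries zeroed),
//   sum_i A_ilk = f_kl * (GP' Q)_lk,   sum_i B_ilk = (1-f_kl) * (GQ' Q)_lk,
//   sum_l (A+B)_ilk = q_ik * (GP F' + GQ (1-F)')_ik,
// so no n x m x K intermediate is ever formed. f is clipped to
// [eps, 1 - eps]; q rows are renormalised every iteration.
// [[Rcpp::export(name = ".em_admixture")]]
Rcpp::List em_admixture(const arma::imat& g, arma::mat q, arma::mat f,
                        double tol, int max_iter, double eps) {
  const uword n = g.n_rows, m = g.n_cols;

  mat G(n, m), G2(n, m), obs(n, m);
  for (uword i = 0; i < n; ++i) {
    for (uword l = 0; l < m; ++l) {
      int gil = g(i, l);
      if (gil < 0) {
        G(i, l) = 0.0; G2(i, l) = 0.0; obs(i, l) = 0.0;
      } else {
        G(i, l) = gil; G2(i, l) = 2.0 - gil; obs(i, l) = 1.0;
      }
    }
  }
  vec Li = sum(obs, 1);            // markers called per accession
  Li.replace(0.0, 1.0);            // guard all-missing accessions

  std::vector<double> trace;
  trace.reserve(std::min(max_iter, 4096));
  double ll_prev = -datum::inf;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    mat P = clamp(q * f, eps, 1.0 - eps);

    // log-likelihood of current parameters (missing entries contribute 0)
    double ll = accu(G % log(P)) + accu(G2 % log(1.0 - P));
    trace.push_back(ll);

    mat GP = G / P;
    mat GQ = G2 / (1.0 - P);

    mat T1 = GP.t() * q;             // m x K: sum_i GP_il q_ik
    mat T2 = GQ.t() * q;
    mat Ft = f.t();                  // m x K
    mat sa = T1 % Ft;
    mat sb = T2 % (1.0 - Ft);
    mat denom = sa + sb;
    denom.replace(0.0, 1.0);
    f = clamp((sa / denom).t(), eps, 1.0 - eps);

    mat U = GP * Ft + GQ * (1.0 - Ft); // n x K: sum_l (A+B)/q
    mat q_new = q % U;
    q_new.each_col() /= (2.0 * Li);
    vec rs = sum(q_new, 1);
    rs.replace(0.0, 1.0);
    q = q_new.each_col() / rs;

    if (std::isfinite(ll_prev)) {
      double rel = std::fabs(ll - ll_prev) / (std::fabs(ll_prev) + 1e-300);
      if (rel < tol) break;
    }
    ll_prev = ll;
  }

  // final log-likelihood at the converged parameters
  mat P = clamp(q * f, eps, 1.0 - eps);
  double ll_final = accu(G % log(P)) + accu(G2 % log(1.0 - P));
  trace.push_back(ll_final);

  return Rcpp::List::create(
    Rcpp::Named("q") = q,
    Rcpp::Named("f") = f,
    Rcpp::Named("loglik_trace") = trace,
    Rcpp::Named("n_iter") = std::min(iter, max_iter));
}
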