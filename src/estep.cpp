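#include <Rcpp.h>
using namespace Rcpp;

// One E step of the Bock-Aitkin EM over a fixed quadrature grid.
//
// resp:      n x J integer matrix of 0-based category codes, NA = missing
// logp:      list of J matrices (Q x ncat_j) of log category probabilities
// log_prior: length-Q log prior mass at the quadrature nodes (sums to 1 on
//            the probability scale)
//
// Returns the marginal log-likelihood, expected node counts n_q and, per
// item, expected category-by-node counts r_jqc.
// [[Rcpp::export]]
List estep_cpp(IntegerMatrix resp, List logp, NumericVector log_prior) {
  const int n = resp.nrow(), J = resp.ncol(), Q = log_prior.size();
  std::vector<NumericMatrix> lp(J), rj(J);
  for (int j = 0; j < J; ++j) {
    lp[j] = as<NumericMatrix>(logp[j]);
    rj[j] = NumericMatrix(Q, lp[j].ncol());
  }
  NumericVector nq(Q);
  double loglik = 0.0;
  std::vector<double> ll(Q), post(Q);

  for (int i = 0; i < n; ++i) {
    for (int q = 0; q < Q; ++q) ll[q] = log_prior[q];
    for (int j = 0; j < J; ++j) {
      const int x = resp(i, j);
      if (x == NA_INTEGER) continue;
      const NumericMatrix& m = lp[j];
      for (int q = 0; q < Q; ++q) ll[q] += m(q, x);
    }
    double mx = ll[0];
    for (int q = 1; q < Q; ++q) if (ll[q] > mx) mx = ll[q];
    double s = 0.0;
    for (int q = 0; q < Q; ++q) { post[q] = std::exp(ll[q] - mx); s += post[q]; }
    loglik += mx + std::log(s);
    for (int q = 0; q < Q; ++q) { post[q] /= s; nq[q] += post[q]; }
    for (int j = 0; j < J; ++j) {
      const int x = resp(i, j);
      if (x == NA_INTEGER) continue;
      NumericMatrix& m = rj[j];
      for (int q = 0; q < Q; ++q) m(q, x) += post[q];
    }
  }
  List r(J);
  for (int j = 0; j < J; ++j) r[j] = rj[j];
  return List::create(_["loglik"] = loglik, _["nq"] = nq, _["r"] = r);
}

// Per-person normalized posterior over quadrature nodes (n x Q), used for
// EAP scoring.
// [[Rcpp::export]]
NumericMatrix posterior_cpp(IntegerMatrix resp, List logp, NumericVector log_prior) {
  const int n = resp.nrow(), J = resp.ncol(), Q = log_prior.size();
  std::vector<NumericMatrix> lp(J);
  for (int j = 0; j < J; ++j) lp[j] = as<NumericMatrix>(logp[j]);
  NumericMatrix out(n, Q);
  std::vector<double> ll(Q);
  for (int i = 0; i < n; ++i) {
    for (int q = 0; q < Q; ++q) ll[q] = log_prior[q];
    for (int j = 0; j < J; ++j) {
      const int x = resp(i, j);
      if (x == NA_INTEGER) continue;
      const NumericMatrix& m = lp[j];
      for (int q = 0; q < Q; ++q) ll[q] += m(q, x);
    }
    double mx = ll[0];
    for (int q = 1; q < Q; ++q) if (ll[q] > mx) mx = ll[q];
    double s = 0.0;
    for (int q = 0; q < Q; ++q) { out(i, q) = std::exp(ll[q] - mx); s += out(i, q); }
    for (int q = 0; q < Q; ++q) out(i, q) /= s;
  }
  return out;
}

// Weighted variant: rows of resp are unique response patterns with
// multiplicities w.  Same return contract as estep_cpp.
// [[Rcpp::export]]
List estep_weighted_cpp(IntegerMatrix resp, NumericVector w, List logp,
                        NumericVector log_prior) {
  const int n = resp.nrow(), J = resp.ncol(), Q = log_prior.size();
  std::vector<NumericMatrix> lp(J), rj(J);
  for (int j = 0; j < J; ++j) {
    lp[j] = as<NumericMatrix>(logp[j]);
    rj[j] = NumericMatrix(Q, lp[j].ncol());
  }
  NumericVector nq(Q);
  double loglik = 0.0;
  std::vector<double> ll(Q), post(Q);
  for (int i = 0; i < n; ++i) {
    for (int q = 0; q < Q; ++q) ll[q] = log_prior[q];
    for (int j = 0; j < J; ++j) {
      const int x = resp(i, j);
      if (x == NA_INTEGER) continue;
      const NumericMatrix& m = lp[j];
      for (int q = 0; q < Q; ++q) ll[q] += m(q, x);
    }
    double mx = ll[0];
    for (int q = 1; q < Q; ++q) if (ll[q] > mx) mx = ll[q];
    double s = 0.0;
    for (int q = 0; q < Q; ++q) { post[q] = std::exp(ll[q] - mx); s += post[q]; }
    loglik += w[i] * (mx + std::log(s));
    const double wi = w[i];
    for (int q = 0; q < Q; ++q) { post[q] = wi * post[q] / s; nq[q] += post[q]; }
    for (int j = 0; j < J; ++j) {
      const int x = resp(i, j);
      if (x == NA_INTEGER) continue;
      NumericMatrix& m = rj[j];
      for (int q = 0; q < Q; ++q) m(q, x) += post[q];
    }
  }
  List r(J);
  for (int j = 0; j < J; ++j) r[j] = rj[j];
  return List::create(_["loglik"] = loglik, _["nq"] = nq, _["r"] = r);
}

// Weighted graded-response complete-data negative log-likelihood and its
// gradient in the (a, d1, log-gap) parameterization used by the M step.
static void grm_fill(const NumericVector& par, int nb,
                     std::vector<double>& d) {
  d[0] = par[1];
  double acc = par[1];
  for (int c = 1; c < nb; ++c) { acc -= std::exp(par[c + 1]); d[c] = acc; }
}

// [[Rcpp::export]]
double item_negll_cpp(NumericVector par, NumericMatrix r, NumericVector nodes) {
  const int Q = nodes.size(), C = r.ncol(), nb = C - 1;
  const double a = par[0];
  std::vector<double> d(nb);
  grm_fill(par, nb, d);
  double f = 0.0;
  for (int q = 0; q < Q; ++q) {
    double Sprev = 1.0;
    for (int c = 0; c < C; ++c) {
      const double Sc = (c < nb) ? 1.0 / (1.0 + std::exp(-(a * nodes[q] + d[c]))) : 0.0;
      double p = Sprev - Sc;
      if (p < 1e-300) p = 1e-300;
      f -= r(q, c) * std::log(p);
      Sprev = Sc;
    }
  }
  return f;
}

// [[Rcpp::export]]
NumericVector item_grad_cpp(NumericVector par, NumericMatrix r,
                            NumericVector nodes) {
  const int Q = nodes.size(), C = r.ncol(), nb = C - 1;
  const double a = par[0];
  std::vector<double> d(nb), S(nb), P(C), gd(nb, 0.0);
  grm_fill(par, nb, d);
  double ga = 0.0;
  for (int q = 0; q < Q; ++q) {
    for (int c = 0; c < nb; ++c)
      S[c] = 1.0 / (1.0 + std::exp(-(a * nodes[q] + d[c])));
    P[0] = 1.0 - S[0];
    for (int c = 1; c < nb; ++c) P[c] = S[c - 1] - S[c];
    P[nb] = S[nb - 1];
    for (int c = 0; c <= nb; ++c) if (P[c] < 1e-300) P[c] = 1e-300;
    for (int c = 0; c < nb; ++c) {
      const double wqc = (r(q, c + 1) / P[c + 1] - r(q, c) / P[c]) *
        S[c] * (1.0 - S[c]);
      ga += wqc * nodes[q];
      gd[c] += wqc;
    }
  }
  NumericVector g(par.size());
  g[0] = -ga;
  double sum_gd = 0.0;
  for (int c = 0; c < nb; ++c) sum_gd += gd[c];
  g[1] = -sum_gd;
  for (int c = 1; c < nb; ++c) {
    double tailsum = 0.0;
    for (int cc = c; cc < nb; ++cc) tailsum += gd[cc];
    g[c + 1] = std::exp(par[c + 1]) * tailsum;
  }
  return g;
}
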