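#include <Rcpp.h>
using namespace Rcpp;

// Sum of item-wise log category probabilities over quadrature nodes.
//
// Y: n x J integer matrix of category codes 0..G, NA_INTEGER for missing.
// logp: list of J matrices, each (G+1) x Q, log p(y = g | node q) for one item.
// Returns n x Q matrix of conditional pattern log-likelihoods.
// [[Rcpp::export(name = ".pattern_loglik_matrix")]]
NumericMatrix pattern_loglik_matrix(IntegerMatrix Y, List logp) {
  const int n = Y.nrow(), J = Y.ncol();
  if (logp.size() != J) stop("logp must have one matrix per item");
  NumericMatrix first = logp[0];
  const int Q = first.ncol();
  NumericMatrix out(n, Q);
  for (int j = 0; j < J; ++j) {
    NumericMatrix m = logp[j];
    for (int i = 0; i < n; ++i) {
      int y = Y(i, j);
      if (y == NA_INTEGER) continue;
      for (int q = 0; q < Q; ++q) out(i, q) += m(y, q);
    }
  }
  return out;
}

// Weighted GRM negative log-likelihood for one item given expected category
// counts r ((G+1) x Q) at quadrature nodes, with the ordered-threshold
// parameterization par = (a, k1, u2..uG), kappa_g = k1 - cumsum(exp(u)).
// grad = true additionally returns the analytic gradient.
static inline double sigmoid(double x) {
  if (x >= 0) { double e = std::exp(-x); return 1.0 / (1.0 + e); }
  double e = std::exp(x); return e / (1.0 + e);
}

// [[Rcpp::export(name = ".item_negQ")]]
NumericVector item_negQ_cpp(NumericVector par, NumericMatrix r,
                            NumericVector nodes, bool grad) {
  const int Q = nodes.size();
  const int G = par.size() - 1;      // number of thresholds
  const double a = par[0];
  std::vector<double> kappa(G);
  kappa[0] = par[1];
  for (int g = 1; g < G; ++g) kappa[g] = kappa[g - 1] - std::exp(par[g + 1]);
  double negQ = 0.0;
  std::vector<double> dz(G, 0.0);    // dL/dz_m summed over q
  double da = 0.0;
  std::vector<double> sig(G + 2), c(G + 1);
  for (int q = 0; q < Q; ++q) {
    const double x = nodes[q];
    sig[0] = 1.0;
    for (int g = 1; g <= G; ++g) sig[g] = sigmoid(a * x + kappa[g - 1]);
    sig[G + 1] = 0.0;
    for (int g = 0; g <= G; ++g) {
      c[g] = sig[g] - sig[g + 1];
      if (c[g] < 1e-250) c[g] = 1e-250;
      negQ -= r(g, q) * std::log(c[g]);
    }
    if (grad) {
      for (int m = 1; m <= G; ++m) {
        double sp = sig[m] * (1.0 - sig[m]);
        double d = sp * (r(m, q) / c[m] - r(m - 1, q) / c[m - 1]);
        dz[m - 1] -= d;            // negative log-likelihood
        da -= d * x;
      }
    }
  }
  if (!grad) return NumericVector::create(negQ);
  NumericVector out(G + 2);
  out[0] = negQ;
  out[1] = da;
  double sum_dz = 0.0;
  for (int m = 0; m < G; ++m) sum_dz += dz[m];
  out[2] = sum_dz;                                  // d/dk1
  for (int h = 1; h < G; ++h) {                     // d/du_h, kappa_m for m>h
    double s = 0.0;
    for (int m = h; m < G; ++m) s += dz[m];
    out[2 + h] = -std::exp(par[h + 1]) * s;
  }
  return out;
}

// One EM E-step for the two-component mixture: per-observation mixture
// log-likelihood, posterior C/IER probabilities, and expected category
// counts at the quadrature nodes for both components.
//
// Y: n x J integer responses (NA = missing).
// logpA: list of J (G+1) x Q log category-probability tables (attentive).
// logpC: (G+1) x Q shared table (C/IER component).
// logw: log quadrature weights; logpi1/logpi2: log mixing proportions.
// Tables are passed Q-major (Q x (G+1)), so the hot loops run over
// contiguous memory; expected counts are returned Q-major as well.
// [[Rcpp::export(name = ".mixture_estep")]]
List mixture_estep(IntegerMatrix Y, List logpA, NumericMatrix logpC,
                   NumericVector logw, double logpi1, double logpi2) {
  const int n = Y.nrow(), J = Y.ncol(), Q = logw.size();
  const int G1 = logpC.ncol();
  std::vector<const double*> pA(J);
  for (int j = 0; j < J; ++j) pA[j] = REAL(as<NumericMatrix>(logpA[j]));
  List rA(J);
  std::vector<double*> rAp(J);
  for (int j = 0; j < J; ++j) {
    NumericMatrix m(Q, G1);
    rA[j] = m;
    rAp[j] = REAL(m);
  }
  NumericMatrix rC(Q, G1);
  double* rCp = REAL(rC);
  const double* pC = REAL(logpC);
  NumericVector p2(n);
  std::vector<double> la(Q), lc(Q), ea(Q), ec(Q);
  std::vector<int> yrow(J);
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int q = 0; q < Q; ++q) { la[q] = logw[q]; lc[q] = logw[q]; }
    for (int j = 0; j < J; ++j) {
      int y = Y(i, j);
      yrow[j] = y;
      if (y == NA_INTEGER) continue;
      const double* colA = pA[j] + (size_t)y * Q;
      const double* colC = pC + (size_t)y * Q;
      for (int q = 0; q < Q; ++q) {
        la[q] += colA[q];
        lc[q] += colC[q];
      }
    }
    double ma = la[0], mc = lc[0];
    for (int q = 1; q < Q; ++q) {
      if (la[q] > ma) ma = la[q];
      if (lc[q] > mc) mc = lc[q];
    }
    double sa = 0.0, sc = 0.0;
    for (int q = 0; q < Q; ++q) {
      ea[q] = std::exp(la[q] - ma); sa += ea[q];
      ec[q] = std::exp(lc[q] - mc); sc += ec[q];
    }
    double lA = ma + std::log(sa), lC = mc + std::log(sc);
    double l1 = logpi1 + lA, l2 = logpi2 + lC;
    double m12 = l1 > l2 ? l1 : l2;
    double lli = m12 + std::log(std::exp(l1 - m12) + std::exp(l2 - m12));
    ll += lli;
    double post2 = std::exp(l2 - lli);
    p2[i] = post2;
    const double fa = (1.0 - post2) / sa, fc = post2 / sc;
    for (int q = 0; q < Q; ++q) { ea[q] *= fa; ec[q] *= fc; }
    for (int j = 0; j < J; ++j) {
      int y = yrow[j];
      if (y == NA_INTEGER) continue;
      double* rj = rAp[j] + (size_t)y * Q;
      double* rc = rCp + (size_t)y * Q;
      for (int q = 0; q < Q; ++q) {
        rj[q] += ea[q];
        rc[q] += ec[q];
      }
    }
  }
  return List::create(_["loglik"] = ll, _["p2"] = p2,
                      _["r_att"] = rA, _["r_cier"] = rC);
}

// Scaled forward recursion for a two-state hidden Markov chain observed
// through error-prone modal assignments.
//
// w: assignment code per observation (1 = attentive, 2 = C/IER), ordered by
//    respondent then occasion.
// first: 1-based index of each respondent's first row; len: rows per respondent.
// init2: per-respondent probability of starting in state 2.
// P: n x 4 matrix of interval transition probabilities (p11, p12, p21, p22);
//    rows corresponding to first occasions are ignored.
// D: 2 x 2 classification-error matrix, D(k, l) = p(assigned l | true k).
// [[Rcpp::export(name = ".forward_loglik_cpp")]]
double forward_loglik_cpp(IntegerVector w, IntegerVector first, IntegerVector len,
                          NumericVector init2, NumericMatrix P, NumericMatrix D) {
  const int N = first.size();
  double ll = 0.0;
  for (int i = 0; i < N; ++i) {
    int idx = first[i] - 1;
    int wi = w[idx] - 1;
    double a1 = (1.0 - init2[i]) * D(0, wi);
    double a2 = init2[i] * D(1, wi);
    double c = a1 + a2;
    if (c <= 0.0) return R_NegInf;
    ll += std::log(c);
    a1 /= c; a2 /= c;
    for (int t = 1; t < len[i]; ++t) {
      int r = idx + t;
      int wt = w[r] - 1;
      double b1 = (a1 * P(r, 0) + a2 * P(r, 2)) * D(0, wt);
      double b2 = (a1 * P(r, 1) + a2 * P(r, 3)) * D(1, wt);
      c = b1 + b2;
      if (c <= 0.0) return R_NegInf;
      ll += std::log(c);
      a1 = b1 / c; a2 = b2 / c;
    }
  }
  return ll;
}
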