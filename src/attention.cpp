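// Multi-head self-attention core (scores, row softmax, weighted values) and
// its backward pass. Activations arrive as (b*t) x d matrices with time
// contiguous within each sample; heads are contiguous column blocks of width
// d/h. Only the O(b * h * t^2) attention arithmetic lives here; projections
// stay in R. Raw column-major pointer access throughout (the Rcpp accessors
// are an order of magnitude slower in this loop).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List mha_core_fwd(const NumericMatrix& Q, const NumericMatrix& K,
                  const NumericMatrix& V, int b, int t, int h) {
  const int d = Q.ncol();
  const int hd = d / h;
  const int n = Q.nrow();  // b * t
  const double scale = 1.0 / std::sqrt((double)hd);
  NumericMatrix O(n, d);
  NumericVector P(Dimension(t, t, h * b));
  const double *q = &Q[0], *k = &K[0], *v = &V[0];
  double *o = &O[0], *pv = &P[0];
  std::vector<double> s(t);

  for (int i = 0; i < b; ++i) {
    const int r0 = i * t;
    for (int hh = 0; hh < h; ++hh) {
      const size_t c0 = (size_t)hh * hd;
      double* Pblk = pv + (size_t)(i * h + hh) * t * t;
      for (int a = 0; a < t; ++a) {
        double mx = R_NegInf;
        for (int bj = 0; bj < t; ++bj) {
          double acc = 0.0;
          for (int kk = 0; kk < hd; ++kk)
            acc += q[r0 + a + (c0 + kk) * n] * k[r0 + bj + (c0 + kk) * n];
          s[bj] = acc * scale;
          if (s[bj] > mx) mx = s[bj];
        }
        double z = 0.0;
        for (int bj = 0; bj < t; ++bj) { s[bj] = std::exp(s[bj] - mx); z += s[bj]; }
        for (int bj = 0; bj < t; ++bj) {
          const double p = s[bj] / z;
          Pblk[a + bj * t] = p;  // row a, col bj
          for (int kk = 0; kk < hd; ++kk)
            o[r0 + a + (c0 + kk) * n] += p * v[r0 + bj + (c0 + kk) * n];
        }
      }
    }
  }
  return List::create(_["O"] = O, _["P"] = P);
}

// [[Rcpp::export]]
List mha_core_bwd(const NumericMatrix& dO, const NumericVector& P,
                  const NumericMatrix& Q, const NumericMatrix& K,
                  const NumericMatrix& V, int b, int t, int h) {
  const int d = Q.ncol();
  const int hd = d / h;
  const int n = Q.nrow();
  const double scale = 1.0 / std::sqrt((double)hd);
  NumericMatrix dQ(n, d), dK(n, d), dV(n, d);
  const double *q = &Q[0], *k = &K[0], *v = &V[0], *dov = &dO[0], *pv = &P[0];
  double *dq = &dQ[0], *dk = &dK[0], *dv = &dV[0];
  std::vector<double> dp(t), ds(t);

  for (int i = 0; i < b; ++i) {
    const int r0 = i * t;
    for (int hh = 0; hh < h; ++hh) {
      const size_t c0 = (size_t)hh * hd;
      const double* Pblk = pv + (size_t)(i * h + hh) * t * t;
      for (int a = 0; a < t; ++a) {
        double dot = 0.0;
        for (int bj = 0; bj < t; ++bj) {
          double acc = 0.0;
          for (int kk = 0; kk < hd; ++kk)
            acc += dov[r0 + a + (c0 + kk) * n] * v[r0 + bj + (c0 + kk) * n];
          dp[bj] = acc;
          dot += acc * Pblk[a + bj * t];
        }
        for (int bj = 0; bj < t; ++bj) {
          const double p = Pblk[a + bj * t];
          const double dsb = p * (dp[bj] - dot) * scale;  // softmax bwd + scaling
          for (int kk = 0; kk < hd; ++kk) {
            const size_t ca = r0 + a + (c0 + kk) * n;
            const size_t cb = r0 + bj + (c0 + kk) * n;
            dv[cb] += p * dov[ca];
            dq[ca] += dsb * k[cb];
            dk[cb] += dsb * q[ca];
          }
        }
      }
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}
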