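#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Felsenstein pruning over compressed site patterns for a reversible
// 4-state model with k discrete rate categories and a proportion of
// invariable sites.
//
// The transition matrix on a branch of length t at relative rate r is
// P(t r) = A diag(exp(lambda * t * r)) B, where A, B, lambda come from the
// eigendecomposition of the (pi-symmetrized) rate matrix, computed in R.
//
// Underflow control: after an internal node's partials are complete, each
// pattern's 4-vector is rescaled to max 1 and the log scale factor is
// accumulated per pattern (per rate category).
//
// Layout notes (hot loop): partials are stored pattern-major with the 4
// states contiguous, and the data matrices are read through raw pointers;
// tip_part is 4 x (ntip * npat) column-major, so a tip's pattern s is the
// contiguous 4-vector at column (taxon-1)*npat + s.
//
// edge: 2-column matrix in postorder (children before parents), 1-based
//       ape node ids (tips 1..ntip, internals above).
// inv_contrib: per-pattern sum_x pi_x * prod_taxa tip_x — the invariable
//       class likelihood (0 for patterns that cannot be constant).
//
// Returns the per-pattern log-likelihood (length npat).
// [[Rcpp::export]]
NumericVector pruning_loglik_cpp(const IntegerMatrix edge,
                                 const NumericVector elen,
                                 const int ntip,
                                 const int nnode,
                                 const int root,
                                 const NumericMatrix tip_part,
                                 const NumericMatrix A,
                                 const NumericMatrix B,
                                 const NumericVector lambda,
                                 const NumericVector rates,
                                 const NumericVector pi,
                                 const double pinv,
                                 const NumericVector inv_contrib) {
  const int npat = tip_part.ncol() / ntip;
  const int nedge = edge.nrow();
  const int k = rates.size();
  NumericVector out(npat);
  if (npat == 0) return out;

  const int* ep = &edge(0, 0); // column-major: parents, then children
  const int* ec = ep + nedge;
  const double* tl = REAL(elen);
  const double* tp = REAL(tip_part);
  const double* Ap = REAL(A);
  const double* Bp = REAL(B);
  const double* lam = REAL(lambda);
  const double* pip = REAL(pi);

  // number of children per node, to trigger per-node rescaling
  std::vector<int> nchild(nnode + 1, 0);
  for (int e = 0; e < nedge; ++e) nchild[ep[e]]++;

  std::vector<double> part((size_t)(nnode + 1) * 4 * npat);
  std::vector<double> scale(npat);
  std::vector<int> done(nnode + 1);
  std::vector<double> logL((size_t)npat * k);
  double P[16];

  for (int c = 0; c < k; ++c) {
    const double r = rates[c];
    std::fill(part.begin(), part.end(), 1.0);
    std::fill(scale.begin(), scale.end(), 0.0);
    std::fill(done.begin(), done.end(), 0);

    for (int e = 0; e < nedge; ++e) {
      const int par = ep[e];
      const int ch = ec[e];
      const double t = tl[e] * r;
      // P = A diag(exp(lambda t)) B, clamped at 0 against round-off;
      // A, B are column-major 4x4
      double ex[4];
      for (int j = 0; j < 4; ++j) ex[j] = std::exp(lam[j] * t);
      for (int i = 0; i < 4; ++i) {
        for (int j = 0; j < 4; ++j) {
          double s = 0.0;
          for (int m = 0; m < 4; ++m) s += Ap[i + 4 * m] * ex[m] * Bp[m + 4 * j];
          P[4 * i + j] = s > 0.0 ? s : 0.0;
        }
      }
      double* pp = &part[(size_t)par * 4 * npat];
      const double* cp =
          (ch <= ntip) ? tp + (size_t)(ch - 1) * 4 * npat
                       : &part[(size_t)ch * 4 * npat];
      for (int s = 0; s < npat; ++s) {
        const double v0 = cp[4 * s + 0];
        const double v1 = cp[4 * s + 1];
        const double v2 = cp[4 * s + 2];
        const double v3 = cp[4 * s + 3];
        pp[4 * s + 0] *= P[0] * v0 + P[1] * v1 + P[2] * v2 + P[3] * v3;
        pp[4 * s + 1] *= P[4] * v0 + P[5] * v1 + P[6] * v2 + P[7] * v3;
        pp[4 * s + 2] *= P[8] * v0 + P[9] * v1 + P[10] * v2 + P[11] * v3;
        pp[4 * s + 3] *= P[12] * v0 + P[13] * v1 + P[14] * v2 + P[15] * v3;
      }
      if (++done[par] == nchild[par] && par != root) {
        // node complete: rescale each pattern's 4-vector to max 1
        for (int s = 0; s < npat; ++s) {
          double* v = pp + 4 * s;
          double mx = v[0];
          if (v[1] > mx) mx = v[1];
          if (v[2] > mx) mx = v[2];
          if (v[3] > mx) mx = v[3];
          if (mx > 0.0 && mx < 1.0) {
            const double inv = 1.0 / mx;
            v[0] *= inv; v[1] *= inv; v[2] *= inv; v[3] *= inv;
            scale[s] += std::log(mx);
          }
        }
      }
    }
    const double* rp = &part[(size_t)root * 4 * npat];
    for (int s = 0; s < npat; ++s) {
      const double L = pip[0] * rp[4 * s] + pip[1] * rp[4 * s + 1] +
                       pip[2] * rp[4 * s + 2] + pip[3] * rp[4 * s + 3];
      logL[(size_t)s * k + c] = (L > 0.0 ? std::log(L) : R_NegInf) + scale[s];
    }
  }

  // mix rate categories (equal weights) and the invariable class
  const double logw = -std::log((double)k);
  for (int s = 0; s < npat; ++s) {
    const double* ls = &logL[(size_t)s * k];
    double mx = R_NegInf;
    for (int c = 0; c < k; ++c)
      if (ls[c] > mx) mx = ls[c];
    double acc = 0.0;
    for (int c = 0; c < k; ++c) acc += std::exp(ls[c] - mx);
    double mixed = mx + logw + std::log(acc); // log mean over categories
    if (pinv > 0.0) {
      const double ic = inv_contrib[s];
      const double b = std::log1p(-pinv) + mixed;
      if (ic > 0.0) {
        const double a = std::log(pinv * ic);
        const double m2 = a > b ? a : b;
        mixed = m2 + std::log(std::exp(a - m2) + std::exp(b - m2));
      } else {
        mixed = b;
      }
    }
    out[s] = mixed;
  }
  return out;
}
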