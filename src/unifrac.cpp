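#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pairwise UniFrac-family distances from branch profiles.
//
// Bt: edges x samples matrix of aggregated descendant proportions (edge-
// major so each sample's profile is contiguous).  b: edge lengths.
// alphas: generalized-UniFrac exponents; 0, 0.25, 0.5, 0.75 and 1 are
// computed by sqrt composition, other values fall back to pow().
//
// Returns a list of n x n distance matrices in the order
// [u_unifrac], [w_unifrac], g_unifrac_<alpha>..., plus a logical
// "degenerate" attribute (some pair had a zero denominator).
// [[Rcpp::export(name = ".unifrac_pairs_cpp")]]
List unifrac_pairs_cpp(NumericMatrix Bt, NumericVector b, NumericVector alphas,
                       bool unweighted, bool weighted) {
  const int E = Bt.nrow(), n = Bt.ncol(), na = alphas.size();
  const int nm = (unweighted ? 1 : 0) + (weighted ? 1 : 0) + na;
  std::vector<NumericMatrix> out;
  out.reserve(nm);
  for (int m = 0; m < nm; ++m) out.push_back(NumericMatrix(n, n));
  std::vector<double> num(nm), den(nm);
  // dispatch codes for the exponent grid, resolved outside the hot loop
  std::vector<int> kind(na);
  for (int k = 0; k < na; ++k) {
    const double al = alphas[k];
    kind[k] = (al == 0.0) ? 0 : (al == 1.0) ? 1 : (al == 0.5) ? 2
              : (al == 0.25) ? 3 : (al == 0.75) ? 4 : 5;
  }
  const double *bp = b.begin();
  bool degenerate = false;

  for (int i = 0; i < n - 1; ++i) {
    const double *ci = &Bt(0, i);
    for (int j = i + 1; j < n; ++j) {
      const double *cj = &Bt(0, j);
      std::fill(num.begin(), num.end(), 0.0);
      std::fill(den.begin(), den.end(), 0.0);
      for (int e = 0; e < E; ++e) {
        const double pi = ci[e], pj = cj[e], be = bp[e];
        const double s = pi + pj;
        int m = 0;
        if (unweighted) {
          const bool qi = pi > 0.0, qj = pj > 0.0;
          if (qi != qj) num[m] += be;
          if (qi || qj) den[m] += be;
          ++m;
        }
        if (s > 0.0) {
          const double a = std::fabs(pi - pj);
          if (weighted) {
            num[m] += be * a;
            den[m] += be * s;
            ++m;
          }
          if (na > 0) {
            const double ratio = a / s;
            const double s5 = std::sqrt(s);
            const double s25 = std::sqrt(s5);
            for (int k = 0; k < na; ++k, ++m) {
              double w;
              switch (kind[k]) {
                case 0: w = 1.0; break;
                case 1: w = s; break;
                case 2: w = s5; break;
                case 3: w = s25; break;
                case 4: w = s5 * s25; break;
                default: w = std::pow(s, alphas[k]);
              }
              num[m] += be * w * ratio;
              den[m] += be * w;
            }
          }
        }
      }
      for (int m = 0; m < nm; ++m) {
        double d = 0.0;
        if (den[m] > 0.0) d = num[m] / den[m]; else degenerate = true;
        out[m](i, j) = d;
        out[m](j, i) = d;
      }
    }
  }
  List res(nm);
  for (int m = 0; m < nm; ++m) res[m] = out[m];
  res.attr("degenerate") = degenerate;
  return res;
}
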