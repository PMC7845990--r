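#include <Rcpp.h>
using namespace Rcpp;

// Pfaff-transformed Gauss hypergeometric series for the repressed bursty
// steady state: returns log 2F1(alpha+m, beta+m; ksum+m; -b) for
// m = 0..m_max, where e = ksum - beta is the second upper parameter after
// the Pfaff transformation (positive for this parameter family). The
// transformed argument is x = b/(1+b) in (0,1), all series terms are
// positive, and the term ratio tends to x, so terms are accumulated in
// linear space (no cancellation) with rescaling against overflow and a
// geometric tail bound as the stopping rule.

// [[Rcpp::export]]
NumericVector log2f1_pfaff_vec(int m_max, double alpha, double e,
                               double ksum, double b, double rtol,
                               int max_terms, bool error_on_max = true) {
  const double x = b / (1.0 + b);
  const double la = -std::log1p(b); // Pfaff prefactor (1+b)^{-(alpha+m)}
  NumericVector out(m_max + 1);
  for (int m = 0; m <= m_max; ++m) {
    const double a = alpha + m, c = ksum + m;
    double S = 1.0, t = 1.0;
    double scale = 0.0; // log offset accumulated by rescaling
    int n = 0;
    for (;;) {
      const double ratio = (a + n) * (e + n) * x / ((c + n) * (n + 1.0));
      t *= ratio;
      S += t;
      ++n;
      if (ratio < 1.0 && t * ratio < rtol * (1.0 - ratio) * S)
        break;
      if (S > 1e250) { t *= 1e-250; S *= 1e-250; scale += 250.0 * M_LN10; }
      if (n >= max_terms) {
        if (error_on_max)
          stop("2F1 series did not converge within %d terms", max_terms);
        return NumericVector::create(NA_REAL); // caller rejects the region
      }
    }
    out[m] = std::log(S) + scale + la * a;
  }
  return out;
}
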