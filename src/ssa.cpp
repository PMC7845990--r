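#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation (Gillespie) of a finite promoter-state model
// coupled to mRNA birth-death dynamics. Degradation rate is 1 (time in units
// of mRNA lifetimes). Production is per promoter state: none (type 0), one
// transcript at a time with an optional destination state (type 1, models
// irreversible RNAP escape), or an instantaneous geometric burst (type 2).
// Returns the mRNA copy number of n_cells independent cells at t_end.
// Uses R's RNG so results are reproducible under set.seed().

// [[Rcpp::export]]
IntegerVector ssa_endpoint_counts(int n_cells, double t_end,
                                  NumericMatrix switch_rates,
                                  IntegerVector prod_type,
                                  NumericVector prod_rate,
                                  NumericVector prod_b,
                                  IntegerVector prod_to,
                                  int init_state) {
  const int S = switch_rates.nrow();
  IntegerVector out(n_cells);

  // per-state total switching rate
  std::vector<double> sw_tot(S, 0.0);
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < S; ++j)
      if (j != i) sw_tot[i] += switch_rates(i, j);

  for (int cell = 0; cell < n_cells; ++cell) {
    int s = init_state;
    long m = 0;
    double t = 0.0;
    for (;;) {
      const double r_deg = (double)m;
      const double r_prod = prod_type[s] ? prod_rate[s] : 0.0;
      const double r_tot = r_deg + r_prod + sw_tot[s];
      if (r_tot <= 0.0) break; // absorbing: nothing can happen any more
      t += R::exp_rand() / r_tot;
      if (t >= t_end) break;
      double u = R::unif_rand() * r_tot;
      if (u < r_deg) {
        --m;
      } else if (u < r_deg + r_prod) {
        if (prod_type[s] == 1) {          // single transcript, maybe escape
          ++m;
          s = prod_to[s];
        } else {                          // geometric burst, mean b
          m += (long)R::rgeom(1.0 / (1.0 + prod_b[s]));
        }
      } else {                            // promoter switch
        u -= r_deg + r_prod;
        for (int j = 0; j < S; ++j) {
          if (j == s) continue;
          u -= switch_rates(s, j);
          if (u < 0.0) { s = j; break; }
        }
      }
    }
    out[cell] = (int)m;
    if (cell % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
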