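#include <Rcpp.h>
using namespace Rcpp;

// Batch wMEC fitness for a GA population.
//
// entries: m x n over {0, 1, NA} (NA = site not covered by the read)
// weights: m x n phred weights, 0 where entries is NA
// pop:     P x m bit matrix; bit 0 -> part 1, bit 1 -> part 2
// weighted: use W for the majority vote (counts otherwise)
//
// For each individual: infer the two haplotypes by (weighted) column
// majority with ties (>=) resolving to allele 1, then count the entries
// disagreeing with their part's haplotype (the unweighted correction
// count is the fitness).
// [[Rcpp::export]]
IntegerVector wmec_fitness_batch(const IntegerMatrix& entries,
                                 const NumericMatrix& weights,
                                 const IntegerMatrix& pop,
                                 const bool weighted) {
  const int m = entries.nrow(), n = entries.ncol(), P = pop.nrow();
  if (pop.ncol() != m) stop("individual length must equal read count");
  IntegerVector fit(P);
  std::vector<double> acc(2 * n);   // n1 - n0 per (part, column)
  std::vector<signed char> hap(2 * n);
  for (int p = 0; p < P; ++p) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < m; ++i) {
        const int e = entries(i, j);
        if (e == NA_INTEGER) continue;
        const double w = weighted ? weights(i, j) : 1.0;
        const int part = pop(p, i);
        acc[part * n + j] += (e == 1) ? w : -w;
      }
    }
    for (int k = 0; k < 2 * n; ++k) hap[k] = (acc[k] >= 0.0) ? 1 : 0;
    int cost = 0;
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < m; ++i) {
        const int e = entries(i, j);
        if (e == NA_INTEGER) continue;
        if (e != hap[pop(p, i) * n + j]) ++cost;
      }
    }
    fit[p] = cost;
  }
  return fit;
}
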