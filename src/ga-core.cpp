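#include <Rcpp.h>
using namespace Rcpp;

// Uniform integer in {0, ..., n-1} from R's RNG (so runs are reproducible
// from set.seed and identical for any worker count).
static inline int r_int(const int n) {
  int v = (int)(unif_rand() * n);
  return (v >= n) ? n - 1 : v;
}

static int wmec_fitness_one(const IntegerMatrix& entries,
                            const NumericMatrix& weights,
                            const std::vector<int>& bits,
                            const bool weighted,
                            std::vector<double>& acc,
                            std::vector<signed char>& hap) {
  const int m = entries.nrow(), n = entries.ncol();
  std::fill(acc.begin(), acc.end(), 0.0);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < m; ++i) {
      const int e = entries(i, j);
      if (e == NA_INTEGER) continue;
      const double w = weighted ? weights(i, j) : 1.0;
      acc[bits[i] * n + j] += (e == 1) ? w : -w;
    }
  }
  for (int k = 0; k < 2 * n; ++k) hap[k] = (acc[k] >= 0.0) ? 1 : 0;
  int cost = 0;
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < m; ++i) {
      const int e = entries(i, j);
      if (e == NA_INTEGER) continue;
      if (e != hap[bits[i] * n + j]) ++cost;
    }
  }
  return cost;
}

// Generational GA with elitism on one wMEC sub-problem.  Mirrors the R
// operator definitions (tournament without replacement, single-point
// crossover, per-bit mutation, circular burst mutation while stalled);
// all randomness comes from R's RNG stream.
// [[Rcpp::export]]
List ga_core(const IntegerMatrix& entries, const NumericMatrix& weights,
             const int pop_size, const double c_r, const double m_r,
             const int kappa, const int max_iter, const int stall_limit,
             const int burst_stall, const bool weighted) {
  const int m = entries.nrow();
  RNGScope rngScope;

  std::vector<std::vector<int>> pop(pop_size, std::vector<int>(m));
  std::vector<std::vector<int>> off(pop_size, std::vector<int>(m));
  std::vector<int> fitness(pop_size);
  std::vector<double> acc(2 * entries.ncol());
  std::vector<signed char> hap(2 * entries.ncol());

  for (int p = 0; p < pop_size; ++p)
    for (int i = 0; i < m; ++i) pop[p][i] = (unif_rand() < 0.5) ? 1 : 0;
  for (int p = 0; p < pop_size; ++p)
    fitness[p] = wmec_fitness_one(entries, weights, pop[p], weighted,
                                  acc, hap);

  int best_p = (int)(std::min_element(fitness.begin(), fitness.end()) -
                     fitness.begin());
  std::vector<int> best_bits = pop[best_p];
  int best_fit = fitness[best_p];

  IntegerVector curve(max_iter);
  curve[0] = best_fit;
  int iter = 1, stall = 0;
  std::string reason = "max_iterations";

  std::vector<int> idx(pop_size), sel(pop_size);
  for (int i = 0; i < pop_size; ++i) idx[i] = i;

  while (true) {
    if (best_fit == 0) { reason = "zero_error"; break; }
    if (stall >= stall_limit) { reason = "stalled"; break; }
    if (iter >= max_iter) { reason = "max_iterations"; break; }

    // tournament selection: kappa distinct entrants, best wins,
    // ties to the first sampled (partial Fisher-Yates draw order)
    for (int s = 0; s < pop_size; ++s) {
      int win = -1, win_fit = 0;
      for (int t = 0; t < kappa; ++t) {
        const int r = t + r_int(pop_size - t);
        std::swap(idx[t], idx[r]);
        if (win < 0 || fitness[idx[t]] < win_fit) {
          win = idx[t];
          win_fit = fitness[idx[t]];
        }
      }
      sel[s] = win;
    }

    // single-point crossover on consecutive pairs
    for (int s = 0; s + 1 < pop_size; s += 2) {
      off[s] = pop[sel[s]];
      off[s + 1] = pop[sel[s + 1]];
      if (m >= 2 && unif_rand() < c_r) {
        const int cut = 1 + r_int(m - 1);   // tail starts at index cut
        for (int i = cut; i < m; ++i) std::swap(off[s][i], off[s + 1][i]);
      }
    }
    if (pop_size % 2 == 1) off[pop_size - 1] = pop[sel[pop_size - 1]];

    // classic per-bit mutation
    for (int p = 0; p < pop_size; ++p)
      for (int i = 0; i < m; ++i)
        if (unif_rand() < m_r) off[p][i] = 1 - off[p][i];

    // burst mutation over one circular run while stalled
    if (stall >= burst_stall)
      for (int p = 0; p < pop_size; ++p) {
        const int start = r_int(m);
        const int run_len = 1 + r_int(m);
        for (int t = 0; t < run_len; ++t)
          if (unif_rand() < m_r) {
            const int i = (start + t) % m;
            off[p][i] = 1 - off[p][i];
          }
      }

    off[0] = best_bits;                     // elitism
    std::swap(pop, off);
    for (int p = 0; p < pop_size; ++p)
      fitness[p] = wmec_fitness_one(entries, weights, pop[p], weighted,
                                    acc, hap);

    ++iter;
    best_p = (int)(std::min_element(fitness.begin(), fitness.end()) -
                   fitness.begin());
    if (fitness[best_p] < best_fit) {
      best_fit = fitness[best_p];
      best_bits = pop[best_p];
      stall = 0;
    } else {
      ++stall;
    }
    curve[iter - 1] = best_fit;
  }

  return List::create(
    _["best_bits"] = IntegerVector(best_bits.begin(), best_bits.end()),
    _["curve"] = curve[Range(0, iter - 1)],
    _["termination_reason"] = reason);
}

// Relabel-and-re-infer coordinate descent: alternately infer the
// haplotype pair from the bipartition by (weighted) column majority and
// move each read to its better-fitting part, until a fixed point (ties
// keep the current label).  Returns the refined bits and their wMEC cost.
// [[Rcpp::export]]
List relabel_refine(const IntegerMatrix& entries,
                    const NumericMatrix& weights,
                    const IntegerVector& bits0, const bool weighted,
                    const int max_iter = 20) {
  const int m = entries.nrow(), n = entries.ncol();
  std::vector<int> bits(bits0.begin(), bits0.end());
  std::vector<double> acc(2 * n);
  std::vector<signed char> hap(2 * n);
  for (int it = 0; it < max_iter; ++it) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < m; ++i) {
        const int e = entries(i, j);
        if (e == NA_INTEGER) continue;
        const double w = weighted ? weights(i, j) : 1.0;
        acc[bits[i] * n + j] += (e == 1) ? w : -w;
      }
    for (int k = 0; k < 2 * n; ++k) hap[k] = (acc[k] >= 0.0) ? 1 : 0;
    bool changed = false;
    for (int i = 0; i < m; ++i) {
      int c0 = 0, c1 = 0;
      for (int j = 0; j < n; ++j) {
        const int e = entries(i, j);
        if (e == NA_INTEGER) continue;
        if (e != hap[j]) ++c0;
        if (e != hap[n + j]) ++c1;
      }
      const int nb = (c0 < c1) ? 0 : ((c1 < c0) ? 1 : bits[i]);
      if (nb != bits[i]) { bits[i] = nb; changed = true; }
    }
    if (!changed) break;
  }
  int cost = 0;
  std::fill(acc.begin(), acc.end(), 0.0);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < m; ++i) {
      const int e = entries(i, j);
      if (e == NA_INTEGER) continue;
      const double w = weighted ? weights(i, j) : 1.0;
      acc[bits[i] * n + j] += (e == 1) ? w : -w;
    }
  for (int k = 0; k < 2 * n; ++k) hap[k] = (acc[k] >= 0.0) ? 1 : 0;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < m; ++i) {
      const int e = entries(i, j);
      if (e == NA_INTEGER) continue;
      if (e != hap[bits[i] * n + j]) ++cost;
    }
  return List::create(_["bits"] = IntegerVector(bits.begin(), bits.end()),
                      _["cost"] = cost);
}

// Cheap per-junction switch screen: with haplotypes fixed (inferred from
// bits) and per-read labels chosen optimally, the change in mismatch
// count if the phase were switched at junction j, accumulated for all
// junctions in one O(entries) pass per read via a difference array.
// Used to shortlist junctions for exact re-scoring.
// [[Rcpp::export]]
NumericVector switch_screen(const IntegerMatrix& entries,
                            const NumericMatrix& weights,
                            const IntegerVector& bits,
                            const bool weighted) {
  const int m = entries.nrow(), n = entries.ncol();
  std::vector<double> acc(2 * n, 0.0);
  std::vector<signed char> hap(2 * n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < m; ++i) {
      const int e = entries(i, j);
      if (e == NA_INTEGER) continue;
      const double w = weighted ? weights(i, j) : 1.0;
      acc[bits[i] * n + j] += (e == 1) ? w : -w;
    }
  for (int k = 0; k < 2 * n; ++k) hap[k] = (acc[k] >= 0.0) ? 1 : 0;

  std::vector<double> diff(n + 2, 0.0);     // difference array over j
  std::vector<int> jj; jj.reserve(n);
  std::vector<int> mm1; mm1.reserve(n);
  std::vector<int> mm2; mm2.reserve(n);
  for (int i = 0; i < m; ++i) {
    jj.clear(); mm1.clear(); mm2.clear();
    for (int j = 0; j < n; ++j) {
      const int e = entries(i, j);
      if (e == NA_INTEGER) continue;
      jj.push_back(j);
      mm1.push_back(e != hap[j]);
      mm2.push_back(e != hap[n + j]);
    }
    const int k = (int)jj.size();
    if (k < 2) continue;
    int tot1 = 0, tot2 = 0;
    for (int t = 0; t < k; ++t) { tot1 += mm1[t]; tot2 += mm2[t]; }
    const int cur = std::min(tot1, tot2);
    int p1 = 0, p2 = 0;
    for (int t = 0; t < k - 1; ++t) {
      p1 += mm1[t]; p2 += mm2[t];
      const int flip = std::min(p1 + (tot2 - p2), p2 + (tot1 - p1));
      const double c = flip - cur;
      // read spans junctions j in (jj[t], jj[t+1]] (1-based: +1 below)
      diff[jj[t] + 2] += c;
      diff[jj[t + 1] + 2] -= c;
    }
  }
  NumericVector out(n);                     // out[j-1] = delta at junction j
  out[0] = R_PosInf;                        // no junction before column 1
  double run = 0.0;
  for (int j = 2; j <= n; ++j) {
    run += diff[j];
    out[j - 1] = run;
  }
  return out;
}
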