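#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Element cost for degree-sequence alignment: max(x,y)/min(x,y) - 1.
// Degrees are >= 1, so the ratio is finite; the cost is 0 iff x == y.
static inline double ratio_cost(double x, double y) {
  return (x >= y) ? x / y - 1.0 : y / x - 1.0;
}

// Full dynamic-time-warping program (no window) over two ordered degree
// sequences. Steps allowed: (i-1,j), (i,j-1), (i-1,j-1).
// [[Rcpp::export(name = ".dtw_cost_cpp")]]
double dtw_cost_cpp(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("degree sequences must be non-empty");
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = R_PosInf;
    for (int j = 1; j <= m; ++j) {
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      cur[j] = ratio_cost(a[i - 1], b[j - 1]) + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Pairwise DTW costs between all pairs of per-node degree sequences at one
// layer. `seqs` holds one sorted degree sequence per node; nodes with an
// empty ring pass a zero-length vector and get NA against every partner.
// [[Rcpp::export(name = ".dtw_pair_matrix_cpp")]]
NumericMatrix dtw_pair_matrix_cpp(List seqs) {
  const int n = seqs.size();
  NumericMatrix out(n, n);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<NumericVector> sv(n);
  for (int i = 0; i < n; ++i) sv[i] = as<NumericVector>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    if (sv[i].size() == 0) continue;
    for (int j = i + 1; j < n; ++j) {
      if (sv[j].size() == 0) continue;
      double d = dtw_cost_cpp(sv[i], sv[j]);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Skip-Gram with negative sampling over a walk corpus.
//
// Classic word2vec-style trainer: linearly decaying learning rate, dynamic
// window shrinkage, unigram^{3/4} negative-sampling table. Single-threaded
// with a private 64-bit LCG so that a fixed seed reproduces the embedding
// bit-identically.
// ---------------------------------------------------------------------------

static inline uint64_t lcg_next(uint64_t& s) {
  s = s * 25214903917ULL + 11ULL;
  return s;
}

// [[Rcpp::export(name = ".sgns_train_cpp")]]
NumericMatrix sgns_train_cpp(List walks, int vocab, int dim, int window,
                             int epochs, int negative, double alpha0,
                             double min_alpha, NumericVector counts,
                             int seed) {
  if (vocab <= 0) stop("empty vocabulary");
  if (dim < 2) stop("embedding dimension must be >= 2");
  const int nwalks = walks.size();
  std::vector<std::vector<int>> corpus(nwalks);
  long long tokens_per_epoch = 0;
  for (int w = 0; w < nwalks; ++w) {
    IntegerVector iv = walks[w];
    corpus[w].assign(iv.begin(), iv.end());   // 0-based vocab indices
    tokens_per_epoch += iv.size();
  }
  if (tokens_per_epoch == 0) stop("empty walk corpus");

  // unigram^{0.75} table for negative sampling
  const int table_size = 100000;
  std::vector<int> table(table_size);
  {
    double total = 0.0;
    for (int v = 0; v < vocab; ++v) total += std::pow(counts[v], 0.75);
    int v = 0;
    double cum = std::pow(counts[0], 0.75) / total;
    for (int t = 0; t < table_size; ++t) {
      table[t] = v;
      if ((t + 1.0) / table_size > cum && v < vocab - 1) {
        ++v;
        cum += std::pow(counts[v], 0.75) / total;
      }
    }
  }

  uint64_t rng = (uint64_t)seed;
  std::vector<double> syn0((size_t)vocab * dim), syn1((size_t)vocab * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) {
    uint64_t r = lcg_next(rng);
    syn0[i] = (((r >> 16) & 0xFFFF) / 65536.0 - 0.5) / dim;
  }

  const long long total_tokens = tokens_per_epoch * (long long)epochs;
  long long processed = 0;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int w = 0; w < nwalks; ++w) {
      const std::vector<int>& walk = corpus[w];
      const int len = (int)walk.size();
      for (int pos = 0; pos < len; ++pos) {
        double alpha = alpha0 * (1.0 - (double)processed / (total_tokens + 1.0));
        if (alpha < min_alpha) alpha = min_alpha;
        ++processed;
        const int center = walk[pos];
        const int b = (int)(lcg_next(rng) % (uint64_t)window);
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          const int p2 = pos + off;
          if (p2 < 0 || p2 >= len) continue;
          const int context = walk[p2];
          double* v_in = &syn0[(size_t)center * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target; double label;
            if (neg == 0) {
              target = context; label = 1.0;
            } else {
              target = table[(size_t)((lcg_next(rng) >> 16) % table_size)];
              if (target == context) continue;
              label = 0.0;
            }
            double* v_out = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v_in[d] * v_out[d];
            const double pred = 1.0 / (1.0 + std::exp(-dot));
            const double g = (label - pred) * alpha;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v_out[d];
              v_out[d] += g * v_in[d];
            }
          }
          for (int d = 0; d < dim; ++d) v_in[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(vocab, dim);
  for (int v = 0; v < vocab; ++v)
    for (int d = 0; d < dim; ++d)
      out(v, d) = syn0[(size_t)v * dim + d];
  return out;
}
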