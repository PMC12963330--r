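// Node2Vec backend: second-order biased random walks over a CSR adjacency,
// and skip-gram with negative sampling (word2vec-style SGD) over the walk
// corpus. Single-threaded and fully determined by the integer seed.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline bool has_neighbor(const std::vector<int> &idx,
                                const std::vector<int> &ptr, int u, int v) {
  // neighbor lists are sorted; binary search for v in N(u)
  return std::binary_search(idx.begin() + ptr[u], idx.begin() + ptr[u + 1], v);
}

// adj_idx: 0-based concatenated sorted neighbor lists; adj_ptr: length n+1.
// Returns a list of 1-based integer walks, walks_per_node per start node,
// each of at most walk_length nodes (isolated nodes yield length-1 walks).
// [[Rcpp::export]]
List cpp_node2vec_walks(IntegerVector adj_idx, IntegerVector adj_ptr,
                        double p, double q, int walks_per_node,
                        int walk_length, int seed) {
  const int n = adj_ptr.size() - 1;
  std::vector<int> idx(adj_idx.begin(), adj_idx.end());
  std::vector<int> ptr(adj_ptr.begin(), adj_ptr.end());
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  List out(static_cast<R_xlen_t>(n) * walks_per_node);
  R_xlen_t w = 0;
  std::vector<double> weights;
  for (int rep = 0; rep < walks_per_node; ++rep) {
    for (int s = 0; s < n; ++s) {
      std::vector<int> walk;
      walk.reserve(walk_length);
      walk.push_back(s);
      int deg = ptr[s + 1] - ptr[s];
      if (deg > 0) {
        // first step: uniform neighbor
        int cur = idx[ptr[s] + static_cast<int>(unif(rng) * deg) % deg];
        walk.push_back(cur);
        int prev = s;
        while ((int)walk.size() < walk_length) {
          int d = ptr[cur + 1] - ptr[cur];
          if (d == 0) break;
          weights.assign(d, 0.0);
          double tot = 0.0;
          for (int k = 0; k < d; ++k) {
            int x = idx[ptr[cur] + k];
            double wk;
            if (x == prev) wk = 1.0 / p;
            else if (has_neighbor(idx, ptr, prev, x)) wk = 1.0;
            else wk = 1.0 / q;
            weights[k] = wk;
            tot += wk;
          }
          double r = unif(rng) * tot, acc = 0.0;
          int pick = d - 1;
          for (int k = 0; k < d; ++k) {
            acc += weights[k];
            if (r <= acc) { pick = k; break; }
          }
          int nxt = idx[ptr[cur] + pick];
          walk.push_back(nxt);
          prev = cur;
          cur = nxt;
        }
      }
      IntegerVector wv(walk.size());
      for (size_t k = 0; k < walk.size(); ++k) wv[k] = walk[k] + 1;
      out[w++] = wv;
    }
  }
  return out;
}

// Skip-gram with negative sampling over a list of 1-based integer walks.
// Returns the input-vector matrix (n_nodes x dim). Negative-sampling
// distribution is unigram^0.75 over corpus token counts; learning rate
// decays linearly from lr to lr/1e4.
// [[Rcpp::export]]
NumericMatrix cpp_sgns_train(List walks, int n_nodes, int dim, int window,
                             int negatives, int epochs, double lr, int seed) {
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // corpus token counts -> negative table
  std::vector<double> cnt(n_nodes, 0.0);
  R_xlen_t total_tokens = 0;
  for (R_xlen_t i = 0; i < walks.size(); ++i) {
    IntegerVector wv = walks[i];
    total_tokens += wv.size();
    for (int t : wv) cnt[t - 1] += 1.0;
  }
  const int TABLE = 1 << 20;
  std::vector<int> neg_table(TABLE);
  {
    double Z = 0.0;
    for (int i = 0; i < n_nodes; ++i) Z += std::pow(cnt[i], 0.75);
    if (Z <= 0.0) Z = 1.0;
    double cum = 0.0;
    int i = 0;
    double share = std::pow(cnt[0], 0.75) / Z;
    for (int t = 0; t < TABLE; ++t) {
      neg_table[t] = i;
      if ((double)(t + 1) / TABLE > cum + share && i < n_nodes - 1) {
        cum += share;
        ++i;
        share = std::pow(cnt[i], 0.75) / Z;
      }
    }
  }

  // init: syn0 ~ U(-0.5/dim, 0.5/dim), syn1 = 0 (word2vec convention)
  std::vector<double> syn0((size_t)n_nodes * dim), syn1((size_t)n_nodes * dim, 0.0);
  for (auto &v : syn0) v = (unif(rng) - 0.5) / dim;

  const double lr_min = lr * 1e-4;
  double processed = 0.0;
  const double total = (double)total_tokens * epochs;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (R_xlen_t i = 0; i < walks.size(); ++i) {
      IntegerVector wv = walks[i];
      const int L = wv.size();
      for (int pos = 0; pos < L; ++pos) {
        double alpha = lr * (1.0 - processed / total);
        if (alpha < lr_min) alpha = lr_min;
        processed += 1.0;
        const int center = wv[pos] - 1;
        double *v_c = &syn0[(size_t)center * dim];
        const int lo = std::max(0, pos - window);
        const int hi = std::min(L - 1, pos + window);
        for (int j = lo; j <= hi; ++j) {
          if (j == pos) continue;
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int m = 0; m <= negatives; ++m) {
            int target;
            double label;
            if (m == 0) { target = wv[j] - 1; label = 1.0; }
            else {
              target = neg_table[(int)(unif(rng) * TABLE) % TABLE];
              if (target == wv[j] - 1) continue;
              label = 0.0;
            }
            double *u_t = &syn1[(size_t)target * dim];
            double z = 0.0;
            for (int k = 0; k < dim; ++k) z += v_c[k] * u_t[k];
            double g = (label - 1.0 / (1.0 + std::exp(-z))) * alpha;
            for (int k = 0; k < dim; ++k) {
              grad[k] += g * u_t[k];
              u_t[k] += g * v_c[k];
            }
          }
          for (int k = 0; k < dim; ++k) v_c[k] += grad[k];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int k = 0; k < dim; ++k) out(i, k) = syn0[(size_t)i * dim + k];
  return out;
}
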