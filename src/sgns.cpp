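// Skip-gram with negative sampling over random-walk corpora.
// Single-threaded on purpose: with a fixed seed the trained matrix is
// bit-identical across runs, which the reproducibility contract requires.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>
#include <vector>

using namespace Rcpp;

static inline double sigmoid_clip(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// walks: list of integer vectors of 1-based node indices.
// Returns the input-embedding matrix, n_nodes x dim.
// [[Rcpp::export]]
arma::mat sgns_train_cpp(List walks, int n_nodes, int dim, int window,
                         int epochs, int negative, double alpha, int seed) {
  int n_walks = walks.size();
  std::vector<std::vector<int>> corpus(n_walks);
  std::vector<double> freq(n_nodes, 0.0);
  size_t total_pairs = 0;
  for (int wi = 0; wi < n_walks; ++wi) {
    IntegerVector w = walks[wi];
    corpus[wi].resize(w.size());
    int len = w.size();
    for (int i = 0; i < len; ++i) {
      int node = w[i] - 1;
      if (node < 0 || node >= n_nodes) stop("walk contains node index out of range");
      corpus[wi][i] = node;
      freq[node] += 1.0;
    }
    for (int i = 0; i < len; ++i) {
      int lo = std::max(0, i - window), hi = std::min(len - 1, i + window);
      total_pairs += (size_t)(hi - lo);   // contexts excluding the centre
    }
  }
  total_pairs *= (size_t)epochs;
  if (total_pairs == 0) stop("empty walk corpus");

  // unigram^0.75 negative-sampling distribution
  std::vector<double> wts(n_nodes);
  for (int i = 0; i < n_nodes; ++i) wts[i] = std::pow(freq[i], 0.75);
  std::discrete_distribution<int> neg_dist(wts.begin(), wts.end());
  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> U(-0.5, 0.5);

  arma::mat Win(n_nodes, dim), Wout(n_nodes, dim, arma::fill::zeros);
  for (int i = 0; i < n_nodes; ++i)
    for (int j = 0; j < dim; ++j) Win(i, j) = U(rng) / dim;

  const double min_alpha = alpha * 1e-4;
  size_t done = 0;
  std::vector<double> neu1e(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int wi = 0; wi < n_walks; ++wi) {
      const std::vector<int>& w = corpus[wi];
      int len = (int)w.size();
      for (int i = 0; i < len; ++i) {
        int centre = w[i];
        int lo = std::max(0, i - window), hi = std::min(len - 1, i + window);
        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          double lr = alpha * (1.0 - (double)done / (double)total_pairs);
          if (lr < min_alpha) lr = min_alpha;
          ++done;
          int ctx = w[j];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int target; double label;
            if (k == 0) { target = ctx; label = 1.0; }
            else {
              target = neg_dist(rng);
              if (target == ctx) continue;
              label = 0.0;
            }
            double f = arma::dot(Win.row(centre), Wout.row(target));
            double g = (label - sigmoid_clip(f)) * lr;
            for (int dd = 0; dd < dim; ++dd) {
              neu1e[dd] += g * Wout(target, dd);
              Wout(target, dd) += g * Win(centre, dd);
            }
          }
          for (int dd = 0; dd < dim; ++dd) Win(centre, dd) += neu1e[dd];
        }
      }
    }
  }
  return Win;
}
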