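#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Sparse per-modality feed-forward network.
//
// Topology: input i has 10 (fan_out) dedicated first-hidden-layer nodes;
// every first-layer node of block b feeds block b's single second-layer
// node; the B second-layer nodes feed one output node. All activations are
// logistic. The sparsity is encoded structurally: only existing edges are
// stored (w1, w2 indexed by first-layer node; w3 by block), so structurally
// absent connections cannot acquire weight during training.
//
// input_of  : for each first-layer node, 0-based column of X it reads.
// block_of  : for each first-layer node, 0-based block index.

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

struct Grads {
  std::vector<double> w1, b1, w2, b2, w3;
  double b3;
  Grads(int H1, int B)
      : w1(H1, 0.0), b1(H1, 0.0), w2(H1, 0.0), b2(B, 0.0), w3(B, 0.0),
        b3(0.0) {}
  void zero() {
    std::fill(w1.begin(), w1.end(), 0.0);
    std::fill(b1.begin(), b1.end(), 0.0);
    std::fill(w2.begin(), w2.end(), 0.0);
    std::fill(b2.begin(), b2.end(), 0.0);
    std::fill(w3.begin(), w3.end(), 0.0);
    b3 = 0.0;
  }
};

// forward pass for one sample; fills a1 (H1), a2 (B); returns a3
static double forward_one(const double *x, const int *input_of,
                          const int *block_of, int H1, int B,
                          const double *w1, const double *b1,
                          const double *w2, const double *b2,
                          const double *w3, double b3, double *a1,
                          double *z2buf, double *a2) {
  for (int b = 0; b < B; ++b) z2buf[b] = b2[b];
  for (int h = 0; h < H1; ++h) {
    double a = sigmoid(w1[h] * x[input_of[h]] + b1[h]);
    a1[h] = a;
    z2buf[block_of[h]] += w2[h] * a;
  }
  double z3 = b3;
  for (int b = 0; b < B; ++b) {
    a2[b] = sigmoid(z2buf[b]);
    z3 += w3[b] * a2[b];
  }
  return sigmoid(z3);
}

// accumulate gradients of mean binary cross-entropy for one sample with
// weight 1/m; also needs the activations from forward_one
static void backward_one(const double *x, double y, const int *input_of,
                         const int *block_of, int H1, int B,
                         const double *w2, const double *w3,
                         const double *a1, const double *a2, double a3,
                         double inv_m, Grads &g, double *d2buf) {
  double d3 = (a3 - y) * inv_m;  // dL/dz3 for BCE + sigmoid
  g.b3 += d3;
  for (int b = 0; b < B; ++b) {
    g.w3[b] += d3 * a2[b];
    d2buf[b] = d3 * w3[b] * a2[b] * (1.0 - a2[b]);
    g.b2[b] += d2buf[b];
  }
  for (int h = 0; h < H1; ++h) {
    double d2 = d2buf[block_of[h]];
    g.w2[h] += d2 * a1[h];
    double d1 = d2 * w2[h] * a1[h] * (1.0 - a1[h]);
    g.b1[h] += d1;
    g.w1[h] += d1 * x[input_of[h]];
  }
}

// [[Rcpp::export(name = ".nn_forward_cpp")]]
List nn_forward_cpp(NumericMatrix X, IntegerVector input_of,
                    IntegerVector block_of, int n_blocks, NumericVector w1,
                    NumericVector b1, NumericVector w2, NumericVector b2,
                    NumericVector w3, double b3) {
  int n = X.nrow(), N = X.ncol(), H1 = input_of.size(), B = n_blocks;
  NumericMatrix A1(n, H1), A2(n, B);
  NumericVector A3(n);
  std::vector<double> x(N), a1(H1), z2(B), a2(B);
  for (int s = 0; s < n; ++s) {
    for (int j = 0; j < N; ++j) x[j] = X(s, j);
    double a3 = forward_one(x.data(), input_of.begin(), block_of.begin(), H1,
                            B, w1.begin(), b1.begin(), w2.begin(), b2.begin(),
                            w3.begin(), b3, a1.data(), z2.data(), a2.data());
    for (int h = 0; h < H1; ++h) A1(s, h) = a1[h];
    for (int b = 0; b < B; ++b) A2(s, b) = a2[b];
    A3[s] = a3;
  }
  return List::create(_["a1"] = A1, _["a2"] = A2, _["a3"] = A3);
}

// [[Rcpp::export(name = ".nn_loss_cpp")]]
double nn_loss_cpp(NumericMatrix X, NumericVector y, IntegerVector input_of,
                   IntegerVector block_of, int n_blocks, NumericVector w1,
                   NumericVector b1, NumericVector w2, NumericVector b2,
                   NumericVector w3, double b3) {
  int n = X.nrow(), N = X.ncol(), H1 = input_of.size(), B = n_blocks;
  std::vector<double> x(N), a1(H1), z2(B), a2(B);
  double loss = 0.0;
  for (int s = 0; s < n; ++s) {
    for (int j = 0; j < N; ++j) x[j] = X(s, j);
    double a3 = forward_one(x.data(), input_of.begin(), block_of.begin(), H1,
                            B, w1.begin(), b1.begin(), w2.begin(), b2.begin(),
                            w3.begin(), b3, a1.data(), z2.data(), a2.data());
    double p = std::min(std::max(a3, 1e-12), 1.0 - 1e-12);
    loss += -(y[s] * std::log(p) + (1.0 - y[s]) * std::log(1.0 - p));
  }
  return loss / n;
}

// [[Rcpp::export(name = ".nn_grad_cpp")]]
List nn_grad_cpp(NumericMatrix X, NumericVector y, IntegerVector input_of,
                 IntegerVector block_of, int n_blocks, NumericVector w1,
                 NumericVector b1, NumericVector w2, NumericVector b2,
                 NumericVector w3, double b3) {
  int n = X.nrow(), N = X.ncol(), H1 = input_of.size(), B = n_blocks;
  std::vector<double> x(N), a1(H1), z2(B), a2(B), d2(B);
  Grads g(H1, B);
  double inv_m = 1.0 / n;
  for (int s = 0; s < n; ++s) {
    for (int j = 0; j < N; ++j) x[j] = X(s, j);
    double a3 = forward_one(x.data(), input_of.begin(), block_of.begin(), H1,
                            B, w1.begin(), b1.begin(), w2.begin(), b2.begin(),
                            w3.begin(), b3, a1.data(), z2.data(), a2.data());
    backward_one(x.data(), y[s], input_of.begin(), block_of.begin(), H1, B,
                 w2.begin(), w3.begin(), a1.data(), a2.data(), a3, inv_m, g,
                 d2.data());
  }
  return List::create(
      _["w1"] = NumericVector(g.w1.begin(), g.w1.end()),
      _["b1"] = NumericVector(g.b1.begin(), g.b1.end()),
      _["w2"] = NumericVector(g.w2.begin(), g.w2.end()),
      _["b2"] = NumericVector(g.b2.begin(), g.b2.end()),
      _["w3"] = NumericVector(g.w3.begin(), g.w3.end()), _["b3"] = g.b3);
}

struct Adam {
  std::vector<double> m, v;
  Adam(int k) : m(k, 0.0), v(k, 0.0) {}
  void step(double *w, const double *g, int k, double lr, double b1d,
            double b2d, double eps, double bc1, double bc2) {
    for (int i = 0; i < k; ++i) {
      m[i] = b1d * m[i] + (1.0 - b1d) * g[i];
      v[i] = b2d * v[i] + (1.0 - b2d) * g[i] * g[i];
      double mhat = m[i] / bc1, vhat = v[i] / bc2;
      w[i] -= lr * mhat / (std::sqrt(vhat) + eps);
    }
  }
};

// Mini-batch ADAM on binary cross-entropy. Batches are drawn uniformly
// without replacement at every step via a partial Fisher-Yates shuffle
// using R's RNG (so results are reproducible under set.seed()).
// [[Rcpp::export(name = ".nn_train_cpp")]]
List nn_train_cpp(NumericMatrix X, NumericVector y, IntegerVector input_of,
                  IntegerVector block_of, int n_blocks, NumericVector w1_,
                  NumericVector b1_, NumericVector w2_, NumericVector b2_,
                  NumericVector w3_, double b3_, int iterations,
                  int batch_size, double lr, double beta1, double beta2,
                  double adam_eps) {
  int n = X.nrow(), N = X.ncol(), H1 = input_of.size(), B = n_blocks;
  if (batch_size > n) stop("batch size exceeds training-set size");

  std::vector<double> w1(w1_.begin(), w1_.end()), b1(b1_.begin(), b1_.end());
  std::vector<double> w2(w2_.begin(), w2_.end()), b2(b2_.begin(), b2_.end());
  std::vector<double> w3(w3_.begin(), w3_.end());
  double b3 = b3_;

  Adam aw1(H1), ab1(H1), aw2(H1), ab2(B), aw3(B), ab3(1);
  Grads g(H1, B);
  std::vector<double> x(N), a1(H1), z2(B), a2(B), d2(B);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  RNGScope rng;
  double inv_m = 1.0 / batch_size;
  for (int t = 1; t <= iterations; ++t) {
    // partial Fisher-Yates: first batch_size entries of idx are the batch
    for (int i = 0; i < batch_size; ++i) {
      int j = i + (int)(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(idx[i], idx[j]);
    }
    g.zero();
    for (int bi = 0; bi < batch_size; ++bi) {
      int s = idx[bi];
      for (int j = 0; j < N; ++j) x[j] = X(s, j);
      double a3 = forward_one(x.data(), input_of.begin(), block_of.begin(),
                              H1, B, w1.data(), b1.data(), w2.data(),
                              b2.data(), w3.data(), b3, a1.data(), z2.data(),
                              a2.data());
      backward_one(x.data(), y[s], input_of.begin(), block_of.begin(), H1, B,
                   w2.data(), w3.data(), a1.data(), a2.data(), a3, inv_m, g,
                   d2.data());
    }
    double bc1 = 1.0 - std::pow(beta1, t), bc2 = 1.0 - std::pow(beta2, t);
    aw1.step(w1.data(), g.w1.data(), H1, lr, beta1, beta2, adam_eps, bc1, bc2);
    ab1.step(b1.data(), g.b1.data(), H1, lr, beta1, beta2, adam_eps, bc1, bc2);
    aw2.step(w2.data(), g.w2.data(), H1, lr, beta1, beta2, adam_eps, bc1, bc2);
    ab2.step(b2.data(), g.b2.data(), B, lr, beta1, beta2, adam_eps, bc1, bc2);
    aw3.step(w3.data(), g.w3.data(), B, lr, beta1, beta2, adam_eps, bc1, bc2);
    ab3.step(&b3, &g.b3, 1, lr, beta1, beta2, adam_eps, bc1, bc2);
  }

  return List::create(_["w1"] = NumericVector(w1.begin(), w1.end()),
                      _["b1"] = NumericVector(b1.begin(), b1.end()),
                      _["w2"] = NumericVector(w2.begin(), w2.end()),
                      _["b2"] = NumericVector(b2.begin(), b2.end()),
                      _["w3"] = NumericVector(w3.begin(), w3.end()),
                      _["b3"] = b3);
}
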