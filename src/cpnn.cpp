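#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Online counter-propagation training: a Kohonen codebook layer plus a
// supervised output layer updated with the same neighborhood factors.
// Sequential per-example updates; all randomness (the per-epoch visit
// order) is drawn from R's RNG so set.seed() gives bit-identical runs.
//
// Examples and codebook vectors are held in contiguous row-per-item
// buffers so the inner distance/update loops stream through memory.

static int find_winner_buf(const std::vector<double> &cb,
                           const double *xi, int n_neurons, int p) {
  int best = 0;
  double best_d = R_PosInf;
  for (int j = 0; j < n_neurons; ++j) {
    const double *wj = &cb[(size_t)j * p];
    double d = 0.0;
    for (int k = 0; k < p; ++k) {
      double diff = xi[k] - wj[k];
      d += diff * diff;
    }
    if (d < best_d) {  // strict: ties keep the lowest flat index
      best_d = d;
      best = j;
    }
  }
  return best;
}

// [[Rcpp::export]]
IntegerVector cpnn_winner_cpp(NumericMatrix codebook, NumericMatrix x) {
  int n = x.nrow(), p = x.ncol(), n_neurons = codebook.nrow();
  std::vector<double> cb((size_t)n_neurons * p), xi(p);
  for (int j = 0; j < n_neurons; ++j)
    for (int k = 0; k < p; ++k) cb[(size_t)j * p + k] = codebook(j, k);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < p; ++k) xi[k] = x(i, k);
    out[i] = find_winner_buf(cb, xi.data(), n_neurons, p) + 1;
  }
  return out;
}

// [[Rcpp::export]]
List cpnn_train_cpp(NumericMatrix x, IntegerVector cls, int n_classes,
                    int rows, int cols, int epochs,
                    double eta0, double eta1, double r0, double r1,
                    NumericMatrix codebook, NumericMatrix outw) {
  int n = x.nrow(), p = x.ncol();
  int n_neurons = rows * cols;
  NumericVector qe(epochs);
  std::vector<int> order(n);

  std::vector<double> xs((size_t)n * p);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < p; ++k) xs[(size_t)i * p + k] = x(i, k);
  std::vector<double> cb((size_t)n_neurons * p);
  for (int j = 0; j < n_neurons; ++j)
    for (int k = 0; k < p; ++k) cb[(size_t)j * p + k] = codebook(j, k);
  std::vector<double> ow((size_t)n_neurons * n_classes);
  for (int j = 0; j < n_neurons; ++j)
    for (int c = 0; c < n_classes; ++c)
      ow[(size_t)j * n_classes + c] = outw(j, c);

  RNGScope scope;

  for (int e = 0; e < epochs; ++e) {
    double frac = (epochs == 1) ? 0.0 : (double)e / (double)(epochs - 1);
    double eta = eta0 + (eta1 - eta0) * frac;
    double radius = r0 + (r1 - r0) * frac;
    double two_sigma2 = 2.0 * radius * radius;
    // beyond this squared grid distance the update factor is < 1e-12
    double d2_cut = two_sigma2 * 27.6;  // 27.6 ~ -log(1e-12)

    for (int i = 0; i < n; ++i) order[i] = i;
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }

    double err = 0.0;
    for (int t = 0; t < n; ++t) {
      int i = order[t];
      const double *xi = &xs[(size_t)i * p];
      int w = find_winner_buf(cb, xi, n_neurons, p);
      const double *ww = &cb[(size_t)w * p];
      double dwin = 0.0;
      for (int k = 0; k < p; ++k) {
        double diff = xi[k] - ww[k];
        dwin += diff * diff;
      }
      err += std::sqrt(dwin);

      int wr = w / cols, wc = w % cols;
      for (int j = 0; j < n_neurons; ++j) {
        int jr = j / cols, jc = j % cols;
        double d2 = (double)((jr - wr) * (jr - wr) + (jc - wc) * (jc - wc));
        if (d2 > d2_cut) continue;
        double a = eta * std::exp(-d2 / two_sigma2);
        double *wj = &cb[(size_t)j * p];
        for (int k = 0; k < p; ++k) wj[k] += a * (xi[k] - wj[k]);
        double *oj = &ow[(size_t)j * n_classes];
        for (int c = 0; c < n_classes; ++c) {
          double target = (cls[i] == c + 1) ? 1.0 : 0.0;
          oj[c] += a * (target - oj[c]);
        }
      }
    }
    qe[e] = err / n;
  }

  for (int j = 0; j < n_neurons; ++j)
    for (int k = 0; k < p; ++k) codebook(j, k) = cb[(size_t)j * p + k];
  for (int j = 0; j < n_neurons; ++j)
    for (int c = 0; c < n_classes; ++c)
      outw(j, c) = ow[(size_t)j * n_classes + c];

  return List::create(_["codebook"] = codebook, _["output"] = outw,
                      _["quantization_error"] = qe);
}
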