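// Numerical core: valid-mode cross-correlation of one-hot sequences with
// convolutional kernels, global max pooling, masked dense head, and the
// Adam/backprop training loop with best-epoch early stopping.
//
// Conventions shared with the R layer:
//   X       : cube (4, L, n)      one-hot sequences, row order A,C,G,T
//   kernels : cube (4, Lf, d)     one 4 x Lf matrix per kernel
//   mask    : vec length d, entries 0/1; masked kernels receive no gradient
//             and their parameters are never touched by the optimizer.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG_EPS = 1e-12;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static inline double bce_one(double p, double y) {
  double pc = std::min(std::max(p, LOG_EPS), 1.0 - LOG_EPS);
  return -(y * std::log(pc) + (1.0 - y) * std::log(1.0 - pc));
}

// Flatten kernels cube into (4*Lf) x d matrix; each slice is column-major
// contiguous so vectorise(slice) stacks positions in order.
static arma::mat kernel_matrix(const arma::cube& kernels) {
  const arma::uword m = kernels.n_rows * kernels.n_cols;
  arma::mat K(m, kernels.n_slices);
  for (arma::uword k = 0; k < kernels.n_slices; ++k)
    K.col(k) = arma::vectorise(kernels.slice(k));
  return K;
}

// im2col: windows of one sequence as a (4*Lf) x P matrix, P = L - Lf + 1.
static arma::mat im2col_seq(const arma::mat& S, arma::uword Lf) {
  const arma::uword P = S.n_cols - Lf + 1;
  arma::mat W(4 * Lf, P);
  for (arma::uword p = 0; p < P; ++p)
    W.col(p) = arma::vectorise(S.cols(p, p + Lf - 1));
  return W;
}

// [[Rcpp::export]]
arma::vec cpp_conv_scan(const arma::mat& S, const arma::mat& K) {
  if (S.n_rows != 4 || K.n_rows != 4)
    stop("sequence and kernel matrices must have 4 rows");
  if (S.n_cols < K.n_cols)
    stop("sequence length %d is shorter than kernel length %d",
         (int)S.n_cols, (int)K.n_cols);
  arma::mat W = im2col_seq(S, K.n_cols);
  return W.t() * arma::vectorise(K);
}

// Pre-activation score matrix h for one kernel over many sequences: n x P.
// [[Rcpp::export]]
arma::mat cpp_activation_matrix(const arma::cube& X, const arma::mat& K) {
  const arma::uword n = X.n_slices, Lf = K.n_cols;
  if (X.n_cols < Lf) stop("sequences shorter than kernel");
  const arma::uword P = X.n_cols - Lf + 1;
  arma::vec kv = arma::vectorise(K);
  arma::mat H(n, P);
  for (arma::uword i = 0; i < n; ++i)
    H.row(i) = (im2col_seq(X.slice(i), Lf).t() * kv).t();
  return H;
}

// Pooled post-ReLU scores z (n x d) and 1-based argmax positions of h.
// [[Rcpp::export]]
List cpp_pool_batch(const arma::cube& X, const arma::cube& kernels) {
  const arma::uword n = X.n_slices, d = kernels.n_slices,
                    Lf = kernels.n_cols;
  if (X.n_cols < Lf) stop("sequences shorter than kernel");
  arma::mat K = kernel_matrix(kernels);
  arma::mat Z(n, d);
  arma::umat A(n, d);
  for (arma::uword i = 0; i < n; ++i) {
    arma::mat H = K.t() * im2col_seq(X.slice(i), Lf); // d x P
    for (arma::uword k = 0; k < d; ++k) {
      arma::uword am = H.row(k).index_max();
      A(i, k) = am + 1;
      double h = H(k, am);
      Z(i, k) = h > 0.0 ? h : 0.0;
    }
  }
  return List::create(_["z"] = Z, _["argmax"] = A);
}

// [[Rcpp::export]]
arma::vec cpp_forward_batch(const arma::cube& X, const arma::cube& kernels,
                            const arma::vec& mask, const arma::vec& w,
                            double b) {
  List pooled = cpp_pool_batch(X, kernels);
  arma::mat Z = pooled["z"];
  arma::vec s = b + Z * (mask % w);
  arma::vec p(s.n_elem);
  for (arma::uword i = 0; i < s.n_elem; ++i) p(i) = sigmoid(s(i));
  return p;
}

// [[Rcpp::export]]
double cpp_mean_bce(const arma::vec& p, const arma::vec& y) {
  double acc = 0.0;
  for (arma::uword i = 0; i < p.n_elem; ++i) acc += bce_one(p(i), y(i));
  return acc / p.n_elem;
}

struct AdamState {
  arma::cube mK, vK;
  arma::vec mw, vw;
  double mb = 0.0, vb = 0.0;
  long t = 0;
};

// Full training loop. Precomputes im2col once; returns the parameters of
// the best validation epoch together with the loss trace.
// [[Rcpp::export]]
List cpp_train(const arma::cube& X, const arma::vec& y,
               const arma::cube& Xval, const arma::vec& yval,
               const arma::cube& kernels0, const arma::vec& mask,
               const arma::vec& w0, double b,
               double lr, int batch_size, int patience, int max_epochs,
               int shuffle_seed,
               double beta1 = 0.9, double beta2 = 0.999, double eps = 1e-8) {
  // deep copies: the SEXP-backed arma objects may alias R memory, and the
  // caller's parameters (and any R-level aliases such as the init
  // snapshot) must never be mutated in place
  arma::cube kernels(kernels0.memptr(), kernels0.n_rows, kernels0.n_cols,
                     kernels0.n_slices);
  arma::vec w(w0.memptr(), w0.n_elem);
  const arma::uword n = X.n_slices, d = kernels.n_slices,
                    Lf = kernels.n_cols;
  if (X.n_cols < Lf) stop("sequences shorter than kernel");
  const arma::uword P = X.n_cols - Lf + 1;
  const arma::uword M = 4 * Lf;

  // im2col cache for the training set (M x P x n)
  arma::cube W(M, P, n);
  for (arma::uword i = 0; i < n; ++i)
    W.slice(i) = im2col_seq(X.slice(i), Lf);

  AdamState adam;
  adam.mK.zeros(4, Lf, d);
  adam.vK.zeros(4, Lf, d);
  adam.mw.zeros(d);
  adam.vw.zeros(d);

  std::mt19937 rng(static_cast<unsigned int>(shuffle_seed));
  std::vector<arma::uword> idx(n);
  for (arma::uword i = 0; i < n; ++i) idx[i] = i;

  arma::cube best_kernels = kernels;
  arma::vec best_w = w;
  double best_b = b;
  double best_vloss = std::numeric_limits<double>::infinity();
  int best_epoch = 0, stale = 0, stopped_epoch = 0;
  std::vector<double> train_trace, val_trace;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double epoch_loss = 0.0;

    for (arma::uword start = 0; start < n;
         start += static_cast<arma::uword>(batch_size)) {
      arma::uword stop_i = std::min(n, start + batch_size);
      arma::uword B = stop_i - start;
      arma::mat K = kernel_matrix(kernels); // M x d

      arma::cube gK(4, Lf, d, arma::fill::zeros);
      arma::vec gw(d, arma::fill::zeros);
      double gb = 0.0;

      for (arma::uword ii = start; ii < stop_i; ++ii) {
        arma::uword i = idx[ii];
        arma::mat H = K.t() * W.slice(i); // d x P
        double s = b;
        arma::vec u(d, arma::fill::zeros);
        arma::uvec am(d);
        for (arma::uword k = 0; k < d; ++k) {
          arma::uword a = H.row(k).index_max();
          am(k) = a;
          double h = H(k, a);
          double z = h > 0.0 ? h : 0.0;
          u(k) = z * mask(k);
          s += w(k) * u(k);
        }
        double p = sigmoid(s);
        epoch_loss += bce_one(p, y(i));
        double ds = (p - y(i)) / static_cast<double>(B);
        gb += ds;
        for (arma::uword k = 0; k < d; ++k) {
          if (mask(k) == 0.0) continue;
          gw(k) += ds * u(k);
          if (u(k) > 0.0) {
            double du = ds * w(k); // mask is 1 here
            arma::vec win = W.slice(i).col(am(k));
            gK.slice(k) += du * arma::reshape(win, 4, Lf);
          }
        }
      }

      // Adam update; masked kernels are skipped entirely (params and
      // moments stay bit-identical).
      adam.t += 1;
      double bc1 = 1.0 - std::pow(beta1, (double)adam.t);
      double bc2 = 1.0 - std::pow(beta2, (double)adam.t);
      for (arma::uword k = 0; k < d; ++k) {
        if (mask(k) == 0.0) continue;
        adam.mK.slice(k) = beta1 * adam.mK.slice(k) +
                           (1.0 - beta1) * gK.slice(k);
        adam.vK.slice(k) = beta2 * adam.vK.slice(k) +
                           (1.0 - beta2) * arma::square(gK.slice(k));
        kernels.slice(k) -= lr * (adam.mK.slice(k) / bc1) /
                            (arma::sqrt(adam.vK.slice(k) / bc2) + eps);
        adam.mw(k) = beta1 * adam.mw(k) + (1.0 - beta1) * gw(k);
        adam.vw(k) = beta2 * adam.vw(k) + (1.0 - beta2) * gw(k) * gw(k);
        w(k) -= lr * (adam.mw(k) / bc1) /
                (std::sqrt(adam.vw(k) / bc2) + eps);
      }
      adam.mb = beta1 * adam.mb + (1.0 - beta1) * gb;
      adam.vb = beta2 * adam.vb + (1.0 - beta2) * gb * gb;
      b -= lr * (adam.mb / bc1) / (std::sqrt(adam.vb / bc2) + eps);
    }

    train_trace.push_back(epoch_loss / n);
    arma::vec pv = cpp_forward_batch(Xval, kernels, mask, w, b);
    double vloss = cpp_mean_bce(pv, yval);
    val_trace.push_back(vloss);
    stopped_epoch = epoch;

    if (vloss < best_vloss) {
      best_vloss = vloss;
      best_kernels = kernels;
      best_w = w;
      best_b = b;
      best_epoch = epoch;
      stale = 0;
    } else {
      stale += 1;
      if (stale >= patience) break;
    }
  }

  return List::create(
      _["kernels"] = best_kernels, _["w"] = best_w, _["b"] = best_b,
      _["train_loss"] = train_trace, _["val_loss"] = val_trace,
      _["best_epoch"] = best_epoch, _["stopped_epoch"] = stopped_epoch,
      _["best_val_loss"] = best_vloss);
}
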