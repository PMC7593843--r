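// Full-batch / mini-batch Adam training of a deep sparse autoencoder.
// The network is a plain feed-forward stack; the sparsity penalty is the
// batch-mean L1 norm of the innermost (code) layer activations. All
// randomness (mini-batch shuffling) comes from R's RNG so runs are
// reproducible under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

// activation codes: 0 = linear, 1 = tanh, 2 = sigmoid
mat activate(const mat& z, int code) {
  switch (code) {
    case 1: return tanh(z);
    case 2: return 1.0 / (1.0 + exp(-z));
    default: return z;
  }
}

// derivative expressed through the activation value a
mat activate_deriv(const mat& a, int code) {
  switch (code) {
    case 1: return 1.0 - square(a);
    case 2: return a % (1.0 - a);
    default: return ones<mat>(a.n_rows, a.n_cols);
  }
}

// Fisher-Yates shuffle driven by R's RNG (deterministic under set.seed)
uvec r_shuffle(unsigned int n) {
  uvec idx = regspace<uvec>(0, n - 1);
  for (unsigned int i = n - 1; i > 0; --i) {
    unsigned int j = (unsigned int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
  return idx;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_train_dsae(const arma::mat& X, Rcpp::List weights,
                          Rcpp::List biases, const arma::ivec& act,
                          double lambda, int code_layer, int epochs,
                          double lr, int batch_size) {
  const int L = weights.size();
  const unsigned int n = X.n_rows;
  std::vector<mat> W(L);
  std::vector<rowvec> b(L);
  for (int l = 0; l < L; ++l) {
    W[l] = Rcpp::as<mat>(weights[l]);
    b[l] = Rcpp::as<rowvec>(biases[l]);
  }

  // Adam state (default moment decay rates, epsilon 1e-8)
  const double beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8;
  std::vector<mat> mW(L), vW(L);
  std::vector<rowvec> mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    mW[l] = zeros<mat>(W[l].n_rows, W[l].n_cols);
    vW[l] = zeros<mat>(W[l].n_rows, W[l].n_cols);
    mb[l] = zeros<rowvec>(b[l].n_elem);
    vb[l] = zeros<rowvec>(b[l].n_elem);
  }
  long step = 0;

  const unsigned int bs = batch_size >= (int)n ? n : (unsigned int)batch_size;
  vec loss_trace(epochs, fill::zeros);
  std::vector<mat> A(L + 1);
  std::vector<mat> D(L);
  Rcpp::RNGScope rng_scope;

  for (int epoch = 0; epoch < epochs; ++epoch) {
    uvec order = bs < n ? r_shuffle(n) : regspace<uvec>(0, n - 1);
    double epoch_loss = 0.0;
    for (unsigned int start = 0; start < n; start += bs) {
      unsigned int stop = std::min(start + bs - 1, n - 1);
      mat Xb;
      if (bs < n) Xb = X.rows(order.subvec(start, stop)); else Xb = X;
      const double m = (double)Xb.n_rows;

      // forward
      A[0] = Xb;
      for (int l = 0; l < L; ++l) {
        A[l + 1] = activate(A[l] * W[l] + repmat(b[l], Xb.n_rows, 1), act[l]);
      }
      const mat resid = A[L] - Xb;
      const mat& code = A[code_layer];
      double loss = accu(square(resid)) / m +
                    lambda * accu(abs(code)) / m;
      epoch_loss += loss * m;

      // backward: D[l] = dLoss/dZ_l
      D[L - 1] = (2.0 / m) * resid % activate_deriv(A[L], act[L - 1]);
      for (int l = L - 2; l >= 0; --l) {
        mat dA = D[l + 1] * W[l + 1].t();
        if (l + 1 == code_layer) {
          dA += (lambda / m) * sign(A[code_layer]);
        }
        D[l] = dA % activate_deriv(A[l + 1], act[l]);
      }

      // Adam update
      ++step;
      const double c1 = 1.0 - std::pow(beta1, (double)step);
      const double c2 = 1.0 - std::pow(beta2, (double)step);
      for (int l = 0; l < L; ++l) {
        mat gW = A[l].t() * D[l];
        rowvec gb = sum(D[l], 0);
        mW[l] = beta1 * mW[l] + (1.0 - beta1) * gW;
        vW[l] = beta2 * vW[l] + (1.0 - beta2) * square(gW);
        mb[l] = beta1 * mb[l] + (1.0 - beta1) * gb;
        vb[l] = beta2 * vb[l] + (1.0 - beta2) * square(gb);
        W[l] -= lr * (mW[l] / c1) / (sqrt(vW[l] / c2) + adam_eps);
        b[l] -= lr * (mb[l] / c1) / (sqrt(vb[l] / c2) + adam_eps);
      }
    }
    epoch_loss /= (double)n;
    if (!std::isfinite(epoch_loss)) {
      Rcpp::stop("training diverged: non-finite loss at epoch %d", epoch + 1);
    }
    loss_trace[epoch] = epoch_loss;
  }

  Rcpp::List outW(L), outb(L);
  for (int l = 0; l < L; ++l) {
    outW[l] = W[l];
    outb[l] = b[l];
  }
  return Rcpp::List::create(Rcpp::Named("weights") = outW,
                            Rcpp::Named("biases") = outb,
                            Rcpp::Named("loss_trace") = loss_trace);
}

// [[Rcpp::export]]
arma::mat cpp_forward(const arma::mat& X, Rcpp::List weights,
                      Rcpp::List biases, const arma::ivec& act,
                      int upto) {
  mat A = X;
  for (int l = 0; l < upto; ++l) {
    A = activate(A * Rcpp::as<mat>(weights[l]) +
                 repmat(Rcpp::as<rowvec>(biases[l]), A.n_rows, 1), act[l]);
  }
  return A;
}
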