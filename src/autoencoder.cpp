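// Symmetric feed-forward autoencoder trained with Adam on minibatch MSE.
// All randomness (weight init, minibatch shuffling) is drawn from R's RNG
// stream so set.seed() makes training fully reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat glorot_init(int fan_in, int fan_out) {
  double lim = std::sqrt(6.0 / (fan_in + fan_out));
  mat W(fan_in, fan_out);
  for (uword i = 0; i < W.n_elem; ++i) W(i) = R::runif(-lim, lim);
  return W;
}

// Fisher-Yates permutation of 0..n-1 using R's RNG
static uvec r_permutation(int n) {
  uvec p = regspace<uvec>(0, n - 1);
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(R::unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(p[i], p[j]);
  }
  return p;
}

static inline mat activate(const mat& Z, int act) {
  if (act == 0) return clamp(Z, 0.0, datum::inf);     // ReLU
  return 1.0 / (1.0 + exp(-Z));                        // sigmoid
}

// [[Rcpp::export]]
Rcpp::List ae_train_cpp(const arma::mat& X,
                        const Rcpp::IntegerVector& widths,
                        const Rcpp::IntegerVector& acts,
                        const Rcpp::IntegerVector& train_rows,
                        int epochs, int batch_size, double lr) {
  const int L = acts.size();              // number of weight layers
  if (widths.size() != L + 1)
    Rcpp::stop("widths must have one more entry than acts");

  std::vector<mat> W(L), mW(L), vW(L);
  std::vector<rowvec> b(L), mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    W[l] = glorot_init(widths[l], widths[l + 1]);
    b[l] = rowvec(widths[l + 1], fill::zeros);
    mW[l] = mat(widths[l], widths[l + 1], fill::zeros);
    vW[l] = mat(widths[l], widths[l + 1], fill::zeros);
    mb[l] = rowvec(widths[l + 1], fill::zeros);
    vb[l] = rowvec(widths[l + 1], fill::zeros);
  }

  uvec tr(train_rows.size());
  for (int i = 0; i < train_rows.size(); ++i) tr[i] = train_rows[i];
  const mat Xtr = X.rows(tr);
  const int ntr = Xtr.n_rows;
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long t = 0;
  double last_loss = NA_REAL;

  std::vector<mat> A(L + 1), Z(L);
  for (int epoch = 0; epoch < epochs; ++epoch) {
    uvec perm = r_permutation(ntr);
    double epoch_sse = 0.0;
    long epoch_elems = 0;
    for (int start = 0; start < ntr; start += batch_size) {
      int stop = std::min(start + batch_size, ntr) - 1;
      mat Xb = Xtr.rows(perm.subvec(start, stop));
      // forward
      A[0] = Xb;
      for (int l = 0; l < L; ++l) {
        Z[l] = A[l] * W[l];
        Z[l].each_row() += b[l];
        A[l + 1] = activate(Z[l], acts[l]);
      }
      const double nb = Xb.n_rows, p = Xb.n_cols;
      mat diff = A[L] - Xb;
      epoch_sse += accu(square(diff));
      epoch_elems += (long)(nb * p);
      // backward: loss = mean over all elements of squared diff
      mat dA = (2.0 / (nb * p)) * diff;
      ++t;
      double corr1 = 1.0 - std::pow(beta1, (double)t);
      double corr2 = 1.0 - std::pow(beta2, (double)t);
      for (int l = L - 1; l >= 0; --l) {
        mat dZ;
        if (acts[l] == 0) dZ = dA % conv_to<mat>::from(Z[l] > 0);
        else              dZ = dA % (A[l + 1] % (1.0 - A[l + 1]));
        mat gW = A[l].t() * dZ;
        rowvec gb = sum(dZ, 0);
        if (l > 0) dA = dZ * W[l].t();
        mW[l] = beta1 * mW[l] + (1 - beta1) * gW;
        vW[l] = beta2 * vW[l] + (1 - beta2) * square(gW);
        mb[l] = beta1 * mb[l] + (1 - beta1) * gb;
        vb[l] = beta2 * vb[l] + (1 - beta2) * square(gb);
        W[l] -= lr * (mW[l] / corr1) / (sqrt(vW[l] / corr2) + eps);
        b[l] -= lr * (mb[l] / corr1) / (sqrt(vb[l] / corr2) + eps);
      }
    }
    last_loss = epoch_sse / (double)epoch_elems;
    if (!std::isfinite(last_loss))
      Rcpp::stop("non-finite training loss at epoch %d", epoch + 1);
  }

  Rcpp::List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) {
    Wout[l] = W[l];
    bout[l] = rowvec(b[l]);
  }
  return Rcpp::List::create(Rcpp::Named("weights") = Wout,
                            Rcpp::Named("biases") = bout,
                            Rcpp::Named("final_train_loss") = last_loss);
}

// Forward pass through the first n_layers weight layers (all if
// n_layers < 0).  acts as in ae_train_cpp.
// [[Rcpp::export]]
arma::mat ae_forward_cpp(const arma::mat& X, const Rcpp::List& weights,
                         const Rcpp::List& biases,
                         const Rcpp::IntegerVector& acts, int n_layers) {
  int L = acts.size();
  if (n_layers >= 0 && n_layers < L) L = n_layers;
  mat A = X;
  for (int l = 0; l < L; ++l) {
    mat W = weights[l];
    rowvec b = biases[l];
    mat Z = A * W;
    Z.each_row() += b;
    A = activate(Z, acts[l]);
  }
  return A;
}
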