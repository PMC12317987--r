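// Incremental (per-sample) error back-propagation for a one-hidden-layer
// perceptron, with momentum, an adaptive learning rate and early stopping
// on a validation split. This is the hot loop behind fit_ncreann(); all
// randomness (initial weights, sample order) is decided in R and passed in,
// so training is fully deterministic given its arguments.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat act_fun(const mat& a, int activation) {
  return activation == 0 ? tanh(a) : a;
}

static double mse_of(const mat& X, const mat& Y, const mat& W1,
                     const vec& b1, const mat& W2, const vec& b2,
                     int activation) {
  // X: N x D (rows = samples), Y: N x M
  mat H = X * W1.t();
  H.each_row() += b1.t();
  H = act_fun(H, activation);
  mat P = H * W2.t();
  P.each_row() += b2.t();
  return accu(square(P - Y)) / double(Y.n_elem);
}

// [[Rcpp::export]]
Rcpp::List train_mlp_cpp(const arma::mat& X, const arma::mat& Y,
                         const arma::uvec& train_idx,
                         const arma::uvec& val_idx,
                         arma::mat W1, arma::vec b1,
                         arma::mat W2, arma::vec b2,
                         int activation,       // 0 = tanh, 1 = identity
                         double eta, double momentum,
                         double lr_up, double lr_down, double max_inc,
                         int max_epochs, int patience) {
  const mat Xtr = X.rows(train_idx);
  const mat Ytr = Y.rows(train_idx);
  const mat Xval = X.rows(val_idx);
  const mat Yval = Y.rows(val_idx);
  const uword N = Xtr.n_rows;

  mat vW1(size(W1), fill::zeros), vW2(size(W2), fill::zeros);
  vec vb1(size(b1), fill::zeros), vb2(size(b2), fill::zeros);

  mat bW1 = W1, bW2 = W2;       // best-validation weights (restored at end)
  vec bb1 = b1, bb2 = b2;
  double best_val = datum::inf;
  int wait = 0, epochs_run = 0;
  bool diverged = false;

  double prev_mse = mse_of(Xtr, Ytr, W1, b1, W2, b2, activation);
  std::vector<double> tr_hist, val_hist, lr_hist;
  std::vector<int> accepted_hist;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    // snapshot for possible epoch rejection
    mat sW1 = W1, sW2 = W2;
    vec sb1 = b1, sb2 = b2;
    mat svW1 = vW1, svW2 = vW2;
    vec svb1 = vb1, svb2 = vb2;

    for (uword n = 0; n < N; ++n) {
      vec x = Xtr.row(n).t();
      vec y = Ytr.row(n).t();
      vec a = W1 * x + b1;
      vec h = (activation == 0) ? vec(tanh(a)) : a;
      vec yhat = W2 * h + b2;
      vec e = yhat - y;                       // dE/dyhat for E = 0.5*sum(e^2)
      vec dh = W2.t() * e;
      vec da = (activation == 0) ? vec(dh % (1.0 - square(h))) : dh;

      vW2 = momentum * vW2 - eta * (e * h.t());
      vb2 = momentum * vb2 - eta * e;
      vW1 = momentum * vW1 - eta * (da * x.t());
      vb1 = momentum * vb1 - eta * da;
      W2 += vW2; b2 += vb2;
      W1 += vW1; b1 += vb1;
    }

    if (!W1.is_finite() || !W2.is_finite() || !b1.is_finite() || !b2.is_finite()) {
      diverged = true;
      break;
    }

    double tr_mse = mse_of(Xtr, Ytr, W1, b1, W2, b2, activation);
    bool accept = std::isfinite(tr_mse) && tr_mse <= prev_mse * max_inc;
    if (!accept) {
      // reject the whole epoch: restore weights, damp the step
      W1 = sW1; W2 = sW2; b1 = sb1; b2 = sb2;
      vW1.zeros(); vW2.zeros(); vb1.zeros(); vb2.zeros();
      eta *= lr_down;
      tr_mse = prev_mse;
      if (eta < 1e-12) { diverged = false; epochs_run = epoch + 1; break; }
    } else {
      if (tr_mse < prev_mse) eta *= lr_up;
      prev_mse = tr_mse;
    }

    double val_mse = val_idx.n_elem > 0
      ? mse_of(Xval, Yval, W1, b1, W2, b2, activation) : tr_mse;
    tr_hist.push_back(tr_mse);
    val_hist.push_back(val_mse);
    lr_hist.push_back(eta);
    accepted_hist.push_back(accept ? 1 : 0);
    epochs_run = epoch + 1;

    if (accept && val_mse < best_val - 1e-12) {
      best_val = val_mse;
      bW1 = W1; bW2 = W2; bb1 = b1; bb2 = b2;
      wait = 0;
    } else {
      if (++wait >= patience) break;
    }
  }

  if (!std::isfinite(best_val)) { bW1 = W1; bW2 = W2; bb1 = b1; bb2 = b2; }

  return Rcpp::List::create(
    Rcpp::Named("W1") = bW1, Rcpp::Named("b1") = bb1,
    Rcpp::Named("W2") = bW2, Rcpp::Named("b2") = bb2,
    Rcpp::Named("train_mse") = tr_hist,
    Rcpp::Named("val_mse") = val_hist,
    Rcpp::Named("lr") = lr_hist,
    Rcpp::Named("accepted") = accepted_hist,
    Rcpp::Named("epochs") = epochs_run,
    Rcpp::Named("best_val_mse") = best_val,
    Rcpp::Named("diverged") = diverged);
}
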