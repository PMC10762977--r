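// Fully-connected autoencoder over genomic bins.
//
// The sample unit is a bin: its feature vector is the cross-cell LRC column
// (length N). Encoder N -> 256 -> 128 -> 64 -> d, decoder mirrored. Leaky
// ReLU after hidden layers, linear latent code and reconstruction. Loss per
// sample is (1/2N)*||y - yhat||^2, averaged over the batch; weights are
// updated with Adam. All randomness (init, per-epoch shuffles) is drawn from
// R's RNG so set.seed() makes training reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LEAKY_SLOPE = 0.01;

static mat leaky(const mat& x) {
  return arma::max(x, LEAKY_SLOPE * x);
}

static mat leaky_grad(const mat& pre) {
  mat g(pre.n_rows, pre.n_cols);
  g.fill(LEAKY_SLOPE);
  g.elem(find(pre > 0)).fill(1.0);
  return g;
}

// fan-in uniform init, driven by R's RNG
static mat init_weight(unsigned int nin, unsigned int nout) {
  double lim = std::sqrt(1.0 / (double)nin);
  mat w(nin, nout);
  for (uword j = 0; j < w.n_cols; ++j)
    for (uword i = 0; i < w.n_rows; ++i)
      w(i, j) = R::runif(-lim, lim);
  return w;
}

struct AdamState {
  std::vector<mat> mW, vW;
  std::vector<rowvec> mb, vb;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
};

// Forward through all layers; activations[l] is the output of layer l
// (activations[0] = input batch, rows = samples).
static void forward(const mat& batch, const std::vector<mat>& W,
                    const std::vector<rowvec>& b, int latent_layer,
                    std::vector<mat>& pre, std::vector<mat>& act) {
  int L = (int)W.size();
  act[0] = batch;
  for (int l = 0; l < L; ++l) {
    pre[l] = act[l] * W[l];
    pre[l].each_row() += b[l];
    bool linear = (l == latent_layer) || (l == L - 1);
    act[l + 1] = linear ? pre[l] : leaky(pre[l]);
  }
}

// [[Rcpp::export(name = ".ae_train_cpp")]]
Rcpp::List ae_train_cpp(const arma::mat& X, int latent_dim,
                        Rcpp::IntegerVector hidden, int epochs, double lr,
                        int batch_size, double plateau_tol, int plateau_window,
                        int min_epochs) {
  // X: N cells x M bins; samples are columns of X
  const int N = (int)X.n_rows, M = (int)X.n_cols;
  mat S = X.t();  // M samples x N features

  std::vector<int> widths;
  widths.push_back(N);
  for (int i = 0; i < hidden.size(); ++i) widths.push_back(hidden[i]);
  widths.push_back(latent_dim);
  for (int i = hidden.size() - 1; i >= 0; --i) widths.push_back(hidden[i]);
  widths.push_back(N);
  const int L = (int)widths.size() - 1;            // number of weight layers
  const int latent_layer = hidden.size();          // index of layer whose output is z

  std::vector<mat> W(L);
  std::vector<rowvec> b(L);
  for (int l = 0; l < L; ++l) {
    W[l] = init_weight(widths[l], widths[l + 1]);
    b[l] = rowvec(widths[l + 1], fill::zeros);
  }
  AdamState ad;
  ad.mW.resize(L); ad.vW.resize(L); ad.mb.resize(L); ad.vb.resize(L);
  for (int l = 0; l < L; ++l) {
    ad.mW[l] = mat(size(W[l]), fill::zeros);
    ad.vW[l] = mat(size(W[l]), fill::zeros);
    ad.mb[l] = rowvec(widths[l + 1], fill::zeros);
    ad.vb[l] = rowvec(widths[l + 1], fill::zeros);
  }

  std::vector<mat> pre(L), act(L + 1);
  std::vector<double> trace;
  trace.reserve(epochs);

  uvec order = regspace<uvec>(0, M - 1);
  int n_done = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle with R's RNG
    for (int i = M - 1; i > 0; --i) {
      int j = (int)std::floor(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double ep_loss = 0.0;
    int n_batches = 0;
    for (int off = 0; off < M; off += batch_size) {
      int bsz = std::min(batch_size, M - off);
      uvec idx = order.subvec(off, off + bsz - 1);
      mat batch = S.rows(idx);
      forward(batch, W, b, latent_layer, pre, act);
      mat diff = act[L] - batch;
      double loss = accu(square(diff)) / (2.0 * N * bsz);
      if (!std::isfinite(loss))
        Rcpp::stop("non-finite reconstruction loss at epoch %d; "
                   "check that the input is normalized LRC", ep + 1);
      ep_loss += loss;
      ++n_batches;

      // backprop: dL/dyhat = diff / (N * bsz)
      mat delta = diff / ((double)N * bsz);
      ad.t += 1;
      double c1 = 1.0 - std::pow(ad.b1, (double)ad.t);
      double c2 = 1.0 - std::pow(ad.b2, (double)ad.t);
      for (int l = L - 1; l >= 0; --l) {
        mat gW = act[l].t() * delta;
        rowvec gb = sum(delta, 0);
        if (l > 0) {
          delta = delta * W[l].t();
          bool prev_linear = ((l - 1) == latent_layer);
          if (!prev_linear) delta %= leaky_grad(pre[l - 1]);
        }
        ad.mW[l] = ad.b1 * ad.mW[l] + (1 - ad.b1) * gW;
        ad.vW[l] = ad.b2 * ad.vW[l] + (1 - ad.b2) * square(gW);
        ad.mb[l] = ad.b1 * ad.mb[l] + (1 - ad.b1) * gb;
        ad.vb[l] = ad.b2 * ad.vb[l] + (1 - ad.b2) * square(gb);
        W[l] -= lr * (ad.mW[l] / c1) / (sqrt(ad.vW[l] / c2) + ad.eps);
        b[l] -= lr * (ad.mb[l] / c1) / (sqrt(ad.vb[l] / c2) + ad.eps);
      }
    }
    trace.push_back(ep_loss / n_batches);
    n_done = ep + 1;
    // loss-plateau early stop on the epoch-mean loss
    if (plateau_window > 0 && n_done >= min_epochs &&
        n_done > plateau_window) {
      double prev = trace[n_done - 1 - plateau_window];
      double now = trace[n_done - 1];
      if (prev - now < plateau_tol * std::max(std::abs(prev), 1e-12)) break;
    }
  }

  Rcpp::List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) {
    Wout[l] = W[l];
    bout[l] = b[l];
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = Wout, Rcpp::Named("biases") = bout,
      Rcpp::Named("loss_trace") = trace,
      Rcpp::Named("epochs_run") = n_done,
      Rcpp::Named("latent_layer") = latent_layer + 1);
}

// [[Rcpp::export(name = ".ae_forward_cpp")]]
Rcpp::List ae_forward_cpp(const arma::mat& X, Rcpp::List weights,
                          Rcpp::List biases, int latent_layer) {
  // Returns the latent codes (d x M) and reconstructions (N x M).
  const int L = weights.size();
  mat S = X.t();
  std::vector<mat> pre(L), act(L + 1);
  std::vector<mat> W(L);
  std::vector<rowvec> b(L);
  for (int l = 0; l < L; ++l) {
    W[l] = Rcpp::as<mat>(weights[l]);
    b[l] = Rcpp::as<rowvec>(biases[l]);
  }
  forward(S, W, b, latent_layer - 1, pre, act);
  mat Z = act[latent_layer].t();      // d x M
  mat Yhat = act[L].t();              // N x M
  return Rcpp::List::create(Rcpp::Named("z") = Z,
                            Rcpp::Named("reconstruction") = Yhat);
}
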