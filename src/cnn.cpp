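// Small 1-D convolutional regressor trained by Adam.
//
// Architecture (fixed topology, sizes taken from the weight list):
//   input (length L, 1 channel)
//   -> conv(kernel k, C1 channels, same padding) + ReLU
//   -> conv(kernel k, C2 channels, same padding) + ReLU
//   -> flatten -> dense(F1) + ReLU -> dense(F2) + ReLU -> dense(F3) + ReLU
//   -> linear output (scalar)
//
// Feature maps are stored as (L*B) x C matrices (row = position within a
// sample block, column = channel) so convolutions become im2col gathers
// followed by BLAS matrix products.  L2 regularization is added to weight
// gradients (not biases).  All randomness (minibatch order) comes from a
// std::mt19937 seeded from R, so training is reproducible.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Zero-padded im2col: H is (L*B) x C, output (L*B) x (C*k) with column
// c*k + j holding channel c shifted by offset j - pad.
arma::mat im2col(const arma::mat& H, int L, int B, int k, int pad) {
  int C = H.n_cols;
  arma::mat out(H.n_rows, C * k, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* src = H.colptr(c);
    for (int j = 0; j < k; ++j) {
      double* dst = out.colptr(c * k + j);
      int o = j - pad;
      for (int b = 0; b < B; ++b) {
        int base = b * L;
        if (o >= 0)
          std::copy(src + base + o, src + base + L, dst + base);
        else
          std::copy(src + base, src + base + L + o, dst + base - o);
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add columns back onto channels.
arma::mat col2im(const arma::mat& G, int L, int B, int k, int pad, int C) {
  arma::mat out(G.n_rows, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* dst = out.colptr(c);
    for (int j = 0; j < k; ++j) {
      const double* src = G.colptr(c * k + j);
      int o = j - pad;
      for (int b = 0; b < B; ++b) {
        int base = b * L;
        if (o >= 0) {
          for (int l = 0; l + o < L; ++l) dst[base + l + o] += src[base + l];
        } else {
          for (int l = -o; l < L; ++l) dst[base + l + o] += src[base + l];
        }
      }
    }
  }
  return out;
}

struct Net {
  arma::mat W1, W2, Wf1, Wf2, Wf3, Wo;        // weights
  arma::rowvec b1, b2, bf1, bf2, bf3;
  double bo;
  int k, C1, C2, pad;

  static Net from_list(const List& w) {
    Net n;
    n.W1 = as<arma::mat>(w["W1"]);   n.b1 = as<arma::rowvec>(w["b1"]);
    n.W2 = as<arma::mat>(w["W2"]);   n.b2 = as<arma::rowvec>(w["b2"]);
    n.Wf1 = as<arma::mat>(w["Wf1"]); n.bf1 = as<arma::rowvec>(w["bf1"]);
    n.Wf2 = as<arma::mat>(w["Wf2"]); n.bf2 = as<arma::rowvec>(w["bf2"]);
    n.Wf3 = as<arma::mat>(w["Wf3"]); n.bf3 = as<arma::rowvec>(w["bf3"]);
    n.Wo = as<arma::mat>(w["Wo"]);   n.bo = as<double>(w["bo"]);
    n.k = n.W1.n_rows;
    n.C1 = n.W1.n_cols;
    n.C2 = n.W2.n_cols;
    n.pad = (n.k - 1) / 2;  // even kernels pad one less on the left
    return n;
  }

  List to_list() const {
    return List::create(
        Named("W1") = W1, Named("b1") = b1, Named("W2") = W2, Named("b2") = b2,
        Named("Wf1") = Wf1, Named("bf1") = bf1, Named("Wf2") = Wf2,
        Named("bf2") = bf2, Named("Wf3") = Wf3, Named("bf3") = bf3,
        Named("Wo") = Wo, Named("bo") = bo);
  }
};

struct Cache {
  arma::mat Xc1, H1, Xc2, H2, F, A1, A2, A3;
  arma::vec out;
  int L, B;
};

// Xb: (L*B) x 1 stacked input samples.
void forward(const Net& n, const arma::mat& Xb, int L, int B, Cache& c) {
  c.L = L; c.B = B;
  c.Xc1 = im2col(Xb, L, B, n.k, n.pad);
  c.H1 = c.Xc1 * n.W1;
  c.H1.each_row() += n.b1;
  c.H1.transform([](double v) { return v > 0.0 ? v : 0.0; });
  c.Xc2 = im2col(c.H1, L, B, n.k, n.pad);
  c.H2 = c.Xc2 * n.W2;
  c.H2.each_row() += n.b2;
  c.H2.transform([](double v) { return v > 0.0 ? v : 0.0; });
  // flatten: F(b, c*L + l) = H2(b*L + l, c)
  c.F.set_size(B, L * n.C2);
  for (int ch = 0; ch < n.C2; ++ch)
    for (int l = 0; l < L; ++l) {
      const double* src = c.H2.colptr(ch) + l;
      double* dst = c.F.colptr(ch * L + l);
      for (int b = 0; b < B; ++b) dst[b] = src[(size_t)b * L];
    }
  c.A1 = c.F * n.Wf1;  c.A1.each_row() += n.bf1;
  c.A1.transform([](double v) { return v > 0.0 ? v : 0.0; });
  c.A2 = c.A1 * n.Wf2; c.A2.each_row() += n.bf2;
  c.A2.transform([](double v) { return v > 0.0 ? v : 0.0; });
  c.A3 = c.A2 * n.Wf3; c.A3.each_row() += n.bf3;
  c.A3.transform([](double v) { return v > 0.0 ? v : 0.0; });
  c.out = c.A3 * n.Wo + n.bo;
}

struct Grads {
  arma::mat W1, W2, Wf1, Wf2, Wf3, Wo;
  arma::rowvec b1, b2, bf1, bf2, bf3;
  double bo;
};

// dOut: B-vector of d(loss)/d(output).  If want_dx, also returns the
// gradient with respect to the stacked input.
arma::mat backward(const Net& n, const Cache& c, const arma::vec& dOut,
                   Grads& g, bool want_dx) {
  int L = c.L, B = c.B;
  g.Wo = c.A3.t() * dOut;
  g.bo = arma::accu(dOut);
  arma::mat dA3 = dOut * n.Wo.t();
  dA3 %= arma::conv_to<arma::mat>::from(c.A3 > 0.0);
  g.Wf3 = c.A2.t() * dA3;  g.bf3 = arma::sum(dA3, 0);
  arma::mat dA2 = dA3 * n.Wf3.t();
  dA2 %= arma::conv_to<arma::mat>::from(c.A2 > 0.0);
  g.Wf2 = c.A1.t() * dA2;  g.bf2 = arma::sum(dA2, 0);
  arma::mat dA1 = dA2 * n.Wf2.t();
  dA1 %= arma::conv_to<arma::mat>::from(c.A1 > 0.0);
  g.Wf1 = c.F.t() * dA1;   g.bf1 = arma::sum(dA1, 0);
  arma::mat dF = dA1 * n.Wf1.t();

  // unflatten
  arma::mat dH2(c.H2.n_rows, c.H2.n_cols);
  for (int ch = 0; ch < n.C2; ++ch)
    for (int l = 0; l < L; ++l) {
      const double* src = dF.colptr(ch * L + l);
      double* dst = dH2.colptr(ch) + l;
      for (int b = 0; b < B; ++b) dst[(size_t)b * L] = src[b];
    }
  dH2 %= arma::conv_to<arma::mat>::from(c.H2 > 0.0);
  g.W2 = c.Xc2.t() * dH2;  g.b2 = arma::sum(dH2, 0);
  arma::mat dXc2 = dH2 * n.W2.t();
  arma::mat dH1 = col2im(dXc2, L, B, n.k, n.pad, n.C1);
  dH1 %= arma::conv_to<arma::mat>::from(c.H1 > 0.0);
  g.W1 = c.Xc1.t() * dH1;  g.b1 = arma::sum(dH1, 0);
  if (!want_dx) return arma::mat();
  arma::mat dXc1 = dH1 * n.W1.t();
  return col2im(dXc1, L, B, n.k, n.pad, 1);
}

// stack a set of columns of X (L x N) into an (L*B) x 1 matrix
arma::mat stack_cols(const arma::mat& X, const arma::uvec& idx) {
  int L = X.n_rows, B = idx.n_elem;
  arma::mat out(L * B, 1);
  for (int b = 0; b < B; ++b)
    std::copy(X.colptr(idx(b)), X.colptr(idx(b)) + L, out.colptr(0) + b * L);
  return out;
}

struct Adam {
  arma::mat m, v;
  Adam(int r, int c) : m(r, c, arma::fill::zeros), v(r, c, arma::fill::zeros) {}
  void step(arma::mat& w, const arma::mat& g, double lr, double t) {
    m = 0.9 * m + 0.1 * g;
    v = 0.999 * v + 0.001 * (g % g);
    arma::mat mh = m / (1.0 - std::pow(0.9, t));
    arma::mat vh = v / (1.0 - std::pow(0.999, t));
    w -= lr * mh / (arma::sqrt(vh) + 1e-8);
  }
};

double mse_on(const Net& n, const arma::mat& X, const arma::vec& y, int chunk) {
  int L = X.n_rows, N = X.n_cols;
  double sse = 0.0;
  Cache c;
  for (int s = 0; s < N; s += chunk) {
    int e = std::min(N, s + chunk);
    arma::uvec idx = arma::regspace<arma::uvec>(s, e - 1);
    forward(n, stack_cols(X, idx), L, e - s, c);
    sse += arma::accu(arma::square(c.out - y.subvec(s, e - 1)));
  }
  return sse / N;
}

}  // namespace

// [[Rcpp::export]]
List cnn_train_cpp(const arma::mat& X, const arma::vec& y, List w0, int epochs,
                   double lr, double l2, int batch, int seed,
                   const arma::mat& Xval, const arma::vec& yval) {
  Net n = Net::from_list(w0);
  int L = X.n_rows, N = X.n_cols;
  std::mt19937 rng(seed);

  Adam aW1(n.W1.n_rows, n.W1.n_cols), aW2(n.W2.n_rows, n.W2.n_cols),
      aWf1(n.Wf1.n_rows, n.Wf1.n_cols), aWf2(n.Wf2.n_rows, n.Wf2.n_cols),
      aWf3(n.Wf3.n_rows, n.Wf3.n_cols), aWo(n.Wo.n_rows, n.Wo.n_cols),
      ab1(1, n.b1.n_elem), ab2(1, n.b2.n_elem), abf1(1, n.bf1.n_elem),
      abf2(1, n.bf2.n_elem), abf3(1, n.bf3.n_elem), abo(1, 1);

  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  arma::vec train_loss(epochs), val_loss(epochs, arma::fill::value(NA_REAL));
  Cache c;
  Grads g;
  double t_adam = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double sse = 0.0;
    for (int s = 0; s < N; s += batch) {
      int e = std::min(N, s + batch);
      int B = e - s;
      arma::uvec idx(B);
      arma::vec yb(B);
      for (int b = 0; b < B; ++b) {
        idx(b) = order[s + b];
        yb(b) = y(order[s + b]);
      }
      forward(n, stack_cols(X, idx), L, B, c);
      arma::vec resid = c.out - yb;
      sse += arma::accu(arma::square(resid));
      arma::vec dOut = 2.0 * resid / B;
      backward(n, c, dOut, g, false);
      t_adam += 1.0;
      arma::mat bo_g(1, 1); bo_g(0, 0) = g.bo;
      arma::mat bo_w(1, 1); bo_w(0, 0) = n.bo;
      aW1.step(n.W1, g.W1 + l2 * n.W1, lr, t_adam);
      aW2.step(n.W2, g.W2 + l2 * n.W2, lr, t_adam);
      aWf1.step(n.Wf1, g.Wf1 + l2 * n.Wf1, lr, t_adam);
      aWf2.step(n.Wf2, g.Wf2 + l2 * n.Wf2, lr, t_adam);
      aWf3.step(n.Wf3, g.Wf3 + l2 * n.Wf3, lr, t_adam);
      aWo.step(n.Wo, g.Wo + l2 * n.Wo, lr, t_adam);
      arma::mat tmp;
      tmp = n.b1;  ab1.step(tmp, arma::mat(g.b1), lr, t_adam);  n.b1 = tmp;
      tmp = n.b2;  ab2.step(tmp, arma::mat(g.b2), lr, t_adam);  n.b2 = tmp;
      tmp = n.bf1; abf1.step(tmp, arma::mat(g.bf1), lr, t_adam); n.bf1 = tmp;
      tmp = n.bf2; abf2.step(tmp, arma::mat(g.bf2), lr, t_adam); n.bf2 = tmp;
      tmp = n.bf3; abf3.step(tmp, arma::mat(g.bf3), lr, t_adam); n.bf3 = tmp;
      abo.step(bo_w, bo_g, lr, t_adam);
      n.bo = bo_w(0, 0);
    }
    train_loss(ep) = sse / N;
    if (Xval.n_cols > 0) val_loss(ep) = mse_on(n, Xval, yval, 256);
    Rcpp::checkUserInterrupt();
  }

  return List::create(Named("weights") = n.to_list(),
                      Named("train_loss") = train_loss,
                      Named("val_loss") = val_loss);
}

// [[Rcpp::export]]
arma::vec cnn_predict_cpp(List w, const arma::mat& X, int chunk) {
  Net n = Net::from_list(w);
  int L = X.n_rows, N = X.n_cols;
  arma::vec out(N);
  Cache c;
  for (int s = 0; s < N; s += chunk) {
    int e = std::min(N, s + chunk);
    arma::uvec idx = arma::regspace<arma::uvec>(s, e - 1);
    forward(n, stack_cols(X, idx), L, e - s, c);
    out.subvec(s, e - 1) = c.out;
  }
  return out;
}

// Gradient of the scalar output with respect to each input value.
// [[Rcpp::export]]
arma::mat cnn_input_grad_cpp(List w, const arma::mat& X, int chunk) {
  Net n = Net::from_list(w);
  int L = X.n_rows, N = X.n_cols;
  arma::mat out(L, N);
  Cache c;
  Grads g;
  for (int s = 0; s < N; s += chunk) {
    int e = std::min(N, s + chunk);
    int B = e - s;
    arma::uvec idx = arma::regspace<arma::uvec>(s, e - 1);
    forward(n, stack_cols(X, idx), L, B, c);
    arma::mat dX = backward(n, c, arma::vec(B, arma::fill::ones), g, true);
    for (int b = 0; b < B; ++b)
      out.col(s + b) = dX.submat(b * L, 0, (b + 1) * L - 1, 0);
  }
  return out;
}
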