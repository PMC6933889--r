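// Core network: 1-D convolution (same padding, stride 1) over a one-hot
// L x 4 sequence, ReLU, flatten, dense(H) + ReLU, dropout, dense(C) + softmax.
// Trained with minibatch Adam on the cross-entropy loss. Everything is kept
// in one translation unit so the whole training loop runs without crossing
// the R/C++ boundary per batch.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;
using arma::uword;

namespace {

struct Net {
  mat Wc;  // (k*4) x K
  vec bc;  // K
  mat W1;  // (L*K) x H
  vec b1;  // H
  mat W2;  // H x C
  vec b2;  // C
  int L, k, K, H, C, pad_l;
  bool conv_relu;
};

Net unpack(const List& params, int L, bool conv_relu) {
  Net n;
  n.Wc = as<mat>(params["Wc"]);
  n.bc = as<vec>(params["bc"]);
  n.W1 = as<mat>(params["W1"]);
  n.b1 = as<vec>(params["b1"]);
  n.W2 = as<mat>(params["W2"]);
  n.b2 = as<vec>(params["b2"]);
  n.k = n.Wc.n_rows / 4;
  n.K = n.Wc.n_cols;
  n.H = n.W1.n_cols;
  n.C = n.W2.n_cols;
  n.L = L;
  // left pad for length-preserving ("same") convolution; right pad implicit
  n.pad_l = (n.k - 1) / 2;
  n.conv_relu = conv_relu;
  if ((uword)(n.L * n.K) != n.W1.n_rows)
    stop("weight shapes inconsistent with input length L");
  return n;
}

List pack(const Net& n) {
  return List::create(_["Wc"] = n.Wc, _["bc"] = n.bc, _["W1"] = n.W1,
                      _["b1"] = n.b1, _["W2"] = n.W2, _["b2"] = n.b2);
}

// Zero-padded patch matrix: M(p, o*4 + c) = X(p - pad_l + o, c).
void im2col(const mat& X, int k, int pad_l, mat& M) {
  const int L = X.n_rows;
  M.zeros(L, k * 4);
  for (int o = 0; o < k; ++o) {
    const int p_lo = std::max(0, pad_l - o);
    const int p_hi = std::min(L, L + pad_l - o);  // exclusive
    if (p_hi <= p_lo) continue;
    const int r_lo = p_lo - pad_l + o;
    const int nrow = p_hi - p_lo;
    for (int c = 0; c < 4; ++c)
      M.submat(p_lo, o * 4 + c, p_hi - 1, o * 4 + c) =
          X.submat(r_lo, c, r_lo + nrow - 1, c);
  }
}

// Adjoint of im2col: scatter dM back onto the input grid.
void col2im(const mat& dM, int k, int pad_l, mat& dX) {
  const int L = dM.n_rows;
  dX.zeros(L, 4);
  for (int o = 0; o < k; ++o) {
    const int p_lo = std::max(0, pad_l - o);
    const int p_hi = std::min(L, L + pad_l - o);
    if (p_hi <= p_lo) continue;
    const int r_lo = p_lo - pad_l + o;
    const int nrow = p_hi - p_lo;
    for (int c = 0; c < 4; ++c)
      dX.submat(r_lo, c, r_lo + nrow - 1, c) +=
          dM.submat(p_lo, o * 4 + c, p_hi - 1, o * 4 + c);
  }
}

void softmax_rows(mat& Z) {
  for (uword i = 0; i < Z.n_rows; ++i) {
    arma::rowvec r = Z.row(i) - Z.row(i).max();
    r = arma::exp(r);
    Z.row(i) = r / arma::accu(r);
  }
}

struct FwdCache {
  cube M;       // L x 4k x B
  cube convpre; // L x K x B (pre-ReLU)
  mat F;        // B x (L*K), post conv activation, flattened
  mat A1lin;    // B x H
  mat A1d;      // B x H, after ReLU (+dropout in training)
  mat P;        // B x C, softmax probabilities
};

// Forward pass for a batch X (L x 4 x B). If drop is non-null it holds the
// inverted-dropout multipliers (0 or 1/(1-rate)) for the hidden layer.
void forward(const Net& net, const cube& X, FwdCache& cc, const mat* drop) {
  const int B = X.n_slices, L = net.L, K = net.K;
  cc.M.set_size(L, net.k * 4, B);
  cc.convpre.set_size(L, K, B);
  cc.F.set_size(B, L * K);
  mat Mi;
  for (int s = 0; s < B; ++s) {
    im2col(X.slice(s), net.k, net.pad_l, Mi);
    cc.M.slice(s) = Mi;
    mat conv = Mi * net.Wc;
    conv.each_row() += net.bc.t();
    cc.convpre.slice(s) = conv;
    if (net.conv_relu) conv = arma::clamp(conv, 0.0, arma::datum::inf);
    cc.F.row(s) = arma::vectorise(conv).t();
  }
  cc.A1lin = cc.F * net.W1;
  cc.A1lin.each_row() += net.b1.t();
  mat A1 = arma::clamp(cc.A1lin, 0.0, arma::datum::inf);
  cc.A1d = drop ? mat(A1 % (*drop)) : A1;
  mat Z = cc.A1d * net.W2;
  Z.each_row() += net.b2.t();
  cc.P = Z;
  softmax_rows(cc.P);
}

struct Grads {
  mat Wc; vec bc; mat W1; vec b1; mat W2; vec b2;
  void zero(const Net& n) {
    Wc.zeros(arma::size(n.Wc)); bc.zeros(arma::size(n.bc));
    W1.zeros(arma::size(n.W1)); b1.zeros(arma::size(n.b1));
    W2.zeros(arma::size(n.W2)); b2.zeros(arma::size(n.b2));
  }
};

// Backward pass from dZ (B x C, already includes loss normalization).
void backward(const Net& net, const FwdCache& cc, const mat& dZ,
              const mat* drop, Grads& g) {
  const int B = cc.P.n_rows, L = net.L, K = net.K;
  g.W2 = cc.A1d.t() * dZ;
  g.b2 = arma::sum(dZ, 0).t();
  mat dA1 = dZ * net.W2.t();
  if (drop) dA1 %= *drop;
  dA1 %= arma::conv_to<mat>::from(cc.A1lin > 0);
  g.W1 = cc.F.t() * dA1;
  g.b1 = arma::sum(dA1, 0).t();
  mat dF = dA1 * net.W1.t();
  g.Wc.zeros(arma::size(net.Wc));
  g.bc.zeros(arma::size(net.bc));
  for (int s = 0; s < B; ++s) {
    mat d = arma::reshape(dF.row(s).t(), L, K);
    if (net.conv_relu) d %= arma::conv_to<mat>::from(cc.convpre.slice(s) > 0);
    g.Wc += cc.M.slice(s).t() * d;
    g.bc += arma::sum(d, 0).t();
  }
}

struct AdamState {
  Grads m, v;
  int t = 0;
  void init(const Net& n) { m.zero(n); v.zero(n); t = 0; }
};

void adam_one(mat& p, mat& m, mat& v, const mat& g, double lr, double c1,
              double c2, double eps) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  p -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
}
void adam_one(vec& p, vec& m, vec& v, const vec& g, double lr, double c1,
              double c2, double eps) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  p -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
}

void adam_step(Net& n, AdamState& st, const Grads& g, double lr) {
  st.t += 1;
  const double c1 = 1.0 - std::pow(0.9, st.t);
  const double c2 = 1.0 - std::pow(0.999, st.t);
  const double eps = 1e-8;
  adam_one(n.Wc, st.m.Wc, st.v.Wc, g.Wc, lr, c1, c2, eps);
  adam_one(n.bc, st.m.bc, st.v.bc, g.bc, lr, c1, c2, eps);
  adam_one(n.W1, st.m.W1, st.v.W1, g.W1, lr, c1, c2, eps);
  adam_one(n.b1, st.m.b1, st.v.b1, g.b1, lr, c1, c2, eps);
  adam_one(n.W2, st.m.W2, st.v.W2, g.W2, lr, c1, c2, eps);
  adam_one(n.b2, st.m.b2, st.v.b2, g.b2, lr, c1, c2, eps);
}

// Weighted cross-entropy loss and accuracy of a probability matrix.
void eval_probs(const mat& P, const arma::ivec& y, const vec& cw,
                double& loss, double& acc) {
  const int n = P.n_rows;
  double ls = 0, ws = 0;
  int correct = 0;
  for (int i = 0; i < n; ++i) {
    const double w = cw((uword)y(i));
    ls += -w * std::log(std::max(P(i, y(i)), 1e-12));
    ws += w;
    if ((int)P.row(i).index_max() == y(i)) ++correct;
  }
  loss = ls / ws;
  acc = (double)correct / n;
}

cube subset_slices(const cube& X, const std::vector<int>& idx, int from,
                   int to) {
  cube out(X.n_rows, X.n_cols, to - from);
  for (int j = from; j < to; ++j) out.slice(j - from) = X.slice(idx[j]);
  return out;
}

mat predict_chunked(const Net& net, const cube& X) {
  const int n = X.n_slices, chunk = 256;
  mat P(n, net.C);
  FwdCache cc;
  for (int s0 = 0; s0 < n; s0 += chunk) {
    const int s1 = std::min(n, s0 + chunk);
    cube Xb(X.n_rows, X.n_cols, s1 - s0);
    for (int j = s0; j < s1; ++j) Xb.slice(j - s0) = X.slice(j);
    forward(net, Xb, cc, nullptr);
    P.rows(s0, s1 - 1) = cc.P;
  }
  return P;
}

}  // namespace

// [[Rcpp::export(name = ".cnn_train_cpp")]]
List cnn_train_cpp(const arma::cube& X, const arma::ivec& y,
                   const arma::cube& Xval, const arma::ivec& yval,
                   const List& params, int epochs, int batch_size, double lr,
                   double dropout, bool conv_relu, int seed,
                   const arma::vec& class_weights) {
  Net net = unpack(params, X.n_rows, conv_relu);
  if ((int)class_weights.n_elem != net.C) stop("class_weights length != C");
  const int n = X.n_slices;
  const bool has_val = Xval.n_slices > 0;
  AdamState st;
  st.init(net);
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  mat history(epochs, 4);
  FwdCache cc;
  Grads g;
  const double keep = 1.0 - dropout;
  for (int e = 0; e < epochs; ++e) {
    std::shuffle(idx.begin(), idx.end(), rng);
    for (int s0 = 0; s0 < n; s0 += batch_size) {
      const int s1 = std::min(n, s0 + batch_size);
      const int B = s1 - s0;
      cube Xb = subset_slices(X, idx, s0, s1);
      arma::ivec yb(B);
      for (int j = 0; j < B; ++j) yb(j) = y(idx[s0 + j]);
      mat drop(B, net.H);
      if (dropout > 0) {
        for (uword q = 0; q < drop.n_elem; ++q)
          drop(q) = (unif(rng) < dropout) ? 0.0 : 1.0 / keep;
      } else {
        drop.ones();
      }
      forward(net, Xb, cc, &drop);
      // weighted softmax + cross-entropy gradient
      mat dZ = cc.P;
      double wsum = 0;
      vec w(B);
      for (int j = 0; j < B; ++j) {
        w(j) = class_weights((uword)yb(j));
        wsum += w(j);
      }
      for (int j = 0; j < B; ++j) {
        dZ(j, yb(j)) -= 1.0;
        dZ.row(j) *= w(j) / wsum;
      }
      backward(net, cc, dZ, &drop, g);
      adam_step(net, st, g, lr);
    }
    double tl, ta, vl = NA_REAL, va = NA_REAL;
    mat Ptr = predict_chunked(net, X);
    eval_probs(Ptr, y, class_weights, tl, ta);
    if (has_val) {
      mat Pv = predict_chunked(net, Xval);
      eval_probs(Pv, yval, class_weights, vl, va);
    }
    history(e, 0) = tl; history(e, 1) = ta;
    history(e, 2) = vl; history(e, 3) = va;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = pack(net), _["history"] = history);
}

// [[Rcpp::export(name = ".cnn_forward_cpp")]]
List cnn_forward_cpp(const arma::cube& X, const List& params, bool training,
                     double dropout, bool conv_relu, int seed) {
  Net net = unpack(params, X.n_rows, conv_relu);
  const int n = X.n_slices;
  if (!training) {
    mat P = predict_chunked(net, X);
    return List::create(_["probs"] = P, _["n_masked"] = 0,
                        _["n_units"] = (double)n * net.H);
  }
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const double keep = 1.0 - dropout;
  mat P(n, net.C);
  double masked = 0;
  FwdCache cc;
  const int chunk = 256;
  for (int s0 = 0; s0 < n; s0 += chunk) {
    const int s1 = std::min(n, s0 + chunk);
    cube Xb(X.n_rows, X.n_cols, s1 - s0);
    for (int j = s0; j < s1; ++j) Xb.slice(j - s0) = X.slice(j);
    mat drop(s1 - s0, net.H);
    for (uword q = 0; q < drop.n_elem; ++q) {
      const bool m = unif(rng) < dropout;
      if (m) masked += 1;
      drop(q) = m ? 0.0 : 1.0 / keep;
    }
    forward(net, Xb, cc, &drop);
    P.rows(s0, s1 - 1) = cc.P;
  }
  return List::create(_["probs"] = P, _["n_masked"] = masked,
                      _["n_units"] = (double)n * net.H);
}

// Gradient of the pre-softmax logit of `target` (0-based) w.r.t. the input,
// evaluated in inference mode (no dropout).
// [[Rcpp::export(name = ".cnn_input_grad_cpp")]]
arma::cube cnn_input_grad_cpp(const arma::cube& X, const List& params,
                              int target, bool conv_relu) {
  Net net = unpack(params, X.n_rows, conv_relu);
  if (target < 0 || target >= net.C) stop("target class out of range");
  const int n = X.n_slices, L = net.L, K = net.K;
  cube out(L, 4, n);
  FwdCache cc;
  mat dX;
  const int chunk = 128;
  for (int s0 = 0; s0 < n; s0 += chunk) {
    const int s1 = std::min(n, s0 + chunk);
    const int B = s1 - s0;
    cube Xb(L, 4, B);
    for (int j = s0; j < s1; ++j) Xb.slice(j - s0) = X.slice(j);
    forward(net, Xb, cc, nullptr);
    // d logit_target / d A1d = W2 col; back through ReLU, W1, conv
    mat dA1 = arma::repmat(net.W2.col(target).t(), B, 1);
    dA1 %= arma::conv_to<mat>::from(cc.A1lin > 0);
    mat dF = dA1 * net.W1.t();
    for (int s = 0; s < B; ++s) {
      mat d = arma::reshape(dF.row(s).t(), L, K);
      if (conv_relu)
        d %= arma::conv_to<mat>::from(cc.convpre.slice(s) > 0);
      mat dM = d * net.Wc.t();
      col2im(dM, net.k, net.pad_l, dX);
      out.slice(s0 + s) = dX;
    }
  }
  return out;
}
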