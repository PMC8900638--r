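// Bi-LSTM -> dropout -> LSTM -> dense(ReLU) -> softmax classifier, trained
// by RMSprop on categorical cross-entropy. Time-step matrices are packed
// into column blocks of one (units x batch*T) matrix so that every
// input-side product and every parameter gradient is a single GEMM; only
// the recurrent term runs per step. Gate order in the stacked weight
// matrices is (input, forget, cell, output).

#include <RcppArmadillo.h>
#include <random>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// Reverse the T column blocks (each B wide) of M.
static mat reverse_blocks(const mat& M, int B, int T) {
  mat R(M.n_rows, M.n_cols);
  for (int t = 0; t < T; ++t)
    R.cols(t * B, t * B + B - 1) = M.cols((T - 1 - t) * B, (T - t) * B - 1);
  return R;
}

struct Cell {
  mat W, U;  // (4H x D), (4H x H)
  vec b;     // 4H
  int H = 0, B = 0, T = 0;
  mat X, I, F, G, O, C, Hs;  // caches, (., B*T)

  void set(const mat& W_, const mat& U_, const vec& b_) {
    W = W_; U = U_; b = b_; H = U.n_rows / 4;
  }

  void forward(const mat& Xall, int T_) {
    X = Xall; T = T_; B = X.n_cols / T;
    const int BT = X.n_cols;
    mat P = W * X;
    P.each_col() += b;
    I.set_size(H, BT); F.set_size(H, BT); G.set_size(H, BT);
    O.set_size(H, BT); C.set_size(H, BT); Hs.set_size(H, BT);
    mat h = zeros(H, B), c = zeros(H, B);
    for (int t = 0; t < T; ++t) {
      const span s(t * B, t * B + B - 1);
      mat A = P.cols(s) + U * h;
      mat i = sigm(A.rows(0, H - 1));
      mat f = sigm(A.rows(H, 2 * H - 1));
      mat g = tanh(A.rows(2 * H, 3 * H - 1));
      mat o = sigm(A.rows(3 * H, 4 * H - 1));
      c = f % c + i % g;
      h = o % tanh(c);
      I.cols(s) = i; F.cols(s) = f; G.cols(s) = g; O.cols(s) = o;
      C.cols(s) = c; Hs.cols(s) = h;
    }
  }

  // dH_ext: external gradient on every h_t, (H x B*T). Returns dX and
  // fills the parameter gradients.
  mat backward(const mat& dH_ext, mat& dW, mat& dU, vec& db) {
    const int BT = X.n_cols;
    mat dA_all(4 * H, BT);
    mat dh_next = zeros(H, B), dc_next = zeros(H, B);
    for (int t = T - 1; t >= 0; --t) {
      const span s(t * B, t * B + B - 1);
      mat dh = dh_next + dH_ext.cols(s);
      mat tc = tanh(C.cols(s));
      mat dc = dc_next + dh % O.cols(s) % (1.0 - tc % tc);
      mat c_prev = (t == 0) ? zeros(H, B)
                            : mat(C.cols((t - 1) * B, t * B - 1));
      dA_all.submat(0, t * B, H - 1, t * B + B - 1) =
        (dc % G.cols(s)) % I.cols(s) % (1.0 - I.cols(s));
      dA_all.submat(H, t * B, 2 * H - 1, t * B + B - 1) =
        (dc % c_prev) % F.cols(s) % (1.0 - F.cols(s));
      dA_all.submat(2 * H, t * B, 3 * H - 1, t * B + B - 1) =
        (dc % I.cols(s)) % (1.0 - G.cols(s) % G.cols(s));
      dA_all.submat(3 * H, t * B, 4 * H - 1, t * B + B - 1) =
        (dh % tc) % O.cols(s) % (1.0 - O.cols(s));
      dh_next = U.t() * dA_all.cols(s);
      dc_next = dc % F.cols(s);
    }
    dW = dA_all * X.t();
    dU = dA_all.cols(B, BT - 1) * Hs.cols(0, BT - B - 1).t();
    db = sum(dA_all, 1);
    return W.t() * dA_all;
  }
};

struct Net {
  Cell fw, bw, l2;
  mat Wd1, Wd2;
  vec bd1, bd2;

  void load(const Rcpp::List& p) {
    fw.set(Rcpp::as<mat>(p["W_f"]), Rcpp::as<mat>(p["U_f"]), Rcpp::as<vec>(p["b_f"]));
    bw.set(Rcpp::as<mat>(p["W_b"]), Rcpp::as<mat>(p["U_b"]), Rcpp::as<vec>(p["b_b"]));
    l2.set(Rcpp::as<mat>(p["W_2"]), Rcpp::as<mat>(p["U_2"]), Rcpp::as<vec>(p["b_2"]));
    Wd1 = Rcpp::as<mat>(p["W_d1"]); bd1 = Rcpp::as<vec>(p["b_d1"]);
    Wd2 = Rcpp::as<mat>(p["W_d2"]); bd2 = Rcpp::as<vec>(p["b_d2"]);
  }

  Rcpp::List dump() const {
    return Rcpp::List::create(
      Rcpp::Named("W_f") = fw.W, Rcpp::Named("U_f") = fw.U, Rcpp::Named("b_f") = fw.b,
      Rcpp::Named("W_b") = bw.W, Rcpp::Named("U_b") = bw.U, Rcpp::Named("b_b") = bw.b,
      Rcpp::Named("W_2") = l2.W, Rcpp::Named("U_2") = l2.U, Rcpp::Named("b_2") = l2.b,
      Rcpp::Named("W_d1") = Wd1, Rcpp::Named("b_d1") = bd1,
      Rcpp::Named("W_d2") = Wd2, Rcpp::Named("b_d2") = bd2);
  }
};

// Pack a batch of trials from the trials x T x F cube into (F x B*T).
static mat gather(const cube& X, const uvec& idx) {
  const int T = X.n_cols, F = X.n_slices, B = idx.n_elem;
  mat out(F, B * T);
  for (int t = 0; t < T; ++t)
    for (int b = 0; b < B; ++b)
      for (int f = 0; f < F; ++f)
        out(f, t * B + b) = X(idx[b], t, f);
  return out;
}

struct ForwardCache {
  mat mask;  // dropout mask (2H1 x B*T), empty when off
  mat h2, a1, r1, probs;
  int B = 0, T = 0;
};

static void net_forward(Net& net, const mat& Xall, int T, double dropout,
                        std::mt19937* rng, ForwardCache& fc) {
  const int B = Xall.n_cols / T;
  fc.B = B; fc.T = T;
  net.fw.forward(Xall, T);
  net.bw.forward(reverse_blocks(Xall, B, T), T);
  mat O = join_cols(net.fw.Hs, reverse_blocks(net.bw.Hs, B, T));
  if (dropout > 0.0 && rng) {
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    fc.mask.set_size(O.n_rows, O.n_cols);
    const double keep = 1.0 / (1.0 - dropout);
    for (uword k = 0; k < fc.mask.n_elem; ++k)
      fc.mask(k) = (unif(*rng) < dropout) ? 0.0 : keep;
    O %= fc.mask;
  } else {
    fc.mask.reset();
  }
  net.l2.forward(O, T);
  fc.h2 = net.l2.Hs.cols((T - 1) * B, T * B - 1);
  fc.a1 = net.Wd1 * fc.h2;
  fc.a1.each_col() += net.bd1;
  fc.r1 = clamp(fc.a1, 0.0, datum::inf);
  mat logits = net.Wd2 * fc.r1;
  logits.each_col() += net.bd2;
  logits.each_row() -= max(logits, 0);
  mat e = exp(logits);
  fc.probs = e.each_row() / sum(e, 0);
}

struct Grads {
  mat dW_f, dU_f, dW_b, dU_b, dW_2, dU_2, dWd1, dWd2;
  vec db_f, db_b, db_2, dbd1, dbd2;
};

static double net_backward(Net& net, ForwardCache& fc, const uvec& y,
                           Grads& g) {
  const int B = fc.B, T = fc.T;
  const int H1 = net.fw.H;
  double loss = 0.0;
  mat dlogits = fc.probs;
  for (int b = 0; b < B; ++b) {
    loss -= std::log(std::max(fc.probs(y[b], b), 1e-300));
    dlogits(y[b], b) -= 1.0;
  }
  loss /= B;
  dlogits /= B;
  g.dWd2 = dlogits * fc.r1.t();
  g.dbd2 = sum(dlogits, 1);
  mat dr1 = net.Wd2.t() * dlogits;
  mat da1 = dr1 % conv_to<mat>::from(fc.a1 > 0.0);
  g.dWd1 = da1 * fc.h2.t();
  g.dbd1 = sum(da1, 1);

  mat dH2 = zeros(net.l2.H, B * T);
  dH2.cols((T - 1) * B, T * B - 1) = net.Wd1.t() * da1;
  mat dO = net.l2.backward(dH2, g.dW_2, g.dU_2, g.db_2);
  if (fc.mask.n_elem) dO %= fc.mask;
  net.fw.backward(dO.rows(0, H1 - 1), g.dW_f, g.dU_f, g.db_f);
  net.bw.backward(reverse_blocks(dO.rows(H1, 2 * H1 - 1), B, T),
                  g.dW_b, g.dU_b, g.db_b);
  return loss;
}

struct RMSState { mat v; bool init = false; };

static void rms_update(mat& p, const mat& grad, RMSState& s,
                       double lr, double rho, double eps) {
  if (!s.init) { s.v.zeros(size(grad)); s.init = true; }
  s.v = rho * s.v + (1.0 - rho) * (grad % grad);
  p -= lr * grad / (sqrt(s.v) + eps);
}

// [[Rcpp::export]]
Rcpp::List lstm_train_cpp(Rcpp::List params, arma::cube X,
                          arma::ivec y, int epochs, int batch_size,
                          double lr, double dropout, int seed,
                          double rho = 0.9, double eps = 1e-7) {
  Net net;
  net.load(params);
  const int n = X.n_rows, T = X.n_cols;
  std::mt19937 rng(static_cast<unsigned>(seed));
  uvec yy = conv_to<uvec>::from(y);
  std::vector<RMSState> st(13);
  std::vector<double> losses;
  std::vector<uword> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    int n_batch = 0;
    for (int start = 0; start < n; start += batch_size) {
      int stop = std::min(start + batch_size, n);
      uvec idx(stop - start);
      for (int i = start; i < stop; ++i) idx[i - start] = order[i];
      ForwardCache fc;
      net_forward(net, gather(X, idx), T, dropout, &rng, fc);
      Grads g;
      double loss = net_backward(net, fc, yy.elem(idx), g);
      if (!std::isfinite(loss))
        Rcpp::stop("NaN/Inf loss at epoch %d, batch %d", ep + 1, n_batch + 1);
      ep_loss += loss; ++n_batch;
      int k = 0;
      rms_update(net.fw.W, g.dW_f, st[k++], lr, rho, eps);
      rms_update(net.fw.U, g.dU_f, st[k++], lr, rho, eps);
      { mat b(net.fw.b); rms_update(b, mat(g.db_f), st[k++], lr, rho, eps); net.fw.b = b; }
      rms_update(net.bw.W, g.dW_b, st[k++], lr, rho, eps);
      rms_update(net.bw.U, g.dU_b, st[k++], lr, rho, eps);
      { mat b(net.bw.b); rms_update(b, mat(g.db_b), st[k++], lr, rho, eps); net.bw.b = b; }
      rms_update(net.l2.W, g.dW_2, st[k++], lr, rho, eps);
      rms_update(net.l2.U, g.dU_2, st[k++], lr, rho, eps);
      { mat b(net.l2.b); rms_update(b, mat(g.db_2), st[k++], lr, rho, eps); net.l2.b = b; }
      rms_update(net.Wd1, g.dWd1, st[k++], lr, rho, eps);
      { mat b(net.bd1); rms_update(b, mat(g.dbd1), st[k++], lr, rho, eps); net.bd1 = b; }
      rms_update(net.Wd2, g.dWd2, st[k++], lr, rho, eps);
      { mat b(net.bd2); rms_update(b, mat(g.dbd2), st[k++], lr, rho, eps); net.bd2 = b; }
    }
    losses.push_back(ep_loss / std::max(n_batch, 1));
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("params") = net.dump(),
                            Rcpp::Named("loss_history") = losses);
}

// [[Rcpp::export]]
arma::mat lstm_predict_cpp(Rcpp::List params, arma::cube X) {
  Net net;
  net.load(params);
  const int n = X.n_rows, T = X.n_cols;
  uvec idx = regspace<uvec>(0, n - 1);
  ForwardCache fc;
  net_forward(net, gather(X, idx), T, 0.0, nullptr, fc);
  return fc.probs.t();  // trials x classes
}

// Loss and full gradient on a batch, dropout off: used by the numerical
// gradient check.
// [[Rcpp::export]]
Rcpp::List lstm_loss_grads_cpp(Rcpp::List params, arma::cube X,
                               arma::ivec y) {
  Net net;
  net.load(params);
  const int T = X.n_cols;
  uvec idx = regspace<uvec>(0, X.n_rows - 1);
  ForwardCache fc;
  net_forward(net, gather(X, idx), T, 0.0, nullptr, fc);
  Grads g;
  double loss = net_backward(net, fc, conv_to<uvec>::from(y), g);
  Rcpp::List gl = Rcpp::List::create(
    Rcpp::Named("W_f") = g.dW_f, Rcpp::Named("U_f") = g.dU_f, Rcpp::Named("b_f") = g.db_f,
    Rcpp::Named("W_b") = g.dW_b, Rcpp::Named("U_b") = g.dU_b, Rcpp::Named("b_b") = g.db_b,
    Rcpp::Named("W_2") = g.dW_2, Rcpp::Named("U_2") = g.dU_2, Rcpp::Named("b_2") = g.db_2,
    Rcpp::Named("W_d1") = g.dWd1, Rcpp::Named("b_d1") = g.dbd1,
    Rcpp::Named("W_d2") = g.dWd2, Rcpp::Named("b_d2") = g.dbd2);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = gl);
}

// [[Rcpp::export]]
double lstm_loss_cpp(Rcpp::List params, arma::cube X, arma::ivec y) {
  Net net;
  net.load(params);
  uvec idx = regspace<uvec>(0, X.n_rows - 1);
  ForwardCache fc;
  net_forward(net, gather(X, idx), X.n_cols, 0.0, nullptr, fc);
  double loss = 0.0;
  for (uword b = 0; b < idx.n_elem; ++b)
    loss -= std::log(std::max(fc.probs(y[b], b), 1e-300));
  return loss / idx.n_elem;
}
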