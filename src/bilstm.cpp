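// Compact bidirectional LSTM for sequence classification / regression.
// Architecture: BiLSTM(h1, return sequences) -> dropout -> BiLSTM(h2, last
// step of each direction) -> dropout -> dense(relu) -> linear output with
// softmax + cross-entropy (classification) or identity + MSE (regression).
// Trained with Adam on minibatches; all randomness from one mt19937 seed.
//
// Data layout: sequences as an arma::cube with dimensions (N, F, L) so that
// slice t is the N x F design matrix of time step t.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;

static const char* PARAM_NAMES[16] = {
  "W1f", "U1f", "b1f", "W1b", "U1b", "b1b",
  "W2f", "U2f", "b2f", "W2b", "U2b", "b2b",
  "Wd", "bd", "Wo", "bo"};

typedef std::vector<mat> Params;

static Params params_from_list(const List& lst) {
  Params p(16);
  for (int k = 0; k < 16; ++k)
    p[k] = Rcpp::as<mat>(lst[PARAM_NAMES[k]]);
  return p;
}

static List params_to_list(const Params& p) {
  List out(16);
  Rcpp::CharacterVector nm(16);
  for (int k = 0; k < 16; ++k) { out[k] = p[k]; nm[k] = PARAM_NAMES[k]; }
  out.attr("names") = nm;
  return out;
}

static inline mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

struct LSTMCache { cube i, f, g, o, c, h; };

// Forward pass of one LSTM direction over X (B, F, L).
static void lstm_forward(const cube& X, const mat& W, const mat& U,
                         const mat& b, bool reverse, LSTMCache& cc) {
  const uword B = X.n_rows, L = X.n_slices, H = U.n_rows;
  cc.i.set_size(B, H, L); cc.f.set_size(B, H, L); cc.g.set_size(B, H, L);
  cc.o.set_size(B, H, L); cc.c.set_size(B, H, L); cc.h.set_size(B, H, L);
  mat h_prev(B, H, fill::zeros), c_prev(B, H, fill::zeros);
  for (uword k = 0; k < L; ++k) {
    const uword t = reverse ? L - 1 - k : k;
    mat z = X.slice(t) * W + h_prev * U;
    z.each_row() += b.row(0);
    mat gi = sigm(z.cols(0, H - 1));
    mat gf = sigm(z.cols(H, 2 * H - 1));
    mat gg = tanh(z.cols(2 * H, 3 * H - 1));
    mat go = sigm(z.cols(3 * H, 4 * H - 1));
    mat c = gf % c_prev + gi % gg;
    mat h = go % tanh(c);
    cc.i.slice(t) = gi; cc.f.slice(t) = gf; cc.g.slice(t) = gg;
    cc.o.slice(t) = go; cc.c.slice(t) = c;  cc.h.slice(t) = h;
    h_prev = h; c_prev = c;
  }
}

// Backward pass of one LSTM direction. dH holds the external gradient on
// the hidden state at every time step; gradients are accumulated into
// dW/dU/db and (if accum_dX) into dX.
static void lstm_backward(const cube& X, const cube& dH, const LSTMCache& cc,
                          const mat& W, const mat& U, bool reverse,
                          mat& dW, mat& dU, mat& db, cube* dX) {
  const uword B = X.n_rows, L = X.n_slices, H = U.n_rows;
  dW.zeros(W.n_rows, W.n_cols);
  dU.zeros(U.n_rows, U.n_cols);
  db.zeros(1, 4 * H);
  mat dh_rec(B, H, fill::zeros), dc(B, H, fill::zeros);
  for (sword k = (sword)L - 1; k >= 0; --k) {
    const uword t = reverse ? L - 1 - k : (uword)k;
    const uword t_prev = reverse ? L - k : (uword)k - 1;  // valid iff k > 0
    const mat& gi = cc.i.slice(t); const mat& gf = cc.f.slice(t);
    const mat& gg = cc.g.slice(t); const mat& go = cc.o.slice(t);
    mat tanhc = tanh(cc.c.slice(t));
    mat dh = dH.slice(t) + dh_rec;
    mat dgo = dh % tanhc;
    dc += dh % go % (1.0 - square(tanhc));
    mat c_prev = (k > 0) ? cc.c.slice(t_prev) : mat(B, H, fill::zeros);
    mat h_prev = (k > 0) ? cc.h.slice(t_prev) : mat(B, H, fill::zeros);
    mat dzi = (dc % gg) % gi % (1.0 - gi);
    mat dzf = (dc % c_prev) % gf % (1.0 - gf);
    mat dzg = (dc % gi) % (1.0 - square(gg));
    mat dzo = dgo % go % (1.0 - go);
    mat dz = join_rows(join_rows(dzi, dzf), join_rows(dzg, dzo));
    dW += X.slice(t).t() * dz;
    dU += h_prev.t() * dz;
    db += sum(dz, 0);
    dh_rec = dz * U.t();
    if (dX) dX->slice(t) += dz * W.t();
    dc = dc % gf;
  }
}

struct ForwardState {
  LSTMCache c1f, c1b, c2f, c2b;
  cube H1, X2;        // layer-1 output and (possibly dropped-out) layer-2 input
  cube mask1;
  mat R, Rdrop, mask2, A, out;
};

static void model_forward(const Params& P, const cube& X, bool training,
                          double dropout, std::mt19937& rng,
                          ForwardState& st) {
  const uword B = X.n_rows, L = X.n_slices;
  const uword H1 = P[1].n_rows, H2 = P[7].n_rows;
  lstm_forward(X, P[0], P[1], P[2], false, st.c1f);
  lstm_forward(X, P[3], P[4], P[5], true, st.c1b);
  st.H1.set_size(B, 2 * H1, L);
  for (uword t = 0; t < L; ++t)
    st.H1.slice(t) = join_rows(st.c1f.h.slice(t), st.c1b.h.slice(t));

  if (training && dropout > 0) {
    std::bernoulli_distribution keep(1.0 - dropout);
    st.mask1.set_size(B, 2 * H1, L);
    for (uword n = 0; n < st.mask1.n_elem; ++n)
      st.mask1(n) = keep(rng) ? 1.0 / (1.0 - dropout) : 0.0;
    st.X2 = st.H1 % st.mask1;
  } else {
    st.mask1.reset();
    st.X2 = st.H1;
  }

  lstm_forward(st.X2, P[6], P[7], P[8], false, st.c2f);
  lstm_forward(st.X2, P[9], P[10], P[11], true, st.c2b);
  st.R = join_rows(st.c2f.h.slice(L - 1), st.c2b.h.slice(0));

  if (training && dropout > 0) {
    std::bernoulli_distribution keep(1.0 - dropout);
    st.mask2.set_size(B, 2 * H2);
    for (uword n = 0; n < st.mask2.n_elem; ++n)
      st.mask2(n) = keep(rng) ? 1.0 / (1.0 - dropout) : 0.0;
    st.Rdrop = st.R % st.mask2;
  } else {
    st.mask2.reset();
    st.Rdrop = st.R;
  }

  mat Z = st.Rdrop * P[12];
  Z.each_row() += P[13].row(0);
  st.A = clamp(Z, 0.0, datum::inf);  // relu
  st.out = st.A * P[14];
  st.out.each_row() += P[15].row(0);
}

static mat softmax_rows(const mat& z) {
  mat s = z;
  s.each_col() -= max(z, 1);
  s = exp(s);
  s.each_col() /= sum(s, 1);
  return s;
}

// loss and (optionally) gradients for one batch
static double model_loss_grad(const Params& P, const cube& X, const mat& Y,
                              const std::string& task, bool training,
                              double dropout, std::mt19937& rng,
                              Params* G) {
  ForwardState st;
  model_forward(P, X, training, dropout, rng, st);
  const uword B = X.n_rows, L = X.n_slices;
  const uword H1 = P[1].n_rows, H2 = P[7].n_rows;
  double loss;
  mat dOut;
  if (task == "classification") {
    mat Pr = softmax_rows(st.out);
    loss = -accu(Y % log(Pr + 1e-12)) / B;
    dOut = (Pr - Y) / B;
  } else {
    mat e = st.out - Y;
    loss = accu(square(e)) / e.n_elem;
    dOut = 2.0 * e / e.n_elem;
  }
  if (!G) return loss;

  Params& g = *G;
  g.assign(16, mat());
  g[14] = st.A.t() * dOut;                    // Wo
  g[15] = sum(dOut, 0);                       // bo
  mat dA = dOut * P[14].t();
  dA %= conv_to<mat>::from(st.A > 0);
  g[12] = st.Rdrop.t() * dA;                  // Wd
  g[13] = sum(dA, 0);                         // bd
  mat dR = dA * P[12].t();
  if (st.mask2.n_elem) dR %= st.mask2;

  cube dH2f(B, H2, L, fill::zeros), dH2b(B, H2, L, fill::zeros);
  dH2f.slice(L - 1) = dR.cols(0, H2 - 1);
  dH2b.slice(0) = dR.cols(H2, 2 * H2 - 1);
  cube dX2(B, 2 * H1, L, fill::zeros);
  lstm_backward(st.X2, dH2f, st.c2f, P[6], P[7], false,
                g[6], g[7], g[8], &dX2);
  lstm_backward(st.X2, dH2b, st.c2b, P[9], P[10], true,
                g[9], g[10], g[11], &dX2);
  if (st.mask1.n_elem) dX2 %= st.mask1;

  cube dH1f = dX2.subcube(0, 0, 0, B - 1, H1 - 1, L - 1);
  cube dH1b = dX2.subcube(0, H1, 0, B - 1, 2 * H1 - 1, L - 1);
  lstm_backward(X, dH1f, st.c1f, P[0], P[1], false, g[0], g[1], g[2], nullptr);
  lstm_backward(X, dH1b, st.c1b, P[3], P[4], true, g[3], g[4], g[5], nullptr);
  return loss;
}

static cube gather_rows(const cube& X, const uvec& idx) {
  cube out(idx.n_elem, X.n_cols, X.n_slices);
  for (uword t = 0; t < X.n_slices; ++t)
    out.slice(t) = X.slice(t).rows(idx);
  return out;
}

static mat glorot(uword nr, uword nc, std::mt19937& rng) {
  double s = std::sqrt(6.0 / (nr + nc));
  std::uniform_real_distribution<double> u(-s, s);
  mat m(nr, nc);
  for (uword n = 0; n < m.n_elem; ++n) m(n) = u(rng);
  return m;
}

// [[Rcpp::export(name = ".bilstm_init_cpp")]]
List bilstm_init_cpp(int input_dim, int h1, int h2, int dense_dim,
                     int output_dim, int seed) {
  std::mt19937 rng(seed);
  Params P(16);
  auto lstm_par = [&](int fin, int H, int base) {
    P[base] = glorot(fin, 4 * H, rng);
    P[base + 1] = glorot(H, 4 * H, rng);
    mat b(1, 4 * H, fill::zeros);
    b.cols(H, 2 * H - 1).fill(1.0);  // forget-gate bias
    P[base + 2] = b;
  };
  lstm_par(input_dim, h1, 0);
  lstm_par(input_dim, h1, 3);
  lstm_par(2 * h1, h2, 6);
  lstm_par(2 * h1, h2, 9);
  P[12] = glorot(2 * h2, dense_dim, rng);
  P[13] = mat(1, dense_dim, fill::zeros);
  P[14] = glorot(dense_dim, output_dim, rng);
  P[15] = mat(1, output_dim, fill::zeros);
  return params_to_list(P);
}

// [[Rcpp::export(name = ".bilstm_loss_grad_cpp")]]
List bilstm_loss_grad_cpp(List params, arma::cube X, arma::mat Y,
                          std::string task) {
  Params P = params_from_list(params);
  std::mt19937 rng(0);
  Params G;
  double loss = model_loss_grad(P, X, Y, task, false, 0.0, rng, &G);
  return List::create(Rcpp::Named("loss") = loss,
                      Rcpp::Named("grads") = params_to_list(G));
}

// [[Rcpp::export(name = ".bilstm_train_cpp")]]
List bilstm_train_cpp(List params, arma::cube X, arma::mat Y,
                      std::string task, int epochs, int batch_size,
                      double lr, double dropout, double val_frac,
                      int patience, int seed, bool verbose) {
  Params P = params_from_list(params);
  const uword N = X.n_rows;
  std::mt19937 rng(seed);

  uvec perm = regspace<uvec>(0, N - 1);
  std::shuffle(perm.begin(), perm.end(), rng);
  uword n_val = (uword)std::floor(val_frac * N);
  if (n_val > 0 && N - n_val < 2) n_val = 0;
  uvec val_idx = n_val > 0 ? perm.head(n_val) : uvec();
  uvec train_idx = perm.tail(N - n_val);
  cube Xval; mat Yval;
  if (n_val > 0) { Xval = gather_rows(X, val_idx); Yval = Y.rows(val_idx); }

  Params M(16), V(16);
  for (int k = 0; k < 16; ++k) {
    M[k] = mat(P[k].n_rows, P[k].n_cols, fill::zeros);
    V[k] = M[k];
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  double best_val = datum::inf;
  Params best = P;
  int bad_epochs = 0;
  std::vector<double> tr_hist, val_hist;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(train_idx.begin(), train_idx.end(), rng);
    double ep_loss = 0; uword n_batches = 0;
    for (uword s = 0; s < train_idx.n_elem; s += batch_size) {
      uword e = std::min<uword>(s + batch_size, train_idx.n_elem);
      uvec bi = train_idx.subvec(s, e - 1);
      cube Xb = gather_rows(X, bi);
      mat Yb = Y.rows(bi);
      Params G;
      ep_loss += model_loss_grad(P, Xb, Yb, task, true, dropout, rng, &G);
      ++n_batches;
      ++step;
      double c1 = 1.0 - std::pow(b1, (double)step);
      double c2 = 1.0 - std::pow(b2, (double)step);
      for (int k = 0; k < 16; ++k) {
        M[k] = b1 * M[k] + (1 - b1) * G[k];
        V[k] = b2 * V[k] + (1 - b2) * square(G[k]);
        P[k] -= lr * (M[k] / c1) / (sqrt(V[k] / c2) + eps);
      }
    }
    tr_hist.push_back(ep_loss / std::max<uword>(1, n_batches));
    if (n_val > 0) {
      double vl = model_loss_grad(P, Xval, Yval, task, false, 0.0, rng,
                                  nullptr);
      val_hist.push_back(vl);
      if (vl < best_val - 1e-6) { best_val = vl; best = P; bad_epochs = 0; }
      else if (++bad_epochs >= patience) break;
    }
    if (verbose)
      Rcpp::Rcout << "epoch " << ep + 1 << " loss " << tr_hist.back()
                  << (n_val > 0 ? " val " : "")
                  << (n_val > 0 ? std::to_string(val_hist.back()) : "")
                  << std::endl;
    Rcpp::checkUserInterrupt();
  }
  if (n_val > 0) P = best;
  return List::create(
    Rcpp::Named("params") = params_to_list(P),
    Rcpp::Named("train_loss") = tr_hist,
    Rcpp::Named("val_loss") = val_hist);
}

// [[Rcpp::export(name = ".bilstm_predict_cpp")]]
arma::mat bilstm_predict_cpp(List params, arma::cube X, std::string task,
                             int batch_size) {
  Params P = params_from_list(params);
  const uword N = X.n_rows, O = P[14].n_cols;
  mat out(N, O);
  std::mt19937 rng(0);
  for (uword s = 0; s < N; s += batch_size) {
    uword e = std::min<uword>(s + batch_size, N);
    uvec bi = regspace<uvec>(s, e - 1);
    cube Xb = gather_rows(X, bi);
    ForwardState st;
    model_forward(P, Xb, false, 0.0, rng, st);
    out.rows(s, e - 1) =
      (task == "classification") ? softmax_rows(st.out) : st.out;
  }
  return out;
}
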