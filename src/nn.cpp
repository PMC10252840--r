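// Hybrid convolutional-recurrent binary classifiers: batched forward,
// backpropagation through time, and Adam training on binary cross-entropy.
//
// Sequences are held as cubes of shape (batch, features, time). The
// convolution has kernel size 1 on a univariate input, so it is a per-time
// step affine map from the scalar sample to `filters` channels, followed by
// a softmax (or ReLU) across the channels. All recurrent layers except the
// last return full sequences; the last returns its final hidden state.
// Layer outputs live in their caches; nothing is duplicated between the
// forward and backward passes (this loop dominates the package's runtime).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

enum RecType { REC_RNN = 0, REC_LSTM = 1, REC_GRU2 = 2, REC_GRU1 = 3, REC_BILSTM = 4 };

struct Arch {
  int conv_filters;
  bool conv_softmax;
  std::vector<int> rec_type;
  std::vector<int> rec_units;
  std::vector<int> rec_input;   // input feature dim per recurrent layer
  double dropout;
  int T;                        // window length
};

// stack time slices: (B, d, T) cube -> (B*T, d) matrix
static mat flatten_time(const cube& X) {
  const uword B = X.n_rows, d = X.n_cols, T = X.n_slices;
  mat M(B * T, d);
  for (uword t = 0; t < T; ++t) M.rows(t * B, t * B + B - 1) = X.slice(t);
  return M;
}

static cube unflatten_time(const mat& M, uword B, uword d, uword T) {
  cube X(B, d, T);
  for (uword t = 0; t < T; ++t) X.slice(t) = M.rows(t * B, t * B + B - 1);
  return X;
}

// ---------------------------------------------------------------- conv ----

struct ConvCache { cube A; mat Xb; };

static void conv_forward(const mat& Xb, const mat& W, const mat& b,
                         bool softmax_act, ConvCache& cache) {
  const uword B = Xb.n_rows, T = Xb.n_cols, F = W.n_cols;
  cache.A.set_size(B, F, T);
  cache.Xb = Xb;
  const rowvec bb = b.row(0);
  mat Z(B, F);
  for (uword t = 0; t < T; ++t) {
    Z = Xb.col(t) * W;          // (B x 1)(1 x F)
    Z.each_row() += bb;
    if (softmax_act) {
      Z.each_col() -= max(Z, 1);
      Z = exp(Z);
      cache.A.slice(t) = Z.each_col() / sum(Z, 1);
    } else {
      cache.A.slice(t) = Z % (Z > 0);
    }
  }
}

static void conv_backward(const cube& dA, bool softmax_act,
                          const ConvCache& cache, mat& dW, mat& db) {
  const uword T = dA.n_slices;
  dW.zeros(1, dA.n_cols);
  db.zeros(1, dA.n_cols);
  mat dZ(dA.n_rows, dA.n_cols);
  for (uword t = 0; t < T; ++t) {
    const mat& A = cache.A.slice(t);
    if (softmax_act) {
      vec s = sum(dA.slice(t) % A, 1);
      dZ = A % (dA.slice(t).each_col() - s);
    } else {
      dZ = dA.slice(t) % (A > 0);
    }
    dW += cache.Xb.col(t).t() * dZ;
    db += sum(dZ, 0);
  }
}

// ---------------------------------------------------------------- rnn -----

struct RnnCache { cube H; };

static const cube& rnn_forward(const cube& X, const mat& Wx, const mat& Wh,
                               const mat& b, RnnCache& cache) {
  const uword B = X.n_rows, T = X.n_slices, u = Wx.n_cols;
  mat Zx = flatten_time(X) * Wx;
  Zx.each_row() += b.row(0);
  cache.H.set_size(B, u, T);
  mat Z(B, u);
  for (uword t = 0; t < T; ++t) {
    Z = Zx.rows(t * B, t * B + B - 1);
    if (t > 0) Z += cache.H.slice(t - 1) * Wh;
    cache.H.slice(t) = tanh(Z);
  }
  return cache.H;
}

static cube rnn_backward(const cube& X, const mat& Wx, const mat& Wh,
                         const RnnCache& cache, const cube& dHout,
                         mat& dWx, mat& dWh, mat& db) {
  const uword B = X.n_rows, T = X.n_slices, u = Wx.n_cols;
  mat carry(B, u, fill::zeros);
  mat dZall(B * T, u);
  mat dz(B, u);
  dWh.zeros(u, u);
  for (uword ti = T; ti-- > 0;) {
    dz = (dHout.slice(ti) + carry) % (1.0 - square(cache.H.slice(ti)));
    if (ti > 0) dWh += cache.H.slice(ti - 1).t() * dz;
    carry = dz * Wh.t();
    dZall.rows(ti * B, ti * B + B - 1) = dz;
  }
  dWx = flatten_time(X).t() * dZall;
  db = sum(dZall, 0);
  return unflatten_time(dZall * Wx.t(), B, X.n_cols, T);
}

// ---------------------------------------------------------------- lstm ----

// direction-parameterized so a BiLSTM needs no reversed input copies:
// logical step s = 0..T-1 reads physical slice (fwd ? s : T-1-s).
struct LstmCache { cube G; cube C; cube H; };  // physical-slice indexing

static void lstm_forward(const cube& X, const mat& Wx, const mat& Wh,
                         const mat& b, bool fwd, LstmCache& cache) {
  const uword B = X.n_rows, T = X.n_slices, u = Wh.n_rows;
  mat Zx = flatten_time(X) * Wx;
  Zx.each_row() += b.row(0);
  cache.G.set_size(B, 4 * u, T);
  cache.C.set_size(B, u, T);
  cache.H.set_size(B, u, T);
  mat Z(B, 4 * u);
  for (uword s = 0; s < T; ++s) {
    const uword t = fwd ? s : T - 1 - s;
    const uword tp = fwd ? t - 1 : t + 1;     // previous physical slice
    Z = Zx.rows(t * B, t * B + B - 1);
    if (s > 0) Z += cache.H.slice(tp) * Wh;
    mat& G = cache.G.slice(t);
    G.cols(0, 2 * u - 1) = 1.0 / (1.0 + exp(-Z.cols(0, 2 * u - 1)));    // i,f
    G.cols(2 * u, 3 * u - 1) = tanh(Z.cols(2 * u, 3 * u - 1));          // g
    G.cols(3 * u, 4 * u - 1) =
      1.0 / (1.0 + exp(-Z.cols(3 * u, 4 * u - 1)));                     // o
    cache.C.slice(t) = G.cols(0, u - 1) % G.cols(2 * u, 3 * u - 1);
    if (s > 0) cache.C.slice(t) += G.cols(u, 2 * u - 1) % cache.C.slice(tp);
    cache.H.slice(t) = G.cols(3 * u, 4 * u - 1) % tanh(cache.C.slice(t));
  }
}

// dHout uses physical slice indexing; dX is accumulated (+=) into dXacc,
// which must be pre-sized (possibly zero-filled) by the caller
static void lstm_backward(const cube& X, const mat& Wx, const mat& Wh,
                          const LstmCache& cache, const cube& dHout, bool fwd,
                          mat& dWx, mat& dWh, mat& db, cube& dXacc) {
  const uword B = X.n_rows, T = X.n_slices, u = Wh.n_rows;
  mat carry_h(B, u, fill::zeros), carry_c(B, u, fill::zeros);
  mat dZall(B * T, 4 * u);
  mat dh(B, u), dc(B, u), tc(B, u), dz(B, 4 * u);
  dWh.zeros(u, 4 * u);
  for (uword s = T; s-- > 0;) {
    const uword t = fwd ? s : T - 1 - s;
    const uword tp = fwd ? t - 1 : t + 1;
    const mat& G = cache.G.slice(t);
    auto i = G.cols(0, u - 1);
    auto f = G.cols(u, 2 * u - 1);
    auto g = G.cols(2 * u, 3 * u - 1);
    auto o = G.cols(3 * u, 4 * u - 1);
    tc = tanh(cache.C.slice(t));
    dh = dHout.slice(t) + carry_h;
    dc = carry_c + dh % o % (1.0 - square(tc));
    dz.cols(0, u - 1) = (dc % g) % i % (1.0 - i);
    if (s > 0)
      dz.cols(u, 2 * u - 1) = (dc % cache.C.slice(tp)) % f % (1.0 - f);
    else
      dz.cols(u, 2 * u - 1).zeros();
    dz.cols(2 * u, 3 * u - 1) = (dc % i) % (1.0 - square(g));
    dz.cols(3 * u, 4 * u - 1) = (dh % tc) % o % (1.0 - o);
    if (s > 0) dWh += cache.H.slice(tp).t() * dz;
    carry_h = dz * Wh.t();
    carry_c = dc % f;
    dZall.rows(t * B, t * B + B - 1) = dz;
  }
  dWx = flatten_time(X).t() * dZall;
  db = sum(dZall, 0);
  mat dXall = dZall * Wx.t();
  for (uword t = 0; t < T; ++t)
    dXacc.slice(t) += dXall.rows(t * B, t * B + B - 1);
}

// ------------------------------------------------------------ gru (x2 bias)

// "double bias" gated recurrent unit: separate input- and recurrent-side
// bias vectors, reset gate applied after the recurrent matrix product.
// Gate order within the 3u blocks: reset, update, candidate.
struct Gru2Cache { cube R, Z, N, HN, H; };

static const cube& gru2_forward(const cube& X, const mat& Wx, const mat& Wh,
                                const mat& bx, const mat& bh,
                                Gru2Cache& cache) {
  const uword B = X.n_rows, T = X.n_slices, u = Wh.n_rows;
  mat Zx = flatten_time(X) * Wx;
  Zx.each_row() += bx.row(0);
  cache.R.set_size(B, u, T); cache.Z.set_size(B, u, T);
  cache.N.set_size(B, u, T); cache.HN.set_size(B, u, T);
  cache.H.set_size(B, u, T);
  const rowvec bhr = bh.row(0);
  mat Hh(B, 3 * u);
  for (uword t = 0; t < T; ++t) {
    if (t > 0) Hh = cache.H.slice(t - 1) * Wh; else Hh.zeros();
    Hh.each_row() += bhr;
    auto zx = Zx.rows(t * B, t * B + B - 1);
    cache.R.slice(t) =
      1.0 / (1.0 + exp(-(zx.cols(0, u - 1) + Hh.cols(0, u - 1))));
    cache.Z.slice(t) =
      1.0 / (1.0 + exp(-(zx.cols(u, 2 * u - 1) + Hh.cols(u, 2 * u - 1))));
    cache.HN.slice(t) = Hh.cols(2 * u, 3 * u - 1);
    cache.N.slice(t) = tanh(zx.cols(2 * u, 3 * u - 1) +
                            cache.R.slice(t) % cache.HN.slice(t));
    cache.H.slice(t) = (1.0 - cache.Z.slice(t)) % cache.N.slice(t);
    if (t > 0)
      cache.H.slice(t) += cache.Z.slice(t) % cache.H.slice(t - 1);
  }
  return cache.H;
}

static cube gru2_backward(const cube& X, const mat& Wx, const mat& Wh,
                          const Gru2Cache& cache, const cube& dHout,
                          mat& dWx, mat& dWh, mat& dbx, mat& dbh) {
  const uword B = X.n_rows, T = X.n_slices, u = Wh.n_rows;
  mat carry(B, u, fill::zeros);
  mat dZxall(B * T, 3 * u);
  mat dh(B, u), dZh(B, 3 * u);
  dWh.zeros(u, 3 * u);
  dbh.zeros(1, 3 * u);
  for (uword ti = T; ti-- > 0;) {
    const mat& r = cache.R.slice(ti);
    const mat& z = cache.Z.slice(ti);
    const mat& n = cache.N.slice(ti);
    dh = dHout.slice(ti) + carry;
    mat dn_pre = dh % (1.0 - z) % (1.0 - square(n));
    if (ti > 0)
      dZh.cols(u, 2 * u - 1) =
        dh % (cache.H.slice(ti - 1) - n) % z % (1.0 - z);
    else
      dZh.cols(u, 2 * u - 1) = dh % (-n) % z % (1.0 - z);
    dZh.cols(0, u - 1) = (dn_pre % cache.HN.slice(ti)) % r % (1.0 - r);
    dZh.cols(2 * u, 3 * u - 1) = dn_pre % r;
    auto rows = dZxall.rows(ti * B, ti * B + B - 1);
    rows.cols(0, 2 * u - 1) = dZh.cols(0, 2 * u - 1);
    rows.cols(2 * u, 3 * u - 1) = dn_pre;
    carry = dh % z + dZh * Wh.t();
    if (ti > 0) dWh += cache.H.slice(ti - 1).t() * dZh;
    dbh += sum(dZh, 0);
  }
  dWx = flatten_time(X).t() * dZxall;
  dbx = sum(dZxall, 0);
  return unflatten_time(dZxall * Wx.t(), B, X.n_cols, T);
}

// ------------------------------------------------------------ gru (x1 bias)

// "single bias" variant: one bias vector, reset gate applied to the hidden
// state before the recurrent product of the candidate.
struct Gru1Cache { cube R, Z, N, H; };

static const cube& gru1_forward(const cube& X, const mat& Wx, const mat& Wh,
                                const mat& b, Gru1Cache& cache) {
  const uword B = X.n_rows, T = X.n_slices, u = Wh.n_rows;
  mat Zx = flatten_time(X) * Wx;
  Zx.each_row() += b.row(0);
  const mat Whrz = Wh.cols(0, 2 * u - 1);
  const mat Whn = Wh.cols(2 * u, 3 * u - 1);
  cache.R.set_size(B, u, T); cache.Z.set_size(B, u, T);
  cache.N.set_size(B, u, T); cache.H.set_size(B, u, T);
  mat Hh(B, 2 * u, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    if (t > 0) Hh = cache.H.slice(t - 1) * Whrz;
    auto zx = Zx.rows(t * B, t * B + B - 1);
    cache.R.slice(t) =
      1.0 / (1.0 + exp(-(zx.cols(0, u - 1) + Hh.cols(0, u - 1))));
    cache.Z.slice(t) =
      1.0 / (1.0 + exp(-(zx.cols(u, 2 * u - 1) + Hh.cols(u, 2 * u - 1))));
    if (t > 0)
      cache.N.slice(t) = tanh(zx.cols(2 * u, 3 * u - 1) +
                              (cache.R.slice(t) % cache.H.slice(t - 1)) * Whn);
    else
      cache.N.slice(t) = tanh(zx.cols(2 * u, 3 * u - 1));
    cache.H.slice(t) = (1.0 - cache.Z.slice(t)) % cache.N.slice(t);
    if (t > 0)
      cache.H.slice(t) += cache.Z.slice(t) % cache.H.slice(t - 1);
  }
  return cache.H;
}

static cube gru1_backward(const cube& X, const mat& Wx, const mat& Wh,
                          const Gru1Cache& cache, const cube& dHout,
                          mat& dWx, mat& dWh, mat& db) {
  const uword B = X.n_rows, T = X.n_slices, u = Wh.n_rows;
  const mat Whrz = Wh.cols(0, 2 * u - 1);
  const mat Whn = Wh.cols(2 * u, 3 * u - 1);
  mat carry(B, u, fill::zeros);
  mat dZxall(B * T, 3 * u);
  mat dWhrz(u, 2 * u, fill::zeros), dWhn(u, u, fill::zeros);
  mat dh(B, u);
  for (uword ti = T; ti-- > 0;) {
    const mat& r = cache.R.slice(ti);
    const mat& z = cache.Z.slice(ti);
    const mat& n = cache.N.slice(ti);
    dh = dHout.slice(ti) + carry;
    mat dn_pre = dh % (1.0 - z) % (1.0 - square(n));
    mat dz_pre = (ti > 0)
      ? mat(dh % (cache.H.slice(ti - 1) - n) % z % (1.0 - z))
      : mat(dh % (-n) % z % (1.0 - z));
    mat drh = dn_pre * Whn.t();
    mat dr_pre = (ti > 0)
      ? mat((drh % cache.H.slice(ti - 1)) % r % (1.0 - r))
      : mat(zeros(B, u));
    auto rows = dZxall.rows(ti * B, ti * B + B - 1);
    rows.cols(0, u - 1) = dr_pre;
    rows.cols(u, 2 * u - 1) = dz_pre;
    rows.cols(2 * u, 3 * u - 1) = dn_pre;
    carry = dh % z + join_rows(dr_pre, dz_pre) * Whrz.t();
    if (ti > 0) {
      carry += drh % r;
      dWhrz += cache.H.slice(ti - 1).t() * join_rows(dr_pre, dz_pre);
      dWhn += (r % cache.H.slice(ti - 1)).t() * dn_pre;
    }
  }
  dWx = flatten_time(X).t() * dZxall;
  db = sum(dZxall, 0);
  dWh = join_rows(dWhrz, dWhn);
  return unflatten_time(dZxall * Wx.t(), B, X.n_cols, T);
}

// ---------------------------------------------------------------- bilstm --

struct BiLstmCache { LstmCache fwd, bwd; cube Hcat; };

static const cube& bilstm_forward(const cube& X, const std::vector<mat>& W,
                                  size_t off, BiLstmCache& cache) {
  lstm_forward(X, W[off], W[off + 1], W[off + 2], true, cache.fwd);
  lstm_forward(X, W[off + 3], W[off + 4], W[off + 5], false, cache.bwd);
  const uword B = X.n_rows, T = X.n_slices, u = cache.fwd.H.n_cols;
  cache.Hcat.set_size(B, 2 * u, T);
  for (uword t = 0; t < T; ++t) {
    cache.Hcat.slice(t).cols(0, u - 1) = cache.fwd.H.slice(t);
    cache.Hcat.slice(t).cols(u, 2 * u - 1) = cache.bwd.H.slice(t);
  }
  return cache.Hcat;
}

static cube bilstm_backward(const cube& X, const std::vector<mat>& W,
                            size_t off, const BiLstmCache& cache,
                            const cube& dHout, std::vector<mat>& G) {
  const uword B = X.n_rows, T = X.n_slices;
  const uword u = W[off].n_cols / 4;
  cube dHf(B, u, T), dHb(B, u, T);
  for (uword t = 0; t < T; ++t) {
    dHf.slice(t) = dHout.slice(t).cols(0, u - 1);
    dHb.slice(t) = dHout.slice(t).cols(u, 2 * u - 1);
  }
  cube dX(B, X.n_cols, T, fill::zeros);
  lstm_backward(X, W[off], W[off + 1], cache.fwd, dHf, true,
                G[off], G[off + 1], G[off + 2], dX);
  lstm_backward(X, W[off + 3], W[off + 4], cache.bwd, dHb, false,
                G[off + 3], G[off + 4], G[off + 5], dX);
  return dX;
}

// ---------------------------------------------------------------- net -----

static Arch parse_arch(const Rcpp::List& arch) {
  Arch a;
  a.conv_filters = Rcpp::as<int>(arch["conv_filters"]);
  a.conv_softmax = Rcpp::as<std::string>(arch["conv_activation"]) == "softmax";
  a.rec_type = Rcpp::as<std::vector<int>>(arch["rec_type"]);
  a.rec_units = Rcpp::as<std::vector<int>>(arch["rec_units"]);
  a.dropout = Rcpp::as<double>(arch["dropout"]);
  a.T = Rcpp::as<int>(arch["window_length"]);
  a.rec_input.resize(a.rec_type.size());
  int d = a.conv_filters;
  for (size_t l = 0; l < a.rec_type.size(); ++l) {
    a.rec_input[l] = d;
    d = (a.rec_type[l] == REC_BILSTM) ? 2 * a.rec_units[l] : a.rec_units[l];
  }
  return a;
}

static int weights_per_layer(int type) {
  switch (type) {
    case REC_RNN: case REC_LSTM: case REC_GRU1: return 3;
    case REC_GRU2: return 4;
    case REC_BILSTM: return 6;
  }
  Rcpp::stop("unknown recurrent layer type");
}

struct NetCache {
  ConvCache conv;
  std::vector<RnnCache> rnn;
  std::vector<LstmCache> lstm;
  std::vector<Gru2Cache> gru2;
  std::vector<Gru1Cache> gru1;
  std::vector<BiLstmCache> bilstm;
  mat feat;                    // dense-layer input (post-dropout if training)
  mat mask;                    // dropout mask (training only)
  vec prob;
};

// output sequence of recurrent layer l (-1 = the conv front end)
static const cube& layer_output(const Arch& a, const NetCache& nc, int l) {
  if (l < 0) return nc.conv.A;
  switch (a.rec_type[l]) {
    case REC_RNN: return nc.rnn[l].H;
    case REC_LSTM: return nc.lstm[l].H;
    case REC_GRU2: return nc.gru2[l].H;
    case REC_GRU1: return nc.gru1[l].H;
    case REC_BILSTM: return nc.bilstm[l].Hcat;
  }
  Rcpp::stop("unknown recurrent layer type");
}

// forward pass; when training, applies inverted dropout using rng
static vec net_forward(const Arch& a, const std::vector<mat>& W,
                       const mat& Xb, bool training, std::mt19937& rng,
                       NetCache& nc) {
  const size_t L = a.rec_type.size();
  nc.rnn.resize(L); nc.lstm.resize(L); nc.gru2.resize(L);
  nc.gru1.resize(L); nc.bilstm.resize(L);

  conv_forward(Xb, W[0], W[1], a.conv_softmax, nc.conv);
  size_t off = 2;
  for (size_t l = 0; l < L; ++l) {
    const cube& X = layer_output(a, nc, int(l) - 1);
    switch (a.rec_type[l]) {
      case REC_RNN:
        rnn_forward(X, W[off], W[off + 1], W[off + 2], nc.rnn[l]); break;
      case REC_LSTM:
        lstm_forward(X, W[off], W[off + 1], W[off + 2], true, nc.lstm[l]); break;
      case REC_GRU2:
        gru2_forward(X, W[off], W[off + 1], W[off + 2], W[off + 3], nc.gru2[l]); break;
      case REC_GRU1:
        gru1_forward(X, W[off], W[off + 1], W[off + 2], nc.gru1[l]); break;
      case REC_BILSTM:
        bilstm_forward(X, W, off, nc.bilstm[l]); break;
    }
    off += weights_per_layer(a.rec_type[l]);
  }
  const cube& Hlast = layer_output(a, nc, int(L) - 1);
  nc.feat = Hlast.slice(Hlast.n_slices - 1);  // last layer: final state

  if (training && a.dropout > 0) {
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    nc.mask.set_size(nc.feat.n_rows, nc.feat.n_cols);
    const double keep = 1.0 - a.dropout;
    for (uword j = 0; j < nc.mask.n_cols; ++j)
      for (uword i = 0; i < nc.mask.n_rows; ++i)
        nc.mask(i, j) = (unif(rng) < keep) ? 1.0 / keep : 0.0;
    nc.feat %= nc.mask;
  } else {
    nc.mask.reset();
  }
  nc.prob = 1.0 / (1.0 + exp(-(nc.feat * W[W.size() - 2] +
                               as_scalar(W[W.size() - 1]))));
  return nc.prob;
}

static void net_backward(const Arch& a, const std::vector<mat>& W,
                         const vec& y, NetCache& nc, std::vector<mat>& G) {
  const size_t L = a.rec_type.size();
  const uword B = y.n_elem;
  const size_t dense_off = W.size() - 2;

  vec dpre = (nc.prob - y) / double(B);
  G[dense_off] = nc.feat.t() * dpre;
  G[dense_off + 1] = mat(1, 1, fill::value(accu(dpre)));
  mat dfeat = dpre * W[dense_off].t();
  if (nc.mask.n_elem > 0) dfeat %= nc.mask;

  // seed gradient only at the final time step of the last recurrent layer
  cube dH(dfeat.n_rows, dfeat.n_cols, a.T, fill::zeros);
  dH.slice(a.T - 1) = dfeat;

  size_t off = dense_off;
  for (size_t l = L; l-- > 0;) {
    off -= weights_per_layer(a.rec_type[l]);
    const cube& X = layer_output(a, nc, int(l) - 1);
    cube dX;
    switch (a.rec_type[l]) {
      case REC_RNN:
        dX = rnn_backward(X, W[off], W[off + 1], nc.rnn[l], dH,
                          G[off], G[off + 1], G[off + 2]); break;
      case REC_LSTM:
        dX.zeros(X.n_rows, X.n_cols, X.n_slices);
        lstm_backward(X, W[off], W[off + 1], nc.lstm[l], dH, true,
                      G[off], G[off + 1], G[off + 2], dX); break;
      case REC_GRU2:
        dX = gru2_backward(X, W[off], W[off + 1], nc.gru2[l], dH,
                           G[off], G[off + 1], G[off + 2], G[off + 3]); break;
      case REC_GRU1:
        dX = gru1_backward(X, W[off], W[off + 1], nc.gru1[l], dH,
                           G[off], G[off + 1], G[off + 2]); break;
      case REC_BILSTM:
        dX = bilstm_backward(X, W, off, nc.bilstm[l], dH, G); break;
    }
    dH = std::move(dX);
  }
  conv_backward(dH, a.conv_softmax, nc.conv, G[0], G[1]);
}

static double bce_loss(const vec& prob, const vec& y) {
  const double eps = 1e-7;
  vec p = clamp(prob, eps, 1.0 - eps);
  return -mean(y % log(p) + (1.0 - y) % log(1.0 - p));
}

static std::vector<mat> weights_from_list(const Rcpp::List& weights) {
  std::vector<mat> W(weights.size());
  for (int i = 0; i < weights.size(); ++i)
    W[i] = Rcpp::as<mat>(weights[i]);
  return W;
}

static Rcpp::List weights_to_list(const std::vector<mat>& W,
                                  const Rcpp::List& proto) {
  Rcpp::List out(W.size());
  out.names() = proto.names();
  for (size_t i = 0; i < W.size(); ++i) out[i] = Rcpp::wrap(W[i]);
  return out;
}

// [[Rcpp::export]]
arma::vec nn_predict_cpp(Rcpp::List weights, Rcpp::List arch, arma::mat X) {
  Arch a = parse_arch(arch);
  std::vector<mat> W = weights_from_list(weights);
  std::mt19937 rng(0);
  const uword n = X.n_rows, chunk = 256;
  vec prob(n);
  NetCache nc;
  for (uword s = 0; s < n; s += chunk) {
    uword e = std::min(s + chunk, n) - 1;
    prob.subvec(s, e) = net_forward(a, W, X.rows(s, e), false, rng, nc);
  }
  return prob;
}

// loss and analytic gradients for one batch, dropout off; used by the
// finite-difference gradient tests
// [[Rcpp::export]]
Rcpp::List nn_loss_grad_cpp(Rcpp::List weights, Rcpp::List arch,
                            arma::mat X, arma::vec y) {
  Arch a = parse_arch(arch);
  a.dropout = 0.0;
  std::vector<mat> W = weights_from_list(weights);
  std::vector<mat> G(W.size());
  std::mt19937 rng(0);
  NetCache nc;
  vec prob = net_forward(a, W, X, true, rng, nc);
  double L = bce_loss(prob, y);
  net_backward(a, W, y, nc, G);
  return Rcpp::List::create(
    Rcpp::Named("loss") = L,
    Rcpp::Named("grads") = weights_to_list(G, weights));
}

// [[Rcpp::export]]
Rcpp::List nn_train_cpp(Rcpp::List weights, Rcpp::List arch,
                        arma::mat X, arma::vec y,
                        Rcpp::Nullable<Rcpp::NumericMatrix> Xval,
                        Rcpp::Nullable<Rcpp::NumericVector> yval,
                        int epochs, int batch_size, double lr,
                        int seed, double threshold) {
  Arch a = parse_arch(arch);
  std::vector<mat> W = weights_from_list(weights);
  std::vector<mat> G(W.size()), M(W.size()), V(W.size());
  for (size_t i = 0; i < W.size(); ++i) {
    M[i] = mat(W[i].n_rows, W[i].n_cols, fill::zeros);
    V[i] = mat(W[i].n_rows, W[i].n_cols, fill::zeros);
  }

  bool has_val = Xval.isNotNull() && yval.isNotNull();
  mat Xv; vec yv;
  if (has_val) {
    Xv = Rcpp::as<mat>(Xval.get());
    yv = Rcpp::as<vec>(yval.get());
  }

  const double b1 = 0.9, b2 = 0.999, adam_eps = 1e-7;
  std::mt19937 rng(static_cast<unsigned>(seed));
  const uword n = X.n_rows;
  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;

  vec tr_loss(epochs), tr_acc(epochs);
  vec va_loss(epochs, fill::value(datum::nan));
  vec va_acc(epochs, fill::value(datum::nan));
  long step = 0;
  NetCache nc;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double loss_sum = 0.0, correct = 0.0;
    for (uword s = 0; s < n; s += batch_size) {
      uword e = std::min<uword>(s + batch_size, n);
      uvec bi(e - s);
      for (uword i = s; i < e; ++i) bi[i - s] = idx[i];
      mat Xb = X.rows(bi);
      vec yb = y.elem(bi);

      vec prob = net_forward(a, W, Xb, true, rng, nc);
      double L = bce_loss(prob, yb);
      if (!std::isfinite(L))
        Rcpp::stop("training diverged: non-finite loss at epoch %d", ep + 1);
      loss_sum += L * yb.n_elem;
      correct += accu((prob >= threshold) == (yb >= 0.5));

      net_backward(a, W, yb, nc, G);
      ++step;
      const double bc1 = 1.0 - std::pow(b1, double(step));
      const double bc2 = 1.0 - std::pow(b2, double(step));
      for (size_t i = 0; i < W.size(); ++i) {
        M[i] *= b1; M[i] += (1.0 - b1) * G[i];
        V[i] *= b2; V[i] += (1.0 - b2) * square(G[i]);
        W[i] -= lr * (M[i] / bc1) / (sqrt(V[i] / bc2) + adam_eps);
      }
    }
    tr_loss[ep] = loss_sum / double(n);
    tr_acc[ep] = correct / double(n);
    if (has_val) {
      vec pv(yv.n_elem);
      for (uword s = 0; s < Xv.n_rows; s += 256) {
        uword e = std::min<uword>(s + 256, Xv.n_rows) - 1;
        pv.subvec(s, e) = net_forward(a, W, Xv.rows(s, e), false, rng, nc);
      }
      va_loss[ep] = bce_loss(pv, yv);
      va_acc[ep] = double(accu((pv >= threshold) == (yv >= 0.5))) / yv.n_elem;
    }
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
    Rcpp::Named("weights") = weights_to_list(W, weights),
    Rcpp::Named("train_loss") = tr_loss,
    Rcpp::Named("train_acc") = tr_acc,
    Rcpp::Named("val_loss") = va_loss,
    Rcpp::Named("val_acc") = va_acc);
}
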