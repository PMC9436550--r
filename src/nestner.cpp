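// Neural core: character CNN, multi-layer BiLSTM, head/tail projections,
// biaffine span scorer, boundary head, and manual reverse-mode gradients.
// All randomness (dropout) draws from R's RNG so set.seed() governs
// training reproducibility end to end.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;

static inline vec sigmoid_vec(const vec& x) { return 1.0 / (1.0 + arma::exp(-x)); }

static mat dropout_mask(int rows, int cols, double p) {
  mat m(rows, cols, arma::fill::ones);
  if (p <= 0.0) return m;
  double keep = 1.0 - p;
  for (int j = 0; j < cols; ++j)
    for (int i = 0; i < rows; ++i)
      m(i, j) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
  return m;
}

static vec softmax_vec(const vec& x) {
  vec z = arma::exp(x - x.max());
  return z / arma::accu(z);
}

// ---------------------------------------------------------------------------
// Character CNN
// ---------------------------------------------------------------------------

struct CharCache {
  mat emb;                       // dc x padded_len
  int orig_len;
  std::vector<arma::uvec> argmax; // per width: argmax position per filter
};

// forward for one token; chars are 0-based rows of E_char
static vec charcnn_fwd(const arma::ivec& chars, const mat& E_char,
                       const std::vector<mat>& convW, const std::vector<vec>& convb,
                       const arma::ivec& widths, CharCache* cache) {
  int dc = E_char.n_cols;
  int len = chars.n_elem;
  int maxw = widths.max();
  int plen = std::max(len, maxw);
  mat emb(dc, plen, arma::fill::zeros);
  for (int j = 0; j < len; ++j) emb.col(j) = E_char.row(chars[j]).t();
  int total = 0;
  for (size_t w = 0; w < convW.size(); ++w) total += convW[w].n_rows;
  vec out(total);
  if (cache) { cache->emb = emb; cache->orig_len = len; cache->argmax.resize(convW.size()); }
  int off = 0;
  for (size_t w = 0; w < convW.size(); ++w) {
    int k = widths[w];
    int F = convW[w].n_rows;
    int npos = plen - k + 1;
    mat scores(F, npos);
    for (int p = 0; p < npos; ++p) {
      vec win = arma::vectorise(emb.cols(p, p + k - 1));
      scores.col(p) = convW[w] * win + convb[w];
    }
    arma::uvec amax(F);
    for (int f = 0; f < F; ++f) {
      arma::uword a;
      out[off + f] = scores.row(f).max(a);
      amax[f] = a;
    }
    if (cache) cache->argmax[w] = amax;
    off += F;
  }
  return out;
}

// backward: dout (total filters) -> grads of conv params and char table
static void charcnn_bwd(const arma::ivec& chars, const CharCache& cache,
                        const std::vector<mat>& convW, const arma::ivec& widths,
                        const vec& dout,
                        std::vector<mat>& dconvW, std::vector<vec>& dconvb, mat& dE_char) {
  int dc = cache.emb.n_rows;
  mat demb(dc, cache.emb.n_cols, arma::fill::zeros);
  int off = 0;
  for (size_t w = 0; w < convW.size(); ++w) {
    int k = widths[w];
    int F = convW[w].n_rows;
    for (int f = 0; f < F; ++f) {
      double g = dout[off + f];
      if (g == 0.0) continue;
      int p = cache.argmax[w][f];
      vec win = arma::vectorise(cache.emb.cols(p, p + k - 1));
      dconvW[w].row(f) += g * win.t();
      dconvb[w][f] += g;
      vec dwin = convW[w].row(f).t() * g;
      demb.cols(p, p + k - 1) += arma::reshape(dwin, dc, k);
    }
    off += F;
  }
  for (int j = 0; j < cache.orig_len; ++j)
    dE_char.row(chars[j]) += demb.col(j).t();
}

// ---------------------------------------------------------------------------
// LSTM (one direction, one layer)
// ---------------------------------------------------------------------------

struct LstmCache {
  mat I, Fg, G, O, C, Tc, H; // gates, cell, tanh(cell), hidden; each h x N
};

// gate layout in the 4h preactivation: [input; forget; candidate; output]
static void lstm_dir_fwd(const mat& X, const mat& W, const mat& R, const vec& b,
                         bool reverse, LstmCache& cc) {
  int N = X.n_cols, h = R.n_cols;
  cc.I.set_size(h, N); cc.Fg.set_size(h, N); cc.G.set_size(h, N);
  cc.O.set_size(h, N); cc.C.set_size(h, N); cc.Tc.set_size(h, N); cc.H.set_size(h, N);
  vec hprev(h, arma::fill::zeros), cprev(h, arma::fill::zeros);
  for (int s = 0; s < N; ++s) {
    int t = reverse ? (N - 1 - s) : s;
    vec a = W * X.col(t) + R * hprev + b;
    vec ig = sigmoid_vec(a.subvec(0, h - 1));
    vec fg = sigmoid_vec(a.subvec(h, 2 * h - 1));
    vec gg = arma::tanh(a.subvec(2 * h, 3 * h - 1));
    vec og = sigmoid_vec(a.subvec(3 * h, 4 * h - 1));
    vec c = fg % cprev + ig % gg;
    vec tc = arma::tanh(c);
    vec hh = og % tc;
    cc.I.col(t) = ig; cc.Fg.col(t) = fg; cc.G.col(t) = gg; cc.O.col(t) = og;
    cc.C.col(t) = c; cc.Tc.col(t) = tc; cc.H.col(t) = hh;
    hprev = hh; cprev = c;
  }
}

static void lstm_dir_bwd(const mat& X, const mat& W, const mat& R,
                         bool reverse, const LstmCache& cc, const mat& dH,
                         mat& dX, mat& dW, mat& dR, vec& db) {
  int N = X.n_cols, h = R.n_cols;
  vec dh_rec(h, arma::fill::zeros), dc_rec(h, arma::fill::zeros);
  for (int s = N - 1; s >= 0; --s) {
    int t = reverse ? (N - 1 - s) : s;
    int tprev = reverse ? (t + 1) : (t - 1);
    bool has_prev = (s > 0);
    vec dh = dH.col(t) + dh_rec;
    vec tc = cc.Tc.col(t);
    vec dog = dh % tc;
    vec dc = dc_rec + dh % cc.O.col(t) % (1.0 - tc % tc);
    vec cprev = has_prev ? vec(cc.C.col(tprev)) : vec(h, arma::fill::zeros);
    vec dig = dc % cc.G.col(t);
    vec dfg = dc % cprev;
    vec dgg = dc % cc.I.col(t);
    dc_rec = dc % cc.Fg.col(t);
    vec da(4 * h);
    da.subvec(0, h - 1)         = dig % cc.I.col(t) % (1.0 - cc.I.col(t));
    da.subvec(h, 2 * h - 1)     = dfg % cc.Fg.col(t) % (1.0 - cc.Fg.col(t));
    da.subvec(2 * h, 3 * h - 1) = dgg % (1.0 - cc.G.col(t) % cc.G.col(t));
    da.subvec(3 * h, 4 * h - 1) = dog % cc.O.col(t) % (1.0 - cc.O.col(t));
    vec hprev = has_prev ? vec(cc.H.col(tprev)) : vec(h, arma::fill::zeros);
    dW += da * X.col(t).t();
    dR += da * hprev.t();
    db += da;
    dX.col(t) += W.t() * da;
    dh_rec = R.t() * da;
  }
}

// ---------------------------------------------------------------------------
// Shared forward machinery
// ---------------------------------------------------------------------------

struct NetConfig {
  int layers, h, m, n_class, maxlen;
  bool use_char, bias_aug, post_softmax, boundary_relu, loss_sum, training;
  double alpha, emb_dropout, lstm_dropout, mlp_dropout;
  arma::ivec widths;
};

static NetConfig read_cfg(const List& cfg) {
  NetConfig c;
  c.layers = as<int>(cfg["lstm_layers"]);
  c.h = as<int>(cfg["hidden_per_dir"]);
  c.m = as<int>(cfg["mlp_size"]);
  c.n_class = as<int>(cfg["n_class"]);
  c.maxlen = as<int>(cfg["max_span_length"]);
  c.use_char = as<bool>(cfg["use_char"]);
  c.bias_aug = as<bool>(cfg["bias_aug"]);
  c.post_softmax = as<bool>(cfg["post_softmax"]);
  c.boundary_relu = as<bool>(cfg["boundary_relu"]);
  c.loss_sum = as<bool>(cfg["loss_sum"]);
  c.training = as<bool>(cfg["training"]);
  c.alpha = as<double>(cfg["alpha"]);
  c.emb_dropout = as<double>(cfg["emb_dropout"]);
  c.lstm_dropout = as<double>(cfg["lstm_dropout"]);
  c.mlp_dropout = as<double>(cfg["mlp_dropout"]);
  c.widths = as<arma::ivec>(cfg["char_widths"]);
  return c;
}

static std::string key(const char* stem, const char* dir, int layer) {
  return std::string(stem) + "_" + dir + "_" + std::to_string(layer);
}

struct ForwardCache {
  mat X, Xdrop, Mx;                  // embedding block
  std::vector<CharCache> charcaches;
  std::vector<LstmCache> fwd, bwd;   // per layer
  std::vector<mat> layer_in;         // input fed to each layer (post dropout)
  std::vector<mat> Ml;               // inter-layer dropout masks
  mat H;                             // final 2h x N
  mat s_pre, e_pre, s_act, e_act, s_rep, e_rep, Ms, Me, S, E; // projections
};

// full encoder forward: embeddings -> BiLSTM stack -> head/tail projections
static void encoder_fwd(const arma::ivec& word_idx, const List& chars,
                        const Nullable<NumericMatrix>& lm,
                        const List& params, const NetConfig& c, ForwardCache& fc) {
  int N = word_idx.n_elem;
  const mat E_word = as<mat>(params["E_word"]);
  int dw = E_word.n_cols;
  mat Xword(dw, N);
  for (int t = 0; t < N; ++t) Xword.col(t) = E_word.row(word_idx[t]).t();

  mat Xchar;
  std::vector<mat> convW; std::vector<vec> convb;
  if (c.use_char) {
    const mat E_char = as<mat>(params["E_char"]);
    for (arma::uword w = 0; w < c.widths.n_elem; ++w) {
      convW.push_back(as<mat>(params[std::string("conv_W") + std::to_string(c.widths[w])]));
      convb.push_back(as<vec>(params[std::string("conv_b") + std::to_string(c.widths[w])]));
    }
    fc.charcaches.resize(N);
    for (int t = 0; t < N; ++t) {
      arma::ivec ch = as<arma::ivec>(chars[t]) - 1;
      vec v = charcnn_fwd(ch, E_char, convW, convb, c.widths, &fc.charcaches[t]);
      if (t == 0) Xchar.set_size(v.n_elem, N);
      Xchar.col(t) = v;
    }
  }

  // concatenation order: contextual block, character block, word block
  int dlm = lm.isNotNull() ? NumericMatrix(lm).nrow() : 0;
  int dch = c.use_char ? Xchar.n_rows : 0;
  fc.X.set_size(dlm + dch + dw, N);
  if (dlm > 0) fc.X.rows(0, dlm - 1) = as<mat>(NumericMatrix(lm));
  if (dch > 0) fc.X.rows(dlm, dlm + dch - 1) = Xchar;
  fc.X.rows(dlm + dch, dlm + dch + dw - 1) = Xword;

  fc.Mx = c.training ? dropout_mask(fc.X.n_rows, N, c.emb_dropout)
                     : mat(fc.X.n_rows, N, arma::fill::ones);
  fc.Xdrop = fc.X % fc.Mx;

  fc.fwd.resize(c.layers); fc.bwd.resize(c.layers);
  fc.layer_in.resize(c.layers); fc.Ml.resize(c.layers);
  mat cur = fc.Xdrop;
  for (int l = 0; l < c.layers; ++l) {
    fc.layer_in[l] = cur;
    const mat Wf = as<mat>(params[key("lstm_W", "f", l + 1)]);
    const mat Rf = as<mat>(params[key("lstm_R", "f", l + 1)]);
    const vec bf = as<vec>(params[key("lstm_b", "f", l + 1)]);
    const mat Wb = as<mat>(params[key("lstm_W", "b", l + 1)]);
    const mat Rb = as<mat>(params[key("lstm_R", "b", l + 1)]);
    const vec bb = as<vec>(params[key("lstm_b", "b", l + 1)]);
    lstm_dir_fwd(cur, Wf, Rf, bf, false, fc.fwd[l]);
    lstm_dir_fwd(cur, Wb, Rb, bb, true, fc.bwd[l]);
    mat H = arma::join_cols(fc.fwd[l].H, fc.bwd[l].H);
    if (l < c.layers - 1) {
      fc.Ml[l] = c.training ? dropout_mask(H.n_rows, N, c.lstm_dropout)
                            : mat(H.n_rows, N, arma::fill::ones);
      H = H % fc.Ml[l];
    }
    cur = H;
  }
  fc.H = cur;

  const mat Ws = as<mat>(params["mlp_s_W"]); const vec bs = as<vec>(params["mlp_s_b"]);
  const mat We = as<mat>(params["mlp_e_W"]); const vec be = as<vec>(params["mlp_e_b"]);
  fc.s_pre = Ws * fc.H; fc.s_pre.each_col() += bs;
  fc.e_pre = We * fc.H; fc.e_pre.each_col() += be;
  fc.s_act = arma::clamp(fc.s_pre, 0.0, arma::datum::inf);
  fc.e_act = arma::clamp(fc.e_pre, 0.0, arma::datum::inf);
  if (c.post_softmax) {
    fc.s_rep.set_size(arma::size(fc.s_act)); fc.e_rep.set_size(arma::size(fc.e_act));
    for (int t = 0; t < N; ++t) {
      fc.s_rep.col(t) = softmax_vec(fc.s_act.col(t));
      fc.e_rep.col(t) = softmax_vec(fc.e_act.col(t));
    }
  } else { fc.s_rep = fc.s_act; fc.e_rep = fc.e_act; }
  fc.Ms = c.training ? dropout_mask(c.m, N, c.mlp_dropout) : mat(c.m, N, arma::fill::ones);
  fc.Me = c.training ? dropout_mask(c.m, N, c.mlp_dropout) : mat(c.m, N, arma::fill::ones);
  fc.S = fc.s_rep % fc.Ms;
  fc.E = fc.e_rep % fc.Me;
}

// backward through projections and encoder given dS, dE (m x N each)
static void encoder_bwd(const arma::ivec& word_idx, const List& chars,
                        const List& params, const NetConfig& c, const ForwardCache& fc,
                        mat dS, mat dE, List& grads) {
  int N = word_idx.n_elem;
  dS %= fc.Ms; dE %= fc.Me;
  if (c.post_softmax) {
    mat dSa(arma::size(dS)), dEa(arma::size(dE));
    for (int t = 0; t < N; ++t) {
      vec p = fc.s_rep.col(t), g = dS.col(t);
      dSa.col(t) = p % (g - arma::dot(g, p));
      vec pe = fc.e_rep.col(t), ge = dE.col(t);
      dEa.col(t) = pe % (ge - arma::dot(ge, pe));
    }
    dS = dSa; dE = dEa;
  }
  mat ds_pre = dS % arma::conv_to<mat>::from(fc.s_pre > 0.0);
  mat de_pre = dE % arma::conv_to<mat>::from(fc.e_pre > 0.0);

  const mat Ws = as<mat>(params["mlp_s_W"]);
  const mat We = as<mat>(params["mlp_e_W"]);
  grads["mlp_s_W"] = wrap(mat(ds_pre * fc.H.t()));
  grads["mlp_s_b"] = wrap(vec(arma::sum(ds_pre, 1)));
  grads["mlp_e_W"] = wrap(mat(de_pre * fc.H.t()));
  grads["mlp_e_b"] = wrap(vec(arma::sum(de_pre, 1)));
  mat dH = Ws.t() * ds_pre + We.t() * de_pre;

  for (int l = c.layers - 1; l >= 0; --l) {
    if (l < c.layers - 1) dH %= fc.Ml[l];
    mat dHf = dH.rows(0, c.h - 1);
    mat dHb = dH.rows(c.h, 2 * c.h - 1);
    const mat Wf = as<mat>(params[key("lstm_W", "f", l + 1)]);
    const mat Rf = as<mat>(params[key("lstm_R", "f", l + 1)]);
    const mat Wb = as<mat>(params[key("lstm_W", "b", l + 1)]);
    const mat Rb = as<mat>(params[key("lstm_R", "b", l + 1)]);
    mat dX(fc.layer_in[l].n_rows, N, arma::fill::zeros);
    mat dWf(arma::size(Wf), arma::fill::zeros), dRf(arma::size(Rf), arma::fill::zeros);
    mat dWb(arma::size(Wb), arma::fill::zeros), dRb(arma::size(Rb), arma::fill::zeros);
    vec dbf(4 * c.h, arma::fill::zeros), dbb(4 * c.h, arma::fill::zeros);
    lstm_dir_bwd(fc.layer_in[l], Wf, Rf, false, fc.fwd[l], dHf, dX, dWf, dRf, dbf);
    lstm_dir_bwd(fc.layer_in[l], Wb, Rb, true, fc.bwd[l], dHb, dX, dWb, dRb, dbb);
    grads[key("lstm_W", "f", l + 1)] = wrap(dWf);
    grads[key("lstm_R", "f", l + 1)] = wrap(dRf);
    grads[key("lstm_b", "f", l + 1)] = wrap(dbf);
    grads[key("lstm_W", "b", l + 1)] = wrap(dWb);
    grads[key("lstm_R", "b", l + 1)] = wrap(dRb);
    grads[key("lstm_b", "b", l + 1)] = wrap(dbb);
    dH = dX;
  }

  // dH is now the gradient wrt the dropped concatenated embedding
  mat dXemb = dH % fc.Mx;
  const mat E_word = as<mat>(params["E_word"]);
  int dw = E_word.n_cols;
  // block offsets: [lm | char | word]
  int dch = 0;
  if (c.use_char) {
    for (arma::uword w = 0; w < c.widths.n_elem; ++w)
      dch += as<mat>(params[std::string("conv_W") + std::to_string(c.widths[w])]).n_rows;
  }
  int dlm = fc.X.n_rows - dch - dw;

  mat dE_word(arma::size(E_word), arma::fill::zeros);
  for (int t = 0; t < N; ++t)
    dE_word.row(word_idx[t]) += dXemb.col(t).subvec(dlm + dch, dlm + dch + dw - 1).t();
  grads["E_word"] = wrap(dE_word);

  if (c.use_char) {
    const mat E_char = as<mat>(params["E_char"]);
    std::vector<mat> convW;
    std::vector<mat> dcw; std::vector<vec> dcb;
    for (arma::uword w = 0; w < c.widths.n_elem; ++w) {
      mat W = as<mat>(params[std::string("conv_W") + std::to_string(c.widths[w])]);
      convW.push_back(W);
      dcw.push_back(mat(arma::size(W), arma::fill::zeros));
      dcb.push_back(vec(W.n_rows, arma::fill::zeros));
    }
    mat dE_char(arma::size(E_char), arma::fill::zeros);
    for (int t = 0; t < N; ++t) {
      arma::ivec ch = as<arma::ivec>(chars[t]) - 1;
      vec dout = dXemb.col(t).subvec(dlm, dlm + dch - 1);
      charcnn_bwd(ch, fc.charcaches[t], convW, c.widths, dout, dcw, dcb, dE_char);
    }
    grads["E_char"] = wrap(dE_char);
    for (arma::uword w = 0; w < c.widths.n_elem; ++w) {
      grads[std::string("conv_W") + std::to_string(c.widths[w])] = wrap(dcw[w]);
      grads[std::string("conv_b") + std::to_string(c.widths[w])] = wrap(dcb[w]);
    }
  }
}

// ---------------------------------------------------------------------------
// Biaffine span scores and boundary head
// ---------------------------------------------------------------------------

// scores(i,j,c) = s1_i' U1_c e1_j + U2 [s_i ; e_j] + b ; NA where not enumerated
static cube biaffine_scores(const mat& S, const mat& E, const cube& U1,
                            const mat& U2, const vec& b, int maxlen, bool bias_aug) {
  int N = S.n_cols, m = S.n_rows, Cp = U1.n_slices;
  mat S1 = bias_aug ? arma::join_cols(S, arma::ones<arma::rowvec>(N)) : S;
  mat E1 = bias_aug ? arma::join_cols(E, arma::ones<arma::rowvec>(N)) : E;
  mat U2s = U2.cols(0, m - 1), U2e = U2.cols(m, 2 * m - 1);
  mat As = U2s * S; // Cp x N, start contributions
  mat Ae = U2e * E;
  cube out(N, N, Cp);
  out.fill(NA_REAL);
  for (int c = 0; c < Cp; ++c) {
    mat M = S1.t() * U1.slice(c) * E1;
    for (int i = 0; i < N; ++i)
      for (int j = i; j < N && (j - i) < maxlen; ++j)
        out(i, j, c) = M(i, j) + As(c, i) + Ae(c, j) + b[c];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_char_cnn(IntegerVector chars, NumericMatrix E_char,
                           List conv_W, List conv_b, IntegerVector widths) {
  arma::ivec ch = as<arma::ivec>(chars) - 1;
  std::vector<mat> W; std::vector<vec> b;
  for (int i = 0; i < conv_W.size(); ++i) {
    W.push_back(as<mat>(conv_W[i]));
    b.push_back(as<vec>(conv_b[i]));
  }
  vec out = charcnn_fwd(ch, as<mat>(E_char), W, b, as<arma::ivec>(widths), nullptr);
  return wrap(out);
}

// [[Rcpp::export]]
List cpp_encode(IntegerVector word_idx, List chars, Nullable<NumericMatrix> lm,
                List params, List cfg) {
  NetConfig c = read_cfg(cfg);
  ForwardCache fc;
  arma::ivec wi = as<arma::ivec>(word_idx) - 1;
  encoder_fwd(wi, chars, lm, params, c, fc);
  return List::create(_["X"] = fc.X, _["H"] = fc.H,
                      _["s"] = fc.S, _["e"] = fc.E,
                      _["s_act"] = fc.s_act, _["e_act"] = fc.e_act);
}

// Evaluation-mode BiLSTM stack over an arbitrary input matrix (features x
// tokens); no dropout.
// [[Rcpp::export]]
NumericMatrix cpp_bilstm(NumericMatrix X, List params, int layers, int h) {
  mat cur = as<mat>(X);
  for (int l = 0; l < layers; ++l) {
    const mat Wf = as<mat>(params[key("lstm_W", "f", l + 1)]);
    const mat Rf = as<mat>(params[key("lstm_R", "f", l + 1)]);
    const vec bf = as<vec>(params[key("lstm_b", "f", l + 1)]);
    const mat Wb = as<mat>(params[key("lstm_W", "b", l + 1)]);
    const mat Rb = as<mat>(params[key("lstm_R", "b", l + 1)]);
    const vec bb = as<vec>(params[key("lstm_b", "b", l + 1)]);
    LstmCache cf, cb;
    lstm_dir_fwd(cur, Wf, Rf, bf, false, cf);
    lstm_dir_fwd(cur, Wb, Rb, bb, true, cb);
    cur = arma::join_cols(cf.H, cb.H);
  }
  return wrap(cur);
}

// [[Rcpp::export]]
List cpp_project(NumericMatrix H, NumericMatrix Ws, NumericVector bs,
                 NumericMatrix We, NumericVector be, bool post_softmax) {
  mat Hm = as<mat>(H);
  mat s = as<mat>(Ws) * Hm; s.each_col() += as<vec>(bs);
  mat e = as<mat>(We) * Hm; e.each_col() += as<vec>(be);
  s = arma::clamp(s, 0.0, arma::datum::inf);
  e = arma::clamp(e, 0.0, arma::datum::inf);
  if (post_softmax) {
    for (arma::uword t = 0; t < s.n_cols; ++t) {
      s.col(t) = softmax_vec(s.col(t));
      e.col(t) = softmax_vec(e.col(t));
    }
  }
  return List::create(_["s"] = s, _["e"] = e);
}

// [[Rcpp::export]]
NumericVector cpp_score_spans(NumericMatrix s, NumericMatrix e, NumericVector U1_arr,
                              NumericMatrix U2, NumericVector b, int maxlen, bool bias_aug) {
  mat S = as<mat>(s), E = as<mat>(e);
  IntegerVector dims = U1_arr.attr("dim");
  cube U1(U1_arr.begin(), dims[0], dims[1], dims[2]);
  cube out = biaffine_scores(S, E, U1, as<mat>(U2), as<vec>(b), maxlen, bias_aug);
  NumericVector res = wrap(out);
  return res;
}

// [[Rcpp::export]]
NumericMatrix cpp_boundary_logits(NumericMatrix s, NumericMatrix e,
                                  NumericMatrix U, NumericVector b, bool relu_act) {
  mat S = as<mat>(s), E = as<mat>(e);
  mat Z = arma::join_cols(S, E);
  if (relu_act) Z = arma::clamp(Z, 0.0, arma::datum::inf);
  mat O = as<mat>(U) * Z;
  O.each_col() += as<vec>(b);
  return wrap(O); // 2 x N, rows (O, I)
}

// Full evaluation-mode forward: span score tensor + boundary probabilities.
// [[Rcpp::export]]
List cpp_sentence_forward(IntegerVector word_idx, List chars, Nullable<NumericMatrix> lm,
                          List params, List cfg) {
  NetConfig c = read_cfg(cfg);
  c.training = false;
  ForwardCache fc;
  arma::ivec wi = as<arma::ivec>(word_idx) - 1;
  int N = wi.n_elem;
  encoder_fwd(wi, chars, lm, params, c, fc);
  IntegerVector dims = as<NumericVector>(params["U1"]).attr("dim");
  NumericVector U1_arr = params["U1"];
  cube U1(U1_arr.begin(), dims[0], dims[1], dims[2]);
  cube scores = biaffine_scores(fc.S, fc.E, U1, as<mat>(params["U2"]),
                                as<vec>(params["b_span"]), std::min(c.maxlen, N), c.bias_aug);
  mat Z = arma::join_cols(fc.S, fc.E);
  if (c.boundary_relu) Z = arma::clamp(Z, 0.0, arma::datum::inf);
  mat O = as<mat>(params["U_bnd"]) * Z;
  O.each_col() += as<vec>(params["b_bnd"]);
  mat bprob(N, 2);
  for (int t = 0; t < N; ++t) bprob.row(t) = softmax_vec(O.col(t)).t();
  return List::create(_["scores"] = wrap(scores), _["boundary"] = wrap(bprob));
}

// ---------------------------------------------------------------------------
// Fused loss + gradient for one sentence
// ---------------------------------------------------------------------------

// gold_labels: N x N integer matrix, 0-based class index (n_class-1 = non-entity),
// read only at enumerated (i <= j, length <= maxlen) cells.
// gold_boundary: length N, 0 = O, 1 = I.
// loss_mask: optional N x N 0/1; when present the span loss covers only cells == 1.
// [[Rcpp::export]]
List cpp_sentence_grad(IntegerVector word_idx, List chars, Nullable<NumericMatrix> lm,
                       IntegerMatrix gold_labels, IntegerVector gold_boundary,
                       Nullable<IntegerMatrix> loss_mask,
                       List params, List cfg) {
  NetConfig c = read_cfg(cfg);
  ForwardCache fc;
  arma::ivec wi = as<arma::ivec>(word_idx) - 1;
  int N = wi.n_elem;
  encoder_fwd(wi, chars, lm, params, c, fc);

  NumericVector U1_arr = params["U1"];
  IntegerVector dims = U1_arr.attr("dim");
  cube U1(U1_arr.begin(), dims[0], dims[1], dims[2]);
  const mat U2 = as<mat>(params["U2"]);
  const vec b_span = as<vec>(params["b_span"]);
  const mat U_bnd = as<mat>(params["U_bnd"]);
  const vec b_bnd = as<vec>(params["b_bnd"]);
  int Cp = c.n_class, m = c.m;
  int maxlen = std::min(c.maxlen, N);

  mat S1 = c.bias_aug ? arma::join_cols(fc.S, arma::ones<arma::rowvec>(N)) : mat(fc.S);
  mat E1 = c.bias_aug ? arma::join_cols(fc.E, arma::ones<arma::rowvec>(N)) : mat(fc.E);
  mat U2s = U2.cols(0, m - 1), U2e = U2.cols(m, 2 * m - 1);
  mat As = U2s * fc.S, Ae = U2e * fc.E;
  std::vector<mat> M(Cp);
  for (int cc = 0; cc < Cp; ++cc) M[cc] = S1.t() * U1.slice(cc) * E1;

  arma::imat gl = as<arma::imat>(gold_labels);
  arma::imat lmask;
  bool has_mask = loss_mask.isNotNull();
  if (has_mask) lmask = as<arma::imat>(IntegerMatrix(loss_mask));

  // span softmax cross-entropy and dscore
  double loss_b = 0.0;
  long n_spans = 0;
  std::vector<mat> D(Cp, mat(N, N, arma::fill::zeros));
  vec sc(Cp);
  for (int i = 0; i < N; ++i)
    for (int j = i; j < N && (j - i) < maxlen; ++j) {
      if (has_mask && lmask(i, j) == 0) continue;
      for (int cc = 0; cc < Cp; ++cc) sc[cc] = M[cc](i, j) + As(cc, i) + Ae(cc, j) + b_span[cc];
      vec p = softmax_vec(sc);
      int g = gl(i, j);
      loss_b += -std::log(std::max(p[g], 1e-300));
      for (int cc = 0; cc < Cp; ++cc) D[cc](i, j) = p[cc] - (cc == g ? 1.0 : 0.0);
      ++n_spans;
    }
  double wspan = 1.0;
  if (!c.loss_sum && n_spans > 0) { loss_b /= n_spans; wspan = 1.0 / n_spans; }
  for (int cc = 0; cc < Cp; ++cc) D[cc] *= wspan;

  // boundary head
  mat Z = arma::join_cols(fc.S, fc.E);
  mat Zact = c.boundary_relu ? mat(arma::clamp(Z, 0.0, arma::datum::inf)) : Z;
  mat O = U_bnd * Zact;
  O.each_col() += b_bnd;
  double loss_d = 0.0;
  mat dO(2, N);
  for (int t = 0; t < N; ++t) {
    vec p = softmax_vec(O.col(t));
    int g = gold_boundary[t]; // 0 = O, 1 = I
    loss_d += -std::log(std::max(p[g], 1e-300));
    dO(0, t) = p[0] - (g == 0 ? 1.0 : 0.0);
    dO(1, t) = p[1] - (g == 1 ? 1.0 : 0.0);
  }
  double wtok = 1.0;
  if (!c.loss_sum) { loss_d /= N; wtok = 1.0 / N; }
  dO *= wtok * c.alpha;

  // ----- backward -----
  List grads;
  // biaffine params
  int m1 = S1.n_rows;
  cube dU1(m1, m1, Cp, arma::fill::zeros);
  mat dU2(Cp, 2 * m, arma::fill::zeros);
  vec db_span(Cp, arma::fill::zeros);
  mat dS(m, N, arma::fill::zeros), dE(m, N, arma::fill::zeros);
  for (int cc = 0; cc < Cp; ++cc) {
    const mat& Dc = D[cc];
    dU1.slice(cc) = S1 * Dc * E1.t();
    mat dS1 = U1.slice(cc) * E1 * Dc.t();
    mat dE1 = U1.slice(cc).t() * S1 * Dc;
    dS += dS1.rows(0, m - 1);
    dE += dE1.rows(0, m - 1);
    vec ri = arma::sum(Dc, 1);  // over j, per start i
    vec cj = arma::sum(Dc, 0).t();
    dU2.submat(cc, 0, cc, m - 1) += (fc.S * ri).t();
    dU2.submat(cc, m, cc, 2 * m - 1) += (fc.E * cj).t();
    dS += U2s.row(cc).t() * ri.t();
    dE += U2e.row(cc).t() * cj.t();
    db_span[cc] = arma::accu(Dc);
  }
  grads["U1"] = wrap(dU1);
  grads["U2"] = wrap(dU2);
  grads["b_span"] = wrap(db_span);

  // boundary params
  grads["U_bnd"] = wrap(mat(dO * Zact.t()));
  grads["b_bnd"] = wrap(vec(arma::sum(dO, 1)));
  mat dZ = U_bnd.t() * dO;
  if (c.boundary_relu) dZ %= arma::conv_to<mat>::from(Z > 0.0);
  dS += dZ.rows(0, m - 1);
  dE += dZ.rows(m, 2 * m - 1);

  encoder_bwd(wi, chars, params, c, fc, dS, dE, grads);

  return List::create(_["loss_b"] = loss_b, _["loss_d"] = loss_d,
                      _["n_spans"] = (double)n_spans, _["grads"] = grads);
}
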