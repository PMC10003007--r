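// Probability-sparse self-attention encoder: forward pass, manual
// backpropagation and Adam training loop. All randomness is driven by an
// explicit std::mt19937_64 so results are reproducible across platforms.
#include <RcppArmadillo.h>
#include <map>
#include <random>
#include <string>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

typedef std::map<std::string, mat> ParamMap;

// ---------------------------------------------------------------------------
// small pieces

static inline mat elu(const mat& x) {
  mat y = x;
  uvec neg = find(x < 0.0);
  y.elem(neg) = exp(x.elem(neg)) - 1.0;
  return y;
}

// derivative expressed through the pre-activation
static inline mat elu_grad(const mat& pre) {
  mat g(pre.n_rows, pre.n_cols, fill::ones);
  uvec neg = find(pre < 0.0);
  g.elem(neg) = exp(pre.elem(neg));
  return g;
}

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// softmax over rows, numerically stable
static mat row_softmax(const mat& s) {
  mat z = s.each_col() - max(s, 1);
  z = exp(z);
  z.each_col() /= sum(z, 1);
  return z;
}

struct Config {
  int L, d, h, dh, layers, ff, stemKernel, convKernel, headKernel,
      headFilters, emb, nCells, stemThreshold, poolWidth;
  double alpha, peBase, c;
  bool usePE, measureExact;
  int stemStages, Ltok, Llast;
  std::vector<int> tokensPerLayer; // token count entering each encoder layer
};

static Config parse_config(const Rcpp::List& cfg) {
  Config c;
  c.L = cfg["inputLength"];
  c.d = cfg["embedDim"];
  c.h = cfg["heads"];
  c.dh = c.d / c.h;
  c.layers = cfg["layers"];
  c.ff = cfg["ffDim"];
  c.stemKernel = cfg["stemKernel"];
  c.convKernel = cfg["convKernel"];
  c.headKernel = cfg["headKernel"];
  c.headFilters = cfg["headFilters"];
  c.emb = cfg["embeddingSize"];
  c.nCells = cfg["nCells"];
  c.stemThreshold = cfg["stemThreshold"];
  c.poolWidth = cfg["poolWidth"];
  c.alpha = cfg["alpha"];
  c.peBase = cfg["peBase"];
  c.c = cfg["samplingFactor"];
  std::string pm = Rcpp::as<std::string>(cfg["positionMode"]);
  c.usePE = (pm == "fixed_absolute");
  std::string mm = Rcpp::as<std::string>(cfg["measureMode"]);
  c.measureExact = (mm == "exact");
  // stem geometry: single conv when L fits under the threshold, otherwise
  // alternating conv+pool stages until the token count fits
  c.stemStages = 0;
  int t = c.L;
  while (t > c.stemThreshold) {
    t /= c.poolWidth;
    c.stemStages++;
  }
  c.Ltok = t;
  c.tokensPerLayer.clear();
  for (int l = 0; l < c.layers; ++l) {
    c.tokensPerLayer.push_back(t);
    if (l < c.layers - 1) t /= c.poolWidth;
  }
  c.Llast = t;
  return c;
}

static ParamMap list_to_params(const Rcpp::List& plist) {
  ParamMap p;
  Rcpp::CharacterVector nm = plist.names();
  for (int i = 0; i < plist.size(); ++i) {
    std::string key = Rcpp::as<std::string>(nm[i]);
    Rcpp::RObject obj = plist[i];
    if (Rf_isMatrix(obj)) {
      p[key] = Rcpp::as<mat>(obj);
    } else {
      vec v = Rcpp::as<vec>(obj);
      p[key] = mat(v); // column vector
    }
  }
  return p;
}

static Rcpp::List params_to_list(const ParamMap& p) {
  Rcpp::List out;
  for (ParamMap::const_iterator it = p.begin(); it != p.end(); ++it)
    out[it->first] = it->second;
  return out;
}

// ---------------------------------------------------------------------------
// position embedding (Ltok x d), sinusoidal with configurable base

static mat position_embedding(int Ltok, int d, double base) {
  mat pe(Ltok, d, fill::zeros);
  for (int i = 0; i < d / 2; ++i) {
    double freq = std::pow(base, -2.0 * i / (double)d);
    for (int pos = 0; pos < Ltok; ++pos) {
      pe(pos, 2 * i) = std::sin(pos * freq);
      pe(pos, 2 * i + 1) = std::cos(pos * freq);
    }
  }
  return pe;
}

// [[Rcpp::export(name = ".cpp_position_embedding")]]
arma::mat cpp_position_embedding(int Ltok, int d, double base) {
  if (d % 2 != 0) Rcpp::stop("embedding width must be even");
  return position_embedding(Ltok, d, base);
}

// ---------------------------------------------------------------------------
// same-padding 1-D convolution over a (tokens x channels) matrix.
// W is ((w*Cin) x Cout), rows grouped by kernel offset.

static mat conv1d(const mat& X, const mat& W, const vec& b, int w) {
  int L = X.n_rows, Cin = X.n_cols, Cout = W.n_cols;
  int pad = (w - 1) / 2;
  mat Xp(L + w - 1, Cin, fill::zeros);
  Xp.rows(pad, pad + L - 1) = X;
  mat Y(L, Cout, fill::zeros);
  Y.each_row() += b.t();
  for (int j = 0; j < w; ++j)
    Y += Xp.rows(j, j + L - 1) * W.rows(j * Cin, (j + 1) * Cin - 1);
  return Y;
}

static void conv1d_backward(const mat& X, const mat& W, int w, const mat& dY,
                            mat& dX, mat& dW, vec& db) {
  int L = X.n_rows, Cin = X.n_cols;
  int pad = (w - 1) / 2;
  mat Xp(L + w - 1, Cin, fill::zeros);
  Xp.rows(pad, pad + L - 1) = X;
  mat dXp(L + w - 1, Cin, fill::zeros);
  dW.zeros(W.n_rows, W.n_cols);
  for (int j = 0; j < w; ++j) {
    dXp.rows(j, j + L - 1) += dY * W.rows(j * Cin, (j + 1) * Cin - 1).t();
    dW.rows(j * Cin, (j + 1) * Cin - 1) = Xp.rows(j, j + L - 1).t() * dY;
  }
  dX = dXp.rows(pad, pad + L - 1);
  db = sum(dY, 0).t();
}

// max pooling along the token axis, width == stride

static mat maxpool(const mat& X, int w, umat& argmax) {
  int Lout = X.n_rows / w, C = X.n_cols;
  mat Y(Lout, C);
  argmax.set_size(Lout, C);
  for (int t = 0; t < Lout; ++t)
    for (int c = 0; c < C; ++c) {
      int best = t * w;
      for (int j = 1; j < w; ++j)
        if (X(t * w + j, c) > X(best, c)) best = t * w + j;
      Y(t, c) = X(best, c);
      argmax(t, c) = best;
    }
  return Y;
}

static mat maxpool_backward(const mat& dY, const umat& argmax, int Lin) {
  mat dX(Lin, dY.n_cols, fill::zeros);
  for (uword t = 0; t < dY.n_rows; ++t)
    for (uword c = 0; c < dY.n_cols; ++c) dX(argmax(t, c), c) += dY(t, c);
  return dX;
}

// row-wise layer normalization with learnable gain/bias
static const double LN_EPS = 1e-5;

struct LNCache {
  mat xhat;    // normalized rows
  vec invstd;  // per-row 1/sqrt(var + eps)
};

static mat layernorm(const mat& X, const vec& g, const vec& b, LNCache& c) {
  vec mu = mean(X, 1);
  mat centered = X.each_col() - mu;
  vec var = mean(square(centered), 1);
  c.invstd = 1.0 / sqrt(var + LN_EPS);
  c.xhat = centered.each_col() % c.invstd;
  mat Y = c.xhat;
  Y.each_row() %= g.t();
  Y.each_row() += b.t();
  return Y;
}

static mat layernorm_backward(const LNCache& c, const vec& g, const mat& dY,
                              mat& dg, mat& db) {
  dg = sum(dY % c.xhat, 0).t();
  db = sum(dY, 0).t();
  mat dxhat = dY.each_row() % g.t();
  vec m1 = mean(dxhat, 1);
  vec m2 = mean(dxhat % c.xhat, 1);
  mat dX = dxhat;
  dX.each_col() -= m1;
  dX -= c.xhat.each_col() % m2;
  dX.each_col() %= c.invstd;
  return dX;
}

// ---------------------------------------------------------------------------
// long-range dependency measurement + probability-sparse attention

// exact: M(q_i,K) = logsumexp_m(s_im) - mean_m(s_im), s = QK^T/sqrt(dh)
static vec measurement_exact(const mat& S) {
  vec mx = max(S, 1);
  vec lse = mx + log(sum(exp(S.each_col() - mx), 1));
  return lse - mean(S, 1);
}

// sampled surrogate: per query, ceil(Lk*ln(Lq)/Lq) keys drawn without
// replacement; Mbar = max(sampled) - mean(sampled)
static vec measurement_sampled(const mat& Q, const mat& K, double scale,
                               std::mt19937_64& rng) {
  int Lq = Q.n_rows, Lk = K.n_rows;
  int kper = (int)std::ceil(Lk * std::log((double)std::max(Lq, 2)) / Lq);
  if (kper < 1) kper = 1;
  if (kper > Lk) kper = Lk;
  vec M(Lq);
  std::vector<int> idx(Lk);
  for (int m = 0; m < Lk; ++m) idx[m] = m;
  for (int i = 0; i < Lq; ++i) {
    // partial Fisher-Yates for a without-replacement draw
    for (int j = 0; j < kper; ++j) {
      std::uniform_int_distribution<int> U(j, Lk - 1);
      std::swap(idx[j], idx[U(rng)]);
    }
    double mx = -datum::inf, sm = 0.0;
    for (int j = 0; j < kper; ++j) {
      double s = dot(Q.row(i), K.row(idx[j])) * scale;
      if (s > mx) mx = s;
      sm += s;
    }
    M(i) = mx - sm / kper;
  }
  return M;
}

static uvec top_u_queries(const vec& M, int u) {
  // ties broken by lowest query index: stable sort on descending score
  std::vector<int> ord(M.n_elem);
  for (uword i = 0; i < M.n_elem; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return M(a) > M(b); });
  uvec sel(u);
  for (int i = 0; i < u; ++i) sel(i) = ord[i];
  return sort(sel);
}

struct AttnCache {
  uvec sel;          // selected query indices (sorted)
  mat P;             // softmax rows for selected queries (u x Lk)
  rowvec vbar;       // column mean of V
  uvec is_sel;       // 0/1 indicator per query
};

static int u_of(double c, int Lq) {
  int u = (int)std::ceil(c * std::log((double)Lq));
  if (u < 1) u = 1;
  if (u > Lq) u = Lq;
  return u;
}

// single-head attention; Q,K,V are (L x dh)
static mat probdep_head(const mat& Q, const mat& K, const mat& V, double c,
                        bool exact, std::mt19937_64& rng, AttnCache* cache) {
  int Lq = Q.n_rows, Lk = K.n_rows;
  double scale = 1.0 / std::sqrt((double)Q.n_cols);
  vec M;
  if (exact) {
    M = measurement_exact(Q * K.t() * scale);
  } else {
    M = measurement_sampled(Q, K, scale, rng);
  }
  int u = u_of(c, Lq);
  uvec sel = top_u_queries(M, u);
  mat S = Q.rows(sel) * K.t() * scale; // (u x Lk)
  mat P = row_softmax(S);
  rowvec vbar = mean(V, 0);
  mat out(Lq, V.n_cols);
  out.each_row() = vbar; // non-dominant queries: softmax of zero scores
  out.rows(sel) = P * V;
  if (cache) {
    cache->sel = sel;
    cache->P = P;
    cache->vbar = vbar;
    cache->is_sel.zeros(Lq);
    cache->is_sel.elem(sel).ones();
  }
  return out;
}

static void probdep_head_backward(const mat& Q, const mat& K, const mat& V,
                                  const AttnCache& cache, const mat& dOut,
                                  mat& dQ, mat& dK, mat& dV) {
  int Lq = Q.n_rows, Lk = K.n_rows;
  double scale = 1.0 / std::sqrt((double)Q.n_cols);
  dQ.zeros(Lq, Q.n_cols);
  dK.zeros(Lk, K.n_cols);
  dV.zeros(Lk, V.n_cols);
  // non-selected rows saw the column mean of V
  rowvec dsum(V.n_cols, fill::zeros);
  for (int i = 0; i < Lq; ++i)
    if (!cache.is_sel(i)) dsum += dOut.row(i);
  dV.each_row() += dsum / (double)Lk;
  // selected rows: dense softmax attention gradient
  const uvec& sel = cache.sel;
  mat dO = dOut.rows(sel);          // (u x dh)
  dV += cache.P.t() * dO;           // V contribution
  mat dP = dO * V.t();              // (u x Lk)
  mat tmp = dP % cache.P;
  vec rowdot = sum(tmp, 1);
  mat dS = tmp - cache.P.each_col() % rowdot; // softmax backward
  dS *= scale;
  dQ.rows(sel) = dS * K;
  dK = dK + dS.t() * Q.rows(sel);
}

// exported single-head front-ends -------------------------------------------

// [[Rcpp::export(name = ".cpp_sparsity_measurement")]]
arma::vec cpp_sparsity_measurement(const arma::mat& Q, const arma::mat& K,
                                   bool exact, int seed) {
  if (K.n_rows == 0) Rcpp::stop("empty key matrix");
  double scale = 1.0 / std::sqrt((double)Q.n_cols);
  if (exact) return measurement_exact(Q * K.t() * scale);
  std::mt19937_64 rng(seed);
  return measurement_sampled(Q, K, scale, rng);
}

// [[Rcpp::export(name = ".cpp_probdep_attention")]]
arma::mat cpp_probdep_attention(const arma::mat& Q, const arma::mat& K,
                                const arma::mat& V, double c, bool exact,
                                int seed) {
  if (Q.n_rows == 0) Rcpp::stop("empty query matrix");
  if (K.n_rows != V.n_rows) Rcpp::stop("K and V row counts differ");
  std::mt19937_64 rng(seed);
  return probdep_head(Q, K, V, c, exact, rng, nullptr);
}

// ---------------------------------------------------------------------------
// full model forward / backward

struct LayerCache {
  mat Xin, Q, K, V, Oheads, R1, X1, pre1, F1e, R2, X2, Cpre, Cact;
  LNCache ln1, ln2;
  std::vector<AttnCache> heads;
  umat poolIdx;
};

struct SeqCache {
  std::vector<mat> stemIn;   // input to each stem conv
  std::vector<mat> stemPre;  // conv pre-activation
  std::vector<mat> stemAct;  // ELU(conv)
  std::vector<umat> stemPool;
  mat u;    // motif embedding (Ltok x d)
  mat X0;
  std::vector<LayerCache> layers;
  mat Xenc;     // encoder output (Llast x d)
  mat headPre;  // head conv pre-activation
  mat headAct;  // ELU(conv)
  vec flat;
  vec zpre, z;  // embedding pre-activation and output
  vec ypre;
  vec y;
};

static std::string key(const char* base, int l) {
  return std::string(base) + std::to_string(l);
}

static void forward_seq(const mat& X, const ParamMap& P, const Config& cfg,
                        const mat& PE, std::mt19937_64& rng, SeqCache& C) {
  // stem
  mat cur = X;
  C.stemIn.clear();
  C.stemPre.clear();
  C.stemAct.clear();
  C.stemPool.clear();
  if (cfg.stemStages == 0) {
    C.stemIn.push_back(cur);
    mat pre = conv1d(cur, P.at("stem_W1"), P.at("stem_b1").col(0),
                     cfg.stemKernel);
    C.stemPre.push_back(pre);
    cur = elu(pre);
    C.stemAct.push_back(cur);
  } else {
    for (int s = 0; s < cfg.stemStages; ++s) {
      C.stemIn.push_back(cur);
      mat pre = conv1d(cur, P.at(key("stem_W", s + 1)),
                       P.at(key("stem_b", s + 1)).col(0), cfg.stemKernel);
      C.stemPre.push_back(pre);
      mat act = elu(pre);
      C.stemAct.push_back(act);
      umat idx;
      cur = maxpool(act, cfg.poolWidth, idx);
      C.stemPool.push_back(idx);
    }
  }
  C.u = cur;
  C.X0 = cfg.alpha * C.u;
  if (cfg.usePE) C.X0 += PE;

  mat Xk = C.X0;
  C.layers.assign(cfg.layers, LayerCache());
  for (int l = 0; l < cfg.layers; ++l) {
    LayerCache& L = C.layers[l];
    L.Xin = Xk;
    L.Q = Xk * P.at(key("Wq", l + 1));
    L.Q.each_row() += P.at(key("bq", l + 1)).col(0).t();
    L.K = Xk * P.at(key("Wk", l + 1));
    L.K.each_row() += P.at(key("bk", l + 1)).col(0).t();
    L.V = Xk * P.at(key("Wv", l + 1));
    L.V.each_row() += P.at(key("bv", l + 1)).col(0).t();
    L.Oheads.set_size(Xk.n_rows, cfg.d);
    L.heads.assign(cfg.h, AttnCache());
    for (int hh = 0; hh < cfg.h; ++hh) {
      span cs(hh * cfg.dh, (hh + 1) * cfg.dh - 1);
      L.Oheads.cols(cs) = probdep_head(L.Q.cols(cs), L.K.cols(cs),
                                       L.V.cols(cs), cfg.c, cfg.measureExact,
                                       rng, &L.heads[hh]);
    }
    mat O = L.Oheads * P.at(key("Wo", l + 1));
    O.each_row() += P.at(key("bo", l + 1)).col(0).t();
    L.R1 = Xk + O;
    L.X1 = layernorm(L.R1, P.at(key("g1", l + 1)).col(0),
                     P.at(key("h1", l + 1)).col(0), L.ln1);
    L.pre1 = L.X1 * P.at(key("W1", l + 1));
    L.pre1.each_row() += P.at(key("b1", l + 1)).col(0).t();
    L.F1e = elu(L.pre1);
    mat F2 = L.F1e * P.at(key("W2", l + 1));
    F2.each_row() += P.at(key("b2", l + 1)).col(0).t();
    L.R2 = L.X1 + F2;
    L.X2 = layernorm(L.R2, P.at(key("g2", l + 1)).col(0),
                     P.at(key("h2", l + 1)).col(0), L.ln2);
    L.Cpre = conv1d(L.X2, P.at(key("Wc", l + 1)),
                    P.at(key("bc", l + 1)).col(0), cfg.convKernel);
    L.Cact = elu(L.Cpre);
    if (l < cfg.layers - 1) {
      Xk = maxpool(L.Cact, cfg.poolWidth, L.poolIdx);
    } else {
      Xk = L.Cact;
    }
  }
  C.Xenc = Xk;

  // sequence embedder: conv -> ELU -> flatten -> affine -> ELU
  C.headPre = conv1d(C.Xenc, P.at("head_Wc"), P.at("head_bc").col(0),
                     cfg.headKernel);
  C.headAct = elu(C.headPre);
  C.flat = vectorise(C.headAct);
  C.zpre = P.at("Wf").t() * C.flat + P.at("bf").col(0);
  C.z = vectorise(elu(mat(C.zpre)));
  C.ypre = P.at("Wp").t() * C.z + P.at("bp").col(0);
  C.y = vectorise(sigmoid(mat(C.ypre)));
}

static void backward_seq(const mat& X, const ParamMap& P, const Config& cfg,
                         const SeqCache& C, const vec& dypre, ParamMap& G) {
  // predictor
  G["Wp"] += C.z * dypre.t();
  G["bp"] += mat(dypre);
  vec dz = P.at("Wp") * dypre;
  vec dzpre = dz % vectorise(elu_grad(mat(C.zpre)));
  G["Wf"] += C.flat * dzpre.t();
  G["bf"] += mat(dzpre);
  vec dflat = P.at("Wf") * dzpre;
  mat dheadAct(dflat);
  dheadAct.reshape(C.headAct.n_rows, C.headAct.n_cols);
  mat dheadPre = dheadAct % elu_grad(C.headPre);
  mat dXenc, dWh;
  vec dbh;
  conv1d_backward(C.Xenc, P.at("head_Wc"), cfg.headKernel, dheadPre, dXenc,
                  dWh, dbh);
  G["head_Wc"] += dWh;
  G["head_bc"] += mat(dbh);

  mat dXk = dXenc;
  for (int l = cfg.layers - 1; l >= 0; --l) {
    const LayerCache& L = C.layers[l];
    mat dCact;
    if (l < cfg.layers - 1) {
      dCact = maxpool_backward(dXk, L.poolIdx, L.Cpre.n_rows);
    } else {
      dCact = dXk;
    }
    mat dCpre = dCact % elu_grad(L.Cpre);
    mat dX2, dWc;
    vec dbc;
    conv1d_backward(L.X2, P.at(key("Wc", l + 1)), cfg.convKernel, dCpre, dX2,
                    dWc, dbc);
    G[key("Wc", l + 1)] += dWc;
    G[key("bc", l + 1)] += mat(dbc);
    // FFN sublayer: residual + layer norm
    mat dg2, db2;
    mat dR2 = layernorm_backward(L.ln2, P.at(key("g2", l + 1)).col(0), dX2,
                                 dg2, db2);
    G[key("g2", l + 1)] += dg2;
    G[key("h2", l + 1)] += db2;
    mat dF2 = dR2;
    G[key("W2", l + 1)] += L.F1e.t() * dF2;
    G[key("b2", l + 1)] += mat(sum(dF2, 0).t());
    mat dF1e = dF2 * P.at(key("W2", l + 1)).t();
    mat dpre1 = dF1e % elu_grad(L.pre1);
    G[key("W1", l + 1)] += L.X1.t() * dpre1;
    G[key("b1", l + 1)] += mat(sum(dpre1, 0).t());
    mat dX1 = dR2 + dpre1 * P.at(key("W1", l + 1)).t();
    // attention sublayer: residual + layer norm
    mat dg1, db1;
    mat dR1 = layernorm_backward(L.ln1, P.at(key("g1", l + 1)).col(0), dX1,
                                 dg1, db1);
    G[key("g1", l + 1)] += dg1;
    G[key("h1", l + 1)] += db1;
    mat dO = dR1;
    G[key("Wo", l + 1)] += L.Oheads.t() * dO;
    G[key("bo", l + 1)] += mat(sum(dO, 0).t());
    mat dOheads = dO * P.at(key("Wo", l + 1)).t();
    mat dQ(L.Q.n_rows, cfg.d, fill::zeros), dK(L.K.n_rows, cfg.d, fill::zeros),
        dV(L.V.n_rows, cfg.d, fill::zeros);
    for (int hh = 0; hh < cfg.h; ++hh) {
      span cs(hh * cfg.dh, (hh + 1) * cfg.dh - 1);
      mat dq, dk, dv;
      probdep_head_backward(L.Q.cols(cs), L.K.cols(cs), L.V.cols(cs),
                            L.heads[hh], dOheads.cols(cs), dq, dk, dv);
      dQ.cols(cs) = dq;
      dK.cols(cs) = dk;
      dV.cols(cs) = dv;
    }
    G[key("Wq", l + 1)] += L.Xin.t() * dQ;
    G[key("bq", l + 1)] += mat(sum(dQ, 0).t());
    G[key("Wk", l + 1)] += L.Xin.t() * dK;
    G[key("bk", l + 1)] += mat(sum(dK, 0).t());
    G[key("Wv", l + 1)] += L.Xin.t() * dV;
    G[key("bv", l + 1)] += mat(sum(dV, 0).t());
    dXk = dR1 + dQ * P.at(key("Wq", l + 1)).t() +
          dK * P.at(key("Wk", l + 1)).t() + dV * P.at(key("Wv", l + 1)).t();
  }

  // uniform input representation and stem
  mat du = cfg.alpha * dXk;
  if (cfg.stemStages == 0) {
    mat dpre = du % elu_grad(C.stemPre[0]);
    mat dXin, dW;
    vec db;
    conv1d_backward(C.stemIn[0], P.at("stem_W1"), cfg.stemKernel, dpre, dXin,
                    dW, db);
    G["stem_W1"] += dW;
    G["stem_b1"] += mat(db);
  } else {
    mat dcur = du;
    for (int s = cfg.stemStages - 1; s >= 0; --s) {
      mat dact = maxpool_backward(dcur, C.stemPool[s], C.stemPre[s].n_rows);
      mat dpre = dact % elu_grad(C.stemPre[s]);
      mat dXin, dW;
      vec db;
      conv1d_backward(C.stemIn[s], P.at(key("stem_W", s + 1)), cfg.stemKernel,
                      dpre, dXin, dW, db);
      G[key("stem_W", s + 1)] += dW;
      G[key("stem_b", s + 1)] += mat(db);
      dcur = dXin;
    }
  }
}

static ParamMap zero_like(const ParamMap& P) {
  ParamMap G;
  for (ParamMap::const_iterator it = P.begin(); it != P.end(); ++it)
    G[it->first] = mat(it->second.n_rows, it->second.n_cols, fill::zeros);
  return G;
}

static const double BCE_EPS = 1e-7;

static double bce(const vec& y, const vec& lab) {
  vec yc = clamp(y, BCE_EPS, 1.0 - BCE_EPS);
  return -mean(lab % log(yc) + (1.0 - lab) % log(1.0 - yc));
}

// loss + gradients over a batch; Xb is (L x 4 x B), Y is (B x N)
static double batch_loss_grad(const ParamMap& P, const Config& cfg,
                              const mat& PE, const cube& Xb, const mat& Y,
                              std::mt19937_64& rng, ParamMap& G) {
  int B = Xb.n_slices;
  double loss = 0.0;
  SeqCache C;
  for (int b = 0; b < B; ++b) {
    forward_seq(Xb.slice(b), P, cfg, PE, rng, C);
    vec lab = Y.row(b).t();
    loss += bce(C.y, lab);
    vec dypre = (C.y - lab) / ((double)cfg.nCells * B);
    backward_seq(Xb.slice(b), P, cfg, C, dypre, G);
  }
  return loss / B;
}

// [[Rcpp::export(name = ".cpp_loss_grad")]]
Rcpp::List cpp_loss_grad(const Rcpp::List& params, const Rcpp::List& config,
                         const arma::cube& Xb, const arma::mat& Y, int seed) {
  Config cfg = parse_config(config);
  ParamMap P = list_to_params(params);
  mat PE = position_embedding(cfg.Ltok, cfg.d, cfg.peBase);
  std::mt19937_64 rng(seed);
  ParamMap G = zero_like(P);
  double loss = batch_loss_grad(P, cfg, PE, Xb, Y, rng, G);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = params_to_list(G));
}

// forward-only prediction; returns y (B x N) and embeddings Z (B x emb)
// [[Rcpp::export(name = ".cpp_predict")]]
Rcpp::List cpp_predict(const Rcpp::List& params, const Rcpp::List& config,
                       const arma::cube& Xb, int seed) {
  Config cfg = parse_config(config);
  ParamMap P = list_to_params(params);
  mat PE = position_embedding(cfg.Ltok, cfg.d, cfg.peBase);
  std::mt19937_64 rng(seed);
  int B = Xb.n_slices;
  mat Yhat(B, cfg.nCells), Z(B, cfg.emb);
  SeqCache C;
  for (int b = 0; b < B; ++b) {
    forward_seq(Xb.slice(b), P, cfg, PE, rng, C);
    Yhat.row(b) = C.y.t();
    Z.row(b) = C.z.t();
  }
  return Rcpp::List::create(Rcpp::Named("y") = Yhat, Rcpp::Named("z") = Z);
}

static double dataset_loss(const ParamMap& P, const Config& cfg, const mat& PE,
                           const cube& X, const mat& Y,
                           std::mt19937_64& rng) {
  double loss = 0.0;
  SeqCache C;
  int B = X.n_slices;
  for (int b = 0; b < B; ++b) {
    forward_seq(X.slice(b), P, cfg, PE, rng, C);
    loss += bce(C.y, Y.row(b).t());
  }
  return loss / B;
}

// Adam training loop with early stopping on the validation loss; the best
// validation-loss parameters are restored before returning.
// [[Rcpp::export(name = ".cpp_train")]]
Rcpp::List cpp_train(const Rcpp::List& params, const Rcpp::List& config,
                     const arma::cube& Xtr, const arma::mat& Ytr,
                     const arma::cube& Xval, const arma::mat& Yval,
                     double lr, int batchSize, int patience, int maxEpochs,
                     int seed, bool verbose) {
  Config cfg = parse_config(config);
  ParamMap P = list_to_params(params);
  mat PE = position_embedding(cfg.Ltok, cfg.d, cfg.peBase);
  std::mt19937_64 rng(seed);

  ParamMap M = zero_like(P), V2 = zero_like(P);
  double b1 = 0.9, b2 = 0.999, adamEps = 1e-8;
  int step = 0;
  int nTr = Xtr.n_slices;
  std::vector<int> order(nTr);
  for (int i = 0; i < nTr; ++i) order[i] = i;

  double bestVal = datum::inf;
  ParamMap bestP = P;
  int bad = 0;
  std::vector<double> trHist, valHist;

  for (int epoch = 0; epoch < maxEpochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double trLoss = 0.0;
    int nBatches = 0;
    for (int start = 0; start < nTr; start += batchSize) {
      int end = std::min(start + batchSize, nTr);
      int B = end - start;
      cube Xb(cfg.L, 4, B);
      mat Yb(B, cfg.nCells);
      for (int b = 0; b < B; ++b) {
        Xb.slice(b) = Xtr.slice(order[start + b]);
        Yb.row(b) = Ytr.row(order[start + b]);
      }
      ParamMap G = zero_like(P);
      trLoss += batch_loss_grad(P, cfg, PE, Xb, Yb, rng, G);
      nBatches++;
      step++;
      double corr = lr * std::sqrt(1.0 - std::pow(b2, step)) /
                    (1.0 - std::pow(b1, step));
      for (ParamMap::iterator it = P.begin(); it != P.end(); ++it) {
        const std::string& k = it->first;
        M[k] = b1 * M[k] + (1.0 - b1) * G[k];
        V2[k] = b2 * V2[k] + (1.0 - b2) * square(G[k]);
        it->second -= corr * M[k] / (sqrt(V2[k]) + adamEps);
      }
    }
    trLoss /= nBatches;
    double valLoss = dataset_loss(P, cfg, PE, Xval, Yval, rng);
    trHist.push_back(trLoss);
    valHist.push_back(valLoss);
    if (verbose)
      Rcpp::Rcout << "epoch " << epoch + 1 << " train " << trLoss << " val "
                  << valLoss << std::endl;
    if (valLoss < bestVal - 1e-12) {
      bestVal = valLoss;
      bestP = P;
      bad = 0;
    } else {
      bad++;
      if (bad >= patience) break;
    }
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("params") = params_to_list(bestP),
      Rcpp::Named("train_loss") = trHist,
      Rcpp::Named("val_loss") = valHist,
      Rcpp::Named("best_val") = bestVal);
}

// token geometry for a config: stem stages, tokens entering each layer,
// tokens at the encoder output (used by the R side to size parameters)
// [[Rcpp::export(name = ".cpp_geometry")]]
Rcpp::List cpp_geometry(const Rcpp::List& config) {
  Config cfg = parse_config(config);
  Rcpp::IntegerVector toks(cfg.tokensPerLayer.begin(),
                           cfg.tokensPerLayer.end());
  return Rcpp::List::create(Rcpp::Named("stemStages") = cfg.stemStages,
                            Rcpp::Named("Ltok") = cfg.Ltok,
                            Rcpp::Named("tokensPerLayer") = toks,
                            Rcpp::Named("Llast") = cfg.Llast);
}
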