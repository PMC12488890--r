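// Tiny causal transformer language model: forward, manual backprop with an
// output-masked cross-entropy loss, Adam, and nucleus sampling with a KV
// cache. Single-threaded, double precision. Parameter layout (flat list):
//   0: E (V x d) token embeddings
//   1: P (maxlen x d) positional embeddings
//   per layer (12 each): ln1_g, ln1_b, Wq, Wk, Wv, Wo, ln2_g, ln2_b,
//                        W1, b1, W2, b2
//   tail: lnf_g, lnf_b, U (d x V), bu (1 x V)
// All randomness draws from R's RNG so set.seed() governs everything.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

static const double LN_EPS = 1e-5;

struct Cfg {
  int V, d, h, ff, layers, maxlen;
};

static Cfg read_cfg(const List& model) {
  List cf = model["config"];
  Cfg c;
  c.V = as<int>(cf["vocab"]);
  c.d = as<int>(cf["d_model"]);
  c.h = as<int>(cf["n_heads"]);
  c.ff = as<int>(cf["d_ff"]);
  c.layers = as<int>(cf["n_layers"]);
  c.maxlen = as<int>(cf["max_len"]);
  return c;
}

static std::vector<mat> get_params(const List& model) {
  List pl = model["params"];
  std::vector<mat> out(pl.size());
  for (int i = 0; i < pl.size(); ++i) out[i] = as<mat>(pl[i]);
  return out;
}

static List wrap_params(const std::vector<mat>& p) {
  List out(p.size());
  for (size_t i = 0; i < p.size(); ++i) out[i] = wrap(p[i]);
  return out;
}

static int layer_base(int l) { return 2 + 12 * l; }

// ---- layer norm ------------------------------------------------------------

static mat ln_fwd(const mat& X, const rowvec& g, const rowvec& b,
                  mat& xhat, vec& inv_std) {
  const int n = X.n_rows;
  xhat.set_size(n, X.n_cols);
  inv_std.set_size(n);
  mat Y(n, X.n_cols);
  for (int i = 0; i < n; ++i) {
    double mu = arma::mean(X.row(i));
    double var = arma::mean(arma::square(X.row(i) - mu));
    double is = 1.0 / std::sqrt(var + LN_EPS);
    inv_std(i) = is;
    xhat.row(i) = (X.row(i) - mu) * is;
    Y.row(i) = xhat.row(i) % g + b;
  }
  return Y;
}

static mat ln_bwd(const mat& dY, const mat& xhat, const vec& inv_std,
                  const rowvec& g, rowvec& dg, rowvec& db) {
  const int n = dY.n_rows;
  mat dX(n, dY.n_cols);
  dg += arma::sum(dY % xhat, 0);
  db += arma::sum(dY, 0);
  for (int i = 0; i < n; ++i) {
    rowvec dyg = dY.row(i) % g;
    double m1 = arma::mean(dyg);
    double m2 = arma::mean(dyg % xhat.row(i));
    dX.row(i) = inv_std(i) * (dyg - m1 - xhat.row(i) * m2);
  }
  return dX;
}

// ---- forward cache for one sequence ---------------------------------------

struct LayerCache {
  mat x_in;              // residual input
  mat xhat1; vec is1;    // ln1
  mat Q, K, Vv;          // projections
  std::vector<mat> A;    // per-head attention weights (L x L)
  mat O;                 // concatenated head outputs (pre-Wo)
  mat x_mid;             // after attention residual
  mat xhat2; vec is2;    // ln2
  mat B;                 // ln2 output
  mat F;                 // relu activations
};

struct FwdCache {
  mat x0;
  std::vector<LayerCache> layers;
  mat x_last;            // final residual stream
  mat xhatf; vec isf;    // final ln
  mat H;                 // final ln output
};

static mat forward_seq(const std::vector<mat>& P, const Cfg& c,
                       const std::vector<int>& ids, FwdCache& fc) {
  const int L = ids.size();
  const int dh = c.d / c.h;
  mat x(L, c.d);
  for (int t = 0; t < L; ++t) {
    x.row(t) = P[0].row(ids[t]) + P[1].row(t);
  }
  fc.x0 = x;
  fc.layers.resize(c.layers);
  for (int l = 0; l < c.layers; ++l) {
    LayerCache& lc = fc.layers[l];
    const int b = layer_base(l);
    lc.x_in = x;
    mat a = ln_fwd(x, P[b].row(0), P[b + 1].row(0), lc.xhat1, lc.is1);
    lc.Q = a * P[b + 2];
    lc.K = a * P[b + 3];
    lc.Vv = a * P[b + 4];
    lc.A.resize(c.h);
    lc.O.set_size(L, c.d);
    const double scale = 1.0 / std::sqrt((double)dh);
    for (int hh = 0; hh < c.h; ++hh) {
      const int cs = hh * dh;
      mat Qh = lc.Q.cols(cs, cs + dh - 1);
      mat Kh = lc.K.cols(cs, cs + dh - 1);
      mat Vh = lc.Vv.cols(cs, cs + dh - 1);
      mat S = Qh * Kh.t() * scale;
      // causal mask + row softmax
      mat A(L, L, arma::fill::zeros);
      for (int t = 0; t < L; ++t) {
        rowvec s = S.row(t).cols(0, t);
        double mx = s.max();
        rowvec e = arma::exp(s - mx);
        A.row(t).cols(0, t) = e / arma::accu(e);
      }
      lc.A[hh] = A;
      lc.O.cols(cs, cs + dh - 1) = A * Vh;
    }
    x = lc.x_in + lc.O * P[b + 5];
    lc.x_mid = x;
    lc.B = ln_fwd(x, P[b + 6].row(0), P[b + 7].row(0), lc.xhat2, lc.is2);
    mat pre = lc.B * P[b + 8];
    pre.each_row() += P[b + 9].row(0);
    lc.F = arma::clamp(pre, 0.0, arma::datum::inf);
    mat ffn = lc.F * P[b + 10];
    ffn.each_row() += P[b + 11].row(0);
    x = x + ffn;
  }
  fc.x_last = x;
  const int tb = 2 + 12 * c.layers;
  fc.H = ln_fwd(x, P[tb].row(0), P[tb + 1].row(0), fc.xhatf, fc.isf);
  return fc.H;
}

// Backward from dH (gradient on the final layer-norm output) down to all
// parameters; grads accumulated into G. Returns nothing.
static void backward_seq(const std::vector<mat>& P, const Cfg& c,
                         const std::vector<int>& ids, const FwdCache& fc,
                         mat dH, std::vector<mat>& G) {
  const int L = ids.size();
  const int dh = c.d / c.h;
  const int tb = 2 + 12 * c.layers;
  rowvec dgf(c.d, arma::fill::zeros), dbf(c.d, arma::fill::zeros);
  mat dx = ln_bwd(dH, fc.xhatf, fc.isf, P[tb].row(0), dgf, dbf);
  G[tb].row(0) += dgf;
  G[tb + 1].row(0) += dbf;

  for (int l = c.layers - 1; l >= 0; --l) {
    const LayerCache& lc = fc.layers[l];
    const int b = layer_base(l);
    // FFN
    mat dffn = dx;                       // residual passthrough stays in dx
    G[b + 11].row(0) += arma::sum(dffn, 0);
    G[b + 10] += lc.F.t() * dffn;
    mat dF = dffn * P[b + 10].t();
    dF.elem(arma::find(lc.F == 0.0)).zeros();
    G[b + 9].row(0) += arma::sum(dF, 0);
    G[b + 8] += lc.B.t() * dF;
    mat dB = dF * P[b + 8].t();
    rowvec dg2(c.d, arma::fill::zeros), db2(c.d, arma::fill::zeros);
    mat dx_mid = dx + ln_bwd(dB, lc.xhat2, lc.is2, P[b + 6].row(0), dg2, db2);
    G[b + 6].row(0) += dg2;
    G[b + 7].row(0) += db2;

    // attention
    mat dattn = dx_mid;                  // gradient on (O * Wo)
    G[b + 5] += lc.O.t() * dattn;
    mat dO = dattn * P[b + 5].t();
    mat dQ(L, c.d, arma::fill::zeros), dK(L, c.d, arma::fill::zeros),
        dV(L, c.d, arma::fill::zeros);
    const double scale = 1.0 / std::sqrt((double)dh);
    for (int hh = 0; hh < c.h; ++hh) {
      const int cs = hh * dh;
      mat dOh = dO.cols(cs, cs + dh - 1);
      mat Vh = lc.Vv.cols(cs, cs + dh - 1);
      const mat& A = lc.A[hh];
      mat dA = dOh * Vh.t();
      dV.cols(cs, cs + dh - 1) += A.t() * dOh;
      // softmax backward row-wise (causal rows)
      mat dS(L, L, arma::fill::zeros);
      for (int t = 0; t < L; ++t) {
        rowvec a = A.row(t).cols(0, t);
        rowvec da = dA.row(t).cols(0, t);
        double dot = arma::accu(da % a);
        dS.row(t).cols(0, t) = a % (da - dot);
      }
      mat Qh = lc.Q.cols(cs, cs + dh - 1);
      mat Kh = lc.K.cols(cs, cs + dh - 1);
      dQ.cols(cs, cs + dh - 1) += dS * Kh * scale;
      dK.cols(cs, cs + dh - 1) += dS.t() * Qh * scale;
    }
    // back through the QKV projections to ln1 output a
    mat a(L, c.d);
    for (int t = 0; t < L; ++t) {
      a.row(t) = lc.xhat1.row(t) % P[b].row(0) + P[b + 1].row(0);
    }
    G[b + 2] += a.t() * dQ;
    G[b + 3] += a.t() * dK;
    G[b + 4] += a.t() * dV;
    mat da = dQ * P[b + 2].t() + dK * P[b + 3].t() + dV * P[b + 4].t();
    rowvec dg1(c.d, arma::fill::zeros), db1(c.d, arma::fill::zeros);
    dx = dx_mid + ln_bwd(da, lc.xhat1, lc.is1, P[b].row(0), dg1, db1);
    G[b].row(0) += dg1;
    G[b + 1].row(0) += db1;
  }

  // embeddings
  for (int t = 0; t < L; ++t) {
    G[0].row(ids[t]) += dx.row(t);
    G[1].row(t) += dx.row(t);
  }
}

// Masked-loss forward+backward for one sequence. mask_pos are 0-based
// positions t whose logits (predicting ids[t+1]) enter the loss.
static double seq_loss_grad(const std::vector<mat>& P, const Cfg& c,
                            const std::vector<int>& ids,
                            const std::vector<int>& mask_pos,
                            std::vector<mat>* G, double inv_tokens) {
  FwdCache fc;
  mat H = forward_seq(P, c, ids, fc);
  const int tb = 2 + 12 * c.layers;
  const mat& U = P[tb + 2];
  const rowvec bu = P[tb + 3].row(0);

  const int M = mask_pos.size();
  mat Hm(M, c.d);
  for (int i = 0; i < M; ++i) Hm.row(i) = H.row(mask_pos[i]);
  mat logits = Hm * U;
  logits.each_row() += bu;

  double loss = 0.0;
  mat dlogits(M, c.V);
  for (int i = 0; i < M; ++i) {
    int label = ids[mask_pos[i] + 1];
    rowvec z = logits.row(i);
    double mx = z.max();
    rowvec e = arma::exp(z - mx);
    double Z = arma::accu(e);
    rowvec p = e / Z;
    loss += -(std::log(p(label) + 1e-300));
    if (G) {
      p(label) -= 1.0;
      dlogits.row(i) = p * inv_tokens;
    }
  }
  if (G) {
    std::vector<mat>& Gr = *G;
    Gr[tb + 2] += Hm.t() * dlogits;
    Gr[tb + 3].row(0) += arma::sum(dlogits, 0);
    mat dHm = dlogits * U.t();
    mat dH(H.n_rows, c.d, arma::fill::zeros);
    for (int i = 0; i < M; ++i) dH.row(mask_pos[i]) = dHm.row(i);
    backward_seq(P, c, ids, fc, dH, Gr);
  }
  return loss;
}

// [[Rcpp::export]]
List tlm_init_cpp(int vocab, int d_model, int n_heads, int d_ff,
                  int n_layers, int max_len) {
  if (d_model % n_heads != 0) stop("d_model must be divisible by n_heads");
  std::vector<mat> P;
  auto randmat = [](int r, int cc, double sd) {
    mat m(r, cc);
    for (int i = 0; i < r; ++i)
      for (int j = 0; j < cc; ++j) m(i, j) = R::rnorm(0.0, sd);
    return m;
  };
  P.push_back(randmat(vocab, d_model, 0.02));       // E
  P.push_back(randmat(max_len, d_model, 0.02));     // P
  for (int l = 0; l < n_layers; ++l) {
    P.push_back(mat(1, d_model, arma::fill::ones));   // ln1_g
    P.push_back(mat(1, d_model, arma::fill::zeros));  // ln1_b
    P.push_back(randmat(d_model, d_model, 0.05));     // Wq
    P.push_back(randmat(d_model, d_model, 0.05));     // Wk
    P.push_back(randmat(d_model, d_model, 0.05));     // Wv
    P.push_back(randmat(d_model, d_model, 0.05));     // Wo
    P.push_back(mat(1, d_model, arma::fill::ones));   // ln2_g
    P.push_back(mat(1, d_model, arma::fill::zeros));  // ln2_b
    P.push_back(randmat(d_model, d_ff, 0.05));        // W1
    P.push_back(mat(1, d_ff, arma::fill::zeros));     // b1
    P.push_back(randmat(d_ff, d_model, 0.05));        // W2
    P.push_back(mat(1, d_model, arma::fill::zeros));  // b2
  }
  P.push_back(mat(1, d_model, arma::fill::ones));     // lnf_g
  P.push_back(mat(1, d_model, arma::fill::zeros));    // lnf_b
  P.push_back(randmat(d_model, vocab, 0.05));         // U
  P.push_back(mat(1, vocab, arma::fill::zeros));      // bu

  List cfg = List::create(_["vocab"] = vocab, _["d_model"] = d_model,
                          _["n_heads"] = n_heads, _["d_ff"] = d_ff,
                          _["n_layers"] = n_layers, _["max_len"] = max_len);
  return List::create(_["config"] = cfg, _["params"] = wrap_params(P),
                      _["opt_t"] = 0);
}

// [[Rcpp::export]]
List tlm_train_cpp(List model, List seqs, List masks, int epochs,
                   double lr, int batch_size) {
  Cfg c = read_cfg(model);
  std::vector<mat> P = get_params(model);
  const int n_par = P.size();

  // Adam state (kept across calls when present)
  std::vector<mat> M(n_par), Vv(n_par);
  int step = as<int>(model["opt_t"]);
  if (model.containsElementNamed("opt_m") && step > 0) {
    List lm = model["opt_m"], lv = model["opt_v"];
    for (int i = 0; i < n_par; ++i) { M[i] = as<mat>(lm[i]); Vv[i] = as<mat>(lv[i]); }
  } else {
    for (int i = 0; i < n_par; ++i) {
      M[i] = mat(P[i].n_rows, P[i].n_cols, arma::fill::zeros);
      Vv[i] = mat(P[i].n_rows, P[i].n_cols, arma::fill::zeros);
    }
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  const int n = seqs.size();
  std::vector<std::vector<int>> ids(n), mpos(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector s = seqs[i], m = masks[i];
    ids[i] = std::vector<int>(s.begin(), s.end());
    mpos[i] = std::vector<int>(m.begin(), m.end());
    if ((int)ids[i].size() > c.maxlen) stop("sequence exceeds max_len");
  }

  NumericVector epoch_loss(epochs);
  std::vector<mat> G(n_par);
  for (int ep = 0; ep < epochs; ++ep) {
    // shuffle with R RNG
    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(R::runif(0.0, 1.0) * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double tot_loss = 0.0; long tot_tokens = 0;
    int pos = 0;
    while (pos < n) {
      int bs = std::min(batch_size, n - pos);
      long btok = 0;
      for (int bi = 0; bi < bs; ++bi) btok += mpos[order[pos + bi]].size();
      if (btok == 0) { pos += bs; continue; }
      for (int i = 0; i < n_par; ++i)
        G[i] = mat(P[i].n_rows, P[i].n_cols, arma::fill::zeros);
      double inv = 1.0 / (double)btok;
      for (int bi = 0; bi < bs; ++bi) {
        int si = order[pos + bi];
        tot_loss += seq_loss_grad(P, c, ids[si], mpos[si], &G, inv);
      }
      tot_tokens += btok;
      // Adam step
      step += 1;
      double bc1 = 1.0 - std::pow(b1, step);
      double bc2 = 1.0 - std::pow(b2, step);
      for (int i = 0; i < n_par; ++i) {
        M[i] = b1 * M[i] + (1.0 - b1) * G[i];
        Vv[i] = b2 * Vv[i] + (1.0 - b2) * (G[i] % G[i]);
        P[i] -= lr * (M[i] / bc1) / (arma::sqrt(Vv[i] / bc2) + eps);
      }
      pos += bs;
      Rcpp::checkUserInterrupt();
    }
    epoch_loss[ep] = tot_tokens > 0 ? tot_loss / tot_tokens : NA_REAL;
  }

  return List::create(_["config"] = model["config"],
                      _["params"] = wrap_params(P),
                      _["opt_t"] = step,
                      _["opt_m"] = wrap_params(M),
                      _["opt_v"] = wrap_params(Vv),
                      _["epoch_loss"] = epoch_loss);
}

// Per-masked-position cross-entropy of one sequence (no gradient).
// [[Rcpp::export]]
NumericVector tlm_position_loss_cpp(List model, IntegerVector seq,
                                    IntegerVector mask_pos) {
  Cfg c = read_cfg(model);
  std::vector<mat> P = get_params(model);
  std::vector<int> ids(seq.begin(), seq.end());
  FwdCache fc;
  mat H = forward_seq(P, c, ids, fc);
  const int tb = 2 + 12 * c.layers;
  NumericVector out(mask_pos.size());
  for (int i = 0; i < mask_pos.size(); ++i) {
    int t = mask_pos[i];
    rowvec z = H.row(t) * P[tb + 2];
    z += P[tb + 3].row(0);
    double mx = z.max();
    rowvec e = arma::exp(z - mx);
    rowvec p = e / arma::accu(e);
    out[i] = -std::log(p(ids[t + 1]) + 1e-300);
  }
  return out;
}

// Gradient of the masked loss w.r.t. the positional-embedding rows, one
// norm per position: verifies the loss mask leaves input positions with
// exactly zero gradient through the output head.
// [[Rcpp::export]]
NumericVector tlm_logit_grad_norms_cpp(List model, IntegerVector seq,
                                       IntegerVector mask_pos) {
  Cfg c = read_cfg(model);
  std::vector<mat> P = get_params(model);
  std::vector<int> ids(seq.begin(), seq.end());
  std::vector<int> mp(mask_pos.begin(), mask_pos.end());
  FwdCache fc;
  mat H = forward_seq(P, c, ids, fc);
  const int tb = 2 + 12 * c.layers;
  const int L = ids.size();
  // dLoss/dH rows: zero unless the position is masked-in
  NumericVector out(L);
  double inv = mp.empty() ? 0.0 : 1.0 / (double)mp.size();
  mat dH(L, c.d, arma::fill::zeros);
  for (size_t i = 0; i < mp.size(); ++i) {
    int t = mp[i];
    rowvec z = H.row(t) * P[tb + 2];
    z += P[tb + 3].row(0);
    double mx = z.max();
    rowvec e = arma::exp(z - mx);
    rowvec p = e / arma::accu(e);
    p(ids[t + 1]) -= 1.0;
    dH.row(t) = (p * inv) * P[tb + 2].t();
  }
  for (int t = 0; t < L; ++t) out[t] = arma::norm(dH.row(t), 2);
  return out;
}

// ---- generation with KV cache ---------------------------------------------

struct KV {
  std::vector<mat> K, V; // per layer, rows = positions
};

static rowvec step_forward(const std::vector<mat>& P, const Cfg& c,
                           int id, int pos, KV& kv) {
  const int dh = c.d / c.h;
  rowvec x = P[0].row(id) + P[1].row(pos);
  mat xh; vec is;
  for (int l = 0; l < c.layers; ++l) {
    const int b = layer_base(l);
    mat xm(1, c.d); xm.row(0) = x;
    mat a = ln_fwd(xm, P[b].row(0), P[b + 1].row(0), xh, is);
    rowvec q = a.row(0) * P[b + 2];
    rowvec k = a.row(0) * P[b + 3];
    rowvec v = a.row(0) * P[b + 4];
    kv.K[l].insert_rows(kv.K[l].n_rows, k);
    kv.V[l].insert_rows(kv.V[l].n_rows, v);
    rowvec o(c.d);
    const double scale = 1.0 / std::sqrt((double)dh);
    const int Lc = kv.K[l].n_rows;
    for (int hh = 0; hh < c.h; ++hh) {
      const int cs = hh * dh;
      rowvec qh = q.cols(cs, cs + dh - 1);
      mat Kh = kv.K[l].cols(cs, cs + dh - 1);
      mat Vh = kv.V[l].cols(cs, cs + dh - 1);
      vec s = Kh * qh.t() * scale;
      double mx = s.max();
      vec e = arma::exp(s - mx);
      vec aw = e / arma::accu(e);
      rowvec oh(dh, arma::fill::zeros);
      for (int t = 0; t < Lc; ++t) oh += aw(t) * Vh.row(t);
      o.cols(cs, cs + dh - 1) = oh;
    }
    x = x + o * P[b + 5];
    mat x1(1, c.d); x1.row(0) = x;
    mat bn = ln_fwd(x1, P[b + 6].row(0), P[b + 7].row(0), xh, is);
    rowvec f = bn.row(0) * P[b + 8] + P[b + 9].row(0);
    f = arma::clamp(f, 0.0, arma::datum::inf);
    x = x + f * P[b + 10] + P[b + 11].row(0);
  }
  const int tb = 2 + 12 * c.layers;
  mat xm(1, c.d); xm.row(0) = x;
  mat h = ln_fwd(xm, P[tb].row(0), P[tb + 1].row(0), xh, is);
  rowvec z = h.row(0) * P[tb + 2];
  z += P[tb + 3].row(0);
  return z;
}

static int sample_token(rowvec logits, double temperature, double top_p) {
  logits /= std::max(temperature, 1e-6);
  double mx = logits.max();
  rowvec e = arma::exp(logits - mx);
  rowvec p = e / arma::accu(e);
  arma::uvec ord = arma::sort_index(p, "descend");
  double cum = 0.0;
  arma::uword cutoff = ord.n_elem;
  for (arma::uword i = 0; i < ord.n_elem; ++i) {
    cum += p(ord(i));
    if (cum >= top_p) { cutoff = i + 1; break; }
  }
  double total = 0.0;
  for (arma::uword i = 0; i < cutoff; ++i) total += p(ord(i));
  double u = R::runif(0.0, 1.0) * total;
  double acc = 0.0;
  for (arma::uword i = 0; i < cutoff; ++i) {
    acc += p(ord(i));
    if (u <= acc) return (int)ord(i);
  }
  return (int)ord(cutoff - 1);
}

// k sampled continuations of a prompt; the prompt KV cache is computed once
// and copied per draw.
// [[Rcpp::export]]
List tlm_generate_cpp(List model, IntegerVector prompt, int k, int max_new,
                      double temperature, double top_p, int eos_id) {
  Cfg c = read_cfg(model);
  std::vector<mat> P = get_params(model);
  if ((int)prompt.size() + max_new > c.maxlen) {
    stop("prompt + max_new exceeds max_len");
  }
  KV base;
  base.K.assign(c.layers, mat(0, c.d));
  base.V.assign(c.layers, mat(0, c.d));
  rowvec last_logits;
  for (int t = 0; t < prompt.size(); ++t) {
    last_logits = step_forward(P, c, prompt[t], t, base);
  }
  List out(k);
  for (int draw = 0; draw < k; ++draw) {
    KV kv = base; // copy prompt cache
    std::vector<int> gen;
    rowvec logits = last_logits;
    int pos = prompt.size();
    for (int stepi = 0; stepi < max_new; ++stepi) {
      int tok = sample_token(logits, temperature, top_p);
      gen.push_back(tok);
      if (tok == eos_id) break;
      logits = step_forward(P, c, tok, pos, kv);
      pos += 1;
    }
    out[draw] = IntegerVector(gen.begin(), gen.end());
    Rcpp::checkUserInterrupt();
  }
  return out;
}
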