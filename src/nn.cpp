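// Compact sequence-model engine: 1-D convolution -> bidirectional LSTM ->
// dense trunk -> task heads, trained with Nadam.  Shapes follow the
// one-hot convention used by the R layer: input is a 4 x 240 x N cube,
// the conv layer is "valid" so the recurrent length is T = 240 - w + 1.
//
// Two tasks share the trunk:
//   task 0 ("polyaid"):   sigmoid classification head + 50-way softmax
//                         cleavage head, loss = BCE + KL(observed||predicted)
//   task 1 ("strength"):  single linear head, loss = MSE
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Dims {
  int w, F, U, D, T, task, pool;
};

Dims get_dims(const Rcpp::List& cfg) {
  Dims d;
  d.w = Rcpp::as<int>(cfg["conv_window"]);
  d.F = Rcpp::as<int>(cfg["conv_filters"]);
  d.U = Rcpp::as<int>(cfg["rnn_units"]);
  d.D = Rcpp::as<int>(cfg["dense_units"]);
  d.task = Rcpp::as<int>(cfg["task_id"]);
  d.pool = cfg.containsElementNamed("pool_id") ?
    Rcpp::as<int>(cfg["pool_id"]) : 0;   // 0 = flatten, 1 = mean+max pool
  d.T = 240 - d.w + 1;
  return d;
}

struct Weights {
  mat Wc; vec bc;
  mat Wxf, Whf; vec bf;   // forward LSTM, gate order [i; f; g; o]
  mat Wxb, Whb; vec bb;   // backward LSTM
  mat Wd; vec bd;         // dense trunk
  mat Wcls; vec bcls;     // classification / strength head
  mat Wclv; vec bclv;     // cleavage head (polyaid only)
};

Weights from_list(const Rcpp::List& L, int task) {
  Weights w;
  w.Wc = Rcpp::as<mat>(L["Wc"]);   w.bc = Rcpp::as<vec>(L["bc"]);
  w.Wxf = Rcpp::as<mat>(L["Wxf"]); w.Whf = Rcpp::as<mat>(L["Whf"]); w.bf = Rcpp::as<vec>(L["bf"]);
  w.Wxb = Rcpp::as<mat>(L["Wxb"]); w.Whb = Rcpp::as<mat>(L["Whb"]); w.bb = Rcpp::as<vec>(L["bb"]);
  w.Wd = Rcpp::as<mat>(L["Wd"]);   w.bd = Rcpp::as<vec>(L["bd"]);
  w.Wcls = Rcpp::as<mat>(L["Wcls"]); w.bcls = Rcpp::as<vec>(L["bcls"]);
  if (task == 0) {
    w.Wclv = Rcpp::as<mat>(L["Wclv"]); w.bclv = Rcpp::as<vec>(L["bclv"]);
  }
  return w;
}

Rcpp::List to_list(const Weights& w, int task) {
  Rcpp::List L = Rcpp::List::create(
    Rcpp::Named("Wc") = w.Wc, Rcpp::Named("bc") = w.bc,
    Rcpp::Named("Wxf") = w.Wxf, Rcpp::Named("Whf") = w.Whf, Rcpp::Named("bf") = w.bf,
    Rcpp::Named("Wxb") = w.Wxb, Rcpp::Named("Whb") = w.Whb, Rcpp::Named("bb") = w.bb,
    Rcpp::Named("Wd") = w.Wd, Rcpp::Named("bd") = w.bd,
    Rcpp::Named("Wcls") = w.Wcls, Rcpp::Named("bcls") = w.bcls);
  if (task == 0) {
    L["Wclv"] = w.Wclv;
    L["bclv"] = w.bclv;
  }
  return L;
}

inline mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// Cached activations for one batch (needed by backward()).
struct Cache {
  cube Xcol;                 // (4w, B, T)
  cube C;                    // conv+relu output (F, B, T)
  cube If, Ff, Gf, Of, Cf, Hf; // forward LSTM internals (U, B, T)
  cube Ib, Fb, Gb, Ob, Cb, Hb; // backward LSTM internals
  mat Hflat;                 // (2U*T, B) flatten mode; (4U, B) pool mode
  umat amax;                 // argmax timestep per (unit, batch) in pool mode
  mat A;                     // trunk activation after dropout scaling (D, B)
  mat Arelu;                 // trunk relu mask source
  mat drop;                  // dropout mask (already scaled), or empty
  mat Pcls;                  // (1, B) sigmoid probs (task 0) / linear (task 1)
  mat Pclv;                  // (50, B) softmax (task 0)
};

void forward(const Weights& w, const Dims& d, const cube& X, bool training,
             double dropout, std::mt19937& rng, Cache& K) {
  const int B = X.n_slices;
  const int w4 = 4 * d.w;
  K.Xcol.set_size(w4, B, d.T);
  K.C.set_size(d.F, B, d.T);
  for (int t = 0; t < d.T; ++t) {
    mat Xt(w4, B);
    for (int b = 0; b < B; ++b) {
      const mat& xb = X.slice(b);             // 4 x 240
      for (int k = 0; k < d.w; ++k)
        Xt.submat(4 * k, b, 4 * k + 3, b) = xb.col(t + k);
    }
    K.Xcol.slice(t) = Xt;
    mat Z = w.Wc * Xt;
    Z.each_col() += w.bc;
    K.C.slice(t) = clamp(Z, 0.0, datum::inf);
  }
  // biLSTM
  auto run_lstm = [&](const mat& Wx, const mat& Wh, const vec& b, bool fwd,
                      cube& I, cube& Fg, cube& G, cube& O, cube& Cc, cube& H) {
    I.set_size(d.U, B, d.T); Fg.set_size(d.U, B, d.T); G.set_size(d.U, B, d.T);
    O.set_size(d.U, B, d.T); Cc.set_size(d.U, B, d.T); H.set_size(d.U, B, d.T);
    mat h(d.U, B, fill::zeros), c(d.U, B, fill::zeros);
    for (int s = 0; s < d.T; ++s) {
      int t = fwd ? s : (d.T - 1 - s);
      mat Z = Wx * K.C.slice(t) + Wh * h;
      Z.each_col() += b;
      mat i = sigm(Z.rows(0, d.U - 1));
      mat f = sigm(Z.rows(d.U, 2 * d.U - 1));
      mat g = tanh(Z.rows(2 * d.U, 3 * d.U - 1));
      mat o = sigm(Z.rows(3 * d.U, 4 * d.U - 1));
      c = f % c + i % g;
      h = o % tanh(c);
      I.slice(t) = i; Fg.slice(t) = f; G.slice(t) = g; O.slice(t) = o;
      Cc.slice(t) = c; H.slice(t) = h;
    }
  };
  run_lstm(w.Wxf, w.Whf, w.bf, true,  K.If, K.Ff, K.Gf, K.Of, K.Cf, K.Hf);
  run_lstm(w.Wxb, w.Whb, w.bb, false, K.Ib, K.Fb, K.Gb, K.Ob, K.Cb, K.Hb);

  if (d.pool == 0) {
    K.Hflat.set_size(2 * d.U * d.T, B);
    for (int t = 0; t < d.T; ++t) {
      K.Hflat.rows(2 * d.U * t, 2 * d.U * t + d.U - 1) = K.Hf.slice(t);
      K.Hflat.rows(2 * d.U * t + d.U, 2 * d.U * (t + 1) - 1) = K.Hb.slice(t);
    }
  } else {
    mat Hmean(2 * d.U, B, fill::zeros);
    mat Hmax(2 * d.U, B);
    Hmax.fill(-datum::inf);
    K.amax.set_size(2 * d.U, B);
    for (int t = 0; t < d.T; ++t) {
      mat Hc = join_cols(K.Hf.slice(t), K.Hb.slice(t));
      Hmean += Hc / d.T;
      for (uword j = 0; j < Hc.n_elem; ++j) {
        if (Hc(j) > Hmax(j)) { Hmax(j) = Hc(j); K.amax(j) = t; }
      }
    }
    K.Hflat = join_cols(Hmean, Hmax);
  }
  mat Zd = w.Wd * K.Hflat;
  Zd.each_col() += w.bd;
  K.Arelu = clamp(Zd, 0.0, datum::inf);
  if (training && dropout > 0.0) {
    K.drop.set_size(d.D, B);
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    for (uword j = 0; j < K.drop.n_elem; ++j)
      K.drop(j) = unif(rng) < dropout ? 0.0 : 1.0 / (1.0 - dropout);
    K.A = K.Arelu % K.drop;
  } else {
    K.drop.reset();
    K.A = K.Arelu;
  }
  mat Zc = w.Wcls * K.A;
  Zc.each_col() += w.bcls;
  K.Pcls = (d.task == 0) ? sigm(Zc) : Zc;
  if (d.task == 0) {
    mat Zv = w.Wclv * K.A;
    Zv.each_col() += w.bclv;
    Zv.each_row() -= max(Zv, 0);
    mat E = exp(Zv);
    rowvec s = sum(E, 0);
    E.each_row() /= s;
    K.Pclv = E;
  }
}

// losses on one forward pass
void losses(const Dims& d, const Cache& K, const rowvec& ycls, const mat& yclv,
            double& Lcls, double& Lclv) {
  const double eps = 1e-7;
  const int B = K.Pcls.n_cols;
  if (d.task == 0) {
    rowvec p = clamp(K.Pcls.row(0), eps, 1.0 - eps);
    Lcls = -mean(ycls % log(p) + (1.0 - ycls) % log(1.0 - p));
    mat pc = clamp(K.Pclv, eps, 1.0);
    mat term = yclv % (log(clamp(yclv, eps, 1.0)) - log(pc));
    term.elem(find(yclv <= 0)).zeros();
    Lclv = accu(term) / B;
  } else {
    Lcls = accu(square(ycls - K.Pcls.row(0))) / B;
    Lclv = 0.0;
  }
}

struct Grads {
  mat Wc; vec bc;
  mat Wxf, Whf; vec bf;
  mat Wxb, Whb; vec bb;
  mat Wd; vec bd;
  mat Wcls; vec bcls;
  mat Wclv; vec bclv;
};

void backward(const Weights& w, const Dims& d, const Cache& K,
              const rowvec& ycls, const mat& yclv, Grads& g) {
  const int B = K.Pcls.n_cols;
  // head gradients (batch-mean losses)
  mat dZc = (K.Pcls - conv_to<mat>::from(ycls)) / B;       // works for both tasks
  if (d.task == 1) dZc *= 2.0;                              // MSE derivative
  g.Wcls = dZc * K.A.t();
  g.bcls = sum(dZc, 1);
  mat dA = w.Wcls.t() * dZc;
  if (d.task == 0) {
    mat dZv = (K.Pclv - yclv) / B;
    g.Wclv = dZv * K.A.t();
    g.bclv = sum(dZv, 1);
    dA += w.Wclv.t() * dZv;
  }
  if (!K.drop.is_empty()) dA %= K.drop;
  mat dZd = dA % conv_to<mat>::from(K.Arelu > 0);
  g.Wd = dZd * K.Hflat.t();
  g.bd = sum(dZd, 1);
  mat dH = w.Wd.t() * dZd;             // (2U*T, B) flatten; (4U, B) pool
  cube dHext(2 * d.U, B, d.T, fill::zeros);
  if (d.pool == 0) {
    for (int t = 0; t < d.T; ++t)
      dHext.slice(t) = dH.rows(2 * d.U * t, 2 * d.U * (t + 1) - 1);
  } else {
    mat dMean = dH.rows(0, 2 * d.U - 1) / d.T;
    mat dMax = dH.rows(2 * d.U, 4 * d.U - 1);
    for (int t = 0; t < d.T; ++t) dHext.slice(t) = dMean;
    for (uword j = 0; j < dMax.n_elem; ++j)
      dHext.slice(K.amax(j))(j) += dMax(j);
  }

  cube dC(d.F, B, d.T, fill::zeros);
  auto back_lstm = [&](const mat& Wx, const mat& Wh, bool fwd,
                       const cube& I, const cube& Fg, const cube& G,
                       const cube& O, const cube& Cc, const cube& H,
                       int row_off, mat& dWx, mat& dWh, vec& db) {
    dWx.zeros(4 * d.U, d.F); dWh.zeros(4 * d.U, d.U); db.zeros(4 * d.U);
    mat dh_rec(d.U, B, fill::zeros), dc_rec(d.U, B, fill::zeros);
    for (int s = d.T - 1; s >= 0; --s) {
      int t = fwd ? s : (d.T - 1 - s);
      mat dh = dHext.slice(t).rows(row_off, row_off + d.U - 1) + dh_rec;
      mat tc = tanh(Cc.slice(t));
      mat do_ = dh % tc;
      mat dtc = dh % O.slice(t) % (1.0 - tc % tc) + dc_rec;
      mat cprev = fwd ? (t > 0 ? Cc.slice(t - 1) : mat(d.U, B, fill::zeros))
                      : (t < d.T - 1 ? Cc.slice(t + 1) : mat(d.U, B, fill::zeros));
      mat hprev = fwd ? (t > 0 ? H.slice(t - 1) : mat(d.U, B, fill::zeros))
                      : (t < d.T - 1 ? H.slice(t + 1) : mat(d.U, B, fill::zeros));
      mat df = dtc % cprev;
      mat di = dtc % G.slice(t);
      mat dg = dtc % I.slice(t);
      dc_rec = dtc % Fg.slice(t);
      mat dZ(4 * d.U, B);
      dZ.rows(0, d.U - 1)             = di % I.slice(t) % (1.0 - I.slice(t));
      dZ.rows(d.U, 2 * d.U - 1)       = df % Fg.slice(t) % (1.0 - Fg.slice(t));
      dZ.rows(2 * d.U, 3 * d.U - 1)   = dg % (1.0 - G.slice(t) % G.slice(t));
      dZ.rows(3 * d.U, 4 * d.U - 1)   = do_ % O.slice(t) % (1.0 - O.slice(t));
      dWx += dZ * K.C.slice(t).t();
      dWh += dZ * hprev.t();
      db  += sum(dZ, 1);
      dh_rec = Wh.t() * dZ;
      dC.slice(t) += Wx.t() * dZ;
    }
  };
  back_lstm(w.Wxf, w.Whf, true,  K.If, K.Ff, K.Gf, K.Of, K.Cf, K.Hf, 0,
            g.Wxf, g.Whf, g.bf);
  back_lstm(w.Wxb, w.Whb, false, K.Ib, K.Fb, K.Gb, K.Ob, K.Cb, K.Hb, d.U,
            g.Wxb, g.Whb, g.bb);

  g.Wc.zeros(d.F, 4 * d.w); g.bc.zeros(d.F);
  for (int t = 0; t < d.T; ++t) {
    mat dZ = dC.slice(t) % conv_to<mat>::from(K.C.slice(t) > 0);
    g.Wc += dZ * K.Xcol.slice(t).t();
    g.bc += sum(dZ, 1);
  }
}

// Nadam state mirrors the weight layout
struct Nadam {
  std::vector<mat> m, v;
  int t = 0;
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
};

void collect(Weights& w, int task, std::vector<mat*>& ptr) {
  ptr = { &w.Wc, &w.Wxf, &w.Whf, &w.Wxb, &w.Whb, &w.Wd, &w.Wcls };
  if (task == 0) ptr.push_back(&w.Wclv);
}

void collect_g(Grads& g, int task, std::vector<mat*>& ptr, std::vector<vec*>& bptr,
               Weights& w, std::vector<vec*>& wb) {
  ptr = { &g.Wc, &g.Wxf, &g.Whf, &g.Wxb, &g.Whb, &g.Wd, &g.Wcls };
  bptr = { &g.bc, &g.bf, &g.bb, &g.bd, &g.bcls };
  wb = { &w.bc, &w.bf, &w.bb, &w.bd, &w.bcls };
  if (task == 0) { ptr.push_back(&g.Wclv); bptr.push_back(&g.bclv); wb.push_back(&w.bclv); }
}

void nadam_step(Nadam& st, std::vector<mat*>& wm, std::vector<mat*>& gm,
                std::vector<vec*>& wb, std::vector<vec*>& gb) {
  // global-norm gradient clipping at 5
  double nrm2 = 0.0;
  for (auto* g : gm) nrm2 += accu(square(*g));
  for (auto* g : gb) nrm2 += accu(square(*g));
  double nrm = std::sqrt(nrm2);
  double scale = nrm > 5.0 ? 5.0 / nrm : 1.0;
  st.t += 1;
  const double bc1 = 1.0 - std::pow(st.b1, st.t);
  const double bc2 = 1.0 - std::pow(st.b2, st.t);
  if (st.m.empty()) {
    for (auto* g : gm) { st.m.push_back(zeros<mat>(size(*g))); st.v.push_back(zeros<mat>(size(*g))); }
    for (auto* g : gb) { st.m.push_back(zeros<mat>(g->n_elem, 1)); st.v.push_back(zeros<mat>(g->n_elem, 1)); }
  }
  size_t k = 0;
  auto upd = [&](mat& W, const mat& G0) {
    mat G = G0 * scale;
    st.m[k] = st.b1 * st.m[k] + (1.0 - st.b1) * G;
    st.v[k] = st.b2 * st.v[k] + (1.0 - st.b2) * square(G);
    mat mhat = st.m[k] / bc1;
    mat vhat = st.v[k] / bc2;
    W -= st.lr * (st.b1 * mhat + (1.0 - st.b1) * G / bc1) / (sqrt(vhat) + st.eps);
    ++k;
  };
  for (size_t j = 0; j < wm.size(); ++j) upd(*wm[j], *gm[j]);
  for (size_t j = 0; j < wb.size(); ++j) {
    mat W(wb[j]->memptr(), wb[j]->n_elem, 1, false, true);
    mat G(gb[j]->memptr(), gb[j]->n_elem, 1, false, true);
    upd(W, G);
  }
}

} // namespace

// [[Rcpp::export]]
Rcpp::List nn_predict_cpp(Rcpp::List weights, Rcpp::List cfg, arma::cube X,
                          int chunk = 256) {
  Dims d = get_dims(cfg);
  Weights w = from_list(weights, d.task);
  const int N = X.n_slices;
  rowvec pcls(N);
  mat pclv;
  if (d.task == 0) pclv.set_size(50, N);
  std::mt19937 rng(1);
  Cache K;
  for (int s = 0; s < N; s += chunk) {
    int e = std::min(N, s + chunk);
    cube Xb = X.slices(s, e - 1);
    forward(w, d, Xb, false, 0.0, rng, K);
    pcls.subvec(s, e - 1) = K.Pcls.row(0);
    if (d.task == 0) pclv.cols(s, e - 1) = K.Pclv;
  }
  if (d.task == 0)
    return Rcpp::List::create(Rcpp::Named("p_class") = pcls,
                              Rcpp::Named("cleavage") = pclv);
  return Rcpp::List::create(Rcpp::Named("score") = pcls);
}

// [[Rcpp::export]]
Rcpp::List nn_train_cpp(Rcpp::List weights, Rcpp::List cfg,
                        arma::cube X, arma::rowvec y, arma::mat yclv,
                        arma::cube Xval, arma::rowvec yval, arma::mat yclv_val,
                        int epochs, int batch_size, double lr, double dropout,
                        int seed, bool verbose = false) {
  Dims d = get_dims(cfg);
  Weights w = from_list(weights, d.task);
  const int N = X.n_slices;
  std::mt19937 rng(static_cast<unsigned>(seed));
  Nadam st; st.lr = lr;
  Cache K;
  Grads g;
  std::vector<mat*> wm, gm; std::vector<vec*> gb, wb;
  collect(w, d.task, wm);

  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;

  mat hist(epochs, 4, fill::zeros);  // train_cls, train_clv, val_cls, val_clv
  double best_val = datum::inf;
  int best_epoch = -1;
  Rcpp::List best_weights = to_list(w, d.task);

  auto eval_val = [&](double& vc, double& vv) {
    vc = 0.0; vv = 0.0;
    const int M = Xval.n_slices;
    int nb = 0;
    for (int s = 0; s < M; s += 256) {
      int e = std::min(M, s + 256);
      cube Xb = Xval.slices(s, e - 1);
      rowvec yb = yval.subvec(s, e - 1);
      mat yv = (d.task == 0) ? yclv_val.cols(s, e - 1) : mat();
      forward(w, d, Xb, false, 0.0, rng, K);
      double lc, lv;
      losses(d, K, yb, yv, lc, lv);
      double frac = double(e - s);
      vc += lc * frac; vv += lv * frac; nb += (e - s);
    }
    if (nb > 0) { vc /= nb; vv /= nb; }
  };

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double tc = 0.0, tv = 0.0; int seen = 0;
    for (int s = 0; s < N; s += batch_size) {
      int e = std::min(N, s + batch_size);
      int B = e - s;
      cube Xb(4, 240, B);
      rowvec yb(B);
      mat yv;
      if (d.task == 0) yv.set_size(50, B);
      for (int b = 0; b < B; ++b) {
        Xb.slice(b) = X.slice(idx[s + b]);
        yb(b) = y(idx[s + b]);
        if (d.task == 0) yv.col(b) = yclv.col(idx[s + b]);
      }
      forward(w, d, Xb, true, dropout, rng, K);
      double lc, lv;
      losses(d, K, yb, yv, lc, lv);
      if (!std::isfinite(lc) || !std::isfinite(lv))
        Rcpp::stop("training diverged (non-finite loss) at epoch %d", ep + 1);
      tc += lc * B; tv += lv * B; seen += B;
      backward(w, d, K, yb, yv, g);
      collect_g(g, d.task, gm, gb, w, wb);
      nadam_step(st, wm, gm, wb, gb);
      Rcpp::checkUserInterrupt();
    }
    double vc, vv;
    eval_val(vc, vv);
    hist(ep, 0) = tc / seen; hist(ep, 1) = tv / seen;
    hist(ep, 2) = vc;        hist(ep, 3) = vv;
    double vtot = vc + vv;
    if (vtot < best_val) {
      best_val = vtot;
      best_epoch = ep + 1;
      best_weights = to_list(w, d.task);
    }
    if (verbose)
      Rcpp::Rcout << "epoch " << (ep + 1) << " train " << (tc + tv) / seen
                  << " val " << vtot << "\n";
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = best_weights,
    Rcpp::Named("final_weights") = to_list(w, d.task),
    Rcpp::Named("history") = hist,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("best_val_loss") = best_val);
}
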