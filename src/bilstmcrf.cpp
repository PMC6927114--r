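// Bi-LSTM-CRF over composed radical+feature embeddings.
//
// Parameters travel as a named R list of numeric matrices/vectors:
//   Ltab (Dl x Vl), Rtab (Dr x Vr)          feature embedding tables
//   LW (D x Dl), RW (D x Dr), bc (D)        composition layer
//   Wf (4H x D), Uf (4H x H), bf (4H)       forward LSTM   [gates i,f,o,g]
//   Wb, Ub, bb                              backward LSTM
//   Wout (T x 2H), bout (T)                 emission projection
//   trans ((T+2) x (T+2))                   CRF transitions, START=T, STOP=T+1
// `pen` is a constant (T+2)^2 matrix of 0 / -1e4 encoding disallowed BIO
// transitions; it is added to trans wherever transitions are scored.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

struct Net {
  mat Ltab, Rtab, LW, RW, Wf, Uf, Wb, Ub, Wout, trans;
  vec bc, bf, bb, bout;
  int Dl, Dr, D, H, T;
};

static Net loadNet(const List &p) {
  Net n;
  n.Ltab = as<mat>(p["Ltab"]); n.Rtab = as<mat>(p["Rtab"]);
  n.LW = as<mat>(p["LW"]); n.RW = as<mat>(p["RW"]); n.bc = as<vec>(p["bc"]);
  n.Wf = as<mat>(p["Wf"]); n.Uf = as<mat>(p["Uf"]); n.bf = as<vec>(p["bf"]);
  n.Wb = as<mat>(p["Wb"]); n.Ub = as<mat>(p["Ub"]); n.bb = as<vec>(p["bb"]);
  n.Wout = as<mat>(p["Wout"]); n.bout = as<vec>(p["bout"]);
  n.trans = as<mat>(p["trans"]);
  n.Dl = n.Ltab.n_rows; n.Dr = n.Rtab.n_rows; n.D = n.LW.n_rows;
  n.H = n.Uf.n_cols; n.T = n.Wout.n_rows;
  return n;
}

static List dumpNet(const Net &n) {
  return List::create(
    Named("Ltab") = n.Ltab, Named("Rtab") = n.Rtab,
    Named("LW") = n.LW, Named("RW") = n.RW, Named("bc") = n.bc,
    Named("Wf") = n.Wf, Named("Uf") = n.Uf, Named("bf") = n.bf,
    Named("Wb") = n.Wb, Named("Ub") = n.Ub, Named("bb") = n.bb,
    Named("Wout") = n.Wout, Named("bout") = n.bout,
    Named("trans") = n.trans);
}

static inline double lse(const vec &v) {
  double m = v.max();
  return m + std::log(arma::accu(arma::exp(v - m)));
}

struct LSTMCache {
  mat ig, fg, og, gg, c, tc, h;   // H x n each
};

// run one direction; idx order given by `rev`
static void lstmForward(const mat &W, const mat &U, const vec &b,
                        const mat &X, bool rev, LSTMCache &cc) {
  int n = X.n_cols, H = U.n_cols;
  cc.ig.set_size(H, n); cc.fg.set_size(H, n); cc.og.set_size(H, n);
  cc.gg.set_size(H, n); cc.c.set_size(H, n); cc.tc.set_size(H, n);
  cc.h.set_size(H, n);
  vec hprev(H, arma::fill::zeros), cprev(H, arma::fill::zeros);
  for (int k = 0; k < n; ++k) {
    int t = rev ? (n - 1 - k) : k;
    vec a = W * X.col(t) + U * hprev + b;
    vec i = 1.0 / (1.0 + arma::exp(-a.subvec(0, H - 1)));
    vec f = 1.0 / (1.0 + arma::exp(-a.subvec(H, 2 * H - 1)));
    vec o = 1.0 / (1.0 + arma::exp(-a.subvec(2 * H, 3 * H - 1)));
    vec g = arma::tanh(a.subvec(3 * H, 4 * H - 1));
    vec c = f % cprev + i % g;
    vec tc = arma::tanh(c);
    vec h = o % tc;
    cc.ig.col(t) = i; cc.fg.col(t) = f; cc.og.col(t) = o; cc.gg.col(t) = g;
    cc.c.col(t) = c; cc.tc.col(t) = tc; cc.h.col(t) = h;
    hprev = h; cprev = c;
  }
}

// backprop one direction; dH is dLoss/dh per position; returns dX and
// accumulates into gW,gU,gb
static mat lstmBackward(const mat &W, const mat &U, const LSTMCache &cc,
                        const mat &X, const mat &dH, bool rev,
                        mat &gW, mat &gU, vec &gb) {
  int n = X.n_cols, H = U.n_cols;
  mat dX(X.n_rows, n, arma::fill::zeros);
  vec dhc(H, arma::fill::zeros), dcc(H, arma::fill::zeros);
  for (int k = n - 1; k >= 0; --k) {
    int t = rev ? (n - 1 - k) : k;
    vec i = cc.ig.col(t), f = cc.fg.col(t), o = cc.og.col(t), g = cc.gg.col(t);
    vec tc = cc.tc.col(t);
    int tprev = rev ? t + 1 : t - 1;
    bool hasPrev = rev ? (t + 1 < n) : (t - 1 >= 0);
    vec cprev = hasPrev ? vec(cc.c.col(tprev)) : vec(H, arma::fill::zeros);
    vec hprev = hasPrev ? vec(cc.h.col(tprev)) : vec(H, arma::fill::zeros);

    vec dh = dH.col(t) + dhc;
    vec do_ = dh % tc;
    vec dc = dcc + dh % o % (1.0 - tc % tc);
    vec di = dc % g, dg = dc % i, df = dc % cprev;

    vec da(4 * H);
    da.subvec(0, H - 1) = di % i % (1.0 - i);
    da.subvec(H, 2 * H - 1) = df % f % (1.0 - f);
    da.subvec(2 * H, 3 * H - 1) = do_ % o % (1.0 - o);
    da.subvec(3 * H, 4 * H - 1) = dg % (1.0 - g % g);

    gW += da * X.col(t).t();
    gU += da * hprev.t();
    gb += da;
    dX.col(t) += W.t() * da;
    dhc = U.t() * da;
    dcc = dc % f;
  }
  return dX;
}

struct FwdCache {
  mat X;          // D x n composed embeddings
  LSTMCache fw, bw;
  mat E;          // T x n emissions
};

static void netForward(const Net &net, const IntegerVector &il,
                       const IntegerVector &ir, FwdCache &fc) {
  int n = il.size();
  fc.X.set_size(net.D, n);
  for (int t = 0; t < n; ++t)
    fc.X.col(t) = net.LW * net.Ltab.col(il[t]) +
                  net.RW * net.Rtab.col(ir[t]) + net.bc;
  lstmForward(net.Wf, net.Uf, net.bf, fc.X, false, fc.fw);
  lstmForward(net.Wb, net.Ub, net.bb, fc.X, true, fc.bw);
  fc.E.set_size(net.T, n);
  for (int t = 0; t < n; ++t) {
    vec h = arma::join_cols(fc.fw.h.col(t), fc.bw.h.col(t));
    fc.E.col(t) = net.Wout * h + net.bout;
  }
}

// CRF forward/backward in log space; returns logZ, fills alpha/beta (T x n)
static double crfAlphaBeta(const mat &E, const mat &effT, int T,
                           mat &alpha, mat &beta) {
  int n = E.n_cols, S = T, P = T + 1;
  alpha.set_size(T, n); beta.set_size(T, n);
  for (int j = 0; j < T; ++j) alpha(j, 0) = effT(S, j) + E(j, 0);
  for (int t = 1; t < n; ++t)
    for (int j = 0; j < T; ++j) {
      vec prev = alpha.col(t - 1) + effT.submat(0, j, T - 1, j);
      alpha(j, t) = lse(prev) + E(j, t);
    }
  for (int j = 0; j < T; ++j) beta(j, n - 1) = effT(j, P);
  for (int t = n - 2; t >= 0; --t)
    for (int k = 0; k < T; ++k) {
      vec nxt = effT.submat(k, 0, k, T - 1).t() + E.col(t + 1) + beta.col(t + 1);
      beta(k, t) = lse(nxt);
    }
  return lse(alpha.col(n - 1) + effT.submat(0, P, T - 1, P));
}

static double goldScore(const mat &E, const mat &effT, const IntegerVector &y,
                        int T) {
  int n = y.size(), S = T, P = T + 1;
  double sc = effT(S, y[0]) + E(y[0], 0);
  for (int t = 1; t < n; ++t) sc += effT(y[t - 1], y[t]) + E(y[t], t);
  sc += effT(y[n - 1], P);
  return sc;
}

// Negative log-likelihood of one sentence and (optionally) its gradients.
static double nllGrad(const Net &net, const IntegerVector &il,
                      const IntegerVector &ir, const IntegerVector &y,
                      const mat &pen, Net *grad) {
  FwdCache fc;
  netForward(net, il, ir, fc);
  int n = il.size(), T = net.T, S = T, P = T + 1;
  mat effT = net.trans + pen;
  mat alpha, beta;
  double logZ = crfAlphaBeta(fc.E, effT, T, alpha, beta);
  double nll = logZ - goldScore(fc.E, effT, y, T);
  if (!grad) return nll;

  // dNLL/dE = marginals - gold indicators; dNLL/dtrans from pair marginals
  mat dE(T, n);
  for (int t = 0; t < n; ++t)
    dE.col(t) = arma::exp(alpha.col(t) + beta.col(t) - logZ);
  for (int t = 0; t < n; ++t) dE(y[t], t) -= 1.0;

  mat &dTr = grad->trans;
  for (int j = 0; j < T; ++j)
    dTr(S, j) += std::exp(alpha(j, 0) + beta(j, 0) - logZ);
  dTr(S, y[0]) -= 1.0;
  for (int t = 1; t < n; ++t) {
    for (int k = 0; k < T; ++k)
      for (int j = 0; j < T; ++j)
        dTr(k, j) += std::exp(alpha(k, t - 1) + effT(k, j) + fc.E(j, t) +
                              beta(j, t) - logZ);
    dTr(y[t - 1], y[t]) -= 1.0;
  }
  for (int j = 0; j < T; ++j)
    dTr(j, P) += std::exp(alpha(j, n - 1) + effT(j, P) - logZ);
  dTr(y[n - 1], P) -= 1.0;

  // emissions -> projection and hidden states
  mat dHf(net.H, n), dHb(net.H, n);
  for (int t = 0; t < n; ++t) {
    vec h = arma::join_cols(fc.fw.h.col(t), fc.bw.h.col(t));
    grad->Wout += dE.col(t) * h.t();
    grad->bout += dE.col(t);
    vec dh = net.Wout.t() * dE.col(t);
    dHf.col(t) = dh.subvec(0, net.H - 1);
    dHb.col(t) = dh.subvec(net.H, 2 * net.H - 1);
  }

  mat dX = lstmBackward(net.Wf, net.Uf, fc.fw, fc.X, dHf, false,
                        grad->Wf, grad->Uf, grad->bf);
  dX += lstmBackward(net.Wb, net.Ub, fc.bw, fc.X, dHb, true,
                     grad->Wb, grad->Ub, grad->bb);

  for (int t = 0; t < n; ++t) {
    vec dx = dX.col(t);
    grad->LW += dx * net.Ltab.col(il[t]).t();
    grad->RW += dx * net.Rtab.col(ir[t]).t();
    grad->bc += dx;
    grad->Ltab.col(il[t]) += net.LW.t() * dx;
    grad->Rtab.col(ir[t]) += net.RW.t() * dx;
  }
  return nll;
}

static Net zeroLike(const Net &n) {
  Net g = n;
  g.Ltab.zeros(); g.Rtab.zeros(); g.LW.zeros(); g.RW.zeros(); g.bc.zeros();
  g.Wf.zeros(); g.Uf.zeros(); g.bf.zeros();
  g.Wb.zeros(); g.Ub.zeros(); g.bb.zeros();
  g.Wout.zeros(); g.bout.zeros(); g.trans.zeros();
  return g;
}

// [[Rcpp::export]]
arma::mat cpp_tagger_emissions(List params, IntegerVector il, IntegerVector ir) {
  Net net = loadNet(params);
  FwdCache fc;
  netForward(net, il, ir, fc);
  return fc.E;
}

// [[Rcpp::export]]
double cpp_tagger_nll(List params, IntegerVector il, IntegerVector ir,
                      IntegerVector y, arma::mat pen) {
  Net net = loadNet(params);
  return nllGrad(net, il, ir, y, pen, nullptr);
}

// [[Rcpp::export]]
List cpp_tagger_grad(List params, IntegerVector il, IntegerVector ir,
                     IntegerVector y, arma::mat pen) {
  Net net = loadNet(params);
  Net grad = zeroLike(net);
  double nll = nllGrad(net, il, ir, y, pen, &grad);
  List out = dumpNet(grad);
  out["nll"] = nll;
  return out;
}

struct Adam {
  std::vector<mat> m, v;
  std::vector<vec> mv, vv;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
};

// [[Rcpp::export]]
List cpp_tagger_train(List params, List data, arma::mat pen, int epochs,
                      double lr, int batchSize, int seed,
                      bool updateComp, bool updateTables) {
  Net net = loadNet(params);
  int N = data.size();
  if (N == 0) stop("cpp_tagger_train: empty corpus");
  if (batchSize < 1) batchSize = 1;

  std::vector<IntegerVector> ils(N), irs(N), ys(N);
  for (int s = 0; s < N; ++s) {
    List d = data[s];
    ils[s] = as<IntegerVector>(d["il"]);
    irs[s] = as<IntegerVector>(d["ir"]);
    ys[s] = as<IntegerVector>(d["y"]);
  }

  std::vector<mat Net::*> mslots = {&Net::Ltab, &Net::Rtab, &Net::LW, &Net::RW,
                                    &Net::Wf, &Net::Uf, &Net::Wb, &Net::Ub,
                                    &Net::Wout, &Net::trans};
  std::vector<vec Net::*> vslots = {&Net::bc, &Net::bf, &Net::bb, &Net::bout};
  // update masks matching the slot lists above
  std::vector<bool> mupd = {updateTables, updateTables, updateComp, updateComp,
                            true, true, true, true, true, true};
  std::vector<bool> vupd = {updateComp, true, true, true};

  Adam ad;
  for (auto s : mslots) ad.m.push_back(mat(arma::size(net.*s), arma::fill::zeros));
  for (auto s : mslots) ad.v.push_back(mat(arma::size(net.*s), arma::fill::zeros));
  for (auto s : vslots) ad.mv.push_back(vec(arma::size(net.*s), arma::fill::zeros));
  for (auto s : vslots) ad.vv.push_back(vec(arma::size(net.*s), arma::fill::zeros));

  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<int> order(N);
  for (int s = 0; s < N; ++s) order[s] = s;

  NumericVector trace(epochs);
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double epLoss = 0.0;
    int pos = 0;
    while (pos < N) {
      int bs = std::min(batchSize, N - pos);
      Net grad = zeroLike(net);
      for (int b = 0; b < bs; ++b)
        epLoss += nllGrad(net, ils[order[pos + b]], irs[order[pos + b]],
                          ys[order[pos + b]], pen, &grad);
      ad.step += 1;
      double corr = std::sqrt(1.0 - std::pow(ad.b2, (double)ad.step)) /
                    (1.0 - std::pow(ad.b1, (double)ad.step));
      for (size_t k = 0; k < mslots.size(); ++k) {
        if (!mupd[k]) continue;
        mat g = (grad.*(mslots[k])) / bs;
        ad.m[k] = ad.b1 * ad.m[k] + (1 - ad.b1) * g;
        ad.v[k] = ad.b2 * ad.v[k] + (1 - ad.b2) * (g % g);
        net.*(mslots[k]) -= lr * corr * ad.m[k] / (arma::sqrt(ad.v[k]) + ad.eps);
      }
      for (size_t k = 0; k < vslots.size(); ++k) {
        if (!vupd[k]) continue;
        vec g = (grad.*(vslots[k])) / bs;
        ad.mv[k] = ad.b1 * ad.mv[k] + (1 - ad.b1) * g;
        ad.vv[k] = ad.b2 * ad.vv[k] + (1 - ad.b2) * (g % g);
        net.*(vslots[k]) -= lr * corr * ad.mv[k] / (arma::sqrt(ad.vv[k]) + ad.eps);
      }
      pos += bs;
    }
    trace[ep] = epLoss / N;
    Rcpp::checkUserInterrupt();
  }
  return List::create(Named("params") = dumpNet(net), Named("trace") = trace);
}
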