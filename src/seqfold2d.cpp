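// Sequence-to-pair predictor kernel: input feed-forward block, N
// bidirectional-LSTM sequence blocks, channel-wise outer-product pair
// transform, N residual 2D-convolution blocks, 3-layer softmax head.
// Forward and analytic backward are implemented here; optimisation
// (AdamW) lives in R. Gradients are verified against finite differences
// in the test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

static const double LN_EPS = 1e-5;

// ---- activations -----------------------------------------------------
static inline mat act_f(const mat &x, int type) {
  if (type == 1) return x % (1.0 / (1.0 + arma::exp(-x)));  // swish
  mat y = x; y.transform([](double v) { return v > 0 ? v : 0.01 * v; });
  return y;                                                  // leaky relu
}
static inline mat act_df(const mat &x, int type) {
  if (type == 1) {
    mat s = 1.0 / (1.0 + arma::exp(-x));
    return s % (1.0 + x % (1.0 - s));
  }
  mat y = x; y.transform([](double v) { return v > 0 ? 1.0 : 0.01; });
  return y;
}

// ---- layer norm (per row, over channels) -----------------------------
struct LNCache { mat xhat; vec inv_std; };
static mat ln_fwd(const mat &x, const rowvec &g, const rowvec &b, LNCache &cc) {
  const double d = (double)x.n_cols;
  vec mu = arma::mean(x, 1);
  mat xc = x.each_col() - mu;
  vec var = arma::sum(arma::square(xc), 1) / d;
  cc.inv_std = 1.0 / arma::sqrt(var + LN_EPS);
  cc.xhat = xc.each_col() % cc.inv_std;
  mat y = cc.xhat.each_row() % g;
  y.each_row() += b;
  return y;
}
static mat ln_bwd(const mat &dy, const rowvec &g, const LNCache &cc,
                  rowvec &dg, rowvec &db) {
  dg = arma::sum(dy % cc.xhat, 0);
  db = arma::sum(dy, 0);
  mat dxh = dy.each_row() % g;
  vec m1 = arma::mean(dxh, 1);
  vec m2 = arma::mean(dxh % cc.xhat, 1);
  mat dx = dxh;
  dx.each_col() -= m1;
  dx -= cc.xhat.each_col() % m2;
  dx.each_col() %= cc.inv_std;
  return dx;
}

// ---- LSTM ------------------------------------------------------------
struct LSTMCache {
  mat X, H, C, I, F, G, O, Tc;  // H/C have L rows (state after step t)
};
static inline rowvec sigm(const rowvec &x) { return 1.0 / (1.0 + arma::exp(-x)); }

static mat lstm_fwd(const mat &X, const mat &W, const mat &U, const rowvec &b,
                    LSTMCache &cc) {
  const arma::uword L = X.n_rows, h = U.n_rows;
  cc.X = X;
  cc.H.set_size(L, h); cc.C.set_size(L, h);
  cc.I.set_size(L, h); cc.F.set_size(L, h); cc.G.set_size(L, h);
  cc.O.set_size(L, h); cc.Tc.set_size(L, h);
  rowvec hp(h, arma::fill::zeros), cp(h, arma::fill::zeros);
  for (arma::uword t = 0; t < L; ++t) {
    rowvec a = X.row(t) * W + hp * U + b;
    rowvec i = sigm(a.cols(0, h - 1));
    rowvec f = sigm(a.cols(h, 2 * h - 1));
    rowvec g = arma::tanh(a.cols(2 * h, 3 * h - 1));
    rowvec o = sigm(a.cols(3 * h, 4 * h - 1));
    rowvec c = f % cp + i % g;
    rowvec tc = arma::tanh(c);
    cc.I.row(t) = i; cc.F.row(t) = f; cc.G.row(t) = g; cc.O.row(t) = o;
    cc.C.row(t) = c; cc.Tc.row(t) = tc;
    hp = o % tc; cc.H.row(t) = hp; cp = c;
  }
  return cc.H;
}
static mat lstm_bwd(const mat &dH, const mat &W, const mat &U,
                    const LSTMCache &cc, mat &dW, mat &dU, rowvec &db) {
  const arma::uword L = dH.n_rows, h = U.n_rows;
  dW.zeros(W.n_rows, W.n_cols); dU.zeros(h, 4 * h); db.zeros(4 * h);
  mat dX(L, cc.X.n_cols, arma::fill::zeros);
  rowvec dh_next(h, arma::fill::zeros), dc(h, arma::fill::zeros);
  for (arma::uword tt = L; tt-- > 0;) {
    rowvec dh = dH.row(tt) + dh_next;
    rowvec i = cc.I.row(tt), f = cc.F.row(tt), g = cc.G.row(tt),
           o = cc.O.row(tt), tc = cc.Tc.row(tt);
    rowvec cprev = tt > 0 ? rowvec(cc.C.row(tt - 1))
                          : rowvec(h, arma::fill::zeros);
    rowvec do_ = dh % tc;
    dc += dh % o % (1.0 - tc % tc);
    rowvec di = dc % g, dg = dc % i, df = dc % cprev;
    rowvec dc_prev = dc % f;
    rowvec da(4 * h);
    da.cols(0, h - 1)         = di % i % (1.0 - i);
    da.cols(h, 2 * h - 1)     = df % f % (1.0 - f);
    da.cols(2 * h, 3 * h - 1) = dg % (1.0 - g % g);
    da.cols(3 * h, 4 * h - 1) = do_ % o % (1.0 - o);
    dW += cc.X.row(tt).t() * da;
    if (tt > 0) dU += cc.H.row(tt - 1).t() * da;
    db += da;
    dX.row(tt) = da * W.t();
    dh_next = da * U.t();
    dc = dc_prev;
  }
  return dX;
}

// ---- 3x3 convolution on an L x L grid stored as (L*L) x C -------------
// cell index = r + c*L; neighbourhood k = (dr+1) + 3*(dc+1); zero padding.
static mat im2col(const mat &in, int L) {
  const int C = in.n_cols;
  mat out(L * L, 9 * C, arma::fill::zeros);
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      const int k = (dr + 1) + 3 * (dc + 1);
      const int r0 = std::max(0, -dr), r1 = std::min(L, L - dr);
      const int c0 = std::max(0, -dc), c1 = std::min(L, L - dc);
      for (int ch = 0; ch < C; ++ch) {
        for (int c = c0; c < c1; ++c) {
          for (int r = r0; r < r1; ++r)
            out(r + c * L, k * C + ch) = in((r + dr) + (c + dc) * L, ch);
        }
      }
    }
  }
  return out;
}
static mat col2im(const mat &dcol, int L, int C) {
  mat din(L * L, C, arma::fill::zeros);
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      const int k = (dr + 1) + 3 * (dc + 1);
      const int r0 = std::max(0, -dr), r1 = std::min(L, L - dr);
      const int c0 = std::max(0, -dc), c1 = std::min(L, L - dc);
      for (int ch = 0; ch < C; ++ch) {
        for (int c = c0; c < c1; ++c) {
          for (int r = r0; r < r1; ++r)
            din((r + dr) + (c + dc) * L, ch) += dcol(r + c * L, k * C + ch);
        }
      }
    }
  }
  return din;
}

static mat drop_mask(arma::uword n, arma::uword m, double p) {
  mat mask(n, m);
  const double keep = 1.0 - p;
  for (arma::uword j = 0; j < m; ++j)
    for (arma::uword i = 0; i < n; ++i)
      mask(i, j) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
  return mask;
}

static mat getm(const List &P, const std::string &nm) {
  return as<mat>(P[nm]);
}
static rowvec getv(const List &P, const std::string &nm) {
  return as<rowvec>(P[nm]);
}

// ---- full network ----------------------------------------------------
// cfg: N, act (0 leaky, 1 swish), dropout
// loss_type: -1 none (predict), 0 CE, 1 soft-F1
// [[Rcpp::export(name = ".sf2d_run_cpp")]]
List sf2d_run_cpp(List P, arma::mat X, arma::mat Y, List cfg,
                  bool training, int loss_type, bool want_grad) {
  const int N = as<int>(cfg["N"]);
  const int atype = as<int>(cfg["act"]);
  const double pdrop = training ? as<double>(cfg["dropout"]) : 0.0;
  const int L = X.n_rows;
  const int L2 = L * L;

  // --- input block
  mat W0 = getm(P, "inp_W0"), W1 = getm(P, "inp_W1");
  rowvec b0 = getv(P, "inp_b0"), b1 = getv(P, "inp_b1");
  mat A0 = X * W0; A0.each_row() += b0;
  mat H0 = act_f(A0, atype);
  mat A1 = H0 * W1; A1.each_row() += b1;
  mat H = act_f(A1, atype);
  const int C = H.n_cols;

  // --- sequence blocks
  std::vector<LNCache> s_ln(N);
  std::vector<LSTMCache> s_lf(N), s_lb(N);
  std::vector<mat> s_Hin(N), s_U(N), s_P1(N), s_A1(N), s_mask(N);
  for (int n = 0; n < N; ++n) {
    const std::string p = "s" + std::to_string(n + 1) + "_";
    s_Hin[n] = H;
    mat Zn = ln_fwd(H, getv(P, p + "ln_g"), getv(P, p + "ln_b"), s_ln[n]);
    mat Hf = lstm_fwd(Zn, getm(P, p + "Wxf"), getm(P, p + "Whf"),
                      getv(P, p + "bf"), s_lf[n]);
    mat Zr = arma::flipud(Zn);
    mat Hb = lstm_fwd(Zr, getm(P, p + "Wxb"), getm(P, p + "Whb"),
                      getv(P, p + "bb"), s_lb[n]);
    Hb = arma::flipud(Hb);
    mat U = arma::join_rows(Hf, Hb);
    s_U[n] = U;
    mat P1 = U * getm(P, p + "Wp"); P1.each_row() += getv(P, p + "bp");
    s_P1[n] = P1;
    mat Aa = act_f(P1, atype);
    s_A1[n] = Aa;
    mat P2 = Aa * getm(P, p + "Wq"); P2.each_row() += getv(P, p + "bq");
    if (pdrop > 0) { s_mask[n] = drop_mask(L, C, pdrop); P2 %= s_mask[n]; }
    H += P2;
  }

  // --- pair transform: Q0[(i,j), c] = H(i,c) * H(j,c)
  mat G = H;
  mat Q(L2, C);
  for (int c = 0; c < C; ++c) {
    mat q = G.col(c) * G.col(c).t();  // L x L
    Q.col(c) = arma::vectorise(q);
  }
  mat Q0 = Q;

  // --- conv blocks
  std::vector<LNCache> c_ln1(N), c_ln2(N);
  std::vector<mat> c_Qin(N), c_T0(N), c_M1(N), c_C1(N), c_mask1(N),
      c_D1(N), c_T1(N), c_M2(N), c_mask2(N);
  for (int n = 0; n < N; ++n) {
    const std::string p = "c" + std::to_string(n + 1) + "_";
    c_Qin[n] = Q;
    mat T0 = ln_fwd(Q, getv(P, p + "n1_g"), getv(P, p + "n1_b"), c_ln1[n]);
    c_T0[n] = T0;
    mat A0c = act_f(T0, atype);
    c_M1[n] = im2col(A0c, L);
    mat C1 = c_M1[n] * getm(P, p + "K1");
    C1.each_row() += getv(P, p + "cb1");
    c_C1[n] = C1;
    mat D1 = C1;
    if (pdrop > 0) { c_mask1[n] = drop_mask(L2, C1.n_cols, pdrop); D1 %= c_mask1[n]; }
    c_D1[n] = D1;
    mat T1 = ln_fwd(D1, getv(P, p + "n2_g"), getv(P, p + "n2_b"), c_ln2[n]);
    c_T1[n] = T1;
    mat A1c = act_f(T1, atype);
    c_M2[n] = im2col(A1c, L);
    mat C2 = c_M2[n] * getm(P, p + "K2");
    C2.each_row() += getv(P, p + "cb2");
    if (pdrop > 0) { c_mask2[n] = drop_mask(L2, C, pdrop); C2 %= c_mask2[n]; }
    Q += C2;
  }

  // --- head
  mat Ah0 = act_f(Q, atype);
  mat Z1 = Ah0 * getm(P, "head_W1"); Z1.each_row() += getv(P, "head_b1");
  mat Ah1 = act_f(Z1, atype);
  mat Z2 = Ah1 * getm(P, "head_W2"); Z2.each_row() += getv(P, "head_b2");
  mat Ah2 = act_f(Z2, atype);
  mat Z3 = Ah2 * getm(P, "head_W3"); Z3.each_row() += getv(P, "head_b3");
  // 2-class softmax, channel 2 = paired
  vec d = Z3.col(1) - Z3.col(0);
  vec praw = 1.0 / (1.0 + arma::exp(-d));
  mat Mraw = arma::reshape(praw, L, L);
  mat Msym = 0.5 * (Mraw + Mraw.t());

  double loss = NA_REAL;
  mat dMsym;
  if (loss_type >= 0) {
    vec y = arma::vectorise(Y);
    vec ps = arma::vectorise(Msym);
    if (loss_type == 0) {
      vec pc = arma::clamp(ps, 1e-7, 1.0 - 1e-7);
      loss = arma::mean(-(y % arma::log(pc) + (1.0 - y) % arma::log(1.0 - pc)));
      if (want_grad) {
        vec dps = (-(y / pc) + (1.0 - y) / (1.0 - pc)) / (double)L2;
        dMsym = arma::reshape(dps, L, L);
      }
    } else {
      const double eps = 1e-12;
      double A = arma::dot(ps, y);
      double D = arma::accu(ps) + arma::accu(y);
      loss = 1.0 - 2.0 * A / (D + eps);
      if (want_grad) {
        vec dps = -(2.0 * y * (D + eps) - 2.0 * A) / ((D + eps) * (D + eps));
        dMsym = arma::reshape(dps, L, L);
      }
    }
  }

  if (!want_grad || loss_type < 0) {
    return List::create(_["ppm"] = Msym, _["loss"] = loss);
  }

  // ================= backward =================
  List Gd;  // gradients, same names as params
  mat dMraw = 0.5 * (dMsym + dMsym.t());
  vec dp = arma::vectorise(dMraw);
  vec dd = dp % praw % (1.0 - praw);
  mat dZ3(L2, 2);
  dZ3.col(0) = -dd; dZ3.col(1) = dd;

  Gd["head_W3"] = mat(Ah2.t() * dZ3);
  Gd["head_b3"] = rowvec(arma::sum(dZ3, 0));
  mat dAh2 = dZ3 * getm(P, "head_W3").t();
  mat dZ2 = dAh2 % act_df(Z2, atype);
  Gd["head_W2"] = mat(Ah1.t() * dZ2);
  Gd["head_b2"] = rowvec(arma::sum(dZ2, 0));
  mat dAh1 = dZ2 * getm(P, "head_W2").t();
  mat dZ1 = dAh1 % act_df(Z1, atype);
  Gd["head_W1"] = mat(Ah0.t() * dZ1);
  Gd["head_b1"] = rowvec(arma::sum(dZ1, 0));
  mat dAh0 = dZ1 * getm(P, "head_W1").t();
  mat dQ = dAh0 % act_df(Q, atype);

  for (int n = N - 1; n >= 0; --n) {
    const std::string p = "c" + std::to_string(n + 1) + "_";
    mat dC2 = dQ;  // through residual add
    if (pdrop > 0) dC2 %= c_mask2[n];
    Gd[p + "K2"] = mat(c_M2[n].t() * dC2);
    Gd[p + "cb2"] = rowvec(arma::sum(dC2, 0));
    mat dM2 = dC2 * getm(P, p + "K2").t();
    const int Cm = c_C1[n].n_cols;
    mat dA1c = col2im(dM2, L, Cm);
    mat dT1 = dA1c % act_df(c_T1[n], atype);
    rowvec dg2, db2;
    mat dD1 = ln_bwd(dT1, getv(P, p + "n2_g"), c_ln2[n], dg2, db2);
    Gd[p + "n2_g"] = dg2; Gd[p + "n2_b"] = db2;
    mat dC1 = dD1;
    if (pdrop > 0) dC1 %= c_mask1[n];
    Gd[p + "K1"] = mat(c_M1[n].t() * dC1);
    Gd[p + "cb1"] = rowvec(arma::sum(dC1, 0));
    mat dM1 = dC1 * getm(P, p + "K1").t();
    mat dA0c = col2im(dM1, L, C);
    mat dT0 = dA0c % act_df(c_T0[n], atype);
    rowvec dg1, db1;
    mat dQin = ln_bwd(dT0, getv(P, p + "n1_g"), c_ln1[n], dg1, db1);
    Gd[p + "n1_g"] = dg1; Gd[p + "n1_b"] = db1;
    dQ += dQin;  // residual
  }

  // pair transform backward
  mat dG(L, C);
  for (int c = 0; c < C; ++c) {
    mat Dq = arma::reshape(dQ.col(c), L, L);
    dG.col(c) = (Dq + Dq.t()) * G.col(c);
  }
  mat dH = dG;

  for (int n = N - 1; n >= 0; --n) {
    const std::string p = "s" + std::to_string(n + 1) + "_";
    mat dP2 = dH;  // through residual add
    if (pdrop > 0) dP2 %= s_mask[n];
    Gd[p + "Wq"] = mat(s_A1[n].t() * dP2);
    Gd[p + "bq"] = rowvec(arma::sum(dP2, 0));
    mat dAa = dP2 * getm(P, p + "Wq").t();
    mat dP1 = dAa % act_df(s_P1[n], atype);
    Gd[p + "Wp"] = mat(s_U[n].t() * dP1);
    Gd[p + "bp"] = rowvec(arma::sum(dP1, 0));
    mat dU = dP1 * getm(P, p + "Wp").t();
    const int h = s_lf[n].H.n_cols;
    mat dHf = dU.cols(0, h - 1);
    mat dHb = dU.cols(h, 2 * h - 1);
    mat dWxf, dWhf, dWxb, dWhb;
    rowvec dbf, dbb;
    mat dZf = lstm_bwd(dHf, getm(P, p + "Wxf"), getm(P, p + "Whf"),
                       s_lf[n], dWxf, dWhf, dbf);
    mat dZb = lstm_bwd(arma::flipud(dHb), getm(P, p + "Wxb"),
                       getm(P, p + "Whb"), s_lb[n], dWxb, dWhb, dbb);
    dZb = arma::flipud(dZb);
    Gd[p + "Wxf"] = dWxf; Gd[p + "Whf"] = dWhf; Gd[p + "bf"] = dbf;
    Gd[p + "Wxb"] = dWxb; Gd[p + "Whb"] = dWhb; Gd[p + "bb"] = dbb;
    mat dZn = dZf + dZb;
    rowvec dlg, dlb;
    mat dHin = ln_bwd(dZn, getv(P, p + "ln_g"), s_ln[n], dlg, dlb);
    Gd[p + "ln_g"] = dlg; Gd[p + "ln_b"] = dlb;
    dH = dH + dHin;  // residual
  }

  // input block backward
  mat dA1i = dH % act_df(A1, atype);
  Gd["inp_W1"] = mat(H0.t() * dA1i);
  Gd["inp_b1"] = rowvec(arma::sum(dA1i, 0));
  mat dH0 = dA1i * W1.t();
  mat dA0i = dH0 % act_df(A0, atype);
  Gd["inp_W0"] = mat(X.t() * dA0i);
  Gd["inp_b0"] = rowvec(arma::sum(dA0i, 0));

  return List::create(_["ppm"] = Msym, _["loss"] = loss, _["grads"] = Gd);
}
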