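// Fast path for the recurrent dual-pathway agent: forward step, episode
// rollout and backpropagation-through-time, mirroring the R reference
// implementation in R/model.R and R/train.R exactly (same layer math, same
// tie-breaking, same guards). The test suite asserts agreement between the
// two routes; the R versions remain the readable reference.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::uword;

// ---- primitives ----------------------------------------------------------

// X: (npix x C), column-major pixel index p = i + (j-1)*h (0-based: i + j*h).
// Output (npix x 9C); column block ob = dx*3+dy holds x[i+dy-1, j+dx-1, c].
static mat im2col(const mat& X, int h, int w) {
  const int C = X.n_cols, npix = h * w;
  mat out(npix, 9 * C, arma::fill::zeros);
  int ob = 0;
  for (int dx = 0; dx <= 2; ++dx) for (int dy = 0; dy <= 2; ++dy, ++ob) {
    for (int c = 0; c < C; ++c) {
      double* dst = out.colptr(ob * C + c);
      const double* src = X.colptr(c);
      for (int j = 0; j < w; ++j) {
        const int js = j + dx - 1;
        if (js < 0 || js >= w) continue;
        const int i0 = std::max(0, 1 - dy), i1 = std::min(h, h + 1 - dy);
        for (int i = i0; i < i1; ++i)
          dst[i + j * h] = src[(i + dy - 1) + js * h];
      }
    }
  }
  return out;
}

static mat col2im(const mat& G, int h, int w) {
  const int C = G.n_cols / 9, npix = h * w;
  mat out(npix, C, arma::fill::zeros);
  int ob = 0;
  for (int dx = 0; dx <= 2; ++dx) for (int dy = 0; dy <= 2; ++dy, ++ob) {
    for (int c = 0; c < C; ++c) {
      const double* src = G.colptr(ob * C + c);
      double* dst = out.colptr(c);
      for (int j = 0; j < w; ++j) {
        const int js = j + dx - 1;
        if (js < 0 || js >= w) continue;
        const int i0 = std::max(0, 1 - dy), i1 = std::min(h, h + 1 - dy);
        for (int i = i0; i < i1; ++i)
          dst[(i + dy - 1) + js * h] += src[i + j * h];
      }
    }
  }
  return out;
}

static mat add_bias(mat Y, const rowvec& b) { Y.each_row() += b; return Y; }

static mat sigm(const mat& X) { return 1.0 / (1.0 + arma::exp(-X)); }

static mat relu(const mat& X) { return X % (X > 0); }

// LRN with channel band |f-g| <= floor(C/2); beta handled generally.
struct LrnCache { mat X, base, P; double alpha, beta; };

static mat lrn_fwd(const mat& X, double k, double alpha, double beta,
                   LrnCache& ca) {
  const int C = X.n_cols;
  const int half = C / 2;
  mat X2 = X % X;
  mat S(X.n_rows, C);
  for (int f = 0; f < C; ++f) {
    const int lo = std::max(0, f - half), hi = std::min(C - 1, f + half);
    S.col(f) = arma::sum(X2.cols(lo, hi), 1);
  }
  mat base = k + alpha * S;
  mat D = (beta == 1.0) ? base : mat(arma::pow(base, beta));
  const double eps = (k == 0.0) ? 1e-8 : 0.0;
  ca.X = X; ca.base = base; ca.P = 1.0 / (D + eps);
  ca.alpha = alpha; ca.beta = beta;
  return X % ca.P;
}

static mat lrn_bwd(const mat& G, const LrnCache& ca) {
  const int C = ca.X.n_cols;
  const int half = C / 2;
  mat Bm1 = (ca.beta == 1.0)
    ? mat(arma::conv_to<mat>::from(ca.base > 0))
    : mat(arma::pow(arma::clamp(ca.base, 0.0, arma::datum::inf),
                    ca.beta - 1.0) % (ca.base > 0));
  mat T = (G % ca.X) % (-(ca.alpha * ca.beta) * Bm1 % ca.P % ca.P);
  mat TS(T.n_rows, C);
  for (int f = 0; f < C; ++f) {
    const int lo = std::max(0, f - half), hi = std::min(C - 1, f + half);
    TS.col(f) = arma::sum(T.cols(lo, hi), 1);
  }
  return G % ca.P + 2.0 * ca.X % TS;
}

// 2x2/stride-2 max pool; ties resolved by corner order TL, BL, TR, BR
// (matching max.col(ties = "first") on that column order in R).
struct PoolCache { arma::umat win; int h, w; };

static mat pool_fwd(const mat& X, int h, int w, PoolCache& ca) {
  const int h2 = h / 2, w2 = w / 2, C = X.n_cols, n2 = h2 * w2;
  mat Y(n2, C);
  ca.win.set_size(n2, C); ca.h = h; ca.w = w;
  for (int c = 0; c < C; ++c) {
    const double* src = X.colptr(c);
    for (int j = 0; j < w2; ++j) for (int i = 0; i < h2; ++i) {
      const int base = 2 * i + 2 * j * h;
      const int cand[4] = { base, base + 1, base + h, base + h + 1 };
      int best = 0;
      double bv = src[cand[0]];
      for (int t = 1; t < 4; ++t)
        if (src[cand[t]] > bv) { bv = src[cand[t]]; best = t; }
      Y(i + j * h2, c) = bv;
      ca.win(i + j * h2, c) = cand[best];
    }
  }
  return Y;
}

static mat pool_bwd(const mat& G, const PoolCache& ca) {
  const int C = G.n_cols;
  mat out(ca.h * ca.w, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (uword p = 0; p < G.n_rows; ++p)
      out(ca.win(p, c), c) += G(p, c);
  return out;
}

static rowvec softmax_row(const rowvec& z) {
  rowvec e = arma::exp(z - z.max());
  return e / arma::accu(e);
}

// ---- parameter bundle -----------------------------------------------------

struct Params {
  mat clf_c1_W, clf_c2_W, clf_c3_W;
  rowvec clf_c1_b, clf_c2_b, clf_c3_b;
  mat clf_fc_Wx, clf_fc_We, clf_fc_Wj; rowvec clf_fc_b;
  mat mot_f1_Wj, mot_f1_Wk, mot_f1_Wo;
  mat mot_f2_Wj, mot_f2_Wk, mot_f2_Wo;
  mat mot_fc_Wx, mot_fc_We, mot_fc_Wj; rowvec mot_fc_b;
  mat mot_ff_Wj, mot_ff_Wk, mot_ff_Wo;
  mat pos_fc_Wx, pos_fc_We; rowvec pos_fc_b;
  mat pos_ff_Wj, pos_ff_Wk, pos_ff_Wo;
  mat fus_W; rowvec fus_b;
  mat hq_W; rowvec hq_b;
  mat hc_W; rowvec hc_b;
  // precombined gate pairs
  mat f1_Wjk, f2_Wjk, mff_Wjk, pff_Wjk;
};

static mat getm(const List& L, const char* nm) {
  return as<mat>(L[nm]);
}
static rowvec getv(const List& L, const char* nm) {
  return as<rowvec>(as<NumericVector>(L[nm]));
}

static Params unpack(const List& pr) {
  Params P;
  P.clf_c1_W = getm(pr, "clf_c1_W"); P.clf_c1_b = getv(pr, "clf_c1_b");
  P.clf_c2_W = getm(pr, "clf_c2_W"); P.clf_c2_b = getv(pr, "clf_c2_b");
  P.clf_c3_W = getm(pr, "clf_c3_W"); P.clf_c3_b = getv(pr, "clf_c3_b");
  P.clf_fc_Wx = getm(pr, "clf_fc_Wx"); P.clf_fc_We = getm(pr, "clf_fc_We");
  P.clf_fc_Wj = getm(pr, "clf_fc_Wj"); P.clf_fc_b = getv(pr, "clf_fc_b");
  P.mot_f1_Wj = getm(pr, "mot_f1_Wj"); P.mot_f1_Wk = getm(pr, "mot_f1_Wk");
  P.mot_f1_Wo = getm(pr, "mot_f1_Wo");
  P.mot_f2_Wj = getm(pr, "mot_f2_Wj"); P.mot_f2_Wk = getm(pr, "mot_f2_Wk");
  P.mot_f2_Wo = getm(pr, "mot_f2_Wo");
  P.mot_fc_Wx = getm(pr, "mot_fc_Wx"); P.mot_fc_We = getm(pr, "mot_fc_We");
  P.mot_fc_Wj = getm(pr, "mot_fc_Wj"); P.mot_fc_b = getv(pr, "mot_fc_b");
  P.mot_ff_Wj = getm(pr, "mot_ff_Wj"); P.mot_ff_Wk = getm(pr, "mot_ff_Wk");
  P.mot_ff_Wo = getm(pr, "mot_ff_Wo");
  P.pos_fc_Wx = getm(pr, "pos_fc_Wx"); P.pos_fc_We = getm(pr, "pos_fc_We");
  P.pos_fc_b = getv(pr, "pos_fc_b");
  P.pos_ff_Wj = getm(pr, "pos_ff_Wj"); P.pos_ff_Wk = getm(pr, "pos_ff_Wk");
  P.pos_ff_Wo = getm(pr, "pos_ff_Wo");
  P.fus_W = getm(pr, "fus_W"); P.fus_b = getv(pr, "fus_b");
  P.hq_W = getm(pr, "hq_W"); P.hq_b = getv(pr, "hq_b");
  P.hc_W = getm(pr, "hc_W"); P.hc_b = getv(pr, "hc_b");
  P.f1_Wjk = arma::join_rows(P.mot_f1_Wj, P.mot_f1_Wk);
  P.f2_Wjk = arma::join_rows(P.mot_f2_Wj, P.mot_f2_Wk);
  P.mff_Wjk = arma::join_rows(P.mot_ff_Wj, P.mot_ff_Wk);
  P.pff_Wjk = arma::join_rows(P.pos_ff_Wj, P.pos_ff_Wk);
  return P;
}

struct Cfg {
  int g, Cg, k1, k2, k3, FCw, m1, m2, M, FF, Pw, PF, U, n_out;
  double lk, la, lb;
};

static Cfg unpack_cfg(const List& cfg) {
  Cfg c;
  c.g = as<int>(cfg["glimpse_size"]);
  c.Cg = as<int>(cfg["glimpse_depth"]);
  IntegerVector cc = cfg["clf_conv"];
  c.k1 = cc[0]; c.k2 = cc[1]; c.k3 = cc[2];
  c.FCw = as<int>(cfg["clf_fc"]);
  IntegerVector mc = cfg["mot_conv"];
  c.m1 = mc[0]; c.m2 = mc[1];
  c.M = as<int>(cfg["mot_fc"]);
  c.FF = as<int>(cfg["mot_ff"]);
  c.Pw = as<int>(cfg["pos_fc"]);
  c.PF = as<int>(cfg["pos_ff"]);
  c.U = as<int>(cfg["fusion"]);
  c.n_out = as<int>(cfg["n_out"]);
  c.lk = as<double>(cfg["lrn_k"]);
  c.la = as<double>(cfg["lrn_alpha"]);
  c.lb = as<double>(cfg["lrn_beta"]);
  return c;
}

struct State {
  mat e_clf, j_clf, e_mot, j_mot, e_pos, H_m1, H_m2, H_mf, H_pf;
};

static State init_state(const Cfg& c) {
  State s;
  s.e_clf.zeros(1, c.FCw); s.j_clf.zeros(1, c.n_out);
  s.e_mot.zeros(1, c.M); s.j_mot.zeros(1, 3);
  s.e_pos.zeros(1, c.Pw);
  s.H_m1.ones(c.g * c.g, c.m1);
  s.H_m2.ones((c.g / 2) * (c.g / 2), c.m2);
  s.H_mf.ones(1, c.FF); s.H_pf.ones(1, c.PF);
  return s;
}

// ---- forward step ---------------------------------------------------------

struct StepCache {
  mat c1_X2, c1_y; LrnCache l1; mat l1y; PoolCache p1; mat p1y;
  mat c2_X2, c2_y; LrnCache l2; mat l2y; PoolCache p2; mat p2y;
  mat c3_X2, c3_y; mat r3;
  mat fcc_in, fcc_a, fcc_y;          // classifier FCEJ (x, e, j inputs kept)
  mat fcc_x, fcc_e, fcc_j;
  mat f1_In2, f1_J, f1_K, f1_H, f1_Hn, f1_O;
  LrnCache ml1; mat ml1y; PoolCache mp1; mat mp1y;
  mat f2_In2, f2_J, f2_K, f2_H, f2_Hn, f2_O;
  LrnCache ml2; mat ml2y; PoolCache mp2; mat mp2y;
  mat fcm_x, fcm_e, fcm_j, fcm_a, fcm_y;
  mat ffm_In, ffm_J, ffm_K, ffm_H, ffm_Hn, ffm_O;
  mat enc, fcp_e, fcp_a, fcp_y;
  mat ffp_In, ffp_J, ffp_K, ffp_H, ffp_Hn, ffp_O;
  mat cat_, fa, fy;
  rowvec q, p;
};

static void step_forward(const Params& P, const Cfg& c, const mat& gm,
                         double theta_deg, State& st, StepCache& ca) {
  const int g = c.g, g2 = g / 2, g4 = g / 4;
  // classifier pipeline
  ca.c1_X2 = im2col(gm, g, g);
  ca.c1_y = add_bias(ca.c1_X2 * P.clf_c1_W, P.clf_c1_b);
  ca.l1y = lrn_fwd(ca.c1_y, c.lk, c.la, c.lb, ca.l1);
  ca.p1y = pool_fwd(relu(ca.l1y), g, g, ca.p1);
  ca.c2_X2 = im2col(ca.p1y, g2, g2);
  ca.c2_y = add_bias(ca.c2_X2 * P.clf_c2_W, P.clf_c2_b);
  ca.l2y = lrn_fwd(ca.c2_y, c.lk, c.la, c.lb, ca.l2);
  ca.p2y = pool_fwd(relu(ca.l2y), g2, g2, ca.p2);
  ca.c3_X2 = im2col(ca.p2y, g4, g4);
  ca.c3_y = add_bias(ca.c3_X2 * P.clf_c3_W, P.clf_c3_b);
  ca.r3 = relu(ca.c3_y);
  ca.fcc_x = mat(ca.r3.memptr(), 1, g4 * g4 * c.k3);  // column-major flatten
  ca.fcc_e = st.e_clf; ca.fcc_j = st.j_clf;
  ca.fcc_a = ca.fcc_x * P.clf_fc_Wx + ca.fcc_e * P.clf_fc_We +
             ca.fcc_j * P.clf_fc_Wj;
  ca.fcc_a += P.clf_fc_b;
  ca.fcc_y = relu(ca.fcc_a);
  // motion pipeline
  ca.f1_H = st.H_m1;
  ca.f1_In2 = im2col(arma::join_rows(gm, st.H_m1), g, g);
  {
    mat JK = sigm(ca.f1_In2 * P.f1_Wjk);
    ca.f1_J = JK.cols(0, c.m1 - 1);
    ca.f1_K = JK.cols(c.m1, 2 * c.m1 - 1);
  }
  ca.f1_Hn = ca.f1_J % (1.0 - ca.f1_H) + (1.0 - ca.f1_K) % ca.f1_H;
  ca.f1_O = arma::tanh(ca.f1_Hn * P.mot_f1_Wo);
  ca.ml1y = lrn_fwd(ca.f1_O, c.lk, c.la, c.lb, ca.ml1);
  ca.mp1y = pool_fwd(relu(ca.ml1y), g, g, ca.mp1);
  ca.f2_H = st.H_m2;
  ca.f2_In2 = im2col(arma::join_rows(ca.mp1y, st.H_m2), g2, g2);
  {
    mat JK = sigm(ca.f2_In2 * P.f2_Wjk);
    ca.f2_J = JK.cols(0, c.m2 - 1);
    ca.f2_K = JK.cols(c.m2, 2 * c.m2 - 1);
  }
  ca.f2_Hn = ca.f2_J % (1.0 - ca.f2_H) + (1.0 - ca.f2_K) % ca.f2_H;
  ca.f2_O = arma::tanh(ca.f2_Hn * P.mot_f2_Wo);
  ca.ml2y = lrn_fwd(ca.f2_O, c.lk, c.la, c.lb, ca.ml2);
  ca.mp2y = pool_fwd(relu(ca.ml2y), g2, g2, ca.mp2);
  ca.fcm_x = mat(ca.mp2y.memptr(), 1, g4 * g4 * c.m2);
  ca.fcm_e = st.e_mot; ca.fcm_j = st.j_mot;
  ca.fcm_a = ca.fcm_x * P.mot_fc_Wx + ca.fcm_e * P.mot_fc_We +
             ca.fcm_j * P.mot_fc_Wj;
  ca.fcm_a += P.mot_fc_b;
  ca.fcm_y = relu(ca.fcm_a);
  ca.ffm_H = st.H_mf;
  ca.ffm_In = arma::join_rows(ca.fcm_y, st.H_mf);
  {
    mat JK = sigm(ca.ffm_In * P.mff_Wjk);
    ca.ffm_J = JK.cols(0, c.FF - 1);
    ca.ffm_K = JK.cols(c.FF, 2 * c.FF - 1);
  }
  ca.ffm_Hn = ca.ffm_J % (1.0 - ca.ffm_H) + (1.0 - ca.ffm_K) % ca.ffm_H;
  ca.ffm_O = arma::tanh(ca.ffm_Hn * P.mot_ff_Wo);
  // position pipeline
  // wrap to [0, 360) without fmod (avoids a versioned libm symbol newer
  // than some host C libraries provide)
  const double tw = theta_deg - 360.0 * std::floor(theta_deg / 360.0);
  const double th = tw * M_PI / 180.0;
  ca.enc = mat(1, 2);
  ca.enc(0, 0) = std::sin(th); ca.enc(0, 1) = std::cos(th);
  ca.fcp_e = st.e_pos;
  ca.fcp_a = ca.enc * P.pos_fc_Wx + ca.fcp_e * P.pos_fc_We;
  ca.fcp_a += P.pos_fc_b;
  ca.fcp_y = relu(ca.fcp_a);
  ca.ffp_H = st.H_pf;
  ca.ffp_In = arma::join_rows(ca.fcp_y, st.H_pf);
  {
    mat JK = sigm(ca.ffp_In * P.pff_Wjk);
    ca.ffp_J = JK.cols(0, c.PF - 1);
    ca.ffp_K = JK.cols(c.PF, 2 * c.PF - 1);
  }
  ca.ffp_Hn = ca.ffp_J % (1.0 - ca.ffp_H) + (1.0 - ca.ffp_K) % ca.ffp_H;
  ca.ffp_O = arma::tanh(ca.ffp_Hn * P.pos_ff_Wo);
  // fusion + heads
  ca.cat_ = arma::join_rows(ca.fcc_y, ca.ffm_O, ca.ffp_O);
  ca.fa = ca.cat_ * P.fus_W;
  ca.fa += P.fus_b;
  ca.fy = relu(ca.fa);
  ca.q = rowvec(mat(ca.fy * P.hq_W)) + P.hq_b;
  rowvec z = rowvec(mat(ca.fy * P.hc_W)) + P.hc_b;
  ca.p = softmax_row(z);
  // advance state
  st.e_clf = ca.fcc_y; st.j_clf = mat(ca.p);
  st.e_mot = ca.fcm_y; st.j_mot = mat(ca.q); st.e_pos = ca.fcp_y;
  st.H_m1 = ca.f1_Hn; st.H_m2 = ca.f2_Hn;
  st.H_mf = ca.ffm_Hn; st.H_pf = ca.ffp_Hn;
}

// ---- backward step --------------------------------------------------------

struct Grads {
  mat clf_c1_W, clf_c2_W, clf_c3_W;
  rowvec clf_c1_b, clf_c2_b, clf_c3_b;
  mat clf_fc_Wx, clf_fc_We, clf_fc_Wj; rowvec clf_fc_b;
  mat mot_f1_Wj, mot_f1_Wk, mot_f1_Wo;
  mat mot_f2_Wj, mot_f2_Wk, mot_f2_Wo;
  mat mot_fc_Wx, mot_fc_We, mot_fc_Wj; rowvec mot_fc_b;
  mat mot_ff_Wj, mot_ff_Wk, mot_ff_Wo;
  mat pos_fc_Wx, pos_fc_We; rowvec pos_fc_b;
  mat pos_ff_Wj, pos_ff_Wk, pos_ff_Wo;
  mat fus_W; rowvec fus_b;
  mat hq_W; rowvec hq_b;
  mat hc_W; rowvec hc_b;
};

static Grads zero_grads(const Params& P) {
  Grads G;
  G.clf_c1_W.zeros(arma::size(P.clf_c1_W)); G.clf_c1_b.zeros(P.clf_c1_b.n_elem);
  G.clf_c2_W.zeros(arma::size(P.clf_c2_W)); G.clf_c2_b.zeros(P.clf_c2_b.n_elem);
  G.clf_c3_W.zeros(arma::size(P.clf_c3_W)); G.clf_c3_b.zeros(P.clf_c3_b.n_elem);
  G.clf_fc_Wx.zeros(arma::size(P.clf_fc_Wx));
  G.clf_fc_We.zeros(arma::size(P.clf_fc_We));
  G.clf_fc_Wj.zeros(arma::size(P.clf_fc_Wj));
  G.clf_fc_b.zeros(P.clf_fc_b.n_elem);
  G.mot_f1_Wj.zeros(arma::size(P.mot_f1_Wj));
  G.mot_f1_Wk.zeros(arma::size(P.mot_f1_Wk));
  G.mot_f1_Wo.zeros(arma::size(P.mot_f1_Wo));
  G.mot_f2_Wj.zeros(arma::size(P.mot_f2_Wj));
  G.mot_f2_Wk.zeros(arma::size(P.mot_f2_Wk));
  G.mot_f2_Wo.zeros(arma::size(P.mot_f2_Wo));
  G.mot_fc_Wx.zeros(arma::size(P.mot_fc_Wx));
  G.mot_fc_We.zeros(arma::size(P.mot_fc_We));
  G.mot_fc_Wj.zeros(arma::size(P.mot_fc_Wj));
  G.mot_fc_b.zeros(P.mot_fc_b.n_elem);
  G.mot_ff_Wj.zeros(arma::size(P.mot_ff_Wj));
  G.mot_ff_Wk.zeros(arma::size(P.mot_ff_Wk));
  G.mot_ff_Wo.zeros(arma::size(P.mot_ff_Wo));
  G.pos_fc_Wx.zeros(arma::size(P.pos_fc_Wx));
  G.pos_fc_We.zeros(arma::size(P.pos_fc_We));
  G.pos_fc_b.zeros(P.pos_fc_b.n_elem);
  G.pos_ff_Wj.zeros(arma::size(P.pos_ff_Wj));
  G.pos_ff_Wk.zeros(arma::size(P.pos_ff_Wk));
  G.pos_ff_Wo.zeros(arma::size(P.pos_ff_Wo));
  G.fus_W.zeros(arma::size(P.fus_W)); G.fus_b.zeros(P.fus_b.n_elem);
  G.hq_W.zeros(arma::size(P.hq_W)); G.hq_b.zeros(P.hq_b.n_elem);
  G.hc_W.zeros(arma::size(P.hc_W)); G.hc_b.zeros(P.hc_b.n_elem);
  return G;
}

struct Carry {
  mat e_clf, j_clf, e_mot, j_mot, e_pos, H_m1, H_m2, H_mf, H_pf;
};

static Carry zero_carry(const Cfg& c) {
  Carry k;
  k.e_clf.zeros(1, c.FCw); k.j_clf.zeros(1, c.n_out);
  k.e_mot.zeros(1, c.M); k.j_mot.zeros(1, 3); k.e_pos.zeros(1, c.Pw);
  k.H_m1.zeros(c.g * c.g, c.m1);
  k.H_m2.zeros((c.g / 2) * (c.g / 2), c.m2);
  k.H_mf.zeros(1, c.FF); k.H_pf.zeros(1, c.PF);
  return k;
}

// dense/conv flip-flop backward (shared): returns gx; gH written in place.
static mat jkff_bwd(const mat& gO, const mat& gH_carry, const mat& In,
                    const mat& J, const mat& K, const mat& H, const mat& Hn,
                    const mat& O, const mat& Wj, const mat& Wk, const mat& Wo,
                    mat& dWj, mat& dWk, mat& dWo, mat& gH_out,
                    bool conv, int h, int w) {
  mat gZo = gO % (1.0 - O % O);
  mat gHn = gZo * Wo.t() + gH_carry;
  dWo += Hn.t() * gZo;
  mat zJ = (gHn % (1.0 - H)) % J % (1.0 - J);
  mat zK = (gHn % (-H)) % K % (1.0 - K);
  dWj += In.t() * zJ;
  dWk += In.t() * zK;
  mat gIn = zJ * Wj.t() + zK * Wk.t();
  if (conv) gIn = col2im(gIn, h, w);
  const int dx = gIn.n_cols - H.n_cols;
  gH_out = gIn.cols(dx, gIn.n_cols - 1) + gHn % (1.0 - K - J);
  return gIn.cols(0, dx - 1);
}

static Carry step_backward(const Params& P, const Cfg& c, const StepCache& ca,
                           rowvec gz, rowvec gq, const Carry& carry,
                           Grads& G) {
  const int g = c.g, g2 = g / 2, g4 = g / 4;
  // fold carried dL/dp through the softmax jacobian
  const rowvec& p = ca.p;
  rowvec gj = rowvec(carry.j_clf.row(0));
  gz += p % (gj - arma::dot(gj, p));
  gq += rowvec(carry.j_mot.row(0));
  // heads
  G.hq_W += ca.fy.t() * gq; G.hq_b += gq;
  G.hc_W += ca.fy.t() * gz; G.hc_b += gz;
  mat gfy = gq * P.hq_W.t() + gz * P.hc_W.t();
  mat gfa = gfy % (ca.fa > 0);
  G.fus_W += ca.cat_.t() * gfa; G.fus_b += rowvec(gfa.row(0));
  mat gcat = gfa * P.fus_W.t();
  mat g_oclf = gcat.cols(0, c.FCw - 1) + carry.e_clf;
  mat g_offm = gcat.cols(c.FCw, c.FCw + c.FF - 1);
  mat g_offp = gcat.cols(c.FCw + c.FF, c.FCw + c.FF + c.PF - 1);
  Carry nk = zero_carry(c);
  // classifier FCEJ
  {
    mat ga = g_oclf % (ca.fcc_a > 0);
    G.clf_fc_Wx += ca.fcc_x.t() * ga;
    G.clf_fc_We += ca.fcc_e.t() * ga;
    G.clf_fc_Wj += ca.fcc_j.t() * ga;
    G.clf_fc_b += rowvec(ga.row(0));
    nk.e_clf = ga * P.clf_fc_We.t();
    nk.j_clf = ga * P.clf_fc_Wj.t();
    mat gflat = ga * P.clf_fc_Wx.t();
    mat gr3(gflat.memptr(), g4 * g4, c.k3);
    mat gc3 = gr3 % (ca.c3_y > 0);
    G.clf_c3_W += ca.c3_X2.t() * gc3;
    G.clf_c3_b += arma::sum(gc3, 0);
    mat gp2 = col2im(gc3 * P.clf_c3_W.t(), g4, g4);
    mat gr2 = pool_bwd(gp2, ca.p2) % (ca.l2y > 0);
    mat gl2 = lrn_bwd(gr2, ca.l2);
    G.clf_c2_W += ca.c2_X2.t() * gl2;
    G.clf_c2_b += arma::sum(gl2, 0);
    mat gp1 = col2im(gl2 * P.clf_c2_W.t(), g2, g2);
    mat gr1 = pool_bwd(gp1, ca.p1) % (ca.l1y > 0);
    mat gl1 = lrn_bwd(gr1, ca.l1);
    G.clf_c1_W += ca.c1_X2.t() * gl1;
    G.clf_c1_b += arma::sum(gl1, 0);
  }
  // motion pipeline
  {
    mat gx_ff = jkff_bwd(g_offm, carry.H_mf, ca.ffm_In, ca.ffm_J, ca.ffm_K,
                         ca.ffm_H, ca.ffm_Hn, ca.ffm_O,
                         P.mot_ff_Wj, P.mot_ff_Wk, P.mot_ff_Wo,
                         G.mot_ff_Wj, G.mot_ff_Wk, G.mot_ff_Wo,
                         nk.H_mf, false, 0, 0);
    mat ga = (gx_ff + carry.e_mot) % (ca.fcm_a > 0);
    G.mot_fc_Wx += ca.fcm_x.t() * ga;
    G.mot_fc_We += ca.fcm_e.t() * ga;
    G.mot_fc_Wj += ca.fcm_j.t() * ga;
    G.mot_fc_b += rowvec(ga.row(0));
    nk.e_mot = ga * P.mot_fc_We.t();
    nk.j_mot = ga * P.mot_fc_Wj.t();
    mat gflat = ga * P.mot_fc_Wx.t();
    mat gmp2(gflat.memptr(), g4 * g4, c.m2);
    mat gmr2 = pool_bwd(gmp2, ca.mp2) % (ca.ml2y > 0);
    mat gml2 = lrn_bwd(gmr2, ca.ml2);
    mat gx2 = jkff_bwd(gml2, carry.H_m2, ca.f2_In2, ca.f2_J, ca.f2_K,
                       ca.f2_H, ca.f2_Hn, ca.f2_O,
                       P.mot_f2_Wj, P.mot_f2_Wk, P.mot_f2_Wo,
                       G.mot_f2_Wj, G.mot_f2_Wk, G.mot_f2_Wo,
                       nk.H_m2, true, g2, g2);
    mat gmr1 = pool_bwd(gx2, ca.mp1) % (ca.ml1y > 0);
    mat gml1 = lrn_bwd(gmr1, ca.ml1);
    jkff_bwd(gml1, carry.H_m1, ca.f1_In2, ca.f1_J, ca.f1_K,
             ca.f1_H, ca.f1_Hn, ca.f1_O,
             P.mot_f1_Wj, P.mot_f1_Wk, P.mot_f1_Wo,
             G.mot_f1_Wj, G.mot_f1_Wk, G.mot_f1_Wo,
             nk.H_m1, true, g, g);
  }
  // position pipeline
  {
    mat gx_pf = jkff_bwd(g_offp, carry.H_pf, ca.ffp_In, ca.ffp_J, ca.ffp_K,
                         ca.ffp_H, ca.ffp_Hn, ca.ffp_O,
                         P.pos_ff_Wj, P.pos_ff_Wk, P.pos_ff_Wo,
                         G.pos_ff_Wj, G.pos_ff_Wk, G.pos_ff_Wo,
                         nk.H_pf, false, 0, 0);
    mat ga = (gx_pf + carry.e_pos) % (ca.fcp_a > 0);
    G.pos_fc_Wx += ca.enc.t() * ga;
    G.pos_fc_We += ca.fcp_e.t() * ga;
    G.pos_fc_b += rowvec(ga.row(0));
    nk.e_pos = ga * P.pos_fc_We.t();
  }
  return nk;
}

// ---- exported entry points ------------------------------------------------

static List state_to_list(const State& st) {
  List s = List::create(
    _["e_clf"] = st.e_clf, _["j_clf"] = st.j_clf, _["e_mot"] = st.e_mot,
    _["j_mot"] = st.j_mot, _["e_pos"] = st.e_pos, _["H_m1"] = st.H_m1,
    _["H_m2"] = st.H_m2, _["H_mf"] = st.H_mf, _["H_pf"] = st.H_pf);
  s.attr("class") = "bias3d_state";
  return s;
}

static State state_from_list(const List& L) {
  State st;
  st.e_clf = getm(L, "e_clf"); st.j_clf = getm(L, "j_clf");
  st.e_mot = getm(L, "e_mot"); st.j_mot = getm(L, "j_mot");
  st.e_pos = getm(L, "e_pos");
  st.H_m1 = getm(L, "H_m1"); st.H_m2 = getm(L, "H_m2");
  st.H_mf = getm(L, "H_mf"); st.H_pf = getm(L, "H_pf");
  return st;
}

// One forward step (no gradients); mirrors bias3d_forward().
// [[Rcpp::export(name = ".cpp_step")]]
List cpp_step(List pr, List cfg, arma::mat gm, double theta, List state) {
  Params P = unpack(pr);
  Cfg c = unpack_cfg(cfg);
  State st = state_from_list(state);
  StepCache ca;
  step_forward(P, c, gm, theta, st, ca);
  return List::create(_["q"] = NumericVector(ca.q.begin(), ca.q.end()),
                      _["p"] = NumericVector(ca.p.begin(), ca.p.end()),
                      _["state"] = state_to_list(st));
}

static NumericVector rv(const rowvec& x) {
  return NumericVector(x.begin(), x.end());
}

// Grads in the exact name/order layout of the R parameter list.
static List grads_to_list(const Grads& G) {
  const int n = 35;
  List out(n);
  CharacterVector nm(n);
  int i = 0;
  auto put = [&](const char* name, SEXP val) { nm[i] = name; out[i] = val; ++i; };
  put("clf_c1_W", wrap(G.clf_c1_W)); put("clf_c1_b", rv(G.clf_c1_b));
  put("clf_c2_W", wrap(G.clf_c2_W)); put("clf_c2_b", rv(G.clf_c2_b));
  put("clf_c3_W", wrap(G.clf_c3_W)); put("clf_c3_b", rv(G.clf_c3_b));
  put("clf_fc_Wx", wrap(G.clf_fc_Wx)); put("clf_fc_We", wrap(G.clf_fc_We));
  put("clf_fc_Wj", wrap(G.clf_fc_Wj)); put("clf_fc_b", rv(G.clf_fc_b));
  put("mot_f1_Wj", wrap(G.mot_f1_Wj)); put("mot_f1_Wk", wrap(G.mot_f1_Wk));
  put("mot_f1_Wo", wrap(G.mot_f1_Wo));
  put("mot_f2_Wj", wrap(G.mot_f2_Wj)); put("mot_f2_Wk", wrap(G.mot_f2_Wk));
  put("mot_f2_Wo", wrap(G.mot_f2_Wo));
  put("mot_fc_Wx", wrap(G.mot_fc_Wx)); put("mot_fc_We", wrap(G.mot_fc_We));
  put("mot_fc_Wj", wrap(G.mot_fc_Wj)); put("mot_fc_b", rv(G.mot_fc_b));
  put("mot_ff_Wj", wrap(G.mot_ff_Wj)); put("mot_ff_Wk", wrap(G.mot_ff_Wk));
  put("mot_ff_Wo", wrap(G.mot_ff_Wo));
  put("pos_fc_Wx", wrap(G.pos_fc_Wx)); put("pos_fc_We", wrap(G.pos_fc_We));
  put("pos_fc_b", rv(G.pos_fc_b));
  put("pos_ff_Wj", wrap(G.pos_ff_Wj)); put("pos_ff_Wk", wrap(G.pos_ff_Wk));
  put("pos_ff_Wo", wrap(G.pos_ff_Wo));
  put("fus_W", wrap(G.fus_W)); put("fus_b", rv(G.fus_b));
  put("hq_W", wrap(G.hq_W)); put("hq_b", rv(G.hq_b));
  put("hc_W", wrap(G.hc_W)); put("hc_b", rv(G.hc_b));
  out.attr("names") = nm;
  return out;
}

// ---- feed-forward classifier (pretraining) --------------------------------

struct PreParams {
  mat c1_W, c2_W, c3_W, fc_W, hd_W;
  rowvec c1_b, c2_b, c3_b, fc_b, hd_b;
};

static PreParams unpack_pre(const List& pr) {
  PreParams P;
  P.c1_W = getm(pr, "c1_W"); P.c1_b = getv(pr, "c1_b");
  P.c2_W = getm(pr, "c2_W"); P.c2_b = getv(pr, "c2_b");
  P.c3_W = getm(pr, "c3_W"); P.c3_b = getv(pr, "c3_b");
  P.fc_W = getm(pr, "fc_W"); P.fc_b = getv(pr, "fc_b");
  P.hd_W = getm(pr, "hd_W"); P.hd_b = getv(pr, "hd_b");
  return P;
}

// One minibatch of the feed-forward classifier: cross-entropy forward and
// backward, gradients averaged with weight 1/batch (mirrors pre_fwd/pre_bwd
// in R/pretrain.R).
// [[Rcpp::export(name = ".cpp_pre_batch")]]
List cpp_pre_batch(List pr, List cfg, List X, IntegerVector y,
                   IntegerVector idx) {
  PreParams P = unpack_pre(pr);
  Cfg c = unpack_cfg(cfg);
  const int g = c.g, g2 = g / 2, g4 = g / 4;
  const int B = idx.size();
  const double w = 1.0 / B;
  mat d_c1_W(arma::size(P.c1_W), arma::fill::zeros);
  mat d_c2_W(arma::size(P.c2_W), arma::fill::zeros);
  mat d_c3_W(arma::size(P.c3_W), arma::fill::zeros);
  mat d_fc_W(arma::size(P.fc_W), arma::fill::zeros);
  mat d_hd_W(arma::size(P.hd_W), arma::fill::zeros);
  rowvec d_c1_b(P.c1_b.n_elem, arma::fill::zeros);
  rowvec d_c2_b(P.c2_b.n_elem, arma::fill::zeros);
  rowvec d_c3_b(P.c3_b.n_elem, arma::fill::zeros);
  rowvec d_fc_b(P.fc_b.n_elem, arma::fill::zeros);
  rowvec d_hd_b(P.hd_b.n_elem, arma::fill::zeros);
  double loss = 0.0;
  int correct = 0;
  for (int s = 0; s < B; ++s) {
    const int i = idx[s] - 1;
    mat gm = as<mat>(X[i]);
    mat c1_X2 = im2col(gm, g, g);
    mat c1_y = add_bias(c1_X2 * P.c1_W, P.c1_b);
    LrnCache l1; mat l1y = lrn_fwd(c1_y, c.lk, c.la, c.lb, l1);
    PoolCache p1; mat p1y = pool_fwd(relu(l1y), g, g, p1);
    mat c2_X2 = im2col(p1y, g2, g2);
    mat c2_y = add_bias(c2_X2 * P.c2_W, P.c2_b);
    LrnCache l2; mat l2y = lrn_fwd(c2_y, c.lk, c.la, c.lb, l2);
    PoolCache p2; mat p2y = pool_fwd(relu(l2y), g2, g2, p2);
    mat c3_X2 = im2col(p2y, g4, g4);
    mat c3_y = add_bias(c3_X2 * P.c3_W, P.c3_b);
    mat r3 = relu(c3_y);
    mat flat(r3.memptr(), 1, r3.n_elem);
    mat a = flat * P.fc_W; a += P.fc_b;
    mat fy = relu(a);
    rowvec z = rowvec(mat(fy * P.hd_W)) + P.hd_b;
    rowvec p = softmax_row(z);
    loss += -std::log(p(y[i]) + 1e-12);
    if ((int)p.index_max() == y[i]) ++correct;
    // backward (cross-entropy)
    rowvec gz = p; gz(y[i]) -= 1.0; gz *= w;
    d_hd_W += fy.t() * gz; d_hd_b += gz;
    mat gfy = gz * P.hd_W.t();
    mat ga = gfy % (a > 0);
    d_fc_W += flat.t() * ga; d_fc_b += rowvec(ga.row(0));
    mat gflat = ga * P.fc_W.t();
    mat gr3(gflat.memptr(), g4 * g4, c.k3);
    mat gc3 = gr3 % (c3_y > 0);
    d_c3_W += c3_X2.t() * gc3; d_c3_b += arma::sum(gc3, 0);
    mat gp2 = col2im(gc3 * P.c3_W.t(), g4, g4);
    mat gr2 = pool_bwd(gp2, p2) % (l2y > 0);
    mat gl2 = lrn_bwd(gr2, l2);
    d_c2_W += c2_X2.t() * gl2; d_c2_b += arma::sum(gl2, 0);
    mat gp1 = col2im(gl2 * P.c2_W.t(), g2, g2);
    mat gr1 = pool_bwd(gp1, p1) % (l1y > 0);
    mat gl1 = lrn_bwd(gr1, l1);
    d_c1_W += c1_X2.t() * gl1; d_c1_b += arma::sum(gl1, 0);
  }
  List grads = List::create(
    _["c1_W"] = d_c1_W, _["c1_b"] = rv(d_c1_b),
    _["c2_W"] = d_c2_W, _["c2_b"] = rv(d_c2_b),
    _["c3_W"] = d_c3_W, _["c3_b"] = rv(d_c3_b),
    _["fc_W"] = d_fc_W, _["fc_b"] = rv(d_fc_b),
    _["hd_W"] = d_hd_W, _["hd_b"] = rv(d_hd_b));
  return List::create(_["grads"] = grads, _["loss"] = loss,
                      _["correct"] = correct);
}

// Class probabilities of the feed-forward classifier for a list of
// glimpse matrices.
// [[Rcpp::export(name = ".cpp_pre_predict")]]
NumericMatrix cpp_pre_predict(List pr, List cfg, List X) {
  PreParams P = unpack_pre(pr);
  Cfg c = unpack_cfg(cfg);
  const int g = c.g, g2 = g / 2, g4 = g / 4;
  const int n = X.size();
  NumericMatrix out(n, c.n_out);
  for (int i = 0; i < n; ++i) {
    mat gm = as<mat>(X[i]);
    mat c1_y = add_bias(im2col(gm, g, g) * P.c1_W, P.c1_b);
    LrnCache l1; PoolCache p1;
    mat p1y = pool_fwd(relu(lrn_fwd(c1_y, c.lk, c.la, c.lb, l1)), g, g, p1);
    mat c2_y = add_bias(im2col(p1y, g2, g2) * P.c2_W, P.c2_b);
    LrnCache l2; PoolCache p2;
    mat p2y = pool_fwd(relu(lrn_fwd(c2_y, c.lk, c.la, c.lb, l2)), g2, g2, p2);
    mat c3_y = add_bias(im2col(p2y, g4, g4) * P.c3_W, P.c3_b);
    mat r3 = relu(c3_y);
    mat flat(r3.memptr(), 1, r3.n_elem);
    mat a = flat * P.fc_W; a += P.fc_b;
    mat fy = relu(a);
    rowvec z = rowvec(mat(fy * P.hd_W)) + P.hd_b;
    rowvec p = softmax_row(z);
    for (int k = 0; k < c.n_out; ++k) out(i, k) = p(k);
  }
  return out;
}

// Roll one training episode on a fixed azimuth grid and return the
// episode gradients, loss components and trajectory. Mirrors
// rollout_episode() + episode_backward() in R/train.R.
//
// glimpses: list of (g*g x depth) matrices, one per grid position
//   (position i <-> theta = i * jump, 0-based).
// labels:   0-based desired class per grid position (n = background).
// start_idx: 0-based start position; actions: 1 right (+1), 2 left (-1),
//   3 stay. If forced_actions is non-empty (length T), exploration is
//   bypassed and those actions are replayed (used by the equivalence
//   tests); otherwise epsilon-greedy actions consume R's RNG.
// [[Rcpp::export(name = ".cpp_episode")]]
List cpp_episode(List pr, List pr_target, List cfg, List glimpses,
                 IntegerVector labels, int start_idx, int target_class,
                 int T, double epsilon, double gamma, double lambda,
                 bool mse_all_actions, double bg_ce_weight,
                 IntegerVector forced_actions) {
  Params P = unpack(pr);
  Params PT = unpack(pr_target);
  Cfg c = unpack_cfg(cfg);
  const int n_grid = glimpses.size();
  std::vector<mat> gms(n_grid);
  for (int i = 0; i < n_grid; ++i) gms[i] = as<mat>(glimpses[i]);
  const double jump = 360.0 / n_grid;

  State st_on = init_state(c), st_tg = init_state(c);
  std::vector<StepCache> caches(T + 1);
  std::vector<rowvec> q_tg(T + 1);
  std::vector<int> idx_seq(T + 1), act(T);
  int idx = start_idx;
  int prev = 0;  // no previous response yet
  RNGScope rng;
  for (int t = 0; t <= T; ++t) {
    idx_seq[t] = idx;
    step_forward(P, c, gms[idx], idx * jump, st_on, caches[t]);
    StepCache tg;
    step_forward(PT, c, gms[idx], idx * jump, st_tg, tg);
    q_tg[t] = tg.q;
    if (t < T) {
      int a;
      if (forced_actions.size() == T) a = forced_actions[t];
      else if (R::runif(0.0, 1.0) < epsilon)
        a = 1 + std::min(2, (int)std::floor(R::runif(0.0, 3.0)));
      else {
        // race-model selection: a response is emitted when its softmax
        // probability crosses lambda; undecided races repeat the
        // previous response (argmax when there is none yet)
        rowvec pq = softmax_row(caches[t].q);
        if (prev == 0 || pq.max() >= lambda) a = (int)pq.index_max() + 1;
        else a = prev;
      }
      act[t] = a;
      prev = a;
      if (a == 1) idx = (idx + 1) % n_grid;
      else if (a == 2) idx = (idx - 1 + n_grid) % n_grid;
    }
  }
  // rewards, TD errors, losses; background CE steps are down-weighted
  const int n_bg = as<int>(cfg["n_classes"]);
  arma::vec rew(T), td(T), wts(T);
  double ce = 0.0, wsum = 0.0;
  for (int t = 0; t < T; ++t) {
    const rowvec& pn = caches[t + 1].p;
    rew[t] = ((int)pn.index_max() == target_class &&
              pn.max() >= lambda) ? 1.0 : 0.0;
    td[t] = rew[t] + gamma * q_tg[t + 1].max() - caches[t].q(act[t] - 1);
    wts[t] = (labels[idx_seq[t]] == n_bg) ? bg_ce_weight : 1.0;
    wsum += wts[t];
    ce += -wts[t] * std::log(caches[t].p(labels[idx_seq[t]]) + 1e-12);
  }
  ce /= wsum;
  const double mse = arma::dot(td, td) / T;
  // backward
  Grads G = zero_grads(P);
  Carry carry = zero_carry(c);
  for (int t = T - 1; t >= 0; --t) {
    rowvec gz = caches[t].p;
    gz(labels[idx_seq[t]]) -= 1.0;
    gz *= wts[t] / wsum;
    rowvec gq(3, arma::fill::zeros);
    if (mse_all_actions) {
      const double boot = rew[t] + gamma * q_tg[t + 1].max();
      for (int a = 0; a < 3; ++a)
        gq(a) = -2.0 * (boot - caches[t].q(a)) / (3.0 * T);
    } else {
      gq(act[t] - 1) = -2.0 * td[t] / T;
    }
    carry = step_backward(P, c, caches[t], gz, gq, carry, G);
  }
  return List::create(
    _["grads"] = grads_to_list(G),
    _["ce"] = ce, _["mse"] = mse, _["loss"] = ce + mse,
    _["reward"] = NumericVector(rew.begin(), rew.end()),
    _["actions"] = IntegerVector(act.begin(), act.end()),
    _["theta_idx"] = IntegerVector(idx_seq.begin(), idx_seq.end()));
}
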