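// Core numerics for the 3D multi-scale normalizing flow and the
// latent-space MAP reconstruction. All reverse-mode passes are written by
// hand: the package must differentiate (a) the negative log-likelihood with
// respect to every flow parameter for training, and (b) the reconstruction
// objective with respect to the latent code, with the model frozen.
//
// Conventions
//  * A volume activation is an (n_vox x C) arma::mat, voxel index
//    v = d + D*(h + H*w) (column-major over (D,H,W)), matching R arrays of
//    dim c(D,H,W,C).
//  * Encode direction: x -> z.  Per level: squeeze, then `depth` steps of
//    (actnorm, invertible 1x1x1 convolution, affine coupling), then a channel
//    split (except at the top level, which emits the whole tensor).
//  * logdet is always accumulated in the encode direction, i.e. it is
//    log|det d f(x)/dx| with f the encoder, so log p(x) = log p(z) + logdet.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

static const double LOG2PI = 1.837877066409345483560659472811;

// ---------------------------------------------------------------------------
// plan: static shape bookkeeping per level
// ---------------------------------------------------------------------------

struct Lvl {
  int D0, H0, W0, C0;      // dims entering the level (before squeeze)
  int fd, fh, fw;          // squeeze factors (2 where the axis is even, else 1)
  int D, H, W, C;          // dims after squeeze (C = C0 * fd*fh*fw)
  int Ca, Cb;              // coupling halves: Ca conditions, Cb is transformed
  int Cz, Ckeep;           // split: Cz factored out as z_k, Ckeep continues
};

static std::vector<Lvl> make_plan(int D, int H, int W, int C, int K) {
  std::vector<Lvl> P;
  for (int k = 0; k < K; ++k) {
    Lvl L;
    L.D0 = D; L.H0 = H; L.W0 = W; L.C0 = C;
    L.fd = (D % 2 == 0 && D > 1) ? 2 : 1;
    L.fh = (H % 2 == 0 && H > 1) ? 2 : 1;
    L.fw = (W % 2 == 0 && W > 1) ? 2 : 1;
    const int f = L.fd * L.fh * L.fw;
    if (f == 1)
      stop("cannot squeeze at level %d: no even spatial axis left", k + 1);
    D /= L.fd; H /= L.fh; W /= L.fw; C *= f;
    if (C % 2 != 0 || C < 2)
      stop("channel count %d at level %d is not an even number >= 2", C, k + 1);
    L.D = D; L.H = H; L.W = W; L.C = C;
    L.Ca = C / 2; L.Cb = C - L.Ca;
    if (k < K - 1) { L.Cz = C / 2; L.Ckeep = C - L.Cz; }
    else           { L.Cz = C;     L.Ckeep = 0; }
    P.push_back(L);
    C = L.Ckeep;
  }
  return P;
}

// [[Rcpp::export]]
List cpp_flow_plan(int D, int H, int W, int C, int K) {
  std::vector<Lvl> P = make_plan(D, H, W, C, K);
  List out(K);
  for (int k = 0; k < K; ++k) {
    const Lvl& L = P[k];
    out[k] = List::create(
      _["dim_in"] = IntegerVector::create(L.D0, L.H0, L.W0, L.C0),
      _["factors"] = IntegerVector::create(L.fd, L.fh, L.fw),
      _["dim"] = IntegerVector::create(L.D, L.H, L.W, L.C),
      _["ca"] = L.Ca, _["cb"] = L.Cb,
      _["cz"] = L.Cz, _["ckeep"] = L.Ckeep,
      _["z_dim"] = IntegerVector::create(L.D, L.H, L.W, L.Cz));
  }
  return out;
}

// ---------------------------------------------------------------------------
// primitive ops
// ---------------------------------------------------------------------------

static inline double sigm(double u) { return 1.0 / (1.0 + std::exp(-u)); }

// squeeze (D,H,W,C) -> (D/fd,H/fh,W/fw,C*f); sub-voxel offsets become the
// fast-running part of the channel index: c_new = c + C*(od + fd*(oh + fh*ow)).
static mat squeeze_fwd(const mat& X, int D, int H, int W, int C,
                       int fd, int fh, int fw) {
  const int D2 = D / fd, H2 = H / fh, W2 = W / fw, f = fd * fh * fw;
  mat Y(D2 * H2 * W2, C * f);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        const int v = d + D * (h + H * w);
        const int off = (d % fd) + fd * ((h % fh) + fh * (w % fw));
        const int v2 = (d / fd) + D2 * ((h / fh) + H2 * (w / fw));
        for (int c = 0; c < C; ++c) Y(v2, c + C * off) = X(v, c);
      }
  return Y;
}

static mat squeeze_inv(const mat& Y, int D, int H, int W, int C,
                       int fd, int fh, int fw) {
  const int D2 = D / fd, H2 = H / fh, W2 = W / fw;
  mat X(D * H * W, C);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        const int v = d + D * (h + H * w);
        const int off = (d % fd) + fd * ((h % fh) + fh * (w % fw));
        const int v2 = (d / fd) + D2 * ((h / fh) + H2 * (w / fw));
        for (int c = 0; c < C; ++c) X(v, c) = Y(v2, c + C * off);
      }
  return X;
}

// im2col for a 3x3x3 'same' zero-padded kernel. Column blocks are ordered by
// offset b = (od+1) + 3*(oh+1) + 9*(ow+1), each block holding Cin columns.
static mat im2col3(const mat& X, int D, int H, int W) {
  const int C = X.n_cols;
  mat Y(D * H * W, C * 27, arma::fill::zeros);
  int b = 0;
  for (int ow = -1; ow <= 1; ++ow)
    for (int oh = -1; oh <= 1; ++oh)
      for (int od = -1; od <= 1; ++od, ++b)
        for (int w = 0; w < W; ++w) {
          const int ws = w + ow; if (ws < 0 || ws >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int hs = h + oh; if (hs < 0 || hs >= H) continue;
            const int dlo = std::max(0, -od), dhi = std::min(D, D - od);
            if (dhi <= dlo) continue;
            const int v0 = dlo + D * (h + H * w);
            const int vs0 = dlo + od + D * (hs + H * ws);
            Y.submat(v0, b * C, v0 + (dhi - dlo) - 1, b * C + C - 1) =
              X.submat(vs0, 0, vs0 + (dhi - dlo) - 1, C - 1);
          }
        }
  return Y;
}

// adjoint of im2col3 (scatter-add), used for input gradients
static mat col2im3(const mat& Yc, int D, int H, int W, int C) {
  mat X(D * H * W, C, arma::fill::zeros);
  int b = 0;
  for (int ow = -1; ow <= 1; ++ow)
    for (int oh = -1; oh <= 1; ++oh)
      for (int od = -1; od <= 1; ++od, ++b)
        for (int w = 0; w < W; ++w) {
          const int ws = w + ow; if (ws < 0 || ws >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int hs = h + oh; if (hs < 0 || hs >= H) continue;
            const int dlo = std::max(0, -od), dhi = std::min(D, D - od);
            if (dhi <= dlo) continue;
            const int v0 = dlo + D * (h + H * w);
            const int vs0 = dlo + od + D * (hs + H * ws);
            X.submat(vs0, 0, vs0 + (dhi - dlo) - 1, C - 1) +=
              Yc.submat(v0, b * C, v0 + (dhi - dlo) - 1, b * C + C - 1);
          }
        }
  return X;
}

static mat conv_fwd(const mat& X, int D, int H, int W,
                    const mat& Wm, const rowvec& bb, int k) {
  mat Y = (k == 1) ? mat(X * Wm) : mat(im2col3(X, D, H, W) * Wm);
  Y.each_row() += bb;
  return Y;
}

// want_dw = false skips the weight-gradient GEMM and the im2col build
// entirely (used when backpropagating through a frozen model).
static void conv_bwd(const mat& X, const mat& dY, int D, int H, int W,
                     const mat& Wm, int k,
                     mat& dX, mat& dWm, rowvec& db, bool want_dw) {
  if (k == 1) {
    dX = dY * Wm.t();
    if (want_dw) dWm = X.t() * dY;
  } else {
    dX = col2im3(dY * Wm.t(), D, H, W, X.n_cols);
    if (want_dw) dWm = im2col3(X, D, H, W).t() * dY;
  }
  if (want_dw) db = arma::sum(dY, 0);
}

// ---------------------------------------------------------------------------
// parameter access
// ---------------------------------------------------------------------------

struct Flow {
  int D, H, W, C, K, depth;
  double eps;
  std::vector<Lvl> plan;
  List par;

  Flow(const List& cfg, const List& params) : par(params) {
    D = cfg["D"]; H = cfg["H"]; W = cfg["W"]; C = cfg["C"];
    K = cfg["K"]; depth = cfg["depth"]; eps = cfg["eps"];
    plan = make_plan(D, H, W, C, K);
  }

  static std::string key(int k, int s, const char* nm) {
    char b[64]; std::snprintf(b, 64, "L%dS%d_%s", k + 1, s + 1, nm);
    return std::string(b);
  }
  static std::string pkey(int k, const char* nm) {
    char b[64]; std::snprintf(b, 64, "prior_L%d_%s", k + 1, nm);
    return std::string(b);
  }

  mat M(const std::string& nm) const {
    NumericVector v = par[nm];
    if (v.hasAttribute("dim")) {
      IntegerVector d = v.attr("dim");
      return mat(v.begin(), d[0], d[1]);
    }
    return mat(v.begin(), v.size(), 1);
  }
  vec V(const std::string& nm) const {
    NumericVector v = par[nm];
    return vec(v.begin(), v.size());
  }
};

// per-step tensors retained for the backward passes
struct StepCache {
  mat an_in, perm_in;      // encode-direction inputs (NLL backward)
  mat a, b;                // coupling halves; b is the *untransformed* half
  mat h1, h2, raw, scale;  // coupling network intermediates
  mat Winv;                // 1x1x1 inverse, cached by the decode pass
};

struct Grad {
  std::map<std::string, mat> g;
  void add(const std::string& nm, const mat& m) {
    std::map<std::string, mat>::iterator it = g.find(nm);
    if (it == g.end()) g[nm] = m; else it->second += m;
  }
};

// ---------------------------------------------------------------------------
// coupling network
// ---------------------------------------------------------------------------

// computes shift / raw / scale from the conditioning half `a`
static void coup_nn_fwd(const Flow& F, int k, int s, const Lvl& L, const mat& a,
                        StepCache* cc, mat& shift, mat& raw, mat& scale) {
  mat W1 = F.M(Flow::key(k, s, "c1_W")); rowvec b1 = F.V(Flow::key(k, s, "c1_b")).t();
  mat W2 = F.M(Flow::key(k, s, "c2_W")); rowvec b2 = F.V(Flow::key(k, s, "c2_b")).t();
  mat W3 = F.M(Flow::key(k, s, "c3_W")); rowvec b3 = F.V(Flow::key(k, s, "c3_b")).t();
  mat h1 = conv_fwd(a, L.D, L.H, L.W, W1, b1, 3);
  h1.transform([](double u) { return u > 0.0 ? u : 0.0; });
  mat h2 = conv_fwd(h1, L.D, L.H, L.W, W2, b2, 1);
  h2.transform([](double u) { return u > 0.0 ? u : 0.0; });
  mat o = conv_fwd(h2, L.D, L.H, L.W, W3, b3, 3);
  shift = o.cols(0, L.Cb - 1);
  raw = o.cols(L.Cb, 2 * L.Cb - 1);
  const double eps = F.eps;
  scale = raw;
  scale.transform([eps](double u) { return sigm(u + 2.0) + eps; });
  if (cc) { cc->a = a; cc->h1 = h1; cc->h2 = h2; cc->raw = raw; cc->scale = scale; }
}

// gradient of the coupling network w.r.t. `a` and its weights
static mat coup_nn_bwd(const Flow& F, int k, int s, const Lvl& L,
                       const StepCache& cc, const mat& dshift, const mat& draw,
                       Grad* G) {
  mat W1 = F.M(Flow::key(k, s, "c1_W"));
  mat W2 = F.M(Flow::key(k, s, "c2_W"));
  mat W3 = F.M(Flow::key(k, s, "c3_W"));
  const bool want_dw = G != 0;
  mat dO = arma::join_rows(dshift, draw);
  mat dh2, dW3; rowvec db3;
  conv_bwd(cc.h2, dO, L.D, L.H, L.W, W3, 3, dh2, dW3, db3, want_dw);
  dh2 %= arma::conv_to<mat>::from(cc.h2 > 0.0);
  mat dh1, dW2; rowvec db2;
  conv_bwd(cc.h1, dh2, L.D, L.H, L.W, W2, 1, dh1, dW2, db2, want_dw);
  dh1 %= arma::conv_to<mat>::from(cc.h1 > 0.0);
  mat da, dW1; rowvec db1;
  conv_bwd(cc.a, dh1, L.D, L.H, L.W, W1, 3, da, dW1, db1, want_dw);
  if (G) {
    G->add(Flow::key(k, s, "c1_W"), dW1); G->add(Flow::key(k, s, "c1_b"), db1.t());
    G->add(Flow::key(k, s, "c2_W"), dW2); G->add(Flow::key(k, s, "c2_b"), db2.t());
    G->add(Flow::key(k, s, "c3_W"), dW3); G->add(Flow::key(k, s, "c3_b"), db3.t());
  }
  return da;
}

// ---------------------------------------------------------------------------
// encode / decode passes
// ---------------------------------------------------------------------------

// One full encode pass. If caches != NULL, per-step tensors are retained.
static void encode_pass(const Flow& F, mat A, std::vector<mat>& zs,
                        double& logdet,
                        std::vector<std::vector<StepCache> >* caches) {
  logdet = 0.0;
  zs.assign(F.K, mat());
  if (caches) caches->assign(F.K, std::vector<StepCache>(F.depth));
  for (int k = 0; k < F.K; ++k) {
    const Lvl& L = F.plan[k];
    A = squeeze_fwd(A, L.D0, L.H0, L.W0, L.C0, L.fd, L.fh, L.fw);
    const int nvox = L.D * L.H * L.W;
    for (int s = 0; s < F.depth; ++s) {
      StepCache* cc = caches ? &((*caches)[k][s]) : 0;
      // actnorm: y = exp(logs) * x + b (per channel)
      vec logs = F.V(Flow::key(k, s, "an_logs"));
      vec bb = F.V(Flow::key(k, s, "an_b"));
      if (cc) cc->an_in = A;
      for (int c = 0; c < L.C; ++c)
        A.col(c) = std::exp(logs[c]) * A.col(c) + bb[c];
      logdet += nvox * arma::accu(logs);
      // invertible 1x1x1 convolution (channel mixing): y_row = x_row * W
      mat Wm = F.M(Flow::key(k, s, "perm_W"));
      if (cc) cc->perm_in = A;
      A = A * Wm;
      double lad, sgn; arma::log_det(lad, sgn, Wm);
      logdet += nvox * lad;
      // affine coupling
      mat a = A.cols(0, L.Ca - 1);
      mat b = A.cols(L.Ca, L.C - 1);
      mat shift, raw, scale;
      coup_nn_fwd(F, k, s, L, a, cc, shift, raw, scale);
      if (cc) cc->b = b;
      A = arma::join_rows(a, scale % b + shift);
      logdet += arma::accu(arma::log(scale));
    }
    if (k < F.K - 1) {
      zs[k] = A.cols(L.Ckeep, L.C - 1);
      A = A.cols(0, L.Ckeep - 1);
    } else {
      zs[k] = A;
    }
  }
}

// One full decode pass (z -> x). logdet is still the encode-direction
// log-determinant evaluated along the path (the same coupling scales are
// visited), so log p(x) = log p(z) + logdet holds for the decoded x.
static mat decode_pass(const Flow& F, const std::vector<mat>& zs,
                       double& logdet,
                       std::vector<std::vector<StepCache> >* caches) {
  logdet = 0.0;
  if (caches) caches->assign(F.K, std::vector<StepCache>(F.depth));
  mat A;
  for (int k = F.K - 1; k >= 0; --k) {
    const Lvl& L = F.plan[k];
    const int nvox = L.D * L.H * L.W;
    A = (k == F.K - 1) ? zs[k] : mat(arma::join_rows(A, zs[k]));
    for (int s = F.depth - 1; s >= 0; --s) {
      StepCache* cc = caches ? &((*caches)[k][s]) : 0;
      // coupling inverse
      mat a = A.cols(0, L.Ca - 1);
      mat bnew = A.cols(L.Ca, L.C - 1);
      mat shift, raw, scale;
      coup_nn_fwd(F, k, s, L, a, cc, shift, raw, scale);
      mat b = (bnew - shift) / scale;
      if (cc) cc->b = b;
      A = arma::join_rows(a, b);
      logdet += arma::accu(arma::log(scale));
      // 1x1x1 convolution inverse
      mat Wm = F.M(Flow::key(k, s, "perm_W"));
      mat Winv = arma::inv(Wm);
      A = A * Winv;
      if (cc) cc->Winv = Winv;
      double lad, sgn; arma::log_det(lad, sgn, Wm);
      logdet += nvox * lad;
      // actnorm inverse
      vec logs = F.V(Flow::key(k, s, "an_logs"));
      vec bb = F.V(Flow::key(k, s, "an_b"));
      for (int c = 0; c < L.C; ++c)
        A.col(c) = (A.col(c) - bb[c]) * std::exp(-logs[c]);
      logdet += nvox * arma::accu(logs);
    }
    A = squeeze_inv(A, L.D0, L.H0, L.W0, L.C0, L.fd, L.fh, L.fw);
  }
  return A;
}

// ---------------------------------------------------------------------------
// helpers to move between R arrays and arma
// ---------------------------------------------------------------------------

static mat as_act(const NumericVector& x, int D, int H, int W, int C) {
  if ((int)x.size() != D * H * W * C)
    stop("input has %d values; the flow expects %d (%dx%dx%dx%d)",
         (int)x.size(), D * H * W * C, D, H, W, C);
  return mat(x.begin(), D * H * W, C);
}

static NumericVector wrap_arr(const mat& A, int D, int H, int W, int C) {
  NumericVector out(A.begin(), A.end());
  out.attr("dim") = IntegerVector::create(D, H, W, C);
  return out;
}

static std::vector<mat> zlist_in(const Flow& F, const List& zl) {
  if ((int)zl.size() != F.K) stop("latent code must have %d levels", F.K);
  std::vector<mat> zs(F.K);
  for (int k = 0; k < F.K; ++k) {
    const Lvl& L = F.plan[k];
    NumericVector zk = zl[k];
    zs[k] = as_act(zk, L.D, L.H, L.W, L.Cz);
  }
  return zs;
}

static List zlist_out(const Flow& F, const std::vector<mat>& zs) {
  List out(F.K);
  for (int k = 0; k < F.K; ++k) {
    const Lvl& L = F.plan[k];
    out[k] = wrap_arr(zs[k], L.D, L.H, L.W, L.Cz);
  }
  return out;
}

// ---------------------------------------------------------------------------
// exported: encode / decode
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_encode(NumericVector x, List params, List cfg) {
  Flow F(cfg, params);
  mat A = as_act(x, F.D, F.H, F.W, F.C);
  std::vector<mat> zs; double logdet;
  encode_pass(F, A, zs, logdet, 0);
  return List::create(_["z"] = zlist_out(F, zs), _["logdet"] = logdet);
}

// [[Rcpp::export]]
List cpp_decode(List z, List params, List cfg) {
  Flow F(cfg, params);
  std::vector<mat> zs = zlist_in(F, z);
  double logdet;
  mat A = decode_pass(F, zs, logdet, 0);
  return List::create(_["x"] = wrap_arr(A, F.D, F.H, F.W, F.C),
                      _["logdet"] = logdet);
}

// ---------------------------------------------------------------------------
// prior: diagonal Gaussian per level with learned mean / log-sd
// ---------------------------------------------------------------------------

static double prior_logp(const Flow& F, const std::vector<mat>& zs,
                         std::vector<mat>* dz, Grad* G, double gw) {
  // returns log N(z; mu, sigma^2); if dz given, writes d(-logN)/dz * gw is NOT
  // applied here -- dz gets d(logN)/dz so callers pick signs explicitly.
  double lp = 0.0;
  if (dz) dz->assign(F.K, mat());
  for (int k = 0; k < F.K; ++k) {
    vec mu = F.V(Flow::pkey(k, "mu"));
    vec logs = F.V(Flow::pkey(k, "logs"));
    vec z = arma::vectorise(zs[k]);
    vec e = (z - mu) % arma::exp(-logs);
    lp += -arma::accu(0.5 * LOG2PI + logs + 0.5 * arma::square(e));
    if (dz) {
      vec d = -e % arma::exp(-logs);          // d logN / dz
      (*dz)[k] = mat(d.memptr(), zs[k].n_rows, zs[k].n_cols);
    }
    if (G) {
      // gradients of gw * (-logN) w.r.t. prior parameters
      G->add(Flow::pkey(k, "mu"), mat(gw * (-e % arma::exp(-logs))));
      G->add(Flow::pkey(k, "logs"), mat(gw * (1.0 - arma::square(e))));
    }
  }
  return lp;
}

// ---------------------------------------------------------------------------
// exported: NLL + parameter gradients (training)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_nll_grad(List xbatch, List params, List cfg, bool want_grad) {
  Flow F(cfg, params);
  const int B = xbatch.size();
  if (B < 1) stop("empty batch");
  Grad G;
  double nll_sum = 0.0;
  NumericVector per(B);

  for (int ib = 0; ib < B; ++ib) {
    NumericVector xb = xbatch[ib];
    mat A = as_act(xb, F.D, F.H, F.W, F.C);
    std::vector<std::vector<StepCache> > CC;
    std::vector<mat> zs; double logdet;
    encode_pass(F, A, zs, logdet, want_grad ? &CC : 0);
    std::vector<mat> dlogN;
    double lp = prior_logp(F, zs, want_grad ? &dlogN : 0,
                           want_grad ? &G : 0, 1.0);
    const double nll = -(lp + logdet);
    if (!std::isfinite(nll))
      stop("non-finite negative log-likelihood for batch element %d", ib + 1);
    nll_sum += nll; per[ib] = nll;
    if (!want_grad) continue;

    // backward through the encoder; dNLL/dz = -dlogN/dz
    mat dKeep;
    for (int k = F.K - 1; k >= 0; --k) {
      const Lvl& L = F.plan[k];
      const int nvox = L.D * L.H * L.W;
      mat dA = (k == F.K - 1) ? mat(-dlogN[k])
                              : mat(arma::join_rows(dKeep, -dlogN[k]));
      for (int s = F.depth - 1; s >= 0; --s) {
        const StepCache& cc = CC[k][s];
        // coupling backward (encode direction); NLL carries -logdet,
        // so d(-log s)/ds = -1/s enters through the raw activations.
        mat da_out = dA.cols(0, L.Ca - 1);
        mat dbnew = dA.cols(L.Ca, L.C - 1);
        mat db = dbnew % cc.scale;
        mat sig = cc.scale - F.eps;
        mat dsig = sig % (1.0 - sig);
        mat ds = dbnew % cc.b - 1.0 / cc.scale;
        mat draw = ds % dsig;
        mat da = da_out + coup_nn_bwd(F, k, s, L, cc, dbnew, draw, &G);
        dA = arma::join_rows(da, db);
        // 1x1x1 convolution backward
        mat Wm = F.M(Flow::key(k, s, "perm_W"));
        mat Winv = arma::inv(Wm);
        G.add(Flow::key(k, s, "perm_W"),
              mat(cc.perm_in.t() * dA - nvox * Winv.t()));
        dA = dA * Wm.t();
        // actnorm backward
        vec logs = F.V(Flow::key(k, s, "an_logs"));
        vec glogs(L.C), gb(L.C);
        for (int c = 0; c < L.C; ++c) {
          glogs[c] = std::exp(logs[c]) *
                     arma::dot(dA.col(c), cc.an_in.col(c)) - nvox;
          gb[c] = arma::accu(dA.col(c));
          dA.col(c) *= std::exp(logs[c]);
        }
        G.add(Flow::key(k, s, "an_logs"), mat(glogs));
        G.add(Flow::key(k, s, "an_b"), mat(gb));
      }
      dKeep = squeeze_inv(dA, L.D0, L.H0, L.W0, L.C0, L.fd, L.fh, L.fw);
    }
    // dKeep now holds dNLL/dx; not needed for training.
  }

  List out = List::create(_["nll"] = nll_sum / B, _["per_sample"] = per);
  if (want_grad) {
    List gl;
    for (std::map<std::string, mat>::iterator it = G.g.begin();
         it != G.g.end(); ++it) {
      NumericVector v(it->second.begin(), it->second.end());
      NumericVector tmpl = params[it->first];
      if (tmpl.hasAttribute("dim")) v.attr("dim") = tmpl.attr("dim");
      gl[it->first] = v;
      for (R_xlen_t i = 0; i < v.size(); ++i) {
        v[i] /= B;
        if (!std::isfinite(v[i]))
          stop("non-finite gradient in %s", it->first.c_str());
      }
    }
    out["grad"] = gl;
  }
  return out;
}

// ---------------------------------------------------------------------------
// exported: reconstruction objective E(z) and its latent gradient
// ---------------------------------------------------------------------------

// E(z) = cycle_w * 0.5 * sum_j ||P_j G(z) - y_j||^2 - prior_w * log p_theta(G(z))
// views: 1 = coronal (average over depth d), 2 = sagittal (average over width w)
// y_j on the same intensity scale as the decoded volume ([0,1]).
// [[Rcpp::export]]
List cpp_recon_eg(List z, List ys, IntegerVector views, List params, List cfg,
                  double cycle_w, double prior_w, bool want_grad) {
  Flow F(cfg, params);
  if (F.C != 1) stop("reconstruction assumes a single-channel volume");
  std::vector<mat> zs = zlist_in(F, z);
  std::vector<std::vector<StepCache> > CC;
  double logdet;
  mat X = decode_pass(F, zs, logdet, want_grad ? &CC : 0);
  const int D = F.D, H = F.H, W = F.W;

  double cycle = 0.0;
  mat dX(D * H * W, 1, arma::fill::zeros);
  for (int j = 0; j < views.size(); ++j) {
    NumericMatrix y = ys[j];
    if (views[j] == 1) {            // coronal: y is H x W
      if (y.nrow() != H || y.ncol() != W) stop("coronal view %d has wrong shape", j + 1);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double s = 0.0;
          for (int d = 0; d < D; ++d) s += X(d + D * (h + H * w), 0);
          const double r = s / D - y(h, w);
          cycle += r * r;
          if (want_grad) {
            const double g = cycle_w * r / D;
            for (int d = 0; d < D; ++d) dX(d + D * (h + H * w), 0) += g;
          }
        }
    } else if (views[j] == 2) {     // sagittal: y is H x D
      if (y.nrow() != H || y.ncol() != D) stop("sagittal view %d has wrong shape", j + 1);
      for (int d = 0; d < D; ++d)
        for (int h = 0; h < H; ++h) {
          double s = 0.0;
          for (int w = 0; w < W; ++w) s += X(d + D * (h + H * w), 0);
          const double r = s / W - y(h, d);
          cycle += r * r;
          if (want_grad) {
            const double g = cycle_w * r / W;
            for (int w = 0; w < W; ++w) dX(d + D * (h + H * w), 0) += g;
          }
        }
    } else stop("unknown view code %d", views[j]);
  }

  std::vector<mat> dlogN;
  double lp = prior_logp(F, zs, want_grad ? &dlogN : 0, 0, 0.0);
  const double loglik = lp + logdet;       // log p_theta(G(z))
  const double E = 0.5 * cycle_w * cycle - prior_w * loglik;

  List out = List::create(_["E"] = E, _["cycle"] = cycle,
                          _["loglik"] = loglik,
                          _["x"] = wrap_arr(X, D, H, W, 1));
  if (!want_grad) return out;

  // reverse through the decoder, visiting layers in encode order;
  // E carries -prior_w * logdet, so d/ds contributes -prior_w / s.
  std::vector<mat> gz(F.K);
  mat dA = dX;
  for (int k = 0; k < F.K; ++k) {
    const Lvl& L = F.plan[k];
    dA = squeeze_fwd(dA, L.D0, L.H0, L.W0, L.C0, L.fd, L.fh, L.fw);
    for (int s = 0; s < F.depth; ++s) {
      const StepCache& cc = CC[k][s];
      // actnorm-inverse backward: x = (y - b) e^{-logs}
      vec logs = F.V(Flow::key(k, s, "an_logs"));
      for (int c = 0; c < L.C; ++c) dA.col(c) *= std::exp(-logs[c]);
      // 1x1x1-inverse backward: x = y * W^{-1} (inverse cached by decode)
      dA = dA * cc.Winv.t();
      // coupling-inverse backward: b = (bnew - shift)/s
      mat g_a = dA.cols(0, L.Ca - 1);
      mat g_b = dA.cols(L.Ca, L.C - 1);
      mat dbnew = g_b / cc.scale;
      mat dshift = -dbnew;
      mat ds = -(g_b % cc.b) / cc.scale - prior_w / cc.scale;
      mat sig = cc.scale - F.eps;
      mat draw = ds % (sig % (1.0 - sig));
      mat da = g_a + coup_nn_bwd(F, k, s, L, cc, dshift, draw, 0);
      dA = arma::join_rows(da, dbnew);
    }
    if (k < F.K - 1) {
      gz[k] = dA.cols(L.Ckeep, L.C - 1);
      dA = dA.cols(0, L.Ckeep - 1);
    } else gz[k] = dA;
  }
  // direct prior term: d(-prior_w * logN)/dz
  for (int k = 0; k < F.K; ++k) gz[k] += -prior_w * dlogN[k];

  for (int k = 0; k < F.K; ++k)
    if (!gz[k].is_finite()) stop("non-finite latent gradient at level %d", k + 1);
  out["grad"] = zlist_out(F, gz);
  return out;
}

// ---------------------------------------------------------------------------
// exported: data-dependent actnorm initialization
// ---------------------------------------------------------------------------

// Runs the encoder over a batch layer by layer; at each actnorm the per-channel
// scale and bias are set so its outputs have zero mean and unit variance on
// this batch, then the pass continues with the new values.
// [[Rcpp::export]]
List cpp_actnorm_init(List xbatch, List params, List cfg) {
  List par = clone(params);
  Flow F(cfg, par);
  const int B = xbatch.size();
  std::vector<mat> As(B);
  for (int ib = 0; ib < B; ++ib) {
    NumericVector xb = xbatch[ib];
    As[ib] = as_act(xb, F.D, F.H, F.W, F.C);
  }
  for (int k = 0; k < F.K; ++k) {
    const Lvl& L = F.plan[k];
    for (int ib = 0; ib < B; ++ib)
      As[ib] = squeeze_fwd(As[ib], L.D0, L.H0, L.W0, L.C0, L.fd, L.fh, L.fw);
    for (int s = 0; s < F.depth; ++s) {
      // batch statistics per channel
      vec mu(L.C, arma::fill::zeros), m2(L.C, arma::fill::zeros);
      const double n = (double)B * L.D * L.H * L.W;
      for (int ib = 0; ib < B; ++ib) {
        mu += arma::sum(As[ib], 0).t();
        m2 += arma::sum(arma::square(As[ib]), 0).t();
      }
      mu /= n; m2 /= n;
      vec sd = arma::sqrt(arma::clamp(m2 - arma::square(mu), 1e-12, arma::datum::inf));
      NumericVector logs = par[Flow::key(k, s, "an_logs")];
      NumericVector bb = par[Flow::key(k, s, "an_b")];
      for (int c = 0; c < L.C; ++c) {
        logs[c] = -std::log(sd[c]);
        bb[c] = -mu[c] / sd[c];
      }
      // apply the whole step with the new values
      Flow F2(cfg, par);
      for (int ib = 0; ib < B; ++ib) {
        mat& A = As[ib];
        for (int c = 0; c < L.C; ++c)
          A.col(c) = std::exp(logs[c]) * A.col(c) + bb[c];
        mat Wm = F2.M(Flow::key(k, s, "perm_W"));
        A = A * Wm;
        mat a = A.cols(0, L.Ca - 1);
        mat b = A.cols(L.Ca, L.C - 1);
        mat shift, raw, scale;
        coup_nn_fwd(F2, k, s, L, a, 0, shift, raw, scale);
        A = arma::join_rows(a, scale % b + shift);
      }
    }
    if (k < F.K - 1)
      for (int ib = 0; ib < B; ++ib) As[ib] = As[ib].cols(0, L.Ckeep - 1);
  }
  return par;
}

// ---------------------------------------------------------------------------
// exported: isolated layer primitives (used by the Jacobian test harness)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_layer_actnorm(NumericVector x, IntegerVector dim, NumericVector logs,
                       NumericVector b, bool inverse) {
  const int D = dim[0], H = dim[1], W = dim[2], C = dim[3];
  mat A = as_act(x, D, H, W, C);
  double logdet = 0.0;
  for (int c = 0; c < C; ++c) {
    if (inverse) A.col(c) = (A.col(c) - b[c]) * std::exp(-logs[c]);
    else A.col(c) = std::exp(logs[c]) * A.col(c) + b[c];
    logdet += (double)(D * H * W) * logs[c];
  }
  return List::create(_["y"] = wrap_arr(A, D, H, W, C), _["logdet"] = logdet);
}

// [[Rcpp::export]]
List cpp_layer_invconv(NumericVector x, IntegerVector dim, NumericMatrix Wm,
                       bool inverse) {
  const int D = dim[0], H = dim[1], W = dim[2], C = dim[3];
  mat A = as_act(x, D, H, W, C);
  mat Wa(Wm.begin(), Wm.nrow(), Wm.ncol());
  double lad, sgn; arma::log_det(lad, sgn, Wa);
  A = inverse ? mat(A * arma::inv(Wa)) : mat(A * Wa);
  return List::create(_["y"] = wrap_arr(A, D, H, W, C),
                      _["logdet"] = (double)(D * H * W) * lad);
}

// [[Rcpp::export]]
List cpp_layer_coupling(NumericVector x, IntegerVector dim, List weights,
                        double eps, bool inverse) {
  const int D = dim[0], H = dim[1], W = dim[2], C = dim[3];
  mat A = as_act(x, D, H, W, C);
  const int Ca = C / 2, Cb = C - Ca;
  mat a = A.cols(0, Ca - 1), bh = A.cols(Ca, C - 1);
  // direct computation without the Flow wrapper
  NumericMatrix W1r = weights["c1_W"], W2r = weights["c2_W"], W3r = weights["c3_W"];
  NumericVector b1r = weights["c1_b"], b2r = weights["c2_b"], b3r = weights["c3_b"];
  mat W1m(W1r.begin(), W1r.nrow(), W1r.ncol());
  mat W2m(W2r.begin(), W2r.nrow(), W2r.ncol());
  mat W3m(W3r.begin(), W3r.nrow(), W3r.ncol());
  rowvec b1(b1r.begin(), b1r.size()), b2(b2r.begin(), b2r.size()),
         b3(b3r.begin(), b3r.size());
  mat h1 = conv_fwd(a, D, H, W, W1m, b1, 3);
  h1.transform([](double u) { return u > 0.0 ? u : 0.0; });
  mat h2 = conv_fwd(h1, D, H, W, W2m, b2, 1);
  h2.transform([](double u) { return u > 0.0 ? u : 0.0; });
  mat o = conv_fwd(h2, D, H, W, W3m, b3, 3);
  mat shift = o.cols(0, Cb - 1), raw = o.cols(Cb, 2 * Cb - 1);
  mat scale = raw;
  scale.transform([eps](double u) { return sigm(u + 2.0) + eps; });
  mat bout = inverse ? mat((bh - shift) / scale) : mat(scale % bh + shift);
  return List::create(_["y"] = wrap_arr(arma::join_rows(a, bout), D, H, W, C),
                      _["logdet"] = arma::accu(arma::log(scale)));
}

// [[Rcpp::export]]
NumericVector cpp_squeeze3(NumericVector x, IntegerVector dim, bool inverse) {
  const int D = dim[0], H = dim[1], W = dim[2], C = dim[3];
  const int fd = (D % 2 == 0 && D > 1) ? 2 : 1;
  const int fh = (H % 2 == 0 && H > 1) ? 2 : 1;
  const int fw = (W % 2 == 0 && W > 1) ? 2 : 1;
  if (inverse) {
    const int f = fd * fh * fw;
    mat Y(x.begin(), (D / fd) * (H / fh) * (W / fw), C * f);
    return wrap_arr(squeeze_inv(Y, D, H, W, C, fd, fh, fw), D, H, W, C);
  }
  mat X(x.begin(), D * H * W, C);
  mat Y = squeeze_fwd(X, D, H, W, C, fd, fh, fw);
  return wrap_arr(Y, D / fd, H / fh, W / fw, C * fd * fh * fw);
}

// ---------------------------------------------------------------------------
// exported: small image utilities (separable Gaussian blur, 3D SSIM)
// ---------------------------------------------------------------------------

static void blur_axis(std::vector<double>& buf, mat& X, int D, int H, int W,
                      int axis, const std::vector<double>& kern) {
  const int R = ((int)kern.size() - 1) / 2;
  const int n[3] = {D, H, W};
  const int len = n[axis];
  std::vector<double> line(len);
  for (int c = 0; c < (int)X.n_cols; ++c)
    for (int w = 0; w < (axis == 2 ? 1 : W); ++w)
      for (int h = 0; h < (axis == 1 ? 1 : H); ++h)
        for (int d = 0; d < (axis == 0 ? 1 : D); ++d) {
          // iterate the orthogonal plane; walk the chosen axis
          for (int t = 0; t < len; ++t) {
            int dd = axis == 0 ? t : d, hh = axis == 1 ? t : h,
                ww = axis == 2 ? t : w;
            line[t] = X(dd + D * (hh + H * ww), c);
          }
          for (int t = 0; t < len; ++t) {
            double s = 0.0;
            for (int r = -R; r <= R; ++r) {
              int u = t + r;
              if (u < 0) u = -u - 1;              // reflect
              if (u >= len) u = 2 * len - u - 1;
              s += kern[r + R] * line[u];
            }
            int dd = axis == 0 ? t : d, hh = axis == 1 ? t : h,
                ww = axis == 2 ? t : w;
            X(dd + D * (hh + H * ww), c) = s;
          }
        }
  (void)buf;
}

// [[Rcpp::export]]
NumericVector cpp_blur3(NumericVector x, IntegerVector dim, double sigma) {
  const int D = dim[0], H = dim[1], W = dim[2],
            C = dim.size() > 3 ? dim[3] : 1;
  mat X(x.begin(), D * H * W, C);
  if (sigma > 0) {
    const int R = std::max(1, (int)std::ceil(3.0 * sigma));
    std::vector<double> kern(2 * R + 1);
    double s = 0.0;
    for (int r = -R; r <= R; ++r) {
      kern[r + R] = std::exp(-0.5 * r * r / (sigma * sigma));
      s += kern[r + R];
    }
    for (int i = 0; i < (int)kern.size(); ++i) kern[i] /= s;
    std::vector<double> buf;
    blur_axis(buf, X, D, H, W, 0, kern);
    blur_axis(buf, X, D, H, W, 1, kern);
    blur_axis(buf, X, D, H, W, 2, kern);
  }
  NumericVector out(X.begin(), X.end());
  out.attr("dim") = dim;
  return out;
}

// Mean SSIM over all fully-interior win^3 windows, uniform weights.
// [[Rcpp::export]]
double cpp_ssim3(NumericVector x, NumericVector y, IntegerVector dim,
                 int win, double K1, double K2, double L) {
  const int D = dim[0], H = dim[1], W = dim[2];
  if (x.size() != y.size()) stop("volumes differ in size");
  if (win > D || win > H || win > W)
    stop("SSIM window (%d) exceeds a volume axis", win);
  const double C1 = (K1 * L) * (K1 * L), C2 = (K2 * L) * (K2 * L);
  const double n = (double)win * win * win;
  double acc = 0.0; long cnt = 0;
  for (int w0 = 0; w0 + win <= W; ++w0)
    for (int h0 = 0; h0 + win <= H; ++h0)
      for (int d0 = 0; d0 + win <= D; ++d0) {
        double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
        for (int w = w0; w < w0 + win; ++w)
          for (int h = h0; h < h0 + win; ++h)
            for (int d = d0; d < d0 + win; ++d) {
              const double a = x[d + D * (h + H * w)];
              const double b = y[d + D * (h + H * w)];
              sx += a; sy += b; sxx += a * a; syy += b * b; sxy += a * b;
            }
        const double mx = sx / n, my = sy / n;
        const double vx = sxx / n - mx * mx, vy = syy / n - my * my;
        const double cxy = sxy / n - mx * my;
        acc += ((2 * mx * my + C1) * (2 * cxy + C2)) /
               ((mx * mx + my * my + C1) * (vx + vy + C2));
        ++cnt;
      }
  return acc / cnt;
}
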