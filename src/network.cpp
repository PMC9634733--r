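// Multi-scale 3-D encoder-decoder voxel classifier with a parallel context
// path and optional deep supervision, plus its training engine (Adam,
// categorical cross-entropy, Glorot-uniform init, L2 weight penalty).
// Feature maps are arma::mat (channels x voxels), voxels column-major in
// x/y/z to match R arrays. Convolutions are 3x3x3 zero-padded via im2col;
// down-sampling is 2x max-pooling, up-sampling a kernel-2 stride-2
// transposed convolution, skip connections concatenate channels.

#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
// single-precision internals: training is memory-bandwidth bound and the
// voxel-classification task needs nowhere near double precision
typedef arma::fmat mat;
typedef arma::fvec vec;
typedef float real;

struct Dim3 {
  int x, y, z;
  long n() const { return (long)x * y * z; }
  Dim3 half() const { return {x / 2, y / 2, z / 2}; }
};

// Convolution via a 1-voxel zero halo: padding makes all 27 kernel
// offsets uniform shifts of the flat voxel index, so a 3x3x3 convolution
// becomes 27 GEMMs on contiguous column blocks of the padded feature map
// (no im2col materialization; feature maps stay cache-resident).
extern "C" void sgemm_(const char*, const char*, const int*, const int*,
                       const int*, const float*, const float*, const int*,
                       const float*, const int*, const float*, float*,
                       const int*);
extern "C" void dgemm_(const char*, const char*, const int*, const int*,
                       const int*, const double*, const double*, const int*,
                       const double*, const int*, const double*, double*,
                       const int*);
static inline void xgemm(char ta, char tb, int m, int n, int k, float alpha,
                         const float* A, int lda, const float* B, int ldb,
                         float beta, float* C, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}
static inline void xgemm(char ta, char tb, int m, int n, int k, double alpha,
                         const double* A, int lda, const double* B, int ldb,
                         double beta, double* C, int ldc) {
  dgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

struct Pad3 {
  int px, py, pz;
  long npad() const { return (long)px * py * pz; }
};
static inline Pad3 padof(const Dim3& d) { return {d.x + 2, d.y + 2, d.z + 2}; }

// interior <-> halo-padded copies (row-of-x memcpy per (y,z))
static void pad_interior(const mat& X, const Dim3& d, mat& Xp) {
  const int C = X.n_rows;
  Pad3 p = padof(d);
  Xp.zeros(C, p.npad());
  for (int z = 0; z < d.z; z++)
    for (int y = 0; y < d.y; y++) {
      long src = (long)d.x * ((long)y + (long)d.y * z);
      long dst = 1 + (long)p.px * ((long)(y + 1) + (long)p.py * (z + 1));
      std::memcpy(Xp.colptr(dst), X.colptr(src),
                  (size_t)C * d.x * sizeof(real));
    }
}
static void unpad_interior(const mat& Xp, const Dim3& d, mat& X) {
  const int C = Xp.n_rows;
  Pad3 p = padof(d);
  X.set_size(C, d.n());
  for (int z = 0; z < d.z; z++)
    for (int y = 0; y < d.y; y++) {
      long dst = (long)d.x * ((long)y + (long)d.y * z);
      long src = 1 + (long)p.px * ((long)(y + 1) + (long)p.py * (z + 1));
      std::memcpy(X.colptr(dst), Xp.colptr(src),
                  (size_t)C * d.x * sizeof(real));
    }
}

struct Param {
  mat W;          // weights
  vec b;          // bias
  mat gW, mW, vW; // grad + Adam state
  vec gb, mb, vb;
  bool is_weight = true;  // L2 applies to W
  void init_shape(int rows, int cols) {
    W.zeros(rows, cols); b.zeros(rows);
    gW.zeros(rows, cols); gb.zeros(rows);
    mW.zeros(rows, cols); vW.zeros(rows, cols);
    mb.zeros(rows); vb.zeros(rows);
  }
};

class Net {
public:
  Dim3 din;                 // main input dims
  int C, K, F, D;
  bool context, deepsup;
  double l2;
  std::vector<Param> P;
  long adam_t = 0;
  int batch_accum = 0;

  // named parameter indices
  std::vector<int> enc_a, enc_b;      // main encoder convs per level
  std::vector<int> cenc_a, cenc_b;    // context encoder convs per level
  int bot_a, bot_b, cbot_a, cbot_b, fuse;
  std::vector<int> up, dec_a, dec_b;  // per decoder level (index = level)
  std::vector<int> aux;               // aux heads, levels 1..D-1
  int head;

  std::vector<int> norm_of;   // per param: instance-norm param index or -1

  int add(int rows, int cols) {
    Param p;
    p.init_shape(rows, cols);
    P.push_back(std::move(p));
    norm_of.push_back(-1);
    return (int)P.size() - 1;
  }

  // conv followed by per-channel instance normalization (learnable
  // gamma/beta, excluded from the L2 penalty)
  int add_conv3n(int f, int cols) {
    int c = add(f, cols);
    int g = add(f, 1);
    P[g].is_weight = false;
    norm_of[c] = g;
    return c;
  }

  Net(Dim3 din_, int C_, int K_, int F_, int D_, bool ctx, bool ds, double l2_)
      : din(din_), C(C_), K(K_), F(F_), D(D_), context(ctx), deepsup(ds),
        l2(l2_) {
    enc_a.resize(D); enc_b.resize(D);
    up.resize(D); dec_a.resize(D); dec_b.resize(D);
    int fB = F << D;
    int cin = C;
    for (int i = 0; i < D; i++) {
      int f = F << i;
      enc_a[i] = add_conv3n(f, 27 * cin);
      enc_b[i] = add_conv3n(f, 27 * f);
      cin = f;
    }
    bot_a = add_conv3n(fB, 27 * (F << (D - 1)));
    bot_b = add_conv3n(fB, 27 * fB);
    if (context) {
      cenc_a.resize(D); cenc_b.resize(D);
      cin = C;
      for (int i = 0; i < D; i++) {
        int f = F << i;
        cenc_a[i] = add_conv3n(f, 27 * cin);
        cenc_b[i] = add_conv3n(f, 27 * f);
        cin = f;
      }
      cbot_a = add_conv3n(fB, 27 * (F << (D - 1)));
      cbot_b = add_conv3n(fB, 27 * fB);
      fuse = add_conv3n(fB, 27 * 2 * fB);
    }
    for (int i = D - 1; i >= 0; i--) {
      int f = F << i;
      int fin = (i == D - 1) ? fB : (F << (i + 1));
      up[i] = add(f, 8 * fin);
      dec_a[i] = add_conv3n(f, 27 * 2 * f);
      dec_b[i] = add_conv3n(f, 27 * f);
    }
    if (deepsup) {
      for (int i = 1; i < D; i++) aux.push_back(add(K, F << i));
    }
    head = add(K, F);
  }

  long nparams() const {
    long n = 0;
    for (const auto& p : P) n += p.W.n_elem + p.b.n_elem;
    return n;
  }

  void glorot_init() {
    // fan_in = receptive field x in-channels = W columns; fan_out = W rows
    for (auto& p : P) {
      if (!p.is_weight) {        // instance-norm gamma/beta
        p.W.ones();
        p.b.zeros();
        continue;
      }
      double limit = std::sqrt(6.0 / (p.W.n_cols + p.W.n_rows));
      for (arma::uword i = 0; i < p.W.n_elem; i++)
        p.W[i] = (2.0 * R::unif_rand() - 1.0) * limit;
      p.b.zeros();
    }
  }

  // ---- layer primitives (caching activations for backward) ----
  // conv -> (instance norm) -> relu; norm statistics are per channel over
  // the patch voxels, so inference is deterministic and batch-free
  struct ConvCache { mat xpad; mat pre; mat xhat; vec sigma; };
  mat conv3(int pi, const mat& X, const Dim3& d, ConvCache& cc, bool relu) {
    const int C = X.n_rows, f = P[pi].W.n_rows;
    Pad3 pd = padof(d);
    const long npad = pd.npad();
    pad_interior(X, d, cc.xpad);
    mat Yp(f, npad, arma::fill::zeros);
    int k = 0;
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++, k++) {
          long sft = (long)dx + (long)pd.px * ((long)dy + (long)pd.py * dz);
          long a = sft < 0 ? -sft : 0;
          long b = npad - 1 - (sft > 0 ? sft : 0);
          if (a > b) continue;
          xgemm('N', 'N', f, (int)(b - a + 1), C, (real)1,
                P[pi].W.colptr((size_t)k * C), f,
                cc.xpad.colptr(a + sft), C, (real)1, Yp.colptr(a), f);
        }
    mat Y;
    unpad_interior(Yp, d, Y);
    Y.each_col() += P[pi].b;
    int ni = norm_of[pi];
    if (ni >= 0) {
      const long n = Y.n_cols;
      cc.xhat.set_size(f, n);
      cc.sigma.set_size(f);
      std::vector<double> sum(f, 0.0), sq(f, 0.0);
      const real* yp = Y.memptr();
      for (long v = 0; v < n; v++)
        for (int c = 0; c < f; c++) {
          real x = yp[v * f + c];
          sum[c] += x;
          sq[c] += (double)x * x;
        }
      std::vector<real> mu(f), inv(f), ga(f), be(f);
      for (int c = 0; c < f; c++) {
        mu[c] = (real)(sum[c] / n);
        double var = sq[c] / n - (double)mu[c] * mu[c];
        if (var < 0) var = 0;
        cc.sigma[c] = (real)std::sqrt(var + 1e-5);
        inv[c] = (real)1 / cc.sigma[c];
        ga[c] = P[ni].W(c, 0);
        be[c] = P[ni].b[c];
      }
      real* xh = cc.xhat.memptr();
      real* yw = Y.memptr();
      for (long v = 0; v < n; v++)
        for (int c = 0; c < f; c++) {
          real h = (yw[v * f + c] - mu[c]) * inv[c];
          xh[v * f + c] = h;
          yw[v * f + c] = ga[c] * h + be[c];
        }
    }
    if (relu) {
      cc.pre = Y;
      Y.transform([](real v) { return v > 0 ? v : (real)0.0; });
    }
    return Y;
  }
  mat conv3_back(int pi, const mat& dYin, const Dim3& d, const ConvCache& cc,
                 bool relu, int cin) {
    mat dY = dYin;
    const int f = dY.n_rows;
    if (relu) {
      for (arma::uword i = 0; i < dY.n_elem; i++)
        if (cc.pre[i] <= 0) dY[i] = 0.0;
    }
    int ni = norm_of[pi];
    if (ni >= 0) {
      const long n = dY.n_cols;
      std::vector<double> dg(f, 0.0), db(f, 0.0), mdx(f, 0.0), mdxx(f, 0.0);
      const real* xh = cc.xhat.memptr();
      real* dyp = dY.memptr();
      std::vector<real> ga(f);
      for (int c = 0; c < f; c++) ga[c] = P[ni].W(c, 0);
      for (long v = 0; v < n; v++)
        for (int c = 0; c < f; c++) {
          real dy = dyp[v * f + c], h = xh[v * f + c];
          dg[c] += (double)dy * h;
          db[c] += dy;
          mdx[c] += (double)ga[c] * dy;
          mdxx[c] += (double)ga[c] * dy * h;
        }
      std::vector<real> m1(f), m2(f), inv(f);
      for (int c = 0; c < f; c++) {
        P[ni].gW(c, 0) += (real)dg[c];
        P[ni].gb[c] += (real)db[c];
        m1[c] = (real)(mdx[c] / n);
        m2[c] = (real)(mdxx[c] / n);
        inv[c] = (real)1 / cc.sigma[c];
      }
      for (long v = 0; v < n; v++)
        for (int c = 0; c < f; c++)
          dyp[v * f + c] = (ga[c] * dyp[v * f + c] - m1[c] -
                            xh[v * f + c] * m2[c]) * inv[c];
    }
    P[pi].gb += arma::sum(dY, 1);
    Pad3 pd = padof(d);
    const long npad = pd.npad();
    mat dYp;
    pad_interior(dY, d, dYp);
    mat dXp(cin, npad, arma::fill::zeros);
    int k = 0;
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++, k++) {
          long sft = (long)dx + (long)pd.px * ((long)dy + (long)pd.py * dz);
          long a = sft < 0 ? -sft : 0;
          long b = npad - 1 - (sft > 0 ? sft : 0);
          if (a > b) continue;
          int len = (int)(b - a + 1);
          // dW_k += dYp[:, a..b] * Xpad[:, a+s..b+s]^T
          xgemm('N', 'T', f, cin, len, (real)1, dYp.colptr(a), f,
                cc.xpad.colptr(a + sft), cin, (real)1,
                P[pi].gW.colptr((size_t)k * cin), f);
          // dXpad[:, a+s..b+s] += W_k^T * dYp[:, a..b]
          xgemm('T', 'N', cin, len, f, (real)1,
                P[pi].W.colptr((size_t)k * cin), f, dYp.colptr(a), f,
                (real)1, dXp.colptr(a + sft), cin);
        }
    mat dX;
    unpad_interior(dXp, d, dX);
    return dX;
  }

  static mat maxpool2(const mat& X, const Dim3& d, arma::umat& amax) {
    Dim3 o = d.half();
    int C = X.n_rows;
    mat Y(C, o.n());
    amax.set_size(C, o.n());
    long v = 0;
    for (int z = 0; z < o.z; z++)
      for (int y = 0; y < o.y; y++)
        for (int x = 0; x < o.x; x++, v++) {
          for (int c = 0; c < C; c++) { Y(c, v) = -1e30f; }
          for (int dz = 0; dz <= 1; dz++)
            for (int dy = 0; dy <= 1; dy++)
              for (int dx = 0; dx <= 1; dx++) {
                long u = (long)(2 * x + dx) +
                         (long)d.x * ((long)(2 * y + dy) +
                                      (long)d.y * (2 * z + dz));
                for (int c = 0; c < C; c++)
                  if (X(c, u) > Y(c, v)) { Y(c, v) = X(c, u); amax(c, v) = u; }
              }
        }
    return Y;
  }
  static mat maxpool2_back(const mat& dY, const Dim3& d, const arma::umat& amax) {
    int C = dY.n_rows;
    mat dX(C, d.n(), arma::fill::zeros);
    for (arma::uword v = 0; v < dY.n_cols; v++)
      for (int c = 0; c < C; c++) dX(c, amax(c, v)) += dY(c, v);
    return dX;
  }

  static mat avgpool2(const mat& X, const Dim3& d) {
    Dim3 o = d.half();
    int C = X.n_rows;
    mat Y(C, o.n(), arma::fill::zeros);
    long v = 0;
    for (int z = 0; z < o.z; z++)
      for (int y = 0; y < o.y; y++)
        for (int x = 0; x < o.x; x++, v++) {
          for (int dz = 0; dz <= 1; dz++)
            for (int dy = 0; dy <= 1; dy++)
              for (int dx = 0; dx <= 1; dx++) {
                long u = (long)(2 * x + dx) +
                         (long)d.x * ((long)(2 * y + dy) +
                                      (long)d.y * (2 * z + dz));
                Y.col(v) += X.col(u);
              }
          Y.col(v) *= 0.125;
        }
    return Y;
  }

  // transposed conv, kernel 2 stride 2; W: (cout x 8*cin), relu applied.
  // Computed as 8 dense GEMMs (one per output offset) + column scatter.
  struct TCache { mat pre; };
  static long toff(int k, long v, const Dim3& dlo) {
    int dx = k & 1, dy = (k >> 1) & 1, dz = (k >> 2) & 1;
    int x = (int)(v % dlo.x), y = (int)((v / dlo.x) % dlo.y),
        z = (int)(v / ((long)dlo.x * dlo.y));
    return (long)(2 * x + dx) +
           (long)(2 * dlo.x) * ((long)(2 * y + dy) +
                                (long)(2 * dlo.y) * (2 * z + dz));
  }
  mat tconv2(int pi, const mat& X, const Dim3& dlo, TCache& tc) {
    Dim3 dhi{dlo.x * 2, dlo.y * 2, dlo.z * 2};
    int cin = X.n_rows, cout = P[pi].W.n_rows;
    mat Y(cout, dhi.n());
    for (int k = 0; k < 8; k++) {
      mat Yk = P[pi].W.cols(k * cin, (k + 1) * cin - 1) * X;
      Yk.each_col() += P[pi].b;
      for (long v = 0; v < dlo.n(); v++)
        Y.col(toff(k, v, dlo)) = Yk.col(v);
    }
    tc.pre = Y;
    Y.transform([](double v2) { return v2 > 0 ? v2 : 0.0; });
    return Y;
  }
  mat tconv2_back(int pi, const mat& dYin, const mat& X, const Dim3& dlo,
                  const TCache& tc) {
    mat dY = dYin;
    for (arma::uword i = 0; i < dY.n_elem; i++)
      if (tc.pre[i] <= 0) dY[i] = 0.0;
    int cin = X.n_rows;
    mat dX(cin, dlo.n(), arma::fill::zeros);
    mat dYk(dY.n_rows, dlo.n());
    for (int k = 0; k < 8; k++) {
      for (long v = 0; v < dlo.n(); v++) dYk.col(v) = dY.col(toff(k, v, dlo));
      P[pi].gW.cols(k * cin, (k + 1) * cin - 1) += dYk * X.t();
      P[pi].gb += arma::sum(dYk, 1);
      dX += P[pi].W.cols(k * cin, (k + 1) * cin - 1).t() * dYk;
    }
    return dX;
  }

  mat conv1(int pi, const mat& X) {
    mat Y = P[pi].W * X;
    Y.each_col() += P[pi].b;
    return Y;
  }
  mat conv1_back(int pi, const mat& dY, const mat& X) {
    P[pi].gW += dY * X.t();
    P[pi].gb += arma::sum(dY, 1);
    return P[pi].W.t() * dY;
  }

  static mat softmax_cols(const mat& logits) {
    mat P = logits;
    const int K = P.n_rows;
    real* p = P.memptr();
    for (arma::uword v = 0; v < P.n_cols; v++, p += K) {
      real mx = p[0];
      for (int k = 1; k < K; k++) mx = std::max(mx, p[k]);
      real s = 0.0f;
      for (int k = 0; k < K; k++) { p[k] = std::exp(p[k] - mx); s += p[k]; }
      for (int k = 0; k < K; k++) p[k] /= s;
    }
    return P;
  }

  // ---- full forward (caches kept when training) ----
  struct FwdState {
    std::vector<mat> skips;                // main encoder pre-pool acts
    std::vector<ConvCache> cc;             // conv caches in call order
    std::vector<arma::umat> pools;         // main encoder pool argmax
    std::vector<arma::umat> cpools;        // context encoder pool argmax
    std::vector<TCache> tcs;
    std::vector<mat> tconv_in, dec_acts;   // decoder inputs per level
    mat xin, cin_ds;                       // inputs (for grads of first convs)
    mat bott_main_in, bott_ctx_in, fuse_in;
    mat final_feat;
    std::vector<mat> aux_feats;
    mat probs;
    std::vector<mat> aux_probs;
  };

  void forward(const mat& Xmain, const mat& Xctx, FwdState& S,
               bool ctx_prepooled = false) {
    S.cc.clear(); S.skips.clear(); S.pools.clear(); S.cpools.clear();
    S.tcs.clear(); S.tconv_in.clear(); S.dec_acts.clear();
    S.aux_feats.clear(); S.aux_probs.clear();

    Dim3 d = din;
    S.xin = Xmain;
    mat h = Xmain;
    // main encoder
    std::vector<Dim3> dims(D + 1);
    for (int i = 0; i < D; i++) {
      dims[i] = d;
      S.cc.emplace_back();
      h = conv3(enc_a[i], h, d, S.cc.back(), true);
      S.cc.emplace_back();
      h = conv3(enc_b[i], h, d, S.cc.back(), true);
      S.skips.push_back(h);
      S.pools.emplace_back();
      h = maxpool2(h, d, S.pools.back());
      d = d.half();
    }
    dims[D] = d;
    S.bott_main_in = h;
    S.cc.emplace_back();
    h = conv3(bot_a, h, d, S.cc.back(), true);
    S.cc.emplace_back();
    h = conv3(bot_b, h, d, S.cc.back(), true);

    if (context) {
      Dim3 cd{din.x * 2, din.y * 2, din.z * 2};
      mat ch = ctx_prepooled ? Xctx : avgpool2(Xctx, cd);
      S.cin_ds = ch;
      Dim3 e = din;
      for (int i = 0; i < D; i++) {
        S.cc.emplace_back();
        ch = conv3(cenc_a[i], ch, e, S.cc.back(), true);
        S.cc.emplace_back();
        ch = conv3(cenc_b[i], ch, e, S.cc.back(), true);
        S.cpools.emplace_back();
        ch = maxpool2(ch, e, S.cpools.back());
        e = e.half();
      }
      S.bott_ctx_in = ch;
      S.cc.emplace_back();
      ch = conv3(cbot_a, ch, e, S.cc.back(), true);
      S.cc.emplace_back();
      ch = conv3(cbot_b, ch, e, S.cc.back(), true);
      S.fuse_in = arma::join_cols(h, ch);
      S.cc.emplace_back();
      h = conv3(fuse, S.fuse_in, d, S.cc.back(), true);
    }

    // decoder
    for (int i = D - 1; i >= 0; i--) {
      S.tconv_in.push_back(h);
      S.tcs.emplace_back();
      mat u = tconv2(up[i], h, dims[i + 1], S.tcs.back());
      mat cat = arma::join_cols(u, S.skips[i]);
      S.dec_acts.push_back(cat);
      S.cc.emplace_back();
      h = conv3(dec_a[i], cat, dims[i], S.cc.back(), true);
      S.cc.emplace_back();
      h = conv3(dec_b[i], h, dims[i], S.cc.back(), true);
      if (deepsup && i >= 1) {
        S.aux_feats.push_back(h);
        S.aux_probs.push_back(softmax_cols(conv1(aux[i - 1], h)));
      }
    }
    S.final_feat = h;
    S.probs = softmax_cols(conv1(head, h));
  }

  // cross-entropy loss + gradient accumulation; gt 0-based, length n.
  // Returns main loss; deep-supervision losses weighted 0.5^level.
  // cw: optional per-class loss weights (empty = unweighted); the loss is
  // normalized by the total weight so its scale stays comparable.
  double backward(const IntegerVector& gt, FwdState& S, double* aux_loss,
                  const std::vector<double>& cw) {
    Dim3 d = din;
    long n = d.n();
    mat dlog = S.probs;
    double loss = 0.0, wsum = 0.0;
    const bool weighted = !cw.empty();
    for (long v = 0; v < n; v++) {
      double w = weighted ? cw[gt[v]] : 1.0;
      wsum += w;
      loss += -w * std::log(std::max((double)S.probs(gt[v], v), 1e-12));
      dlog(gt[v], v) -= 1.0;
      if (weighted)
        for (int k = 0; k < K; k++) dlog(k, v) *= (real)w;
    }
    loss /= wsum;
    dlog /= (real)wsum;

    int cci = (int)S.cc.size();
    // head
    mat dh = conv1_back(head, dlog, S.final_feat);
    *aux_loss = 0.0;

    // decoder backward, reverse order (levels 0 .. D-1 ascending)
    std::vector<Dim3> dims(D + 1);
    Dim3 dd = din;
    for (int i = 0; i <= D; i++) { dims[i] = dd; dd = dd.half(); }

    int tci = (int)S.tcs.size();
    int auxi = (int)S.aux_probs.size();
    for (int i = 0; i <= D - 1; i++) {
      // aux head gradient joins at level i >= 1
      if (deepsup && i >= 1) {
        auxi--;
        // subsampled gt: take voxel at stride 2^i
        int s = 1 << i;
        Dim3 di = dims[i];
        long ni = di.n();
        mat dla = S.aux_probs[auxi];
        double al = 0.0;
        long v = 0;
        for (int z = 0; z < di.z; z++)
          for (int y = 0; y < di.y; y++)
            for (int x = 0; x < di.x; x++, v++) {
              long g = (long)(x * s) +
                       (long)din.x * ((long)(y * s) + (long)din.y * (z * s));
              double wv = weighted ? cw[gt[g]] : 1.0;
              al += -wv * std::log(std::max((double)dla(gt[g], v), 1e-12));
              dla(gt[g], v) -= 1.0;
              if (weighted)
                for (int k = 0; k < K; k++) dla(k, v) *= (real)wv;
            }
        double w = std::pow(0.5, i);
        // per-level weight sum mirrors the main normalization
        double wni = 0.0;
        if (weighted) {
          long v2 = 0;
          for (int z = 0; z < di.z; z++)
            for (int y = 0; y < di.y; y++)
              for (int x = 0; x < di.x; x++, v2++) {
                long g = (long)(x * s) +
                         (long)din.x * ((long)(y * s) + (long)din.y * (z * s));
                wni += cw[gt[g]];
              }
        } else wni = (double)ni;
        al = al / wni * w;
        *aux_loss += al;
        dla *= (real)(w / wni);
        dh += conv1_back(aux[i - 1], dla, S.aux_feats[auxi]);
      }
      // two convs of decoder level i (caches at the end of cc, in order)
      cci -= 1;
      mat d2 = conv3_back(dec_b[i], dh, dims[i], S.cc[cci], true, F << i);
      cci -= 1;
      mat dcat = conv3_back(dec_a[i], d2, dims[i], S.cc[cci],
                            true, 2 * (F << i));
      int f = F << i;
      mat du = dcat.rows(0, f - 1);
      mat dskip = dcat.rows(f, 2 * f - 1);
      tci -= 1;
      dh = tconv2_back(up[i], du, S.tconv_in[tci], dims[i + 1], S.tcs[tci]);
      // stash the skip-connection gradient; encoder backward adds it in
      S.skips[i] = dskip;
    }

    // fusion / context path backward
    if (context) {
      int fB = F << D;
      cci -= 1;
      mat dfuse = conv3_back(fuse, dh, dims[D], S.cc[cci], true, 2 * fB);
      mat dmainb = dfuse.rows(0, fB - 1);
      mat dctxb = dfuse.rows(fB, 2 * fB - 1);
      // context bottleneck
      cci -= 1;
      mat dc = conv3_back(cbot_b, dctxb, dims[D], S.cc[cci], true, fB);
      cci -= 1;
      dc = conv3_back(cbot_a, dc, dims[D], S.cc[cci], true, F << (D - 1));
      // context encoder backward
      for (int i = D - 1; i >= 0; i--) {
        dc = maxpool2_back(dc, dims[i], S.cpools[i]);
        cci -= 1;
        dc = conv3_back(cenc_b[i], dc, dims[i], S.cc[cci], true, F << i);
        cci -= 1;
        int cin = (i == 0) ? C : (F << (i - 1));
        dc = conv3_back(cenc_a[i], dc, dims[i], S.cc[cci], true, cin);
      }
      dh = dmainb;
    }

    // main bottleneck backward
    cci -= 1;
    dh = conv3_back(bot_b, dh, dims[D], S.cc[cci], true, F << D);
    cci -= 1;
    dh = conv3_back(bot_a, dh, dims[D], S.cc[cci], true, F << (D - 1));

    // main encoder backward (deepest level first); skip grads were stashed
    for (int i = D - 1; i >= 0; i--) {
      mat dact = maxpool2_back(dh, dims[i], S.pools[i]);
      dact += S.skips[i];  // skip-connection gradient
      cci -= 1;
      dact = conv3_back(enc_b[i], dact, dims[i], S.cc[cci], true, F << i);
      cci -= 1;
      int cin = (i == 0) ? C : (F << (i - 1));
      dh = conv3_back(enc_a[i], dact, dims[i], S.cc[cci], true, cin);
    }
    batch_accum++;
    return loss;
  }

  double l2_penalty() const {
    double s = 0.0;
    for (const auto& p : P)
      if (p.is_weight) s += arma::accu(arma::square(p.W));
    return l2 * s;
  }

  void adam_step(double lr, double beta1, double beta2, double eps) {
    adam_t++;
    double bc1 = 1.0 - std::pow(beta1, (double)adam_t);
    double bc2 = 1.0 - std::pow(beta2, (double)adam_t);
    double nb = std::max(1, batch_accum);
    for (auto& p : P) {
      mat g = p.gW / nb;
      if (p.is_weight) g += (real)(2.0 * l2) * p.W;
      p.mW = beta1 * p.mW + (1 - beta1) * g;
      p.vW = beta2 * p.vW + (1 - beta2) * arma::square(g);
      p.W -= lr * (p.mW / bc1) / (arma::sqrt(p.vW / bc2) + eps);
      vec gb = p.gb / nb;
      p.mb = beta1 * p.mb + (1 - beta1) * gb;
      p.vb = beta2 * p.vb + (1 - beta2) * arma::square(gb);
      p.b -= lr * (p.mb / bc1) / (arma::sqrt(p.vb / bc2) + eps);
      p.gW.zeros();
      p.gb.zeros();
    }
    batch_accum = 0;
  }

  void zero_grads() {
    for (auto& p : P) { p.gW.zeros(); p.gb.zeros(); }
    batch_accum = 0;
  }
};

// ---- R interface -----------------------------------------------------------

static mat patch_to_mat(const NumericVector& arr, int C, long n) {
  // arr laid out as (x,y,z,channel): column c is a contiguous block
  mat X(C, n);
  for (int c = 0; c < C; c++)
    for (long v = 0; v < n; v++) X(c, v) = arr[c * n + v];
  return X;
}

// ---- compact training dataset: single-precision samples resident in
// C++, context stored pre-pooled (the network pools it at entry anyway),
// cutting memory ~16x versus R double arrays.
struct DSample {
  mat main;            // C x n
  mat ctx;             // C x n (pre-pooled) or empty
  std::vector<int> gt; // n, 0-based
};

// [[Rcpp::export]]
SEXP ds_create() {
  auto* v = new std::vector<DSample>();
  Rcpp::XPtr<std::vector<DSample>> ptr(v, true);
  return ptr;
}

// [[Rcpp::export]]
int ds_add(SEXP dsp, NumericVector main_patch,
           Nullable<NumericVector> context_patch, IntegerVector gt,
           IntegerVector main_dims, int channels) {
  Rcpp::XPtr<std::vector<DSample>> ds(dsp);
  Dim3 d{main_dims[0], main_dims[1], main_dims[2]};
  long n = d.n();
  DSample sm;
  sm.main = patch_to_mat(main_patch, channels, n);
  if (context_patch.isNotNull()) {
    NumericVector cp(context_patch);
    mat full = patch_to_mat(cp, channels, 8 * n);
    Dim3 cd{d.x * 2, d.y * 2, d.z * 2};
    sm.ctx = Net::avgpool2(full, cd);
  }
  sm.gt.assign(gt.begin(), gt.end());
  ds->push_back(std::move(sm));
  return (int)ds->size();
}

// [[Rcpp::export]]
int ds_size(SEXP dsp) {
  Rcpp::XPtr<std::vector<DSample>> ds(dsp);
  return (int)ds->size();
}

// per-class ground-truth voxel counts over the dataset
// [[Rcpp::export]]
NumericVector ds_class_counts(SEXP dsp, int classes) {
  Rcpp::XPtr<std::vector<DSample>> ds(dsp);
  NumericVector cnt(classes);
  for (auto& sm : *ds)
    for (int g : sm.gt) cnt[g] += 1.0;
  return cnt;
}

// [[Rcpp::export]]
NumericVector net_accumulate_ds(SEXP p, SEXP dsp, int i,
                                Nullable<NumericVector> class_weights = R_NilValue) {
  Rcpp::XPtr<Net> net(p);
  Rcpp::XPtr<std::vector<DSample>> ds(dsp);
  if (i < 0 || i >= (int)ds->size()) stop("dataset index out of range");
  DSample& sm = (*ds)[i];
  if ((long)sm.gt.size() != net->din.n()) stop("gt patch size mismatch");
  IntegerVector gt(sm.gt.begin(), sm.gt.end());
  std::vector<double> cw;
  if (class_weights.isNotNull()) {
    NumericVector w(class_weights);
    cw.assign(w.begin(), w.end());
  }
  Net::FwdState S;
  net->forward(sm.main, sm.ctx, S, true);
  double aux = 0.0;
  double main_loss = net->backward(gt, S, &aux, cw);
  return NumericVector::create(_["main"] = main_loss, _["aux"] = aux,
                               _["l2"] = net->l2_penalty());
}

// [[Rcpp::export]]
SEXP net_create(IntegerVector main_dims, int channels, int classes,
                int base_filters, int depth, bool context_path,
                bool deep_supervision, double l2) {
  Dim3 d{main_dims[0], main_dims[1], main_dims[2]};
  if (d.x % (1 << depth) || d.y % (1 << depth) || d.z % (1 << depth))
    stop("main input dims must be divisible by 2^depth");
  Net* net = new Net(d, channels, classes, base_filters, depth, context_path,
                     deep_supervision, l2);
  Rcpp::XPtr<Net> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
void net_init_glorot(SEXP p) {
  Rcpp::XPtr<Net> net(p);
  net->glorot_init();
}

// [[Rcpp::export]]
double net_nparams(SEXP p) {
  Rcpp::XPtr<Net> net(p);
  return (double)net->nparams();
}

// [[Rcpp::export]]
NumericVector net_get_weights(SEXP p) {
  Rcpp::XPtr<Net> net(p);
  std::vector<double> out;
  for (auto& q : net->P) {
    out.insert(out.end(), q.W.begin(), q.W.end());
    out.insert(out.end(), q.b.begin(), q.b.end());
  }
  return wrap(out);
}

// Accumulated raw gradients (same layout as net_get_weights), without the
// L2 term and without batch normalization — used for gradient checking.
// [[Rcpp::export]]
NumericVector net_get_grads(SEXP p) {
  Rcpp::XPtr<Net> net(p);
  std::vector<double> out;
  for (auto& q : net->P) {
    out.insert(out.end(), q.gW.begin(), q.gW.end());
    out.insert(out.end(), q.gb.begin(), q.gb.end());
  }
  return wrap(out);
}

// [[Rcpp::export]]
void net_set_weights(SEXP p, NumericVector w) {
  Rcpp::XPtr<Net> net(p);
  long k = 0;
  for (auto& q : net->P) {
    for (auto& v : q.W) v = w[k++];
    for (auto& v : q.b) v = w[k++];
  }
  if (k != (long)w.size()) stop("weight vector length mismatch");
}

// [[Rcpp::export]]
NumericVector net_forward(SEXP p, NumericVector main_patch,
                          Nullable<NumericVector> context_patch) {
  Rcpp::XPtr<Net> net(p);
  long n = net->din.n();
  mat X = patch_to_mat(main_patch, net->C, n);
  mat Xc;
  if (net->context) {
    if (context_patch.isNull()) stop("model requires a context patch");
    NumericVector cp(context_patch);
    Xc = patch_to_mat(cp, net->C, 8 * n);
  }
  Net::FwdState S;
  net->forward(X, Xc, S);
  NumericVector out((long)net->K * n);
  for (int k = 0; k < net->K; k++)
    for (long v = 0; v < n; v++) out[(long)k * n + v] = S.probs(k, v);
  out.attr("dim") = IntegerVector::create(net->din.x, net->din.y, net->din.z,
                                          net->K);
  return out;
}

// Forward + backward on one sample, accumulating gradients. gt is 0-based
// class per voxel at main resolution. Returns loss components.
// [[Rcpp::export]]
NumericVector net_accumulate(SEXP p, NumericVector main_patch,
                             Nullable<NumericVector> context_patch,
                             IntegerVector gt,
                             Nullable<NumericVector> class_weights = R_NilValue) {
  Rcpp::XPtr<Net> net(p);
  long n = net->din.n();
  if ((long)gt.size() != n) stop("gt patch size mismatch");
  mat X = patch_to_mat(main_patch, net->C, n);
  mat Xc;
  if (net->context) {
    if (context_patch.isNull()) stop("model requires a context patch");
    NumericVector cp(context_patch);
    Xc = patch_to_mat(cp, net->C, 8 * n);
  }
  Net::FwdState S;
  net->forward(X, Xc, S);
  std::vector<double> cw;
  if (class_weights.isNotNull()) {
    NumericVector w(class_weights);
    if ((int)w.size() != net->K) stop("class_weights length mismatch");
    cw.assign(w.begin(), w.end());
  }
  double aux = 0.0;
  double main_loss = net->backward(gt, S, &aux, cw);
  return NumericVector::create(_["main"] = main_loss, _["aux"] = aux,
                               _["l2"] = net->l2_penalty());
}

// Set the softmax-head biases (main head and any deep-supervision heads)
// to the given per-class values, e.g. log class priors.
// [[Rcpp::export]]
void net_set_head_bias(SEXP p, NumericVector b) {
  Rcpp::XPtr<Net> net(p);
  if ((int)b.size() != net->K) stop("bias length must equal classes");
  for (int k = 0; k < net->K; k++) net->P[net->head].b[k] = (real)b[k];
  for (size_t a = 0; a < net->aux.size(); a++)
    for (int k = 0; k < net->K; k++) net->P[net->aux[a]].b[k] = (real)b[k];
}

// [[Rcpp::export]]
void net_step(SEXP p, double lr, double beta1 = 0.9, double beta2 = 0.999,
              double eps = 1e-8) {
  Rcpp::XPtr<Net> net(p);
  net->adam_step(lr, beta1, beta2, eps);
}

// [[Rcpp::export]]
void net_zero_grads(SEXP p) {
  Rcpp::XPtr<Net> net(p);
  net->zero_grads();
}

// [[Rcpp::export]]
List net_info(SEXP p) {
  Rcpp::XPtr<Net> net(p);
  return List::create(
      _["main_dims"] = IntegerVector::create(net->din.x, net->din.y, net->din.z),
      _["channels"] = net->C, _["classes"] = net->K,
      _["base_filters"] = net->F, _["depth"] = net->D,
      _["context_path"] = net->context, _["deep_supervision"] = net->deepsup,
      _["l2"] = net->l2, _["n_params"] = (double)net->nparams(),
      _["adam_t"] = (double)net->adam_t);
}
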