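// Single-precision training/inference engine for the residual 1-D CNN +
// stacked indRNN classifier. Feature maps are stored as (rows = batch*time,
// cols = channels); the convolutional stage keeps rows sample-major
// (sample b occupies rows [b*T, (b+1)*T)), the recurrent stage time-major
// (time t occupies rows [t*B, (t+1)*B)).
//
// Parameter list order (must match the R builder in R/model_build.R):
//   per block:  W1 b1 g1 be1 rm1 rv1 | W2 ... | W3 ... | [Wp bp gp bep rmp rvp]
//   per rnn layer: Wr (units x in) u b g be rm rv
//   dense: Wd bd Wo bo
// rm/rv are batch-norm running stats (state, not trained).

#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::IntegerVector;
using Rcpp::NumericVector;
using Rcpp::stop;

typedef std::vector<fmat> ParamSet;

// the engine churns through large short-lived buffers; keep glibc from
// serving them via mmap so pages are reused instead of re-faulted
static void tune_allocator() {
#ifdef __GLIBC__
  static bool done = false;
  if (!done) {
    mallopt(M_MMAP_MAX, 0);
    mallopt(M_TRIM_THRESHOLD, 1 << 30);
    done = true;
  }
#endif
}

struct EngineCfg {
  int n_blocks;
  std::vector<int> cin, fout, proj;
  std::vector<std::array<int,3>> kern, strd;
  int pool_w;                    // <= 1 = no pooling
  std::vector<int> rnn_units, rnn_in;
  int dense_units, n_class;
  float leaky, bn_eps, bn_mom, u_clip;
};

static EngineCfg parse_cfg(const List& cfg) {
  EngineCfg c;
  IntegerVector fout = cfg["filters"], cin = cfg["cin"], proj = cfg["proj"];
  List kern = cfg["kernels"], strd = cfg["strides"];
  c.n_blocks = fout.size();
  for (int b = 0; b < c.n_blocks; ++b) {
    c.fout.push_back(fout[b]);
    c.cin.push_back(cin[b]);
    c.proj.push_back(proj[b]);
    IntegerVector kb = kern[b], sb = strd[b];
    c.kern.push_back({kb[0], kb[1], kb[2]});
    c.strd.push_back({sb[0], sb[1], sb[2]});
  }
  c.pool_w = Rcpp::as<int>(cfg["pool_w"]);
  IntegerVector ru = cfg["rnn_units"];
  int d = c.fout[c.n_blocks - 1];
  for (int l = 0; l < ru.size(); ++l) {
    c.rnn_units.push_back(ru[l]);
    c.rnn_in.push_back(d);
    d = ru[l];
  }
  c.dense_units = Rcpp::as<int>(cfg["dense_units"]);
  c.n_class = Rcpp::as<int>(cfg["n_class"]);
  c.leaky = Rcpp::as<double>(cfg["leaky_slope"]);
  c.bn_eps = Rcpp::as<double>(cfg["bn_eps"]);
  c.bn_mom = Rcpp::as<double>(cfg["bn_momentum"]);
  c.u_clip = Rcpp::as<double>(cfg["u_clip"]);
  return c;
}

static ParamSet params_from_r(const List& pl) {
  ParamSet P;
  P.reserve(pl.size());
  for (int i = 0; i < pl.size(); ++i) {
    SEXP el = pl[i];
    if (Rf_isMatrix(el)) {
      P.push_back(conv_to<fmat>::from(Rcpp::as<mat>(el)));
    } else {
      NumericVector v(el);
      fmat m(v.size(), 1);
      for (int j = 0; j < v.size(); ++j) m(j, 0) = (float)v[j];
      P.push_back(m);
    }
  }
  return P;
}

static List params_to_r(const ParamSet& P, const List& proto) {
  List out(proto.size());
  out.names() = proto.names();
  for (size_t i = 0; i < P.size(); ++i) {
    if (Rf_isMatrix(proto[i])) {
      out[i] = Rcpp::wrap(conv_to<mat>::from(P[i]));
    } else {
      NumericVector v(P[i].n_rows);
      for (uword j = 0; j < P[i].n_rows; ++j) v[j] = P[i](j, 0);
      out[i] = v;
    }
  }
  return out;
}

static inline int out_len(int T, int stride) { return (T + stride - 1) / stride; }

// im2col over a sample-major batch map X (B*T x C): result (B*T_out x C*k)
// with column index j*C + c for tap j, channel c ("same" padding, left pad
// floor((span - T)/2) where span = (T_out-1)*stride + k).
static fmat im2col_batch(const fmat& X, int B, int T, int k, int stride,
                         int T_out) {
  const int C = X.n_cols;
  const int pad = std::max((T_out - 1) * stride + k - T, 0) / 2;
  fmat cols(B * (size_t)T_out, (size_t)C * k);   // uninitialized
  for (int j = 0; j < k; ++j) {
    // valid output positions t with 0 <= t*stride - pad + j < T
    const int t0 = std::max(0, (pad - j + stride - 1) / stride);
    const int t1 = std::min(T_out - 1, (T - 1 + pad - j) / stride);
    for (int c = 0; c < C; ++c) {
      const float* src = X.colptr(c);
      float* dst = cols.colptr((size_t)j * C + c);
      for (int b = 0; b < B; ++b) {
        const float* s = src + (size_t)b * T - pad + j;
        float* d = dst + (size_t)b * T_out;
        for (int t = 0; t < std::min(t0, T_out); ++t) d[t] = 0.0f;
        if (t1 >= t0) {
          if (stride == 1) {
            std::memcpy(d + t0, s + t0, (size_t)(t1 - t0 + 1) * sizeof(float));
          } else {
            for (int t = t0; t <= t1; ++t) d[t] = s[(size_t)t * stride];
          }
        }
        for (int t = std::max(t1 + 1, 0); t < T_out; ++t) d[t] = 0.0f;
      }
    }
  }
  return cols;
}

// adjoint of im2col_batch: accumulate gradient columns back onto the input map
static fmat col2im_batch(const fmat& dcols, int B, int T, int C, int k,
                         int stride, int T_out) {
  const int pad = std::max((T_out - 1) * stride + k - T, 0) / 2;
  fmat dX(B * (size_t)T, C, fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int t0 = std::max(0, (pad - j + stride - 1) / stride);
    const int t1 = std::min(T_out - 1, (T - 1 + pad - j) / stride);
    if (t1 < t0) continue;
    for (int c = 0; c < C; ++c) {
      const float* src = dcols.colptr((size_t)j * C + c);
      float* dst = dX.colptr(c);
      for (int b = 0; b < B; ++b) {
        const float* __restrict s = src + (size_t)b * T_out;
        float* __restrict d = dst + (size_t)b * T - pad + j;
        if (stride == 1) {
          for (int t = t0; t <= t1; ++t) d[t] += s[t];
        } else {
          for (int t = t0; t <= t1; ++t) d[(size_t)t * stride] += s[t];
        }
      }
    }
  }
  return dX;
}

// batch-norm cache: the pre-normalization map Z plus per-channel mean and
// inverse std, from which xhat is recomputed on the fly in the backward pass
struct BnCache { fmat Z; fvec mean, istd; };

// blocked float accumulation: SIMD-friendly with bounded rounding error
static inline void col_sums(const float* a, uword N, double& s_out,
                            double& ss_out) {
  double s = 0.0, ss = 0.0;
  uword i = 0;
  for (; i + 1024 <= N; i += 1024) {
    float bs = 0.0f, bss = 0.0f;
    const float* __restrict p = a + i;
    for (uword j = 0; j < 1024; ++j) { bs += p[j]; bss += p[j] * p[j]; }
    s += bs; ss += bss;
  }
  float bs = 0.0f, bss = 0.0f;
  for (; i < N; ++i) { bs += a[i]; bss += a[i] * a[i]; }
  s_out = s + bs; ss_out = ss + bss;
}

// batch norm over rows, per column; training mode updates running stats.
// If act, LeakyReLU(slope) is fused into the output. Consumes Z (moved into
// the cache when one is supplied).
static fmat bn_forward(fmat&& Z, fmat& g, fmat& be, fmat& rm, fmat& rv,
                       float eps, float mom, bool train, BnCache* cache,
                       bool act, float slope) {
  const uword N = Z.n_rows, C = Z.n_cols;
  const float invN = 1.0f / (float)N;
  fmat Y(N, C);
  if (cache) { cache->mean.set_size(C); cache->istd.set_size(C); }
  for (uword c = 0; c < C; ++c) {
    const float* __restrict a = Z.colptr(c);
    float m, istd;
    if (train) {
      double s, ss;
      col_sums(a, N, s, ss);
      m = (float)(s * invN);
      float v = (float)(ss * invN) - m * m;
      if (v < 0.0f) v = 0.0f;
      istd = 1.0f / std::sqrt(v + eps);
      rm(c, 0) = mom * rm(c, 0) + (1.0f - mom) * m;
      rv(c, 0) = mom * rv(c, 0) +
                 (1.0f - mom) * v * (N > 1 ? (float)N / (float)(N - 1) : 1.0f);
    } else {
      m = rm(c, 0);
      istd = 1.0f / std::sqrt(rv(c, 0) + eps);
    }
    if (cache) { cache->mean(c) = m; cache->istd(c) = istd; }
    // y = scale * z + shift, leaky fused as max(y, slope*y) (slope in [0,1))
    const float scale = g(c, 0) * istd;
    const float shift = be(c, 0) - scale * m;
    float* __restrict y = Y.colptr(c);
    if (act) {
      for (uword i = 0; i < N; ++i) {
        const float o = scale * a[i] + shift;
        const float os = o * slope;
        y[i] = o > os ? o : os;
      }
    } else {
      for (uword i = 0; i < N; ++i) y[i] = scale * a[i] + shift;
    }
  }
  if (cache) cache->Z = std::move(Z);
  return Y;
}

// backward through (optional LeakyReLU) + batch norm: dOut is the gradient
// at the layer output; when act, Yact is the activated output whose sign
// recovers the LeakyReLU mask. Returns dZ; accumulates dg/dbe.
static fmat bn_backward(const fmat& dOut, const fmat* Yact, float slope,
                        const BnCache& cache, const fmat& g,
                        fmat& dg, fmat& dbe) {
  const uword N = dOut.n_rows, C = dOut.n_cols;
  const float invN = 1.0f / (float)N;
  fmat dA(N, C);
  dg.set_size(C, 1);
  dbe.set_size(C, 1);
  for (uword c = 0; c < C; ++c) {
    const float* __restrict dout = dOut.colptr(c);
    const float* __restrict ya = Yact ? Yact->colptr(c) : nullptr;
    const float* __restrict z = cache.Z.colptr(c);
    const float m = cache.mean(c), istd = cache.istd(c);
    float* __restrict da = dA.colptr(c);
    // pass 1: dy (leaky mask applied), stashed in da; sums of dy and dy*z
    float sd = 0.0f, sdz = 0.0f;
    if (ya) {
      for (uword i = 0; i < N; ++i) {
        const float dy = (ya[i] < 0.0f) ? dout[i] * slope : dout[i];
        da[i] = dy;
        sd += dy;
        sdz += dy * z[i];
      }
    } else {
      for (uword i = 0; i < N; ++i) {
        const float dy = dout[i];
        da[i] = dy;
        sd += dy;
        sdz += dy * z[i];
      }
    }
    const float sdx = istd * (sdz - m * sd);   // sum(dy * xhat)
    dg(c, 0) = sdx;
    dbe(c, 0) = sd;
    const float gc = g(c, 0);
    const float s1 = gc * sd * invN, s2 = gc * sdx * invN;
    const float k1 = gc * istd;             // coefficient of dy
    // dz = k1*dy - istd*s1 - xhat*istd*s2,  xhat = (z - m)*istd
    const float k3 = istd * istd * s2;
    const float k2 = istd * s1 - k3 * m;
    for (uword i = 0; i < N; ++i) {
      da[i] = k1 * da[i] - k2 - k3 * z[i];
    }
  }
  return dA;
}

// sign of the activated value equals the sign of the pre-activation
static inline fmat leaky_bwd(const fmat& dY, const fmat& Yact, float slope) {
  fmat dA(arma::size(dY));
  const float* __restrict y = Yact.memptr();
  const float* __restrict s = dY.memptr();
  float* __restrict d = dA.memptr();
  for (uword i = 0; i < dA.n_elem; ++i) {
    d[i] = (y[i] < 0.0f) ? s[i] * slope : s[i];
  }
  return dA;
}

static inline void leaky_fwd(fmat& A, float slope) {
  float* __restrict a = A.memptr();
  const uword n = A.n_elem;
  for (uword i = 0; i < n; ++i) {
    const float v = a[i], vs = v * slope;
    a[i] = v > vs ? v : vs;
  }
}

struct ConvCache {
  fmat cols;        // im2col of the input
  fmat act;         // layer output (post-BN, post-activation if any)
  BnCache bn;
  int T_in, T_out, C_in;
};

struct BlockCache {
  ConvCache c1, c2, c3, cp;
  fmat in;          // block input (identity-shortcut backprop)
  fmat out;         // post-add activated output
  int T_in, T_out;
};

struct RnnCache {
  fmat S;           // layer input, time-major (B*T x d)
  BnCache bn;       // bn.Z holds the hidden-state sequence (B*T x units)
};

struct NetCache {
  std::vector<BlockCache> blocks;
  int B;
  int T_pool;
  std::vector<RnnCache> rnn;
  fmat h_last, d1;  // dense stage
  fmat probs;
};

class Engine {
public:
  EngineCfg cfg;
  ParamSet P;
  std::vector<int> base_block, base_rnn;   // parameter indices
  int base_dense;

  Engine(const List& cfg_r, const List& params_r)
      : cfg(parse_cfg(cfg_r)), P(params_from_r(params_r)) {
    int idx = 0;
    for (int b = 0; b < cfg.n_blocks; ++b) {
      base_block.push_back(idx);
      idx += 18 + (cfg.proj[b] ? 6 : 0);
    }
    for (size_t l = 0; l < cfg.rnn_units.size(); ++l) {
      base_rnn.push_back(idx);
      idx += 7;
    }
    base_dense = idx;
    if ((int)P.size() != idx + 4) {
      stop("parameter list length does not match architecture");
    }
  }

  // one conv + BN (+ optional fused LeakyReLU); X sample-major (B*T x C);
  // result lands in cc.act. The conv bias is mathematically inert under the
  // following batch norm (the mean subtraction cancels it exactly), so it is
  // neither added here nor given a gradient; it stays at its initial value.
  void conv_bn(const fmat& X, int B, int T, int k, int stride, int pbase,
               bool act, bool train, ConvCache& cc) {
    const int T_out = out_len(T, stride);
    cc.T_in = T; cc.T_out = T_out; cc.C_in = X.n_cols;
    cc.cols = im2col_batch(X, B, T, k, stride, T_out);
    fmat Z = cc.cols * P[pbase];          // (B*T_out x F)
    cc.act = bn_forward(std::move(Z), P[pbase + 2], P[pbase + 3],
                        P[pbase + 4], P[pbase + 5], cfg.bn_eps, cfg.bn_mom,
                        train, &cc.bn, act, cfg.leaky);
  }

  // backward through conv_bn; returns dX (unless !need_dx), accumulates grads
  fmat conv_bn_bwd(const fmat& dOut, int B, int k, int stride, int pbase,
                   bool act, const ConvCache& cc, ParamSet& G,
                   bool need_dx = true) {
    fmat dg, dbe;
    fmat dZ = bn_backward(dOut, act ? &cc.act : nullptr, cfg.leaky, cc.bn,
                          P[pbase + 2], dg, dbe);
    G[pbase + 2] += dg;
    G[pbase + 3] += dbe;
    G[pbase] += cc.cols.t() * dZ;
    if (!need_dx) return fmat();
    fmat dcols = dZ * P[pbase].t();
    return col2im_batch(dcols, B, cc.T_in, cc.C_in, k, stride, cc.T_out);
  }

  const fmat& block_forward(const fmat& X, int B, int T, int b, bool train,
                            BlockCache& bc) {
    bc.in = X;
    bc.T_in = T;
    const auto& k = cfg.kern[b];
    const auto& s = cfg.strd[b];
    const int pb = base_block[b];
    conv_bn(X, B, T, k[0], s[0], pb, true, train, bc.c1);
    conv_bn(bc.c1.act, B, bc.c1.T_out, k[1], s[1], pb + 6, true, train, bc.c2);
    conv_bn(bc.c2.act, B, bc.c2.T_out, k[2], s[2], pb + 12, false, train,
            bc.c3);
    const int T3 = bc.c3.T_out;
    const int s_total = s[0] * s[1] * s[2];
    if (cfg.proj[b]) {
      conv_bn(X, B, T, 1, s_total, pb + 18, false, train, bc.cp);
      bc.out = bc.c3.act + bc.cp.act;
    } else {
      // strided subsampling of the input (identity shortcut)
      bc.out = bc.c3.act;
      for (uword c = 0; c < X.n_cols; ++c) {
        const float* src = X.colptr(c);
        float* dst = bc.out.colptr(c);
        for (int bb = 0; bb < B; ++bb) {
          for (int t = 0; t < T3; ++t) {
            dst[(size_t)bb * T3 + t] += src[(size_t)bb * T + (size_t)t * s_total];
          }
        }
      }
    }
    leaky_fwd(bc.out, cfg.leaky);
    bc.T_out = T3;
    return bc.out;
  }

  fmat block_backward(const fmat& dOut, int B, int b, const BlockCache& bc,
                      ParamSet& G, bool need_dx = true) {
    const auto& k = cfg.kern[b];
    const auto& s = cfg.strd[b];
    const int pb = base_block[b];
    fmat dAdd = leaky_bwd(dOut, bc.out, cfg.leaky);
    const int s_total = s[0] * s[1] * s[2];
    fmat dX_short;
    if (cfg.proj[b]) {
      dX_short = conv_bn_bwd(dAdd, B, 1, s_total, pb + 18, false, bc.cp, G,
                             need_dx);
    } else if (need_dx) {
      dX_short.zeros(B * (size_t)bc.T_in, bc.in.n_cols);
      for (uword c = 0; c < dX_short.n_cols; ++c) {
        const float* src = dAdd.colptr(c);
        float* dst = dX_short.colptr(c);
        for (int bb = 0; bb < B; ++bb) {
          for (int t = 0; t < bc.T_out; ++t) {
            dst[(size_t)bb * bc.T_in + (size_t)t * s_total] =
              src[(size_t)bb * bc.T_out + t];
          }
        }
      }
    }
    fmat d2 = conv_bn_bwd(dAdd, B, k[2], s[2], pb + 12, false, bc.c3, G);
    fmat d1 = conv_bn_bwd(d2, B, k[1], s[1], pb + 6, true, bc.c2, G);
    if (!need_dx) {
      conv_bn_bwd(d1, B, k[0], s[0], pb, true, bc.c1, G, false);
      return fmat();
    }
    fmat dX = conv_bn_bwd(d1, B, k[0], s[0], pb, true, bc.c1, G);
    return dX + dX_short;
  }

  // non-overlapping mean pooling with width w over time, sample-major
  static fmat pool_fwd(const fmat& X, int B, int T, int w, int& T_out) {
    T_out = T / w;
    fmat Y(B * (size_t)T_out, X.n_cols);
    const float inv = 1.0f / (float)w;
    for (uword c = 0; c < X.n_cols; ++c) {
      const float* src = X.colptr(c);
      float* dst = Y.colptr(c);
      for (int b = 0; b < B; ++b) {
        for (int t = 0; t < T_out; ++t) {
          float acc = 0.0f;
          for (int j = 0; j < w; ++j) acc += src[(size_t)b * T + (size_t)t * w + j];
          dst[(size_t)b * T_out + t] = acc * inv;
        }
      }
    }
    return Y;
  }
  static fmat pool_bwd(const fmat& dY, int B, int T, int w, int T_out, int C) {
    fmat dX(B * (size_t)T, C, fill::zeros);
    const float inv = 1.0f / (float)w;
    for (int c = 0; c < C; ++c) {
      const float* src = dY.colptr(c);
      float* dst = dX.colptr(c);
      for (int b = 0; b < B; ++b) {
        for (int t = 0; t < T_out; ++t) {
          const float v = src[(size_t)b * T_out + t] * inv;
          for (int j = 0; j < w; ++j) dst[(size_t)b * T + (size_t)t * w + j] = v;
        }
      }
    }
    return dX;
  }

  // sample-major (B blocks of T rows) <-> time-major (T blocks of B rows)
  static fmat to_time_major(const fmat& X, int B, int T) {
    fmat S(X.n_rows, X.n_cols);
    for (uword c = 0; c < X.n_cols; ++c) {
      const float* src = X.colptr(c);
      float* dst = S.colptr(c);
      for (int b = 0; b < B; ++b) {
        for (int t = 0; t < T; ++t) dst[(size_t)t * B + b] = src[(size_t)b * T + t];
      }
    }
    return S;
  }
  static fmat to_sample_major(const fmat& S, int B, int T) {
    fmat X(S.n_rows, S.n_cols);
    for (uword c = 0; c < S.n_cols; ++c) {
      const float* src = S.colptr(c);
      float* dst = X.colptr(c);
      for (int b = 0; b < B; ++b) {
        for (int t = 0; t < T; ++t) dst[(size_t)b * T + t] = src[(size_t)t * B + b];
      }
    }
    return X;
  }

  // indRNN layer: h_t = relu(W x_t + u .* h_{t-1} + b), BN over the output
  // sequence; input S time-major (B*T x d); returns the BN'd sequence.
  // The hidden-state sequence H doubles as the BN cache's Z.
  fmat rnn_forward(const fmat& S, int B, int T, int l, bool train,
                   RnnCache& rc) {
    const int pb = base_rnn[l];
    rc.S = S;
    fmat Z = S * P[pb].t();               // W stored (units x d)
    Z.each_row() += P[pb + 2].col(0).t();
    const int units = Z.n_cols;
    fmat H(Z.n_rows, units);
    const float* u = P[pb + 1].memptr();
    // per unit: one contiguous sweep down the column (time-major blocks of B)
    for (int c = 0; c < units; ++c) {
      const float uc = u[c];
      const float* __restrict z = Z.colptr(c);
      float* __restrict h = H.colptr(c);
      for (int b = 0; b < B; ++b) h[b] = z[b] > 0.0f ? z[b] : 0.0f;
      for (int t = 1; t < T; ++t) {
        const size_t r0 = (size_t)t * B;
        for (int b = 0; b < B; ++b) {
          const float v = z[r0 + b] + uc * h[r0 - B + b];
          h[r0 + b] = v > 0.0f ? v : 0.0f;
        }
      }
    }
    return bn_forward(std::move(H), P[pb + 3], P[pb + 4], P[pb + 5],
                      P[pb + 6], cfg.bn_eps, cfg.bn_mom, train, &rc.bn,
                      false, 0.0f);
  }

  fmat rnn_backward(const fmat& dOut, int B, int T, int l, const RnnCache& rc,
                    ParamSet& G) {
    const int pb = base_rnn[l];
    fmat dg, dbe;
    fmat dH = bn_backward(dOut, nullptr, 0.0f, rc.bn, P[pb + 3], dg, dbe);
    G[pb + 3] += dg;
    G[pb + 4] += dbe;
    const fmat& H = rc.bn.Z;               // hidden states (pre-BN)
    const int units = H.n_cols;
    const float* u = P[pb + 1].memptr();
    fmat E(H.n_rows, units);               // dL/dz_t
    fvec du(units, fill::zeros);
    std::vector<float> du_lane(B);
    for (int c = 0; c < units; ++c) {
      const float uc = u[c];
      const float* __restrict h = H.colptr(c);
      const float* __restrict dh = dH.colptr(c);
      float* __restrict e = E.colptr(c);
      std::fill(du_lane.begin(), du_lane.end(), 0.0f);
      for (int t = T - 1; t >= 0; --t) {
        const size_t r0 = (size_t)t * B;
        if (t < T - 1) {
          for (int b = 0; b < B; ++b) {
            const float g_tb = dh[r0 + b] + uc * e[r0 + B + b];
            e[r0 + b] = (h[r0 + b] > 0.0f) ? g_tb : 0.0f;
          }
        } else {
          for (int b = 0; b < B; ++b) {
            e[r0 + b] = (h[r0 + b] > 0.0f) ? dh[r0 + b] : 0.0f;
          }
        }
        if (t > 0) {
          for (int b = 0; b < B; ++b) {
            du_lane[b] += e[r0 + b] * h[r0 - B + b];
          }
        }
      }
      double acc = 0.0;
      for (int b = 0; b < B; ++b) acc += du_lane[b];
      du(c) = (float)acc;
    }
    G[pb] += E.t() * rc.S;                 // dW (units x d)
    G[pb + 1] += du;
    G[pb + 2] += arma::sum(E, 0).t();
    return E * P[pb];                      // dS (B*T x d)
  }

  fmat forward(const fmat& Xb, int B, bool train, NetCache& nc) {
    nc.B = B;
    const int T0 = Xb.n_rows / B;
    int T = T0;
    nc.blocks.resize(cfg.n_blocks);
    const fmat* A = &Xb;
    for (int b = 0; b < cfg.n_blocks; ++b) {
      block_forward(*A, B, T, b, train, nc.blocks[b]);
      A = &nc.blocks[b].out;
      T = nc.blocks[b].T_out;
    }
    fmat pooled;
    if (cfg.pool_w > 1) {
      int Tp;
      pooled = pool_fwd(*A, B, T, cfg.pool_w, Tp);
      T = Tp;
      A = &pooled;
    }
    nc.T_pool = T;
    if (T < 1) stop("time axis collapsed to zero before the recurrent stage");
    fmat S = to_time_major(*A, B, T);
    nc.rnn.resize(cfg.rnn_units.size());
    for (size_t l = 0; l < cfg.rnn_units.size(); ++l) {
      S = rnn_forward(S, B, T, (int)l, train, nc.rnn[l]);
    }
    nc.h_last = S.rows((size_t)(T - 1) * B, (size_t)T * B - 1);
    fmat d1 = nc.h_last * P[base_dense];
    d1.each_row() += P[base_dense + 1].col(0).t();
    leaky_fwd(d1, cfg.leaky);
    nc.d1 = std::move(d1);
    fmat logits = nc.d1 * P[base_dense + 2];
    logits.each_row() += P[base_dense + 3].col(0).t();
    // row-wise stable softmax
    fvec mx = arma::max(logits, 1);
    logits.each_col() -= mx;
    fmat ex = arma::exp(logits);
    fvec den = arma::sum(ex, 1);
    ex.each_col() /= den;
    nc.probs = ex;
    return ex;
  }

  // backward from softmax + cross-entropy; y 0-based labels
  void backward(const NetCache& nc, const ivec& y, ParamSet& G) {
    const int B = nc.B;
    fmat dlogits = nc.probs;
    for (int i = 0; i < B; ++i) dlogits(i, y(i)) -= 1.0f;
    dlogits /= (float)B;
    G[base_dense + 2] += nc.d1.t() * dlogits;
    G[base_dense + 3] += arma::sum(dlogits, 0).t();
    fmat dd1 = leaky_bwd(dlogits * P[base_dense + 2].t(), nc.d1, cfg.leaky);
    G[base_dense] += nc.h_last.t() * dd1;
    G[base_dense + 1] += arma::sum(dd1, 0).t();
    fmat dh_last = dd1 * P[base_dense].t();
    const int T = nc.T_pool;
    fmat dS(B * (size_t)T, nc.h_last.n_cols, fill::zeros);
    dS.rows((size_t)(T - 1) * B, (size_t)T * B - 1) = dh_last;
    for (int l = (int)cfg.rnn_units.size() - 1; l >= 0; --l) {
      dS = rnn_backward(dS, B, T, l, nc.rnn[l], G);
    }
    fmat dA = to_sample_major(dS, B, T);
    int T_conv = nc.blocks[cfg.n_blocks - 1].T_out;
    if (cfg.pool_w > 1) {
      dA = pool_bwd(dA, B, T_conv, cfg.pool_w, T, dA.n_cols);
    }
    for (int b = cfg.n_blocks - 1; b >= 0; --b) {
      dA = block_backward(dA, B, b, nc.blocks[b], G, /*need_dx=*/b > 0);
    }
  }

  ParamSet zero_grads() const {
    ParamSet G;
    G.reserve(P.size());
    for (const auto& p : P) G.emplace_back(arma::size(p), fill::zeros);
    return G;
  }

  // indices of running-stat entries (not updated by SGD)
  std::vector<bool> state_mask() const {
    std::vector<bool> is_state(P.size(), false);
    for (int b = 0; b < cfg.n_blocks; ++b) {
      const int pb = base_block[b];
      const int n_conv = cfg.proj[b] ? 4 : 3;
      for (int cidx = 0; cidx < n_conv; ++cidx) {
        is_state[pb + cidx * 6 + 4] = true;
        is_state[pb + cidx * 6 + 5] = true;
      }
    }
    for (size_t l = 0; l < cfg.rnn_units.size(); ++l) {
      is_state[base_rnn[l] + 5] = true;
      is_state[base_rnn[l] + 6] = true;
    }
    return is_state;
  }
};

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_rcnn_forward(const List& params, const List& cfg,
                                     const Rcpp::NumericMatrix& X,
                                     bool training = false) {
  tune_allocator();
  Engine eng(cfg, params);
  const int n = X.ncol(), L = X.nrow();
  // stack columns as sample-major rows (B*L x 1)
  fmat Xb(n * (size_t)L, 1);
  for (int j = 0; j < n; ++j) {
    float* d = Xb.colptr(0) + (size_t)j * L;
    for (int i = 0; i < L; ++i) d[i] = (float)X(i, j);
  }
  NetCache nc;
  fmat probs = eng.forward(Xb, n, training, nc);
  Rcpp::NumericMatrix out(n, eng.cfg.n_class);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < eng.cfg.n_class; ++c) out(i, c) = probs(i, c);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_rcnn_train(const List& params, const List& cfg,
                    const Rcpp::NumericMatrix& X, const IntegerVector& y,
                    const Rcpp::IntegerMatrix& epoch_order, int batch_size,
                    double lr, double momentum) {
  tune_allocator();
  Engine eng(cfg, params);
  const int n = X.ncol(), L = X.nrow();
  const int epochs = epoch_order.ncol();
  if (epoch_order.nrow() != n) stop("epoch_order must have one row per sample");
  fmat Xf(L, n);
  for (int j = 0; j < n; ++j) {
    float* d = Xf.colptr(j);
    for (int i = 0; i < L; ++i) d[i] = (float)X(i, j);
  }
  std::vector<bool> is_state = eng.state_mask();
  ParamSet V = eng.zero_grads();
  NumericVector loss_hist(epochs);
  const float flr = (float)lr, fmom = (float)momentum;
  for (int e = 0; e < epochs; ++e) {
    double eloss = 0.0;
    int seen = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int B = std::min(batch_size, n - start);
      fmat Xb(B * (size_t)L, 1);
      ivec yb(B);
      for (int i = 0; i < B; ++i) {
        const int src = epoch_order(start + i, e) - 1;   // 1-based from R
        std::memcpy(Xb.colptr(0) + (size_t)i * L, Xf.colptr(src),
                    (size_t)L * sizeof(float));
        yb(i) = y[src];
      }
      NetCache nc;
      fmat probs = eng.forward(Xb, B, true, nc);
      double bl = 0.0;
      for (int i = 0; i < B; ++i) {
        bl -= std::log((double)probs(i, yb(i)) + 1e-12);
      }
      eloss += bl;
      seen += B;
      ParamSet G = eng.zero_grads();
      eng.backward(nc, yb, G);
      for (size_t p = 0; p < eng.P.size(); ++p) {
        if (is_state[p]) continue;
        V[p] = fmom * V[p] - flr * G[p];
        eng.P[p] += V[p];
      }
      // recurrent-weight constraint |u| <= u_clip after every update
      for (size_t l = 0; l < eng.cfg.rnn_units.size(); ++l) {
        fmat& u = eng.P[eng.base_rnn[l] + 1];
        u = arma::clamp(u, -eng.cfg.u_clip, eng.cfg.u_clip);
      }
      Rcpp::checkUserInterrupt();
    }
    loss_hist[e] = eloss / std::max(seen, 1);
  }
  // batch-norm statistics calibration: one forward-only sweep (original
  // sample order) replacing the momentum-smoothed running statistics with
  // the exact average of per-batch statistics under the final weights, so
  // inference-mode normalization is well-defined even after few epochs
  {
    for (size_t p = 0; p < eng.P.size(); ++p) {
      if (is_state[p]) eng.P[p].zeros();
    }
    int nb = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int B = std::min(batch_size, n - start);
      if (B < 2) break;                       // no batch statistics from one case
      fmat Xb(B * (size_t)L, 1);
      for (int i = 0; i < B; ++i) {
        std::memcpy(Xb.colptr(0) + (size_t)i * L, Xf.colptr(start + i),
                    (size_t)L * sizeof(float));
      }
      eng.cfg.bn_mom = (float)nb / (float)(nb + 1);   // cumulative average
      NetCache nc;
      eng.forward(Xb, B, true, nc);
      ++nb;
    }
    if (nb == 0) {                            // degenerate set: identity stats
      for (int b = 0; b < eng.cfg.n_blocks; ++b) {
        const int n_conv = eng.cfg.proj[b] ? 4 : 3;
        for (int cidx = 0; cidx < n_conv; ++cidx) {
          eng.P[eng.base_block[b] + cidx * 6 + 5].ones();
        }
      }
      for (size_t l = 0; l < eng.cfg.rnn_units.size(); ++l) {
        eng.P[eng.base_rnn[l] + 6].ones();
      }
    }
  }
  return List::create(Rcpp::Named("params") = params_to_r(eng.P, params),
                      Rcpp::Named("loss") = loss_hist);
}
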