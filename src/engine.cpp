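// Compact single-precision CNN engine: forward/backward for the layer set
// used by the three landmark networks (plain/grouped/depthwise convolution,
// batch normalisation, ReLU6, residual add, elementwise product, bilinear
// upsampling, fully connected, global depthwise convolution, DSNT) plus an
// Adam optimiser. Activations are stored NHWC-style: one column per sample,
// element index (i*W + j)*C + c. All dimensions are provided by the R-side
// network expansion and cross-checked here.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <memory>
#include <random>
#include <cmath>

using namespace arma;

static inline int conv_out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

struct Param {
  fmat w, g, m, v;
  void init_adam() { m.zeros(size(w)); v.zeros(size(w)); }
};

struct Network; // fwd

struct Node {
  std::string type;
  std::vector<int> in; // input node indices, 0-based
  int C = 0, H = 0, W = 0;
  fmat out, gout;
  virtual void forward(Network& net, bool train) = 0;
  virtual void backward(Network& net) = 0;
  virtual std::vector<Param*> params() { return {}; }
  virtual ~Node() {}
  int feat() const { return C * H * W; }
};

struct Network {
  std::vector<std::unique_ptr<Node>> nodes;
  std::mt19937 rng;
  long adam_t = 0;
  Node& n(int i) { return *nodes[i]; }
  std::vector<Param*> all_params() {
    std::vector<Param*> ps;
    for (auto& nd : nodes) for (Param* p : nd->params()) ps.push_back(p);
    return ps;
  }
};

// ---------------------------------------------------------------------------

struct InputNode : Node {
  InputNode() { type = "input"; }
  void forward(Network&, bool) override {}
  void backward(Network&) override {}
};

// Convolution. Three execution paths: groups == 1 (single im2col + GEMM),
// 1 < groups < Cin (per-group im2col), groups == Cin == Cout (direct
// depthwise). Weight layout: (Cout, Kg) with Kg = (Cin/groups)*k*k and the
// im2col row index (ky*k + kx)*Cg + c.
struct ConvNode : Node {
  int cin, cout, k, stride, pad, groups;
  bool use_bias;
  Param wt, bias;
  fmat cols;            // saved for backward (per group loop reuses layout)
  std::vector<fmat> gcols; // cols per group when groups > 1
  int inH = 0, inW = 0;

  void forward(Network& net, bool train) override {
    const fmat& X = net.n(in[0]).out;
    const int N = X.n_cols;
    inH = net.n(in[0]).H; inW = net.n(in[0]).W;
    const int OH = conv_out_dim(inH, k, stride, pad);
    const int OW = conv_out_dim(inW, k, stride, pad);
    if (OH != H || OW != W) Rcpp::stop("conv: dim mismatch");
    out.set_size((size_t)cout * OH * OW, N);
    if (groups == cin && cout == cin) { fwd_depthwise(X, N, OH, OW); return; }
    const int cg = cin / groups, og = cout / groups;
    const int Kg = cg * k * k;
    if (groups > 1 && (int)gcols.size() != groups) gcols.resize(groups);
    for (int g = 0; g < groups; ++g) {
      fmat& cl = (groups == 1) ? cols : gcols[g];
      im2col(X, cl, N, OH, OW, g * cg, cg);
      fmat og_out = wt.w.rows(g * og, (g + 1) * og - 1) * cl; // (og, N*OH*OW)
      // scatter into NHWC output
      for (int n0 = 0; n0 < N; ++n0) {
        float* dst = out.colptr(n0);
        const float* src = og_out.colptr((size_t)n0 * OH * OW);
        for (int p = 0; p < OH * OW; ++p)
          std::memcpy(dst + (size_t)p * cout + g * og, src + (size_t)p * og,
                      og * sizeof(float));
      }
    }
    if (use_bias)
      for (size_t n0 = 0; n0 < out.n_cols; ++n0) {
        float* dst = out.colptr(n0);
        for (int p = 0; p < OH * OW; ++p)
          for (int c = 0; c < cout; ++c) dst[(size_t)p * cout + c] += bias.w(c, 0);
      }
    if (!train) { cols.reset(); for (auto& m0 : gcols) m0.reset(); }
  }

  void im2col(const fmat& X, fmat& cl, int N, int OH, int OW, int c0, int cg) {
    const int Kg = cg * k * k;
    cl.set_size(Kg, (size_t)N * OH * OW);
    const bool full = (cg == cin); // ungrouped: kx-run is contiguous in NHWC
    for (int n0 = 0; n0 < N; ++n0) {
      const float* src = X.colptr(n0);
      for (int oy = 0; oy < OH; ++oy)
        for (int ox = 0; ox < OW; ++ox) {
          float* dst = cl.colptr((size_t)n0 * OH * OW + oy * OW + ox);
          const int ix0 = ox * stride - pad;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oy * stride - pad + ky;
            float* drow = dst + (size_t)ky * k * cg;
            if (iy < 0 || iy >= inH) {
              std::memset(drow, 0, (size_t)k * cg * sizeof(float));
              continue;
            }
            if (full) {
              // one contiguous copy over the valid kx range
              const int kx_lo = std::max(0, -ix0);
              const int kx_hi = std::min(k, inW - ix0);
              if (kx_lo > 0) std::memset(drow, 0, (size_t)kx_lo * cg * sizeof(float));
              if (kx_hi < k)
                std::memset(drow + (size_t)kx_hi * cg, 0,
                            (size_t)(k - kx_hi) * cg * sizeof(float));
              if (kx_hi > kx_lo)
                std::memcpy(drow + (size_t)kx_lo * cg,
                            src + (size_t)(iy * inW + ix0 + kx_lo) * cin,
                            (size_t)(kx_hi - kx_lo) * cg * sizeof(float));
            } else {
              for (int kx = 0; kx < k; ++kx) {
                const int ix = ix0 + kx;
                float* d = drow + (size_t)kx * cg;
                if (ix < 0 || ix >= inW)
                  std::memset(d, 0, cg * sizeof(float));
                else
                  std::memcpy(d, src + (size_t)(iy * inW + ix) * cin + c0,
                              cg * sizeof(float));
              }
            }
          }
        }
    }
  }

  void fwd_depthwise(const fmat& X, int N, int OH, int OW) {
    out.zeros();
    for (int n0 = 0; n0 < N; ++n0) {
      const float* src = X.colptr(n0);
      float* dst = out.colptr(n0);
      for (int oy = 0; oy < OH; ++oy)
        for (int ox = 0; ox < OW; ++ox) {
          float* d = dst + (size_t)(oy * OW + ox) * cout;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= inH) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = ox * stride - pad + kx;
              if (ix < 0 || ix >= inW) continue;
              const float* s = src + (size_t)(iy * inW + ix) * cin;
              // weight element (c, ky*k+kx); (cout, k*k) column-major
              const float* wcol = wt.w.colptr(ky * k + kx);
              for (int c = 0; c < cout; ++c) d[c] += wcol[c] * s[c];
            }
          }
        }
      if (use_bias)
        for (int p = 0; p < OH * OW; ++p)
          for (int c = 0; c < cout; ++c) dst[(size_t)p * cout + c] += bias.w(c, 0);
    }
  }

  void backward(Network& net) override {
    const fmat& X = net.n(in[0]).out;
    fmat& gin = net.n(in[0]).gout;
    const int N = X.n_cols;
    const int OH = H, OW = W;
    wt.g.zeros(size(wt.w));
    if (use_bias) bias.g.zeros(size(bias.w));
    if (use_bias) {
      for (int n0 = 0; n0 < N; ++n0) {
        const float* g0 = gout.colptr(n0);
        for (int p = 0; p < OH * OW; ++p)
          for (int c = 0; c < cout; ++c) bias.g(c, 0) += g0[(size_t)p * cout + c];
      }
    }
    if (groups == cin && cout == cin) { bwd_depthwise(X, gin, N, OH, OW); return; }
    const bool need_dx = in[0] != 0; // no input gradient for the image itself
    const int cg = cin / groups, og = cout / groups;
    for (int g = 0; g < groups; ++g) {
      fmat& cl = (groups == 1) ? cols : gcols[g];
      // gather gout for this group into (og, N*OH*OW)
      fmat gg(og, (size_t)N * OH * OW);
      for (int n0 = 0; n0 < N; ++n0) {
        const float* src = gout.colptr(n0);
        for (int p = 0; p < OH * OW; ++p)
          std::memcpy(gg.colptr((size_t)n0 * OH * OW + p),
                      src + (size_t)p * cout + g * og, og * sizeof(float));
      }
      wt.g.rows(g * og, (g + 1) * og - 1) = gg * cl.t();
      if (need_dx) {
        fmat dcols = wt.w.rows(g * og, (g + 1) * og - 1).t() * gg;
        col2im_add(dcols, gin, N, OH, OW, g * cg, cg);
      }
    }
  }

  void col2im_add(const fmat& dcols, fmat& gin, int N, int OH, int OW,
                  int c0, int cg) {
    for (int n0 = 0; n0 < N; ++n0) {
      float* dst = gin.colptr(n0);
      for (int oy = 0; oy < OH; ++oy)
        for (int ox = 0; ox < OW; ++ox) {
          const float* src = dcols.colptr((size_t)n0 * OH * OW + oy * OW + ox);
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= inH) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = ox * stride - pad + kx;
              if (ix < 0 || ix >= inW) continue;
              float* d = dst + (size_t)(iy * inW + ix) * cin + c0;
              const float* s = src + (size_t)(ky * k + kx) * cg;
              for (int c = 0; c < cg; ++c) d[c] += s[c];
            }
          }
        }
    }
  }

  void bwd_depthwise(const fmat& X, fmat& gin, int N, int OH, int OW) {
    for (int n0 = 0; n0 < N; ++n0) {
      const float* src = X.colptr(n0);
      const float* g0 = gout.colptr(n0);
      float* gi = gin.colptr(n0);
      for (int oy = 0; oy < OH; ++oy)
        for (int ox = 0; ox < OW; ++ox) {
          const float* gp = g0 + (size_t)(oy * OW + ox) * cout;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= inH) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = ox * stride - pad + kx;
              if (ix < 0 || ix >= inW) continue;
              const float* s = src + (size_t)(iy * inW + ix) * cin;
              float* giw = gi + (size_t)(iy * inW + ix) * cin;
              float* wg = wt.g.colptr(ky * k + kx);
              const float* wv = wt.w.colptr(ky * k + kx);
              for (int c = 0; c < cout; ++c) {
                wg[c] += gp[c] * s[c];
                giw[c] += gp[c] * wv[c];
              }
            }
          }
        }
    }
  }

  std::vector<Param*> params() override {
    std::vector<Param*> p{&wt};
    if (use_bias) p.push_back(&bias);
    return p;
  }
};

// Batch normalisation over (N, H, W) per channel; NHWC strided access.
struct BNNode : Node {
  Param gamma, beta;
  fvec run_mean, run_var, mean, invstd;
  fmat xhat;
  float momentum = 0.1f, eps = 1e-5f;

  void forward(Network& net, bool train) override {
    const fmat& X = net.n(in[0]).out;
    const int N = X.n_cols, HW = H * W;
    const double cnt = (double)N * HW;
    out.set_size(size(X));
    const size_t rows = (size_t)HW * N; // view data as C x (HW*N)
    const float* xall = X.memptr();
    float* oall = out.memptr();
    if (train) {
      fvec acc(C, fill::zeros), acc2(C, fill::zeros);
      float* a1 = acc.memptr(); float* a2 = acc2.memptr();
      for (size_t p = 0; p < rows; ++p) {
        const float* xp = xall + p * C;
        for (int c = 0; c < C; ++c) { a1[c] += xp[c]; a2[c] += xp[c] * xp[c]; }
      }
      mean = acc / (float)cnt;
      fvec var = acc2 / (float)cnt - mean % mean;
      var.transform([](float v) { return v < 0 ? 0.0f : v; });
      invstd = 1.0f / sqrt(var + eps);
      run_mean = (1 - momentum) * run_mean + momentum * mean;
      run_var = (1 - momentum) * run_var + momentum * var;
      xhat.set_size(size(X));
      float* xh = xhat.memptr();
      fvec sc = gamma.w.col(0) % invstd;
      fvec sh = beta.w.col(0) - gamma.w.col(0) % mean % invstd;
      fvec hs = invstd, hh = -mean % invstd;
      const float *scp = sc.memptr(), *shp = sh.memptr(),
                  *hsp = hs.memptr(), *hhp = hh.memptr();
      for (size_t p = 0; p < rows; ++p) {
        const float* xp = xall + p * C;
        float* op = oall + p * C;
        float* hp = xh + p * C;
        for (int c = 0; c < C; ++c) {
          hp[c] = xp[c] * hsp[c] + hhp[c];
          op[c] = xp[c] * scp[c] + shp[c];
        }
      }
    } else {
      fvec is = 1.0f / sqrt(run_var + eps);
      fvec sc = gamma.w.col(0) % is;
      fvec sh = beta.w.col(0) - gamma.w.col(0) % run_mean % is;
      const float *scp = sc.memptr(), *shp = sh.memptr();
      for (size_t p = 0; p < rows; ++p) {
        const float* xp = xall + p * C;
        float* op = oall + p * C;
        for (int c = 0; c < C; ++c) op[c] = xp[c] * scp[c] + shp[c];
      }
    }
  }

  void backward(Network& net) override {
    fmat& gin = net.n(in[0]).gout;
    const int N = gout.n_cols, HW = H * W;
    const float cnt = (float)N * HW;
    const size_t rows = (size_t)HW * N;
    fvec sg(C, fill::zeros), sgx(C, fill::zeros);
    const float* gall = gout.memptr();
    const float* xh = xhat.memptr();
    float* s1 = sg.memptr(); float* s2 = sgx.memptr();
    for (size_t p = 0; p < rows; ++p) {
      const float* gp = gall + p * C;
      const float* hp = xh + p * C;
      for (int c = 0; c < C; ++c) { s1[c] += gp[c]; s2[c] += gp[c] * hp[c]; }
    }
    gamma.g = sgx; beta.g = sg;
    fvec k1 = gamma.w.col(0) % invstd;            // dx = k1*(g - (sg + xh*sgx)/cnt)
    fvec k2 = (sg / cnt), k3 = (sgx / cnt);
    const float *k1p = k1.memptr(), *k2p = k2.memptr(), *k3p = k3.memptr();
    float* giall = gin.memptr();
    for (size_t p = 0; p < rows; ++p) {
      const float* gp = gall + p * C;
      const float* hp = xh + p * C;
      float* gi = giall + p * C;
      for (int c = 0; c < C; ++c)
        gi[c] += k1p[c] * (gp[c] - k2p[c] - hp[c] * k3p[c]);
    }
  }
  std::vector<Param*> params() override { return {&gamma, &beta}; }
};

struct ReLU6Node : Node {
  void forward(Network& net, bool) override {
    const fmat& X = net.n(in[0]).out;
    out.set_size(size(X));
    const float* x = X.memptr();
    float* o = out.memptr();
    for (size_t i = 0; i < X.n_elem; ++i)
      o[i] = x[i] < 0.0f ? 0.0f : (x[i] > 6.0f ? 6.0f : x[i]);
  }
  void backward(Network& net) override {
    const fmat& X = net.n(in[0]).out;
    fmat& gin = net.n(in[0]).gout;
    const float* x = X.memptr();
    const float* g = gout.memptr();
    float* gi = gin.memptr();
    for (size_t i = 0; i < X.n_elem; ++i)
      if (x[i] > 0.0f && x[i] < 6.0f) gi[i] += g[i];
  }
};

struct AddNode : Node {
  void forward(Network& net, bool) override {
    out = net.n(in[0]).out + net.n(in[1]).out;
  }
  void backward(Network& net) override {
    net.n(in[0]).gout += gout;
    net.n(in[1]).gout += gout;
  }
};

struct MulNode : Node {
  void forward(Network& net, bool) override {
    out = net.n(in[0]).out % net.n(in[1]).out;
  }
  void backward(Network& net) override {
    net.n(in[0]).gout += gout % net.n(in[1]).out;
    net.n(in[1]).gout += gout % net.n(in[0]).out;
  }
};

// Bilinear upsampling to (H, W) with half-pixel-centre sampling
// (align_corners = FALSE convention).
struct UpsampleNode : Node {
  std::vector<int> y0s, x0s;
  std::vector<float> wys, wxs;
  int inH = 0, inW = 0;
  void prep(int ih, int iw) {
    if (ih == inH && iw == inW && !y0s.empty()) return;
    inH = ih; inW = iw;
    y0s.assign(H, 0); x0s.assign(W, 0); wys.assign(H, 0); wxs.assign(W, 0);
    const double sy = (double)ih / H, sx = (double)iw / W;
    for (int oy = 0; oy < H; ++oy) {
      double fy = (oy + 0.5) * sy - 0.5;
      if (fy < 0) fy = 0; if (fy > ih - 1) fy = ih - 1;
      y0s[oy] = std::min((int)std::floor(fy), ih - 2 < 0 ? 0 : ih - 2);
      wys[oy] = (float)(fy - y0s[oy]);
      if (ih == 1) { y0s[oy] = 0; wys[oy] = 0; }
    }
    for (int ox = 0; ox < W; ++ox) {
      double fx = (ox + 0.5) * sx - 0.5;
      if (fx < 0) fx = 0; if (fx > iw - 1) fx = iw - 1;
      x0s[ox] = std::min((int)std::floor(fx), iw - 2 < 0 ? 0 : iw - 2);
      wxs[ox] = (float)(fx - x0s[ox]);
      if (iw == 1) { x0s[ox] = 0; wxs[ox] = 0; }
    }
  }
  void forward(Network& net, bool) override {
    const Node& src = net.n(in[0]);
    prep(src.H, src.W);
    const fmat& X = src.out;
    const int N = X.n_cols;
    out.set_size((size_t)C * H * W, N);
    for (int n0 = 0; n0 < N; ++n0) {
      const float* x = X.colptr(n0);
      float* o = out.colptr(n0);
      for (int oy = 0; oy < H; ++oy) {
        const int y0 = y0s[oy], y1 = std::min(y0 + 1, inH - 1);
        const float wy = wys[oy];
        for (int ox = 0; ox < W; ++ox) {
          const int x0 = x0s[ox], x1 = std::min(x0 + 1, inW - 1);
          const float wx = wxs[ox];
          const float* p00 = x + (size_t)(y0 * inW + x0) * C;
          const float* p01 = x + (size_t)(y0 * inW + x1) * C;
          const float* p10 = x + (size_t)(y1 * inW + x0) * C;
          const float* p11 = x + (size_t)(y1 * inW + x1) * C;
          float* d = o + (size_t)(oy * W + ox) * C;
          const float w00 = (1 - wy) * (1 - wx), w01 = (1 - wy) * wx,
                      w10 = wy * (1 - wx), w11 = wy * wx;
          for (int c = 0; c < C; ++c)
            d[c] = w00 * p00[c] + w01 * p01[c] + w10 * p10[c] + w11 * p11[c];
        }
      }
    }
  }
  void backward(Network& net) override {
    fmat& gin = net.n(in[0]).gout;
    const int N = gout.n_cols;
    for (int n0 = 0; n0 < N; ++n0) {
      float* gi = gin.colptr(n0);
      const float* g0 = gout.colptr(n0);
      for (int oy = 0; oy < H; ++oy) {
        const int y0 = y0s[oy], y1 = std::min(y0 + 1, inH - 1);
        const float wy = wys[oy];
        for (int ox = 0; ox < W; ++ox) {
          const int x0 = x0s[ox], x1 = std::min(x0 + 1, inW - 1);
          const float wx = wxs[ox];
          const float* g = g0 + (size_t)(oy * W + ox) * C;
          float* p00 = gi + (size_t)(y0 * inW + x0) * C;
          float* p01 = gi + (size_t)(y0 * inW + x1) * C;
          float* p10 = gi + (size_t)(y1 * inW + x0) * C;
          float* p11 = gi + (size_t)(y1 * inW + x1) * C;
          const float w00 = (1 - wy) * (1 - wx), w01 = (1 - wy) * wx,
                      w10 = wy * (1 - wx), w11 = wy * wx;
          for (int c = 0; c < C; ++c) {
            p00[c] += w00 * g[c]; p01[c] += w01 * g[c];
            p10[c] += w10 * g[c]; p11[c] += w11 * g[c];
          }
        }
      }
    }
  }
};

// Reinterpret (C,H,W) as (C*H*W,1,1); data layout unchanged.
struct FlattenNode : Node {
  void forward(Network& net, bool) override { out = net.n(in[0]).out; }
  void backward(Network& net) override { net.n(in[0]).gout += gout; }
};

// Channel concatenation of 1x1 features (used by the FC head).
struct ConcatNode : Node {
  void forward(Network& net, bool) override {
    out = join_cols(net.n(in[0]).out, net.n(in[1]).out);
  }
  void backward(Network& net) override {
    const int f0 = net.n(in[0]).feat();
    net.n(in[0]).gout += gout.rows(0, f0 - 1);
    net.n(in[1]).gout += gout.rows(f0, gout.n_rows - 1);
  }
};

struct FCNode : Node {
  int nin, nout;
  Param wt, bias;
  void forward(Network& net, bool) override {
    const fmat& X = net.n(in[0]).out;
    out = wt.w * X;
    out.each_col() += bias.w.col(0);
  }
  void backward(Network& net) override {
    const fmat& X = net.n(in[0]).out;
    wt.g = gout * X.t();
    bias.g = sum(gout, 1);
    net.n(in[0]).gout += wt.w.t() * gout;
  }
  std::vector<Param*> params() override { return {&wt, &bias}; }
};

// Global depthwise convolution: per-channel spatial inner product with a
// learnable kernel the size of the feature map. Weight stored in activation
// layout ((H*W)*C vector).
struct GDConvNode : Node {
  int inC, inH, inW;
  Param wt; // ((H*W)*C) x 1
  void forward(Network& net, bool) override {
    const fmat& X = net.n(in[0]).out;
    const int N = X.n_cols, HW = inH * inW;
    out.zeros(inC, N);
    for (int n0 = 0; n0 < N; ++n0) {
      const float* x = X.colptr(n0);
      const float* w0 = wt.w.colptr(0);
      float* o = out.colptr(n0);
      for (int p = 0; p < HW; ++p) {
        const size_t off = (size_t)p * inC;
        for (int c = 0; c < inC; ++c) o[c] += w0[off + c] * x[off + c];
      }
    }
  }
  void backward(Network& net) override {
    const fmat& X = net.n(in[0]).out;
    fmat& gin = net.n(in[0]).gout;
    const int N = X.n_cols, HW = inH * inW;
    wt.g.zeros(size(wt.w));
    for (int n0 = 0; n0 < N; ++n0) {
      const float* x = X.colptr(n0);
      const float* g0 = gout.colptr(n0);
      const float* w0 = wt.w.colptr(0);
      float* wg = wt.g.colptr(0);
      float* gi = gin.colptr(n0);
      for (int p = 0; p < HW; ++p) {
        const size_t off = (size_t)p * inC;
        for (int c = 0; c < inC; ++c) {
          wg[off + c] += g0[c] * x[off + c];
          gi[off + c] += g0[c] * w0[off + c];
        }
      }
    }
  }
  std::vector<Param*> params() override { return {&wt}; }
};

// DSNT: per-channel spatial softmax followed by expectation over signed
// coordinate grids X_{i,j} = (2j-(n+1))/n, Y_{i,j} = (2i-(m+1))/m (1-based).
// Output: interleaved (x1, y1, ..., xP, yP), one column per sample.
// The normalised heatmaps are kept for the distribution regulariser, whose
// gradient is injected via reg_grad before the softmax backward pass.
struct DSNTNode : Node {
  int P, m, n;
  fvec gx, gy;      // length m*n, spatial-position order (i*n + j)
  fmat Zn;          // normalised heatmaps, ((m*n)*P) x N, activation layout
  fmat reg_grad;    // dLoss/dZn from the regulariser (may be empty)
  void build_grids() {
    gx.set_size(m * n); gy.set_size(m * n);
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < n; ++j) {
        gx(i * n + j) = (2.0f * (j + 1) - (n + 1)) / n;
        gy(i * n + j) = (2.0f * (i + 1) - (m + 1)) / m;
      }
  }
  void forward(Network& net, bool) override {
    const fmat& X = net.n(in[0]).out; // ((m*n)*P) x N
    const int N = X.n_cols, S = m * n;
    Zn.set_size(size(X));
    out.zeros(2 * P, N);
    std::vector<float> mx(P), sm(P);
    for (int n0 = 0; n0 < N; ++n0) {
      const float* x = X.colptr(n0);
      float* z = Zn.colptr(n0);
      float* o = out.colptr(n0);
      std::fill(mx.begin(), mx.end(), -std::numeric_limits<float>::infinity());
      for (int p = 0; p < S; ++p) {
        const float* xp = x + (size_t)p * P;
        for (int c = 0; c < P; ++c) if (xp[c] > mx[c]) mx[c] = xp[c];
      }
      std::fill(sm.begin(), sm.end(), 0.0f);
      for (int p = 0; p < S; ++p) {
        const float* xp = x + (size_t)p * P;
        float* zp = z + (size_t)p * P;
        for (int c = 0; c < P; ++c) { zp[c] = std::exp(xp[c] - mx[c]); sm[c] += zp[c]; }
      }
      for (int p = 0; p < S; ++p) {
        float* zp = z + (size_t)p * P;
        for (int c = 0; c < P; ++c) {
          zp[c] /= sm[c];
          o[2 * c] += zp[c] * gx(p);
          o[2 * c + 1] += zp[c] * gy(p);
        }
      }
    }
  }
  void backward(Network& net) override {
    fmat& gin = net.n(in[0]).gout;
    const int N = gout.n_cols, S = m * n;
    const bool has_reg = reg_grad.n_elem > 0;
    std::vector<float> dot(P);
    for (int n0 = 0; n0 < N; ++n0) {
      const float* g0 = gout.colptr(n0);
      const float* z = Zn.colptr(n0);
      const float* rg = has_reg ? reg_grad.colptr(n0) : nullptr;
      float* gi = gin.colptr(n0);
      // t = dL/dZn ; dlogits = Zn .* (t - sum(t .* Zn))
      std::fill(dot.begin(), dot.end(), 0.0f);
      for (int p = 0; p < S; ++p) {
        const float* zp = z + (size_t)p * P;
        for (int c = 0; c < P; ++c) {
          float t = g0[2 * c] * gx(p) + g0[2 * c + 1] * gy(p);
          if (has_reg) t += rg[(size_t)p * P + c];
          dot[c] += t * zp[c];
        }
      }
      for (int p = 0; p < S; ++p) {
        const float* zp = z + (size_t)p * P;
        float* gp = gi + (size_t)p * P;
        for (int c = 0; c < P; ++c) {
          float t = g0[2 * c] * gx(p) + g0[2 * c + 1] * gy(p);
          if (has_reg) t += rg[(size_t)p * P + c];
          gp[c] += zp[c] * (t - dot[c]);
        }
      }
    }
    reg_grad.reset();
  }
};

// ---------------------------------------------------------------------------
// Build

static std::unique_ptr<Node> make_node(const Rcpp::List& nd) {
  const std::string type = Rcpp::as<std::string>(nd["type"]);
  std::unique_ptr<Node> node;
  if (type == "input") node.reset(new InputNode());
  else if (type == "conv") {
    auto* c = new ConvNode();
    c->cin = nd["cin"]; c->cout = nd["cout"]; c->k = nd["k"];
    c->stride = nd["stride"]; c->pad = nd["pad"]; c->groups = nd["groups"];
    c->use_bias = nd["bias"];
    node.reset(c);
  } else if (type == "bn") node.reset(new BNNode());
  else if (type == "relu6") node.reset(new ReLU6Node());
  else if (type == "add") node.reset(new AddNode());
  else if (type == "mul") node.reset(new MulNode());
  else if (type == "upsample") node.reset(new UpsampleNode());
  else if (type == "flatten") node.reset(new FlattenNode());
  else if (type == "concat") node.reset(new ConcatNode());
  else if (type == "fc") {
    auto* f = new FCNode();
    f->nin = nd["nin"]; f->nout = nd["nout"];
    node.reset(f);
  } else if (type == "gdconv") node.reset(new GDConvNode());
  else if (type == "dsnt") {
    auto* d = new DSNTNode();
    d->P = nd["npoints"]; d->m = nd["m"]; d->n = nd["n"];
    d->build_grids();
    node.reset(d);
  } else Rcpp::stop("unknown node type: " + type);
  node->type = type;
  node->C = nd["C"]; node->H = nd["H"]; node->W = nd["W"];
  if (nd.containsElementNamed("in")) {
    Rcpp::IntegerVector iv = nd["in"];
    for (int i : iv) node->in.push_back(i - 1);
  }
  return node;
}

static void init_params(Network& net) {
  std::normal_distribution<float> nr(0.0f, 1.0f);
  for (auto& nd : net.nodes) {
    if (nd->type == "conv") {
      auto* c = static_cast<ConvNode*>(nd.get());
      const int Kg = (c->cin / c->groups) * c->k * c->k;
      const float std0 = std::sqrt(2.0f / Kg);
      if (c->groups == c->cin && c->cout == c->cin)
        c->wt.w.set_size(c->cout, c->k * c->k);
      else
        c->wt.w.set_size(c->cout, Kg);
      for (auto& v : c->wt.w) v = std0 * nr(net.rng);
      if (c->use_bias) c->bias.w.zeros(c->cout, 1);
      c->wt.init_adam(); if (c->use_bias) c->bias.init_adam();
    } else if (nd->type == "bn") {
      auto* b = static_cast<BNNode*>(nd.get());
      b->gamma.w.ones(b->C, 1); b->beta.w.zeros(b->C, 1);
      b->run_mean.zeros(b->C); b->run_var.ones(b->C);
      b->gamma.init_adam(); b->beta.init_adam();
    } else if (nd->type == "fc") {
      auto* f = static_cast<FCNode*>(nd.get());
      const float std0 = std::sqrt(2.0f / f->nin);
      f->wt.w.set_size(f->nout, f->nin);
      for (auto& v : f->wt.w) v = std0 * nr(net.rng);
      f->bias.w.zeros(f->nout, 1);
      f->wt.init_adam(); f->bias.init_adam();
    } else if (nd->type == "gdconv") {
      auto* g = static_cast<GDConvNode*>(nd.get());
      g->wt.w.set_size((size_t)g->inH * g->inW * g->inC, 1);
      const float v0 = 1.0f / (g->inH * g->inW); // start at global average pooling
      g->wt.w.fill(v0);
      g->wt.init_adam();
    }
  }
}

// [[Rcpp::export]]
SEXP nn_build(Rcpp::List spec, int seed) {
  auto* net = new Network();
  for (int i = 0; i < spec.size(); ++i) {
    Rcpp::List nd = spec[i];
    auto node = make_node(nd);
    if (node->type == "gdconv") {
      auto* g = static_cast<GDConvNode*>(node.get());
      const Rcpp::List& src = spec[Rcpp::as<int>(nd["in"]) - 1];
      g->inC = src["C"]; g->inH = src["H"]; g->inW = src["W"];
    }
    net->nodes.push_back(std::move(node));
  }
  net->rng.seed((unsigned)seed);
  init_params(*net);
  Rcpp::XPtr<Network> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
double nn_num_params(SEXP netp) {
  Rcpp::XPtr<Network> net(netp);
  double tot = 0;
  for (Param* p : net->all_params()) tot += p->w.n_elem;
  return tot;
}

// [[Rcpp::export]]
Rcpp::NumericVector nn_get_params(SEXP netp) {
  Rcpp::XPtr<Network> net(netp);
  std::vector<double> v;
  for (Param* p : net->all_params())
    for (float x : p->w) v.push_back(x);
  return Rcpp::wrap(v);
}

// [[Rcpp::export]]
void nn_set_params(SEXP netp, Rcpp::NumericVector v) {
  Rcpp::XPtr<Network> net(netp);
  size_t total = 0;
  for (Param* p : net->all_params()) total += p->w.n_elem;
  if (total != (size_t)v.size())
    Rcpp::stop("parameter vector length mismatch");
  size_t i = 0;
  for (Param* p : net->all_params())
    for (float& x : p->w) x = (float)v[i++];
}

// [[Rcpp::export]]
Rcpp::NumericVector nn_get_buffers(SEXP netp) {
  Rcpp::XPtr<Network> net(netp);
  std::vector<double> v;
  for (auto& nd : net->nodes)
    if (nd->type == "bn") {
      auto* b = static_cast<BNNode*>(nd.get());
      for (float x : b->run_mean) v.push_back(x);
      for (float x : b->run_var) v.push_back(x);
    }
  return Rcpp::wrap(v);
}

// [[Rcpp::export]]
void nn_set_buffers(SEXP netp, Rcpp::NumericVector v) {
  Rcpp::XPtr<Network> net(netp);
  size_t i = 0;
  for (auto& nd : net->nodes)
    if (nd->type == "bn") {
      auto* b = static_cast<BNNode*>(nd.get());
      for (float& x : b->run_mean) x = (float)v[i++];
      for (float& x : b->run_var) x = (float)v[i++];
    }
  if (i != (size_t)v.size()) Rcpp::stop("buffer vector length mismatch");
}

static void forward_all(Network& net, const fmat& X, bool train) {
  net.nodes[0]->out = X;
  for (size_t i = 1; i < net.nodes.size(); ++i)
    net.nodes[i]->forward(net, train);
}

// [[Rcpp::export]]
Rcpp::List nn_forward(SEXP netp, Rcpp::NumericMatrix X, bool train = false) {
  Rcpp::XPtr<Network> net(netp);
  fmat Xf(X.nrow(), X.ncol());
  for (int j = 0; j < X.ncol(); ++j)
    for (int i = 0; i < X.nrow(); ++i) Xf(i, j) = (float)X(i, j);
  forward_all(*net, Xf, train);
  Rcpp::List shapes(net->nodes.size());
  for (size_t i = 0; i < net->nodes.size(); ++i) {
    Node& nd = *net->nodes[i];
    shapes[i] = Rcpp::List::create(
        Rcpp::Named("type") = nd.type, Rcpp::Named("C") = nd.C,
        Rcpp::Named("H") = nd.H, Rcpp::Named("W") = nd.W,
        Rcpp::Named("n_out") = (double)nd.out.n_rows);
  }
  const fmat& o = net->nodes.back()->out;
  Rcpp::NumericMatrix out(o.n_rows, o.n_cols);
  for (size_t j = 0; j < o.n_cols; ++j)
    for (size_t i = 0; i < o.n_rows; ++i) out(i, j) = o(i, j);
  return Rcpp::List::create(Rcpp::Named("output") = out,
                            Rcpp::Named("shapes") = shapes);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix nn_heatmaps(SEXP netp) {
  // normalised DSNT heatmaps from the last forward pass
  Rcpp::XPtr<Network> net(netp);
  for (auto& nd : net->nodes)
    if (nd->type == "dsnt") {
      auto* d = static_cast<DSNTNode*>(nd.get());
      Rcpp::NumericMatrix out(d->Zn.n_rows, d->Zn.n_cols);
      for (size_t j = 0; j < d->Zn.n_cols; ++j)
        for (size_t i = 0; i < d->Zn.n_rows; ++i) out(i, j) = d->Zn(i, j);
      return out;
    }
  Rcpp::stop("network has no DSNT node");
}

// ---------------------------------------------------------------------------
// Dataset store

struct DataSet {
  fmat X;  // (C*H*W) x N, pixel values scaled to [0,1]
  fmat T;  // (2P) x N, normalised coordinates
  fmat Tg; // cached heatmap targets (rendered once per training run)
  int tg_p = 0, tg_h = 0, tg_w = 0;
  float tg_sigma = 0;
};

// [[Rcpp::export]]
SEXP ds_new(Rcpp::RawMatrix images, Rcpp::NumericMatrix coords) {
  auto* ds = new DataSet();
  ds->X.set_size(images.nrow(), images.ncol());
  for (int j = 0; j < images.ncol(); ++j)
    for (int i = 0; i < images.nrow(); ++i)
      ds->X(i, j) = (float)images(i, j) / 255.0f;
  ds->T.set_size(coords.nrow(), coords.ncol());
  for (int j = 0; j < coords.ncol(); ++j)
    for (int i = 0; i < coords.nrow(); ++i) ds->T(i, j) = (float)coords(i, j);
  Rcpp::XPtr<DataSet> ptr(ds, true);
  return ptr;
}

// ---------------------------------------------------------------------------
// Losses

struct LossCfg {
  std::string head, loss;
  float beta, wingw, wingeps, lambda, sigma_t, hm_sigma;
  int P;
};

static LossCfg read_cfg(const Rcpp::List& cfg) {
  LossCfg c;
  c.head = Rcpp::as<std::string>(cfg["head"]);
  c.loss = Rcpp::as<std::string>(cfg["loss"]);
  c.beta = Rcpp::as<double>(cfg["beta"]);
  c.wingw = Rcpp::as<double>(cfg["wing_w"]);
  c.wingeps = Rcpp::as<double>(cfg["wing_eps"]);
  c.lambda = Rcpp::as<double>(cfg["lambda"]);
  c.sigma_t = Rcpp::as<double>(cfg["sigma_t"]);
  c.hm_sigma = Rcpp::as<double>(cfg["hm_sigma"]);
  c.P = Rcpp::as<int>(cfg["n_points"]);
  return c;
}

// elementwise losses on pred - target; fills grad (d loss_sum / d pred)
// without intermediate difference matrices; returns the loss sum
static double elem_loss(const fmat& pred, const fmat& target, fmat& grad,
                        const LossCfg& c) {
  double tot = 0;
  grad.set_size(size(pred));
  const float* p = pred.memptr();
  const float* t = target.memptr();
  float* g = grad.memptr();
  const size_t n = pred.n_elem;
  if (c.loss == "l1") {
    for (size_t i = 0; i < n; ++i) {
      const float d = p[i] - t[i];
      tot += std::fabs((double)d);
      g[i] = d > 0 ? 1.0f : (d < 0 ? -1.0f : 0.0f);
    }
  } else if (c.loss == "mse") {
    for (size_t i = 0; i < n; ++i) {
      const float d = p[i] - t[i];
      tot += (double)d * d;
      g[i] = 2.0f * d;
    }
  } else if (c.loss == "smooth_l1") {
    for (size_t i = 0; i < n; ++i) {
      const float d = p[i] - t[i];
      const float a = std::fabs(d);
      if (a < c.beta) { tot += 0.5 * a * a / c.beta; g[i] = d / c.beta; }
      else { tot += a - 0.5 * c.beta; g[i] = d > 0 ? 1.0f : -1.0f; }
    }
  } else if (c.loss == "wing") {
    const float C0 = c.wingw - c.wingw * std::log(1.0f + c.wingw / c.wingeps);
    for (size_t i = 0; i < n; ++i) {
      const float d = p[i] - t[i];
      const float a = std::fabs(d);
      if (a < c.wingw) {
        tot += c.wingw * std::log(1.0f + a / c.wingeps);
        g[i] = (d >= 0 ? 1.0f : -1.0f) * c.wingw / (c.wingeps + a);
      } else {
        tot += a - C0;
        g[i] = d > 0 ? 1.0f : -1.0f;
      }
    }
  } else Rcpp::stop("unknown loss: " + c.loss);
  return tot;
}

// Gaussian heatmap targets (peak value 1) in activation layout; coordinates
// given in heatmap-pixel units (0-based, x = column, y = row).
static void render_targets(fmat& Tg, const fmat& Tn, int P, int hh, int hw,
                           float sigma, bool normalise) {
  const int N = Tn.n_cols;
  Tg.zeros((size_t)hh * hw * P, N);
  const float s2 = 2.0f * sigma * sigma;
  for (int n0 = 0; n0 < N; ++n0) {
    float* t = Tg.colptr(n0);
    for (int p = 0; p < P; ++p) {
      // normalised -> heatmap pixel centre coords
      const float xn = Tn(2 * p, n0), yn = Tn(2 * p + 1, n0);
      float cx = (xn * hw + hw - 1) / 2.0f;
      float cy = (yn * hh + hh - 1) / 2.0f;
      if (normalise) { // clamp centre into grid for the regulariser target
        cx = std::min(std::max(cx, 0.0f), (float)hw - 1);
        cy = std::min(std::max(cy, 0.0f), (float)hh - 1);
      } else if (cx < 0 || cx > hw - 1 || cy < 0 || cy > hh - 1) {
        continue; // out-of-frame landmark: all-zero channel
      }
      const int r = (int)std::ceil(4 * sigma) + 1;
      const int y0 = std::max(0, (int)std::floor(cy) - r),
                y1 = std::min(hh - 1, (int)std::ceil(cy) + r);
      const int x0 = std::max(0, (int)std::floor(cx) - r),
                x1 = std::min(hw - 1, (int)std::ceil(cx) + r);
      double mass = 0;
      for (int i = y0; i <= y1; ++i)
        for (int j = x0; j <= x1; ++j) {
          const float dx = j - cx, dy = i - cy;
          const float v = std::exp(-(dx * dx + dy * dy) / s2);
          t[(size_t)(i * hw + j) * P + p] = v;
          mass += v;
        }
      if (normalise && mass > 0) {
        for (int i = y0; i <= y1; ++i)
          for (int j = x0; j <= x1; ++j)
            t[(size_t)(i * hw + j) * P + p] /= (float)mass;
      }
    }
  }
}

// loss + output-gradient for one batch; returns mean loss.
// Tg_batch: pre-rendered heatmap targets for the batch (hm head), or null.
static double batch_loss(Network& net, const fmat& Tn, const LossCfg& c,
                         fmat& gout, const fmat* Tg_batch = nullptr) {
  Node& last = *net.nodes.back();
  const int N = last.out.n_cols;
  if (c.head == "fc") {
    const double tot = elem_loss(last.out, Tn, gout, c);
    gout /= (float)last.out.n_elem;
    return tot / last.out.n_elem;
  }
  if (c.head == "hm") {
    fmat Tg_local;
    const fmat* Tg = Tg_batch;
    if (!Tg) {
      render_targets(Tg_local, Tn, c.P, last.H, last.W, c.hm_sigma, false);
      Tg = &Tg_local;
    }
    const double tot = elem_loss(last.out, *Tg, gout, c);
    gout /= (float)last.out.n_elem;
    return tot / last.out.n_elem;
  }
  if (c.head == "dsnt") {
    // coordinate MSE + lambda * mean JS(Zn || target Gaussian)
    DSNTNode* dn = nullptr;
    for (auto& nd : net.nodes)
      if (nd->type == "dsnt") dn = static_cast<DSNTNode*>(nd.get());
    if (!dn) Rcpp::stop("dsnt head requires a dsnt node");
    LossCfg cm = c; cm.loss = "mse";
    double tot = elem_loss(last.out, Tn, gout, cm);
    gout /= (float)last.out.n_elem;
    const size_t d_n_elem = last.out.n_elem;
    double js_tot = 0;
    if (c.lambda > 0) {
      fmat Q;
      render_targets(Q, Tn, c.P, dn->m, dn->n, c.sigma_t, true);
      const float scale = c.lambda / ((float)c.P * N);
      dn->reg_grad.set_size(size(dn->Zn));
      for (size_t i = 0; i < dn->Zn.n_elem; ++i) {
        const double P0 = dn->Zn[i], Q0 = Q[i];
        const double M = 0.5 * (P0 + Q0);
        double term = 0, g = 0;
        if (P0 > 1e-30) { term += 0.5 * P0 * std::log(P0 / M); g = 0.5 * std::log(P0 / M); }
        if (Q0 > 1e-30) term += 0.5 * Q0 * std::log(Q0 / M);
        js_tot += term;
        dn->reg_grad[i] = scale * (float)g;
      }
    }
    return tot / d_n_elem + c.lambda * js_tot / ((double)c.P * N);
  }
  Rcpp::stop("unknown head: " + c.head);
}

static void backward_all(Network& net, const fmat& gfinal) {
  for (auto& nd : net.nodes) nd->gout.zeros(nd->out.n_rows, nd->out.n_cols);
  net.nodes.back()->gout = gfinal;
  for (size_t i = net.nodes.size(); i-- > 1;) net.nodes[i]->backward(net);
}

static void adam_step(Network& net, float lr, float b1, float b2, float eps) {
  net.adam_t += 1;
  const float bc1 = 1.0f - std::pow(b1, (float)net.adam_t);
  const float bc2 = 1.0f - std::pow(b2, (float)net.adam_t);
  for (Param* p : net.all_params()) {
    float* w = p->w.memptr();
    float* m = p->m.memptr();
    float* v = p->v.memptr();
    const float* g = p->g.memptr();
    const size_t n = p->w.n_elem;
    for (size_t i = 0; i < n; ++i) {
      m[i] = b1 * m[i] + (1 - b1) * g[i];
      v[i] = b2 * v[i] + (1 - b2) * g[i] * g[i];
      w[i] -= lr * (m[i] / bc1) / (std::sqrt(v[i] / bc2) + eps);
    }
  }
}

// [[Rcpp::export]]
double nn_train_epoch(SEXP netp, SEXP dsp, Rcpp::IntegerVector order,
                      int batch_size, Rcpp::List cfg) {
  Rcpp::XPtr<Network> net(netp);
  Rcpp::XPtr<DataSet> ds(dsp);
  LossCfg c = read_cfg(cfg);
  const float lr = Rcpp::as<double>(cfg["lr"]);
  const float b1 = Rcpp::as<double>(cfg["beta1"]);
  const float b2 = Rcpp::as<double>(cfg["beta2"]);
  const float eps = Rcpp::as<double>(cfg["adam_eps"]);
  const int n = order.size();
  double loss_sum = 0;
  int n_batches = 0;
  if (c.head == "hm") {
    // render the (fixed) target heatmaps once and reuse across epochs
    Node& last = *net->nodes.back();
    const size_t tot = (size_t)last.H * last.W * c.P * ds->T.n_cols;
    if (tot < (size_t)4e8 &&
        (ds->tg_p != c.P || ds->tg_h != last.H || ds->tg_w != last.W ||
         ds->tg_sigma != (float)c.hm_sigma)) {
      render_targets(ds->Tg, ds->T, c.P, last.H, last.W, c.hm_sigma, false);
      ds->tg_p = c.P; ds->tg_h = last.H; ds->tg_w = last.W;
      ds->tg_sigma = (float)c.hm_sigma;
    }
  }
  for (int s = 0; s < n; s += batch_size) {
    const int e = std::min(n, s + batch_size);
    const int bn = e - s;
    if (bn < 2) break; // batch statistics need >= 2 samples
    uvec idx(bn);
    for (int i = 0; i < bn; ++i) idx(i) = order[s + i];
    fmat X = ds->X.cols(idx);
    fmat Tn = ds->T.cols(idx);
    forward_all(*net, X, true);
    fmat gfinal;
    fmat Tg_batch;
    const fmat* tg = nullptr;
    if (c.head == "hm" && ds->Tg.n_cols == ds->T.n_cols) {
      Tg_batch = ds->Tg.cols(idx);
      tg = &Tg_batch;
    }
    const double l = batch_loss(*net, Tn, c, gfinal, tg);
    if (!std::isfinite(l)) Rcpp::stop("non-finite training loss (divergence)");
    backward_all(*net, gfinal);
    adam_step(*net, lr, b1, b2, eps);
    loss_sum += l;
    n_batches += 1;
    Rcpp::checkUserInterrupt();
  }
  return loss_sum / std::max(1, n_batches);
}

// decode predictions to normalised coordinates (eval mode)
static fmat predict_coords_raw(Network& net, const fmat& X, const LossCfg& c) {
  forward_all(net, X, false);
  Node& last = *net.nodes.back();
  const int N = X.n_cols;
  if (c.head == "fc" || c.head == "dsnt") return last.out;
  // hm: per-channel argmax, ties broken by first occurrence in row-major scan
  fmat coords(2 * c.P, N);
  const int hh = last.H, hw = last.W;
  for (int n0 = 0; n0 < N; ++n0) {
    const float* z = last.out.colptr(n0);
    for (int p = 0; p < c.P; ++p) {
      float best = -std::numeric_limits<float>::infinity();
      int bi = 0, bj = 0;
      for (int i = 0; i < hh; ++i)
        for (int j = 0; j < hw; ++j) {
          const float v = z[(size_t)(i * hw + j) * c.P + p];
          if (v > best) { best = v; bi = i; bj = j; }
        }
      coords(2 * p, n0) = (2.0f * (bj + 1) - (hw + 1)) / hw;
      coords(2 * p + 1, n0) = (2.0f * (bi + 1) - (hh + 1)) / hh;
    }
  }
  return coords;
}

// [[Rcpp::export]]
Rcpp::List nn_param_grads(SEXP netp, SEXP dsp, Rcpp::IntegerVector idx,
                          Rcpp::List cfg) {
  // training-mode loss and parameter gradients for one fixed batch;
  // no optimiser step. Used for finite-difference gradient verification.
  Rcpp::XPtr<Network> net(netp);
  Rcpp::XPtr<DataSet> ds(dsp);
  LossCfg c = read_cfg(cfg);
  uvec ii(idx.size());
  for (int i = 0; i < idx.size(); ++i) ii(i) = idx[i];
  fmat X = ds->X.cols(ii);
  fmat Tn = ds->T.cols(ii);
  forward_all(*net, X, true);
  fmat gfinal;
  const double l = batch_loss(*net, Tn, c, gfinal);
  backward_all(*net, gfinal);
  std::vector<double> g;
  for (Param* p : net->all_params())
    for (float x : p->g) g.push_back(x);
  return Rcpp::List::create(Rcpp::Named("loss") = l,
                            Rcpp::Named("grads") = Rcpp::wrap(g));
}

// [[Rcpp::export]]
Rcpp::NumericMatrix nn_predict(SEXP netp, SEXP dsp, Rcpp::IntegerVector idx,
                               Rcpp::List cfg, int batch_size = 100) {
  Rcpp::XPtr<Network> net(netp);
  Rcpp::XPtr<DataSet> ds(dsp);
  LossCfg c = read_cfg(cfg);
  const int n = idx.size();
  Rcpp::NumericMatrix out(2 * c.P, n);
  for (int s = 0; s < n; s += batch_size) {
    const int e = std::min(n, s + batch_size);
    uvec ii(e - s);
    for (int i = s; i < e; ++i) ii(i - s) = idx[i];
    fmat X = ds->X.cols(ii);
    fmat co = predict_coords_raw(*net, X, c);
    for (int j = s; j < e; ++j)
      for (size_t i = 0; i < co.n_rows; ++i) out(i, j) = co(i, j - s);
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix nn_predict_mat(SEXP netp, Rcpp::NumericMatrix X,
                                   Rcpp::List cfg) {
  Rcpp::XPtr<Network> net(netp);
  LossCfg c = read_cfg(cfg);
  fmat Xf(X.nrow(), X.ncol());
  for (int j = 0; j < X.ncol(); ++j)
    for (int i = 0; i < X.nrow(); ++i) Xf(i, j) = (float)X(i, j);
  fmat co = predict_coords_raw(*net, Xf, c);
  Rcpp::NumericMatrix out(co.n_rows, co.n_cols);
  for (size_t j = 0; j < co.n_cols; ++j)
    for (size_t i = 0; i < co.n_rows; ++i) out(i, j) = co(i, j);
  return out;
}

// [[Rcpp::export]]
double nn_eval_loss(SEXP netp, SEXP dsp, Rcpp::IntegerVector idx,
                    Rcpp::List cfg, int batch_size = 100) {
  // evaluation-mode mean loss (no parameter update)
  Rcpp::XPtr<Network> net(netp);
  Rcpp::XPtr<DataSet> ds(dsp);
  LossCfg c = read_cfg(cfg);
  const int n = idx.size();
  double tot = 0;
  int nb = 0;
  for (int s = 0; s < n; s += batch_size) {
    const int e = std::min(n, s + batch_size);
    uvec ii(e - s);
    for (int i = s; i < e; ++i) ii(i - s) = idx[i];
    fmat X = ds->X.cols(ii);
    fmat Tn = ds->T.cols(ii);
    forward_all(*net, X, false);
    fmat gdummy;
    tot += batch_loss(*net, Tn, c, gdummy);
    nb += 1;
  }
  for (auto& nd : net->nodes) // discard regulariser grads from eval passes
    if (nd->type == "dsnt") static_cast<DSNTNode*>(nd.get())->reg_grad.reset();
  return tot / std::max(1, nb);
}
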