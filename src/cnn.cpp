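// Ordinal defocus patch classifier: conv(32,5x5) - maxpool2 - conv(64,5x5) -
// maxpool2 - FC1024 - dropout(0.5) - FC(n_levels) - softmax, trained with the
// discrete ranked probability score and Adam. Single precision throughout;
// convolutions via im2col + BLAS gemm. Input patches are raw 16-bit counts,
// optionally gain/offset-augmented, then scaled by 1/65535.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#if defined(__GLIBC__)
#include <malloc.h>
#endif

using arma::fmat;
using arma::fvec;
using arma::uword;

namespace {

constexpr int PS = 84;          // patch side
constexpr int C1_OUT = 32, C2_OUT = 64;
constexpr int K = 5;            // conv kernel side
constexpr int O1 = PS - K + 1;  // 80
constexpr int P1S = O1 / 2;     // 40
constexpr int O2 = P1S - K + 1; // 36
constexpr int P2S = O2 / 2;     // 18
constexpr int FLAT = C2_OUT * P2S * P2S; // 20736
constexpr int FC1 = 1024;

struct Params {
  fmat W1, W2, W3, W4;
  fvec b1, b2, b3, b4;
};

struct Adam {
  Params m, v;
  long t = 0;
};

void zeros_like(Params& p) {
  p.W1.zeros(C1_OUT, K * K);
  p.W2.zeros(C2_OUT, K * K * C1_OUT);
  p.W3.zeros(FC1, FLAT);
  p.W4.resize(0, 0); // sized by caller (n_levels)
  p.b1.zeros(C1_OUT); p.b2.zeros(C2_OUT); p.b3.zeros(FC1);
}

fmat trunc_normal(uword nr, uword nc, float sd, std::mt19937& rng) {
  std::normal_distribution<float> nd(0.0f, sd);
  fmat out(nr, nc);
  for (uword i = 0; i < out.n_elem; ++i) {
    float x;
    do { x = nd(rng); } while (std::fabs(x) > 2.0f * sd);
    out[i] = x;
  }
  return out;
}

Params init_params(int n_levels, std::mt19937& rng) {
  Params p;
  p.W1 = trunc_normal(C1_OUT, K * K, std::sqrt(2.0f / (K * K)), rng);
  p.W2 = trunc_normal(C2_OUT, K * K * C1_OUT,
                      std::sqrt(2.0f / (K * K * C1_OUT)), rng);
  p.W3 = trunc_normal(FC1, FLAT, std::sqrt(2.0f / FLAT), rng);
  p.W4 = trunc_normal(n_levels, FC1, std::sqrt(2.0f / FC1), rng);
  p.b1.zeros(C1_OUT); p.b2.zeros(C2_OUT); p.b3.zeros(FC1);
  p.b4.zeros(n_levels);
  return p;
}

// im2col for conv1: X (PS*PS x B) raw normalized patches ->
// cols (25 x O1*O1*B), column index b*O1*O1 + oj*O1 + oi
void im2col1(const fmat& X, fmat& cols) {
  const int area = O1 * O1;
  for (uword b = 0; b < X.n_cols; ++b) {
    const float* img = X.colptr(b);
    for (int oj = 0; oj < O1; ++oj) {
      for (int oi = 0; oi < O1; ++oi) {
        float* dst = cols.colptr(b * area + oj * O1 + oi);
        for (int kj = 0; kj < K; ++kj) {
          const float* src = img + (oj + kj) * PS + oi;
          for (int ki = 0; ki < K; ++ki) dst[ki + K * kj] = src[ki];
        }
      }
    }
  }
}

// 2x2 max pool over spatial grid: in (C x S*S*B) -> out (C x (S/2)^2*B),
// recording the winning input column per (row, outcol)
void maxpool(const fmat& in, int S, fmat& out, arma::umat& argc) {
  const int H = S / 2, in_area = S * S, out_area = H * H;
  const uword B = in.n_cols / in_area, C = in.n_rows;
  for (uword b = 0; b < B; ++b) {
    for (int pj = 0; pj < H; ++pj) {
      for (int pi = 0; pi < H; ++pi) {
        const uword oc = b * out_area + pj * H + pi;
        uword c0 = b * in_area + (2 * pj) * S + 2 * pi;
        const uword cand[4] = {c0, c0 + 1, c0 + S, c0 + S + 1};
        for (uword r = 0; r < C; ++r) {
          float best = in(r, cand[0]); uword bi = cand[0];
          for (int q = 1; q < 4; ++q) {
            float v = in(r, cand[q]);
            if (v > best) { best = v; bi = cand[q]; }
          }
          out(r, oc) = best;
          argc(r, oc) = bi;
        }
      }
    }
  }
}

void unpool(const fmat& dout, const arma::umat& argc, fmat& din) {
  din.zeros();
  for (uword c = 0; c < dout.n_cols; ++c)
    for (uword r = 0; r < dout.n_rows; ++r)
      din(r, argc(r, c)) += dout(r, c);
}

// im2col for conv2: P1 (C1_OUT x P1S*P1S*B) -> cols (800 x O2*O2*B)
void im2col2(const fmat& P1, fmat& cols) {
  const int in_area = P1S * P1S, out_area = O2 * O2;
  const uword B = P1.n_cols / in_area;
  for (uword b = 0; b < B; ++b) {
    for (int oj = 0; oj < O2; ++oj) {
      for (int kj = 0; kj < K; ++kj) {
        for (int ki = 0; ki < K; ++ki) {
          const int q = ki + K * kj;
          for (int oi = 0; oi < O2; ++oi) {
            const float* src = P1.colptr(b * in_area + (oj + kj) * P1S + oi + ki);
            float* dst = cols.colptr(b * out_area + oj * O2 + oi) + q * C1_OUT;
            std::memcpy(dst, src, C1_OUT * sizeof(float));
          }
        }
      }
    }
  }
}

// scatter-accumulate the transpose of im2col2 (gradient w.r.t. P1)
void col2im2(const fmat& dcols, fmat& dP1) {
  const int in_area = P1S * P1S, out_area = O2 * O2;
  const uword B = dP1.n_cols / in_area;
  dP1.zeros();
  for (uword b = 0; b < B; ++b) {
    for (int oj = 0; oj < O2; ++oj) {
      for (int kj = 0; kj < K; ++kj) {
        for (int ki = 0; ki < K; ++ki) {
          const int q = ki + K * kj;
          for (int oi = 0; oi < O2; ++oi) {
            const float* src = dcols.colptr(b * out_area + oj * O2 + oi) + q * C1_OUT;
            float* dst = dP1.colptr(b * in_area + (oj + kj) * P1S + oi + ki);
            for (int c = 0; c < C1_OUT; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
}

struct Prof {
  double im2col = 0, gemm_f = 0, pool = 0, fc = 0, loss = 0,
         back_fc = 0, back_conv = 0, adam = 0, sample = 0;
  bool on = false;
  arma::wall_clock clk;
  void tic() { if (on) clk.tic(); }
  double toc() { return on ? clk.toc() : 0.0; }
};

struct Cache {
  fmat X1, A1, P1, X2, A2, P2, H3, H3d, P;
  arma::umat arg1, arg2;
  fmat drop; // dropout keep mask, already scaled
  fmat dX2, dA2, dA1, dP1; // backward scratch, reused across steps
  fmat dW3, dH3, dFflat;
};

// forward pass on a normalized batch X (PS*PS x B)
void forward(const Params& p, const fmat& X, Cache& c, bool train,
             float dropout, std::mt19937* rng) {
  const uword B = X.n_cols;
  c.X1.set_size(K * K, (uword)O1 * O1 * B);
  im2col1(X, c.X1);
  c.A1 = p.W1 * c.X1;
  c.A1.each_col() += p.b1;
  c.A1.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  c.P1.set_size(C1_OUT, (uword)P1S * P1S * B);
  c.arg1.set_size(C1_OUT, c.P1.n_cols);
  maxpool(c.A1, O1, c.P1, c.arg1);
  c.X2.set_size(K * K * C1_OUT, (uword)O2 * O2 * B);
  im2col2(c.P1, c.X2);
  c.A2 = p.W2 * c.X2;
  c.A2.each_col() += p.b2;
  c.A2.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  c.P2.set_size(C2_OUT, (uword)P2S * P2S * B);
  c.arg2.set_size(C2_OUT, c.P2.n_cols);
  maxpool(c.A2, O2, c.P2, c.arg2);
  const fmat F(const_cast<float*>(c.P2.memptr()), FLAT, B, false, true);
  c.H3 = p.W3 * F;
  c.H3.each_col() += p.b3;
  c.H3.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  if (train && dropout > 0.0f) {
    std::bernoulli_distribution keep(1.0 - dropout);
    c.drop.set_size(c.H3.n_rows, c.H3.n_cols);
    const float scale = 1.0f / (1.0f - dropout);
    for (uword i = 0; i < c.drop.n_elem; ++i)
      c.drop[i] = keep(*rng) ? scale : 0.0f;
    c.H3d = c.H3 % c.drop;
  } else {
    c.H3d = c.H3;
  }
  fmat Z = p.W4 * c.H3d;
  Z.each_col() += p.b4;
  Z.each_row() -= arma::max(Z, 0);
  c.P = arma::exp(Z);
  c.P.each_row() /= arma::sum(c.P, 0);
}

// mean RPS over the batch and gradient w.r.t. logits (into dZ)
float rps_and_grad(const fmat& P, const arma::ivec& labels, fmat& dZ) {
  const uword N = P.n_rows, B = P.n_cols;
  fmat cp = arma::cumsum(P, 0);
  float loss = 0.0f;
  fmat g(N, B);
  for (uword b = 0; b < B; ++b) {
    float acc = 0.0f; // reverse cumulative of 2*(Pc - Tc)
    for (uword i = N; i-- > 0;) {
      float tc = (int)i >= labels[b] ? 1.0f : 0.0f;
      float d = cp(i, b) - tc;
      loss += d * d;
      acc += 2.0f * d;
      g(i, b) = acc;
    }
  }
  arma::frowvec gp = arma::sum(g % P, 0);
  g.each_row() -= gp;
  dZ = P % g;
  dZ /= (float)B;
  return loss / (float)B;
}

// single-pass in-place Adam (no large temporaries)
void adam_core(float* w, const float* g, float* m, float* v, uword n,
               float lr, long t) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  const float corr = lr * std::sqrt(1.0f - std::pow(b2, (float)t)) /
                     (1.0f - std::pow(b1, (float)t));
  for (uword i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1.0f - b1) * g[i];
    v[i] = b2 * v[i] + (1.0f - b2) * g[i] * g[i];
    w[i] -= corr * m[i] / (std::sqrt(v[i]) + eps);
  }
}

void adam_update(fmat& w, const fmat& g, fmat& m, fmat& v, float lr, long t) {
  adam_core(w.memptr(), g.memptr(), m.memptr(), v.memptr(), w.n_elem, lr, t);
}

void adam_update_vec(fvec& w, const fvec& g, fvec& m, fvec& v, float lr,
                     long t) {
  adam_core(w.memptr(), g.memptr(), m.memptr(), v.memptr(), w.n_elem, lr, t);
}

// zero the entries of d where the (post-relu) activation is zero
void relu_backward(fmat& d, const fmat& a) {
  const float* ap = a.memptr();
  float* dp = d.memptr();
  for (uword i = 0; i < d.n_elem; ++i)
    if (ap[i] <= 0.0f) dp[i] = 0.0f;
}

Params list_to_params(const Rcpp::List& w) {
  Params p;
  p.W1 = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(w["W1"]));
  p.W2 = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(w["W2"]));
  p.W3 = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(w["W3"]));
  p.W4 = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(w["W4"]));
  p.b1 = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(w["b1"]));
  p.b2 = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(w["b2"]));
  p.b3 = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(w["b3"]));
  p.b4 = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(w["b4"]));
  return p;
}

Rcpp::List params_to_list(const Params& p) {
  return Rcpp::List::create(
      Rcpp::Named("W1") = arma::conv_to<arma::mat>::from(p.W1),
      Rcpp::Named("b1") = arma::conv_to<arma::vec>::from(p.b1),
      Rcpp::Named("W2") = arma::conv_to<arma::mat>::from(p.W2),
      Rcpp::Named("b2") = arma::conv_to<arma::vec>::from(p.b2),
      Rcpp::Named("W3") = arma::conv_to<arma::mat>::from(p.W3),
      Rcpp::Named("b3") = arma::conv_to<arma::vec>::from(p.b3),
      Rcpp::Named("W4") = arma::conv_to<arma::mat>::from(p.W4),
      Rcpp::Named("b4") = arma::conv_to<arma::vec>::from(p.b4));
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cnn_init_weights(int n_levels, int seed) {
  std::mt19937 rng((unsigned)seed);
  return params_to_list(init_params(n_levels, rng));
}

// raw: PS*PS x n matrix of raw counts; labels: 0-based levels
// [[Rcpp::export]]
Rcpp::List cnn_train(const arma::mat& raw, const arma::ivec& labels,
                     int steps, int batch, double lr, double dropout,
                     bool augment, double gain_lo, double gain_hi,
                     double offset_lo, double offset_hi, int n_levels,
                     int seed, bool lr_decay = false,
                     int img_h = 84, int img_w = 84,
                     Rcpp::Nullable<Rcpp::List> init_weights = R_NilValue) {
  if (labels.n_elem != raw.n_cols) Rcpp::stop("labels/images mismatch");
  if (labels.min() < 0 || labels.max() >= n_levels)
    Rcpp::stop("labels out of range");
#if defined(__GLIBC__)
  mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
#endif
  std::mt19937 rng((unsigned)seed);
  Params p = init_weights.isNotNull()
                 ? list_to_params(Rcpp::List(init_weights))
                 : init_params(n_levels, rng);
  Adam opt;
  zeros_like(opt.m); zeros_like(opt.v);
  opt.m.W4.zeros(n_levels, FC1); opt.v.W4.zeros(n_levels, FC1);
  opt.m.b4.zeros(n_levels); opt.v.b4.zeros(n_levels);

  // raw columns may be whole images (img_h x img_w, col-major) from which
  // 84 x 84 crops are drawn afresh at every step, or pre-cut 84 x 84
  // patches (img_h = img_w = PS)
  if ((uword)img_h * (uword)img_w != raw.n_rows || img_h < PS || img_w < PS)
    Rcpp::stop("raw columns must be img_h x img_w images with both dims >= %d",
               PS);
  const fmat rawf = arma::conv_to<fmat>::from(raw);
  std::uniform_int_distribution<uword> pick(0, raw.n_cols - 1);
  std::uniform_int_distribution<int> pick_r(0, img_h - PS);
  std::uniform_int_distribution<int> pick_c(0, img_w - PS);
  std::uniform_real_distribution<float> lg(std::log((float)gain_lo),
                                           std::log((float)gain_hi));
  std::uniform_real_distribution<float> lo_(std::log((float)offset_lo),
                                            std::log((float)offset_hi));
  Cache c;
  fmat X(PS * PS, batch);
  arma::ivec yb(batch);
  Rcpp::NumericVector trace(steps);

  Prof prof;
  prof.on = std::getenv("FOCUSQC_PROF") != nullptr;
  for (int s = 0; s < steps; ++s) {
    prof.tic();
    for (int b = 0; b < batch; ++b) {
      uword idx = pick(rng);
      yb[b] = labels[idx];
      const int r0 = (img_h == PS) ? 0 : pick_r(rng);
      const int c0 = (img_w == PS) ? 0 : pick_c(rng);
      float g = 1.0f, o = 0.0f;
      if (augment) { g = std::exp(lg(rng)); o = std::exp(lo_(rng)); }
      const float* src = rawf.colptr(idx) + (uword)c0 * img_h + r0;
      float* dst = X.colptr(b);
      for (int j = 0; j < PS; ++j) {
        const float* col = src + (uword)j * img_h;
        for (int i = 0; i < PS; ++i) {
          float v = col[i] * g + o;
          v = v < 0.0f ? 0.0f : (v > 65535.0f ? 65535.0f : v);
          dst[j * PS + i] = v / 65535.0f;
        }
      }
    }
    prof.sample += prof.toc();
    prof.tic();
    forward(p, X, c, true, (float)dropout, &rng);
    prof.fc += prof.toc();
    prof.tic();
    fmat dZ;
    float loss = rps_and_grad(c.P, yb, dZ);
    if (!std::isfinite(loss)) Rcpp::stop("training loss diverged (non-finite)");
    trace[s] = loss;

    // backward (large scratch matrices live in the cache and are reused)
    fmat dW4 = dZ * c.H3d.t();
    fvec db4 = arma::sum(dZ, 1);
    c.dH3 = p.W4.t() * dZ;
    if (dropout > 0) c.dH3 %= c.drop;
    relu_backward(c.dH3, c.H3);
    const fmat F(const_cast<float*>(c.P2.memptr()), FLAT, batch, false, true);
    if (c.dW3.n_rows != FC1) c.dW3.set_size(FC1, FLAT);
    c.dW3 = c.dH3 * F.t();
    fvec db3 = arma::sum(c.dH3, 1);
    c.dFflat = p.W3.t() * c.dH3; // FLAT x B
    const fmat dP2(const_cast<float*>(c.dFflat.memptr()), C2_OUT,
                   (uword)P2S * P2S * batch, false, true);
    c.dA2.set_size(C2_OUT, c.A2.n_cols);
    unpool(dP2, c.arg2, c.dA2);
    relu_backward(c.dA2, c.A2);
    fmat dW2 = c.dA2 * c.X2.t();
    fvec db2 = arma::sum(c.dA2, 1);
    c.dX2.set_size(p.W2.n_cols, c.dA2.n_cols);
    c.dX2 = p.W2.t() * c.dA2;
    c.dP1.set_size(C1_OUT, c.P1.n_cols);
    col2im2(c.dX2, c.dP1);
    c.dA1.set_size(C1_OUT, c.A1.n_cols);
    unpool(c.dP1, c.arg1, c.dA1);
    relu_backward(c.dA1, c.A1);
    fmat dW1 = c.dA1 * c.X1.t();
    fvec db1 = arma::sum(c.dA1, 1);
    prof.back_conv += prof.toc();
    prof.tic();

    ++opt.t;
    // linear decay to 10% of the base rate over the run
    const float lr_s = lr_decay
        ? (float)lr * (1.0f - 0.9f * (float)s / (float)steps)
        : (float)lr;
    adam_update(p.W1, dW1, opt.m.W1, opt.v.W1, lr_s, opt.t);
    adam_update(p.W2, dW2, opt.m.W2, opt.v.W2, lr_s, opt.t);
    adam_update(p.W3, c.dW3, opt.m.W3, opt.v.W3, lr_s, opt.t);
    adam_update(p.W4, dW4, opt.m.W4, opt.v.W4, lr_s, opt.t);
    adam_update_vec(p.b1, db1, opt.m.b1, opt.v.b1, lr_s, opt.t);
    adam_update_vec(p.b2, db2, opt.m.b2, opt.v.b2, lr_s, opt.t);
    adam_update_vec(p.b3, db3, opt.m.b3, opt.v.b3, lr_s, opt.t);
    adam_update_vec(p.b4, db4, opt.m.b4, opt.v.b4, lr_s, opt.t);
    prof.adam += prof.toc();
    if (s % 50 == 0) Rcpp::checkUserInterrupt();
  }
  if (prof.on) {
    Rcpp::Rcout << "profile (s): sample " << prof.sample
                << " forward " << prof.fc << " loss+backward " << prof.back_conv
                << " adam " << prof.adam << std::endl;
  }
  Rcpp::List out = params_to_list(p);
  out["loss_trace"] = trace;
  return out;
}

// inference: raw counts (PS*PS x n) -> class probabilities (n_levels x n)
// [[Rcpp::export]]
arma::mat cnn_predict(const Rcpp::List& weights, const arma::mat& raw,
                      int chunk = 128) {
  Params p = list_to_params(weights);
  const uword n = raw.n_cols;
  arma::mat out(p.W4.n_rows, n);
  Cache c;
  for (uword start = 0; start < n; start += chunk) {
    uword end = std::min(n, start + (uword)chunk) - 1;
    fmat X = arma::conv_to<fmat>::from(raw.cols(start, end)) / 65535.0f;
    forward(p, X, c, false, 0.0f, nullptr);
    out.cols(start, end) = arma::conv_to<arma::mat>::from(c.P);
  }
  return out;
}
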