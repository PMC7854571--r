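// Convolutional denoising autoencoder: forward, backward and RMSprop training.
//
// Layout conventions
//   * An image stack crosses the R boundary as a numeric array (H, W, N).
//   * Inside a network pass a feature map is an arma::fmat of size (H*W, C):
//     column c is channel c's plane, stored column-major within the plane
//     (p = y + x*H, matching R's array layout).
//   * A convolution weight is an R matrix of size (Cin*K*K, Cout); column o
//     is the flattened patch kernel producing output channel o.  Convolution
//     is then  out = im2col(F) %*% W  — one GEMM with M = H*W.
//
// All arithmetic is single precision; parameters are converted from/to
// double at the boundary so serialized models restore bit-identical
// inference.

#include <RcppArmadillo.h>
#include <random>
#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

namespace {

enum OpType { CONV_RELU, CONV_LINEAR, POOL, UPSAMPLE, DROPOUT };

struct Op {
  OpType type;
  int cin, cout;   // conv only
};

// The block architecture implied by a BlockSpec: E encoder modules of
// (V convolutions, 2x2 max pool, dropout), then E decoder modules of
// (2x nearest upsample, convolution, dropout), then a 1-channel linear
// convolution.
std::vector<Op> make_arch(int channels, int enc_mods, int convs_per, bool with_dropout) {
  std::vector<Op> ops;
  for (int m = 0; m < enc_mods; ++m) {
    for (int v = 0; v < convs_per; ++v) {
      int cin = (m == 0 && v == 0) ? 1 : channels;
      ops.push_back({CONV_RELU, cin, channels});
    }
    ops.push_back({POOL, 0, 0});
    if (with_dropout) ops.push_back({DROPOUT, 0, 0});
  }
  for (int m = 0; m < enc_mods; ++m) {
    ops.push_back({UPSAMPLE, 0, 0});
    ops.push_back({CONV_RELU, channels, channels});
    if (with_dropout) ops.push_back({DROPOUT, 0, 0});
  }
  ops.push_back({CONV_LINEAR, channels, 1});
  return ops;
}

// im2col for same-padded stride-1 convolution on an (H*W, C) feature map.
// Output: (H*W, C*K*K); column c*K*K + kx*K + ky holds the input plane
// shifted by (ky - pad, kx - pad), zero outside.
void im2col(const fmat& F, int H, int W, int K, fmat& col) {
  const int pad = K / 2, HW = H * W, C = (int)F.n_cols;
  col.set_size(HW, C * K * K);
  for (int c = 0; c < C; ++c) {
    const float* src = F.colptr(c);
    for (int kx = 0; kx < K; ++kx) {
      int dx = kx - pad;
      for (int ky = 0; ky < K; ++ky) {
        int dy = ky - pad;
        float* dst = col.colptr(c * K * K + kx * K + ky);
        int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
        int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        // zero the padding border, copy the interior
        if (x0 > 0) std::memset(dst, 0, sizeof(float) * (size_t)x0 * H);
        if (x1 < W) std::memset(dst + (size_t)x1 * H, 0, sizeof(float) * (size_t)(W - x1) * H);
        for (int x = x0; x < x1; ++x) {
          float* d = dst + (size_t)x * H;
          if (y1 <= y0) { std::memset(d, 0, sizeof(float) * H); continue; }
          if (y0 > 0) std::memset(d, 0, sizeof(float) * y0);
          if (y1 < H) std::memset(d + y1, 0, sizeof(float) * (H - y1));
          std::memcpy(d + y0, src + (size_t)(x + dx) * H + (y0 + dy),
                      sizeof(float) * (y1 - y0));
        }
      }
    }
  }
}

// Adjoint of im2col: scatter-add columns of `col` back onto an (H*W, C) map.
void col2im(const fmat& col, int H, int W, int K, fmat& F) {
  const int pad = K / 2, HW = H * W;
  const int C = (int)col.n_cols / (K * K);
  F.zeros(HW, C);
  for (int c = 0; c < C; ++c) {
    float* dst = F.colptr(c);
    for (int kx = 0; kx < K; ++kx) {
      int dx = kx - pad;
      for (int ky = 0; ky < K; ++ky) {
        int dy = ky - pad;
        const float* src = col.colptr(c * K * K + kx * K + ky);
        int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
        int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        if (y1 <= y0) continue;
        for (int x = x0; x < x1; ++x) {
          float* d = dst + (size_t)(x + dx) * H + (y0 + dy);
          const float* s = src + (size_t)x * H + y0;
          for (int y = 0; y < y1 - y0; ++y) d[y] += s[y];
        }
      }
    }
  }
}

void maxpool2(const fmat& F, int H, int W, fmat& out, arma::umat& argmax) {
  const int Ho = H / 2, Wo = W / 2, C = (int)F.n_cols;
  out.set_size(Ho * Wo, C);
  argmax.set_size(Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const float* src = F.colptr(c);
    float* dst = out.colptr(c);
    arma::uword* am = argmax.colptr(c);
    for (int x = 0; x < Wo; ++x) {
      for (int y = 0; y < Ho; ++y) {
        size_t p00 = (size_t)(2 * x) * H + 2 * y;
        size_t cand[4] = {p00, p00 + 1, p00 + H, p00 + H + 1};
        size_t best = cand[0];
        for (int i = 1; i < 4; ++i) if (src[cand[i]] > src[best]) best = cand[i];
        dst[(size_t)x * Ho + y] = src[best];
        am[(size_t)x * Ho + y] = best;
      }
    }
  }
}

void maxpool2_back(const fmat& dOut, const arma::umat& argmax, int H, int W, fmat& dF) {
  const int C = (int)dOut.n_cols;
  dF.zeros(H * W, C);
  for (int c = 0; c < C; ++c) {
    const float* g = dOut.colptr(c);
    const arma::uword* am = argmax.colptr(c);
    float* d = dF.colptr(c);
    for (size_t i = 0; i < dOut.n_rows; ++i) d[am[i]] += g[i];
  }
}

void upsample2(const fmat& F, int H, int W, fmat& out) {
  const int Ho = 2 * H, C = (int)F.n_cols;
  out.set_size(4 * H * W, C);
  for (int c = 0; c < C; ++c) {
    const float* src = F.colptr(c);
    float* dst = out.colptr(c);
    for (int x = 0; x < W; ++x) {
      for (int y = 0; y < H; ++y) {
        float v = src[(size_t)x * H + y];
        size_t p = (size_t)(2 * x) * Ho + 2 * y;
        dst[p] = v; dst[p + 1] = v; dst[p + Ho] = v; dst[p + Ho + 1] = v;
      }
    }
  }
}

void upsample2_back(const fmat& dOut, int H, int W, fmat& dF) {
  // H, W are the *input* (pre-upsample) dimensions.
  const int Ho = 2 * H, C = (int)dOut.n_cols;
  dF.set_size(H * W, C);
  for (int c = 0; c < C; ++c) {
    const float* g = dOut.colptr(c);
    float* d = dF.colptr(c);
    for (int x = 0; x < W; ++x) {
      for (int y = 0; y < H; ++y) {
        size_t p = (size_t)(2 * x) * Ho + 2 * y;
        d[(size_t)x * H + y] = g[p] + g[p + 1] + g[p + Ho] + g[p + Ho + 1];
      }
    }
  }
}

struct ConvParams {
  fmat W;   // (Cin*K*K, Cout)
  fvec b;   // (Cout)
  fmat gW, mW;  // gradient accumulator, RMSprop cache
  fvec gb, mb;
};

struct Net {
  std::vector<Op> ops;
  std::vector<ConvParams> convs;  // one per conv op, in order
  int K;
};

Net build_net(const List& params, int channels, int enc_mods, int convs_per,
              int kernel, bool with_dropout) {
  Net net;
  net.K = kernel;
  net.ops = make_arch(channels, enc_mods, convs_per, with_dropout);
  size_t nconv = 0;
  for (const Op& op : net.ops)
    if (op.type == CONV_RELU || op.type == CONV_LINEAR) ++nconv;
  if ((size_t)params.size() != nconv)
    stop("parameter list has %d layers; architecture needs %d", (int)params.size(), (int)nconv);
  size_t i = 0;
  for (const Op& op : net.ops) {
    if (op.type != CONV_RELU && op.type != CONV_LINEAR) continue;
    List layer = params[i++];
    NumericMatrix Wr = layer["W"];
    NumericVector br = layer["b"];
    if (Wr.nrow() != op.cin * kernel * kernel || Wr.ncol() != op.cout)
      stop("weight matrix %d has wrong shape", (int)i);
    ConvParams cp;
    cp.W = arma::conv_to<fmat>::from(arma::mat(Wr.begin(), Wr.nrow(), Wr.ncol(), false));
    cp.b = arma::conv_to<fvec>::from(arma::vec(br.begin(), br.size(), false));
    cp.gW.zeros(cp.W.n_rows, cp.W.n_cols);
    cp.gb.zeros(cp.b.n_elem);
    cp.mW.zeros(cp.W.n_rows, cp.W.n_cols);
    cp.mb.zeros(cp.b.n_elem);
    net.convs.push_back(cp);
  }
  return net;
}

List export_params(const Net& net) {
  List out(net.convs.size());
  for (size_t i = 0; i < net.convs.size(); ++i) {
    const ConvParams& cp = net.convs[i];
    NumericMatrix Wr(cp.W.n_rows, cp.W.n_cols);
    std::copy(cp.W.begin(), cp.W.end(), Wr.begin());
    NumericVector br(cp.b.n_elem);
    std::copy(cp.b.begin(), cp.b.end(), br.begin());
    out[i] = List::create(Named("W") = Wr, Named("b") = br);
  }
  return out;
}

struct PassState {
  // saved per-op quantities needed for the backward pass
  std::vector<fmat> cols;         // im2col of each conv op's input
  std::vector<arma::umat> pools;  // argmax per POOL op
  std::vector<fmat> dropmasks;    // mask per DROPOUT op
  std::vector<fmat> outputs;      // output of each op (for ReLU mask)
};

// Forward through the net.  If `train`, dropout is active and state is saved.
fmat forward(Net& net, const fmat& x0, int H0, int W0, bool train,
             double drop_rate, std::mt19937* rng, PassState* st) {
  fmat x = x0;
  int H = H0, W = W0;
  size_t ci = 0, pi = 0, di = 0;
  fmat scratch_col;
  // dropout mask via raw 32-bit threshold: cheap and seed-deterministic
  const uint32_t keep_thr =
      (uint32_t)std::min<double>(4294967295.0, (1.0 - drop_rate) * 4294967296.0);
  const float keep_scale = drop_rate > 0 ? (float)(1.0 / (1.0 - drop_rate)) : 1.0f;
  for (size_t oi = 0; oi < net.ops.size(); ++oi) {
    const Op& op = net.ops[oi];
    switch (op.type) {
    case CONV_RELU:
    case CONV_LINEAR: {
      ConvParams& cp = net.convs[ci];
      fmat& col = st ? st->cols[ci] : scratch_col;
      ++ci;
      im2col(x, H, W, net.K, col);
      fmat out = col * cp.W;
      out.each_row() += cp.b.t();
      if (op.type == CONV_RELU) out.for_each([](float& v) { if (v < 0) v = 0; });
      x = std::move(out);
      break;
    }
    case POOL: {
      fmat out; arma::umat am;
      maxpool2(x, H, W, out, am);
      if (st) st->pools[pi] = std::move(am);
      ++pi;
      H /= 2; W /= 2;
      x = std::move(out);
      break;
    }
    case UPSAMPLE: {
      fmat out;
      upsample2(x, H, W, out);
      H *= 2; W *= 2;
      x = std::move(out);
      break;
    }
    case DROPOUT: {
      if (train && drop_rate > 0) {
        fmat mask(x.n_rows, x.n_cols);
        for (size_t i = 0; i < mask.n_elem; ++i)
          mask[i] = ((*rng)() < keep_thr) ? keep_scale : 0.0f;
        x %= mask;
        if (st) st->dropmasks[di] = std::move(mask);
      }
      ++di;
      break;
    }
    }
    if (st && op.type == CONV_RELU) st->outputs[oi] = x;
  }
  return x;
}

// Backward pass; accumulates gradients into net.convs[*].gW/gb.
void backward(Net& net, const PassState& st, const fmat& dOut0, int H0, int W0) {
  // reconstruct spatial dims op-by-op first
  std::vector<std::pair<int,int>> dims(net.ops.size());
  int H = H0, W = W0;
  for (size_t oi = 0; oi < net.ops.size(); ++oi) {
    dims[oi] = {H, W};  // input dims of op oi
    if (net.ops[oi].type == POOL) { H /= 2; W /= 2; }
    if (net.ops[oi].type == UPSAMPLE) { H *= 2; W *= 2; }
  }
  fmat d = dOut0;
  int ci = (int)net.convs.size() - 1;
  int pi = -1, di = -1;
  for (const Op& op : net.ops) {
    if (op.type == POOL) ++pi;
    if (op.type == DROPOUT) ++di;
  }
  for (int oi = (int)net.ops.size() - 1; oi >= 0; --oi) {
    const Op& op = net.ops[oi];
    int Hi = dims[oi].first, Wi = dims[oi].second;
    switch (op.type) {
    case CONV_RELU:
    case CONV_LINEAR: {
      ConvParams& cp = net.convs[ci];
      const fmat& col = st.cols[ci];
      --ci;
      if (op.type == CONV_RELU) {
        const fmat& out = st.outputs[oi];
        for (size_t i = 0; i < d.n_elem; ++i) if (out[i] <= 0) d[i] = 0;
      }
      cp.gW += col.t() * d;
      cp.gb += arma::sum(d, 0).t();
      if (oi > 0) {
        fmat dcol = d * cp.W.t();
        col2im(dcol, Hi, Wi, net.K, d);
      }
      break;
    }
    case POOL: {
      fmat dF;
      maxpool2_back(d, st.pools[pi--], Hi, Wi, dF);
      d = std::move(dF);
      break;
    }
    case UPSAMPLE: {
      fmat dF;
      upsample2_back(d, Hi, Wi, dF);
      d = std::move(dF);
      break;
    }
    case DROPOUT: {
      if (di >= 0 && st.dropmasks[di].n_elem > 0) d %= st.dropmasks[di];
      --di;
      break;
    }
    }
  }
}

// Squared gradients in the RMSprop caches underflow to denormal floats,
// which are pathologically slow; flush them to zero for the numerical
// work (restoring the previous mode on exit).
struct DenormalGuard {
#ifdef __SSE2__
  unsigned int ftz, daz;
  DenormalGuard() {
    ftz = _MM_GET_FLUSH_ZERO_MODE();
    daz = _MM_GET_DENORMALS_ZERO_MODE();
    _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
    _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
  }
  ~DenormalGuard() {
    _MM_SET_FLUSH_ZERO_MODE(ftz);
    _MM_SET_DENORMALS_ZERO_MODE(daz);
  }
#endif
};

void check_dims(int H, int W, int enc_mods, int pool) {
  int f = 1;
  for (int i = 0; i < enc_mods; ++i) f *= pool;
  if (H % f != 0 || W % f != 0)
    stop("image side (%d x %d) not divisible by %d (pooling factor)", H, W, f);
}

} // namespace

// [[Rcpp::export(name = ".cae_init")]]
List cae_init(int channels, int enc_mods, int convs_per, int kernel, int seed) {
  std::vector<Op> ops = make_arch(channels, enc_mods, convs_per, false);
  std::mt19937 rng((unsigned)seed);
  List out;
  for (const Op& op : ops) {
    if (op.type != CONV_RELU && op.type != CONV_LINEAR) continue;
    int fan_in = op.cin * kernel * kernel;
    double lim = std::sqrt(3.0 / fan_in);  // LeCun uniform
    std::uniform_real_distribution<double> unif(-lim, lim);
    NumericMatrix W(fan_in, op.cout);
    for (R_xlen_t i = 0; i < W.size(); ++i) W[i] = unif(rng);
    NumericVector b(op.cout);
    out.push_back(List::create(Named("W") = W, Named("b") = b));
  }
  return out;
}

// [[Rcpp::export(name = ".cae_apply")]]
NumericVector cae_apply(List params, NumericVector images, int channels,
                        int enc_mods, int convs_per, int kernel, int pool) {
  DenormalGuard dg;
  IntegerVector dim = images.attr("dim");
  if (dim.size() != 3) stop("images must be an (H, W, N) array");
  int H = dim[0], W = dim[1], N = dim[2];
  check_dims(H, W, enc_mods, pool);
  Net net = build_net(params, channels, enc_mods, convs_per, kernel, false);
  NumericVector out(images.size());
  out.attr("dim") = dim;
  const size_t HW = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    fmat x(HW, 1);
    for (size_t i = 0; i < HW; ++i) x[i] = (float)images[(size_t)n * HW + i];
    fmat y = forward(net, x, H, W, false, 0.0, nullptr, nullptr);
    for (size_t i = 0; i < HW; ++i) out[(size_t)n * HW + i] = y[i];
  }
  return out;
}

// [[Rcpp::export(name = ".cae_train")]]
List cae_train(List params, NumericVector inputs, NumericVector targets,
               int channels, int enc_mods, int convs_per, int kernel, int pool,
               int epochs, int batch_size, double lr, double dropout_rate,
               int seed) {
  DenormalGuard dg;
  IntegerVector dim = inputs.attr("dim");
  IntegerVector tdim = targets.attr("dim");
  if (dim.size() != 3 || tdim.size() != 3) stop("stacks must be (H, W, N) arrays");
  for (int i = 0; i < 3; ++i)
    if (dim[i] != tdim[i]) stop("inputs and targets must have identical dimensions");
  int H = dim[0], W = dim[1], N = dim[2];
  check_dims(H, W, enc_mods, pool);
  const bool with_dropout = dropout_rate > 0;
  Net net = build_net(params, channels, enc_mods, convs_per, kernel, with_dropout);
  std::mt19937 rng((unsigned)seed);

  const size_t HW = (size_t)H * W;
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;

  const double rho = 0.9, eps = 1e-7;
  NumericVector loss_hist(epochs);
  PassState st;
  st.cols.resize(net.convs.size());
  st.outputs.resize(net.ops.size());
  size_t npool = 0, ndrop = 0;
  for (const Op& op : net.ops) {
    if (op.type == POOL) ++npool;
    if (op.type == DROPOUT) ++ndrop;
  }
  st.pools.resize(npool);
  st.dropmasks.resize(ndrop);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0;
    for (int b0 = 0; b0 < N; b0 += batch_size) {
      int bn = std::min(batch_size, N - b0);
      for (ConvParams& cp : net.convs) { cp.gW.zeros(); cp.gb.zeros(); }
      for (int k = 0; k < bn; ++k) {
        int n = idx[b0 + k];
        fmat x(HW, 1), t(HW, 1);
        for (size_t i = 0; i < HW; ++i) {
          x[i] = (float)inputs[(size_t)n * HW + i];
          t[i] = (float)targets[(size_t)n * HW + i];
        }
        fmat y = forward(net, x, H, W, true, dropout_rate, &rng, &st);
        fmat diff = y - t;
        ep_loss += arma::accu(arma::square(diff)) / (double)HW;
        // d(MSE)/dy with MSE averaged over pixels and the batch
        fmat dOut = diff * (float)(2.0 / ((double)HW * bn));
        backward(net, st, dOut, H, W);
      }
      for (ConvParams& cp : net.convs) {
        cp.mW = (float)rho * cp.mW + (float)(1.0 - rho) * arma::square(cp.gW);
        cp.W -= (float)lr * cp.gW / (arma::sqrt(cp.mW) + (float)eps);
        cp.mb = (float)rho * cp.mb + (float)(1.0 - rho) * arma::square(cp.gb);
        cp.b -= (float)lr * cp.gb / (arma::sqrt(cp.mb) + (float)eps);
      }
    }
    loss_hist[ep] = ep_loss / N;
    Rcpp::checkUserInterrupt();
  }
  return List::create(Named("params") = export_params(net),
                      Named("loss") = loss_hist);
}

// Mean-square-error loss and its analytic parameter gradients for one stack,
// dropout disabled.  Exposed for finite-difference verification.
// [[Rcpp::export(name = ".cae_loss_grad")]]
List cae_loss_grad(List params, NumericVector inputs, NumericVector targets,
                   int channels, int enc_mods, int convs_per, int kernel, int pool) {
  DenormalGuard dg;
  IntegerVector dim = inputs.attr("dim");
  int H = dim[0], W = dim[1], N = dim[2];
  check_dims(H, W, enc_mods, pool);
  Net net = build_net(params, channels, enc_mods, convs_per, kernel, false);
  PassState st;
  st.cols.resize(net.convs.size());
  st.outputs.resize(net.ops.size());
  st.pools.resize(net.convs.size());  // upper bound
  size_t npool = 0;
  for (const Op& op : net.ops) if (op.type == POOL) ++npool;
  st.pools.resize(npool);
  const size_t HW = (size_t)H * W;
  double loss = 0.0;
  for (int n = 0; n < N; ++n) {
    fmat x(HW, 1), t(HW, 1);
    for (size_t i = 0; i < HW; ++i) {
      x[i] = (float)inputs[(size_t)n * HW + i];
      t[i] = (float)targets[(size_t)n * HW + i];
    }
    fmat y = forward(net, x, H, W, false, 0.0, nullptr, &st);
    fmat diff = y - t;
    loss += arma::accu(arma::square(diff)) / (double)HW;
    fmat dOut = diff * (float)(2.0 / ((double)HW * N));
    backward(net, st, dOut, H, W);
  }
  List grads(net.convs.size());
  for (size_t i = 0; i < net.convs.size(); ++i) {
    const ConvParams& cp = net.convs[i];
    NumericMatrix gW(cp.gW.n_rows, cp.gW.n_cols);
    std::copy(cp.gW.begin(), cp.gW.end(), gW.begin());
    NumericVector gb(cp.gb.n_elem);
    std::copy(cp.gb.begin(), cp.gb.end(), gb.begin());
    grads[i] = List::create(Named("W") = gW, Named("b") = gb);
  }
  return List::create(Named("loss") = loss / N, Named("grads") = grads);
}

// [[Rcpp::export(name = ".cae_param_count")]]
double cae_param_count(int channels, int enc_mods, int convs_per, int kernel) {
  std::vector<Op> ops = make_arch(channels, enc_mods, convs_per, false);
  double n = 0;
  for (const Op& op : ops)
    if (op.type == CONV_RELU || op.type == CONV_LINEAR)
      n += (double)op.cout * (op.cin * kernel * kernel + 1);
  return n;
}
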