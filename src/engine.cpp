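// Compact CNN engine for the PPG-NET architecture: standard, depthwise and
// pointwise convolutions, batch normalization, residual blocks, max pooling,
// global average pooling, a dense softmax head, and an SGD(+momentum)
// trainer with early stopping. Single-threaded and deterministic given the
// seed. The layer traversal order here defines the canonical weight order
// used by the R side (see cpp_weight_template).

#include <RcppArmadillo.h>
#include <random>
#if defined(__SSE2__)
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// Subnormal floats cost ~100x on x86; gradients and batch-norm statistics
// routinely underflow into that range during training, so flush them to
// zero inside the engine (the ~1e-308 magnitudes carry no information here).
inline void flush_denormals() {
#if defined(__SSE2__)
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
}

struct Geom { int oh, ow, pad; };

Geom same_geom(int in_h, int k, int s) {
  int oh = (in_h + s - 1) / s;
  int pad_total = std::max((oh - 1) * s + k - in_h, 0);
  Geom g; g.oh = oh; g.ow = oh; g.pad = pad_total / 2;  // square inputs only
  return g;
}

// im2col for a (H,W,C) cube; rows = output pixels (col-major oi fastest),
// cols = c*k*k + kj*k + ki, matching a column-major (k,k,C,N) weight array.
mat im2col(const cube& x, int k, int s, int pad, int oh, int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(oh * ow, k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int q = c * k * k + kj * k + ki;
        for (int oj = 0; oj < ow; ++oj) {
          const int in_j = oj * s - pad + kj;
          if (in_j < 0 || in_j >= W) continue;
          for (int oi = 0; oi < oh; ++oi) {
            const int in_i = oi * s - pad + ki;
            if (in_i < 0 || in_i >= H) continue;
            out(oi + oj * oh, q) = x(in_i, in_j, c);
          }
        }
      }
  return out;
}

cube col2im(const mat& cols, int H, int W, int C, int k, int s, int pad,
            int oh, int ow) {
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int q = c * k * k + kj * k + ki;
        for (int oj = 0; oj < ow; ++oj) {
          const int in_j = oj * s - pad + kj;
          if (in_j < 0 || in_j >= W) continue;
          for (int oi = 0; oi < oh; ++oi) {
            const int in_i = oi * s - pad + ki;
            if (in_i < 0 || in_i >= H) continue;
            x(in_i, in_j, c) += cols(oi + oj * oh, q);
          }
        }
      }
  return x;
}

typedef std::vector<cube> Batch;

enum LayerType { CONV, DWCONV, PWCONV, BNORM, RELU, MAXPOOL };

struct Layer {
  LayerType type;
  int k = 1, s = 1;
  bool has_bias = false;
  // parameters (interpretation depends on type)
  mat W;       // CONV: (k*k*M, N); DW: (k*k, M); PW: (M, N)
  vec b;       // bias (CONV/PW when no BN)
  vec gamma, beta, rmean, rvar;  // BNORM
  // gradients
  mat dW; vec db, dgamma, dbeta;
  // caches
  Batch in_cache;
  std::vector<mat> col_cache;
  std::vector<umat> pool_idx;   // argmax linear indices per sample
  Batch xhat_cache;
  vec bn_std;
  int in_h = 0, in_w = 0, in_c = 0;
  Geom g;
};

Layer make_conv(int k, int s, int M, int N, bool bias) {
  Layer l; l.type = CONV; l.k = k; l.s = s; l.has_bias = bias;
  l.W.set_size(k * k * M, N); if (bias) l.b.zeros(N);
  return l;
}
Layer make_dw(int k, int M) {
  Layer l; l.type = DWCONV; l.k = k; l.s = 1;
  l.W.set_size(k * k, M);
  return l;
}
Layer make_pw(int M, int N, bool bias) {
  Layer l; l.type = PWCONV; l.has_bias = bias;
  l.W.set_size(M, N); if (bias) l.b.zeros(N);
  return l;
}
Layer make_bn(int C) {
  Layer l; l.type = BNORM;
  l.gamma.ones(C); l.beta.zeros(C); l.rmean.zeros(C); l.rvar.ones(C);
  return l;
}
Layer make_relu() { Layer l; l.type = RELU; return l; }
Layer make_pool() { Layer l; l.type = MAXPOOL; l.k = 3; l.s = 2; return l; }

const double BN_MOMENTUM = 0.9;
const double BN_EPS = 1e-5;

// Magnitudes below this carry no information for learning but, once
// subnormal, make BLAS kernels orders of magnitude slower (the BLAS worker
// thread does not inherit the engine's flush-to-zero mode). Scrubbing the
// tensors that feed the big matrix products keeps training time flat.
const double TINY = 1e-30;

Batch layer_forward(Layer& l, const Batch& x, bool training) {
  const int n = x.size();
  Batch out(n);
  l.in_h = x[0].n_rows; l.in_w = x[0].n_cols; l.in_c = x[0].n_slices;
  switch (l.type) {
  case CONV: {
    const int M = l.in_c, N = l.W.n_cols;
    if ((int)l.W.n_rows != l.k * l.k * M) Rcpp::stop("conv weight shape mismatch");
    l.g = same_geom(l.in_h, l.k, l.s);
    if (l.g.oh < 1) Rcpp::stop("input smaller than total downsampling factor");
    l.col_cache.assign(n, mat());
    for (int i = 0; i < n; ++i) {
      l.col_cache[i] = im2col(x[i], l.k, l.s, l.g.pad, l.g.oh, l.g.ow);
      mat o = l.col_cache[i] * l.W;
      if (l.has_bias) o.each_row() += l.b.t();
      out[i] = cube(o.memptr(), l.g.oh, l.g.ow, N);
    }
    break;
  }
  case DWCONV: {
    const int M = l.in_c;
    l.g = same_geom(l.in_h, l.k, 1);
    l.in_cache = x;
    for (int i = 0; i < n; ++i) {
      cube o(l.g.oh, l.g.ow, M);
      for (int c = 0; c < M; ++c) {
        cube xc(const_cast<double*>(x[i].slice(c).memptr()),
                l.in_h, l.in_w, 1, false);
        mat cols = im2col(xc, l.k, 1, l.g.pad, l.g.oh, l.g.ow);
        vec oc = cols * l.W.col(c);
        o.slice(c) = reshape(mat(oc), l.g.oh, l.g.ow);
      }
      out[i] = o;
    }
    break;
  }
  case PWCONV: {
    const int M = l.in_c, N = l.W.n_cols;
    if ((int)l.W.n_rows != M) Rcpp::stop("pointwise weight shape mismatch");
    l.in_cache = x;
    for (int i = 0; i < n; ++i) {
      mat xm(const_cast<double*>(x[i].memptr()), l.in_h * l.in_w, M, false);
      mat o = xm * l.W;
      if (l.has_bias) o.each_row() += l.b.t();
      out[i] = cube(o.memptr(), l.in_h, l.in_w, N);
    }
    break;
  }
  case BNORM: {
    const int C = l.in_c;
    const double m_total = (double)n * l.in_h * l.in_w;
    vec mu(C), var(C);
    if (training) {
      for (int c = 0; c < C; ++c) {
        double s1 = 0, s2 = 0;
        for (int i = 0; i < n; ++i) {
          s1 += accu(x[i].slice(c));
          s2 += accu(square(x[i].slice(c)));
        }
        mu(c) = s1 / m_total;
        var(c) = s2 / m_total - mu(c) * mu(c);
      }
      l.rmean = BN_MOMENTUM * l.rmean + (1 - BN_MOMENTUM) * mu;
      l.rvar  = BN_MOMENTUM * l.rvar  + (1 - BN_MOMENTUM) * var;
    } else { mu = l.rmean; var = l.rvar; }
    l.bn_std = sqrt(var + BN_EPS);
    l.xhat_cache.assign(n, cube());
    for (int i = 0; i < n; ++i) {
      cube xh = x[i];
      for (int c = 0; c < C; ++c)
        xh.slice(c) = (x[i].slice(c) - mu(c)) / l.bn_std(c);
      l.xhat_cache[i] = xh;
      cube o = xh;
      for (int c = 0; c < C; ++c)
        o.slice(c) = xh.slice(c) * l.gamma(c) + l.beta(c);
      out[i] = o;
    }
    break;
  }
  case RELU: {
    l.in_cache = x;
    for (int i = 0; i < n; ++i) out[i] = max(x[i], zeros<cube>(size(x[i])));
    break;
  }
  case MAXPOOL: {
    l.g = same_geom(l.in_h, l.k, l.s);
    if (l.g.oh < 1) Rcpp::stop("input smaller than total downsampling factor");
    const int C = l.in_c;
    l.pool_idx.assign(n, umat());
    for (int i = 0; i < n; ++i) {
      cube o(l.g.oh, l.g.ow, C);
      umat idx(l.g.oh * l.g.ow, C);
      for (int c = 0; c < C; ++c)
        for (int oj = 0; oj < l.g.ow; ++oj)
          for (int oi = 0; oi < l.g.oh; ++oi) {
            double best = -datum::inf; uword bi = 0;
            for (int kj = 0; kj < l.k; ++kj) {
              int j = oj * l.s - l.g.pad + kj;
              if (j < 0 || j >= l.in_w) continue;
              for (int ki = 0; ki < l.k; ++ki) {
                int ii = oi * l.s - l.g.pad + ki;
                if (ii < 0 || ii >= l.in_h) continue;
                double v = x[i](ii, j, c);
                if (v > best) { best = v; bi = ii + (uword)j * l.in_h; }
              }
            }
            o(oi, oj, c) = best;
            idx(oi + oj * l.g.oh, c) = bi;
          }
      out[i] = o;
      l.pool_idx[i] = idx;
    }
    break;
  }
  }
  return out;
}

Batch layer_backward(Layer& l, const Batch& dout) {
  const int n = dout.size();
  Batch dx(n);
  switch (l.type) {
  case CONV: {
    const int N = l.W.n_cols;
    l.dW.zeros(l.W.n_rows, N);
    if (l.has_bias) l.db.zeros(N);
    for (int i = 0; i < n; ++i) {
      mat dmat(const_cast<double*>(dout[i].memptr()), l.g.oh * l.g.ow, N, false);
      l.dW += l.col_cache[i].t() * dmat;
      if (l.has_bias) l.db += sum(dmat, 0).t();
      mat dcols = dmat * l.W.t();
      dx[i] = col2im(dcols, l.in_h, l.in_w, l.in_c, l.k, l.s, l.g.pad,
                     l.g.oh, l.g.ow);
    }
    break;
  }
  case DWCONV: {
    const int M = l.in_c;
    l.dW.zeros(l.k * l.k, M);
    for (int i = 0; i < n; ++i) {
      cube d(l.in_h, l.in_w, M, fill::zeros);
      for (int c = 0; c < M; ++c) {
        cube xc(const_cast<double*>(l.in_cache[i].slice(c).memptr()),
                l.in_h, l.in_w, 1, false);
        mat cols = im2col(xc, l.k, 1, l.g.pad, l.g.oh, l.g.ow);
        vec dvec = vectorise(dout[i].slice(c));
        l.dW.col(c) += cols.t() * dvec;
        mat dcols = dvec * l.W.col(c).t();
        cube dc = col2im(dcols, l.in_h, l.in_w, 1, l.k, 1, l.g.pad,
                         l.g.oh, l.g.ow);
        d.slice(c) = dc.slice(0);
      }
      dx[i] = d;
    }
    break;
  }
  case PWCONV: {
    const int M = l.W.n_rows, N = l.W.n_cols;
    l.dW.zeros(M, N);
    if (l.has_bias) l.db.zeros(N);
    for (int i = 0; i < n; ++i) {
      mat xm(const_cast<double*>(l.in_cache[i].memptr()), l.in_h * l.in_w, M, false);
      mat dmat(const_cast<double*>(dout[i].memptr()), l.in_h * l.in_w, N, false);
      l.dW += xm.t() * dmat;
      if (l.has_bias) l.db += sum(dmat, 0).t();
      mat dxm = dmat * l.W.t();
      dx[i] = cube(dxm.memptr(), l.in_h, l.in_w, M);
    }
    break;
  }
  case BNORM: {
    const int C = l.in_c;
    const double m_total = (double)n * l.in_h * l.in_w;
    l.dgamma.zeros(C); l.dbeta.zeros(C);
    vec sum_dxhat(C, fill::zeros), sum_dxhat_xhat(C, fill::zeros);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < C; ++c) {
        const mat& do_ = dout[i].slice(c);
        const mat& xh = l.xhat_cache[i].slice(c);
        l.dgamma(c) += accu(do_ % xh);
        l.dbeta(c) += accu(do_);
        sum_dxhat(c) += accu(do_) * l.gamma(c);
        sum_dxhat_xhat(c) += accu(do_ % xh) * l.gamma(c);
      }
    for (int i = 0; i < n; ++i) {
      cube d(l.in_h, l.in_w, C);
      for (int c = 0; c < C; ++c) {
        mat dxhat = dout[i].slice(c) * l.gamma(c);
        d.slice(c) = (m_total * dxhat - sum_dxhat(c)
                      - l.xhat_cache[i].slice(c) * sum_dxhat_xhat(c))
                     / (m_total * l.bn_std(c));
      }
      dx[i] = d;
    }
    break;
  }
  case RELU: {
    for (int i = 0; i < n; ++i)
      dx[i] = dout[i] % conv_to<cube>::from(l.in_cache[i] > 0);
    break;
  }
  case MAXPOOL: {
    const int C = l.in_c;
    for (int i = 0; i < n; ++i) {
      cube d(l.in_h, l.in_w, C, fill::zeros);
      for (int c = 0; c < C; ++c) {
        double* dsl = d.slice(c).memptr();
        for (int r = 0; r < (int)l.pool_idx[i].n_rows; ++r)
          dsl[l.pool_idx[i](r, c)] +=
            dout[i](r % dout[i].n_rows, r / dout[i].n_rows, c);
      }
      dx[i] = d;
    }
    break;
  }
  }
  return dx;
}

// A block is a plain layer sequence or a residual unit (main + shortcut).
struct Block {
  std::vector<Layer> main;
  std::vector<Layer> shortcut;  // empty => identity when residual
  bool residual = false;
  Batch in_cache;               // only for residual identity backward
};

struct Net {
  std::vector<Block> blocks;
  mat denseW; vec denseb;
  mat ddenseW; vec ddenseb;
  int n_classes = 4;
  int gap_h = 0, gap_w = 0, gap_c = 0;
};

void push_sep(std::vector<Layer>& v, int M, int N, bool bn) {
  v.push_back(make_dw(3, M));
  v.push_back(make_pw(M, N, !bn));
  if (bn) v.push_back(make_bn(N));
}

Net build_net(const Rcpp::List& cfg) {
  Net net;
  Rcpp::IntegerVector input = cfg["input_size"];
  int C = input[2];
  std::vector<int> stem = Rcpp::as<std::vector<int> >(cfg["stem_widths"]);
  std::vector<int> entry = Rcpp::as<std::vector<int> >(cfg["entry_widths"]);
  int mid_blocks = Rcpp::as<int>(cfg["middle_blocks"]);
  int mid_w = Rcpp::as<int>(cfg["middle_width"]);
  std::vector<int> exitw = Rcpp::as<std::vector<int> >(cfg["exit_widths"]);
  bool bn = Rcpp::as<bool>(cfg["use_batch_normalization"]);
  net.n_classes = Rcpp::as<int>(cfg["n_classes"]);
  if (stem.size() != 2) Rcpp::stop("stem_widths must have length 2");

  // stem: two standard 3x3 convolutions, the first with stride 2
  Block stemb;
  stemb.main.push_back(make_conv(3, 2, C, stem[0], !bn));
  if (bn) stemb.main.push_back(make_bn(stem[0]));
  stemb.main.push_back(make_relu());
  stemb.main.push_back(make_conv(3, 1, stem[0], stem[1], !bn));
  if (bn) stemb.main.push_back(make_bn(stem[1]));
  stemb.main.push_back(make_relu());
  net.blocks.push_back(stemb);
  int cur = stem[1];

  // entry flow: downsampling residual blocks with 1x1 stride-2 shortcuts
  for (size_t i = 0; i < entry.size(); ++i) {
    Block b; b.residual = true;
    if (i > 0) b.main.push_back(make_relu());
    push_sep(b.main, cur, entry[i], bn);
    b.main.push_back(make_relu());
    push_sep(b.main, entry[i], entry[i], bn);
    b.main.push_back(make_pool());
    b.shortcut.push_back(make_conv(1, 2, cur, entry[i], !bn));
    if (bn) b.shortcut.push_back(make_bn(entry[i]));
    net.blocks.push_back(b);
    cur = entry[i];
  }

  // optional transition into the middle width
  if (mid_w != cur) {
    Block t;
    t.main.push_back(make_relu());
    t.main.push_back(make_pw(cur, mid_w, !bn));
    if (bn) t.main.push_back(make_bn(mid_w));
    net.blocks.push_back(t);
    cur = mid_w;
  }

  // middle flow: identity-shortcut residual blocks of three separable convs
  for (int m = 0; m < mid_blocks; ++m) {
    Block b; b.residual = true;
    for (int r = 0; r < 3; ++r) {
      b.main.push_back(make_relu());
      push_sep(b.main, cur, cur, bn);
    }
    net.blocks.push_back(b);
  }

  // exit flow: separable convolutions
  Block e;
  for (size_t i = 0; i < exitw.size(); ++i) {
    e.main.push_back(make_relu());
    push_sep(e.main, cur, exitw[i], bn);
    cur = exitw[i];
  }
  e.main.push_back(make_relu());
  net.blocks.push_back(e);

  net.denseW.set_size(cur, net.n_classes);
  net.denseb.zeros(net.n_classes);
  return net;
}

// --- canonical weight (de)serialization -------------------------------

void collect_arrays(std::vector<Layer>& layers, const std::string& prefix,
                    std::vector<std::pair<std::string, Layer*> >& out) {
  for (size_t i = 0; i < layers.size(); ++i) {
    char buf[64];
    snprintf(buf, sizeof(buf), "%s_l%02d", prefix.c_str(), (int)i);
    out.push_back(std::make_pair(std::string(buf), &layers[i]));
  }
}

std::vector<std::pair<std::string, Layer*> > all_layers(Net& net) {
  std::vector<std::pair<std::string, Layer*> > out;
  for (size_t b = 0; b < net.blocks.size(); ++b) {
    char buf[32];
    snprintf(buf, sizeof(buf), "b%02d_main", (int)b);
    collect_arrays(net.blocks[b].main, buf, out);
    snprintf(buf, sizeof(buf), "b%02d_short", (int)b);
    collect_arrays(net.blocks[b].shortcut, buf, out);
  }
  return out;
}

Rcpp::List dump_weights(Net& net) {
  Rcpp::List out;
  std::vector<std::pair<std::string, Layer*> > ls = all_layers(net);
  for (size_t i = 0; i < ls.size(); ++i) {
    Layer* l = ls[i].second;
    const std::string& nm = ls[i].first;
    switch (l->type) {
    case CONV:
      out[nm + "_convW"] = l->W;
      if (l->has_bias) out[nm + "_convb"] = l->b;
      break;
    case DWCONV: out[nm + "_dwW"] = l->W; break;
    case PWCONV:
      out[nm + "_pwW"] = l->W;
      if (l->has_bias) out[nm + "_pwb"] = l->b;
      break;
    case BNORM:
      out[nm + "_bngamma"] = l->gamma;
      out[nm + "_bnbeta"] = l->beta;
      out[nm + "_bnrmean"] = l->rmean;
      out[nm + "_bnrvar"] = l->rvar;
      break;
    default: break;
    }
  }
  out["dense_W"] = net.denseW;
  out["dense_b"] = net.denseb;
  return out;
}

void load_weights(Net& net, const Rcpp::List& w) {
  std::vector<std::pair<std::string, Layer*> > ls = all_layers(net);
  for (size_t i = 0; i < ls.size(); ++i) {
    Layer* l = ls[i].second;
    const std::string& nm = ls[i].first;
    switch (l->type) {
    case CONV: {
      mat W = Rcpp::as<mat>(w[nm + "_convW"]);
      if (W.n_rows != l->W.n_rows || W.n_cols != l->W.n_cols)
        Rcpp::stop("weight shape mismatch at %s", nm.c_str());
      l->W = W;
      if (l->has_bias) l->b = Rcpp::as<vec>(w[nm + "_convb"]);
      break;
    }
    case DWCONV: l->W = Rcpp::as<mat>(w[nm + "_dwW"]); break;
    case PWCONV:
      l->W = Rcpp::as<mat>(w[nm + "_pwW"]);
      if (l->has_bias) l->b = Rcpp::as<vec>(w[nm + "_pwb"]);
      break;
    case BNORM:
      l->gamma = Rcpp::as<vec>(w[nm + "_bngamma"]);
      l->beta = Rcpp::as<vec>(w[nm + "_bnbeta"]);
      l->rmean = Rcpp::as<vec>(w[nm + "_bnrmean"]);
      l->rvar = Rcpp::as<vec>(w[nm + "_bnrvar"]);
      break;
    default: break;
    }
  }
  net.denseW = Rcpp::as<mat>(w["dense_W"]);
  net.denseb = Rcpp::as<vec>(w["dense_b"]);
}

// --- network forward / backward ---------------------------------------

Batch seq_forward(std::vector<Layer>& layers, Batch x, bool training) {
  for (size_t i = 0; i < layers.size(); ++i)
    x = layer_forward(layers[i], x, training);
  return x;
}
Batch seq_backward(std::vector<Layer>& layers, Batch d) {
  for (int i = (int)layers.size() - 1; i >= 0; --i)
    d = layer_backward(layers[i], d);
  return d;
}

// forward to logits; activations cached inside layers for backward
mat net_forward(Net& net, Batch x, bool training) {
  for (size_t b = 0; b < net.blocks.size(); ++b) {
    Block& blk = net.blocks[b];
    if (!blk.residual) {
      x = seq_forward(blk.main, x, training);
    } else {
      Batch m = seq_forward(blk.main, x, training);
      Batch s = blk.shortcut.empty()
        ? x : seq_forward(blk.shortcut, x, training);
      for (size_t i = 0; i < x.size(); ++i) m[i] += s[i];
      x = m;
    }
    for (size_t i = 0; i < x.size(); ++i) x[i].clean(TINY);
  }
  const int n = x.size();
  net.gap_h = x[0].n_rows; net.gap_w = x[0].n_cols; net.gap_c = x[0].n_slices;
  mat feats(n, net.gap_c);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < net.gap_c; ++c)
      feats(i, c) = accu(x[i].slice(c)) / (net.gap_h * net.gap_w);
  mat logits = feats * net.denseW;
  logits.each_row() += net.denseb.t();
  net.ddenseW = feats;  // stash activations; net_backward replaces with grad
  return logits;
}

Batch net_backward(Net& net, const mat& dlogits) {
  const int n = dlogits.n_rows;
  mat feats = net.ddenseW;          // stashed activations
  net.ddenseW = feats.t() * dlogits;
  net.ddenseb = sum(dlogits, 0).t();
  mat dfeats = dlogits * net.denseW.t();
  Batch d(n);
  for (int i = 0; i < n; ++i) {
    cube g(net.gap_h, net.gap_w, net.gap_c);
    for (int c = 0; c < net.gap_c; ++c)
      g.slice(c).fill(dfeats(i, c) / (net.gap_h * net.gap_w));
    d[i] = g;
  }
  for (int b = (int)net.blocks.size() - 1; b >= 0; --b) {
    Block& blk = net.blocks[b];
    if (!blk.residual) {
      d = seq_backward(blk.main, d);
    } else {
      Batch dm = seq_backward(blk.main, d);
      Batch ds = blk.shortcut.empty() ? d : seq_backward(blk.shortcut, d);
      for (size_t i = 0; i < dm.size(); ++i) dm[i] += ds[i];
      d = dm;
    }
    for (size_t i = 0; i < d.size(); ++i) d[i].clean(TINY);
  }
  return d;
}

// --- SGD with momentum -------------------------------------------------

struct ParamRef { mat* W; mat* G; };

void collect_params(Net& net, std::vector<ParamRef>& prefs,
                    std::vector<std::pair<vec*, vec*> >& vrefs) {
  std::vector<std::pair<std::string, Layer*> > ls = all_layers(net);
  for (size_t i = 0; i < ls.size(); ++i) {
    Layer* l = ls[i].second;
    switch (l->type) {
    case CONV: case DWCONV: case PWCONV: {
      ParamRef p; p.W = &l->W; p.G = &l->dW; prefs.push_back(p);
      if (l->has_bias) vrefs.push_back(std::make_pair(&l->b, &l->db));
      break;
    }
    case BNORM:
      vrefs.push_back(std::make_pair(&l->gamma, &l->dgamma));
      vrefs.push_back(std::make_pair(&l->beta, &l->dbeta));
      break;
    default: break;
    }
  }
}

Batch slice_input(const cube& X_flat, int H, int W, int C,
                  const std::vector<int>& idx) {
  // X_flat: (H, W, C*N) stacking; sample i occupies slices [i*C, (i+1)*C)
  Batch out(idx.size());
  for (size_t i = 0; i < idx.size(); ++i)
    out[i] = X_flat.slices(idx[i] * C, (idx[i] + 1) * C - 1);
  return out;
}

mat softmax_rows(const mat& logits) {
  mat p = logits;
  for (uword i = 0; i < p.n_rows; ++i) {
    rowvec r = p.row(i) - p.row(i).max();
    r = exp(r);
    p.row(i) = r / accu(r);
  }
  return p;
}

struct EvalResult { double accuracy; double loss; };

EvalResult eval_metrics(Net& net, const cube& X, int H, int W, int C,
                        const Rcpp::IntegerVector& y,
                        const std::vector<int>& idx, int batch) {
  int correct = 0;
  double loss = 0;
  for (size_t start = 0; start < idx.size(); start += batch) {
    std::vector<int> b(idx.begin() + start,
                       idx.begin() + std::min(start + batch, idx.size()));
    mat logits = net_forward(net, slice_input(X, H, W, C, b), false);
    mat p = softmax_rows(logits);
    for (size_t i = 0; i < b.size(); ++i) {
      loss -= std::log(std::max(p(i, y[b[i]]), 1e-12));
      // ties broken toward the lowest class index
      double mx = logits.row(i).max();
      uword pred = 0;
      for (uword k = 0; k < logits.n_cols; ++k)
        if (logits(i, k) == mx) { pred = k; break; }
      if ((int)pred == y[b[i]]) ++correct;
    }
  }
  EvalResult r;
  r.accuracy = idx.empty() ? 0.0 : (double)correct / idx.size();
  r.loss = idx.empty() ? 0.0 : loss / idx.size();
  return r;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_weight_template(Rcpp::List cfg) {
  flush_denormals();
  Net net = build_net(cfg);
  return dump_weights(net);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_predict(Rcpp::List cfg, Rcpp::List weights,
                                Rcpp::NumericVector X) {
  flush_denormals();
  Net net = build_net(cfg);
  load_weights(net, weights);
  Rcpp::IntegerVector dims = X.attr("dim");
  if (dims.size() != 4) Rcpp::stop("X must be an H x W x C x N array");
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  cube Xc(X.begin(), H, W, C * N, false);
  Rcpp::NumericMatrix out(N, net.n_classes);
  const int batch = 16;
  for (int start = 0; start < N; start += batch) {
    std::vector<int> idx;
    for (int i = start; i < std::min(start + batch, N); ++i) idx.push_back(i);
    mat logits = net_forward(net, slice_input(Xc, H, W, C, idx), false);
    mat p = softmax_rows(logits);
    for (size_t i = 0; i < idx.size(); ++i)
      for (int k = 0; k < net.n_classes; ++k) out(idx[i], k) = p(i, k);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_train(Rcpp::List cfg, Rcpp::List weights, Rcpp::NumericVector X,
                     Rcpp::IntegerVector y, Rcpp::IntegerVector train_idx,
                     Rcpp::IntegerVector val_idx, Rcpp::List hyper) {
  flush_denormals();
  Net net = build_net(cfg);
  load_weights(net, weights);
  Rcpp::IntegerVector dims = X.attr("dim");
  if (dims.size() != 4) Rcpp::stop("X must be an H x W x C x N array");
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  cube Xc(X.begin(), H, W, C * N, false);
  if (y.size() != N) Rcpp::stop("labels do not match image count");
  if (train_idx.size() == 0) Rcpp::stop("empty training fold");

  double lr = Rcpp::as<double>(hyper["learning_rate"]);
  double mom = Rcpp::as<double>(hyper["momentum"]);
  int batch = Rcpp::as<int>(hyper["batch_size"]);
  int epochs = Rcpp::as<int>(hyper["epochs"]);
  int patience = Rcpp::as<int>(hyper["early_stop_patience"]);
  int seed = Rcpp::as<int>(hyper["seed"]);
  bool verbose = Rcpp::as<bool>(hyper["verbose"]);
  int snapshot_k = hyper.containsElementNamed("snapshot_k")
    ? Rcpp::as<int>(hyper["snapshot_k"]) : 0;

  std::vector<int> tr(train_idx.begin(), train_idx.end());
  std::vector<int> va(val_idx.begin(), val_idx.end());

  std::vector<ParamRef> prefs;
  std::vector<std::pair<vec*, vec*> > vrefs;
  collect_params(net, prefs, vrefs);
  { ParamRef p; p.W = &net.denseW; p.G = &net.ddenseW; prefs.push_back(p); }
  vrefs.push_back(std::make_pair(&net.denseb, &net.ddenseb));
  std::vector<mat> vel(prefs.size());
  std::vector<vec> velv(vrefs.size());
  for (size_t i = 0; i < prefs.size(); ++i) vel[i].zeros(size(*prefs[i].W));
  for (size_t i = 0; i < vrefs.size(); ++i) velv[i].zeros(vrefs[i].first->n_elem);

  Rcpp::NumericVector h_loss, h_tracc, h_valacc, h_valloss;
  // early stopping monitors validation cross-entropy: it keeps improving
  // after accuracy saturates, so the kept weights are the best-calibrated
  // epoch, never one past the plateau
  double best_val_loss = datum::inf, best_val_acc = 0;
  int best_epoch = -1, stale = 0, stopped = epochs;
  Rcpp::List best_weights = dump_weights(net);
  std::vector<Rcpp::List> snaps;   // weight snapshots of the last snapshot_k epochs

  for (int ep = 0; ep < epochs; ++ep) {
    std::mt19937 rng(seed + ep * 9973);
    std::shuffle(tr.begin(), tr.end(), rng);   // shuffle training set only
    double ep_loss = 0; int nb = 0;
    for (size_t start = 0; start < tr.size(); start += batch) {
      std::vector<int> b(tr.begin() + start,
                         tr.begin() + std::min(start + batch, tr.size()));
      mat logits = net_forward(net, slice_input(Xc, H, W, C, b), true);
      mat p = softmax_rows(logits);
      double loss = 0;
      mat dlogits = p;
      for (size_t i = 0; i < b.size(); ++i) {
        loss -= std::log(std::max(p(i, y[b[i]]), 1e-12));
        dlogits(i, y[b[i]]) -= 1.0;
      }
      loss /= b.size();
      dlogits /= (double)b.size();
      if (!std::isfinite(loss))
        Rcpp::stop("non-finite training loss at epoch %d (diverged; lower the learning rate)", ep + 1);
      ep_loss += loss; ++nb;
      net_backward(net, dlogits);
      for (size_t i = 0; i < prefs.size(); ++i) {
        vel[i] = mom * vel[i] - lr * (*prefs[i].G);
        vel[i].clean(TINY);
        *prefs[i].W += vel[i];
        prefs[i].W->clean(TINY);
      }
      for (size_t i = 0; i < vrefs.size(); ++i) {
        velv[i] = mom * velv[i] - lr * (*vrefs[i].second);
        velv[i].clean(TINY);
        *vrefs[i].first += velv[i];
        vrefs[i].first->clean(TINY);
      }
    }
    EvalResult trm = eval_metrics(net, Xc, H, W, C, y, tr, batch);
    EvalResult vam = va.empty() ? trm : eval_metrics(net, Xc, H, W, C, y, va, batch);
    h_loss.push_back(ep_loss / nb);
    h_tracc.push_back(trm.accuracy);
    h_valacc.push_back(vam.accuracy);
    h_valloss.push_back(vam.loss);
    if (verbose)
      Rcpp::Rcout << "epoch " << (ep + 1) << " loss " << ep_loss / nb
                  << " train_acc " << trm.accuracy << " val_acc " << vam.accuracy
                  << " val_loss " << vam.loss << "\n";
    if (snapshot_k > 0) {
      snaps.push_back(dump_weights(net));
      if ((int)snaps.size() > snapshot_k) snaps.erase(snaps.begin());
    }
    if (vam.loss < best_val_loss - 1e-6) {   // min-delta: plateau-scale changes do not reset patience
      best_val_loss = vam.loss; best_val_acc = vam.accuracy;
      best_epoch = ep; stale = 0;
      best_weights = dump_weights(net);
    } else if (++stale >= patience) {
      stopped = ep + 1;
      break;
    }
    Rcpp::checkUserInterrupt();
  }

  Rcpp::List snaps_out(snaps.size());
  for (size_t i = 0; i < snaps.size(); ++i) snaps_out[i] = snaps[i];
  return Rcpp::List::create(
    Rcpp::Named("weights") = best_weights,
    Rcpp::Named("history") = Rcpp::List::create(
      Rcpp::Named("loss") = h_loss,
      Rcpp::Named("train_accuracy") = h_tracc,
      Rcpp::Named("val_accuracy") = h_valacc,
      Rcpp::Named("val_loss") = h_valloss),
    Rcpp::Named("best_epoch") = best_epoch + 1,
    Rcpp::Named("best_val_accuracy") = best_val_acc,
    Rcpp::Named("best_val_loss") = best_val_loss,
    Rcpp::Named("stopped_epoch") = stopped,
    Rcpp::Named("snapshots") = snaps_out);
}
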