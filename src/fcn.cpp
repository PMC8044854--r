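// Fully convolutional classifier: three conv->batchnorm->ReLU->dropout blocks,
// optional 2x2 max pooling after blocks 1-2, global max pooling, 2-way softmax.
// Hand-rolled forward/backward with Adam or SGD so the classifier has no
// dependency on an external deep-learning runtime. All randomness (dropout,
// batch-order shuffling) comes from a splitmix/xoshiro-style generator seeded
// from R, so training is bit-reproducible for a given seed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::uvec;

namespace {

// ---------------------------------------------------------------------------
// deterministic RNG (independent of compiler's std::distributions)
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {  // splitmix64
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

struct Params {
  std::vector<mat> W;      // conv kernels, (F_l x k*k*C_{l-1})
  std::vector<vec> gamma, beta, rmean, rvar;  // batchnorm per block
  mat Wout;                // 2 x F3
  vec bout;                // 2
  int kernel;
  bool inner_pool;
};

Params params_from_list(const List& p) {
  Params out;
  List W = p["conv_w"], g = p["bn_gamma"], b = p["bn_beta"], rm = p["bn_rmean"],
       rv = p["bn_rvar"];
  for (int l = 0; l < 3; ++l) {
    out.W.push_back(as<mat>(W[l]));
    out.gamma.push_back(as<vec>(g[l]));
    out.beta.push_back(as<vec>(b[l]));
    out.rmean.push_back(as<vec>(rm[l]));
    out.rvar.push_back(as<vec>(rv[l]));
  }
  out.Wout = as<mat>(p["out_w"]);
  out.bout = as<vec>(p["out_b"]);
  out.kernel = as<int>(p["kernel"]);
  out.inner_pool = as<bool>(p["inner_pool"]);
  return out;
}

List params_to_list(const Params& p) {
  return List::create(
      _["conv_w"] = List::create(p.W[0], p.W[1], p.W[2]),
      _["bn_gamma"] = List::create(p.gamma[0], p.gamma[1], p.gamma[2]),
      _["bn_beta"] = List::create(p.beta[0], p.beta[1], p.beta[2]),
      _["bn_rmean"] = List::create(p.rmean[0], p.rmean[1], p.rmean[2]),
      _["bn_rvar"] = List::create(p.rvar[0], p.rvar[1], p.rvar[2]),
      _["out_w"] = p.Wout, _["out_b"] = p.bout, _["kernel"] = p.kernel,
      _["inner_pool"] = p.inner_pool);
}

// batch stored as vector of cubes (H x W x C), one per sample
typedef std::vector<cube> Batch;

Batch batch_from_array(const NumericVector& a) {
  IntegerVector d = a.attr("dim");
  if (d.size() != 4) stop("batch array must be h x w x ch x n");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  Batch b;
  b.reserve(N);
  const double* ptr = a.begin();
  size_t stride = (size_t)H * W * C;
  for (int i = 0; i < N; ++i) {
    cube x(ptr + i * stride, H, W, C);  // copies
    b.push_back(std::move(x));
  }
  return b;
}

// im2col with 'same' zero padding: out (k*k*C x H*W), column = pixel (col-major)
void im2col(const cube& x, int k, mat& out) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices, k2 = k / 2;
  out.set_size((size_t)k * k * C, (size_t)H * W);
  out.zeros();
  mat sh(H, W);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int dw = -k2; dw <= k2; ++dw) {
      for (int dh = -k2; dh <= k2; ++dh) {
        int r = c * k * k + (dw + k2) * k + (dh + k2);
        sh.zeros();
        int h0 = std::max(0, -dh), h1 = std::min(H - 1, H - 1 - dh);
        int w0 = std::max(0, -dw), w1 = std::min(W - 1, W - 1 - dw);
        if (h0 <= h1 && w0 <= w1)
          sh.submat(h0, w0, h1, w1) = xc.submat(h0 + dh, w0 + dw, h1 + dh, w1 + dw);
        out.row(r) = arma::vectorise(sh).t();
      }
    }
  }
}

// adjoint of im2col: accumulate column gradients back onto an H x W x C cube
void col2im(const mat& dcol, int k, int H, int W, int C, cube& dx) {
  dx.set_size(H, W, C);
  dx.zeros();
  int k2 = k / 2;
  for (int c = 0; c < C; ++c) {
    mat& dc = dx.slice(c);
    for (int dw = -k2; dw <= k2; ++dw) {
      for (int dh = -k2; dh <= k2; ++dh) {
        int r = c * k * k + (dw + k2) * k + (dh + k2);
        mat sh = arma::reshape(dcol.row(r), H, W);
        int h0 = std::max(0, -dh), h1 = std::min(H - 1, H - 1 - dh);
        int w0 = std::max(0, -dw), w1 = std::min(W - 1, W - 1 - dw);
        if (h0 <= h1 && w0 <= w1)
          dc.submat(h0 + dh, w0 + dw, h1 + dh, w1 + dw) += sh.submat(h0, w0, h1, w1);
      }
    }
  }
}

// 2x2 max pooling, ceil mode (all pixels participate); argmax kept for backward
void maxpool2(const cube& x, cube& y, arma::ucube& amax) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  y.set_size(Ho, Wo, C);
  amax.set_size(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        double best = -arma::datum::inf;
        arma::uword bi = 0;
        for (int dw = 0; dw < 2; ++dw)
          for (int dh = 0; dh < 2; ++dh) {
            int hh = 2 * h + dh, ww = 2 * w + dw;
            if (hh < H && ww < W && x(hh, ww, c) > best) {
              best = x(hh, ww, c);
              bi = (arma::uword)(hh + (size_t)H * ww);
            }
          }
        y(h, w, c) = best;
        amax(h, w, c) = bi;
      }
}

struct BlockCache {
  mat Xcol;        // im2col of block input
  mat Z;           // conv output (F x HW)
  vec mu, var;     // batch stats
  mat xhat;        // normalized
  mat relu_mask;   // 1 where post-BN pre-relu > 0
  mat drop_mask;   // inverted-dropout multiplier
  int H, W, Cin;
  arma::ucube pool_amax;  // if pooled
  int Hp, Wp;             // pooled dims
  bool pooled;
};

struct SampleCache {
  std::vector<BlockCache> blocks;  // 3
  uvec gmax_idx;                   // argmax per feature (global max pool)
  vec phi;                         // pooled feature vector
};

struct ForwardOut {
  mat probs;   // N x 2
  mat logits;  // N x 2
  std::vector<SampleCache> caches;
};

const double BN_EPS = 1e-5;
const double BN_MOMENTUM = 0.9;

// forward pass over one padded batch.
// training=true: batch statistics + dropout + running-stat update.
ForwardOut fcn_forward_batch(Params& p, const Batch& batch, bool training,
                             double dropout, Rng* rng, bool keep_cache) {
  int N = batch.size();
  ForwardOut out;
  out.caches.resize(keep_cache ? N : 0);
  // per-sample current activation cubes
  std::vector<cube> cur(batch);
  mat phi;  // N x F3 later
  for (int l = 0; l < 3; ++l) {
    int F = p.W[l].n_rows;
    // conv via im2col per sample, concatenated stats for BN
    std::vector<mat> Z(N), Xc(N);
    double ntot = 0;
    vec sum(F, arma::fill::zeros), sumsq(F, arma::fill::zeros);
    for (int i = 0; i < N; ++i) {
      im2col(cur[i], p.kernel, Xc[i]);
      Z[i] = p.W[l] * Xc[i];  // F x HW
      ntot += Z[i].n_cols;
      sum += arma::sum(Z[i], 1);
      sumsq += arma::sum(arma::square(Z[i]), 1);
    }
    vec mu, var;
    if (training) {
      mu = sum / ntot;
      var = sumsq / ntot - arma::square(mu);
      var.transform([](double v) { return v < 0 ? 0.0 : v; });
      p.rmean[l] = BN_MOMENTUM * p.rmean[l] + (1 - BN_MOMENTUM) * mu;
      p.rvar[l] = BN_MOMENTUM * p.rvar[l] + (1 - BN_MOMENTUM) * var;
    } else {
      mu = p.rmean[l];
      var = p.rvar[l];
    }
    vec inv_sd = 1.0 / arma::sqrt(var + BN_EPS);
    for (int i = 0; i < N; ++i) {
      int H = cur[i].n_rows, W = cur[i].n_cols, Cin = cur[i].n_slices;
      mat xhat = Z[i];
      xhat.each_col() -= mu;
      xhat.each_col() %= inv_sd;
      mat act = xhat;
      act.each_col() %= p.gamma[l];
      act.each_col() += p.beta[l];
      mat relu_mask = arma::conv_to<mat>::from(act > 0);
      act %= relu_mask;
      mat drop_mask;
      if (training && dropout > 0) {
        drop_mask.set_size(act.n_rows, act.n_cols);
        double keep = 1.0 - dropout, scale = 1.0 / keep;
        for (arma::uword j = 0; j < drop_mask.n_elem; ++j)
          drop_mask(j) = (rng->unif() < keep) ? scale : 0.0;
        act %= drop_mask;
      }
      // back to cube (H x W x F)
      cube a(H, W, F);
      for (int f = 0; f < F; ++f)
        a.slice(f) = arma::reshape(act.row(f), H, W);
      BlockCache bc;
      if (keep_cache) {
        bc.Xcol = std::move(Xc[i]);
        bc.Z = std::move(Z[i]);
        bc.mu = mu;
        bc.var = var;
        bc.xhat = std::move(xhat);
        bc.relu_mask = std::move(relu_mask);
        bc.drop_mask = std::move(drop_mask);
        bc.H = H;
        bc.W = W;
        bc.Cin = Cin;
        bc.pooled = false;
      }
      if (l < 2 && p.inner_pool && (a.n_rows > 1 || a.n_cols > 1)) {
        cube pooled;
        arma::ucube amax;
        maxpool2(a, pooled, amax);
        if (keep_cache) {
          bc.pooled = true;
          bc.pool_amax = std::move(amax);
          bc.Hp = pooled.n_rows;
          bc.Wp = pooled.n_cols;
        }
        cur[i] = std::move(pooled);
      } else {
        cur[i] = std::move(a);
      }
      if (keep_cache) out.caches[i].blocks.push_back(std::move(bc));
    }
  }
  // global max pooling + linear head
  int F3 = p.W[2].n_rows;
  phi.set_size(N, F3);
  for (int i = 0; i < N; ++i) {
    uvec idx(F3);
    for (int f = 0; f < F3; ++f) {
      arma::uword a;
      double m = cur[i].slice(f).max(a);
      phi(i, f) = m;
      idx(f) = a;
    }
    if (keep_cache) {
      out.caches[i].gmax_idx = idx;
      out.caches[i].phi = phi.row(i).t();
      // record final block spatial dims for unpooling
      out.caches[i].blocks[2].Hp = cur[i].n_rows;
      out.caches[i].blocks[2].Wp = cur[i].n_cols;
    }
  }
  mat logits = phi * p.Wout.t();
  logits.each_row() += p.bout.t();
  mat probs = logits;
  for (int i = 0; i < N; ++i) {
    double m = probs.row(i).max();
    probs.row(i) = arma::exp(probs.row(i) - m);
    probs.row(i) /= arma::accu(probs.row(i));
  }
  out.probs = std::move(probs);
  out.logits = std::move(logits);
  return out;
}

struct Grads {
  std::vector<mat> W;
  std::vector<vec> gamma, beta;
  mat Wout;
  vec bout;
  void init(const Params& p) {
    W.clear();
    gamma.clear();
    beta.clear();
    for (int l = 0; l < 3; ++l) {
      W.push_back(mat(p.W[l].n_rows, p.W[l].n_cols, arma::fill::zeros));
      gamma.push_back(vec(p.gamma[l].n_elem, arma::fill::zeros));
      beta.push_back(vec(p.beta[l].n_elem, arma::fill::zeros));
    }
    Wout = mat(p.Wout.n_rows, p.Wout.n_cols, arma::fill::zeros);
    bout = vec(p.bout.n_elem, arma::fill::zeros);
  }
};

// backward for one batch; fills grads. labels in {0,1}; weights per sample.
// Loss: sum_i w_i * CE_i / sum_i w_i
double fcn_backward_batch(Params& p, const Batch& batch, ForwardOut& fo,
                          const arma::ivec& y, const vec& w, Grads& g) {
  int N = batch.size();
  double wsum = arma::accu(w);
  double loss = 0;
  mat dlogits(N, 2);
  for (int i = 0; i < N; ++i) {
    double py = std::max(fo.probs(i, y(i)), 1e-12);
    loss += w(i) * (-std::log(py));
    dlogits.row(i) = fo.probs.row(i) * (w(i) / wsum);
    dlogits(i, y(i)) -= w(i) / wsum;
  }
  loss /= wsum;
  // head
  mat phi(N, p.W[2].n_rows);
  for (int i = 0; i < N; ++i) phi.row(i) = fo.caches[i].phi.t();
  g.Wout += dlogits.t() * phi;
  g.bout += arma::sum(dlogits, 0).t();
  mat dphi = dlogits * p.Wout;  // N x F3
  // per-sample backward through blocks
  int F3 = p.W[2].n_rows;
  // BN backward needs batch-level reductions; process block by block,
  // first computing per-sample dact (gradient w.r.t. post-dropout activation)
  // then the joint BN reduction, then conv backward producing input grads.
  // Block 3 input grads per sample:
  std::vector<mat> dact(N);  // gradient wrt activation (F x HW of that block)
  // seed from global max pooling into block-3 activation map
  for (int i = 0; i < N; ++i) {
    BlockCache& bc = fo.caches[i].blocks[2];
    int Hp = bc.Hp, Wp = bc.Wp;
    mat da(F3, (size_t)Hp * Wp, arma::fill::zeros);
    for (int f = 0; f < F3; ++f) da(f, fo.caches[i].gmax_idx(f)) = dphi(i, f);
    dact[i] = std::move(da);
  }
  for (int l = 2; l >= 0; --l) {
    int F = p.W[l].n_rows;
    // undo pooling (blocks 0,1 only)
    if (l < 2) {
      for (int i = 0; i < N; ++i) {
        BlockCache& bc = fo.caches[i].blocks[l];
        if (bc.pooled) {
          mat da(F, (size_t)bc.H * bc.W, arma::fill::zeros);
          // dact[i] currently F x (Hp*Wp)
          for (int f = 0; f < F; ++f)
            for (int j = 0; j < bc.Hp * bc.Wp; ++j) {
              int hh = j % bc.Hp, ww = j / bc.Hp;
              da(f, bc.pool_amax(hh, ww, f)) += dact[i](f, j);
            }
          dact[i] = std::move(da);
        }
      }
    }
    // dropout + relu + BN gamma/beta
    double ntot = 0;
    vec sum_dxhat(F, arma::fill::zeros), sum_dxhat_xhat(F, arma::fill::zeros);
    for (int i = 0; i < N; ++i) {
      BlockCache& bc = fo.caches[i].blocks[l];
      if (bc.drop_mask.n_elem) dact[i] %= bc.drop_mask;
      dact[i] %= bc.relu_mask;  // now grad wrt BN output
      g.gamma[l] += arma::sum(dact[i] % bc.xhat, 1);
      g.beta[l] += arma::sum(dact[i], 1);
      // grad wrt xhat
      dact[i].each_col() %= p.gamma[l];
      sum_dxhat += arma::sum(dact[i], 1);
      sum_dxhat_xhat += arma::sum(dact[i] % bc.xhat, 1);
      ntot += dact[i].n_cols;
    }
    vec inv_sd = 1.0 / arma::sqrt(fo.caches[0].blocks[l].var + BN_EPS);
    // dZ = inv_sd/N * (N*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
    std::vector<mat> dZ(N);
    for (int i = 0; i < N; ++i) {
      BlockCache& bc = fo.caches[i].blocks[l];
      mat t = dact[i] * ntot;
      t.each_col() -= sum_dxhat;
      mat t2 = bc.xhat;
      t2.each_col() %= sum_dxhat_xhat;
      t -= t2;
      t.each_col() %= inv_sd / ntot;
      dZ[i] = std::move(t);
    }
    // conv backward
    for (int i = 0; i < N; ++i) {
      BlockCache& bc = fo.caches[i].blocks[l];
      g.W[l] += dZ[i] * bc.Xcol.t();
      if (l > 0) {
        mat dXcol = p.W[l].t() * dZ[i];
        cube dx;
        col2im(dXcol, p.kernel, bc.H, bc.W, bc.Cin, dx);
        // dx is grad wrt block l input = pooled output of block l-1
        int Fprev = p.W[l - 1].n_rows;
        mat da(Fprev, (size_t)bc.H * bc.W);
        for (int f = 0; f < Fprev; ++f) da.row(f) = arma::vectorise(dx.slice(f)).t();
        dact[i] = std::move(da);
      }
    }
  }
  return loss;
}

struct AdamState {
  Grads m, v;
  long t = 0;
};

void apply_update(Params& p, Grads& g, AdamState& st, const std::string& opt,
                  double lr, double b1, double b2, double eps, double momentum) {
  st.t += 1;
  auto upd = [&](mat& w, mat& gm, mat& mm, mat& vm) {
    if (opt == "adam") {
      mm = b1 * mm + (1 - b1) * gm;
      vm = b2 * vm + (1 - b2) * (gm % gm);
      mat mhat = mm / (1 - std::pow(b1, (double)st.t));
      mat vhat = vm / (1 - std::pow(b2, (double)st.t));
      w -= lr * mhat / (arma::sqrt(vhat) + eps);
    } else {  // sgd
      mm = momentum * mm + gm;
      w -= lr * mm;
    }
  };
  auto updv = [&](vec& w, vec& gv, vec& mv, vec& vv) {
    if (opt == "adam") {
      mv = b1 * mv + (1 - b1) * gv;
      vv = b2 * vv + (1 - b2) * (gv % gv);
      vec mhat = mv / (1 - std::pow(b1, (double)st.t));
      vec vhat = vv / (1 - std::pow(b2, (double)st.t));
      w -= lr * mhat / (arma::sqrt(vhat) + eps);
    } else {
      mv = momentum * mv + gv;
      w -= lr * mv;
    }
  };
  for (int l = 0; l < 3; ++l) {
    upd(p.W[l], g.W[l], st.m.W[l], st.v.W[l]);
    updv(p.gamma[l], g.gamma[l], st.m.gamma[l], st.v.gamma[l]);
    updv(p.beta[l], g.beta[l], st.m.beta[l], st.v.beta[l]);
  }
  upd(p.Wout, g.Wout, st.m.Wout, st.v.Wout);
  updv(p.bout, g.bout, st.m.bout, st.v.bout);
}

// evaluation: loss + accuracy over batches (eval mode)
void eval_batches(Params& p, const std::vector<Batch>& bx,
                  const std::vector<arma::ivec>& by, const std::vector<vec>& bw,
                  double& loss, double& acc) {
  double lsum = 0, wsum = 0;
  long ncorrect = 0, n = 0;
  for (size_t b = 0; b < bx.size(); ++b) {
    ForwardOut fo = fcn_forward_batch(p, bx[b], false, 0.0, nullptr, false);
    for (arma::uword i = 0; i < fo.probs.n_rows; ++i) {
      double py = std::max(fo.probs(i, by[b](i)), 1e-12);
      lsum += bw[b](i) * (-std::log(py));
      wsum += bw[b](i);
      int pred = fo.probs(i, 1) > fo.probs(i, 0) ? 1 : 0;
      if (pred == by[b](i)) ++ncorrect;
      ++n;
    }
  }
  loss = lsum / wsum;
  acc = (double)ncorrect / (double)n;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_fcn_forward(List params, List batches) {
  Params p = params_from_list(params);
  std::vector<mat> outs;
  long n = 0;
  for (int b = 0; b < batches.size(); ++b) {
    Batch bb = batch_from_array(batches[b]);
    ForwardOut fo = fcn_forward_batch(p, bb, false, 0.0, nullptr, false);
    n += fo.probs.n_rows;
    outs.push_back(fo.probs);
  }
  NumericMatrix res(n, 2);
  long r = 0;
  for (auto& m : outs)
    for (arma::uword i = 0; i < m.n_rows; ++i, ++r) {
      res(r, 0) = m(i, 0);
      res(r, 1) = m(i, 1);
    }
  return res;
}

// train_x: list of per-sample h x w x c arrays; batches are re-drawn from a
// fresh seeded shuffle every epoch and zero-padded to the largest height and
// width within each batch (content anchored top-left).
// [[Rcpp::export]]
List cpp_fcn_train(List params, List train_x, IntegerVector train_y,
                   NumericVector train_w, int batch_size, List eval_x,
                   List eval_y, List eval_w, List opts) {
  Params p = params_from_list(params);
  int epochs = as<int>(opts["epochs"]);
  std::string optimizer = as<std::string>(opts["optimizer"]);
  double lr = as<double>(opts["learning_rate"]);
  double b1 = as<double>(opts["beta1"]), b2 = as<double>(opts["beta2"]);
  double eps = as<double>(opts["epsilon"]);
  double momentum = as<double>(opts["momentum"]);
  double dropout = as<double>(opts["dropout"]);
  uint64_t seed = (uint64_t)as<double>(opts["seed"]);
  Rng rng(seed);

  int ntr = train_x.size();
  std::vector<cube> samples(ntr);
  for (int i = 0; i < ntr; ++i) {
    NumericVector a = train_x[i];
    IntegerVector d = a.attr("dim");
    if (d.size() != 3) stop("each training crop must be h x w x ch");
    samples[i] = cube(a.begin(), d[0], d[1], d[2]);
  }
  arma::ivec y_all = as<arma::ivec>(train_y);
  vec w_all = as<vec>(train_w);

  int ne = eval_x.size();
  std::vector<Batch> ex(ne);
  std::vector<arma::ivec> ey(ne);
  std::vector<vec> ew(ne);
  for (int b = 0; b < ne; ++b) {
    ex[b] = batch_from_array(eval_x[b]);
    ey[b] = as<arma::ivec>(eval_y[b]);
    ew[b] = as<vec>(eval_w[b]);
  }

  AdamState st;
  st.m.init(p);
  st.v.init(p);
  mat history(epochs, 4);
  Params best = p;
  double best_loss = arma::datum::inf;
  int best_epoch = 0;
  std::vector<int> order(ntr);
  for (int i = 0; i < ntr; ++i) order[i] = i;

  for (int e = 0; e < epochs; ++e) {
    // fresh sample shuffle, hence fresh batch composition, every epoch
    for (int i = ntr - 1; i > 0; --i) std::swap(order[i], order[rng.below(i + 1)]);
    double lsum = 0, wsum = 0;
    long ncorrect = 0, n = 0;
    Grads g;
    for (int s = 0; s < ntr; s += batch_size) {
      int bn = std::min(batch_size, ntr - s);
      int H = 0, W = 0, C = samples[order[s]].n_slices;
      for (int i = 0; i < bn; ++i) {
        H = std::max(H, (int)samples[order[s + i]].n_rows);
        W = std::max(W, (int)samples[order[s + i]].n_cols);
      }
      Batch bx(bn);
      arma::ivec by(bn);
      vec bw(bn);
      for (int i = 0; i < bn; ++i) {
        const cube& src = samples[order[s + i]];
        cube padded(H, W, C, arma::fill::zeros);
        padded.subcube(0, 0, 0, src.n_rows - 1, src.n_cols - 1, C - 1) = src;
        bx[i] = std::move(padded);
        by(i) = y_all(order[s + i]);
        bw(i) = w_all(order[s + i]);
      }
      ForwardOut fo = fcn_forward_batch(p, bx, true, dropout, &rng, true);
      g.init(p);
      double bl = fcn_backward_batch(p, bx, fo, by, bw, g);
      double bwsum = arma::accu(bw);
      lsum += bl * bwsum;
      wsum += bwsum;
      for (arma::uword i = 0; i < fo.probs.n_rows; ++i, ++n)
        if ((fo.probs(i, 1) > fo.probs(i, 0) ? 1 : 0) == by(i)) ++ncorrect;
      apply_update(p, g, st, optimizer, lr, b1, b2, eps, momentum);
    }
    double vloss, vacc;
    eval_batches(p, ex, ey, ew, vloss, vacc);
    history(e, 0) = lsum / wsum;
    history(e, 1) = (double)ncorrect / (double)n;
    history(e, 2) = vloss;
    history(e, 3) = vacc;
    if (vloss < best_loss) {
      best_loss = vloss;
      best = p;
      best_epoch = e + 1;  // 1-based
    }
    if ((e & 7) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["best_params"] = params_to_list(best),
                      _["final_params"] = params_to_list(p),
                      _["history"] = history, _["checkpoint_epoch"] = best_epoch,
                      _["best_val_loss"] = best_loss);
}

// ---------------------------------------------------------------------------
// 8-connected component labeling (ImageJ-style foreground connectivity)
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int c0 = 0; c0 < W; ++c0) {
    for (int r0 = 0; r0 < H; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r0, c0));
      lab(r0, c0) = next;
      while (!stack.empty()) {
        int r = stack.back().first, c = stack.back().second;
        stack.pop_back();
        for (int dr = -1; dr <= 1; ++dr)
          for (int dc = -1; dc <= 1; ++dc) {
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              stack.push_back(std::make_pair(rr, cc));
            }
          }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Moore-neighbour contour tracing perimeter with diagonal correction
// (axial step 1, diagonal step sqrt(2)). Returns 0 for single-pixel regions.
// [[Rcpp::export]]
double cpp_trace_perimeter(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  // offsets clockwise starting East (row increases downward)
  const int dr[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  const int dc[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  int sr = -1, sc = -1;
  for (int r = 0; r < H && sr < 0; ++r)
    for (int c = 0; c < W; ++c)
      if (mask(r, c)) {
        sr = r;
        sc = c;
        break;
      }
  if (sr < 0) return NA_REAL;
  auto fg = [&](int r, int c) {
    return r >= 0 && r < H && c >= 0 && c < W && mask(r, c);
  };
  // single pixel?
  bool alone = true;
  for (int d = 0; d < 8; ++d)
    if (fg(sr + dr[d], sc + dc[d])) alone = false;
  if (alone) return 0.0;
  const double SQRT2 = 1.4142135623730951;
  int cr = sr, cc = sc, back = 4;  // backtrack points West (scan order guarantee)
  double per = 0.0;
  long guard = 8L * H * W + 64;
  int d_first = -1;
  bool first = true;
  while (guard-- > 0) {
    int moved = -1;
    for (int i = 1; i <= 8; ++i) {
      int d = (back + i) % 8;
      if (fg(cr + dr[d], cc + dc[d])) {
        moved = d;
        break;
      }
    }
    if (moved < 0) break;  // cannot happen (not alone)
    // stop when about to repeat the opening move of the contour
    if (!first && cr == sr && cc == sc && moved == d_first) break;
    if (first) d_first = moved;
    first = false;
    cr += dr[moved];
    cc += dc[moved];
    per += (moved % 2 == 1) ? SQRT2 : 1.0;
    back = (moved + 4) % 8;
  }
  return per;
}
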