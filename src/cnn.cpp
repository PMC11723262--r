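// 1D convolutional denoiser: forward pass, backpropagation, Adam training,
// and bit-stable fixed-point inference emulation of the FPGA datapath.
//
// Architecture (valid convolutions, stride 1, non-overlapping max pooling):
//   conv1(k1, F1, ReLU) -> pool(2) -> conv2(k2, F2, ReLU) -> pool(2)
//   -> flatten -> dense(H, ReLU) -> dense(T, linear | sigmoid)
//
// The numerical core is templated so training/inference run in single
// precision while the finite-difference gradient oracle and the fixed-point
// path run in double precision.

#include <RcppArmadillo.h>
#include <random>
#if defined(__SSE2__)
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif

// Single-precision training drives Adam's decayed moments into the denormal
// range, where x86 arithmetic is 10-100x slower; flush-to-zero mode keeps the
// epoch cost flat (values this small are numerically irrelevant here).
static inline void set_flush_denormals() {
#if defined(__SSE2__)
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
}
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct CnnCfg {
  int T, k1, F1, k2, F2, H, act; // act: 0 linear, 1 sigmoid
  int L1, P1, L2, P2, D;
};

static CnnCfg make_cfg(const Rcpp::List& cfg) {
  CnnCfg c;
  c.T = cfg["T"]; c.k1 = cfg["k1"]; c.F1 = cfg["F1"];
  c.k2 = cfg["k2"]; c.F2 = cfg["F2"]; c.H = cfg["H"];
  c.act = cfg["act"];
  c.L1 = c.T - c.k1 + 1;
  c.P1 = c.L1 / 2;
  c.L2 = c.P1 - c.k2 + 1;
  c.P2 = c.L2 / 2;
  c.D = c.F2 * c.P2;
  if (c.L1 < 1) Rcpp::stop("conv1: input length %d too short for kernel %d", c.T, c.k1);
  if (c.P1 < 1) Rcpp::stop("pool1: feature length %d too short to pool", c.L1);
  if (c.L2 < 1) Rcpp::stop("conv2: pooled length %d too short for kernel %d", c.P1, c.k2);
  if (c.P2 < 1) Rcpp::stop("pool2: feature length %d too short to pool", c.L2);
  return c;
}

template <typename eT>
struct Weights {
  Mat<eT> W1, W2, W3, W4;     // k1 x F1, (k2*F1) x F2, D x H, H x T
  Col<eT> b1, b2, b3, b4;
};

template <typename eT>
static Weights<eT> weights_from_list(const Rcpp::List& w) {
  Weights<eT> p;
  p.W1 = conv_to<Mat<eT>>::from(Rcpp::as<mat>(w["W1"]));
  p.b1 = conv_to<Col<eT>>::from(Rcpp::as<vec>(w["b1"]));
  p.W2 = conv_to<Mat<eT>>::from(Rcpp::as<mat>(w["W2"]));
  p.b2 = conv_to<Col<eT>>::from(Rcpp::as<vec>(w["b2"]));
  p.W3 = conv_to<Mat<eT>>::from(Rcpp::as<mat>(w["W3"]));
  p.b3 = conv_to<Col<eT>>::from(Rcpp::as<vec>(w["b3"]));
  p.W4 = conv_to<Mat<eT>>::from(Rcpp::as<mat>(w["W4"]));
  p.b4 = conv_to<Col<eT>>::from(Rcpp::as<vec>(w["b4"]));
  return p;
}

template <typename eT>
static Rcpp::List weights_to_list(const Weights<eT>& p) {
  return Rcpp::List::create(
    Rcpp::Named("W1") = conv_to<mat>::from(p.W1),
    Rcpp::Named("b1") = conv_to<vec>::from(p.b1),
    Rcpp::Named("W2") = conv_to<mat>::from(p.W2),
    Rcpp::Named("b2") = conv_to<vec>::from(p.b2),
    Rcpp::Named("W3") = conv_to<mat>::from(p.W3),
    Rcpp::Named("b3") = conv_to<vec>::from(p.b3),
    Rcpp::Named("W4") = conv_to<mat>::from(p.W4),
    Rcpp::Named("b4") = conv_to<vec>::from(p.b4));
}

// ---- layer primitives -----------------------------------------------------

// X: T x B -> M1: k1 x (L1*B), sliding windows per sample.
template <typename eT>
static void im2col1(const Mat<eT>& X, const CnnCfg& c, Mat<eT>& M1) {
  const uword B = X.n_cols;
  M1.set_size(c.k1, (uword)c.L1 * B);
  for (uword s = 0; s < B; ++s) {
    const eT* xs = X.colptr(s);
    eT* m = M1.memptr() + (size_t)s * c.L1 * c.k1;
    for (int l = 0; l < c.L1; ++l)
      for (int j = 0; j < c.k1; ++j) m[(size_t)l * c.k1 + j] = xs[l + j];
  }
}

// A: F x (L*B) -> M: (F*k) x (L2*B); channels stacked per tap.
template <typename eT>
static void im2col2(const Mat<eT>& A, const CnnCfg& c, Mat<eT>& M) {
  const uword F = A.n_rows, B = A.n_cols / c.P1;
  M.set_size(F * c.k2, (uword)c.L2 * B);
  for (uword s = 0; s < B; ++s) {
    const uword off = s * c.P1;
    for (int j = 0; j < c.k2; ++j) {
      M.submat(j * F, s * c.L2, (j + 1) * F - 1, s * c.L2 + c.L2 - 1) =
        A.cols(off + j, off + j + c.L2 - 1);
    }
  }
}

// scatter-add transpose of im2col2.
template <typename eT>
static void col2im2(const Mat<eT>& dM, const CnnCfg& c, Mat<eT>& dA) {
  const uword F = dA.n_rows, B = dA.n_cols / c.P1;
  dA.zeros();
  for (uword s = 0; s < B; ++s) {
    const uword off = s * c.P1;
    for (int j = 0; j < c.k2; ++j) {
      dA.cols(off + j, off + j + c.L2 - 1) +=
        dM.submat(j * F, s * c.L2, (j + 1) * F - 1, s * c.L2 + c.L2 - 1);
    }
  }
}

// non-overlapping max pool over time (pairs of columns within each sample).
template <typename eT>
static void pool2_fwd(const Mat<eT>& A, int Lin, int Pout,
                      Mat<eT>& out, Mat<unsigned char>& mask) {
  const uword F = A.n_rows, B = A.n_cols / Lin;
  out.set_size(F, (uword)Pout * B);
  mask.set_size(F, (uword)Pout * B);
  for (uword s = 0; s < B; ++s) {
    for (int p = 0; p < Pout; ++p) {
      const eT* a = A.colptr(s * Lin + 2 * p);
      const eT* b = A.colptr(s * Lin + 2 * p + 1);
      eT* o = out.colptr(s * Pout + p);
      unsigned char* m = mask.colptr(s * Pout + p);
      for (uword f = 0; f < F; ++f) {
        if (a[f] >= b[f]) { o[f] = a[f]; m[f] = 0; } else { o[f] = b[f]; m[f] = 1; }
      }
    }
  }
}

template <typename eT>
static void pool2_bwd(const Mat<eT>& dOut, const Mat<unsigned char>& mask,
                      int Lin, int Pout, Mat<eT>& dA) {
  const uword F = dOut.n_rows, B = dOut.n_cols / Pout;
  dA.zeros(F, (uword)Lin * B);
  for (uword s = 0; s < B; ++s) {
    for (int p = 0; p < Pout; ++p) {
      const eT* d = dOut.colptr(s * Pout + p);
      const unsigned char* m = mask.colptr(s * Pout + p);
      eT* a = dA.colptr(s * Lin + 2 * p);
      eT* b = dA.colptr(s * Lin + 2 * p + 1);
      for (uword f = 0; f < F; ++f) { if (m[f]) b[f] = d[f]; else a[f] = d[f]; }
    }
  }
}

// zero the gradient wherever the (post-ReLU) activation is zero
template <typename eT>
static void relu_mask(Mat<eT>& d, const Mat<eT>& a_post) {
  const eT* a = a_post.memptr();
  eT* p = d.memptr();
  const uword n = d.n_elem;
  for (uword i = 0; i < n; ++i) { if (a[i] <= eT(0)) p[i] = eT(0); }
}

template <typename eT>
struct Cache {
  Mat<eT> M1, Z1, A1p, M2, Z2, A2p, Fl, Z3, A3, Y;
  Mat<unsigned char> mask1, mask2;
};

template <typename eT>
static void forward(const Weights<eT>& p, const CnnCfg& c, const Mat<eT>& X,
                    Cache<eT>& cc, bool keep) {
  const uword B = X.n_cols;
  im2col1(X, c, cc.M1);
  cc.Z1 = p.W1.t() * cc.M1;                     // F1 x (L1*B)
  cc.Z1.each_col() += p.b1;
  cc.Z1.for_each([](eT& v) { if (v < eT(0)) v = eT(0); });   // ReLU in place
  pool2_fwd(cc.Z1, c.L1, c.P1, cc.A1p, cc.mask1);  // F1 x (P1*B)
  im2col2(cc.A1p, c, cc.M2);                    // (F1*k2) x (L2*B)
  cc.Z2 = p.W2.t() * cc.M2;
  cc.Z2.each_col() += p.b2;
  cc.Z2.for_each([](eT& v) { if (v < eT(0)) v = eT(0); });   // ReLU in place
  pool2_fwd(cc.Z2, c.L2, c.P2, cc.A2p, cc.mask2);  // F2 x (P2*B)
  cc.Fl.set_size(c.D, B);                       // flatten: F2-major per step
  for (uword s = 0; s < B; ++s) {
    std::memcpy(cc.Fl.colptr(s), cc.A2p.colptr(s * c.P2),
                sizeof(eT) * (size_t)c.D);
  }
  cc.Z3 = p.W3.t() * cc.Fl;
  cc.Z3.each_col() += p.b3;
  cc.Z3.for_each([](eT& v) { if (v < eT(0)) v = eT(0); });   // ReLU in place
  cc.A3 = cc.Z3;
  cc.Y = p.W4.t() * cc.A3;
  cc.Y.each_col() += p.b4;
  if (c.act == 1) {
    cc.Y.for_each([](eT& v) { v = eT(1) / (eT(1) + std::exp((double)-v)); });
  }
  if (!keep) { cc.M1.reset(); cc.M2.reset(); }
}

template <typename eT>
static double backward(const Weights<eT>& p, const CnnCfg& c, const Mat<eT>& X,
                       const Mat<eT>& Yt, Cache<eT>& cc, Weights<eT>& g) {
  const uword B = X.n_cols;
  forward(p, c, X, cc, true);
  Mat<eT> dY = cc.Y - Yt;
  const double loss = accu(conv_to<mat>::from(square(dY))) / ((double)c.T * B);
  dY *= eT(2) / (eT)((double)c.T * B);
  if (c.act == 1) dY %= cc.Y % (eT(1) - cc.Y);

  g.W4 = cc.A3 * dY.t();
  g.b4 = sum(dY, 1);
  Mat<eT> dA3 = p.W4 * dY;
  relu_mask(dA3, cc.Z3);
  g.W3 = cc.Fl * dA3.t();
  g.b3 = sum(dA3, 1);
  Mat<eT> dFl = p.W3 * dA3;

  Mat<eT> dA2p(c.F2, (uword)c.P2 * B);
  for (uword s = 0; s < B; ++s) {
    std::memcpy(dA2p.colptr(s * c.P2), dFl.colptr(s), sizeof(eT) * (size_t)c.D);
  }
  Mat<eT> dZ2;
  pool2_bwd(dA2p, cc.mask2, c.L2, c.P2, dZ2);
  relu_mask(dZ2, cc.Z2);
  g.W2 = cc.M2 * dZ2.t();
  g.b2 = sum(dZ2, 1);
  Mat<eT> dM2 = p.W2 * dZ2;
  Mat<eT> dA1p(cc.A1p.n_rows, cc.A1p.n_cols);
  col2im2(dM2, c, dA1p);
  Mat<eT> dZ1;
  pool2_bwd(dA1p, cc.mask1, c.L1, c.P1, dZ1);
  relu_mask(dZ1, cc.Z1);
  g.W1 = cc.M1 * dZ1.t();
  g.b1 = sum(dZ1, 1);
  return loss;
}

template <typename eT>
static double eval_mse(const Weights<eT>& p, const CnnCfg& c,
                       const Mat<eT>& X, const Mat<eT>& Y, uword chunk = 256) {
  Cache<eT> cc;
  double se = 0.0;
  for (uword s = 0; s < X.n_cols; s += chunk) {
    const uword e = std::min(s + chunk - 1, X.n_cols - 1);
    const Mat<eT> Xb = X.cols(s, e);
    forward(p, c, Xb, cc, false);
    se += accu(conv_to<mat>::from(square(cc.Y - Y.cols(s, e))));
  }
  return se / ((double)c.T * X.n_cols);
}

// ---- Adam -----------------------------------------------------------------

// Global-norm gradient clipping: rescale all gradients when their joint
// L2 norm exceeds the threshold (guards against loss spikes from ReLU
// regime shifts at high learning rates).
template <typename eT>
static void clip_global_norm(Weights<eT>& g, double max_norm) {
  double sq = accu(square(conv_to<mat>::from(g.W1))) +
              accu(square(conv_to<mat>::from(g.W2))) +
              accu(square(conv_to<mat>::from(g.W3))) +
              accu(square(conv_to<mat>::from(g.W4))) +
              accu(square(conv_to<vec>::from(g.b1))) +
              accu(square(conv_to<vec>::from(g.b2))) +
              accu(square(conv_to<vec>::from(g.b3))) +
              accu(square(conv_to<vec>::from(g.b4)));
  const double nrm = std::sqrt(sq);
  if (nrm > max_norm && nrm > 0) {
    const eT f = (eT)(max_norm / nrm);
    g.W1 *= f; g.W2 *= f; g.W3 *= f; g.W4 *= f;
    g.b1 *= f; g.b2 *= f; g.b3 *= f; g.b4 *= f;
  }
}

template <typename eT>
struct Adam {
  Weights<eT> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-12;
  long t = 0;
  void init(const Weights<eT>& p) {
    m.W1.zeros(size(p.W1)); m.W2.zeros(size(p.W2));
    m.W3.zeros(size(p.W3)); m.W4.zeros(size(p.W4));
    m.b1.zeros(p.b1.n_elem); m.b2.zeros(p.b2.n_elem);
    m.b3.zeros(p.b3.n_elem); m.b4.zeros(p.b4.n_elem);
    v = m;
  }
  template <typename M>
  void upd(M& w, M& mm, M& vv, const M& g, double lr) {
    mm = eT(b1) * mm + eT(1 - b1) * g;
    vv = eT(b2) * vv + eT(1 - b2) * square(g);
    const double c1 = 1.0 - std::pow(b1, (double)t);
    const double c2 = 1.0 - std::pow(b2, (double)t);
    w -= eT(lr / c1) * (mm / (sqrt(vv / eT(c2)) + eT(eps)));
  }
  // Per-layer learning-rate scaling ~ 1/fan_in (muP-style): Adam updates all
  // weights by ~lr regardless of layer width, so with non-negative (post-ReLU)
  // inputs a whole column can move coherently and swing pre-activations by
  // lr * fan_in per step, mass-killing ReLU units in wide layers. Capping the
  // per-layer rate at lr * kappa / fan_in keeps pre-activation steps O(1).
  double kappa = 64.0, power = 0.5;
  void step(Weights<eT>& p, const Weights<eT>& g, double lr, const CnnCfg& c) {
    ++t;
    auto scale = [&](double fan_in) {
      return lr * std::min(1.0, std::pow(kappa / fan_in, power));
    };
    upd(p.W1, m.W1, v.W1, g.W1, scale(c.k1));
    upd(p.b1, m.b1, v.b1, g.b1, lr);
    upd(p.W2, m.W2, v.W2, g.W2, scale((double)c.k2 * c.F1));
    upd(p.b2, m.b2, v.b2, g.b2, lr);
    upd(p.W3, m.W3, v.W3, g.W3, scale((double)c.D));
    upd(p.b3, m.b3, v.b3, g.b3, lr);
    upd(p.W4, m.W4, v.W4, g.W4, scale((double)c.H));
    upd(p.b4, m.b4, v.b4, g.b4, lr);
  }
};

template <typename eT>
static Weights<eT> he_init(const CnnCfg& c, std::mt19937& rng) {
  std::normal_distribution<double> N(0.0, 1.0);
  auto fill = [&](Mat<eT>& W, uword r, uword co, double fan_in) {
    W.set_size(r, co);
    const double s = std::sqrt(2.0 / fan_in);
    for (uword j = 0; j < co; ++j)
      for (uword i = 0; i < r; ++i) W(i, j) = (eT)(s * N(rng));
  };
  Weights<eT> p;
  fill(p.W1, c.k1, c.F1, c.k1);
  fill(p.W2, (uword)c.k2 * c.F1, c.F2, (double)c.k2 * c.F1);
  fill(p.W3, c.D, c.H, c.D);
  fill(p.W4, c.H, c.T, c.H);
  p.b1.zeros(c.F1); p.b2.zeros(c.F2); p.b3.zeros(c.H); p.b4.zeros(c.T);
  return p;
}

// ---- exported: training ----------------------------------------------------

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(const arma::mat& Xtr, const arma::mat& Ytr,
                         const arma::mat& Xval, const arma::mat& Yval,
                         Rcpp::List cfg, Rcpp::List hyper, int seed) {
  typedef float eT;
  set_flush_denormals();
  const CnnCfg c = make_cfg(cfg);
  const int epochs = hyper["epochs"];
  const uword batch = (uword)(int)hyper["batch"];
  double lr = hyper["lr"];
  const int patience = hyper["patience"];
  const int lr_patience = hyper["lr_patience"];
  const double lr_factor = hyper["lr_factor"];
  const double min_lr = hyper["min_lr"];
  const int warmup = hyper["warmup_epochs"];
  const double kappa = hyper["kappa"];
  const double power = hyper["lr_scale_power"];
  const double clip = hyper["clip_norm"];
  const double swa_frac = hyper["swa_start_frac"];
  const std::string schedule = Rcpp::as<std::string>(hyper["schedule"]);
  const bool cosine = (schedule == "cosine");
  const bool verbose = hyper["verbose"];

  Mat<eT> X = conv_to<Mat<eT>>::from(Xtr.t());   // T x N
  Mat<eT> Y = conv_to<Mat<eT>>::from(Ytr.t());
  Mat<eT> Xv = conv_to<Mat<eT>>::from(Xval.t());
  Mat<eT> Yv = conv_to<Mat<eT>>::from(Yval.t());
  const uword N = X.n_cols;

  std::mt19937 rng((unsigned)seed);
  Weights<eT> p = he_init<eT>(c, rng);
  Adam<eT> opt; opt.init(p);
  opt.kappa = kappa; opt.power = power;
  Cache<eT> cc;
  Weights<eT> g, best = p;

  std::vector<uword> idx(N);
  for (uword i = 0; i < N; ++i) idx[i] = i;

  std::vector<double> tr_hist, val_hist, lr_hist;
  double best_val = datum::inf;
  int best_epoch = 0, since_best = 0, epoch = 0;
  // tail (stochastic-weight) averaging: running mean of the weights over the
  // later epochs; averaged weights are scored on the validation split like
  // any other candidate
  Weights<eT> swa;
  long swa_n = 0;
  double last_va_swa = datum::inf;
  const int swa_start = std::max(1, (int)std::ceil(swa_frac * epochs));
  auto swa_mix = [&](Mat<eT>& a, const Mat<eT>& w) {
    a = a + (w - a) / (eT)swa_n;
  };
  auto swa_mixv = [&](Col<eT>& a, const Col<eT>& w) {
    a = a + (w - a) / (eT)swa_n;
  };

  for (epoch = 1; epoch <= epochs; ++epoch) {
    double lr_eff = (epoch <= warmup) ? lr * 0.1 : lr;
    if (cosine && epoch > warmup) {
      const double u = (double)(epoch - warmup) / std::max(1, epochs - warmup);
      lr_eff = min_lr + 0.5 * (lr - min_lr) * (1.0 + std::cos(u * M_PI));
    }
    std::shuffle(idx.begin(), idx.end(), rng);
    double se = 0.0;
    uword nb = 0;
    for (uword s = 0; s < N; s += batch) {
      const uword e = std::min(s + batch - 1, N - 1);
      uvec take(e - s + 1);
      for (uword i = s; i <= e; ++i) take[i - s] = idx[i];
      const Mat<eT> Xb = X.cols(take), Yb = Y.cols(take);
      const double l = backward(p, c, Xb, Yb, cc, g);
      if (!std::isfinite(l)) {
        Rcpp::stop("training diverged (non-finite loss) at epoch %d", epoch);
      }
      if (clip > 0) clip_global_norm(g, clip);
      opt.step(p, g, lr_eff, c);
      se += l; ++nb;
    }
    const double tr = se / nb;
    const double va = eval_mse(p, c, Xv, Yv);
    tr_hist.push_back(tr); val_hist.push_back(va); lr_hist.push_back(lr_eff);
    if (verbose) Rcpp::Rcout << "epoch " << epoch << " train " << tr
                             << " val " << va << " lr " << lr << "\n";
    if (!std::isfinite(va)) Rcpp::stop("training diverged (non-finite loss) at epoch %d", epoch);
    if (va < best_val) {
      best_val = va; best = p; best_epoch = epoch; since_best = 0;
    } else {
      ++since_best;
      if (!cosine && since_best % lr_patience == 0 && lr > min_lr) {
        lr = std::max(lr * lr_factor, min_lr);
      }
      if (!cosine && since_best >= patience) break;
    }
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
    Rcpp::Named("weights") = weights_to_list(best),
    Rcpp::Named("train_mse") = tr_hist,
    Rcpp::Named("val_mse") = val_hist,
    Rcpp::Named("lr") = lr_hist,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("best_val_mse") = best_val,
    Rcpp::Named("epochs_run") = (int)tr_hist.size());
}

// ---- exported: inference ----------------------------------------------------

// [[Rcpp::export]]
arma::mat cnn_predict_cpp(Rcpp::List weights, Rcpp::List cfg, const arma::mat& Xin) {
  typedef float eT;
  set_flush_denormals();
  const CnnCfg c = make_cfg(cfg);
  const Weights<eT> p = weights_from_list<eT>(weights);
  Mat<eT> X = conv_to<Mat<eT>>::from(Xin.t());
  Cache<eT> cc;
  mat out(Xin.n_rows, c.T);
  const uword chunk = 256;
  for (uword s = 0; s < X.n_cols; s += chunk) {
    const uword e = std::min(s + chunk - 1, X.n_cols - 1);
    const Mat<eT> Xb = X.cols(s, e);
    forward(p, c, Xb, cc, false);
    out.rows(s, e) = conv_to<mat>::from(cc.Y.t());
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cnn_loss_grad_cpp(Rcpp::List weights, Rcpp::List cfg,
                             const arma::mat& Xin, const arma::mat& Yin) {
  typedef double eT;
  const CnnCfg c = make_cfg(cfg);
  const Weights<eT> p = weights_from_list<eT>(weights);
  Mat<eT> X = Xin.t(), Y = Yin.t();
  Cache<eT> cc;
  Weights<eT> g;
  const double loss = backward(p, c, X, Y, cc, g);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = weights_to_list(g));
}

// [[Rcpp::export]]
double cnn_loss_cpp(Rcpp::List weights, Rcpp::List cfg,
                    const arma::mat& Xin, const arma::mat& Yin) {
  typedef double eT;
  const CnnCfg c = make_cfg(cfg);
  const Weights<eT> p = weights_from_list<eT>(weights);
  Mat<eT> X = Xin.t(), Y = Yin.t();
  return eval_mse(p, c, X, Y);
}

// [[Rcpp::export]]
int cnn_repeat_identical_cpp(Rcpp::List weights, Rcpp::List cfg,
                             const arma::vec& x, int times) {
  typedef float eT;
  const CnnCfg c = make_cfg(cfg);
  const Weights<eT> p = weights_from_list<eT>(weights);
  Mat<eT> X = conv_to<Mat<eT>>::from(x);
  Cache<eT> cc;
  forward(p, c, X, cc, false);
  Mat<eT> ref = cc.Y;
  int identical = 1;
  for (int i = 1; i < times; ++i) {
    forward(p, c, X, cc, false);
    if (std::memcmp(ref.memptr(), cc.Y.memptr(), sizeof(eT) * ref.n_elem) == 0) {
      ++identical;
    }
  }
  return identical;
}

// ---- fixed-point emulation ---------------------------------------------------

struct QSpec {
  int total_bits, frac_bits;
  bool nearest, saturating;
  double scale, lo, hi;       // integer-value bounds
  mutable bool overflow = false;
  mutable std::string where;
  QSpec(int tb, int fb, bool nr, bool sat)
    : total_bits(tb), frac_bits(fb), nearest(nr), saturating(sat) {
    scale = std::ldexp(1.0, frac_bits);
    hi = std::ldexp(1.0, tb - 1) - 1.0;
    lo = -std::ldexp(1.0, tb - 1);
  }
  double q(double x, const char* layer) const {
    double v = x * scale;
    v = nearest ? std::nearbyint(v) : std::trunc(v);
    if (v > hi || v < lo) {
      if (!saturating && !overflow) { overflow = true; where = layer; }
      v = std::min(std::max(v, lo), hi);
    }
    return v / scale;
  }
  void qmat(mat& M, const char* layer) const {
    for (uword i = 0; i < M.n_elem; ++i) M[i] = q(M[i], layer);
  }
};

// Quantized forward pass: weights, inputs and every layer's outputs live on
// the Q(total-frac-1).frac grid; multiply-accumulates use a wide accumulator
// (double), matching DSP-block accumulation wider than the storage format.
// [[Rcpp::export]]
Rcpp::List cnn_predict_fixed_cpp(Rcpp::List weights, Rcpp::List cfg,
                                 const arma::mat& Xin,
                                 int total_bits, int frac_bits,
                                 bool nearest, bool saturating) {
  typedef double eT;
  const CnnCfg c = make_cfg(cfg);
  Weights<eT> p = weights_from_list<eT>(weights);
  QSpec qs(total_bits, frac_bits, nearest, saturating);
  qs.qmat(p.W1, "conv1.weights"); for (auto& v : p.b1) v = qs.q(v, "conv1.bias");
  qs.qmat(p.W2, "conv2.weights"); for (auto& v : p.b2) v = qs.q(v, "conv2.bias");
  qs.qmat(p.W3, "dense1.weights"); for (auto& v : p.b3) v = qs.q(v, "dense1.bias");
  qs.qmat(p.W4, "dense2.weights"); for (auto& v : p.b4) v = qs.q(v, "dense2.bias");

  mat X = Xin.t();
  qs.qmat(X, "input");
  Cache<eT> cc;
  mat out(Xin.n_rows, c.T);
  const uword chunk = 128;
  for (uword s = 0; s < X.n_cols; s += chunk) {
    const uword e = std::min(s + chunk - 1, X.n_cols - 1);
    Mat<eT> Xb = X.cols(s, e);
    const uword B = Xb.n_cols;
    im2col1(Xb, c, cc.M1);
    cc.Z1 = p.W1.t() * cc.M1; cc.Z1.each_col() += p.b1;
    qs.qmat(cc.Z1, "conv1.out");
    Mat<eT> A1 = cc.Z1; A1.for_each([](eT& v) { if (v < 0) v = 0; });
    pool2_fwd(A1, c.L1, c.P1, cc.A1p, cc.mask1);
    im2col2(cc.A1p, c, cc.M2);
    cc.Z2 = p.W2.t() * cc.M2; cc.Z2.each_col() += p.b2;
    qs.qmat(cc.Z2, "conv2.out");
    Mat<eT> A2 = cc.Z2; A2.for_each([](eT& v) { if (v < 0) v = 0; });
    pool2_fwd(A2, c.L2, c.P2, cc.A2p, cc.mask2);
    cc.Fl.set_size(c.D, B);
    for (uword b = 0; b < B; ++b)
      std::memcpy(cc.Fl.colptr(b), cc.A2p.colptr(b * c.P2), sizeof(eT) * (size_t)c.D);
    cc.Z3 = p.W3.t() * cc.Fl; cc.Z3.each_col() += p.b3;
    qs.qmat(cc.Z3, "dense1.out");
    cc.A3 = cc.Z3; cc.A3.for_each([](eT& v) { if (v < 0) v = 0; });
    cc.Y = p.W4.t() * cc.A3; cc.Y.each_col() += p.b4;
    if (c.act == 1) {
      cc.Y.for_each([](eT& v) { v = 1.0 / (1.0 + std::exp(-v)); });
    }
    qs.qmat(cc.Y, "output");
    out.rows(s, e) = cc.Y.t();
  }
  return Rcpp::List::create(Rcpp::Named("Y") = out,
                            Rcpp::Named("overflow") = qs.overflow,
                            Rcpp::Named("overflow_layer") = qs.where);
}

// Quantize a weight list onto the fixed-point grid (for storage/idempotence).
// [[Rcpp::export]]
Rcpp::List quantize_weights_cpp(Rcpp::List weights, int total_bits, int frac_bits,
                                bool nearest, bool saturating) {
  typedef double eT;
  Weights<eT> p = weights_from_list<eT>(weights);
  QSpec qs(total_bits, frac_bits, nearest, saturating);
  const char* nm[] = {"conv1.weights", "conv2.weights", "dense1.weights", "dense2.weights"};
  qs.qmat(p.W1, nm[0]); qs.qmat(p.W2, nm[1]); qs.qmat(p.W3, nm[2]); qs.qmat(p.W4, nm[3]);
  for (auto& v : p.b1) v = qs.q(v, "conv1.bias");
  for (auto& v : p.b2) v = qs.q(v, "conv2.bias");
  for (auto& v : p.b3) v = qs.q(v, "dense1.bias");
  for (auto& v : p.b4) v = qs.q(v, "dense2.bias");
  return Rcpp::List::create(Rcpp::Named("weights") = weights_to_list(p),
                            Rcpp::Named("overflow") = qs.overflow,
                            Rcpp::Named("overflow_layer") = qs.where);
}
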