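// Minimal 1-D convolutional / dense network with Adam and early stopping.
// Architectures supported:
//   conv : input C x L -> conv(K filters, width w) -> ReLU -> max-pool
//          (non-overlapping bins of P) -> dense(H) -> ReLU -> dense(F) -> sigmoid
//   dense: input D -> dense(H) -> ReLU -> dense(F) -> sigmoid
// Training is deterministic for a fixed seed (std::mt19937 drives init and
// shuffling; single-threaded).
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

struct Arch {
  bool conv;
  bool mean_channel;
  int C, L, K, w, P, H, F;
  int Lc, npool, Dflat;
};

static Arch parse_arch(const List& a) {
  Arch ar;
  std::string type = as<std::string>(a["type"]);
  ar.conv = (type == "conv");
  ar.H = as<int>(a["hidden"]);
  ar.F = as<int>(a["outputs"]);
  if (ar.conv) {
    ar.C = as<int>(a["in_channels"]);
    ar.L = as<int>(a["input_length"]);
    ar.K = as<int>(a["filters"]);
    ar.w = as<int>(a["kernel"]);
    ar.P = as<int>(a["pool"]);
    ar.Lc = ar.L - ar.w + 1;
    ar.npool = (ar.Lc + ar.P - 1) / ar.P;
    // per segment and filter: max of the ReLU'd activations, optionally
    // concatenated with the mean (dense gradients for unseeded training).
    ar.mean_channel = !a.containsElementNamed("mean_channel") ||
                      as<bool>(a["mean_channel"]);
    ar.Dflat = (ar.mean_channel ? 2 : 1) * ar.K * ar.npool;
  } else {
    ar.C = 0; ar.L = 0; ar.K = 0; ar.w = 0; ar.P = 0;
    ar.Dflat = as<int>(a["input_dim"]);
    ar.Lc = 0; ar.npool = 0;
  }
  if (ar.H < 1) stop("hidden must be >= 1");
  return ar;
}

struct Weights {
  mat Wc; vec bc;   // conv only
  mat W1; vec b1;
  mat W2; vec b2;
};

static Weights parse_weights(const List& wl, const Arch& ar) {
  Weights w;
  if (ar.conv) {
    w.Wc = as<mat>(wl["Wc"]); w.bc = as<vec>(wl["bc"]);
  }
  w.W1 = as<mat>(wl["W1"]); w.b1 = as<vec>(wl["b1"]);
  w.W2 = as<mat>(wl["W2"]); w.b2 = as<vec>(wl["b2"]);
  return w;
}

static List weights_to_list(const Weights& w, const Arch& ar) {
  if (ar.conv)
    return List::create(_["Wc"] = w.Wc, _["bc"] = w.bc, _["W1"] = w.W1,
                        _["b1"] = w.b1, _["W2"] = w.W2, _["b2"] = w.b2);
  return List::create(_["W1"] = w.W1, _["b1"] = w.b1, _["W2"] = w.W2,
                      _["b2"] = w.b2);
}

static double rnorm_det(std::mt19937& rng) {
  // Box-Muller on explicit uniforms: independent of libstdc++'s
  // normal_distribution implementation.
  std::uniform_real_distribution<double> U(0.0, 1.0);
  double u1 = 1.0 - U(rng), u2 = U(rng);
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

static mat he_init(int r, int c, double fan_in, std::mt19937& rng) {
  mat M(r, c);
  double sd = std::sqrt(2.0 / fan_in);
  for (uword j = 0; j < M.n_cols; ++j)
    for (uword i = 0; i < M.n_rows; ++i) M(i, j) = sd * rnorm_det(rng);
  return M;
}

// [[Rcpp::export]]
List nn_init_cpp(List arch, int seed) {
  Arch ar = parse_arch(arch);
  std::mt19937 rng(static_cast<uint32_t>(seed));
  Weights w;
  if (ar.conv) {
    w.Wc = he_init(ar.K, ar.C * ar.w, ar.C * ar.w, rng);
    w.bc = zeros<vec>(ar.K);
  }
  w.W1 = he_init(ar.H, ar.Dflat, ar.Dflat, rng);
  w.b1 = zeros<vec>(ar.H);
  w.W2 = he_init(ar.F, ar.H, ar.H, rng);
  w.b2 = zeros<vec>(ar.F);
  return weights_to_list(w, ar);
}

// im2col for one sample: (C*w) x Lc
static void im2col(const mat& X, int w, mat& M) {
  int Lc = X.n_cols - w + 1;
  for (int p = 0; p < Lc; ++p)
    M.col(p) = vectorise(X.cols(p, p + w - 1));
}

// forward pass for one conv sample; returns flat vector, fills caches
static void conv_pool(const Arch& ar, const Weights& w, const mat& M,
                      mat& Araw, vec& flat, uvec& amax) {
  Araw = w.Wc * M;
  Araw.each_col() += w.bc;
  int half = ar.K * ar.npool;
  flat.set_size(ar.Dflat);
  amax.set_size(half);
  for (int s = 0; s < ar.npool; ++s) {
    int c0 = s * ar.P;
    int c1 = std::min(ar.Lc, c0 + ar.P) - 1;
    for (int k = 0; k < ar.K; ++k) {
      double best = 0.0; uword bi = c0;  // ReLU floor 0
      double sum = 0.0;
      for (int c = c0; c <= c1; ++c) {
        double v = Araw(k, c);
        if (v > best) { best = v; bi = c; }
        if (v > 0) sum += v;
      }
      flat(k + s * ar.K) = best;
      amax(k + s * ar.K) = bi;
      if (ar.mean_channel) flat(half + k + s * ar.K) = sum / (c1 - c0 + 1);
    }
  }
}

static void dense_forward(const Weights& w, const vec& flat, vec& z1, vec& h1,
                          vec& z2) {
  z1 = w.W1 * flat + w.b1;
  h1 = clamp(z1, 0.0, datum::inf);
  z2 = w.W2 * h1 + w.b2;
}

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// weighted BCE with logits; pw = per-feature weight applied to positives
static double bce_from_logits(const vec& z, const vec& y, const vec& pw) {
  double s = 0.0;
  for (uword i = 0; i < z.n_elem; ++i) {
    double zi = z(i);
    double l = std::max(zi, 0.0) - zi * y(i) +
               std::log1p(std::exp(-std::fabs(zi)));
    s += (y(i) > 0.5 ? pw(i) : 1.0) * l;
  }
  return s / z.n_elem;
}

struct Adam {
  mat mWc, vWc, mW1, vW1, mW2, vW2;
  vec mbc, vbc, mb1, vb1, mb2, vb2;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const Weights& w, bool conv) {
    if (conv) {
      mWc = zeros<mat>(size(w.Wc)); vWc = mWc;
      mbc = zeros<vec>(w.bc.n_elem); vbc = mbc;
    }
    mW1 = zeros<mat>(size(w.W1)); vW1 = mW1;
    mb1 = zeros<vec>(w.b1.n_elem); vb1 = mb1;
    mW2 = zeros<mat>(size(w.W2)); vW2 = mW2;
    mb2 = zeros<vec>(w.b2.n_elem); vb2 = mb2;
  }
  template <typename T>
  void upd(T& w, T& m, T& v, const T& g, double lr) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    double bc1 = 1 - std::pow(b1, (double)t), bc2 = 1 - std::pow(b2, (double)t);
    w -= lr * (m / bc1) / (sqrt(v / bc2) + eps);
  }
};

// Evaluate mean loss over a dataset (conv: cube C x L x N; dense: mat D x N)
static double eval_loss(const Arch& ar, const Weights& w, const cube& Xc,
                        const mat& Xd, const mat& Y, const vec& pw) {
  int N = Y.n_cols;
  double tot = 0.0;
  mat M, Araw;
  if (ar.conv) M.set_size(ar.C * ar.w, ar.Lc);
  vec flat, z1, h1, z2;
  uvec amax;
  for (int i = 0; i < N; ++i) {
    if (ar.conv) {
      im2col(Xc.slice(i), ar.w, M);
      conv_pool(ar, w, M, Araw, flat, amax);
    } else {
      flat = Xd.col(i);
    }
    dense_forward(w, flat, z1, h1, z2);
    tot += bce_from_logits(z2, Y.col(i), pw);
  }
  return tot / N;
}

// [[Rcpp::export]]
List nn_train_cpp(SEXP Xs, arma::mat Y, SEXP Xvs, arma::mat Yval, List arch,
                  List weights0, List hyper) {
  Arch ar = parse_arch(arch);
  Weights w = parse_weights(weights0, ar);
  cube Xc, Xvc; mat Xd, Xvd;
  if (ar.conv) { Xc = as<cube>(Xs); Xvc = as<cube>(Xvs); }
  else { Xd = as<mat>(Xs); Xvd = as<mat>(Xvs); }
  int N = Y.n_cols;
  double lr = as<double>(hyper["lr"]);
  double wd = hyper.containsElementNamed("weight_decay")
                ? as<double>(hyper["weight_decay"]) : 0.0;
  double dropout = hyper.containsElementNamed("dropout")
                ? as<double>(hyper["dropout"]) : 0.0;
  double l1 = hyper.containsElementNamed("l1_readout")
                ? as<double>(hyper["l1_readout"]) : 0.0;
  int batch = as<int>(hyper["batch"]);
  int epochs = as<int>(hyper["epochs"]);
  int patience = as<int>(hyper["patience"]);
  int seed = as<int>(hyper["seed"]);

  std::mt19937 rng(static_cast<uint32_t>(seed));
  Adam opt; opt.init(w, ar.conv);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;

  // per-feature positive-class weight n_neg/n_pos (clamped to [1, 20]):
  // rare peak labels otherwise let the loss saturate at the base rate
  vec pw(ar.F, fill::ones);
  bool use_pw = !hyper.containsElementNamed("pos_weight") ||
                as<bool>(hyper["pos_weight"]);
  if (use_pw) {
    for (int f = 0; f < ar.F; ++f) {
      double npos = accu(Y.row(f));
      if (npos > 0 && npos < N)
        pw(f) = std::min(20.0, std::max(1.0, (N - npos) / npos));
    }
  }

  Weights best = w;
  double best_val = datum::inf;
  int best_epoch = 0, bad = 0;
  std::vector<double> tr_hist, val_hist;

  mat M, Araw;
  if (ar.conv) M.set_size(ar.C * ar.w, ar.Lc);
  vec flat, z1, h1, z2;
  uvec amax;

  for (int ep = 1; ep <= epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0;
    for (int b0 = 0; b0 < N; b0 += batch) {
      int b1i = std::min(N, b0 + batch);
      int B = b1i - b0;
      Weights g;
      if (ar.conv) { g.Wc = zeros<mat>(size(w.Wc)); g.bc = zeros<vec>(ar.K); }
      g.W1 = zeros<mat>(size(w.W1)); g.b1 = zeros<vec>(ar.H);
      g.W2 = zeros<mat>(size(w.W2)); g.b2 = zeros<vec>(ar.F);
      std::uniform_real_distribution<double> U01(0.0, 1.0);
      for (int ii = b0; ii < b1i; ++ii) {
        int i = idx[ii];
        if (ar.conv) {
          im2col(Xc.slice(i), ar.w, M);
          conv_pool(ar, w, M, Araw, flat, amax);
        } else {
          flat = Xd.col(i);
        }
        // inverted dropout on the pooled features and the hidden layer
        vec mflat, mh1;
        if (dropout > 0) {
          double keep = 1.0 - dropout;
          mflat.set_size(flat.n_elem);
          for (uword q = 0; q < flat.n_elem; ++q)
            mflat(q) = (U01(rng) < keep) ? 1.0 / keep : 0.0;
          flat %= mflat;
        }
        dense_forward(w, flat, z1, h1, z2);
        if (dropout > 0) {
          double keep = 1.0 - dropout;
          mh1.set_size(h1.n_elem);
          for (uword q = 0; q < h1.n_elem; ++q)
            mh1(q) = (U01(rng) < keep) ? 1.0 / keep : 0.0;
          h1 %= mh1;
          z2 = w.W2 * h1 + w.b2;  // recompute logits on dropped h1
        }
        vec y = Y.col(i);
        ep_loss += bce_from_logits(z2, y, pw) * ((double)1.0 / N);
        // gradient of mean-over-features weighted BCE, averaged over batch
        vec dz2(ar.F);
        for (int f = 0; f < ar.F; ++f)
          dz2(f) = (y(f) > 0.5 ? pw(f) : 1.0) *
                   (sigmoid(z2(f)) - y(f)) / (ar.F * (double)B);
        g.W2 += dz2 * h1.t();
        g.b2 += dz2;
        vec dh1 = w.W2.t() * dz2;
        if (dropout > 0) dh1 %= mh1;
        vec dz1 = dh1 % conv_to<vec>::from(z1 > 0);
        g.W1 += dz1 * flat.t();
        g.b1 += dz1;
        if (ar.conv) {
          vec dflat = w.W1.t() * dz1;
          if (dropout > 0) dflat %= mflat;
          int half = ar.K * ar.npool;
          for (int j = 0; j < half; ++j) {  // max channel
            double d = dflat(j);
            if (d == 0.0) continue;
            uword c = amax(j);
            int k = j % ar.K;
            if (Araw(k, c) > 0) {  // ReLU gate (flat==0 when preact<=0)
              g.Wc.row(k) += d * M.col(c).t();
              g.bc(k) += d;
            }
          }
          for (int j = 0; ar.mean_channel && j < half; ++j) {  // mean channel
            double d = dflat(half + j);
            if (d == 0.0) continue;
            int k = j % ar.K;
            int s = j / ar.K;
            int c0 = s * ar.P;
            int c1 = std::min(ar.Lc, c0 + ar.P) - 1;
            double dm = d / (c1 - c0 + 1);
            for (int c = c0; c <= c1; ++c) {
              if (Araw(k, c) > 0) {
                g.Wc.row(k) += dm * M.col(c).t();
                g.bc(k) += dm;
              }
            }
          }
        }
      }
      opt.t += 1;
      if (wd > 0) {  // decoupled (AdamW-style) weight decay, not on biases
        if (ar.conv) w.Wc *= (1.0 - lr * wd);
        w.W1 *= (1.0 - lr * wd);
        w.W2 *= (1.0 - lr * wd);
      }
      if (ar.conv) { opt.upd(w.Wc, opt.mWc, opt.vWc, g.Wc, lr);
                     opt.upd(w.bc, opt.mbc, opt.vbc, g.bc, lr); }
      opt.upd(w.W1, opt.mW1, opt.vW1, g.W1, lr);
      if (l1 > 0) {  // proximal soft-threshold: sparse first-layer readout
        double th = lr * l1;
        w.W1.transform([th](double v) {
          return (v > th) ? v - th : ((v < -th) ? v + th : 0.0);
        });
      }
      opt.upd(w.b1, opt.mb1, opt.vb1, g.b1, lr);
      opt.upd(w.W2, opt.mW2, opt.vW2, g.W2, lr);
      opt.upd(w.b2, opt.mb2, opt.vb2, g.b2, lr);
    }
    if (!std::isfinite(ep_loss)) stop("non-finite training loss at epoch %d", ep);
    double vl = eval_loss(ar, w, Xvc, Xvd, Yval, pw);
    tr_hist.push_back(ep_loss);
    val_hist.push_back(vl);
    if (vl < best_val - 1e-6) {
      best_val = vl; best = w; best_epoch = ep; bad = 0;
    } else if (++bad >= patience) break;
  }
  return List::create(_["weights"] = weights_to_list(best, ar),
                      _["train_loss"] = tr_hist, _["val_loss"] = val_hist,
                      _["best_epoch"] = best_epoch, _["best_val"] = best_val);
}

// Pooled conv features (Dflat x N) for a conv architecture; debugging aid.
// [[Rcpp::export]]
arma::mat nn_features_cpp(SEXP Xs, List arch, List weights) {
  Arch ar = parse_arch(arch);
  if (!ar.conv) stop("conv architecture required");
  Weights w = parse_weights(weights, ar);
  cube Xc = as<cube>(Xs);
  int N = Xc.n_slices;
  mat out(ar.Dflat, N);
  mat M(ar.C * ar.w, ar.Lc), Araw;
  vec flat; uvec amax;
  for (int i = 0; i < N; ++i) {
    im2col(Xc.slice(i), ar.w, M);
    conv_pool(ar, w, M, Araw, flat, amax);
    out.col(i) = flat;
  }
  return out;
}

// Mean loss and analytic gradients over a batch (uniform class weights).
// Exposed for gradient checking against finite differences in the tests.
// [[Rcpp::export]]
List nn_loss_grad_cpp(SEXP Xs, arma::mat Y, List arch, List weights) {
  Arch ar = parse_arch(arch);
  Weights w = parse_weights(weights, ar);
  cube Xc; mat Xd;
  if (ar.conv) Xc = as<cube>(Xs); else Xd = as<mat>(Xs);
  int N = Y.n_cols;
  vec pw(ar.F, fill::ones);
  Weights g;
  if (ar.conv) { g.Wc = zeros<mat>(size(w.Wc)); g.bc = zeros<vec>(ar.K); }
  g.W1 = zeros<mat>(size(w.W1)); g.b1 = zeros<vec>(ar.H);
  g.W2 = zeros<mat>(size(w.W2)); g.b2 = zeros<vec>(ar.F);
  mat M, Araw;
  if (ar.conv) M.set_size(ar.C * ar.w, ar.Lc);
  vec flat, z1, h1, z2;
  uvec amax;
  double loss = 0.0;
  for (int i = 0; i < N; ++i) {
    if (ar.conv) {
      im2col(Xc.slice(i), ar.w, M);
      conv_pool(ar, w, M, Araw, flat, amax);
    } else flat = Xd.col(i);
    dense_forward(w, flat, z1, h1, z2);
    vec y = Y.col(i);
    loss += bce_from_logits(z2, y, pw) / N;
    vec dz2(ar.F);
    for (int f = 0; f < ar.F; ++f)
      dz2(f) = (sigmoid(z2(f)) - y(f)) / (ar.F * (double)N);
    g.W2 += dz2 * h1.t();
    g.b2 += dz2;
    vec dh1 = w.W2.t() * dz2;
    vec dz1 = dh1 % conv_to<vec>::from(z1 > 0);
    g.W1 += dz1 * flat.t();
    g.b1 += dz1;
    if (ar.conv) {
      vec dflat = w.W1.t() * dz1;
      int half = ar.K * ar.npool;
      for (int j = 0; j < half; ++j) {
        double d = dflat(j);
        if (d == 0.0) continue;
        uword c = amax(j);
        int k = j % ar.K;
        if (Araw(k, c) > 0) {
          g.Wc.row(k) += d * M.col(c).t();
          g.bc(k) += d;
        }
      }
      for (int j = 0; ar.mean_channel && j < half; ++j) {
        double d = dflat(half + j);
        if (d == 0.0) continue;
        int k = j % ar.K;
        int s = j / ar.K;
        int c0 = s * ar.P;
        int c1 = std::min(ar.Lc, c0 + ar.P) - 1;
        double dm = d / (c1 - c0 + 1);
        for (int c = c0; c <= c1; ++c) {
          if (Araw(k, c) > 0) {
            g.Wc.row(k) += dm * M.col(c).t();
            g.bc(k) += dm;
          }
        }
      }
    }
  }
  return List::create(_["loss"] = loss,
                      _["grad"] = weights_to_list(g, ar));
}

// [[Rcpp::export]]
arma::mat nn_predict_cpp(SEXP Xs, List arch, List weights) {
  Arch ar = parse_arch(arch);
  Weights w = parse_weights(weights, ar);
  cube Xc; mat Xd;
  int N;
  if (ar.conv) { Xc = as<cube>(Xs); N = Xc.n_slices; }
  else { Xd = as<mat>(Xs); N = Xd.n_cols; }
  mat out(ar.F, N);
  mat M, Araw;
  if (ar.conv) M.set_size(ar.C * ar.w, ar.Lc);
  vec flat, z1, h1, z2;
  uvec amax;
  for (int i = 0; i < N; ++i) {
    if (ar.conv) {
      im2col(Xc.slice(i), ar.w, M);
      conv_pool(ar, w, M, Araw, flat, amax);
    } else flat = Xd.col(i);
    dense_forward(w, flat, z1, h1, z2);
    for (int f = 0; f < ar.F; ++f) out(f, i) = sigmoid(z2(f));
  }
  return out;
}

// Full two-phase saturated mutagenesis of one window.
// X: C x L one-hot (C = 4); refidx: length-L 0-based base index, -1 for N.
// Returns p_ref plus an L x 3 matrix of mutant probabilities (non-reference
// bases in A<C<G<T order). Rows with refidx == -1 are filled with p_ref.
// Uses incremental recomputation of the conv feature map: a single-base edit
// touches at most `kernel` conv columns and at most two pool segments.
// [[Rcpp::export]]
List mutagenesis_two_phase_cpp(arma::mat X, List arch1, List weights1,
                               List arch2, List weights2,
                               arma::ivec refidx) {
  Arch a1 = parse_arch(arch1), a2 = parse_arch(arch2);
  if (!a1.conv || a2.conv) stop("phase1 must be conv, phase2 dense");
  Weights w1 = parse_weights(weights1, a1), w2 = parse_weights(weights2, a2);
  int L = X.n_cols;
  if ((int)X.n_rows != a1.C || L != a1.L) stop("window shape mismatch");

  mat M(a1.C * a1.w, a1.Lc);
  im2col(X, a1.w, M);
  mat Araw; vec flat; uvec amax;
  conv_pool(a1, w1, M, Araw, flat, amax);

  // per-segment ReLU'd maxima are in `flat`; recompute helper for a segment
  // with some replaced columns held in Anew (k x ncols starting at c0new)
  vec z1, h1, z2, fz1, fh1, fz2;
  dense_forward(w1, flat, z1, h1, z2);
  vec p1(a1.F);
  for (int f = 0; f < a1.F; ++f) p1(f) = sigmoid(z2(f));
  dense_forward(w2, p1, fz1, fh1, fz2);
  double p_ref = sigmoid(fz2(0));

  mat alt(L, 3);
  vec flat2 = flat;
  for (int i = 0; i < L; ++i) {
    int rb = refidx(i);
    if (rb < 0) { alt.row(i).fill(p_ref); continue; }
    int p0 = std::max(0, i - a1.w + 1);
    int p1c = std::min(a1.Lc - 1, i);
    int s0 = p0 / a1.P, s1 = p1c / a1.P;
    int col = 0;
    for (int b = 0; b < 4; ++b) {
      if (b == rb) continue;
      // new conv activations for affected columns
      int nc = p1c - p0 + 1;
      mat Anew(a1.K, nc);
      for (int p = p0; p <= p1c; ++p) {
        // conv at column p with X(:, i) replaced by e_b:
        // subtract old contribution of base rb, add base b, at offset i-p
        int off = i - p;
        vec acol = Araw.col(p);
        for (int k = 0; k < a1.K; ++k) {
          double delta = w1.Wc(k, b + off * a1.C) - w1.Wc(k, rb + off * a1.C);
          acol(k) += delta;
        }
        Anew.col(p - p0) = acol;
      }
      // update affected pool segments in flat2 (max and mean channels)
      int half = a1.K * a1.npool;
      for (int s = s0; s <= s1; ++s) {
        int c0 = s * a1.P;
        int c1 = std::min(a1.Lc, c0 + a1.P) - 1;
        for (int k = 0; k < a1.K; ++k) {
          double best = 0.0, sum = 0.0;
          for (int c = c0; c <= c1; ++c) {
            double v = (c >= p0 && c <= p1c) ? Anew(k, c - p0) : Araw(k, c);
            if (v > best) best = v;
            if (v > 0) sum += v;
          }
          flat2(k + s * a1.K) = best;
          if (a1.mean_channel) flat2(half + k + s * a1.K) = sum / (c1 - c0 + 1);
        }
      }
      dense_forward(w1, flat2, z1, h1, z2);
      vec q(a1.F);
      for (int f = 0; f < a1.F; ++f) q(f) = sigmoid(z2(f));
      dense_forward(w2, q, fz1, fh1, fz2);
      alt(i, col++) = sigmoid(fz2(0));
      // restore touched segments
      for (int s = s0; s <= s1; ++s)
        for (int k = 0; k < a1.K; ++k) {
          flat2(k + s * a1.K) = flat(k + s * a1.K);
          if (a1.mean_channel)
            flat2(half + k + s * a1.K) = flat(half + k + s * a1.K);
        }
    }
  }
  return List::create(_["p_ref"] = p_ref, _["alt"] = alt);
}
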