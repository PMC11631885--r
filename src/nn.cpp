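// Large-kernel 1D convolutional sequence labeller.
//
// Architecture: stem conv (1 -> C, kernel k) -> BN -> ReLU, then `nblocks`
// residual blocks (conv C -> C kernel k -> BN -> ReLU, identity added), then a
// width-1 convolution to `nclasses` logits and a per-position softmax.
// Stride 1 with zero padding of (k-1)/2 per side keeps the output length equal
// to the input length.
//
// All arithmetic is float32 (standard for CNN training) with double
// accumulation for losses. Convolutions are evaluated as k shifted GEMMs over
// a zero-padded stack of the batch, so BLAS does the bulk of the work; the
// per-item pre/post padding of (k-1)/2 zero rows guarantees a shifted read
// never crosses into a neighbouring item's data.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

namespace {

struct Net {
  int k = 151, C = 64, nblocks = 5, nclasses = 3;
  fmat stemW;               // k x C (single input channel)
  std::vector<fcube> W;     // nblocks cubes, each C x C x k (slice = Cin x Cout)
  fmat headW;               // C x nclasses
  fvec headB;               // nclasses
  // one BN per conv: index 0 = stem, 1..nblocks = blocks
  std::vector<fvec> gam, bet, rmean, rvar;
};

const float BN_EPS = 1e-5f;

Net net_from_list(const List& L) {
  Net n;
  n.k = Rcpp::as<int>(L["kernel_size"]);
  n.C = Rcpp::as<int>(L["channels"]);
  n.nblocks = Rcpp::as<int>(L["n_blocks"]);
  n.nclasses = Rcpp::as<int>(L["n_classes"]);
  n.stemW = conv_to<fmat>::from(Rcpp::as<arma::mat>(L["stem_w"]));
  List bw = L["block_w"];
  for (int i = 0; i < n.nblocks; ++i) {
    Rcpp::NumericVector a = bw[i];
    Rcpp::IntegerVector d = a.attr("dim");
    cube c(a.begin(), d[0], d[1], d[2]);
    n.W.push_back(conv_to<fcube>::from(c));
  }
  n.headW = conv_to<fmat>::from(Rcpp::as<arma::mat>(L["head_w"]));
  n.headB = conv_to<fvec>::from(Rcpp::as<arma::vec>(L["head_b"]));
  List g = L["bn_gamma"], b = L["bn_beta"], rm = L["bn_rmean"], rv = L["bn_rvar"];
  for (int i = 0; i <= n.nblocks; ++i) {
    n.gam.push_back(conv_to<fvec>::from(Rcpp::as<arma::vec>(g[i])));
    n.bet.push_back(conv_to<fvec>::from(Rcpp::as<arma::vec>(b[i])));
    n.rmean.push_back(conv_to<fvec>::from(Rcpp::as<arma::vec>(rm[i])));
    n.rvar.push_back(conv_to<fvec>::from(Rcpp::as<arma::vec>(rv[i])));
  }
  return n;
}

List net_to_list(const Net& n) {
  List bw(n.nblocks);
  for (int i = 0; i < n.nblocks; ++i) {
    cube c = conv_to<cube>::from(n.W[i]);
    Rcpp::NumericVector a(c.begin(), c.end());
    a.attr("dim") = Rcpp::IntegerVector::create(n.C, n.C, n.k);
    bw[i] = a;
  }
  List g(n.nblocks + 1), b(n.nblocks + 1), rm(n.nblocks + 1), rv(n.nblocks + 1);
  for (int i = 0; i <= n.nblocks; ++i) {
    g[i] = conv_to<vec>::from(n.gam[i]);
    b[i] = conv_to<vec>::from(n.bet[i]);
    rm[i] = conv_to<vec>::from(n.rmean[i]);
    rv[i] = conv_to<vec>::from(n.rvar[i]);
  }
  return List::create(
      Named("kernel_size") = n.k, Named("channels") = n.C,
      Named("n_blocks") = n.nblocks, Named("n_classes") = n.nclasses,
      Named("stem_w") = conv_to<mat>::from(n.stemW), Named("block_w") = bw,
      Named("head_w") = conv_to<mat>::from(n.headW),
      Named("head_b") = conv_to<vec>::from(n.headB), Named("bn_gamma") = g,
      Named("bn_beta") = b, Named("bn_rmean") = rm, Named("bn_rvar") = rv);
}

// Scatter valid rows (B*T x C) into a zero-padded stack (B*(T+2P) x C).
fmat pad_stack(const fmat& V, int B, int T, int P) {
  const int Hb = T + 2 * P;
  fmat X(B * Hb, V.n_cols, fill::zeros);
  for (int b = 0; b < B; ++b)
    X.rows(b * Hb + P, b * Hb + P + T - 1) = V.rows(b * T, b * T + T - 1);
  return X;
}

// Same-length conv over the padded stack; slice kk of W is Cin x Cout.
// Valid output position t of item b lands at full-row index b*(T+2P)+t.
fmat conv_fwd(const fmat& V, int B, int T, int P, const fcube& W) {
  fmat X = pad_stack(V, B, T, P);
  const int k = W.n_slices, H = X.n_rows, Hb = T + 2 * P;
  fmat Yfull(H - k + 1, W.n_cols, fill::zeros);
  for (int kk = 0; kk < k; ++kk)
    Yfull += X.rows(kk, kk + H - k) * W.slice(kk);
  fmat Yv(B * T, W.n_cols);
  for (int b = 0; b < B; ++b)
    Yv.rows(b * T, b * T + T - 1) = Yfull.rows(b * Hb, b * Hb + T - 1);
  return Yv;
}

void conv_bwd(const fmat& V, const fmat& dYv, int B, int T, int P,
              const fcube& W, fmat& dV, fcube& dW) {
  fmat X = pad_stack(V, B, T, P);
  const int k = W.n_slices, H = X.n_rows, Hb = T + 2 * P;
  fmat dYfull(H - k + 1, dYv.n_cols, fill::zeros);
  for (int b = 0; b < B; ++b)
    dYfull.rows(b * Hb, b * Hb + T - 1) = dYv.rows(b * T, b * T + T - 1);
  fmat dX(H, X.n_cols, fill::zeros);
  dW.zeros(W.n_rows, W.n_cols, k);
  for (int kk = 0; kk < k; ++kk) {
    dX.rows(kk, kk + H - k) += dYfull * W.slice(kk).t();
    dW.slice(kk) = X.rows(kk, kk + H - k).t() * dYfull;
  }
  dV.set_size(B * T, X.n_cols);
  for (int b = 0; b < B; ++b)
    dV.rows(b * T, b * T + T - 1) = dX.rows(b * Hb + P, b * Hb + P + T - 1);
}

struct BnCache {
  fmat xhat;
  fvec istd;
};

fmat bn_fwd_train(const fmat& X, fvec& gam, fvec& bet, fvec& rmean, fvec& rvar,
                  float momentum, BnCache& cache) {
  const float N = static_cast<float>(X.n_rows);
  frowvec mu = mean(X, 0);
  frowvec va = mean(square(X.each_row() - mu), 0);
  fvec istd = 1.0f / sqrt(va.t() + BN_EPS);
  cache.xhat = (X.each_row() - mu);
  cache.xhat.each_row() %= istd.t();
  cache.istd = istd;
  rmean = (1.0f - momentum) * rmean + momentum * mu.t();
  rvar = (1.0f - momentum) * rvar + momentum * (va.t() * (N / std::max(N - 1.0f, 1.0f)));
  fmat Y = cache.xhat;
  Y.each_row() %= gam.t();
  Y.each_row() += bet.t();
  return Y;
}

fmat bn_fwd_infer(const fmat& X, const fvec& gam, const fvec& bet,
                  const fvec& rmean, const fvec& rvar) {
  fvec istd = 1.0f / sqrt(rvar + BN_EPS);
  fmat Y = X.each_row() - rmean.t();
  Y.each_row() %= (gam % istd).t();
  Y.each_row() += bet.t();
  return Y;
}

fmat bn_bwd(const fmat& dY, const BnCache& cache, const fvec& gam, fvec& dgam,
            fvec& dbet) {
  const float N = static_cast<float>(dY.n_rows);
  dgam = sum(dY % cache.xhat, 0).t();
  dbet = sum(dY, 0).t();
  fmat dxhat = dY;
  dxhat.each_row() %= gam.t();
  frowvec s1 = sum(dxhat, 0);
  frowvec s2 = sum(dxhat % cache.xhat, 0);
  fmat dX = N * dxhat;
  dX.each_row() -= s1;
  dX -= cache.xhat.each_row() % s2;
  dX.each_row() %= (cache.istd.t() / N);
  return dX;
}

// stem weights are stored k x C; conv machinery wants a 1 x C x k cube
fcube stem_as_cube(const fmat& stemW) {
  const int k = stemW.n_rows, C = stemW.n_cols;
  fcube c(1, C, k);
  for (int kk = 0; kk < k; ++kk)
    for (int cc = 0; cc < C; ++cc) c(0, cc, kk) = stemW(kk, cc);
  return c;
}

// Per-position softmax of logits (rows), in place; returns probs.
fmat softmax_rows(const fmat& Z) {
  fmat P = Z.each_col() - max(Z, 1);
  P = exp(P);
  P.each_col() /= sum(P, 1);
  return P;
}

// Combined CE + focal loss on the true-class probability:
// L = (1 + alpha*(1-p)^gamma) * (-log p), p clipped to [eps, 1-eps].
// Returns mean loss; fills dlogits (softmax jacobian applied) if wanted.
double loss_and_grad(const fmat& probs, const Rcpp::IntegerVector& y,
                     double alpha, double gamma, double eps, fmat* dlogits) {
  const uword N = probs.n_rows;
  double total = 0.0;
  if (dlogits) dlogits->zeros(N, probs.n_cols);
  for (uword i = 0; i < N; ++i) {
    const int t = y[i];
    double p = std::min(std::max(static_cast<double>(probs(i, t)), eps), 1.0 - eps);
    double focal = alpha * std::pow(1.0 - p, gamma);
    total += (1.0 + focal) * (-std::log(p));
    if (dlogits) {
      double dLdp = -(1.0 + focal) / p;
      if (gamma > 0.0)
        dLdp += alpha * gamma * std::pow(1.0 - p, gamma - 1.0) * std::log(p);
      const double g = dLdp * p / static_cast<double>(N);
      for (uword j = 0; j < probs.n_cols; ++j)
        (*dlogits)(i, j) = static_cast<float>(-g * probs(i, j));
      (*dlogits)(i, t) += static_cast<float>(g);
    }
  }
  return total / static_cast<double>(N);
}

struct FwdCache {
  fmat stem_in, stem_bnout;          // input; BN output pre-ReLU (mask source)
  BnCache stem_bn;
  std::vector<fmat> blk_in, blk_bnout;  // block input; BN output pre-ReLU
  std::vector<BnCache> blk_bn;
  fmat head_in, probs;
};

// Forward over a stacked batch V (B*T x 1). training selects batch vs running BN.
fmat forward(Net& net, const fmat& V, int B, int T, bool training,
             float momentum, FwdCache* cache) {
  const int P = (net.k - 1) / 2;
  fcube stemC = stem_as_cube(net.stemW);
  fmat h;
  {
    fmat z = conv_fwd(V, B, T, P, stemC);
    fmat zb;
    BnCache bc;
    if (training)
      zb = bn_fwd_train(z, net.gam[0], net.bet[0], net.rmean[0], net.rvar[0],
                        momentum, bc);
    else
      zb = bn_fwd_infer(z, net.gam[0], net.bet[0], net.rmean[0], net.rvar[0]);
    h = clamp(zb, 0.0f, std::numeric_limits<float>::max());
    if (cache) {
      cache->stem_in = V;
      cache->stem_bnout = zb;
      cache->stem_bn = bc;
    }
  }
  for (int i = 0; i < net.nblocks; ++i) {
    if (cache) cache->blk_in.push_back(h);
    fmat z = conv_fwd(h, B, T, P, net.W[i]);
    fmat zb;
    BnCache bc;
    if (training)
      zb = bn_fwd_train(z, net.gam[i + 1], net.bet[i + 1], net.rmean[i + 1],
                        net.rvar[i + 1], momentum, bc);
    else
      zb = bn_fwd_infer(z, net.gam[i + 1], net.bet[i + 1], net.rmean[i + 1],
                        net.rvar[i + 1]);
    fmat r = clamp(zb, 0.0f, std::numeric_limits<float>::max());
    if (cache) {
      cache->blk_bnout.push_back(zb);
      cache->blk_bn.push_back(bc);
    }
    h += r;  // identity residual
  }
  fmat logits = h * net.headW;
  logits.each_row() += net.headB.t();
  fmat probs = softmax_rows(logits);
  if (cache) {
    cache->head_in = h;
    cache->probs = probs;
  }
  return probs;
}

struct Grads {
  fmat stemW, headW;
  fvec headB;
  std::vector<fcube> W;
  std::vector<fvec> gam, bet;
};

void backward(Net& net, FwdCache& c, const fmat& dlogits, int B, int T,
              Grads& g) {
  const int P = (net.k - 1) / 2;
  g.headW = c.head_in.t() * dlogits;
  g.headB = sum(dlogits, 0).t();
  fmat dh = dlogits * net.headW.t();
  g.W.assign(net.nblocks, fcube());
  g.gam.assign(net.nblocks + 1, fvec());
  g.bet.assign(net.nblocks + 1, fvec());
  for (int i = net.nblocks - 1; i >= 0; --i) {
    fmat dr = dh % conv_to<fmat>::from(c.blk_bnout[i] > 0.0f);
    fmat dz = bn_bwd(dr, c.blk_bn[i], net.gam[i + 1], g.gam[i + 1], g.bet[i + 1]);
    fmat dvin;
    conv_bwd(c.blk_in[i], dz, B, T, P, net.W[i], dvin, g.W[i]);
    dh += dvin;  // identity path already in dh
  }
  fmat dr = dh % conv_to<fmat>::from(c.stem_bnout > 0.0f);
  fmat dz = bn_bwd(dr, c.stem_bn, net.gam[0], g.gam[0], g.bet[0]);
  fcube stemC = stem_as_cube(net.stemW);
  fmat dvin;
  fcube dstem;
  conv_bwd(c.stem_in, dz, B, T, P, stemC, dvin, dstem);
  // stem weights live as k x C; dstem is 1 x C x k
  g.stemW.set_size(net.k, net.C);
  for (int kk = 0; kk < net.k; ++kk)
    for (int cc = 0; cc < net.C; ++cc) g.stemW(kk, cc) = dstem(0, cc, kk);
}

}  // namespace

// [[Rcpp::export]]
List cpp_nn_init(int kernel_size, int channels, int n_blocks, int n_classes,
                 int seed) {
  Net n;
  n.k = kernel_size;
  n.C = channels;
  n.nblocks = n_blocks;
  n.nclasses = n_classes;
  std::mt19937 rng(static_cast<uint32_t>(seed));
  auto rnorm = [&](float sd) {
    std::normal_distribution<float> d(0.0f, sd);
    return [&rng, d]() mutable { return d(rng); };
  };
  {
    auto g = rnorm(std::sqrt(2.0f / (kernel_size * 1)));
    n.stemW.set_size(kernel_size, channels);
    n.stemW.imbue(g);
  }
  for (int i = 0; i < n_blocks; ++i) {
    auto g = rnorm(std::sqrt(2.0f / (kernel_size * channels)));
    fcube w(channels, channels, kernel_size);
    w.imbue(g);
    n.W.push_back(w);
  }
  {
    auto g = rnorm(std::sqrt(1.0f / channels));
    n.headW.set_size(channels, n_classes);
    n.headW.imbue(g);
    n.headB.zeros(n_classes);
  }
  for (int i = 0; i <= n_blocks; ++i) {
    n.gam.push_back(fvec(channels, fill::ones));
    n.bet.push_back(fvec(channels, fill::zeros));
    n.rmean.push_back(fvec(channels, fill::zeros));
    n.rvar.push_back(fvec(channels, fill::ones));
  }
  return net_to_list(n);
}

// X: n x T matrix of 0/1 doubles. Returns n x T x nclasses probability array
// (inference mode: BN running statistics).
// [[Rcpp::export]]
Rcpp::NumericVector cpp_nn_forward(List net_r, const arma::mat& X) {
  Net net = net_from_list(net_r);
  const int n = X.n_rows, T = X.n_cols;
  fmat V(n * T, 1);
  for (int b = 0; b < n; ++b)
    for (int t = 0; t < T; ++t) V(b * T + t, 0) = static_cast<float>(X(b, t));
  fmat probs = forward(net, V, n, T, false, 0.1f, nullptr);
  Rcpp::NumericVector out(n * T * net.nclasses);
  out.attr("dim") = Rcpp::IntegerVector::create(n, T, net.nclasses);
  for (int b = 0; b < n; ++b)
    for (int t = 0; t < T; ++t)
      for (int c = 0; c < net.nclasses; ++c)
        out[b + n * (t + T * c)] = probs(b * T + t, c);
  return out;
}

// [[Rcpp::export]]
double cpp_nn_eval_loss(List net_r, const arma::mat& X,
                        const Rcpp::IntegerMatrix& Y, double alpha,
                        double gamma, double clip_eps) {
  Net net = net_from_list(net_r);
  const int n = X.n_rows, T = X.n_cols;
  fmat V(n * T, 1);
  Rcpp::IntegerVector y(n * T);
  for (int b = 0; b < n; ++b)
    for (int t = 0; t < T; ++t) {
      V(b * T + t, 0) = static_cast<float>(X(b, t));
      y[b * T + t] = Y(b, t);
    }
  fmat probs = forward(net, V, n, T, false, 0.1f, nullptr);
  return loss_and_grad(probs, y, alpha, gamma, clip_eps, nullptr);
}

// [[Rcpp::export]]
List cpp_nn_train(List net_r, const arma::mat& X, const Rcpp::IntegerMatrix& Y,
                  List opts) {
  Net net = net_from_list(net_r);
  const int n = X.n_rows, T = X.n_cols;
  const int epochs = Rcpp::as<int>(opts["epochs"]);
  const int batch = std::max(1, Rcpp::as<int>(opts["batch_size"]));
  const double lr = Rcpp::as<double>(opts["learning_rate"]);
  const double alpha = Rcpp::as<double>(opts["alpha"]);
  const double gamma = Rcpp::as<double>(opts["gamma"]);
  const double clip_eps = Rcpp::as<double>(opts["clip_eps"]);
  const double val_frac = Rcpp::as<double>(opts["validation_fraction"]);
  const int patience = Rcpp::as<int>(opts["patience"]);
  const int seed = Rcpp::as<int>(opts["seed"]);
  const float momentum = 0.1f;
  const float b1 = 0.9f, b2 = 0.999f, adam_eps = 1e-8f;

  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::vector<int> idx(n);
  std::iota(idx.begin(), idx.end(), 0);
  std::shuffle(idx.begin(), idx.end(), rng);
  const int n_val = static_cast<int>(std::floor(val_frac * n + 0.5));
  std::vector<int> val_idx(idx.end() - n_val, idx.end());
  std::vector<int> tr_idx(idx.begin(), idx.end() - n_val);
  if (tr_idx.empty()) Rcpp::stop("empty training split");

  // Adam moment mirrors, one pair per parameter array
  Grads m, v;
  m.stemW.zeros(size(net.stemW)); v.stemW.zeros(size(net.stemW));
  m.headW.zeros(size(net.headW)); v.headW.zeros(size(net.headW));
  m.headB.zeros(net.headB.n_elem); v.headB.zeros(net.headB.n_elem);
  for (int i = 0; i < net.nblocks; ++i) {
    m.W.push_back(fcube(size(net.W[i]), fill::zeros));
    v.W.push_back(fcube(size(net.W[i]), fill::zeros));
  }
  for (int i = 0; i <= net.nblocks; ++i) {
    m.gam.push_back(fvec(net.C, fill::zeros));
    v.gam.push_back(fvec(net.C, fill::zeros));
    m.bet.push_back(fvec(net.C, fill::zeros));
    v.bet.push_back(fvec(net.C, fill::zeros));
  }
  long step = 0;
  auto adam = [&](auto& w, const auto& g, auto& mm, auto& vv) {
    mm = b1 * mm + (1.0f - b1) * g;
    vv = b2 * vv + (1.0f - b2) * square(g);
    const float bc1 = 1.0f - std::pow(b1, static_cast<float>(step));
    const float bc2 = 1.0f - std::pow(b2, static_cast<float>(step));
    w -= static_cast<float>(lr) * (mm / bc1) / (sqrt(vv / bc2) + adam_eps);
  };

  std::vector<double> tr_hist, val_hist;
  Net best = net;
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = -1, wait = 0;

  auto make_batch = [&](const std::vector<int>& which, fmat& V,
                        Rcpp::IntegerVector& y) {
    const int B = static_cast<int>(which.size());
    V.set_size(B * T, 1);
    y = Rcpp::IntegerVector(B * T);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < T; ++t) {
        V(b * T + t, 0) = static_cast<float>(X(which[b], t));
        y[b * T + t] = Y(which[b], t);
      }
  };

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(tr_idx.begin(), tr_idx.end(), rng);
    double ep_loss = 0.0;
    int n_batches = 0;
    for (size_t s = 0; s < tr_idx.size(); s += batch) {
      std::vector<int> which(tr_idx.begin() + s,
                             tr_idx.begin() + std::min(s + batch, tr_idx.size()));
      const int B = static_cast<int>(which.size());
      fmat V;
      Rcpp::IntegerVector y;
      make_batch(which, V, y);
      FwdCache cache;
      fmat probs = forward(net, V, B, T, true, momentum, &cache);
      fmat dlogits;
      double L = loss_and_grad(probs, y, alpha, gamma, clip_eps, &dlogits);
      if (!std::isfinite(L))
        Rcpp::stop("non-finite training loss at epoch %d", ep + 1);
      ep_loss += L;
      ++n_batches;
      Grads g;
      backward(net, cache, dlogits, B, T, g);
      ++step;
      adam(net.stemW, g.stemW, m.stemW, v.stemW);
      for (int i = 0; i < net.nblocks; ++i) adam(net.W[i], g.W[i], m.W[i], v.W[i]);
      adam(net.headW, g.headW, m.headW, v.headW);
      adam(net.headB, g.headB, m.headB, v.headB);
      for (int i = 0; i <= net.nblocks; ++i) {
        adam(net.gam[i], g.gam[i], m.gam[i], v.gam[i]);
        adam(net.bet[i], g.bet[i], m.bet[i], v.bet[i]);
      }
      Rcpp::checkUserInterrupt();
    }
    tr_hist.push_back(ep_loss / std::max(1, n_batches));

    double vl = NA_REAL;
    if (n_val > 0) {
      fmat V;
      Rcpp::IntegerVector y;
      make_batch(val_idx, V, y);
      fmat probs = forward(net, V, n_val, T, false, momentum, nullptr);
      vl = loss_and_grad(probs, y, alpha, gamma, clip_eps, nullptr);
      val_hist.push_back(vl);
      if (vl < best_val - 1e-9) {
        best_val = vl;
        best = net;
        best_epoch = ep + 1;
        wait = 0;
      } else if (++wait >= patience) {
        break;
      }
    }
  }
  const Net& final_net = (n_val > 0 && best_epoch > 0) ? best : net;
  return List::create(
      Named("net") = net_to_list(final_net),
      Named("train_loss") = tr_hist, Named("val_loss") = val_hist,
      Named("best_epoch") = best_epoch,
      Named("n_train") = static_cast<int>(tr_idx.size()),
      Named("n_val") = n_val);
}
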