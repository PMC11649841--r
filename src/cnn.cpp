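// Compact CNN for scoring windowed time-lagged cross-correlation matrices.
// Architecture: conv blocks (same-padding conv -> ReLU -> 2x2 max pool),
// global average pooling, one dense ReLU layer (the embedding), dropout,
// sigmoid output.  Trained with Adam on weighted binary cross-entropy.
// Single-threaded; all randomness goes through R's RNG so results are
// reproducible with set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

struct ConvLayer {
  std::vector<cube> W;   // one (k x k x Cin) cube per filter
  vec b;
  int k;
};

struct Net {
  std::vector<ConvLayer> conv;
  mat dense_W;   // D x Cgap
  vec dense_b;   // D
  vec out_w;     // D
  double out_b;
  int pool;
};

struct Cache {
  std::vector<cube> A;        // inputs to each conv layer
  std::vector<cube> Z;        // pre-activation conv outputs
  std::vector<cube> P;        // pooled activations
  std::vector<arma::ucube> argr, argc;  // pool argmax coordinates
  vec g;                      // GAP vector
  vec e_pre, e, e_drop, mask; // dense layer
  double z, p;
};

static cube pad_cube(const cube& A, int p) {
  cube Ap(A.n_rows + 2 * p, A.n_cols + 2 * p, A.n_slices, arma::fill::zeros);
  Ap.subcube(p, p, 0, p + A.n_rows - 1, p + A.n_cols - 1, A.n_slices - 1) = A;
  return Ap;
}

static cube conv_same(const cube& A, const ConvLayer& L) {
  const int R = A.n_rows, C = A.n_cols, Cin = A.n_slices;
  const int F = L.W.size(), k = L.k, p = k / 2;
  cube Ap = pad_cube(A, p);
  cube Z(R, C, F);
  for (int f = 0; f < F; ++f) {
    mat acc(R, C, arma::fill::value(L.b(f)));
    for (int c = 0; c < Cin; ++c)
      for (int a = 0; a < k; ++a)
        for (int bb = 0; bb < k; ++bb)
          acc += L.W[f](a, bb, c) *
                 Ap.slice(c).submat(a, bb, a + R - 1, bb + C - 1);
    Z.slice(f) = acc;
  }
  return Z;
}

static void pool_forward(const cube& Zr, int pool, cube& P,
                         arma::ucube& argr, arma::ucube& argc) {
  const int R2 = Zr.n_rows / pool, C2 = Zr.n_cols / pool, F = Zr.n_slices;
  P.set_size(R2, C2, F);
  argr.set_size(R2, C2, F);
  argc.set_size(R2, C2, F);
  for (int f = 0; f < F; ++f)
    for (int i = 0; i < R2; ++i)
      for (int j = 0; j < C2; ++j) {
        double best = -arma::datum::inf;
        int br = 0, bc = 0;
        for (int a = 0; a < pool; ++a)
          for (int b = 0; b < pool; ++b) {
            double v = Zr(i * pool + a, j * pool + b, f);
            if (v > best) { best = v; br = i * pool + a; bc = j * pool + b; }
          }
        P(i, j, f) = best;
        argr(i, j, f) = br;
        argc(i, j, f) = bc;
      }
}

static double forward(const Net& net, const mat& x, Cache& cc,
                      bool training, double dropout) {
  const int L = net.conv.size();
  cc.A.assign(L, cube());
  cc.Z.assign(L, cube());
  cc.P.assign(L, cube());
  cc.argr.assign(L, arma::ucube());
  cc.argc.assign(L, arma::ucube());
  cube A(x.n_rows, x.n_cols, 1);
  A.slice(0) = x;
  for (int l = 0; l < L; ++l) {
    cc.A[l] = A;
    cc.Z[l] = conv_same(A, net.conv[l]);
    cube Zr = arma::clamp(cc.Z[l], 0.0, arma::datum::inf);
    pool_forward(Zr, net.pool, cc.P[l], cc.argr[l], cc.argc[l]);
    A = cc.P[l];
  }
  // flatten the final feature map: the lag position of correlation ridges
  // is the discriminative feature, so spatial information must survive into
  // the dense layer (no global pooling)
  cc.g = arma::vectorise(A);
  cc.e_pre = net.dense_W * cc.g + net.dense_b;
  cc.e = arma::clamp(cc.e_pre, 0.0, arma::datum::inf);
  cc.mask.ones(cc.e.n_elem);
  if (training && dropout > 0) {
    for (arma::uword i = 0; i < cc.mask.n_elem; ++i)
      cc.mask(i) = (R::unif_rand() < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
  }
  cc.e_drop = cc.e % cc.mask;
  cc.z = arma::dot(net.out_w, cc.e_drop) + net.out_b;
  cc.p = 1.0 / (1.0 + std::exp(-cc.z));
  return cc.p;
}

// Gradient accumulators mirror Net
struct Grads {
  std::vector<ConvLayer> conv;
  mat dense_W; vec dense_b; vec out_w; double out_b;
  void zero_like(const Net& net) {
    conv.resize(net.conv.size());
    for (size_t l = 0; l < net.conv.size(); ++l) {
      conv[l].k = net.conv[l].k;
      conv[l].b = arma::zeros<vec>(net.conv[l].b.n_elem);
      conv[l].W.assign(net.conv[l].W.size(),
                       cube(net.conv[l].W[0].n_rows, net.conv[l].W[0].n_cols,
                            net.conv[l].W[0].n_slices, arma::fill::zeros));
    }
    dense_W = arma::zeros<mat>(net.dense_W.n_rows, net.dense_W.n_cols);
    dense_b = arma::zeros<vec>(net.dense_b.n_elem);
    out_w = arma::zeros<vec>(net.out_w.n_elem);
    out_b = 0.0;
  }
};

static void backward(const Net& net, const Cache& cc, double dz, Grads& g) {
  g.out_w += dz * cc.e_drop;
  g.out_b += dz;
  vec de = (dz * net.out_w) % cc.mask;
  vec de_pre = de % arma::conv_to<vec>::from(cc.e_pre > 0);
  g.dense_W += de_pre * cc.g.t();
  g.dense_b += de_pre;
  vec dg = net.dense_W.t() * de_pre;
  const int L = net.conv.size();
  // un-flatten the gradient back onto the final feature map
  const cube& Plast = cc.P[L - 1];
  cube dP(Plast.n_rows, Plast.n_cols, Plast.n_slices);
  std::memcpy(dP.memptr(), dg.memptr(), dg.n_elem * sizeof(double));
  for (int l = L - 1; l >= 0; --l) {
    const cube& Z = cc.Z[l];
    cube dZ(Z.n_rows, Z.n_cols, Z.n_slices, arma::fill::zeros);
    // unpool
    for (arma::uword f = 0; f < dP.n_slices; ++f)
      for (arma::uword i = 0; i < dP.n_rows; ++i)
        for (arma::uword j = 0; j < dP.n_cols; ++j)
          dZ(cc.argr[l](i, j, f), cc.argc[l](i, j, f), f) += dP(i, j, f);
    // ReLU
    dZ %= arma::conv_to<cube>::from(Z > 0);
    const ConvLayer& Lw = net.conv[l];
    const cube& A = cc.A[l];
    const int R = A.n_rows, C = A.n_cols, Cin = A.n_slices;
    const int F = Lw.W.size(), k = Lw.k, p = k / 2;
    cube Ap = pad_cube(A, p);
    cube dAp(Ap.n_rows, Ap.n_cols, Cin, arma::fill::zeros);
    for (int f = 0; f < F; ++f) {
      g.conv[l].b(f) += arma::accu(dZ.slice(f));
      for (int c = 0; c < Cin; ++c)
        for (int a = 0; a < k; ++a)
          for (int bb = 0; bb < k; ++bb) {
            g.conv[l].W[f](a, bb, c) +=
              arma::accu(dZ.slice(f) %
                         Ap.slice(c).submat(a, bb, a + R - 1, bb + C - 1));
            dAp.slice(c).submat(a, bb, a + R - 1, bb + C - 1) +=
              Lw.W[f](a, bb, c) * dZ.slice(f);
          }
    }
    if (l > 0)
      dP = dAp.subcube(p, p, 0, p + R - 1, p + C - 1, Cin - 1);
  }
}

// ---- Adam ----------------------------------------------------------------
struct Adam {
  Grads m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const Net& net) { m.zero_like(net); v.zero_like(net); }
  void upd(double& w, double& mm, double& vv, double gg, double lr) {
    mm = b1 * mm + (1 - b1) * gg;
    vv = b2 * vv + (1 - b2) * gg * gg;
    double mh = mm / (1 - std::pow(b1, (double)t));
    double vh = vv / (1 - std::pow(b2, (double)t));
    w -= lr * mh / (std::sqrt(vh) + eps);
  }
  template <class T>
  void upd_arr(T& w, T& mm, T& vv, const T& gg, double lr) {
    for (arma::uword i = 0; i < w.n_elem; ++i)
      upd(w(i), mm(i), vv(i), gg(i), lr);
  }
  void step(Net& net, const Grads& g, double lr) {
    ++t;
    for (size_t l = 0; l < net.conv.size(); ++l) {
      for (size_t f = 0; f < net.conv[l].W.size(); ++f)
        upd_arr(net.conv[l].W[f], m.conv[l].W[f], v.conv[l].W[f],
                g.conv[l].W[f], lr);
      upd_arr(net.conv[l].b, m.conv[l].b, v.conv[l].b, g.conv[l].b, lr);
    }
    upd_arr(net.dense_W, m.dense_W, v.dense_W, g.dense_W, lr);
    upd_arr(net.dense_b, m.dense_b, v.dense_b, g.dense_b, lr);
    upd_arr(net.out_w, m.out_w, v.out_w, g.out_w, lr);
    upd(net.out_b, m.out_b, v.out_b, g.out_b, lr);
  }
};

// ---- (de)serialization ---------------------------------------------------
static List net_to_list(const Net& net) {
  List convs(net.conv.size());
  for (size_t l = 0; l < net.conv.size(); ++l) {
    const ConvLayer& L = net.conv[l];
    const int k = L.k, Cin = L.W[0].n_slices, F = L.W.size();
    NumericVector W(k * k * Cin * F);
    W.attr("dim") = IntegerVector::create(k, k, Cin, F);
    for (int f = 0; f < F; ++f)
      for (int c = 0; c < Cin; ++c)
        for (int bb = 0; bb < k; ++bb)
          for (int a = 0; a < k; ++a)
            W[((f * Cin + c) * k + bb) * k + a] = L.W[f](a, bb, c);
    convs[l] = List::create(_["W"] = W, _["b"] = NumericVector(L.b.begin(),
                                                               L.b.end()));
  }
  return List::create(
    _["conv"] = convs,
    _["dense_W"] = wrap(net.dense_W), _["dense_b"] = wrap(net.dense_b),
    _["out_w"] = wrap(net.out_w), _["out_b"] = net.out_b,
    _["pool"] = net.pool);
}

static Net net_from_list(const List& wl) {
  Net net;
  net.pool = as<int>(wl["pool"]);
  List convs = wl["conv"];
  for (int l = 0; l < convs.size(); ++l) {
    List cl = convs[l];
    NumericVector W = cl["W"];
    IntegerVector dim = W.attr("dim");
    const int k = dim[0], Cin = dim[2], F = dim[3];
    ConvLayer L;
    L.k = k;
    L.b = as<vec>(cl["b"]);
    L.W.assign(F, cube(k, k, Cin));
    for (int f = 0; f < F; ++f)
      for (int c = 0; c < Cin; ++c)
        for (int bb = 0; bb < k; ++bb)
          for (int a = 0; a < k; ++a)
            L.W[f](a, bb, c) = W[((f * Cin + c) * k + bb) * k + a];
    net.conv.push_back(L);
  }
  net.dense_W = as<mat>(wl["dense_W"]);
  net.dense_b = as<vec>(wl["dense_b"]);
  net.out_w = as<vec>(wl["out_w"]);
  net.out_b = as<double>(wl["out_b"]);
  return net;
}

static Net init_net(int R, int C, IntegerVector filters, int kernel,
                    int pool, int dense_width) {
  Net net;
  net.pool = pool;
  int Cin = 1, r = R, c = C;
  for (int l = 0; l < filters.size(); ++l) {
    ConvLayer L;
    L.k = kernel;
    const int F = filters[l];
    double sdw = std::sqrt(2.0 / (kernel * kernel * Cin));
    L.W.assign(F, cube(kernel, kernel, Cin));
    for (int f = 0; f < F; ++f)
      for (arma::uword i = 0; i < L.W[f].n_elem; ++i)
        L.W[f](i) = R::norm_rand() * sdw;
    L.b = arma::zeros<vec>(F);
    net.conv.push_back(L);
    Cin = F;
    r /= pool; c /= pool;
    if (r < 1 || c < 1)
      stop("matrix shape too small for the configured conv/pool stack");
  }
  const int D = dense_width;
  const int flat = r * c * Cin;
  double sdd = std::sqrt(2.0 / flat);
  net.dense_W.set_size(D, flat);
  for (arma::uword i = 0; i < net.dense_W.n_elem; ++i)
    net.dense_W(i) = R::norm_rand() * sdd;
  net.dense_b = arma::zeros<vec>(D);
  double sdo = std::sqrt(1.0 / D);
  net.out_w.set_size(D);
  for (int i = 0; i < D; ++i) net.out_w(i) = R::norm_rand() * sdo;
  net.out_b = 0.0;
  return net;
}

// [[Rcpp::export]]
List cnn_train_cpp(const arma::cube& X, const arma::vec& y,
                   const arma::vec& wts, IntegerVector filters, int kernel,
                   int pool, int dense_width, double dropout, double lr,
                   int batch_size, int epochs, const arma::cube& Xval,
                   const arma::vec& yval, bool has_val) {
  RNGScope scope;
  const int n = X.n_slices;
  Net net = init_net(X.n_rows, X.n_cols, filters, kernel, pool, dense_width);
  Adam adam;
  adam.init(net);
  Grads g;
  Cache cc;
  std::vector<double> tr_loss, va_loss;
  IntegerVector base = seq_len(n);
  for (int ep = 0; ep < epochs; ++ep) {
    IntegerVector ord = sample(base, n, false);  // R RNG permutation
    double loss = 0.0, wsum = 0.0;
    for (int b0 = 0; b0 < n; b0 += batch_size) {
      const int b1 = std::min(n, b0 + batch_size);
      g.zero_like(net);
      for (int ii = b0; ii < b1; ++ii) {
        const int i = ord[ii] - 1;
        double p = forward(net, X.slice(i), cc, true, dropout);
        p = std::min(1.0 - 1e-12, std::max(1e-12, p));
        loss += -wts(i) * (y(i) * std::log(p) +
                           (1 - y(i)) * std::log(1 - p));
        wsum += wts(i);
        backward(net, cc, wts(i) * (p - y(i)) / (b1 - b0), g);
      }
      adam.step(net, g, lr);
    }
    tr_loss.push_back(loss / wsum);
    if (has_val) {
      double vl = 0.0;
      for (arma::uword i = 0; i < Xval.n_slices; ++i) {
        double p = forward(net, Xval.slice(i), cc, false, 0.0);
        p = std::min(1.0 - 1e-12, std::max(1e-12, p));
        vl += -(yval(i) * std::log(p) + (1 - yval(i)) * std::log(1 - p));
      }
      va_loss.push_back(vl / Xval.n_slices);
    } else {
      va_loss.push_back(NA_REAL);
    }
  }
  return List::create(_["weights"] = net_to_list(net),
                      _["train_loss"] = wrap(tr_loss),
                      _["val_loss"] = wrap(va_loss));
}

// [[Rcpp::export]]
List cnn_forward_cpp(const List& weights, const arma::cube& X) {
  Net net = net_from_list(weights);
  const int n = X.n_slices;
  vec scores(n);
  Cache cc;
  mat emb;
  for (int i = 0; i < n; ++i) {
    scores(i) = forward(net, X.slice(i), cc, false, 0.0);
    if (i == 0) emb.set_size(n, cc.e.n_elem);
    emb.row(i) = cc.e.t();
  }
  return List::create(_["scores"] = wrap(scores),
                      _["embeddings"] = wrap(emb));
}
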