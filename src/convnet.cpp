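// Minimal sequential convolutional network used by the CNN observer and the
// small learned reconstructor.  Layers: 3x3 same-padding convolution, ReLU,
// 2x2 average pooling, 2x2 nearest-neighbour upsampling, dense readout, and
// a global residual connection to input channel 0.  Training is Adam on
// binary cross-entropy (scalar sigmoid readout) or mean-squared error
// (image output).  All randomness is driven by an explicit seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

enum LayerType { L_CONV = 1, L_RELU = 2, L_POOL = 3, L_UP = 4,
                 L_DENSE = 5, L_ADDIN = 6 };

struct Layer {
  int type;
  int p1;  // conv: cin, dense: input dim
  int p2;  // conv: cout
};

static std::vector<Layer> parseArch(const Rcpp::IntegerMatrix& arch) {
  std::vector<Layer> layers;
  for (int i = 0; i < arch.nrow(); ++i)
    layers.push_back({arch(i, 0), arch(i, 1), arch(i, 2)});
  return layers;
}

static int layerParams(const Layer& l) {
  if (l.type == L_CONV) return l.p2 * l.p1 * 9 + l.p2;
  if (l.type == L_DENSE) return l.p1 + 1;
  return 0;
}

// [[Rcpp::export]]
int cpp_net_nparams(Rcpp::IntegerMatrix arch) {
  int n = 0;
  for (const Layer& l : parseArch(arch)) n += layerParams(l);
  return n;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_net_init(Rcpp::IntegerMatrix arch, int seed) {
  std::vector<Layer> layers = parseArch(arch);
  int n = cpp_net_nparams(arch);
  Rcpp::NumericVector theta(n);
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  int off = 0;
  for (const Layer& l : layers) {
    if (l.type == L_CONV) {
      double sd = std::sqrt(2.0 / (9.0 * l.p1));  // He init
      for (int k = 0; k < l.p2 * l.p1 * 9; ++k) theta[off + k] = sd * gauss(rng);
      off += layerParams(l);  // biases stay zero
    } else if (l.type == L_DENSE) {
      double sd = std::sqrt(1.0 / l.p1);
      for (int k = 0; k < l.p1; ++k) theta[off + k] = sd * gauss(rng);
      off += layerParams(l);
    }
  }
  return theta;
}

static cube padChannels(const cube& in) {
  cube pad(in.n_rows + 2, in.n_cols + 2, in.n_slices, fill::zeros);
  for (uword c = 0; c < in.n_slices; ++c)
    pad.slice(c).submat(1, 1, in.n_rows, in.n_cols) = in.slice(c);
  return pad;
}

static cube convFwd(const cube& in, const double* w, int cin, int cout) {
  const uword H = in.n_rows, W = in.n_cols;
  cube pad = padChannels(in);
  cube out(H, W, cout);
  const double* bias = w + (size_t)cout * cin * 9;
  for (int oc = 0; oc < cout; ++oc) {
    mat acc(H, W);
    acc.fill(bias[oc]);
    const double* wp = w + (size_t)oc * cin * 9;
    for (int ic = 0; ic < cin; ++ic) {
      const mat& P = pad.slice(ic);
      for (int v = 0; v < 3; ++v)
        for (int u = 0; u < 3; ++u)
          acc += wp[u + 3 * v] * P.submat(u, v, u + H - 1, v + W - 1);
      wp += 9;
    }
    out.slice(oc) = acc;
  }
  return out;
}

static cube convBwd(const cube& in, const cube& dOut, const double* w,
                    double* g, int cin, int cout) {
  const uword H = in.n_rows, W = in.n_cols;
  cube pad = padChannels(in);
  cube dPad(H + 2, W + 2, cin, fill::zeros);
  double* gBias = g + (size_t)cout * cin * 9;
  for (int oc = 0; oc < cout; ++oc) {
    const mat& D = dOut.slice(oc);
    gBias[oc] += accu(D);
    const double* wp = w + (size_t)oc * cin * 9;
    double* gp = g + (size_t)oc * cin * 9;
    for (int ic = 0; ic < cin; ++ic) {
      const mat& P = pad.slice(ic);
      mat& dP = dPad.slice(ic);
      for (int v = 0; v < 3; ++v)
        for (int u = 0; u < 3; ++u) {
          gp[u + 3 * v] += accu(P.submat(u, v, u + H - 1, v + W - 1) % D);
          dP.submat(u, v, u + H - 1, v + W - 1) += wp[u + 3 * v] * D;
        }
      wp += 9;
      gp += 9;
    }
  }
  cube dIn(H, W, cin);
  for (int ic = 0; ic < cin; ++ic)
    dIn.slice(ic) = dPad.slice(ic).submat(1, 1, H, W);
  return dIn;
}

static cube poolFwd(const cube& in) {
  const uword H = in.n_rows / 2, W = in.n_cols / 2;
  cube out(H, W, in.n_slices);
  for (uword c = 0; c < in.n_slices; ++c)
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i)
        out(i, j, c) = 0.25 * (in(2 * i, 2 * j, c) + in(2 * i + 1, 2 * j, c) +
                               in(2 * i, 2 * j + 1, c) + in(2 * i + 1, 2 * j + 1, c));
  return out;
}

static cube poolBwd(const cube& in, const cube& dOut) {
  cube dIn(in.n_rows, in.n_cols, in.n_slices);
  for (uword c = 0; c < in.n_slices; ++c)
    for (uword j = 0; j < dOut.n_cols; ++j)
      for (uword i = 0; i < dOut.n_rows; ++i) {
        double d = 0.25 * dOut(i, j, c);
        dIn(2 * i, 2 * j, c) = d;
        dIn(2 * i + 1, 2 * j, c) = d;
        dIn(2 * i, 2 * j + 1, c) = d;
        dIn(2 * i + 1, 2 * j + 1, c) = d;
      }
  return dIn;
}

static cube upFwd(const cube& in) {
  cube out(in.n_rows * 2, in.n_cols * 2, in.n_slices);
  for (uword c = 0; c < in.n_slices; ++c)
    for (uword j = 0; j < in.n_cols; ++j)
      for (uword i = 0; i < in.n_rows; ++i) {
        double v = in(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out;
}

static cube upBwd(const cube& in, const cube& dOut) {
  cube dIn(in.n_rows, in.n_cols, in.n_slices);
  for (uword c = 0; c < in.n_slices; ++c)
    for (uword j = 0; j < in.n_cols; ++j)
      for (uword i = 0; i < in.n_rows; ++i)
        dIn(i, j, c) = dOut(2 * i, 2 * j, c) + dOut(2 * i + 1, 2 * j, c) +
                       dOut(2 * i, 2 * j + 1, c) + dOut(2 * i + 1, 2 * j + 1, c);
  return dIn;
}

// Forward pass caching every activation (acts[0] is the input cube).
static std::vector<cube> forwardPass(const std::vector<Layer>& layers,
                                     const double* theta, const cube& x) {
  std::vector<cube> acts;
  acts.push_back(x);
  const double* w = theta;
  for (const Layer& l : layers) {
    const cube& in = acts.back();
    switch (l.type) {
      case L_CONV:
        acts.push_back(convFwd(in, w, l.p1, l.p2));
        w += layerParams(l);
        break;
      case L_RELU: {
        cube o = in;
        o.transform([](double v) { return v > 0.0 ? v : 0.0; });
        acts.push_back(o);
        break;
      }
      case L_POOL: acts.push_back(poolFwd(in)); break;
      case L_UP:   acts.push_back(upFwd(in)); break;
      case L_DENSE: {
        double z = w[l.p1];  // bias
        const double* xp = in.memptr();
        for (int k = 0; k < l.p1; ++k) z += w[k] * xp[k];
        cube o(1, 1, 1);
        o(0, 0, 0) = z;
        acts.push_back(o);
        w += layerParams(l);
        break;
      }
      case L_ADDIN: {
        cube o = in;
        o.slice(0) += acts[0].slice(0);
        acts.push_back(o);
        break;
      }
      default: Rcpp::stop("unknown layer type");
    }
  }
  return acts;
}

// Backward pass accumulating parameter gradients into g.
static void backwardPass(const std::vector<Layer>& layers, const double* theta,
                         double* g, const std::vector<cube>& acts, cube dOut) {
  // per-layer parameter offsets
  std::vector<size_t> offs(layers.size());
  size_t off = 0;
  for (size_t i = 0; i < layers.size(); ++i) {
    offs[i] = off;
    off += layerParams(layers[i]);
  }
  for (int i = (int)layers.size() - 1; i >= 0; --i) {
    const Layer& l = layers[i];
    const cube& in = acts[i];
    switch (l.type) {
      case L_CONV:
        dOut = convBwd(in, dOut, theta + offs[i], g + offs[i], l.p1, l.p2);
        break;
      case L_RELU: {
        cube mask = in;
        mask.transform([](double v) { return v > 0.0 ? 1.0 : 0.0; });
        dOut %= mask;
        break;
      }
      case L_POOL: dOut = poolBwd(in, dOut); break;
      case L_UP:   dOut = upBwd(in, dOut); break;
      case L_DENSE: {
        double dz = dOut(0, 0, 0);
        double* gp = g + offs[i];
        const double* xp = in.memptr();
        const double* wp = theta + offs[i];
        cube dIn(in.n_rows, in.n_cols, in.n_slices);
        double* dp = dIn.memptr();
        for (int k = 0; k < l.p1; ++k) {
          gp[k] += dz * xp[k];
          dp[k] = dz * wp[k];
        }
        gp[l.p1] += dz;
        dOut = dIn;
        break;
      }
      case L_ADDIN:
        break;  // gradient passes through unchanged (input grad unused)
      default: Rcpp::stop("unknown layer type");
    }
  }
}

static cube sampleCube(const double* X, int H, int W, int C, int n) {
  return cube(const_cast<double*>(X) + (size_t)n * H * W * C, H, W, C, true);
}

// [[Rcpp::export]]
Rcpp::List cpp_net_train(Rcpp::IntegerMatrix arch, Rcpp::NumericVector theta0,
                         Rcpp::NumericVector X, Rcpp::NumericVector y,
                         std::string loss, int epochs, int batch, double lr,
                         int seed, double weightDecay = 0.0) {
  std::vector<Layer> layers = parseArch(arch);
  Rcpp::IntegerVector dims = X.attr("dim");
  if (dims.size() != 4) Rcpp::stop("X must have dim (H, W, C, N)");
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int nPar = cpp_net_nparams(arch);
  if (theta0.size() != nPar) Rcpp::stop("theta has wrong length");

  vec theta(theta0.begin(), nPar);
  vec m(nPar, fill::zeros), v(nPar, fill::zeros), grad(nPar);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  const bool bce = (loss == "bce");
  const size_t imgLen = (size_t)H * W;

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;

  Rcpp::NumericVector lossTrace(epochs);
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double epochLoss = 0.0;
    for (int start = 0; start < N; start += batch) {
      int end = std::min(start + batch, N);
      int bs = end - start;
      grad.zeros();
      for (int b = start; b < end; ++b) {
        int s = idx[b];
        cube x = sampleCube(X.begin(), H, W, C, s);
        std::vector<cube> acts = forwardPass(layers, theta.memptr(), x);
        cube dOut;
        if (bce) {
          double z = acts.back()(0, 0, 0);
          double p = 1.0 / (1.0 + std::exp(-z));
          double yy = y[s];
          epochLoss += -(yy * std::log(std::max(p, 1e-12)) +
                         (1.0 - yy) * std::log(std::max(1.0 - p, 1e-12)));
          dOut = cube(1, 1, 1);
          dOut(0, 0, 0) = (p - yy) / bs;
        } else {
          const cube& out = acts.back();
          if (out.n_slices != 1) Rcpp::stop("mse loss expects 1 output channel");
          mat tgt(const_cast<double*>(y.begin()) + imgLen * s, H, W, true);
          mat diff = out.slice(0) - tgt;
          epochLoss += accu(square(diff)) / imgLen;
          dOut = cube(H, W, 1);
          dOut.slice(0) = (2.0 / (double)imgLen / bs) * diff;
        }
        backwardPass(layers, theta.memptr(), grad.memptr(), acts, dOut);
      }
      ++step;
      m = b1 * m + (1.0 - b1) * grad;
      v = b2 * v + (1.0 - b2) * square(grad);
      vec mhat = m / (1.0 - std::pow(b1, (double)step));
      vec vhat = v / (1.0 - std::pow(b2, (double)step));
      theta -= lr * (mhat / (sqrt(vhat) + eps) + weightDecay * theta);
    }
    lossTrace[ep] = epochLoss / N;
  }
  return Rcpp::List::create(
      Rcpp::Named("theta") = Rcpp::NumericVector(theta.begin(), theta.end()),
      Rcpp::Named("loss") = lossTrace);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_net_predict(Rcpp::IntegerMatrix arch,
                                    Rcpp::NumericVector theta,
                                    Rcpp::NumericVector X,
                                    std::string loss) {
  std::vector<Layer> layers = parseArch(arch);
  Rcpp::IntegerVector dims = X.attr("dim");
  if (dims.size() != 4) Rcpp::stop("X must have dim (H, W, C, N)");
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  if ((int)theta.size() != cpp_net_nparams(arch))
    Rcpp::stop("theta has wrong length");
  const bool bce = (loss == "bce");
  if (bce) {
    Rcpp::NumericVector out(N);
    for (int s = 0; s < N; ++s) {
      cube x = sampleCube(X.begin(), H, W, C, s);
      std::vector<cube> acts = forwardPass(layers, theta.begin(), x);
      out[s] = acts.back()(0, 0, 0);  // logit: a monotone transform suffices
    }
    return out;
  }
  Rcpp::NumericVector out((size_t)H * W * N);
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, N);
  for (int s = 0; s < N; ++s) {
    cube x = sampleCube(X.begin(), H, W, C, s);
    std::vector<cube> acts = forwardPass(layers, theta.begin(), x);
    std::copy(acts.back().memptr(), acts.back().memptr() + (size_t)H * W,
              out.begin() + (size_t)H * W * s);
  }
  return out;
}

// Single-sample loss (used for finite-difference gradient checks in tests).
// [[Rcpp::export]]
double cpp_net_loss(Rcpp::IntegerMatrix arch, Rcpp::NumericVector theta,
                    Rcpp::NumericVector X, Rcpp::NumericVector y,
                    std::string loss) {
  std::vector<Layer> layers = parseArch(arch);
  Rcpp::IntegerVector dims = X.attr("dim");
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const bool bce = (loss == "bce");
  const size_t imgLen = (size_t)H * W;
  double total = 0.0;
  for (int s = 0; s < N; ++s) {
    cube x = sampleCube(X.begin(), H, W, C, s);
    std::vector<cube> acts = forwardPass(layers, theta.begin(), x);
    if (bce) {
      double z = acts.back()(0, 0, 0);
      double p = 1.0 / (1.0 + std::exp(-z));
      total += -(y[s] * std::log(std::max(p, 1e-12)) +
                 (1.0 - y[s]) * std::log(std::max(1.0 - p, 1e-12)));
    } else {
      mat tgt(const_cast<double*>(y.begin()) + imgLen * s, H, W, true);
      total += accu(square(acts.back().slice(0) - tgt)) / imgLen;
    }
  }
  return total / N;
}

// Parameter gradient averaged over the dataset (for gradient checks).
// [[Rcpp::export]]
Rcpp::NumericVector cpp_net_grad(Rcpp::IntegerMatrix arch,
                                 Rcpp::NumericVector theta,
                                 Rcpp::NumericVector X, Rcpp::NumericVector y,
                                 std::string loss) {
  std::vector<Layer> layers = parseArch(arch);
  Rcpp::IntegerVector dims = X.attr("dim");
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const bool bce = (loss == "bce");
  const size_t imgLen = (size_t)H * W;
  vec grad(cpp_net_nparams(arch), fill::zeros);
  for (int s = 0; s < N; ++s) {
    cube x = sampleCube(X.begin(), H, W, C, s);
    std::vector<cube> acts = forwardPass(layers, theta.begin(), x);
    cube dOut;
    if (bce) {
      double z = acts.back()(0, 0, 0);
      double p = 1.0 / (1.0 + std::exp(-z));
      dOut = cube(1, 1, 1);
      dOut(0, 0, 0) = (p - y[s]) / N;
    } else {
      mat tgt(const_cast<double*>(y.begin()) + imgLen * s, H, W, true);
      dOut = cube(H, W, 1);
      dOut.slice(0) = (2.0 / (double)imgLen / N) * (acts.back().slice(0) - tgt);
    }
    backwardPass(layers, theta.begin(), grad.memptr(), acts, dOut);
  }
  return Rcpp::NumericVector(grad.begin(), grad.end());
}
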