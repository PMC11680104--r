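// Compact encoder-decoder segmentation network (one-level U-Net):
// conv3x3 -> ReLU -> maxpool2 -> conv3x3 -> ReLU -> nearest-upsample2
// -> concat skip -> conv3x3 -> ReLU -> conv1x1 -> sigmoid.
// Forward, analytic backprop and the compound soft-Dice + cross-entropy
// loss live here; the Adam loop stays in R.
//
// Parameter vector layout for base width C (must match .unetLayout in R):
//   W1[9*1*C], b1[C], W2[9*C*2C], b2[2C], W3[9*3C*C], b3[C], W4[C], b4[1]
// Conv weight index: ((co*Cin + ci)*9 + (ky+1)*3 + (kx+1)), ky/kx in -1..1.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::cube;
using arma::mat;

static inline std::size_t widx(int Cin, int ci, int co, int ky, int kx) {
  return ((std::size_t)co * Cin + ci) * 9 + (std::size_t)(ky + 1) * 3 + (kx + 1);
}

// Inner loops run over contiguous column spans (column-major storage), which
// the compiler auto-vectorizes; subview arithmetic is far slower here.
static void conv3_fwd(const cube& in, const double* W, const double* b,
                      int Cin, int Cout, cube& out) {
  const int H = in.n_rows, Wd = in.n_cols;
  out.set_size(H, Wd, Cout);
  for (int co = 0; co < Cout; ++co) {
    out.slice(co).fill(b[co]);
    for (int ci = 0; ci < Cin; ++ci) {
      const mat& X = in.slice(ci);
      for (int ky = -1; ky <= 1; ++ky) {
        for (int kx = -1; kx <= 1; ++kx) {
          const double w = W[widx(Cin, ci, co, ky, kx)];
          const int r0 = std::max(0, -ky), r1 = H - 1 - std::max(0, ky);
          const int c0 = std::max(0, -kx), c1 = Wd - 1 - std::max(0, kx);
          const int len = r1 - r0 + 1;
          for (int j = c0; j <= c1; ++j) {
            double* o = out.slice_colptr(co, j) + r0;
            const double* x = X.colptr(j + kx) + r0 + ky;
            for (int i = 0; i < len; ++i) o[i] += w * x[i];
          }
        }
      }
    }
  }
}

static void conv3_bwd(const cube& in, const cube& dOut, const double* W,
                      int Cin, int Cout, cube& dIn, double* dW, double* db) {
  const int H = in.n_rows, Wd = in.n_cols;
  dIn.zeros(H, Wd, Cin);
  for (int co = 0; co < Cout; ++co) {
    db[co] += arma::accu(dOut.slice(co));
    for (int ci = 0; ci < Cin; ++ci) {
      const mat& X = in.slice(ci);
      for (int ky = -1; ky <= 1; ++ky) {
        for (int kx = -1; kx <= 1; ++kx) {
          const int r0 = std::max(0, -ky), r1 = H - 1 - std::max(0, ky);
          const int c0 = std::max(0, -kx), c1 = Wd - 1 - std::max(0, kx);
          const int len = r1 - r0 + 1;
          const double w = W[widx(Cin, ci, co, ky, kx)];
          double acc = 0.0;
          for (int j = c0; j <= c1; ++j) {
            const double* d = dOut.slice_colptr(co, j) + r0;
            const double* x = X.colptr(j + kx) + r0 + ky;
            double* di = dIn.slice_colptr(ci, j + kx) + r0 + ky;
            for (int i = 0; i < len; ++i) {
              di[i] += w * d[i];
              acc += d[i] * x[i];
            }
          }
          dW[widx(Cin, ci, co, ky, kx)] += acc;
        }
      }
    }
  }
}

static void relu_fwd(cube& z) { z.transform([](double v) { return v > 0 ? v : 0.0; }); }

struct Offsets {
  std::size_t w1, b1, w2, b2, w3, b3, w4, b4, total;
  explicit Offsets(int C) {
    w1 = 0;                 b1 = w1 + 9ull * C;
    w2 = b1 + C;            b2 = w2 + 9ull * C * 2 * C;
    w3 = b2 + 2ull * C;     b3 = w3 + 9ull * 3 * C * C;
    w4 = b3 + C;            b4 = w4 + C;
    total = b4 + 1;
  }
};

// [[Rcpp::export]]
int cpp_unet_nparams(int C) { return (int)Offsets(C).total; }

struct Caches {
  cube a1;           // post-ReLU encoder activations (H x W x C)
  cube z1, z2, z3;   // pre-activations
  cube p1;           // pooled (H/2 x W/2 x C)
  arma::ucube argp;  // pooling argmax, 0..3 = 2*dy + dx
  cube a2, ct, a3;
  mat logit, prob;
};

static void forward(const mat& img, const double* P, int C, Caches& K) {
  const Offsets o(C);
  const int H = img.n_rows, W = img.n_cols;
  cube in(H, W, 1);
  in.slice(0) = img;

  conv3_fwd(in, P + o.w1, P + o.b1, 1, C, K.z1);
  K.a1 = K.z1; relu_fwd(K.a1);

  const int H2 = H / 2, W2 = W / 2;
  K.p1.set_size(H2, W2, C);
  K.argp.set_size(H2, W2, C);
  for (int c = 0; c < C; ++c) {
    const mat& A = K.a1.slice(c);
    for (int j = 0; j < W2; ++j) {
      for (int i = 0; i < H2; ++i) {
        double best = A(2 * i, 2 * j); unsigned arg = 0;
        if (A(2 * i, 2 * j + 1) > best) { best = A(2 * i, 2 * j + 1); arg = 1; }
        if (A(2 * i + 1, 2 * j) > best) { best = A(2 * i + 1, 2 * j); arg = 2; }
        if (A(2 * i + 1, 2 * j + 1) > best) { best = A(2 * i + 1, 2 * j + 1); arg = 3; }
        K.p1(i, j, c) = best; K.argp(i, j, c) = arg;
      }
    }
  }

  conv3_fwd(K.p1, P + o.w2, P + o.b2, C, 2 * C, K.z2);
  K.a2 = K.z2; relu_fwd(K.a2);

  // nearest upsample x2, then concat with the encoder skip
  K.ct.set_size(H, W, 3 * C);
  for (int c = 0; c < 2 * C; ++c) {
    const mat& A = K.a2.slice(c);
    mat& U = K.ct.slice(c);
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i) {
        const double v = A(i, j);
        U(2 * i, 2 * j) = v; U(2 * i, 2 * j + 1) = v;
        U(2 * i + 1, 2 * j) = v; U(2 * i + 1, 2 * j + 1) = v;
      }
  }
  for (int c = 0; c < C; ++c) K.ct.slice(2 * C + c) = K.a1.slice(c);

  conv3_fwd(K.ct, P + o.w3, P + o.b3, 3 * C, C, K.z3);
  K.a3 = K.z3; relu_fwd(K.a3);

  K.logit.set_size(H, W);
  K.logit.fill(P[o.b4]);
  for (int c = 0; c < C; ++c) K.logit += P[o.w4 + c] * K.a3.slice(c);
  K.prob = 1.0 / (1.0 + arma::exp(-K.logit));
}

// [[Rcpp::export]]
arma::mat cpp_unet_forward(const arma::mat& img, const arma::vec& params, int C) {
  Caches K;
  forward(img, params.memptr(), C, K);
  return K.prob;
}

// [[Rcpp::export]]
List cpp_unet_grad(const arma::mat& img, const arma::mat& mask,
                   const arma::vec& params, int C, double diceWeight) {
  const Offsets o(C);
  if ((std::size_t)params.n_elem != o.total)
    stop("parameter vector has wrong length for C=%d", C);
  const double* P = params.memptr();
  Caches K;
  forward(img, P, C, K);
  const int H = img.n_rows, W = img.n_cols;
  const double N = (double)H * W;

  mat pc = arma::clamp(K.prob, 1e-7, 1.0 - 1e-7);
  const double bce = -arma::accu(mask % arma::log(pc) +
                                 (1.0 - mask) % arma::log(1.0 - pc)) / N;
  const double smooth = 1.0;
  const double A = arma::accu(K.prob % mask);
  const double B = arma::accu(K.prob) + arma::accu(mask);
  const double dice = (2.0 * A + smooth) / (B + smooth);

  // d loss / d logit: BCE term simplifies to (p - m)/N; Dice term via chain rule
  mat dlogit = (K.prob - mask) / N;
  const double denom = (B + smooth) * (B + smooth);
  mat dDice_dp = (2.0 * mask * (B + smooth) - (2.0 * A + smooth)) / denom;
  dlogit -= diceWeight * dDice_dp % (K.prob % (1.0 - K.prob));

  arma::vec grad(o.total, arma::fill::zeros);
  double* G = grad.memptr();

  // conv1x1 head
  cube da3(H, W, C);
  for (int c = 0; c < C; ++c) {
    G[o.w4 + c] += arma::accu(dlogit % K.a3.slice(c));
    da3.slice(c) = P[o.w4 + c] * dlogit;
  }
  G[o.b4] += arma::accu(dlogit);

  cube dz3 = da3 % arma::conv_to<cube>::from(K.z3 > 0);
  cube dct;
  conv3_bwd(K.ct, dz3, P + o.w3, 3 * C, C, dct, G + o.w3, G + o.b3);

  const int H2 = H / 2, W2 = W / 2;
  cube da2(H2, W2, 2 * C);
  for (int c = 0; c < 2 * C; ++c) {
    const mat& D = dct.slice(c);
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i)
        da2(i, j, c) = D(2 * i, 2 * j) + D(2 * i, 2 * j + 1) +
                       D(2 * i + 1, 2 * j) + D(2 * i + 1, 2 * j + 1);
  }
  cube dz2 = da2 % arma::conv_to<cube>::from(K.z2 > 0);
  cube dp1;
  conv3_bwd(K.p1, dz2, P + o.w2, C, 2 * C, dp1, G + o.w2, G + o.b2);

  cube da1(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) da1.slice(c) = dct.slice(2 * C + c);  // skip path
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i) {
        const unsigned a = K.argp(i, j, c);
        da1(2 * i + (a >> 1), 2 * j + (a & 1), c) += dp1(i, j, c);
      }
  }
  cube dz1 = da1 % arma::conv_to<cube>::from(K.z1 > 0);
  cube in(H, W, 1); in.slice(0) = img;
  cube dIn;
  conv3_bwd(in, dz1, P + o.w1, 1, C, dIn, G + o.w1, G + o.b1);

  return List::create(_["loss"] = bce + diceWeight * (1.0 - dice),
                      _["bce"] = bce, _["soft_dice"] = dice,
                      _["grad"] = grad);
}
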