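#include <Rcpp.h>
#include <R_ext/BLAS.h>
using namespace Rcpp;

// Compact 3D convolutional classifier for 50x50 snippet sequences:
//   conv3d(1 -> c1, K^3, stride s1) + SELU
//   conv3d(c1 -> c2, K^3, stride s2) + SELU
//   global average pool over (t, h, w)  [+ inverted dropout in training]
//   fully connected c2 -> 1 + sigmoid
// Strides replace intermediate pooling so the net stays CPU-trainable.
// Convolutions run as im2col + BLAS dgemm; activations and gradients are
// laid out (h, w, t, channel) with the spatial index fastest.
//
// Flat parameter vector layout (column-major weight matrices):
//   W1: P1 x c1 with P1 = K^3      patch index p = kh + K kw + K^2 kt
//   b1: c1
//   W2: P2 x c2 with P2 = K^3 c1   p = kh + K kw + K^2 kt + K^3 ci
//   b2: c2
//   w3: c2,  b3: 1

static const double SELU_L = 1.0507009873554805;
static const double SELU_A = 1.6732632423543772;

static inline double selu(double x) {
  return x > 0 ? SELU_L * x : SELU_L * SELU_A * (std::exp(x) - 1.0);
}
static inline double selu_grad_from_act(double a) {
  return a > 0 ? SELU_L : a + SELU_L * SELU_A;
}

struct Dims {
  int H, W, T, K, c1, c2, s1, s2;
  int H1, W1, T1, H2, W2, T2;
  int P1, P2, nvox1, nvox2;
  int oW1, ob1, oW2, ob2, ow3, ob3, nparam;
  Dims(int H_, int W_, int T_, int K_, int c1_, int c2_, int s1_, int s2_) {
    H = H_; W = W_; T = T_; K = K_; c1 = c1_; c2 = c2_; s1 = s1_; s2 = s2_;
    H1 = (H - K) / s1 + 1; W1 = (W - K) / s1 + 1; T1 = (T - K) / s1 + 1;
    H2 = (H1 - K) / s2 + 1; W2 = (W1 - K) / s2 + 1; T2 = (T1 - K) / s2 + 1;
    if (H2 < 1 || W2 < 1 || T2 < 1) stop("clip too small for architecture");
    P1 = K * K * K; P2 = P1 * c1;
    nvox1 = H1 * W1 * T1; nvox2 = H2 * W2 * T2;
    oW1 = 0; ob1 = P1 * c1;
    oW2 = ob1 + c1; ob2 = oW2 + P2 * c2;
    ow3 = ob2 + c2; ob3 = ow3 + c2;
    nparam = ob3 + 1;
  }
};

// [[Rcpp::export]]
int cpp_filternet_nparam(int H, int W, int T, int K, int c1, int c2,
                         int s1, int s2) {
  return Dims(H, W, T, K, c1, c2, s1, s2).nparam;
}

// gather K^3 x cin patches of in (h, w, t, c layout, sizes Hi/Wi/Ti) into
// col (P x nvox, column-major), output grid Ho/Wo/To at stride s
static void im2col(const double* in, int Hi, int Wi, int Ti, int cin,
                   int K, int s, int Ho, int Wo, int To, double* col) {
  int P = K * K * K * cin;
  size_t planei = (size_t)Hi * Wi;
  for (int t = 0; t < To; ++t)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        size_t v = h + (size_t)Ho * (w + (size_t)Wo * t);
        double* dst = col + v * P;
        for (int ci = 0; ci < cin; ++ci) {
          const double* src = in + (size_t)ci * planei * Ti;
          for (int kt = 0; kt < K; ++kt)
            for (int kw = 0; kw < K; ++kw) {
              const double* s0 = src + (h * s) + (size_t)Hi *
                                 ((w * s + kw) + (size_t)Wi * (t * s + kt));
              double* d0 = dst + K * kw + K * K * kt + K * K * K * ci;
              for (int kh = 0; kh < K; ++kh) d0[kh] = s0[kh];
            }
        }
      }
}

// scatter-add the transpose of im2col
static void col2im_add(const double* col, int Hi, int Wi, int Ti, int cin,
                       int K, int s, int Ho, int Wo, int To, double* in) {
  int P = K * K * K * cin;
  size_t planei = (size_t)Hi * Wi;
  for (int t = 0; t < To; ++t)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        size_t v = h + (size_t)Ho * (w + (size_t)Wo * t);
        const double* src = col + v * P;
        for (int ci = 0; ci < cin; ++ci) {
          double* dst = in + (size_t)ci * planei * Ti;
          for (int kt = 0; kt < K; ++kt)
            for (int kw = 0; kw < K; ++kw) {
              double* d0 = dst + (h * s) + (size_t)Hi *
                           ((w * s + kw) + (size_t)Wi * (t * s + kt));
              const double* s0 = src + K * kw + K * K * kt + K * K * K * ci;
              for (int kh = 0; kh < K; ++kh) d0[kh] += s0[kh];
            }
        }
      }
}

// Z (nvox x cout) = col^T (nvox x P) * W (P x cout)
static void gemm_tn(int M, int N, int Kd, const double* A, const double* B,
                    double* C) {
  double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("T", "N", &M, &N, &Kd, &one, A, &Kd, B, &Kd, &zero, C,
                  &M FCONE FCONE);
}

// Forward + (optionally) full backward pass for one clip (H x W x T
// array). dropmask: length c2, already inverted-scaled (0 or 1/(1-p));
// all-ones for inference. Returns prob, loss and (optionally) the
// parameter gradient.
// [[Rcpp::export]]
List cpp_filternet_sample(NumericVector clip, NumericVector par,
                          int K, int c1, int c2, int s1, int s2,
                          NumericVector dropmask, double label,
                          bool want_grad) {
  IntegerVector dim = clip.attr("dim");
  Dims d(dim[0], dim[1], dim[2], K, c1, c2, s1, s2);
  if (par.size() != d.nparam) stop("parameter vector has wrong length");
  const double* p = par.begin();
  std::vector<double> col1((size_t)d.P1 * d.nvox1);
  std::vector<double> col2((size_t)d.P2 * d.nvox2);
  std::vector<double> a1((size_t)d.nvox1 * d.c1);
  std::vector<double> a2((size_t)d.nvox2 * d.c2);
  std::vector<double> gap(d.c2);

  im2col(clip.begin(), d.H, d.W, d.T, 1, K, s1, d.H1, d.W1, d.T1,
         col1.data());
  gemm_tn(d.nvox1, d.c1, d.P1, col1.data(), p + d.oW1, a1.data());
  for (int c = 0; c < d.c1; ++c) {
    double b = p[d.ob1 + c];
    double* z = &a1[(size_t)c * d.nvox1];
    for (int v = 0; v < d.nvox1; ++v) z[v] = selu(z[v] + b);
  }
  im2col(a1.data(), d.H1, d.W1, d.T1, d.c1, K, s2, d.H2, d.W2, d.T2,
         col2.data());
  gemm_tn(d.nvox2, d.c2, d.P2, col2.data(), p + d.oW2, a2.data());
  for (int c = 0; c < d.c2; ++c) {
    double b = p[d.ob2 + c];
    double* z = &a2[(size_t)c * d.nvox2];
    double s = 0;
    for (int v = 0; v < d.nvox2; ++v) {
      z[v] = selu(z[v] + b);
      s += z[v];
    }
    gap[c] = s / d.nvox2;
  }
  double logit = p[d.ob3];
  for (int c = 0; c < d.c2; ++c)
    logit += p[d.ow3 + c] * gap[c] * dropmask[c];
  double prob = 1.0 / (1.0 + std::exp(-logit));
  double eps = 1e-12;
  double loss = -(label * std::log(prob + eps) +
                  (1.0 - label) * std::log(1.0 - prob + eps));
  if (!want_grad)
    return List::create(_["prob"] = prob, _["loss"] = loss);

  NumericVector grad(d.nparam);
  double* g = grad.begin();
  double dlogit = prob - label;
  g[d.ob3] = dlogit;
  std::vector<double> dz2((size_t)d.nvox2 * d.c2);
  for (int c = 0; c < d.c2; ++c) {
    g[d.ow3 + c] = dlogit * gap[c] * dropmask[c];
    double dgap = dlogit * p[d.ow3 + c] * dropmask[c] / d.nvox2;
    const double* a = &a2[(size_t)c * d.nvox2];
    double* dz = &dz2[(size_t)c * d.nvox2];
    double bs = 0;
    for (int v = 0; v < d.nvox2; ++v) {
      dz[v] = dgap * selu_grad_from_act(a[v]);
      bs += dz[v];
    }
    g[d.ob2 + c] = bs;
  }
  {  // dW2 = col2 (P2 x nvox2) * dz2 (nvox2 x c2)
    double one = 1.0, zero = 0.0;
    F77_CALL(dgemm)("N", "N", &d.P2, &d.c2, &d.nvox2, &one, col2.data(),
                    &d.P2, dz2.data(), &d.nvox2, &zero, g + d.oW2, &d.P2
                    FCONE FCONE);
  }
  // dcol2 = W2 (P2 x c2) * dz2^T (c2 x nvox2)
  std::vector<double> dcol2((size_t)d.P2 * d.nvox2);
  {
    double one = 1.0, zero = 0.0;
    F77_CALL(dgemm)("N", "T", &d.P2, &d.nvox2, &d.c2, &one, p + d.oW2,
                    &d.P2, dz2.data(), &d.nvox2, &zero, dcol2.data(),
                    &d.P2 FCONE FCONE);
  }
  std::vector<double> da1((size_t)d.nvox1 * d.c1, 0.0);
  col2im_add(dcol2.data(), d.H1, d.W1, d.T1, d.c1, K, s2, d.H2, d.W2,
             d.T2, da1.data());
  for (int c = 0; c < d.c1; ++c) {
    const double* a = &a1[(size_t)c * d.nvox1];
    double* dz = &da1[(size_t)c * d.nvox1];
    double bs = 0;
    for (int v = 0; v < d.nvox1; ++v) {
      dz[v] *= selu_grad_from_act(a[v]);
      bs += dz[v];
    }
    g[d.ob1 + c] = bs;
  }
  {  // dW1 = col1 (P1 x nvox1) * dz1 (nvox1 x c1)
    double one = 1.0, zero = 0.0;
    F77_CALL(dgemm)("N", "N", &d.P1, &d.c1, &d.nvox1, &one, col1.data(),
                    &d.P1, da1.data(), &d.nvox1, &zero, g + d.oW1, &d.P1
                    FCONE FCONE);
  }
  return List::create(_["prob"] = prob, _["loss"] = loss,
                      _["grad"] = grad);
}
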