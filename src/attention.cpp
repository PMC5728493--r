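#include <Rcpp.h>
using namespace Rcpp;

// Per-pixel waggle-band periodogram scores over a sliding window.
// The window ending at frame n (1-based, n >= b) holds the last b
// intensity values of a pixel; the series is min-max normalised to
// [-1, 1] and projected onto a sine/cosine pair at each waggle-band
// frequency. Score = (sum cos-proj)^2 + (sum sin-proj)^2.
//
// Implementation notes (numerics only, semantics match the definition):
// the video is transposed to pixel-major order so each time series is
// contiguous, and the complex projection S_n = sum_{j=n-b+1..n} B_j e^{i w j}
// is slid in O(1) per frame. Because the normalisation B' = a B + c is
// affine, the normalised score is |a S_n + c U_n|^2 with U_n the window
// sum of e^{i w j} (identical for all pixels), so min/max tracking is the
// only per-window O(b) work. The phase factor from re-indexing the basis
// to the window start has unit magnitude and drops out of the score.

struct BandScorer {
  int H, W, T, b, nf;
  std::vector<double> ts;                 // pixel-major copy: [px][t]
  std::vector<double> cosj, sinj;         // e^{i w j}, per freq, per frame
  std::vector<double> Ure, Uim;           // window sums of e^{i w j}
  BandScorer(const NumericVector& video, int b_, const NumericVector& freqs,
             double sr)
      : b(b_), nf(freqs.size()) {
    IntegerVector dims = video.attr("dim");
    H = dims[0]; W = dims[1]; T = dims[2];
    if (T < b) stop("video shorter than the scoring window");
    size_t npx = (size_t)H * W;
    ts.resize(npx * T);
    const double* vid = video.begin();
    for (int t = 0; t < T; ++t)
      for (size_t p = 0; p < npx; ++p)
        ts[p * T + t] = vid[(size_t)t * npx + p];
    cosj.resize((size_t)nf * T);
    sinj.resize((size_t)nf * T);
    for (int f = 0; f < nf; ++f) {
      double w = 2.0 * M_PI * freqs[f] / sr;
      for (int j = 0; j < T; ++j) {
        // basis index m = 1..b maps to absolute frame j = n-b+m (0-based
        // j used here; constant offset only rotates the phase)
        cosj[(size_t)f * T + j] = std::cos(w * (j + 1));
        sinj[(size_t)f * T + j] = std::sin(w * (j + 1));
      }
    }
    Ure.assign((size_t)nf * T, 0.0);
    Uim.assign((size_t)nf * T, 0.0);
    for (int f = 0; f < nf; ++f) {
      double cre = 0, cim = 0;
      for (int j = 0; j < T; ++j) {
        cre += cosj[(size_t)f * T + j];
        cim += sinj[(size_t)f * T + j];
        if (j >= b) {
          cre -= cosj[(size_t)f * T + j - b];
          cim -= sinj[(size_t)f * T + j - b];
        }
        Ure[(size_t)f * T + j] = cre;
        Uim[(size_t)f * T + j] = cim;
      }
    }
  }

  // visit(n, p, score): called for every full window (n = 0-based end
  // frame >= b-1) and pixel p (column-major index) with the max
  // waggle-band score.
  template <class F> void scan(F visit) {
    size_t npx = (size_t)H * W;
    std::vector<double> Sre(nf), Sim(nf);
    for (size_t p = 0; p < npx; ++p) {
      const double* v = &ts[p * T];
      for (int f = 0; f < nf; ++f) { Sre[f] = 0; Sim[f] = 0; }
      for (int j = 0; j < b - 1; ++j)
        for (int f = 0; f < nf; ++f) {
          Sre[f] += v[j] * cosj[(size_t)f * T + j];
          Sim[f] += v[j] * sinj[(size_t)f * T + j];
        }
      for (int n = b - 1; n < T; ++n) {
        for (int f = 0; f < nf; ++f) {
          Sre[f] += v[n] * cosj[(size_t)f * T + n];
          Sim[f] += v[n] * sinj[(size_t)f * T + n];
          if (n >= b) {
            Sre[f] -= v[n - b] * cosj[(size_t)f * T + n - b];
            Sim[f] -= v[n - b] * sinj[(size_t)f * T + n - b];
          }
        }
        double mn = v[n - b + 1], mx = mn;
        for (int j = n - b + 2; j <= n; ++j) {
          double x = v[j];
          if (x < mn) mn = x;
          if (x > mx) mx = x;
        }
        double best = 0.0;
        if (mx > mn) {
          double a = 2.0 / (mx - mn);
          double c = -1.0 - 2.0 * mn / (mx - mn);
          for (int f = 0; f < nf; ++f) {
            double re = a * Sre[f] + c * Ure[(size_t)f * T + n];
            double im = a * Sim[f] + c * Uim[(size_t)f * T + n];
            double sc = re * re + im * im;
            if (sc > best) best = sc;
          }
        }
        visit(n, p, best);
      }
    }
  }
};

// video: H x W x T array. Returns a list of length T; element n holds an
// integer matrix (k x 2) of activated pixel positions (x = column,
// y = row, 1-based) for the window ending at frame n. Warm-up frames
// (n < b) yield 0 x 2 matrices.
// [[Rcpp::export]]
List cpp_dd_activations(NumericVector video, int b, NumericVector freqs,
                        double sr, double th) {
  BandScorer sc(video, b, freqs, sr);
  std::vector<std::vector<int>> xs(sc.T), ys(sc.T);
  int H = sc.H;
  sc.scan([&](int n, size_t p, double score) {
    if (score >= th) {
      xs[n].push_back((int)(p / H) + 1);
      ys[n].push_back((int)(p % H) + 1);
    }
  });
  List out(sc.T);
  for (int n = 0; n < sc.T; ++n) {
    IntegerMatrix am(xs[n].size(), 2);
    for (size_t k = 0; k < xs[n].size(); ++k) {
      am(k, 0) = xs[n][k];
      am(k, 1) = ys[n][k];
    }
    out[n] = am;
  }
  return out;
}

// Max-over-band score for every pixel and every full window; used for
// threshold calibration on bee-free clips. Returns H x W x (T - b + 1).
// [[Rcpp::export]]
NumericVector cpp_dd_maxscores(NumericVector video, int b,
                               NumericVector freqs, double sr) {
  BandScorer sc(video, b, freqs, sr);
  size_t plane = (size_t)sc.H * sc.W;
  int nwin = sc.T - b + 1;
  NumericVector out(plane * nwin);
  out.attr("dim") = IntegerVector::create(sc.H, sc.W, nwin);
  double* o = out.begin();
  sc.scan([&](int n, size_t p, double score) {
    o[p + plane * (n - b + 1)] = score;
  });
  return out;
}
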