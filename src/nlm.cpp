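#include <Rcpp.h>
using namespace Rcpp;

// Non-local-means denoising of a single channel (Buades patch weighting).
// img: h x w intensities on the 0-255 scale. h2 = h (filter strength),
// templ/search: odd window diameters. Border handled by clamped indexing.
static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export(name = ".nlm_denoise_channel")]]
NumericMatrix nlm_denoise_channel(NumericMatrix img, double h, int templ, int search) {
  const int nr = img.nrow(), nc = img.ncol();
  const int tr = templ / 2, sr = search / 2;
  const double h2 = h * h;
  const int npatch = templ * templ;
  NumericMatrix out(nr, nc);

  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double wsum = 0.0, acc = 0.0, wmax = 0.0;
      for (int di = -sr; di <= sr; ++di) {
        for (int dj = -sr; dj <= sr; ++dj) {
          if (di == 0 && dj == 0) continue;
          const int ci = i + di, cj = j + dj;
          // mean squared patch difference
          double d2 = 0.0;
          for (int pi = -tr; pi <= tr; ++pi) {
            for (int pj = -tr; pj <= tr; ++pj) {
              const int a_i = clampi(i + pi, 0, nr - 1);
              const int a_j = clampi(j + pj, 0, nc - 1);
              const int b_i = clampi(ci + pi, 0, nr - 1);
              const int b_j = clampi(cj + pj, 0, nc - 1);
              const double diff = img(a_i, a_j) - img(b_i, b_j);
              d2 += diff * diff;
            }
          }
          d2 /= npatch;
          const double w = std::exp(-d2 / h2);
          if (w > wmax) wmax = w;
          wsum += w;
          acc += w * img(clampi(ci, 0, nr - 1), clampi(cj, 0, nc - 1));
        }
      }
      // reference pixel gets the maximal neighbour weight (standard convention)
      const double wself = wmax > 0.0 ? wmax : 1.0;
      wsum += wself;
      acc += wself * img(i, j);
      out(i, j) = acc / wsum;
    }
  }
  return out;
}
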