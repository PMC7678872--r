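#include <Rcpp.h>
using namespace Rcpp;

// Hot paths of the movie renderer and trace extraction. Movies are stored as
// (rows x cols x frames) arrays, i.e. pixel-fastest in memory, so all loops
// below iterate frames outermost over contiguous per-frame slices.

// Fill a movie with per-frame background plus Gaussian read noise.
// bgt has one (already bleach-corrected) background value per frame.
// Normals come from a Box-Muller transform of R's seeded uniform stream,
// so results are reproducible under set.seed() (and cheap at ~5e7 draws
// per movie, where the default inversion sampler is the bottleneck).
// [[Rcpp::export]]
NumericVector render_base_cpp(int npix, int nframes, NumericVector bgt,
                              double read_sd) {
  NumericVector out(R_xlen_t(npix) * nframes);
  RNGScope scope;
  R_xlen_t k = 0;
  if (read_sd > 0) {
    R_xlen_t n = out.size(), i = 0;
    double b;
    while (i < n) {
      double u1 = unif_rand(), u2 = unif_rand();
      double r = read_sd * sqrt(-2.0 * log(u1)), th = 2.0 * M_PI * u2;
      b = bgt[int(i / npix)];
      out[i++] = b + r * cos(th);
      if (i < n) {
        b = bgt[int(i / npix)];
        out[i++] = b + r * sin(th);
      }
    }
  } else {
    for (int f = 0; f < nframes; ++f) {
      double b = bgt[f];
      for (int p = 0; p < npix; ++p) out[k++] = b;
    }
  }
  return out;
}

// Clamp intensities into the camera's representable range, in place.
// Only called on freshly allocated arrays owned by the renderer.
// [[Rcpp::export]]
void clip_range_cpp(NumericVector x, double lo, double hi) {
  R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] < lo) x[i] = lo;
    else if (x[i] > hi) x[i] = hi;
  }
}

// Mean intensity per grid square per frame.
// pix: 0-based within-frame linear pixel indices, concatenated over squares;
// offsets: 0-based start of each square's run in pix, length nsquares + 1.
// Returns an (nsquares x nframes) matrix.
// [[Rcpp::export]]
NumericMatrix square_means_cpp(NumericVector movie, int npix, int nframes,
                               IntegerVector pix, IntegerVector offsets) {
  int ns = offsets.size() - 1;
  NumericMatrix out(ns, nframes);
  for (int f = 0; f < nframes; ++f) {
    R_xlen_t base = R_xlen_t(f) * npix;
    for (int s = 0; s < ns; ++s) {
      double acc = 0;
      int a = offsets[s], b = offsets[s + 1];
      for (int j = a; j < b; ++j) acc += movie[base + pix[j]];
      out(s, f) = acc / double(b - a);
    }
  }
  return out;
}
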