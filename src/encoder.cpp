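#include <Rcpp.h>
using namespace Rcpp;

// Multi-channel 2D convolution, 3x3 kernels, stride 1, zero-padded "same",
// followed by ReLU. Input and output are H x W x C arrays (column-major,
// dim attribute set by the caller). Weights are kh x kw x inC x outC.
// Plain loops: the arrays involved (<= 1024 x 1024 x 16) stay well inside
// memory, and a single pass is what a fixed random-filter bank needs.

// [[Rcpp::export]]
NumericVector conv2dSameRelu(NumericVector input, NumericVector weights,
                             NumericVector bias) {
  IntegerVector din = input.attr("dim");
  IntegerVector dw = weights.attr("dim");
  const int H = din[0], W = din[1], Cin = din[2];
  const int kh = dw[0], kw = dw[1], wCin = dw[2], Cout = dw[3];
  if (wCin != Cin) stop("weight / input channel mismatch");
  const int oh = kh / 2, ow = kw / 2;
  if (kh != 3 || kw != 3) stop("conv2dSameRelu expects 3x3 kernels");
  NumericVector out(static_cast<R_xlen_t>(H) * W * Cout);
  out.attr("dim") = IntegerVector::create(H, W, Cout);
  const double *wgt = weights.begin();
  double *y = out.begin();
  // single-precision working copy: the filter bank is random projection
  // machinery, so float accumulation is ample and halves memory traffic
  std::vector<float> xf(input.size());
  for (R_xlen_t k = 0; k < input.size(); ++k)
    xf[k] = static_cast<float>(input[k]);
  std::vector<float> acc(H), zcol(H, 0.0f);
  for (int co = 0; co < Cout; ++co) {
    const float b = static_cast<float>(bias[co]);
    double *yc = y + static_cast<R_xlen_t>(co) * H * W;
    float wk[3][3 * 16];  // [dj][di + 3*ci], Cin <= 16 in this architecture
    if (Cin > 16) stop("conv2dSameRelu supports at most 16 input channels");
    for (int ci = 0; ci < Cin; ++ci)
      for (int dj = 0; dj < 3; ++dj)
        for (int di = 0; di < 3; ++di)
          wk[dj][di + 3 * ci] = static_cast<float>(
              wgt[di + 3 * (dj + 3 * (ci + static_cast<R_xlen_t>(wCin) * co))]);
    for (int j = 0; j < W; ++j) {
      std::fill(acc.begin(), acc.end(), b);
      for (int ci = 0; ci < Cin; ++ci) {
        const float *xc = xf.data() + static_cast<size_t>(ci) * H * W;
        for (int dj = 0; dj < 3; ++dj) {
          const int jj = j + dj - ow;
          const float *xcol =
              (jj < 0 || jj >= W) ? zcol.data() : xc + static_cast<size_t>(jj) * H;
          const float w0 = wk[dj][0 + 3 * ci], w1 = wk[dj][1 + 3 * ci],
                      w2 = wk[dj][2 + 3 * ci];
          // di = 1: aligned; di = 0/2: shifted by one row, edges clamped out
          for (int i = 0; i < H; ++i) acc[i] += w1 * xcol[i];
          for (int i = 1; i < H; ++i) acc[i] += w0 * xcol[i - 1];
          for (int i = 0; i < H - 1; ++i) acc[i] += w2 * xcol[i + 1];
        }
      }
      double *ycol = yc + static_cast<R_xlen_t>(j) * H;
      for (int i = 0; i < H; ++i)
        ycol[i] = acc[i] > 0.0f ? static_cast<double>(acc[i]) : 0.0;
    }
  }
  return out;
}

// Bilinear resize of an H x W x C array to side x side (half-pixel centers,
// edge clamped) with channel values passed through unchanged.
// [[Rcpp::export]]
NumericVector resizeBilinear(NumericVector input, int side) {
  IntegerVector din = input.attr("dim");
  const int H = din[0], W = din[1], C = din[2];
  if (H < 1 || W < 1 || side < 1) stop("invalid resize geometry");
  NumericVector out(static_cast<R_xlen_t>(side) * side * C);
  out.attr("dim") = IntegerVector::create(side, side, C);
  const double sy = static_cast<double>(H) / side;
  const double sx = static_cast<double>(W) / side;
  std::vector<int> i0(side), i1(side), j0(side), j1(side);
  std::vector<double> fi(side), fj(side);
  for (int t = 0; t < side; ++t) {
    double src = (t + 0.5) * sy - 0.5;
    src = std::min(std::max(src, 0.0), H - 1.0);
    i0[t] = static_cast<int>(std::floor(src));
    i1[t] = std::min(i0[t] + 1, H - 1);
    fi[t] = src - i0[t];
    src = (t + 0.5) * sx - 0.5;
    src = std::min(std::max(src, 0.0), W - 1.0);
    j0[t] = static_cast<int>(std::floor(src));
    j1[t] = std::min(j0[t] + 1, W - 1);
    fj[t] = src - j0[t];
  }
  const double *x = input.begin();
  double *y = out.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = x + static_cast<R_xlen_t>(c) * H * W;
    double *yc = y + static_cast<R_xlen_t>(c) * side * side;
    for (int j = 0; j < side; ++j) {
      const double *cL = xc + static_cast<R_xlen_t>(j0[j]) * H;
      const double *cR = xc + static_cast<R_xlen_t>(j1[j]) * H;
      const double fx = fj[j];
      for (int i = 0; i < side; ++i) {
        const double top = cL[i0[i]] * (1 - fx) + cR[i0[i]] * fx;
        const double bot = cL[i1[i]] * (1 - fx) + cR[i1[i]] * fx;
        yc[i + static_cast<R_xlen_t>(j) * side] =
            top * (1 - fi[i]) + bot * fi[i];
      }
    }
  }
  return out;
}

// 2x2 max pooling, stride 2, per channel. H and W must be even.
// [[Rcpp::export]]
NumericVector maxPool2(NumericVector input) {
  IntegerVector din = input.attr("dim");
  const int H = din[0], W = din[1], C = din[2];
  if (H % 2 || W % 2) stop("maxPool2 requires even spatial dimensions");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out(static_cast<R_xlen_t>(Ho) * Wo * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  const double *x = input.begin();
  double *y = out.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = x + static_cast<R_xlen_t>(c) * H * W;
    double *yc = y + static_cast<R_xlen_t>(c) * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      const double *c0 = xc + static_cast<R_xlen_t>(2 * j) * H;
      const double *c1 = c0 + H;
      for (int i = 0; i < Ho; ++i) {
        const int r = 2 * i;
        double m = c0[r];
        if (c0[r + 1] > m) m = c0[r + 1];
        if (c1[r] > m) m = c1[r];
        if (c1[r + 1] > m) m = c1[r + 1];
        yc[i + static_cast<R_xlen_t>(j) * Ho] = m;
      }
    }
  }
  return out;
}
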