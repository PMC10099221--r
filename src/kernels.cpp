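// Low-level numeric kernels for the conv-net engine: im2col GEMM convolution
// with exact backward passes, 2x2 max pooling, nearest-neighbour upsampling,
// and bilinear ROI alignment. Feature maps are (h, w, channels) cubes matching
// R arrays of dim c(h, w, c); all indices 0-based internally.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col: patch rows laid out as r = dy + dx*k + c*k*k, columns t = oi + oj*ho.
// Iterates patch offsets outermost so inner loops are tight strided copies.
static arma::mat im2col(const arma::cube& x, int k, int stride, int pad,
                        int ho, int wo) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const int R = k * k * cin;
  arma::mat cols(R, ho * wo, arma::fill::zeros);
  double* cp = cols.memptr();
  const double* xp = x.memptr();
  for (int c = 0; c < cin; ++c) {
    const double* sl = xp + (size_t)c * h * w;
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int r = dy + dx * k + c * k * k;
        // valid output rows: 0 <= oi*stride - pad + dy <= h-1 (cols likewise)
        const int oiLo = std::max(0, (pad - dy + stride - 1) / stride);
        const int oiHi = std::min(ho - 1, (h - 1 + pad - dy) / stride);
        const int ojLo = std::max(0, (pad - dx + stride - 1) / stride);
        const int ojHi = std::min(wo - 1, (w - 1 + pad - dx) / stride);
        for (int oj = ojLo; oj <= ojHi; ++oj) {
          const int j = oj * stride - pad + dx;
          const double* src = sl + (size_t)j * h + (oiLo * stride - pad + dy);
          double* dst = cp + (size_t)(oiLo + oj * ho) * R + r;
          for (int oi = oiLo; oi <= oiHi; ++oi) {
            *dst = *src;
            dst += R;
            src += stride;
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
List cpp_conv2d_fwd(const arma::cube& x, const arma::mat& W,
                    const arma::vec& b, int k, int stride, int pad) {
  const int h = x.n_rows, w = x.n_cols;
  const int ho = (h + 2 * pad - k) / stride + 1;
  const int wo = (w + 2 * pad - k) / stride + 1;
  const int cout = W.n_cols;
  arma::mat cols = im2col(x, k, stride, pad, ho, wo);
  arma::mat outm = cols.t() * W;          // (ho*wo) x cout
  outm.each_row() += b.t();
  arma::cube out(ho, wo, cout);
  for (int c = 0; c < cout; ++c)
    out.slice(c) = arma::reshape(outm.col(c), ho, wo);
  return List::create(_["out"] = out, _["cols"] = cols);
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::mat& cols, const arma::mat& W,
                    const arma::cube& gout, int h, int w, int cin,
                    int k, int stride, int pad) {
  const int ho = gout.n_rows, wo = gout.n_cols, cout = gout.n_slices;
  arma::mat G(ho * wo, cout);
  for (int c = 0; c < cout; ++c)
    G.col(c) = arma::vectorise(gout.slice(c));
  arma::mat gW = cols * G;                 // (k*k*cin) x cout
  arma::vec gb = arma::sum(G, 0).t();
  arma::mat gcols = W * G.t();             // (k*k*cin) x (ho*wo)
  arma::cube gx(h, w, cin, arma::fill::zeros);
  const int R = k * k * cin;
  const double* gp = gcols.memptr();
  double* xp = gx.memptr();
  for (int c = 0; c < cin; ++c) {
    double* sl = xp + (size_t)c * h * w;
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int r = dy + dx * k + c * k * k;
        const int oiLo = std::max(0, (pad - dy + stride - 1) / stride);
        const int oiHi = std::min(ho - 1, (h - 1 + pad - dy) / stride);
        const int ojLo = std::max(0, (pad - dx + stride - 1) / stride);
        const int ojHi = std::min(wo - 1, (w - 1 + pad - dx) / stride);
        for (int oj = ojLo; oj <= ojHi; ++oj) {
          const int j = oj * stride - pad + dx;
          double* dst = sl + (size_t)j * h + (oiLo * stride - pad + dy);
          const double* src = gp + (size_t)(oiLo + oj * ho) * R + r;
          for (int oi = oiLo; oi <= oiHi; ++oi) {
            *dst += *src;
            src += R;
            dst += stride;
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::cube& x) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const int ho = h / 2, wo = w / 2;
  arma::cube out(ho, wo, cin);
  IntegerMatrix idx(ho * wo, cin);   // 0-based linear index into (h, w) slice
  for (int c = 0; c < cin; ++c) {
    const arma::mat& sl = x.slice(c);
    for (int oj = 0; oj < wo; ++oj) {
      for (int oi = 0; oi < ho; ++oi) {
        int bi = 2 * oi, bj = 2 * oj;
        double best = sl(bi, bj); int besti = bi, bestj = bj;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            if (sl(bi + di, bj + dj) > best) {
              best = sl(bi + di, bj + dj);
              besti = bi + di; bestj = bj + dj;
            }
          }
        out(oi, oj, c) = best;
        idx(oi + oj * ho, c) = besti + bestj * h;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& g, const IntegerMatrix& idx,
                            int h, int w) {
  const int ho = g.n_rows, wo = g.n_cols, cin = g.n_slices;
  arma::cube gx(h, w, cin, arma::fill::zeros);
  for (int c = 0; c < cin; ++c) {
    arma::mat& sl = gx.slice(c);
    for (int oj = 0; oj < wo; ++oj)
      for (int oi = 0; oi < ho; ++oi) {
        const int lin = idx(oi + oj * ho, c);
        sl(lin % h, lin / h) += g(oi, oj, c);
      }
  }
  return gx;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_fwd(const arma::cube& x) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  arma::cube out(2 * h, 2 * w, cin);
  for (int c = 0; c < cin; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        const double v = x(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube& g) {
  const int ho = g.n_rows / 2, wo = g.n_cols / 2, cin = g.n_slices;
  arma::cube gx(ho, wo, cin);
  for (int c = 0; c < cin; ++c)
    for (int j = 0; j < wo; ++j)
      for (int i = 0; i < ho; ++i)
        gx(i, j, c) = g(2 * i, 2 * j, c) + g(2 * i + 1, 2 * j, c) +
                      g(2 * i, 2 * j + 1, c) + g(2 * i + 1, 2 * j + 1, c);
  return gx;
}

// backward of cpp_roi_align: scatter output-bin gradients to the four
// bilinear corners of each sample position
// [[Rcpp::export]]
arma::cube cpp_roi_align_bwd(const arma::cube& g, const arma::vec& box,
                             int h, int w) {
  const int out_h = g.n_rows, out_w = g.n_cols, cin = g.n_slices;
  const double bw = box(2) - box(0), bh = box(3) - box(1);
  arma::cube gx(h, w, cin, arma::fill::zeros);
  for (int oj = 0; oj < out_w; ++oj) {
    const double sx = box(0) + (oj + 0.5) * bw / out_w - 0.5;
    double px = std::min(std::max(sx, 0.0), (double)(w - 1));
    const int x0 = (int)std::floor(px);
    const int x1 = std::min(x0 + 1, w - 1);
    const double fx = px - x0;
    for (int oi = 0; oi < out_h; ++oi) {
      const double sy = box(1) + (oi + 0.5) * bh / out_h - 0.5;
      double py = std::min(std::max(sy, 0.0), (double)(h - 1));
      const int y0 = (int)std::floor(py);
      const int y1 = std::min(y0 + 1, h - 1);
      const double fy = py - y0;
      for (int c = 0; c < cin; ++c) {
        const double gv = g(oi, oj, c);
        gx(y0, x0, c) += (1 - fy) * (1 - fx) * gv;
        gx(y0, x1, c) += (1 - fy) * fx * gv;
        gx(y1, x0, c) += fy * (1 - fx) * gv;
        gx(y1, x1, c) += fy * fx * gv;
      }
    }
  }
  return gx;
}

// Bilinear ROI alignment / resize. box = (x1, y1, x2, y2) in continuous
// half-open coordinates of the input grid (x horizontal = columns). One
// sample per output bin at its centre; border clamp.
// [[Rcpp::export]]
arma::cube cpp_roi_align(const arma::cube& x, const arma::vec& box,
                         int out_h, int out_w) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const double bw = box(2) - box(0), bh = box(3) - box(1);
  arma::cube out(out_h, out_w, cin, arma::fill::zeros);
  for (int oj = 0; oj < out_w; ++oj) {
    const double sx = box(0) + (oj + 0.5) * bw / out_w - 0.5;
    double px = std::min(std::max(sx, 0.0), (double)(w - 1));
    const int x0 = (int)std::floor(px);
    const int x1 = std::min(x0 + 1, w - 1);
    const double fx = px - x0;
    for (int oi = 0; oi < out_h; ++oi) {
      const double sy = box(1) + (oi + 0.5) * bh / out_h - 0.5;
      double py = std::min(std::max(sy, 0.0), (double)(h - 1));
      const int y0 = (int)std::floor(py);
      const int y1 = std::min(y0 + 1, h - 1);
      const double fy = py - y0;
      for (int c = 0; c < cin; ++c) {
        out(oi, oj, c) =
          (1 - fy) * ((1 - fx) * x(y0, x0, c) + fx * x(y0, x1, c)) +
          fy * ((1 - fx) * x(y1, x0, c) + fx * x(y1, x1, c));
      }
    }
  }
  return out;
}
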