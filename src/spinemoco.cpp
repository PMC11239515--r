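// Low-level numerics: 3x3 convolution (im2col + GEMM), bilinear warping with
// analytic gradients, and edge-clamped box-window sums. Array layouts follow
// R column-major conventions: images are (nx, ny[, c][, n]) with the first
// in-plane axis called x (lateral) and the second y (anterior-posterior).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---- 3x3 convolution, zero padding 1, stride s -----------------------------

static void im2col3(const double* x, int H, int W, int C, int s,
                    arma::mat& col, int Ho, int Wo) {
  // col is (9*C) x (Ho*Wo); row index r = kh + 3*kw + 9*c
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        const int r = kh + 3 * kw + 9 * c;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s + kw - 1;
          double* dst = col.colptr(0) + r; // strided fill below
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho)
              col(r, ho + (size_t)Ho * wo) = 0.0;
            continue;
          }
          const double* xcw = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * s + kh - 1;
            col(r, ho + (size_t)Ho * wo) =
              (hi >= 0 && hi < H) ? xcw[hi] : 0.0;
          }
          (void)dst;
        }
      }
    }
  }
}

static void col2im3(const arma::mat& gcol, int H, int W, int C, int s,
                    double* gx, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* xc = gx + (size_t)H * W * c;
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        const int r = kh + 3 * kw + 9 * c;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s + kw - 1;
          if (wi < 0 || wi >= W) continue;
          double* xcw = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * s + kh - 1;
            if (hi >= 0 && hi < H)
              xcw[hi] += gcol(r, ho + (size_t)Ho * wo);
          }
        }
      }
    }
  }
}

// x: (H, W, Cin, N), w: (3, 3, Cin, Cout), b: length Cout
// [[Rcpp::export(name = ".conv2dFwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  IntegerVector wd = w.attr("dim");
  const int Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  const int Ho = (H + stride - 1) / stride, Wo = (W + stride - 1) / stride;
  // weight matrix (9*Cin x Cout): same memory layout as the R array
  arma::mat Wm(const_cast<double*>(w.begin()), 9 * Cin, Cout, false, true);
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(9 * C, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (size_t)H * W * C * n, H, W, C, stride, col, Ho, Wo);
    arma::mat Y(y.begin() + (size_t)Ho * Wo * Cout * n,
                (size_t)Ho * Wo, Cout, false, true);
    Y = col.t() * Wm;
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export(name = ".conv2dBwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  IntegerVector wd = w.attr("dim");
  const int Cin = wd[2], Cout = wd[3];
  const int Ho = (H + stride - 1) / stride, Wo = (W + stride - 1) / stride;
  arma::mat Wm(const_cast<double*>(w.begin()), 9 * Cin, Cout, false, true);
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat gWm(gw.begin(), 9 * Cin, Cout, false, true);
  arma::vec gbv(gb.begin(), Cout, false, true);
  arma::mat col(9 * C, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (size_t)H * W * C * n, H, W, C, stride, col, Ho, Wo);
    arma::mat G(const_cast<double*>(gy.begin()) + (size_t)Ho * Wo * Cout * n,
                (size_t)Ho * Wo, Cout, false, true);
    gWm += col * G;
    gbv += arma::sum(G, 0).t();
    arma::mat gcol = Wm * G.t();
    col2im3(gcol, H, W, C, stride, gx.begin() + (size_t)H * W * C * n, Ho, Wo);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---- bilinear warp with edge clamp -----------------------------------------
// out(p) = img(p + u(p)); img: (H, W, N); field: (H, W, 2, N) with
// component 1 = displacement along the first axis, 2 = along the second.

// [[Rcpp::export(name = ".warpFwd")]]
NumericVector warp_fwd(NumericVector img, NumericVector field) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1], N = d[2];
  NumericVector out(img.size());
  out.attr("dim") = d;
  for (int n = 0; n < N; ++n) {
    const double* I = img.begin() + (size_t)H * W * n;
    const double* ux = field.begin() + (size_t)H * W * 2 * n;
    const double* uy = ux + (size_t)H * W;
    double* O = out.begin() + (size_t)H * W * n;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const size_t idx = h + (size_t)H * w;
        double xs = h + ux[idx], ys = w + uy[idx];
        if (xs < 0) xs = 0; if (xs > H - 1) xs = H - 1;
        if (ys < 0) ys = 0; if (ys > W - 1) ys = W - 1;
        const int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
        const int x1 = std::min(x0 + 1, H - 1), y1 = std::min(y0 + 1, W - 1);
        const double fx = xs - x0, fy = ys - y0;
        const double i00 = I[x0 + (size_t)H * y0], i10 = I[x1 + (size_t)H * y0];
        const double i01 = I[x0 + (size_t)H * y1], i11 = I[x1 + (size_t)H * y1];
        O[idx] = (1 - fx) * (1 - fy) * i00 + fx * (1 - fy) * i10 +
                 (1 - fx) * fy * i01 + fx * fy * i11;
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".warpBwd")]]
List warp_bwd(NumericVector img, NumericVector field, NumericVector gout) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1], N = d[2];
  NumericVector gimg(img.size());
  gimg.attr("dim") = d;
  NumericVector gfield(field.size());
  gfield.attr("dim") = field.attr("dim");
  for (int n = 0; n < N; ++n) {
    const double* I = img.begin() + (size_t)H * W * n;
    const double* ux = field.begin() + (size_t)H * W * 2 * n;
    const double* uy = ux + (size_t)H * W;
    const double* G = gout.begin() + (size_t)H * W * n;
    double* gI = gimg.begin() + (size_t)H * W * n;
    double* gux = gfield.begin() + (size_t)H * W * 2 * n;
    double* guy = gux + (size_t)H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const size_t idx = h + (size_t)H * w;
        double xs = h + ux[idx], ys = w + uy[idx];
        bool cx = false, cy = false; // clamped => zero field gradient
        if (xs < 0) { xs = 0; cx = true; }
        if (xs > H - 1) { xs = H - 1; cx = true; }
        if (ys < 0) { ys = 0; cy = true; }
        if (ys > W - 1) { ys = W - 1; cy = true; }
        const int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
        const int x1 = std::min(x0 + 1, H - 1), y1 = std::min(y0 + 1, W - 1);
        const double fx = xs - x0, fy = ys - y0;
        const double g = G[idx];
        const size_t i00 = x0 + (size_t)H * y0, i10 = x1 + (size_t)H * y0;
        const size_t i01 = x0 + (size_t)H * y1, i11 = x1 + (size_t)H * y1;
        gI[i00] += g * (1 - fx) * (1 - fy);
        gI[i10] += g * fx * (1 - fy);
        gI[i01] += g * (1 - fx) * fy;
        gI[i11] += g * fx * fy;
        if (!cx) {
          // d out / d xs = (1-fy)*(i10-i00) + fy*(i11-i01)
          gux[idx] = g * ((1 - fy) * (I[i10] - I[i00]) +
                          fy * (I[i11] - I[i01]));
        }
        if (!cy) {
          guy[idx] = g * ((1 - fx) * (I[i01] - I[i00]) +
                          fx * (I[i11] - I[i10]));
        }
      }
    }
  }
  return List::create(_["gimg"] = gimg, _["gfield"] = gfield);
}

// ---- edge-clamped box-window sums (for windowed NCC) -----------------------
// S(p) = sum over the n x n window centered at p of X(clamp(q)).

// [[Rcpp::export(name = ".boxSum")]]
NumericMatrix box_sum(NumericMatrix x, int n) {
  const int H = x.nrow(), W = x.ncol(), k = n / 2;
  NumericMatrix out(H, W);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      double s = 0.0;
      for (int dw = -k; dw <= k; ++dw) {
        int wq = std::min(std::max(w + dw, 0), W - 1);
        for (int dh = -k; dh <= k; ++dh) {
          int hq = std::min(std::max(h + dh, 0), H - 1);
          s += x(hq, wq);
        }
      }
      out(h, w) = s;
    }
  }
  return out;
}

// Adjoint of box_sum: scatter y(p) into every clamp(p + d), d in window.
// [[Rcpp::export(name = ".boxSumAdj")]]
NumericMatrix box_sum_adj(NumericMatrix y, int n) {
  const int H = y.nrow(), W = y.ncol(), k = n / 2;
  NumericMatrix out(H, W);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      const double v = y(h, w);
      for (int dw = -k; dw <= k; ++dw) {
        int wq = std::min(std::max(w + dw, 0), W - 1);
        for (int dh = -k; dh <= k; ++dh) {
          int hq = std::min(std::max(h + dh, 0), H - 1);
          out(hq, wq) += v;
        }
      }
    }
  }
  return out;
}
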