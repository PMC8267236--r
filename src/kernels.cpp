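// Low-level tensor kernels for the segmentation network.
//
// Layout convention (R column-major):
//   activations: H x W x C x N   (pixel-major within a channel plane)
//   conv weight: kh x kw x Cin x Cout
// All convolutions are stride 1; spatial downsampling is done by max pooling
// and upsampling by factor-2 bilinear interpolation, matching the
// encoder/decoder design.
//
// im2col uses a (P x K) layout, P = Ho*Wo output pixels, K = kh*kw*Cin, so
// that the hot inner loops write/read contiguous memory and the GEMM output
// (P x Cout) aliases the activation array directly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C,
                             int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-D array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// col is P x K, column k = ki + kh*(kj + kw*c); entry (q, k), q = oi + Ho*oj.
static void im2col(const double* x, int H, int W, int C, int kh, int kw,
                   int pad, int dil, int Ho, int Wo, arma::mat& col) {
  const size_t P = (size_t)Ho * Wo;
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        double* ccol = col.colptr(ki + kh * (kj + kw * c));
        for (int oj = 0; oj < Wo; ++oj) {
          const int jj = oj - pad + dil * kj;
          if (jj < 0 || jj >= W) continue;
          const double* xcol = xc + (size_t)H * jj;
          double* cdst = ccol + (size_t)Ho * oj;
          const int i0 = std::max(0, pad - dil * ki);
          const int i1 = std::min(Ho, H + pad - dil * ki);
          for (int oi = i0; oi < i1; ++oi) {
            cdst[oi] = xcol[oi - pad + dil * ki];
          }
        }
      }
    }
  }
}

// transpose of im2col: accumulate P x K gradient columns back into gx.
static void col2im(const arma::mat& col, int H, int W, int C, int kh, int kw,
                   int pad, int dil, int Ho, int Wo, double* gx) {
  for (int c = 0; c < C; ++c) {
    double* xc = gx + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const double* ccol = col.colptr(ki + kh * (kj + kw * c));
        for (int oj = 0; oj < Wo; ++oj) {
          const int jj = oj - pad + dil * kj;
          if (jj < 0 || jj >= W) continue;
          double* xcol = xc + (size_t)H * jj;
          const double* csrc = ccol + (size_t)Ho * oj;
          const int i0 = std::max(0, pad - dil * ki);
          const int i1 = std::min(Ho, H + pad - dil * ki);
          for (int oi = i0; oi < i1; ++oi) {
            xcol[oi - pad + dil * ki] += csrc[oi];
          }
        }
      }
    }
  }
}

// weight array (kh,kw,Cin,Cout) -> K x Cout matrix, rows aligned with
// im2col's column index. The array memory is already in exactly this
// order, so alias it.
static arma::mat weight_matrix(const NumericVector& w, int K, int Cout) {
  return arma::mat(const_cast<double*>(w.begin()), K, Cout, false, true);
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int pad, int dil) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weight must be 4-D (kh, kw, Cin, Cout)");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weight expects %d", C, Cin);
  if (b.size() != Cout) stop("conv2d: bias length must equal Cout");
  const int Ho = H + 2 * pad - dil * (kh - 1);
  const int Wo = W + 2 * pad - dil * (kw - 1);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: non-positive output size");
  const size_t P = (size_t)Ho * Wo;
  const int K = kh * kw * Cin;
  const bool one_by_one = (kh == 1 && kw == 1 && pad == 0 && dil == 1);

  NumericVector y(P * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm = weight_matrix(w, K, Cout);
  arma::mat col;
  if (!one_by_one) col.set_size(P, K);
  for (int n = 0; n < N; ++n) {
    arma::mat Y(y.begin() + P * Cout * n, P, Cout, false, true);
    if (one_by_one) {
      // pointwise convolution: plain GEMM on the aliased activation matrix
      arma::mat X(const_cast<double*>(x.begin()) + P * C * n, P, C, false,
                  true);
      Y = X * Wm;
    } else {
      im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, pad, dil,
             Ho, Wo, col);
      Y = col * Wm;
    }
    for (int o = 0; o < Cout; ++o) Y.col(o) += b[o];
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gy, int pad,
               int dil) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho, Wo, Cg, Ng;
  get_dims4(gy, Ho, Wo, Cg, Ng);
  if (Cg != Cout || Ng != N) stop("conv2d_bw: gradient shape mismatch");
  const size_t P = (size_t)Ho * Wo;
  const int K = kh * kw * Cin;

  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(Cout);

  arma::mat Wm = weight_matrix(w, K, Cout);
  arma::mat GW(gw.begin(), K, Cout, false, true);
  const bool one_by_one = (kh == 1 && kw == 1 && pad == 0 && dil == 1);
  arma::mat col, Gcol;
  if (!one_by_one) {
    col.set_size(P, K);
    Gcol.set_size(P, K);
  }
  for (int n = 0; n < N; ++n) {
    arma::mat GY(const_cast<double*>(gy.begin()) + P * Cout * n, P, Cout,
                 false, true);
    for (int o = 0; o < Cout; ++o) gb[o] += arma::accu(GY.col(o));
    if (one_by_one) {
      arma::mat X(const_cast<double*>(x.begin()) + P * C * n, P, C, false,
                  true);
      arma::mat GX(gx.begin() + P * C * n, P, C, false, true);
      GW += X.t() * GY;
      GX = GY * Wm.t();
    } else {
      im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, pad, dil,
             Ho, Wo, col);
      GW += col.t() * GY;
      Gcol = GY * Wm.t();
      col2im(Gcol, H, W, C, kh, kw, pad, dil, Ho, Wo,
             gx.begin() + (size_t)H * W * C * n);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled values and the 0-based linear
// index (within the full input array) of each argmax for the backward pass.
// [[Rcpp::export]]
List maxpool2_fw(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  if (H % 2 != 0 || W % 2 != 0) stop("maxpool2: spatial dims must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  size_t q = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int oj = 0; oj < Wo; ++oj) {
        for (int oi = 0; oi < Ho; ++oi, ++q) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bidx = 0;
          for (int dj = 0; dj < 2; ++dj) {
            for (int di = 0; di < 2; ++di) {
              const size_t lin =
                  base + (size_t)(2 * oi + di) + (size_t)H * (2 * oj + dj);
              if (xp[lin] > best) {
                best = xp[lin];
                bidx = lin;
              }
            }
          }
          yp[q] = best;
          ip[q] = (int)bidx;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw(IntegerVector idx, NumericVector gy, int H, int W) {
  int Ho, Wo, C, N;
  get_dims4(gy, Ho, Wo, C, N);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* gp = gy.begin();
  const int* ip = idx.begin();
  double* xp = gx.begin();
  for (size_t q = 0; q < (size_t)gy.size(); ++q) xp[(size_t)ip[q]] += gp[q];
  return gx;
}

// Factor-2 bilinear upsampling with half-pixel centers (source coordinate
// s = (o + 0.5)/2 - 0.5, clamped at the border).
static void bilinear_axis(int Ho, int H, std::vector<int>& i0,
                          std::vector<int>& i1, std::vector<double>& t) {
  i0.resize(Ho); i1.resize(Ho); t.resize(Ho);
  for (int o = 0; o < Ho; ++o) {
    double s = (o + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    int lo = (int)std::floor(s);
    int hi = lo + 1 < H ? lo + 1 : H - 1;
    i0[o] = lo; i1[o] = hi; t[o] = s - lo;
  }
}

// [[Rcpp::export]]
NumericVector upsample2_fw(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> rt, ct;
  bilinear_axis(Ho, H, r0, r1, rt);
  bilinear_axis(Wo, W, c0, c1, ct);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
      double* yc = yp + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int oj = 0; oj < Wo; ++oj) {
        const double tw = ct[oj];
        const double* xa = xc + (size_t)H * c0[oj];
        const double* xb = xc + (size_t)H * c1[oj];
        double* ycol = yc + (size_t)Ho * oj;
        for (int oi = 0; oi < Ho; ++oi) {
          const double th = rt[oi];
          const double va = (1 - th) * xa[r0[oi]] + th * xa[r1[oi]];
          const double vb = (1 - th) * xb[r0[oi]] + th * xb[r1[oi]];
          ycol[oi] = (1 - tw) * va + tw * vb;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bw(NumericVector gy) {
  int Ho, Wo, C, N;
  get_dims4(gy, Ho, Wo, C, N);
  if (Ho % 2 != 0 || Wo % 2 != 0) stop("upsample2_bw: odd output dims");
  const int H = Ho / 2, W = Wo / 2;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> rt, ct;
  bilinear_axis(Ho, H, r0, r1, rt);
  bilinear_axis(Wo, W, c0, c1, ct);
  const double* gp = gy.begin();
  double* xp = gx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
      const double* gc = gp + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int oj = 0; oj < Wo; ++oj) {
        const double tw = ct[oj];
        double* xa = xc + (size_t)H * c0[oj];
        double* xb = xc + (size_t)H * c1[oj];
        const double* gcol = gc + (size_t)Ho * oj;
        for (int oi = 0; oi < Ho; ++oi) {
          const double th = rt[oi];
          const double g = gcol[oi];
          xa[r0[oi]] += (1 - tw) * (1 - th) * g;
          xa[r1[oi]] += (1 - tw) * th * g;
          xb[r0[oi]] += tw * (1 - th) * g;
          xb[r1[oi]] += tw * th * g;
        }
      }
    }
  }
  return gx;
}

// Fused batch-norm (+ optional ReLU) forward. In training mode the batch
// statistics are computed here (population variance over H, W, N per
// channel); in eval mode the supplied running statistics are used.
// Returns y, the saved normalized activations xhat, the inverse std, and
// the batch statistics (for the running-average update done in R).
// [[Rcpp::export]]
List bn_relu_fw(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector rmean, NumericVector rvar, bool training,
                bool relu, double eps) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const size_t P = (size_t)H * W;
  NumericVector y(x.size()), xhat(x.size());
  y.attr("dim") = x.attr("dim");
  xhat.attr("dim") = x.attr("dim");
  NumericVector mu(C), var(C), invstd(C);
  const double m = (double)(P * N);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + P * (c + (size_t)C * n);
        for (size_t q = 0; q < P; ++q) {
          s += xc[q];
          s2 += xc[q] * xc[q];
        }
      }
      mu[c] = s / m;
      var[c] = std::max(0.0, s2 / m - mu[c] * mu[c]);
    }
  } else {
    for (int c = 0; c < C; ++c) {
      mu[c] = rmean[c];
      var[c] = rvar[c];
    }
  }
  for (int c = 0; c < C; ++c) {
    invstd[c] = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c], b = beta[c], mc = mu[c], is = invstd[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = P * (c + (size_t)C * n);
      const double* xc = x.begin() + off;
      double* yc = y.begin() + off;
      double* hc = xhat.begin() + off;
      for (size_t q = 0; q < P; ++q) {
        const double xh = (xc[q] - mc) * is;
        hc[q] = xh;
        double v = g * xh + b;
        if (relu && v < 0) v = 0;
        yc[q] = v;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["mu"] = mu, _["var"] = var);
}

// Backward of the fused batch-norm (+ ReLU). The ReLU mask is recovered
// from the saved output (y > 0).
// [[Rcpp::export]]
List bn_relu_bw(NumericVector gy, NumericVector y, NumericVector xhat,
                NumericVector gamma, NumericVector invstd, bool training,
                bool relu) {
  int H, W, C, N;
  get_dims4(gy, H, W, C, N);
  const size_t P = (size_t)H * W;
  NumericVector gx(gy.size());
  gx.attr("dim") = gy.attr("dim");
  NumericVector ggamma(C), gbeta(C);
  const double m = (double)(P * N);
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const size_t off = P * (c + (size_t)C * n);
      const double* gc = gy.begin() + off;
      const double* yc = y.begin() + off;
      const double* hc = xhat.begin() + off;
      for (size_t q = 0; q < P; ++q) {
        const double g = (relu && yc[q] <= 0) ? 0.0 : gc[q];
        s1 += g;
        s2 += g * hc[q];
      }
    }
    gbeta[c] = s1;
    ggamma[c] = s2;
    const double k = gamma[c] * invstd[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = P * (c + (size_t)C * n);
      const double* gc = gy.begin() + off;
      const double* yc = y.begin() + off;
      const double* hc = xhat.begin() + off;
      double* xc = gx.begin() + off;
      for (size_t q = 0; q < P; ++q) {
        const double g = (relu && yc[q] <= 0) ? 0.0 : gc[q];
        xc[q] = training ? k * (g - s1 / m - hc[q] * s2 / m) : k * g;
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}

// Composite BCE + smoothed-Dice segmentation loss from logits, with the
// full gradient wrt the logits computed in the same pass. Dice is computed
// per (channel, sample) slab and averaged; BCE is the global pixel mean.
// Returns value, bce, dice components and the gradient array dz such that
// d(loss)/d(z) = dz.
// [[Rcpp::export]]
List seg_loss_fwbw(NumericVector z, NumericVector target, double alpha_bce,
                   double eps, double clamp) {
  int H, W, C, N;
  get_dims4(z, H, W, C, N);
  if (target.size() != z.size()) stop("seg_loss: shape mismatch");
  const size_t P = (size_t)H * W;
  const int S = C * N;  // slabs
  NumericVector dz(z.size());
  dz.attr("dim") = z.attr("dim");
  std::vector<double> p((size_t)z.size());
  const double* zp = z.begin();
  const double* tp = target.begin();
  double bce = 0.0;
  double dice = 0.0;
  const double ntot = (double)z.size();

  for (int s = 0; s < S; ++s) {
    const double* ts = tp + P * s;
    const double* zs = zp + P * s;
    double* ps = p.data() + P * s;
    double s_tp = 0, s_t2 = 0, s_p2 = 0;
    for (size_t q = 0; q < P; ++q) {
      const double pv = 1.0 / (1.0 + std::exp(-zs[q]));
      ps[q] = pv;
      const double pc = std::min(std::max(pv, clamp), 1.0 - clamp);
      bce -= ts[q] * std::log(pc) + (1.0 - ts[q]) * std::log(1.0 - pc);
      s_tp += ts[q] * pv;
      s_t2 += ts[q] * ts[q];
      s_p2 += pv * pv;
    }
    const double den = s_t2 + s_p2 + eps;
    dice += 1.0 - 2.0 * s_tp / den;
    // gradient: BCE term + Dice term, both through the sigmoid
    double* ds = dz.begin() + P * s;
    for (size_t q = 0; q < P; ++q) {
      const double pv = ps[q];
      const double pc = std::min(std::max(pv, clamp), 1.0 - clamp);
      const double dbce =
          alpha_bce * (-ts[q] / pc + (1.0 - ts[q]) / (1.0 - pc)) / ntot;
      const double ddice =
          -(2.0 * ts[q] * den - 4.0 * s_tp * pv) / (den * den) / (double)S;
      ds[q] = (dbce + ddice) * pv * (1.0 - pv);
    }
  }
  bce /= ntot;
  dice /= (double)S;
  return List::create(_["value"] = alpha_bce * bce + dice, _["bce"] = bce,
                      _["dice"] = dice, _["dz"] = dz);
}
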