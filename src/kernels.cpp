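// Numeric kernels for the detection networks.
//
// Layout conventions (column-major R arrays):
//   activations x : dim (C, H, W)       -> x[c + C*(h + H*w)]
//   conv weights  : dim (k, k, Cin/g, Cout) -> w[ki + k*(kj + k*(c + (Cin/g)*co))]
//   im2col rows   : row = ki + k*(kj + k*c), matching the weight layout, so a
//                   grouped convolution is one GEMM per group.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double get_x(const double* x, int C, int H, int W,
                           int c, int h, int w) {
  if (h < 0 || h >= H || w < 0 || w >= W) return 0.0;
  return x[c + (size_t)C * (h + (size_t)H * w)];
}

static void im2col(const double* x, int C, int H, int W,
                   int k, int stride, int pad, int c0, int cg,
                   int Ho, int Wo, arma::mat& col) {
  // col is (k*k*cg) x (Ho*Wo)
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int p = ho + Ho * wo;
      double* dst = col.colptr(p);
      for (int c = 0; c < cg; ++c) {
        for (int kj = 0; kj < k; ++kj) {
          int wi = wo * stride - pad + kj;
          for (int ki = 0; ki < k; ++ki) {
            int hi = ho * stride - pad + ki;
            dst[ki + k * (kj + k * c)] = get_x(x, C, H, W, c0 + c, hi, wi);
          }
        }
      }
    }
  }
}

static void col2im_add(double* dx, int C, int H, int W,
                       int k, int stride, int pad, int c0, int cg,
                       int Ho, int Wo, const arma::mat& dcol) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int p = ho + Ho * wo;
      const double* src = dcol.colptr(p);
      for (int c = 0; c < cg; ++c) {
        for (int kj = 0; kj < k; ++kj) {
          int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            dx[(c0 + c) + (size_t)C * (hi + (size_t)H * wi)] +=
              src[ki + k * (kj + k * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector bias,
                        int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2];
  int k = wd[0], cg = wd[2], Cout = wd[3];
  int G = groups, cout_g = Cout / G;
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y(Cout * (size_t)Ho * Wo);
  y.attr("dim") = IntegerVector::create(Cout, Ho, Wo);
  arma::mat col(k * k * cg, (size_t)Ho * Wo);
  for (int g = 0; g < G; ++g) {
    im2col(x.begin(), C, H, W, k, stride, pad, g * cg, cg, Ho, Wo, col);
    arma::mat Wg(const_cast<double*>(w.begin()) + (size_t)k * k * cg * cout_g * g,
                 k * k * cg, cout_g, false, true);
    arma::mat out = Wg.t() * col;  // cout_g x P
    for (size_t p = 0; p < (size_t)Ho * Wo; ++p) {
      for (int co = 0; co < cout_g; ++co) {
        double v = out(co, p);
        if (bias.size() > 0) v += bias[g * cout_g + co];
        y[(g * cout_g + co) + (size_t)Cout * p] = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
               int stride, int pad, int groups, bool need_dx, bool has_bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = dy.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2];
  int k = wd[0], cg = wd[2], Cout = wd[3];
  int Ho = yd[1], Wo = yd[2];
  int G = groups, cout_g = Cout / G;
  size_t P = (size_t)Ho * Wo;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(has_bias ? Cout : 0);
  NumericVector dx(need_dx ? x.size() : 0);
  if (need_dx) dx.attr("dim") = xd;
  arma::mat col(k * k * cg, P);
  for (int g = 0; g < G; ++g) {
    im2col(x.begin(), C, H, W, k, stride, pad, g * cg, cg, Ho, Wo, col);
    arma::mat dYg(cout_g, P);
    for (size_t p = 0; p < P; ++p)
      for (int co = 0; co < cout_g; ++co)
        dYg(co, p) = dy[(g * cout_g + co) + (size_t)Cout * p];
    arma::mat dWg = col * dYg.t();  // (k*k*cg) x cout_g
    std::copy(dWg.begin(), dWg.end(),
              dw.begin() + (size_t)k * k * cg * cout_g * g);
    if (has_bias) {
      arma::vec s = arma::sum(dYg, 1);
      for (int co = 0; co < cout_g; ++co) db[g * cout_g + co] = s(co);
    }
    if (need_dx) {
      arma::mat Wg(const_cast<double*>(w.begin()) + (size_t)k * k * cg * cout_g * g,
                   k * k * cg, cout_g, false, true);
      arma::mat dcol = Wg * dYg;
      col2im_add(dx.begin(), C, H, W, k, stride, pad, g * cg, cg, Ho, Wo, dcol);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool2d_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y(C * (size_t)Ho * Wo);
  IntegerVector idx(C * (size_t)Ho * Wo);  // flat argmax into x, or -1
  y.attr("dim") = IntegerVector::create(C, Ho, Wo);
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int c = 0; c < C; ++c) {
        double best = -std::numeric_limits<double>::infinity();
        long besti = -1;
        for (int kj = 0; kj < k; ++kj) {
          int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            double v = x[c + (size_t)C * (hi + (size_t)H * wi)];
            if (v > best) { best = v; besti = c + (size_t)C * (hi + (size_t)H * wi); }
          }
        }
        size_t o = c + (size_t)C * (ho + (size_t)Ho * wo);
        y[o] = best;
        idx[o] = (int)besti;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2d_bw(IntegerVector idx, NumericVector dy,
                           IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2]);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    if (idx[i] >= 0) dx[idx[i]] += dy[i];
  return dx;
}

// [[Rcpp::export]]
NumericVector upsample2x_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2];
  NumericVector y((size_t)C * 2 * H * 2 * W);
  y.attr("dim") = IntegerVector::create(C, 2 * H, 2 * W);
  for (int w = 0; w < 2 * W; ++w)
    for (int h = 0; h < 2 * H; ++h)
      for (int c = 0; c < C; ++c)
        y[c + (size_t)C * (h + (size_t)2 * H * w)] =
          x[c + (size_t)C * ((h / 2) + (size_t)H * (w / 2))];
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2x_bw(NumericVector dy, IntegerVector xdim) {
  int C = xdim[0], H = xdim[1], W = xdim[2];
  NumericVector dx((size_t)C * H * W);
  dx.attr("dim") = xdim;
  for (int w = 0; w < 2 * W; ++w)
    for (int h = 0; h < 2 * H; ++h)
      for (int c = 0; c < C; ++c)
        dx[c + (size_t)C * ((h / 2) + (size_t)H * (w / 2))] +=
          dy[c + (size_t)C * (h + (size_t)2 * H * w)];
  return dx;
}

static inline void bilinear_weights(double hs, double ws, int H, int W,
                                    int* hh, int* ww, double* wt) {
  int h0 = (int)std::floor(hs), w0 = (int)std::floor(ws);
  double ah = hs - h0, aw = ws - w0;
  hh[0] = h0; ww[0] = w0; wt[0] = (1 - ah) * (1 - aw);
  hh[1] = h0 + 1; ww[1] = w0; wt[1] = ah * (1 - aw);
  hh[2] = h0; ww[2] = w0 + 1; wt[2] = (1 - ah) * aw;
  hh[3] = h0 + 1; ww[3] = w0 + 1; wt[3] = ah * aw;
}

// Modulated deformable convolution (DCNv2), stride 1, square kernel.
// offsets: (2*k*k, Ho, Wo), channel 2t = dy(h), 2t+1 = dx(w); mask: (k*k, Ho, Wo)
// already squashed to [0, 1].
// [[Rcpp::export]]
NumericVector dcn_fw(NumericVector x, NumericVector w, NumericVector bias,
                     NumericVector offsets, NumericVector mask,
                     int pad, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2];
  int k = wd[0], cg = wd[2], Cout = wd[3];
  int G = groups, cout_g = Cout / G;
  int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  size_t P = (size_t)Ho * Wo;
  NumericVector y(Cout * P);
  y.attr("dim") = IntegerVector::create(Cout, Ho, Wo);
  arma::mat col(k * k * cg, P);
  int hh[4], ww[4]; double wt[4];
  for (int g = 0; g < G; ++g) {
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        size_t p = ho + (size_t)Ho * wo;
        double* dst = col.colptr(p);
        for (int kj = 0; kj < k; ++kj)
          for (int ki = 0; ki < k; ++ki) {
            int t = ki * k + kj;  // tap index (row-major over (ki,kj))
            double dh = offsets[(2 * t) + (size_t)(2 * k * k) * p];
            double dwo = offsets[(2 * t + 1) + (size_t)(2 * k * k) * p];
            double m = mask[t + (size_t)(k * k) * p];
            double hs = ho - pad + ki + dh;
            double ws = wo - pad + kj + dwo;
            bilinear_weights(hs, ws, H, W, hh, ww, wt);
            for (int c = 0; c < cg; ++c) {
              double v = 0;
              for (int q = 0; q < 4; ++q)
                v += wt[q] * get_x(x.begin(), C, H, W, g * cg + c, hh[q], ww[q]);
              dst[ki + k * (kj + k * c)] = m * v;
            }
          }
      }
    arma::mat Wg(const_cast<double*>(w.begin()) + (size_t)k * k * cg * cout_g * g,
                 k * k * cg, cout_g, false, true);
    arma::mat out = Wg.t() * col;
    for (size_t p = 0; p < P; ++p)
      for (int co = 0; co < cout_g; ++co) {
        double v = out(co, p);
        if (bias.size() > 0) v += bias[g * cout_g + co];
        y[(g * cout_g + co) + (size_t)Cout * p] = v;
      }
  }
  return y;
}

// [[Rcpp::export]]
List dcn_bw(NumericVector x, NumericVector w, NumericVector offsets,
            NumericVector mask, NumericVector dy, int pad, int groups,
            bool has_bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = dy.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2];
  int k = wd[0], cg = wd[2], Cout = wd[3];
  int Ho = yd[1], Wo = yd[2];
  int G = groups, cout_g = Cout / G;
  size_t P = (size_t)Ho * Wo;
  NumericVector dx(x.size()); dx.attr("dim") = xd;
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  NumericVector db(has_bias ? Cout : 0);
  NumericVector doff(offsets.size()); doff.attr("dim") = offsets.attr("dim");
  NumericVector dmask(mask.size()); dmask.attr("dim") = mask.attr("dim");
  arma::mat col(k * k * cg, P);
  int hh[4], ww[4]; double wt[4];
  for (int g = 0; g < G; ++g) {
    // rebuild the deformed im2col (sampled values, pre-mask kept separately)
    arma::mat samp(k * k * cg, P);  // bilinear samples, unmasked
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        size_t p = ho + (size_t)Ho * wo;
        double* dc = col.colptr(p);
        double* ds = samp.colptr(p);
        for (int kj = 0; kj < k; ++kj)
          for (int ki = 0; ki < k; ++ki) {
            int t = ki * k + kj;
            double dh = offsets[(2 * t) + (size_t)(2 * k * k) * p];
            double dwo = offsets[(2 * t + 1) + (size_t)(2 * k * k) * p];
            double m = mask[t + (size_t)(k * k) * p];
            double hs = ho - pad + ki + dh;
            double ws = wo - pad + kj + dwo;
            bilinear_weights(hs, ws, H, W, hh, ww, wt);
            for (int c = 0; c < cg; ++c) {
              double v = 0;
              for (int q = 0; q < 4; ++q)
                v += wt[q] * get_x(x.begin(), C, H, W, g * cg + c, hh[q], ww[q]);
              ds[ki + k * (kj + k * c)] = v;
              dc[ki + k * (kj + k * c)] = m * v;
            }
          }
      }
    arma::mat dYg(cout_g, P);
    for (size_t p = 0; p < P; ++p)
      for (int co = 0; co < cout_g; ++co)
        dYg(co, p) = dy[(g * cout_g + co) + (size_t)Cout * p];
    arma::mat dWg = col * dYg.t();
    std::copy(dWg.begin(), dWg.end(),
              dw.begin() + (size_t)k * k * cg * cout_g * g);
    if (has_bias) {
      arma::vec s = arma::sum(dYg, 1);
      for (int co = 0; co < cout_g; ++co) db[g * cout_g + co] = s(co);
    }
    arma::mat Wg(const_cast<double*>(w.begin()) + (size_t)k * k * cg * cout_g * g,
                 k * k * cg, cout_g, false, true);
    arma::mat dcol = Wg * dYg;  // gradient wrt masked samples
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        size_t p = ho + (size_t)Ho * wo;
        const double* dc = dcol.colptr(p);
        const double* ds = samp.colptr(p);
        for (int kj = 0; kj < k; ++kj)
          for (int ki = 0; ki < k; ++ki) {
            int t = ki * k + kj;
            double dh = offsets[(2 * t) + (size_t)(2 * k * k) * p];
            double dwo = offsets[(2 * t + 1) + (size_t)(2 * k * k) * p];
            double m = mask[t + (size_t)(k * k) * p];
            double hs = ho - pad + ki + dh;
            double ws = wo - pad + kj + dwo;
            bilinear_weights(hs, ws, H, W, hh, ww, wt);
            double g_dh = 0, g_dw = 0, g_m = 0;
            for (int c = 0; c < cg; ++c) {
              double gout = dc[ki + k * (kj + k * c)];
              g_m += gout * ds[ki + k * (kj + k * c)];
              double gsamp = gout * m;
              // scatter into dx and accumulate position gradients
              int h0 = (int)std::floor(hs), w0 = (int)std::floor(ws);
              double ah = hs - h0, aw = ws - w0;
              double v00 = get_x(x.begin(), C, H, W, g * cg + c, h0, w0);
              double v10 = get_x(x.begin(), C, H, W, g * cg + c, h0 + 1, w0);
              double v01 = get_x(x.begin(), C, H, W, g * cg + c, h0, w0 + 1);
              double v11 = get_x(x.begin(), C, H, W, g * cg + c, h0 + 1, w0 + 1);
              g_dh += gsamp * ((1 - aw) * (v10 - v00) + aw * (v11 - v01));
              g_dw += gsamp * ((1 - ah) * (v01 - v00) + ah * (v11 - v10));
              for (int q = 0; q < 4; ++q) {
                if (hh[q] < 0 || hh[q] >= H || ww[q] < 0 || ww[q] >= W) continue;
                dx[(g * cg + c) + (size_t)C * (hh[q] + (size_t)H * ww[q])] +=
                  gsamp * wt[q];
              }
            }
            doff[(2 * t) + (size_t)(2 * k * k) * p] += g_dh;
            doff[(2 * t + 1) + (size_t)(2 * k * k) * p] += g_dw;
            dmask[t + (size_t)(k * k) * p] += g_m;
          }
      }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db,
                      _["doff"] = doff, _["dmask"] = dmask);
}

// training-mode forward that also returns the im2col buffers (one per
// group) so the backward pass skips re-gathering
// [[Rcpp::export]]
List conv2d_fw_train(NumericVector x, NumericVector w, NumericVector bias,
                     int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2];
  int k = wd[0], cg = wd[2], Cout = wd[3];
  int G = groups, cout_g = Cout / G;
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y(Cout * (size_t)Ho * Wo);
  y.attr("dim") = IntegerVector::create(Cout, Ho, Wo);
  List cols(G);
  for (int g = 0; g < G; ++g) {
    NumericMatrix colr(k * k * cg, (size_t)Ho * Wo);
    arma::mat col(colr.begin(), k * k * cg, (size_t)Ho * Wo, false, true);
    im2col(x.begin(), C, H, W, k, stride, pad, g * cg, cg, Ho, Wo, col);
    arma::mat Wg(const_cast<double*>(w.begin()) + (size_t)k * k * cg * cout_g * g,
                 k * k * cg, cout_g, false, true);
    arma::mat out = Wg.t() * col;
    for (size_t p = 0; p < (size_t)Ho * Wo; ++p)
      for (int co = 0; co < cout_g; ++co) {
        double v = out(co, p);
        if (bias.size() > 0) v += bias[g * cout_g + co];
        y[(g * cout_g + co) + (size_t)Cout * p] = v;
      }
    cols[g] = colr;
  }
  return List::create(_["y"] = y, _["cols"] = cols);
}

// [[Rcpp::export]]
List conv2d_bw_cached(List cols, NumericVector w, NumericVector dy,
                      IntegerVector xdim, int stride, int pad, int groups,
                      bool need_dx, bool has_bias) {
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = dy.attr("dim");
  int C = xdim[0], H = xdim[1], W = xdim[2];
  int k = wd[0], cg = wd[2], Cout = wd[3];
  int Ho = yd[1], Wo = yd[2];
  int G = groups, cout_g = Cout / G;
  size_t P = (size_t)Ho * Wo;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(has_bias ? Cout : 0);
  NumericVector dx(need_dx ? (size_t)C * H * W : 0);
  if (need_dx) dx.attr("dim") = xdim;
  for (int g = 0; g < G; ++g) {
    NumericMatrix colr = cols[g];
    arma::mat col(colr.begin(), k * k * cg, P, false, true);
    arma::mat dYg(cout_g, P);
    for (size_t p = 0; p < P; ++p)
      for (int co = 0; co < cout_g; ++co)
        dYg(co, p) = dy[(g * cout_g + co) + (size_t)Cout * p];
    arma::mat dWg = col * dYg.t();
    std::copy(dWg.begin(), dWg.end(),
              dw.begin() + (size_t)k * k * cg * cout_g * g);
    if (has_bias) {
      arma::vec s = arma::sum(dYg, 1);
      for (int co = 0; co < cout_g; ++co) db[g * cout_g + co] = s(co);
    }
    if (need_dx) {
      arma::mat Wg(const_cast<double*>(w.begin()) + (size_t)k * k * cg * cout_g * g,
                   k * k * cg, cout_g, false, true);
      arma::mat dcol = Wg * dYg;
      col2im_add(dx.begin(), C, H, W, k, stride, pad, g * cg, cg, Ho, Wo, dcol);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// fused SGD-with-momentum + EMA update over a list of parameter
// environments (each with $value, $grad, optionally $mom, $ema, $trainable)
// [[Rcpp::export]]
void sgd_ema_step(List params, double lr, double momentum, double ema_decay,
                  bool do_ema) {
  int n = params.size();
  for (int i = 0; i < n; ++i) {
    Environment p = params[i];
    if (!as<bool>(p.get("trainable"))) continue;
    RObject gr = p.get("grad");
    if (gr.isNULL()) continue;
    NumericVector g(gr);
    NumericVector v(p.get("value"));
    RObject mo = p.exists("mom") ? p.get("mom") : R_NilValue;
    NumericVector m;
    if (mo.isNULL()) {
      m = NumericVector(g.size());
      p.assign("mom", m);
    } else {
      m = NumericVector(mo);
    }
    RObject eo = (do_ema && p.exists("ema")) ? p.get("ema") : R_NilValue;
    NumericVector e;
    bool have_e = false;
    if (do_ema) {
      if (eo.isNULL()) {
        e = clone(v);
        p.assign("ema", e);
        have_e = true;
      } else {
        e = NumericVector(eo);
        have_e = true;
      }
    }
    for (R_xlen_t j = 0; j < g.size(); ++j) {
      m[j] = momentum * m[j] + g[j];
      v[j] -= lr * m[j];
      if (have_e) e[j] = ema_decay * e[j] + (1 - ema_decay) * v[j];
    }
  }
}

#include <dlfcn.h>
// pin BLAS to one thread: the training loop issues thousands of small
// GEMMs per second, where thread-pool synchronization costs far more than
// it buys; resolved dynamically so non-OpenBLAS builds are unaffected
// [[Rcpp::export]]
bool blas_single_thread() {
  typedef void (*setfn)(int);
  setfn f = (setfn)dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
  if (f == nullptr) return false;
  f(1);
  return true;
}
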