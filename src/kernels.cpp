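// Numerical kernels: IIR filtering with initial state (for zero-phase
// Butterworth filtering) and the conv/pool primitives of the
// time-distributed CNN (im2col + GEMM, max-pooling with argmax).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Direct-form II transposed IIR filter with initial conditions zi
// (a[0] assumed 1 after normalization).
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x,
                         NumericVector zi) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nf = std::max(nb, na);
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(nf - 1, 0.0);
  for (int i = 0; i < std::min((int)zi.size(), nf - 1); ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int k = 0; k < nf - 2; ++k)
      z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    z[nf - 2] = bb[nf - 1] * xi - aa[nf - 1] * yi;
    y[i] = yi;
  }
  return y;
}

// im2col for a H x W x C cube and k x k valid convolution
static arma::mat im2col(const arma::cube& input, int k) {
  int Ho = input.n_rows - k + 1, Wo = input.n_cols - k + 1, C = input.n_slices;
  arma::mat out(Ho * Wo, k * k * C);
  int col = 0;
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        const arma::mat& sl = input.slice(c);
        arma::mat patch = sl.submat(di, dj, di + Ho - 1, dj + Wo - 1);
        out.col(col++) = arma::vectorise(patch);
      }
  return out;
}

// valid 2-D convolution (correlation), weights (k*k*Cin) x Cout
// [[Rcpp::export(name = ".conv2d_fw")]]
arma::cube conv2d_fw(const arma::cube& input, const arma::mat& W,
                     const arma::vec& b, int k) {
  int Ho = input.n_rows - k + 1, Wo = input.n_cols - k + 1;
  int Cout = W.n_cols;
  arma::mat cols = im2col(input, k);
  arma::mat out = cols * W;        // (Ho*Wo) x Cout
  out.each_row() += b.t();
  arma::cube res(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    res.slice(c) = arma::reshape(out.col(c), Ho, Wo);
  return res;
}

// backward pass of valid convolution; gout is (Ho, Wo, Cout)
// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(const arma::cube& input, const arma::mat& W,
               const arma::cube& gout, int k) {
  int Ho = gout.n_rows, Wo = gout.n_cols;
  int Cout = W.n_cols, Cin = input.n_slices;
  arma::mat g(Ho * Wo, Cout);
  for (int c = 0; c < Cout; ++c) g.col(c) = arma::vectorise(gout.slice(c));
  arma::mat cols = im2col(input, k);
  arma::mat gW = cols.t() * g;                 // (k*k*Cin) x Cout
  arma::vec gb = arma::sum(g, 0).t();
  // input gradient: scatter g * W^T back through im2col
  arma::mat gcols = g * W.t();                 // (Ho*Wo) x (k*k*Cin)
  arma::cube gin(input.n_rows, input.n_cols, Cin, arma::fill::zeros);
  int col = 0;
  for (int c = 0; c < Cin; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        arma::mat patch = arma::reshape(gcols.col(col++), Ho, Wo);
        gin.slice(c).submat(di, dj, di + Ho - 1, dj + Wo - 1) += patch;
      }
  return List::create(_["gin"] = gin, _["gW"] = gW, _["gb"] = gb);
}

// 2x2 (or k x k) max pooling with stride = k; returns pooled cube + argmax
// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(const arma::cube& input, int k) {
  int Ho = input.n_rows / k, Wo = input.n_cols / k, C = input.n_slices;
  arma::cube out(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = -arma::datum::inf;
        unsigned bi = 0;
        for (int dj = 0; dj < k; ++dj)
          for (int di = 0; di < k; ++di) {
            int r = i * k + di, s = j * k + dj;
            double v = input(r, s, c);
            if (v > best) { best = v; bi = r + s * input.n_rows; }
          }
        out(i, j, c) = best;
        idx(i, j, c) = bi;
      }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
arma::cube maxpool_bw(const arma::ucube& idx, const arma::cube& gout,
                      int H, int W) {
  int C = gout.n_slices;
  arma::cube gin(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* slice = gin.slice(c).memptr();
    for (unsigned u = 0; u < gout.n_rows * gout.n_cols; ++u) {
      slice[idx.slice(c)(u)] += gout.slice(c)(u);
    }
  }
  return gin;
}

// ---- fused time-distributed block ----------------------------------------
// Forward/backward for all T windows of one sample. Computed in single
// precision (the GEMMs dominate training time; float32 is ample for
// gradient training and results stay deterministic). The forward pass
// keeps its activations in a C++-side cache handed back to R as an
// external pointer, so no large arrays cross the R boundary.

struct TDCache {
  arma::fcube wf;        // input windows (H, W, T)
  arma::fcube r1, r2;    // post-ReLU conv outputs, (.,.,F*T)
  arma::ucube idx;       // pooling argmax
  arma::fmat fl, ad;     // flattened pooled features, pre-ReLU dense
  arma::fmat cols1, cols2;   // im2col matrices, reused by the backward pass
};

static arma::fmat im2col_f(const arma::fcube& input, int k) {
  int Ho = input.n_rows - k + 1, Wo = input.n_cols - k + 1, C = input.n_slices;
  arma::fmat out(Ho * Wo, k * k * C);
  int col = 0;
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        arma::fmat patch = input.slice(c).submat(di, dj, di + Ho - 1,
                                                 dj + Wo - 1);
        out.col(col++) = arma::vectorise(patch);
      }
  return out;
}

// Forward: conv(k x k, F)+ReLU, conv+ReLU, kp x kp max-pool, flatten,
// dense+ReLU; windows is (H, W, T). Returns feats (U x T) and, when keep,
// an external pointer to the activation cache for the backward pass.
// [[Rcpp::export(name = ".td_fw")]]
List td_fw(const arma::cube& windows, const arma::mat& W1, const arma::vec& b1,
           const arma::mat& W2, const arma::vec& b2, const arma::mat& Wd,
           const arma::vec& bd, int k, int kp, bool keep) {
  int T = windows.n_slices, F = W1.n_cols;
  int H1 = windows.n_rows - k + 1, Wd1 = windows.n_cols - k + 1;
  int H2 = H1 - k + 1, Wd2 = Wd1 - k + 1;
  int Hp = H2 / kp, Wp = Wd2 / kp;
  int flat = Hp * Wp * F;
  arma::fmat W1f = arma::conv_to<arma::fmat>::from(W1);
  arma::fvec b1f = arma::conv_to<arma::fvec>::from(b1);
  arma::fmat W2f = arma::conv_to<arma::fmat>::from(W2);
  arma::fvec b2f = arma::conv_to<arma::fvec>::from(b2);
  arma::fmat Wdf = arma::conv_to<arma::fmat>::from(Wd);
  arma::fvec bdf = arma::conv_to<arma::fvec>::from(bd);

  TDCache* cc = new TDCache();
  cc->wf = arma::conv_to<arma::fcube>::from(windows);
  cc->r1.set_size(H1, Wd1, F * T);
  cc->r2.set_size(H2, Wd2, F * T);
  cc->idx.set_size(Hp, Wp, F * T);
  cc->fl.set_size(flat, T);

  // conv1 over all T windows in one GEMM
  cc->cols1.set_size(T * H1 * Wd1, k * k);
  for (int t = 0; t < T; ++t) {
    arma::fcube xin(const_cast<float*>(cc->wf.slice_memptr(t)),
                    cc->wf.n_rows, cc->wf.n_cols, 1, false, true);
    cc->cols1.rows(t * H1 * Wd1, (t + 1) * H1 * Wd1 - 1) = im2col_f(xin, k);
  }
  arma::fmat c1 = cc->cols1 * W1f;
  c1.each_row() += b1f.t();
  c1.transform([](float v) { return v > 0 ? v : 0.0f; });
  for (int t = 0; t < T; ++t)
    for (int c = 0; c < F; ++c)
      cc->r1.slice(t * F + c) = arma::reshape(
        c1.col(c).subvec(t * H1 * Wd1, (t + 1) * H1 * Wd1 - 1), H1, Wd1);

  // conv2 over all T windows in one GEMM
  cc->cols2.set_size(T * H2 * Wd2, k * k * F);
  for (int t = 0; t < T; ++t)
    cc->cols2.rows(t * H2 * Wd2, (t + 1) * H2 * Wd2 - 1) =
      im2col_f(cc->r1.slices(t * F, t * F + F - 1), k);
  arma::fmat c2 = cc->cols2 * W2f;
  c2.each_row() += b2f.t();
  c2.transform([](float v) { return v > 0 ? v : 0.0f; });
  for (int t = 0; t < T; ++t) {
    for (int c = 0; c < F; ++c)
      cc->r2.slice(t * F + c) = arma::reshape(
        c2.col(c).subvec(t * H2 * Wd2, (t + 1) * H2 * Wd2 - 1), H2, Wd2);
    // max pool
    for (int c = 0; c < F; ++c) {
      const arma::fmat& sl = cc->r2.slice(t * F + c);
      for (int j = 0; j < Wp; ++j)
        for (int i = 0; i < Hp; ++i) {
          float best = -arma::datum::inf; unsigned bi = 0;
          for (int dj = 0; dj < kp; ++dj)
            for (int di = 0; di < kp; ++di) {
              int r = i * kp + di, s = j * kp + dj;
              float v = sl(r, s);
              if (v > best) { best = v; bi = r + s * H2; }
            }
          cc->fl(c * Hp * Wp + j * Hp + i, t) = best;
          cc->idx(i, j, t * F + c) = bi;
        }
    }
  }
  cc->ad = Wdf.t() * cc->fl;
  cc->ad.each_col() += bdf;
  arma::fmat feats = cc->ad;
  feats.transform([](float v) { return v > 0 ? v : 0.0f; });
  arma::mat feats_d = arma::conv_to<arma::mat>::from(feats);
  if (!keep) {
    delete cc;
    return List::create(_["feats"] = feats_d);
  }
  XPtr<TDCache> ptr(cc, true);
  return List::create(_["feats"] = feats_d, _["cache"] = ptr);
}

// Backward of the fused block; dfeats is (U, T). Input gradient not needed.
// The cache is consumed: it is freed on exit (training calls backward
// exactly once per kept forward).
// [[Rcpp::export(name = ".td_bw")]]
List td_bw(SEXP cache_, const arma::mat& W1, const arma::mat& W2,
           const arma::mat& Wd, const arma::mat& dfeats, int k, int kp) {
  if (R_ExternalPtrAddr(cache_) == nullptr)
    stop("activation cache already consumed");
  XPtr<TDCache> cc(cache_);
  int F = W1.n_cols;
  int H1 = cc->r1.n_rows, Wd1 = cc->r1.n_cols;
  int H2 = cc->r2.n_rows, Wd2 = cc->r2.n_cols;
  int T = cc->wf.n_slices;
  int Hp = H2 / kp, Wp = Wd2 / kp;
  arma::fmat W2f = arma::conv_to<arma::fmat>::from(W2);
  arma::fmat Wdf = arma::conv_to<arma::fmat>::from(Wd);
  arma::fmat drd = arma::conv_to<arma::fmat>::from(dfeats);
  for (arma::uword u = 0; u < drd.n_elem; ++u)
    if (cc->ad(u) <= 0) drd(u) = 0;
  arma::fmat gWd = cc->fl * drd.t();
  arma::fvec gbd = arma::sum(drd, 1);
  arma::fmat dfl = Wdf * drd;                  // flat x T

  // unpool + conv2 ReLU mask, stacked over T
  arma::fmat g2(T * H2 * Wd2, F, arma::fill::zeros);
  for (int t = 0; t < T; ++t)
    for (int c = 0; c < F; ++c) {
      const arma::fmat& r2t = cc->r2.slice(t * F + c);
      for (int j = 0; j < Wp; ++j)
        for (int i = 0; i < Hp; ++i) {
          unsigned u = cc->idx(i, j, t * F + c);
          if (r2t(u) > 0)
            g2(t * H2 * Wd2 + u, c) += dfl(c * Hp * Wp + j * Hp + i, t);
        }
    }
  arma::fmat gW2 = cc->cols2.t() * g2;
  arma::fvec gb2 = arma::sum(g2, 0).t();
  arma::fmat gcols = g2 * W2f.t();             // (T*H2*Wd2) x (k*k*F)

  arma::fmat g1(T * H1 * Wd1, F, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    arma::fcube dr1(H1, Wd1, F, arma::fill::zeros);
    int col = 0;
    for (int c = 0; c < F; ++c)
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di) {
          arma::fmat patch(gcols.colptr(col) + t * H2 * Wd2, H2, Wd2,
                           false, true);
          dr1.slice(c).submat(di, dj, di + H2 - 1, dj + Wd2 - 1) += patch;
          ++col;
        }
    for (int c = 0; c < F; ++c) {
      const arma::fmat& r1t = cc->r1.slice(t * F + c);
      arma::fmat ds = dr1.slice(c);
      for (arma::uword u = 0; u < ds.n_elem; ++u)
        if (r1t(u) <= 0) ds(u) = 0;
      g1.col(c).subvec(t * H1 * Wd1, (t + 1) * H1 * Wd1 - 1) =
        arma::vectorise(ds);
    }
  }
  arma::fmat gW1 = cc->cols1.t() * g1;
  arma::fvec gb1 = arma::sum(g1, 0).t();
  delete (TDCache*) R_ExternalPtrAddr(cache_);   // consume the cache
  R_ClearExternalPtr(cache_);
  return List::create(
      _["gW1"] = arma::conv_to<arma::mat>::from(gW1),
      _["gb1"] = arma::conv_to<arma::vec>::from(gb1),
      _["gW2"] = arma::conv_to<arma::mat>::from(gW2),
      _["gb2"] = arma::conv_to<arma::vec>::from(gb2),
      _["gWd"] = arma::conv_to<arma::mat>::from(gWd),
      _["gbd"] = arma::conv_to<arma::vec>::from(gbd));
}
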