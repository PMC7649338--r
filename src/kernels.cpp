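// Numerical kernels for the stacked U-Net layers and post-processing.
// Layout convention matches R arrays: H x W x C, column-major, pixel
// linear index p = i + j*H (0-based). Convolutions are stride-1 with
// zero "same" padding; weights are flattened to Cout x (Cin*k*k) with
// row index r = c*k*k + dj*k + di.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, pad = (k - 1) / 2;
  arma::mat M(C * k * k, H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xs = x.slice(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = c * k * k + dj * k + di;
        const int i0 = std::max(0, pad - di), i1 = std::min(H, H + pad - di);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = i0; i < i1; ++i)
            M(r, i + j * H) = xs(i + di - pad, sj);
        }
      }
    }
  }
  return M;
}

static arma::cube col2im(const arma::mat& M, const int H, const int W,
                         const int C, const int k) {
  const int pad = (k - 1) / 2;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& xs = dx.slice(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = c * k * k + dj * k + di;
        const int i0 = std::max(0, pad - di), i1 = std::min(H, H + pad - di);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = i0; i < i1; ++i)
            xs(i + di - pad, sj) += M(r, i + j * H);
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, const int k) {
  const int H = x.n_rows, Wd = x.n_cols, Cout = W.n_rows;
  arma::mat M = im2col(x, k);
  arma::mat y = W * M;
  y.each_col() += b;
  arma::cube out(H, Wd, Cout);
  for (int co = 0; co < Cout; ++co)
    out.slice(co) = arma::reshape(y.row(co), H, Wd);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& W,
                    const arma::cube& dy, const int k) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices, Cout = dy.n_slices;
  arma::mat dym(Cout, H * Wd);
  for (int co = 0; co < Cout; ++co)
    dym.row(co) = arma::vectorise(dy.slice(co)).t();
  arma::mat M = im2col(x, k);
  arma::mat dW = dym * M.t();
  arma::vec db = arma::sum(dym, 1);
  arma::mat dM = W.t() * dym;
  arma::cube dx = col2im(dM, H, Wd, C, k);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling, stride 2; H and W must be even. idx stores the
// within-window argmax as di + 2*dj (first maximum wins, fixed scan order).
// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xs = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = xs(2 * i, 2 * j);
        unsigned int bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double v = xs(2 * i + di, 2 * j + dj);
            if (v > best) { best = v; bi = di + 2 * dj; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& dy, const arma::ucube& idx) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  arma::cube dx(2 * Ho, 2 * Wo, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const unsigned int b = idx(i, j, c);
        dx(2 * i + (b % 2), 2 * j + (b / 2), c) += dy(i, j, c);
      }
  return dx;
}

// Transposed convolution, 2x2 kernel, stride 2 (exact upsampling by 2).
// W is Cin x (4*Cout) with column index co*4 + dj*2 + di.
// [[Rcpp::export]]
arma::cube cpp_deconv2_fwd(const arma::cube& x, const arma::mat& W,
                           const arma::vec& b) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols / 4, P = H * Wd;
  arma::mat X(P, Cin);
  for (int c = 0; c < Cin; ++c) X.col(c) = arma::vectorise(x.slice(c));
  arma::mat Y = X * W;  // P x 4Cout
  arma::cube y(2 * H, 2 * Wd, Cout);
  for (int co = 0; co < Cout; ++co) {
    arma::mat& ys = y.slice(co);
    ys.fill(b(co));
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        const arma::vec col = Y.col(co * 4 + dj * 2 + di);
        for (int j = 0; j < Wd; ++j)
          for (int i = 0; i < H; ++i)
            ys(2 * i + di, 2 * j + dj) += col(i + j * H);
      }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_deconv2_bwd(const arma::cube& x, const arma::mat& W,
                     const arma::cube& dy) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices, P = H * Wd;
  arma::mat G(P, 4 * Cout);
  arma::vec db(Cout);
  for (int co = 0; co < Cout; ++co) {
    const arma::mat& ds = dy.slice(co);
    db(co) = arma::accu(ds);
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        arma::vec col(P);
        for (int j = 0; j < Wd; ++j)
          for (int i = 0; i < H; ++i)
            col(i + j * H) = ds(2 * i + di, 2 * j + dj);
        G.col(co * 4 + dj * 2 + di) = col;
      }
  }
  arma::mat X(P, Cin);
  for (int c = 0; c < Cin; ++c) X.col(c) = arma::vectorise(x.slice(c));
  arma::mat dW = X.t() * G;
  arma::mat dXm = G * W.t();
  arma::cube dx(H, Wd, Cin);
  for (int c = 0; c < Cin; ++c)
    dx.slice(c) = arma::reshape(dXm.col(c), H, Wd);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Bilinear resize with the half-pixel (pixel-center aligned) convention.
static inline void src_coords(const int io, const int Ho, const int Hi,
                              int& lo, int& hi, double& w) {
  double s = (io + 0.5) * (double)Hi / (double)Ho - 0.5;
  if (s < 0) s = 0;
  if (s > Hi - 1) s = Hi - 1;
  lo = (int)std::floor(s);
  hi = std::min(lo + 1, Hi - 1);
  w = s - lo;
}

// [[Rcpp::export]]
arma::cube cpp_resize_bilinear(const arma::cube& x, const int Ho,
                               const int Wo) {
  const int Hi = x.n_rows, Wi = x.n_cols, C = x.n_slices;
  arma::cube y(Ho, Wo, C);
  std::vector<int> ilo(Ho), ihi(Ho), jlo(Wo), jhi(Wo);
  std::vector<double> iw(Ho), jw(Wo);
  for (int i = 0; i < Ho; ++i) src_coords(i, Ho, Hi, ilo[i], ihi[i], iw[i]);
  for (int j = 0; j < Wo; ++j) src_coords(j, Wo, Wi, jlo[j], jhi[j], jw[j]);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xs = x.slice(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const double a = xs(ilo[i], jlo[j]) * (1 - iw[i]) + xs(ihi[i], jlo[j]) * iw[i];
        const double b = xs(ilo[i], jhi[j]) * (1 - iw[i]) + xs(ihi[i], jhi[j]) * iw[i];
        y(i, j, c) = a * (1 - jw[j]) + b * jw[j];
      }
  }
  return y;
}

// Adjoint of cpp_resize_bilinear: scatter-add dy (Ho x Wo) back to Hi x Wi.
// [[Rcpp::export]]
arma::cube cpp_resize_bilinear_bwd(const arma::cube& dy, const int Hi,
                                   const int Wi) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  arma::cube dx(Hi, Wi, C, arma::fill::zeros);
  std::vector<int> ilo(Ho), ihi(Ho), jlo(Wo), jhi(Wo);
  std::vector<double> iw(Ho), jw(Wo);
  for (int i = 0; i < Ho; ++i) src_coords(i, Ho, Hi, ilo[i], ihi[i], iw[i]);
  for (int j = 0; j < Wo; ++j) src_coords(j, Wo, Wi, jlo[j], jhi[j], jw[j]);
  for (int c = 0; c < C; ++c) {
    arma::mat& xs = dx.slice(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const double g = dy(i, j, c);
        xs(ilo[i], jlo[j]) += g * (1 - iw[i]) * (1 - jw[j]);
        xs(ihi[i], jlo[j]) += g * iw[i] * (1 - jw[j]);
        xs(ilo[i], jhi[j]) += g * (1 - iw[i]) * jw[j];
        xs(ihi[i], jhi[j]) += g * iw[i] * jw[j];
      }
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube cpp_resize_nearest(const arma::cube& x, const int Ho,
                              const int Wo) {
  const int Hi = x.n_rows, Wi = x.n_cols, C = x.n_slices;
  arma::cube y(Ho, Wo, C);
  std::vector<int> si(Ho), sj(Wo);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) * (double)Hi / (double)Ho - 0.5;
    si[i] = std::min(Hi - 1, std::max(0, (int)std::lround(s)));
  }
  for (int j = 0; j < Wo; ++j) {
    double s = (j + 0.5) * (double)Wi / (double)Wo - 0.5;
    sj[j] = std::min(Wi - 1, std::max(0, (int)std::lround(s)));
  }
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        y(i, j, c) = x(si[i], sj[j], c);
  return y;
}

// 8-connected component labeling, labels assigned in column-major scan order.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * H);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int ni = pi + di, nj = pj + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back(ni + nj * H);
            }
          }
      }
    }
  return lab;
}

// Marker-based watershed by priority flood: grow labels outward from the
// markers in order of decreasing distance-transform value, restricted to the
// mask. Deterministic: ties broken by lower linear pixel index.
// [[Rcpp::export]]
IntegerMatrix cpp_marker_watershed(const NumericMatrix& dist,
                                   const IntegerMatrix& markers,
                                   const IntegerMatrix& mask) {
  const int H = dist.nrow(), W = dist.ncol();
  IntegerMatrix lab(H, W);
  typedef std::pair<double, int> Node;  // (priority, linear index)
  struct Cmp {
    bool operator()(const Node& a, const Node& b) const {
      if (a.first != b.first) return a.first < b.first;  // max-heap on dist
      return a.second > b.second;                        // min on index
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (markers(i, j) != 0 && mask(i, j) != 0) {
        lab(i, j) = markers(i, j);
        pq.push(Node(dist(i, j), i + j * H));
      }
  while (!pq.empty()) {
    const int p = pq.top().second;
    pq.pop();
    const int pi = p % H, pj = p / H, l = lab(pi, pj);
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0) continue;
        const int ni = pi + di, nj = pj + dj;
        if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
        if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
          lab(ni, nj) = l;
          pq.push(Node(dist(ni, nj), ni + nj * H));
        }
      }
  }
  return lab;
}

// Separable square max filter (radius r), used for local-peak detection.
// [[Rcpp::export]]
NumericMatrix cpp_maxfilter(const NumericMatrix& x, const int r) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double m = x(i, j);
      for (int d = -r; d <= r; ++d) {
        const int ii = i + d;
        if (ii >= 0 && ii < H && x(ii, j) > m) m = x(ii, j);
      }
      tmp(i, j) = m;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double m = tmp(i, j);
      for (int d = -r; d <= r; ++d) {
        const int jj = j + d;
        if (jj >= 0 && jj < W && tmp(i, jj) > m) m = tmp(i, jj);
      }
      out(i, j) = m;
    }
  return out;
}
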