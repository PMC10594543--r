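// Numeric kernels: ZNCC template matching, connected-component labeling,
// and the convolution/pooling primitives behind the segmentation network.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>
using namespace Rcpp;

// Zero-mean normalized cross-correlation of `templ` against every valid
// position of `frame`, exhaustive integer search. Returns the 0-based (x, y)
// of the best match; ties broken by smallest (y, x) in lexicographic order
// (scan order is y outer, x inner, strict improvement required to move).
// [[Rcpp::export]]
List cpp_zncc_best_match(const arma::mat& frame, const arma::mat& templ) {
  const int fh = frame.n_rows, fw = frame.n_cols;
  const int th = templ.n_rows, tw = templ.n_cols;
  if (th > fh || tw > fw) stop("template larger than frame");
  const double n = (double)th * tw;
  arma::mat t0 = templ - arma::accu(templ) / n;
  const double tnorm = std::sqrt(arma::accu(t0 % t0));
  if (tnorm <= 0) stop("untextured template");

  // integral images for window sums / sums of squares
  arma::mat I1 = arma::cumsum(arma::cumsum(frame, 0), 1);
  arma::mat I2 = arma::cumsum(arma::cumsum(frame % frame, 0), 1);
  auto boxsum = [&](const arma::mat& I, int y, int x) {
    double s = I(y + th - 1, x + tw - 1);
    if (y > 0) s -= I(y - 1, x + tw - 1);
    if (x > 0) s -= I(y + th - 1, x - 1);
    if (y > 0 && x > 0) s += I(y - 1, x - 1);
    return s;
  };

  double best = -2.0;
  int bx = 0, by = 0;
  for (int y = 0; y + th <= fh; ++y) {
    for (int x = 0; x + tw <= fw; ++x) {
      double s1 = boxsum(I1, y, x), s2 = boxsum(I2, y, x);
      double var = s2 - s1 * s1 / n;
      if (var <= 1e-12) continue;  // flat window cannot beat any match
      double num = arma::accu(frame.submat(y, x, y + th - 1, x + tw - 1) % t0);
      double score = num / (std::sqrt(var) * tnorm);
      if (score > best) { best = score; bx = x; by = y; }
    }
  }
  if (best <= -2.0) stop("untextured frame: no valid match position");
  return List::create(_["x"] = bx, _["y"] = by, _["score"] = best);
}

// Connected-component labeling of a 0/255 mask, BFS from the first
// unlabeled foreground pixel in raster-scan (row-major) order, so labels
// are deterministic and contiguous from 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label_cc(const IntegerMatrix& mask, int connectivity) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  const int dy4[] = {-1, 1, 0, 0}, dx4[] = {0, 0, -1, 1};
  const int dy8[] = {-1, -1, -1, 0, 0, 1, 1, 1},
            dx8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int* dy = connectivity == 8 ? dy8 : dy4;
  const int* dx = connectivity == 8 ? dx8 : dx4;
  const int nn = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int,int> > q;
  for (int i = 0; i < h; ++i) {     // raster scan: rows outer
    for (int j = 0; j < w; ++j) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop();
        for (int k = 0; k < nn; ++k) {
          int ii = p.first + dy[k], jj = p.second + dx[k];
          if (ii < 0 || jj < 0 || ii >= h || jj >= w) continue;
          if (mask(ii, jj) != 0 && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}

// "Same"-padded k x k convolution via im2col + GEMM. x is H x W x Cin,
// W_mat is Cout x (k*k*Cin) with kernel index order (ki, kj, c) fastest
// first. Returns the output cube and the im2col matrix for backprop.
// [[Rcpp::export]]
List cpp_conv2d_forward(const arma::cube& x, const arma::mat& W_mat,
                        const arma::vec& b, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = k / 2, cout = W_mat.n_rows;
  arma::mat xcol(k * k * C, (size_t)H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int r = c * k * k + kj * k + ki;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + ki - pad;
            if (si < 0 || si >= H) continue;
            xcol(r, (size_t)j * H + i) = x(si, sj, c);
          }
        }
      }
  arma::mat y = W_mat * xcol;
  y.each_col() += b;
  arma::cube yc(H, W, cout);
  for (int co = 0; co < cout; ++co)
    yc.slice(co) = arma::reshape(y.row(co), H, W);
  return List::create(_["y"] = yc, _["xcol"] = xcol);
}

// Gradient of the convolution above. dy is H x W x Cout.
// [[Rcpp::export]]
List cpp_conv2d_backward(const arma::cube& dy, const arma::mat& W_mat,
                         const arma::mat& xcol, int k, int cin) {
  const int H = dy.n_rows, W = dy.n_cols, cout = dy.n_slices;
  const int pad = k / 2;
  arma::mat dymat(cout, (size_t)H * W);
  for (int co = 0; co < cout; ++co)
    dymat.row(co) = arma::vectorise(dy.slice(co)).t();
  arma::mat dW = dymat * xcol.t();
  arma::vec db = arma::sum(dymat, 1);
  arma::mat dxcol = W_mat.t() * dymat;
  arma::cube dx(H, W, cin, arma::fill::zeros);
  for (int c = 0; c < cin; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int r = c * k * k + kj * k + ki;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + ki - pad;
            if (si < 0 || si >= H) continue;
            dx(si, sj, c) += dxcol(r, (size_t)j * H + i);
          }
        }
      }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling, stride 2; H and W must be even. Returns pooled cube and
// the within-block argmax (0..3, column-major within the block) for backprop.
// [[Rcpp::export]]
List cpp_maxpool2_forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) stop("maxpool2 needs even dimensions");
  arma::cube y(H / 2, W / 2, C);
  arma::icube idx(H / 2, W / 2, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W / 2; ++j)
      for (int i = 0; i < H / 2; ++i) {
        double best = x(2 * i, 2 * j, c);
        int bk = 0;
        for (int k = 1; k < 4; ++k) {
          double v = x(2 * i + k % 2, 2 * j + k / 2, c);
          if (v > best) { best = v; bk = k; }
        }
        y(i, j, c) = best;
        idx(i, j, c) = bk;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_backward(const arma::cube& dy, const arma::icube& idx) {
  const int h = dy.n_rows, w = dy.n_cols, C = dy.n_slices;
  arma::cube dx(2 * h, 2 * w, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        int k = idx(i, j, c);
        dx(2 * i + k % 2, 2 * j + k / 2, c) += dy(i, j, c);
      }
  return dx;
}
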