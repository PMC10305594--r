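// Numerical kernels for the DRU-Net segmentation pipeline.
//
// Feature tensors are stored channel-fastest: an R numeric array with
// dim = c(C, X, Y, Z) in column-major order. Convolutions are computed by
// unrolling local neighbourhoods into a column matrix (vol2col) and calling
// BLAS gemm through Armadillo; backward passes rebuild the column matrix
// instead of caching it, trading FLOPs for memory. Batch size is always 1
// (whole patches), matching the training protocol.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline size_t vox_index(int C, int X, int Y, int i, int j, int k) {
  return (size_t)C * ((size_t)i + (size_t)X * ((size_t)j + (size_t)Y * (size_t)k));
}

// Unroll 3x3x3 neighbourhoods (zero padding 1) for output slices [z0, z1).
// col has 27*C rows; row index = offset * C + channel with offsets ordered
// dz-major, dx fastest, each offset in {-1,0,1} mapped from 0..2.
template <typename eT>
static void vol2col_slab(const eT* x, int C, int X, int Y, int Z,
                         int z0, int z1, arma::Mat<eT>& col) {
  size_t vcol = 0;
  for (int k = z0; k < z1; ++k) {
    for (int j = 0; j < Y; ++j) {
      for (int i = 0; i < X; ++i, ++vcol) {
        eT* cptr = col.colptr(vcol);
        int o = 0;
        for (int dz = -1; dz <= 1; ++dz) {
          const int sk = k + dz;
          for (int dy = -1; dy <= 1; ++dy) {
            const int sj = j + dy;
            for (int dx = -1; dx <= 1; ++dx, ++o) {
              const int si = i + dx;
              eT* dst = cptr + (size_t)o * C;
              if (si < 0 || si >= X || sj < 0 || sj >= Y || sk < 0 || sk >= Z) {
                std::fill(dst, dst + C, (eT)0);
              } else {
                const eT* src = x + vox_index(C, X, Y, si, sj, sk);
                std::copy(src, src + C, dst);
              }
            }
          }
        }
      }
    }
  }
}

// Accumulate a column-matrix gradient back onto the source grid (adjoint of
// vol2col_slab).
template <typename eT>
static void col2vol_slab_add(const arma::Mat<eT>& gcol, eT* gx,
                             int C, int X, int Y, int Z, int z0, int z1) {
  size_t vcol = 0;
  for (int k = z0; k < z1; ++k) {
    for (int j = 0; j < Y; ++j) {
      for (int i = 0; i < X; ++i, ++vcol) {
        const eT* cptr = gcol.colptr(vcol);
        int o = 0;
        for (int dz = -1; dz <= 1; ++dz) {
          const int sk = k + dz;
          for (int dy = -1; dy <= 1; ++dy) {
            const int sj = j + dy;
            for (int dx = -1; dx <= 1; ++dx, ++o) {
              const int si = i + dx;
              if (si < 0 || si >= X || sj < 0 || sj >= Y || sk < 0 || sk >= Z)
                continue;
              eT* dst = gx + vox_index(C, X, Y, si, sj, sk);
              const eT* src = cptr + (size_t)o * C;
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
          }
        }
      }
    }
  }
}

static int slab_size(int C, int X, int Y, size_t elem) {
  // keep the unrolled column matrix below ~128 MiB
  size_t bytes_per_z = (size_t)27 * C * X * Y * elem;
  int zs = (int)((size_t)134217728 / std::max<size_t>(bytes_per_z, 1));
  return std::max(1, zs);
}

template <typename eT>
static arma::Mat<eT> as_eT(const double* p, int nr, int nc) {
  arma::Mat<eT> m(nr, nc);
  const size_t n = (size_t)nr * nc;
  for (size_t i = 0; i < n; ++i) m.memptr()[i] = (eT)p[i];
  return m;
}

template <typename eT>
static void conv3d_fwd_impl(const double* x, int C, int X, int Y, int Z,
                            const double* W, int Co, double* out) {
  arma::Mat<eT> Wm = as_eT<eT>(W, Co, 27 * C);
  arma::Mat<eT> xc = as_eT<eT>(x, C, (int)((size_t)X * Y * Z));
  const int zslab = slab_size(C, X, Y, sizeof(eT));
  arma::Mat<eT> col, outm;
  for (int z0 = 0; z0 < Z; z0 += zslab) {
    const int z1 = std::min(Z, z0 + zslab);
    const size_t V = (size_t)X * Y * (z1 - z0);
    col.set_size(27 * C, V);
    vol2col_slab<eT>(xc.memptr(), C, X, Y, Z, z0, z1, col);
    outm = Wm * col;
    double* op = out + (size_t)Co * X * Y * z0;
    const size_t n = (size_t)Co * V;
    for (size_t i = 0; i < n; ++i) op[i] = (double)outm.memptr()[i];
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, IntegerVector dims,
                             NumericMatrix W, bool single = false) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int Co = W.nrow();
  if (W.ncol() != 27 * C) stop("conv3d: weight has %d columns, expected %d", W.ncol(), 27 * C);
  NumericVector out((size_t)Co * X * Y * Z);
  if (single)
    conv3d_fwd_impl<float>(x.begin(), C, X, Y, Z, W.begin(), Co, out.begin());
  else
    conv3d_fwd_impl<double>(x.begin(), C, X, Y, Z, W.begin(), Co, out.begin());
  out.attr("dim") = IntegerVector::create(Co, X, Y, Z);
  return out;
}

template <typename eT>
static void conv3d_bwd_impl(const double* x, int C, int X, int Y, int Z,
                            const double* W, int Co, const double* gout,
                            double* gx, double* gW) {
  arma::Mat<eT> Wm = as_eT<eT>(W, Co, 27 * C);
  arma::Mat<eT> xc = as_eT<eT>(x, C, (int)((size_t)X * Y * Z));
  arma::Mat<eT> gWm(Co, 27 * C, arma::fill::zeros);
  arma::Col<eT> gxv((size_t)C * X * Y * Z, arma::fill::zeros);
  const int zslab = slab_size(C, X, Y, sizeof(eT));
  arma::Mat<eT> col, gcol;
  for (int z0 = 0; z0 < Z; z0 += zslab) {
    const int z1 = std::min(Z, z0 + zslab);
    const size_t V = (size_t)X * Y * (z1 - z0);
    col.set_size(27 * C, V);
    vol2col_slab<eT>(xc.memptr(), C, X, Y, Z, z0, z1, col);
    arma::Mat<eT> goutm = as_eT<eT>(gout + (size_t)Co * X * Y * z0, Co, (int)V);
    gWm += goutm * col.t();
    gcol = Wm.t() * goutm;
    col2vol_slab_add<eT>(gcol, gxv.memptr(), C, X, Y, Z, z0, z1);
  }
  for (size_t i = 0; i < (size_t)Co * 27 * C; ++i) gW[i] = (double)gWm.memptr()[i];
  for (size_t i = 0; i < gxv.n_elem; ++i) gx[i] = (double)gxv.memptr()[i];
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, IntegerVector dims, NumericMatrix W,
                    NumericVector gout, bool single = false) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int Co = W.nrow();
  NumericVector gx(x.size());
  NumericMatrix gW(Co, 27 * C);
  if (single)
    conv3d_bwd_impl<float>(x.begin(), C, X, Y, Z, W.begin(), Co, gout.begin(),
                           gx.begin(), gW.begin());
  else
    conv3d_bwd_impl<double>(x.begin(), C, X, Y, Z, W.begin(), Co, gout.begin(),
                            gx.begin(), gW.begin());
  gx.attr("dim") = dims;
  return List::create(_["gx"] = gx, _["gW"] = gW);
}

// strided 2x2x2 down-convolution (no padding; dims must be even)

static void vol2col_down(const double* x, int C, int X, int Y, int Z, arma::mat& col) {
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  size_t vcol = 0;
  for (int k = 0; k < Zo; ++k)
    for (int j = 0; j < Yo; ++j)
      for (int i = 0; i < Xo; ++i, ++vcol) {
        double* cptr = col.colptr(vcol);
        int o = 0;
        for (int dz = 0; dz <= 1; ++dz)
          for (int dy = 0; dy <= 1; ++dy)
            for (int dx = 0; dx <= 1; ++dx, ++o) {
              const double* src = x + vox_index(C, X, Y, 2 * i + dx, 2 * j + dy, 2 * k + dz);
              std::copy(src, src + C, cptr + (size_t)o * C);
            }
      }
}

// [[Rcpp::export]]
NumericVector convdown_fwd_cpp(NumericVector x, IntegerVector dims, NumericMatrix W) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  if (X % 2 || Y % 2 || Z % 2)
    stop("transition down needs even spatial dims, got %dx%dx%d", X, Y, Z);
  const int Co = W.nrow();
  if (W.ncol() != 8 * C) stop("convdown: weight has %d columns, expected %d", W.ncol(), 8 * C);
  const size_t V = (size_t)(X / 2) * (Y / 2) * (Z / 2);
  arma::mat col(8 * C, V);
  vol2col_down(x.begin(), C, X, Y, Z, col);
  NumericVector out((size_t)Co * V);
  arma::mat Wm(W.begin(), Co, 8 * C, false);
  arma::mat outm(out.begin(), Co, V, false, true);
  outm = Wm * col;
  out.attr("dim") = IntegerVector::create(Co, X / 2, Y / 2, Z / 2);
  return out;
}

// [[Rcpp::export]]
List convdown_bwd_cpp(NumericVector x, IntegerVector dims, NumericMatrix W,
                      NumericVector gout) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int Co = W.nrow();
  const size_t V = (size_t)(X / 2) * (Y / 2) * (Z / 2);
  arma::mat col(8 * C, V);
  vol2col_down(x.begin(), C, X, Y, Z, col);
  arma::mat goutm(gout.begin(), Co, V, false);
  NumericMatrix gW(Co, 8 * C);
  arma::mat gWm(gW.begin(), Co, 8 * C, false);
  gWm = goutm * col.t();
  arma::mat gcol = arma::mat(W.begin(), Co, 8 * C, false).t() * goutm;
  NumericVector gx(x.size());
  // adjoint of vol2col_down: stride 2, kernel 2 -> each input voxel is read once
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  size_t vcol = 0;
  for (int k = 0; k < Zo; ++k)
    for (int j = 0; j < Yo; ++j)
      for (int i = 0; i < Xo; ++i, ++vcol) {
        const double* cptr = gcol.colptr(vcol);
        int o = 0;
        for (int dz = 0; dz <= 1; ++dz)
          for (int dy = 0; dy <= 1; ++dy)
            for (int dx = 0; dx <= 1; ++dx, ++o) {
              double* dst = gx.begin() + vox_index(C, X, Y, 2 * i + dx, 2 * j + dy, 2 * k + dz);
              const double* src = cptr + (size_t)o * C;
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
      }
  gx.attr("dim") = dims;
  return List::create(_["gx"] = gx, _["gW"] = gW);
}

// transposed 2x2x2 stride-2 convolution: W is (8*Co) x Ci; each input voxel
// populates a disjoint 2x2x2 output cell, so no accumulation is needed.

// [[Rcpp::export]]
NumericVector convup_fwd_cpp(NumericVector x, IntegerVector dims, NumericMatrix W) {
  const int Ci = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  if (W.ncol() != Ci) stop("convup: weight has %d columns, expected %d", W.ncol(), Ci);
  if (W.nrow() % 8) stop("convup: weight rows must be a multiple of 8");
  const int Co = W.nrow() / 8;
  const size_t V = (size_t)X * Y * Z;
  arma::mat Xm(x.begin(), Ci, V, false);
  arma::mat Wm(W.begin(), 8 * Co, Ci, false);
  arma::mat tmp = Wm * Xm;  // (8*Co) x V
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector out((size_t)Co * Xo * Yo * Zo);
  size_t v = 0;
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i, ++v) {
        const double* cptr = tmp.colptr(v);
        int o = 0;
        for (int dz = 0; dz <= 1; ++dz)
          for (int dy = 0; dy <= 1; ++dy)
            for (int dx = 0; dx <= 1; ++dx, ++o) {
              double* dst = out.begin() + vox_index(Co, Xo, Yo, 2 * i + dx, 2 * j + dy, 2 * k + dz);
              std::copy(cptr + (size_t)o * Co, cptr + (size_t)(o + 1) * Co, dst);
            }
      }
  out.attr("dim") = IntegerVector::create(Co, Xo, Yo, Zo);
  return out;
}

// [[Rcpp::export]]
List convup_bwd_cpp(NumericVector x, IntegerVector dims, NumericMatrix W,
                    NumericVector gout) {
  const int Ci = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int Co = W.nrow() / 8;
  const size_t V = (size_t)X * Y * Z;
  const int Xo = 2 * X, Yo = 2 * Y;
  arma::mat gtmp(8 * Co, V);
  size_t v = 0;
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i, ++v) {
        double* cptr = gtmp.colptr(v);
        int o = 0;
        for (int dz = 0; dz <= 1; ++dz)
          for (int dy = 0; dy <= 1; ++dy)
            for (int dx = 0; dx <= 1; ++dx, ++o) {
              const double* src = gout.begin() + vox_index(Co, Xo, Yo, 2 * i + dx, 2 * j + dy, 2 * k + dz);
              std::copy(src, src + Co, cptr + (size_t)o * Co);
            }
      }
  arma::mat Xm(x.begin(), Ci, V, false);
  arma::mat Wm(W.begin(), 8 * Co, Ci, false);
  NumericVector gx(x.size());
  NumericMatrix gW(8 * Co, Ci);
  arma::mat gxm(gx.begin(), Ci, V, false, true);
  arma::mat gWm(gW.begin(), 8 * Co, Ci, false, true);
  gxm = Wm.t() * gtmp;
  gWm = gtmp * Xm.t();
  gx.attr("dim") = dims;
  return List::create(_["gx"] = gx, _["gW"] = gW);
}

// connected-component labelling on a binary grid, 6- or 26-connectivity,
// iterative flood fill

// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dims,
                                   int connectivity) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  const size_t n = (size_t)X * Y * Z;
  IntegerVector labels(n);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || labels[s] != 0) continue;
    ++next;
    labels[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const size_t cur = stack.back();
      stack.pop_back();
      const int i = cur % X, j = (cur / X) % Y, k = cur / ((size_t)X * Y);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
              continue;
            const int ni = i + dx, nj = j + dy, nk = k + dz;
            if (ni < 0 || ni >= X || nj < 0 || nj >= Y || nk < 0 || nk >= Z) continue;
            const size_t nb = (size_t)ni + (size_t)X * (nj + (size_t)Y * nk);
            if (mask[nb] != 0 && labels[nb] == 0) {
              labels[nb] = next;
              stack.push_back(nb);
            }
          }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// in-plane (axial) rotation of every z-slice about the slice centre;
// method 0 = bilinear, 1 = nearest neighbour

// [[Rcpp::export]]
NumericVector rotate_slices_cpp(NumericVector x, IntegerVector dims,
                                double angle_deg, int method, double fill) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const double th = angle_deg * M_PI / 180.0;
  const double ca = std::cos(th), sa = std::sin(th);
  const double cx = (X - 1) / 2.0, cy = (Y - 1) / 2.0;
  NumericVector out((size_t)X * Y * Z);
  for (int k = 0; k < Z; ++k) {
    const double* src = x.begin() + (size_t)X * Y * k;
    double* dst = out.begin() + (size_t)X * Y * k;
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        // pull: source coordinate = inverse rotation of output coordinate
        const double u = i - cx, v = j - cy;
        const double si = ca * u + sa * v + cx;
        const double sj = -sa * u + ca * v + cy;
        double val = fill;
        if (method == 1) {
          const int ri = (int)std::lround(si), rj = (int)std::lround(sj);
          if (ri >= 0 && ri < X && rj >= 0 && rj < Y) val = src[ri + (size_t)X * rj];
        } else {
          const int i0 = (int)std::floor(si), j0 = (int)std::floor(sj);
          if (i0 >= -1 && i0 <= X - 1 && j0 >= -1 && j0 <= Y - 1) {
            const double fi = si - i0, fj = sj - j0;
            double acc = 0.0;
            for (int b = 0; b <= 1; ++b)
              for (int a = 0; a <= 1; ++a) {
                const int ii = i0 + a, jj = j0 + b;
                const double wgt = (a ? fi : 1 - fi) * (b ? fj : 1 - fj);
                const double pix = (ii >= 0 && ii < X && jj >= 0 && jj < Y)
                                       ? src[ii + (size_t)X * jj]
                                       : fill;
                acc += wgt * pix;
              }
            val = acc;
          }
        }
        dst[i + (size_t)X * j] = val;
      }
  }
  out.attr("dim") = dims;
  return out;
}

// for every row of A (points, mm), the distance to the nearest row of B

// [[Rcpp::export]]
NumericVector directed_min_dists_cpp(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
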