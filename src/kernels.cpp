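#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Dense 3D numeric kernels shared by the preprocessing, network and metric code.
// Volumes are column-major R arrays:
//   activations  (X, Y, Z, C)
//   conv weights (k, k, k, Cin, Cout)

static inline int out_dim(int n, int k, int s, int p) { return (n + 2 * p - k) / s + 1; }

// Blocked im2col + BLAS matrix multiply. Column j of the patch matrix holds
// the (kx, ky, kz, ci) tap matching the column-major weight layout
// (k, k, k, Cin, Cout), so y = A * W directly.
static void im2col_block(const double *px, int X, int Y, int Z, int Ci, int K,
                         int stride, int pad, int Xo, int Yo, int zo0, int zb,
                         arma::mat &A) {
  const int Nxy = Xo * Yo;
  for (int ci = 0; ci < Ci; ++ci)
    for (int kz = 0; kz < K; ++kz)
      for (int ky = 0; ky < K; ++ky)
        for (int kx = 0; kx < K; ++kx) {
          const int j = kx + K * (ky + K * (kz + K * ci));
          double *col = A.colptr(j);
          for (int dz = 0; dz < zb; ++dz) {
            const int zi = (zo0 + dz) * stride - pad + kz;
            for (int yo = 0; yo < Yo; ++yo) {
              const int yi = yo * stride - pad + ky;
              double *dst = col + dz * Nxy + yo * Xo;
              if (zi < 0 || zi >= Z || yi < 0 || yi >= Y) {
                std::fill(dst, dst + Xo, 0.0);
                continue;
              }
              const double *row =
                  px + (R_xlen_t)X * (yi + (R_xlen_t)Y * (zi + (R_xlen_t)Z * ci));
              // xo range with in-bounds xi = xo*stride - pad + kx
              const int off = kx - pad;
              int lo = (off >= 0) ? 0 : (-off + stride - 1) / stride;
              int hi = (X - 1 - off) / stride + 1;  // exclusive
              if (hi > Xo) hi = Xo;
              if (lo > hi) lo = hi;
              std::fill(dst, dst + lo, 0.0);
              if (stride == 1) {
                std::copy(row + lo + off, row + hi + off, dst + lo);
              } else {
                for (int xo = lo; xo < hi; ++xo) dst[xo] = row[xo * stride + off];
              }
              std::fill(dst + hi, dst + Xo, 0.0);
            }
          }
        }
}

static int pick_zblock(int Xo, int Yo, int Zo, int KC) {
  const double budget = 8e6; // doubles per patch matrix block
  int zb = (int)(budget / ((double)Xo * Yo * KC));
  if (zb < 1) zb = 1;
  if (zb > Zo) zb = Zo;
  return zb;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  const int K = wd[0], Co = wd[4];
  if (wd[3] != Ci) stop("conv3d: input channels (%d) do not match weights (%d)", Ci, wd[3]);
  const int Xo = out_dim(X, K, stride, pad), Yo = out_dim(Y, K, stride, pad),
            Zo = out_dim(Z, K, stride, pad);
  if (Xo < 1 || Yo < 1 || Zo < 1) stop("conv3d: output would be empty");
  const int KC = K * K * K * Ci;
  NumericVector y((R_xlen_t)Xo * Yo * Zo * Co);
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Co);
  const arma::mat W(const_cast<double *>(w.begin()), KC, Co, false, true);
  const int Nxy = Xo * Yo;
  const int zb_max = pick_zblock(Xo, Yo, Zo, KC);
  static std::vector<double> Abuf;
  if (Abuf.size() < (size_t)Nxy * zb_max * KC) Abuf.resize((size_t)Nxy * zb_max * KC);
  for (int zo0 = 0; zo0 < Zo; zo0 += zb_max) {
    const int zb = std::min(zb_max, Zo - zo0);
    arma::mat Ause(Abuf.data(), Nxy * zb, KC, false, true);
    im2col_block(x.begin(), X, Y, Z, Ci, K, stride, pad, Xo, Yo, zo0, zb, Ause);
    arma::mat Yblk = Ause * W;
    for (int co = 0; co < Co; ++co) {
      double *dst = y.begin() + (R_xlen_t)Nxy * zo0 +
                    (R_xlen_t)Nxy * Zo * co;
      const double *srcp = Yblk.colptr(co);
      const double bias = b[co];
      for (int i = 0; i < Nxy * zb; ++i) dst[i] = srcp[i] + bias;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector gd = gy.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  const int K = wd[0], Co = wd[4];
  const int Xo = gd[0], Yo = gd[1], Zo = gd[2];
  const int KC = K * K * K * Ci;
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Co);
  const arma::mat W(const_cast<double *>(w.begin()), KC, Co, false, true);
  arma::mat GW(gw.begin(), KC, Co, false, true);
  const int Nxy = Xo * Yo;
  const int zb_max = pick_zblock(Xo, Yo, Zo, KC);
  static std::vector<double> Abuf2, GAbuf;
  if (Abuf2.size() < (size_t)Nxy * zb_max * KC) Abuf2.resize((size_t)Nxy * zb_max * KC);
  if (GAbuf.size() < (size_t)Nxy * zb_max * KC) GAbuf.resize((size_t)Nxy * zb_max * KC);
  double *pgx = gx.begin();
  for (int zo0 = 0; zo0 < Zo; zo0 += zb_max) {
    const int zb = std::min(zb_max, Zo - zo0);
    arma::mat Ause(Abuf2.data(), Nxy * zb, KC, false, true);
    im2col_block(x.begin(), X, Y, Z, Ci, K, stride, pad, Xo, Yo, zo0, zb, Ause);
    arma::mat G(Nxy * zb, Co);
    for (int co = 0; co < Co; ++co) {
      const double *srcp = gy.begin() + (R_xlen_t)Nxy * zo0 +
                           (R_xlen_t)Nxy * Zo * co;
      std::copy(srcp, srcp + Nxy * zb, G.colptr(co));
      gb[co] += std::accumulate(srcp, srcp + Nxy * zb, 0.0);
    }
    GW += Ause.t() * G;
    arma::mat GA(GAbuf.data(), Nxy * zb, KC, false, true);
    GA = G * W.t();  // (Nxy*zb) x KC, scatter back (col2im)
    for (int ci = 0; ci < Ci; ++ci)
      for (int kz = 0; kz < K; ++kz)
        for (int ky = 0; ky < K; ++ky)
          for (int kx = 0; kx < K; ++kx) {
            const int j = kx + K * (ky + K * (kz + K * ci));
            const double *col = GA.colptr(j);
            for (int dz = 0; dz < zb; ++dz) {
              const int zi = (zo0 + dz) * stride - pad + kz;
              if (zi < 0 || zi >= Z) continue;
              for (int yo = 0; yo < Yo; ++yo) {
                const int yi = yo * stride - pad + ky;
                if (yi < 0 || yi >= Y) continue;
                const double *srcrow = col + dz * Nxy + yo * Xo;
                double *dstrow =
                    pgx + (R_xlen_t)X * (yi + (R_xlen_t)Y * (zi + (R_xlen_t)Z * ci));
                const int off = kx - pad;
                int lo = (off >= 0) ? 0 : (-off + stride - 1) / stride;
                int hi = (X - 1 - off) / stride + 1;
                if (hi > Xo) hi = Xo;
                if (lo > hi) lo = hi;
                if (stride == 1) {
                  double *d2 = dstrow + off;
                  for (int xo = lo; xo < hi; ++xo) d2[xo] += srcrow[xo];
                } else {
                  for (int xo = lo; xo < hi; ++xo) dstrow[xo * stride + off] += srcrow[xo];
                }
              }
            }
          }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Trilinear / nearest resampling between voxel grids with centre-aligned
// world coordinates: world(i) = (i + 0.5) * spacing.
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector x, NumericVector in_spacing,
                             IntegerVector out_dim, NumericVector out_spacing,
                             int nearest) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2];
  const int Xo = out_dim[0], Yo = out_dim[1], Zo = out_dim[2];
  NumericVector y((R_xlen_t)Xo * Yo * Zo);
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo);
  const double *px = x.begin();
  double *py = y.begin();
  const int dims[3] = {X, Y, Z};
  double u[3];
  for (int zo = 0; zo < Zo; ++zo)
    for (int yo = 0; yo < Yo; ++yo)
      for (int xo = 0; xo < Xo; ++xo) {
        const int idx[3] = {xo, yo, zo};
        for (int a = 0; a < 3; ++a) {
          double w = (idx[a] + 0.5) * out_spacing[a];
          double v = w / in_spacing[a] - 0.5;
          if (v < 0) v = 0;
          if (v > dims[a] - 1) v = dims[a] - 1;
          u[a] = v;
        }
        double val;
        if (nearest) {
          const int i0 = (int)std::floor(u[0] + 0.5), j0 = (int)std::floor(u[1] + 0.5),
                    l0 = (int)std::floor(u[2] + 0.5);
          val = px[i0 + (R_xlen_t)X * (j0 + (R_xlen_t)Y * l0)];
        } else {
          const int i0 = (int)std::floor(u[0]), j0 = (int)std::floor(u[1]), l0 = (int)std::floor(u[2]);
          const int i1 = std::min(i0 + 1, X - 1), j1 = std::min(j0 + 1, Y - 1), l1 = std::min(l0 + 1, Z - 1);
          const double fx = u[0] - i0, fy = u[1] - j0, fz = u[2] - l0;
          double c00 = px[i0 + (R_xlen_t)X * (j0 + (R_xlen_t)Y * l0)] * (1 - fx) +
                       px[i1 + (R_xlen_t)X * (j0 + (R_xlen_t)Y * l0)] * fx;
          double c10 = px[i0 + (R_xlen_t)X * (j1 + (R_xlen_t)Y * l0)] * (1 - fx) +
                       px[i1 + (R_xlen_t)X * (j1 + (R_xlen_t)Y * l0)] * fx;
          double c01 = px[i0 + (R_xlen_t)X * (j0 + (R_xlen_t)Y * l1)] * (1 - fx) +
                       px[i1 + (R_xlen_t)X * (j0 + (R_xlen_t)Y * l1)] * fx;
          double c11 = px[i0 + (R_xlen_t)X * (j1 + (R_xlen_t)Y * l1)] * (1 - fx) +
                       px[i1 + (R_xlen_t)X * (j1 + (R_xlen_t)Y * l1)] * fx;
          val = (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz;
        }
        py[xo + (R_xlen_t)Xo * (yo + (R_xlen_t)Yo * zo)] = val;
      }
  return y;
}

// Connected-component labelling of a binary 3D mask (6/18/26 connectivity).
// Labels are assigned in first-encounter (column-major scan) order, from 1.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, int connectivity) {
  IntegerVector md = mask.attr("dim");
  const int X = md[0], Y = md[1], Z = md[2];
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  std::vector<int> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int order = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (order == 0) continue;
        if (connectivity == 6 && order > 1) continue;
        if (connectivity == 18 && order > 2) continue;
        offs.push_back(dx);
        offs.push_back(dy);
        offs.push_back(dz);
      }
  IntegerVector lab((R_xlen_t)X * Y * Z);
  lab.attr("dim") = md;
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < mask.size(); ++start) {
    if (!mask[start] || lab[start]) continue;
    lab[start] = ++next;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int cx = cur % X, cy = (cur / X) % Y, cz = cur / ((R_xlen_t)X * Y);
      for (size_t o = 0; o < offs.size(); o += 3) {
        const int nx = cx + offs[o], ny = cy + offs[o + 1], nz = cz + offs[o + 2];
        if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z) continue;
        const R_xlen_t ni = nx + (R_xlen_t)X * (ny + (R_xlen_t)Y * nz);
        if (mask[ni] && !lab[ni]) {
          lab[ni] = next;
          stack.push_back(ni);
        }
      }
    }
  }
  return lab;
}

static inline int reflect_idx(int i, int n) {
  // symmetric (edge-inclusive) reflection: -1 -> 0, -2 -> 1, n -> n-1, ...
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable uniform box mean filter with symmetric boundary reflection,
// window (2r+1)^3; used for local SSIM moments.
// [[Rcpp::export]]
NumericVector cpp_box_filter3(NumericVector x, int r) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2];
  const int w = 2 * r + 1;
  NumericVector a = clone(x), b((R_xlen_t)X * Y * Z);
  double *pa = a.begin(), *pb = b.begin();
  // axis 0
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y) {
      const R_xlen_t base = (R_xlen_t)X * (y + (R_xlen_t)Y * z);
      for (int i = 0; i < X; ++i) {
        double s = 0;
        for (int k = -r; k <= r; ++k) s += pa[reflect_idx(i + k, X) + base];
        pb[i + base] = s / w;
      }
    }
  std::swap(pa, pb);
  // axis 1
  for (int z = 0; z < Z; ++z)
    for (int i = 0; i < X; ++i) {
      const R_xlen_t zb = (R_xlen_t)X * (R_xlen_t)Y * z;
      for (int y = 0; y < Y; ++y) {
        double s = 0;
        for (int k = -r; k <= r; ++k) s += pa[i + (R_xlen_t)X * reflect_idx(y + k, Y) + zb];
        pb[i + (R_xlen_t)X * y + zb] = s / w;
      }
    }
  std::swap(pa, pb);
  // axis 2
  for (int y = 0; y < Y; ++y)
    for (int i = 0; i < X; ++i) {
      for (int z = 0; z < Z; ++z) {
        double s = 0;
        for (int k = -r; k <= r; ++k)
          s += pa[i + (R_xlen_t)X * (y + (R_xlen_t)Y * reflect_idx(z + k, Z))];
        pb[i + (R_xlen_t)X * (y + (R_xlen_t)Y * z)] = s / w;
      }
    }
  NumericVector out;
  // after three swaps pa/pb alternate: result is in pb's buffer (pa after swap?)
  // We wrote the final pass into pb; figure out which NumericVector owns it.
  if (pb == b.begin()) out = b; else out = a;
  out.attr("dim") = IntegerVector::create(X, Y, Z);
  return out;
}
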