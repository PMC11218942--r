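// Numerical kernels: 3D convolution (im2col + GEMM), 2x2x2 max-pooling,
// trilinear sampling with gradients, tetrahedral voxelization, nearest
// neighbours, point-to-triangle distances, and containing-tet location.
// Layout conventions follow R column-major arrays:
//   image grids  : dim (D1, D2, D3, C)
//   conv weights : dim (3, 3, 3, Cin, Cout)
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

#if defined(__SSE2__)
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif

// Flush subnormal floats to zero: vanishing gradients in deep backward
// passes otherwise trigger 50-100x slowdowns on x86.
// [[Rcpp::export(name = ".cpp_enable_ftz")]]
void cpp_enable_ftz() {
#if defined(__SSE2__)
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
}

// ---------------------------------------------------------------------------
// Direct 3x3x3 "same" convolution with zero padding, written as 27*Cin*Cout
// shifted axpy passes with stride-1 inner loops (no im2col temporaries --
// cheaper and far more memory-stable than GEMM at these channel counts).

// dst[i,j,k] += w * src[i+ox, j+oy, k+oz] over the valid overlap
static void shifted_axpy(double w, const double* __restrict src,
                         double* __restrict dst,
                         int D1, int D2, int D3, int ox, int oy, int oz) {
  if (w == 0.0) return;
  const int klo = std::max(0, -oz), khi = std::min(D3, D3 - oz);
  const int jlo = std::max(0, -oy), jhi = std::min(D2, D2 - oy);
  const int ilo = std::max(0, -ox), ihi = std::min(D1, D1 - ox);
  for (int k = klo; k < khi; ++k)
    for (int j = jlo; j < jhi; ++j) {
      const double* __restrict s =
        src + ((size_t)((k + oz) * D2 + (j + oy)) * D1 + ox);
      double* __restrict d = dst + ((size_t)(k * D2 + j) * D1);
      for (int i = ilo; i < ihi; ++i) d[i] += w * s[i];
    }
}

// sum over the valid overlap of a[i+ox, j+oy, k+oz] * g[i,j,k]
static double shifted_dot(const double* __restrict a, const double* __restrict g,
                          int D1, int D2, int D3, int ox, int oy, int oz) {
  const int klo = std::max(0, -oz), khi = std::min(D3, D3 - oz);
  const int jlo = std::max(0, -oy), jhi = std::min(D2, D2 - oy);
  const int ilo = std::max(0, -ox), ihi = std::min(D1, D1 - ox);
  double acc = 0.0;
  for (int k = klo; k < khi; ++k)
    for (int j = jlo; j < jhi; ++j) {
      const double* __restrict s =
        a + ((size_t)((k + oz) * D2 + (j + oy)) * D1 + ox);
      const double* __restrict d = g + ((size_t)(k * D2 + j) * D1);
      for (int i = ilo; i < ihi; ++i) acc += s[i] * d[i];
    }
  return acc;
}

static inline size_t widx(int dx, int dy, int dz, int ci, int co, int Cin) {
  return (size_t)dx + 3 * ((size_t)dy + 3 * ((size_t)dz + 3 * ((size_t)ci + (size_t)Cin * co)));
}

// [[Rcpp::export(name = ".cpp_conv3d_forward")]]
NumericVector cpp_conv3d_forward(NumericVector x, NumericVector w, NumericVector b,
                                 IntegerVector dims) {
  const int D1 = dims[0], D2 = dims[1], D3 = dims[2], Cin = dims[3], Cout = dims[4];
  const size_t nvox = (size_t)D1 * D2 * D3;
  NumericVector res(nvox * Cout);
  for (int co = 0; co < Cout; ++co) {
    double* oc = res.begin() + nvox * co;
    std::fill(oc, oc + nvox, b[co]);
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = x.begin() + nvox * ci;
      for (int dz = 0; dz < 3; ++dz)
        for (int dy = 0; dy < 3; ++dy)
          for (int dx = 0; dx < 3; ++dx)
            shifted_axpy(w[widx(dx, dy, dz, ci, co, Cin)], xc, oc,
                         D1, D2, D3, dx - 1, dy - 1, dz - 1);
    }
  }
  res.attr("dim") = IntegerVector::create(D1, D2, D3, Cout);
  return res;
}

// [[Rcpp::export(name = ".cpp_conv3d_backward")]]
List cpp_conv3d_backward(NumericVector x, NumericVector w, NumericVector gout,
                         IntegerVector dims) {
  const int D1 = dims[0], D2 = dims[1], D3 = dims[2], Cin = dims[3], Cout = dims[4];
  const size_t nvox = (size_t)D1 * D2 * D3;
  NumericVector dx(nvox * Cin), dw((size_t)27 * Cin * Cout), db(Cout);
  for (int co = 0; co < Cout; ++co) {
    const double* gc = gout.begin() + nvox * co;
    double acc = 0.0;
    for (size_t t = 0; t < nvox; ++t) acc += gc[t];
    db[co] = acc;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = x.begin() + nvox * ci;
      double* dxc = dx.begin() + nvox * ci;
      for (int dz = 0; dz < 3; ++dz)
        for (int dy = 0; dy < 3; ++dy)
          for (int dx_ = 0; dx_ < 3; ++dx_) {
            const size_t q = widx(dx_, dy, dz, ci, co, Cin);
            dw[q] = shifted_dot(xc, gc, D1, D2, D3, dx_ - 1, dy - 1, dz - 1);
            // dx[p] += w_q * g[p - offset]
            shifted_axpy(w[q], gc, dxc, D1, D2, D3, 1 - dx_, 1 - dy, 1 - dz);
          }
    }
  }
  dx.attr("dim") = IntegerVector::create(D1, D2, D3, Cin);
  dw.attr("dim") = IntegerVector::create(3, 3, 3, Cin, Cout);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 1x1x1 convolution (channel mixing) -- used for residual projections.
// [[Rcpp::export(name = ".cpp_conv1_forward")]]
NumericVector cpp_conv1_forward(NumericVector x, NumericVector w, NumericVector b,
                                IntegerVector dims) {
  const int nvox = dims[0] * dims[1] * dims[2];
  const int Cin = dims[3], Cout = dims[4];
  arma::mat X(const_cast<double*>(x.begin()), nvox, Cin, false, true);
  arma::mat W(const_cast<double*>(w.begin()), Cin, Cout, false, true);
  arma::mat out = X * W;
  out.each_row() += arma::rowvec(const_cast<double*>(b.begin()), Cout, false, true);
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(dims[0], dims[1], dims[2], Cout);
  return res;
}

// [[Rcpp::export(name = ".cpp_maxpool3d_forward")]]
List cpp_maxpool3d_forward(NumericVector x, IntegerVector dims) {
  const int D1 = dims[0], D2 = dims[1], D3 = dims[2], C = dims[3];
  const int O1 = D1 / 2, O2 = D2 / 2, O3 = D3 / 2;
  const size_t nin = (size_t)D1 * D2 * D3;
  NumericVector out((size_t)O1 * O2 * O3 * C);
  IntegerVector arg((size_t)O1 * O2 * O3 * C);
  const double* xp = x.begin();
  size_t o = 0;
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + nin * c;
    for (int k = 0; k < O3; ++k)
      for (int j = 0; j < O2; ++j)
        for (int i = 0; i < O1; ++i, ++o) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bidx = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                size_t idx = (size_t)((2 * k + dk) * D2 + (2 * j + dj)) * D1 + (2 * i + di);
                if (xc[idx] > best) { best = xc[idx]; bidx = idx; }
              }
          out[o] = best;
          arg[o] = (int)(bidx + nin * c);  // 0-based linear index into x
        }
  }
  out.attr("dim") = IntegerVector::create(O1, O2, O3, C);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".cpp_maxpool3d_backward")]]
NumericVector cpp_maxpool3d_backward(NumericVector gout, IntegerVector argmax,
                                     IntegerVector in_dims) {
  size_t n = (size_t)in_dims[0] * in_dims[1] * in_dims[2] * in_dims[3];
  NumericVector dx(n);
  for (R_xlen_t t = 0; t < gout.size(); ++t) dx[argmax[t]] += gout[t];
  dx.attr("dim") = in_dims;
  return dx;
}

// Trilinear sampling of a (D1,D2,D3,C) grid at K continuous 0-based index
// coordinates; out-of-bounds coordinates are clamped to the boundary.
// [[Rcpp::export(name = ".cpp_trilinear_forward")]]
NumericMatrix cpp_trilinear_forward(NumericVector grid, NumericMatrix pts,
                                    IntegerVector dims) {
  const int D1 = dims[0], D2 = dims[1], D3 = dims[2], C = dims[3];
  const size_t nvox = (size_t)D1 * D2 * D3;
  const int K = pts.nrow();
  NumericMatrix out(K, C);
  for (int p = 0; p < K; ++p) {
    double cx = std::min(std::max(pts(p, 0), 0.0), (double)(D1 - 1));
    double cy = std::min(std::max(pts(p, 1), 0.0), (double)(D2 - 1));
    double cz = std::min(std::max(pts(p, 2), 0.0), (double)(D3 - 1));
    int i0 = clampi((int)std::floor(cx), 0, D1 - 2), i1 = i0 + 1;
    int j0 = clampi((int)std::floor(cy), 0, D2 - 2), j1 = j0 + 1;
    int k0 = clampi((int)std::floor(cz), 0, D3 - 2), k1 = k0 + 1;
    if (D1 == 1) { i0 = i1 = 0; } if (D2 == 1) { j0 = j1 = 0; } if (D3 == 1) { k0 = k1 = 0; }
    double fx = cx - i0, fy = cy - j0, fz = cz - k0;
    for (int c = 0; c < C; ++c) {
      const double* g = grid.begin() + nvox * c;
      auto at = [&](int i, int j, int k) { return g[(size_t)(k * D2 + j) * D1 + i]; };
      double v =
        at(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
        at(i1, j0, k0) * fx * (1 - fy) * (1 - fz) +
        at(i0, j1, k0) * (1 - fx) * fy * (1 - fz) +
        at(i1, j1, k0) * fx * fy * (1 - fz) +
        at(i0, j0, k1) * (1 - fx) * (1 - fy) * fz +
        at(i1, j0, k1) * fx * (1 - fy) * fz +
        at(i0, j1, k1) * (1 - fx) * fy * fz +
        at(i1, j1, k1) * fx * fy * fz;
      out(p, c) = v;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_trilinear_backward")]]
List cpp_trilinear_backward(NumericVector grid, NumericMatrix pts,
                            NumericMatrix gout, IntegerVector dims) {
  const int D1 = dims[0], D2 = dims[1], D3 = dims[2], C = dims[3];
  const size_t nvox = (size_t)D1 * D2 * D3;
  const int K = pts.nrow();
  NumericVector dgrid(nvox * C);
  NumericMatrix dpts(K, 3);
  for (int p = 0; p < K; ++p) {
    bool inx = pts(p, 0) > 0.0 && pts(p, 0) < (double)(D1 - 1);
    bool iny = pts(p, 1) > 0.0 && pts(p, 1) < (double)(D2 - 1);
    bool inz = pts(p, 2) > 0.0 && pts(p, 2) < (double)(D3 - 1);
    double cx = std::min(std::max(pts(p, 0), 0.0), (double)(D1 - 1));
    double cy = std::min(std::max(pts(p, 1), 0.0), (double)(D2 - 1));
    double cz = std::min(std::max(pts(p, 2), 0.0), (double)(D3 - 1));
    int i0 = clampi((int)std::floor(cx), 0, D1 - 2), i1 = i0 + 1;
    int j0 = clampi((int)std::floor(cy), 0, D2 - 2), j1 = j0 + 1;
    int k0 = clampi((int)std::floor(cz), 0, D3 - 2), k1 = k0 + 1;
    if (D1 == 1) { i0 = i1 = 0; inx = false; }
    if (D2 == 1) { j0 = j1 = 0; iny = false; }
    if (D3 == 1) { k0 = k1 = 0; inz = false; }
    double fx = cx - i0, fy = cy - j0, fz = cz - k0;
    double wx[2] = {1 - fx, fx}, wy[2] = {1 - fy, fy}, wz[2] = {1 - fz, fz};
    double dwx[2] = {-1.0, 1.0};
    int ii[2] = {i0, i1}, jj[2] = {j0, j1}, kk[2] = {k0, k1};
    for (int c = 0; c < C; ++c) {
      double* dg = dgrid.begin() + nvox * c;
      const double* g = grid.begin() + nvox * c;
      const double go = gout(p, c);
      for (int a = 0; a < 2; ++a)
        for (int b = 0; b < 2; ++b)
          for (int d = 0; d < 2; ++d) {
            size_t idx = (size_t)(kk[d] * D2 + jj[b]) * D1 + ii[a];
            dg[idx] += go * wx[a] * wy[b] * wz[d];
            double gv = g[idx];
            if (inx) dpts(p, 0) += go * gv * dwx[a] * wy[b] * wz[d];
            if (iny) dpts(p, 1) += go * gv * wx[a] * dwx[b] * wz[d];
            if (inz) dpts(p, 2) += go * gv * wx[a] * wy[b] * dwx[d];
          }
    }
  }
  dgrid.attr("dim") = dims;
  return List::create(_["dgrid"] = dgrid, _["dpts"] = dpts);
}

// ---------------------------------------------------------------------------
// Barycentric voxelization: voxel center (0-based index coords) is 1 iff it
// lies inside (or on the boundary of, tol) any tetrahedron.
// nodes are given in continuous index coordinates.
// [[Rcpp::export(name = ".cpp_voxelize_tets")]]
IntegerVector cpp_voxelize_tets(NumericMatrix nodes, IntegerMatrix tets,
                                IntegerVector dims, double tol) {
  const int D1 = dims[0], D2 = dims[1], D3 = dims[2];
  IntegerVector mask((size_t)D1 * D2 * D3);
  const int M = tets.nrow();
  for (int t = 0; t < M; ++t) {
    double vx[4], vy[4], vz[4];
    for (int a = 0; a < 4; ++a) {
      int id = tets(t, a);
      vx[a] = nodes(id, 0); vy[a] = nodes(id, 1); vz[a] = nodes(id, 2);
    }
    int ilo = clampi((int)std::ceil(*std::min_element(vx, vx + 4) - tol), 0, D1 - 1);
    int ihi = clampi((int)std::floor(*std::max_element(vx, vx + 4) + tol), 0, D1 - 1);
    int jlo = clampi((int)std::ceil(*std::min_element(vy, vy + 4) - tol), 0, D2 - 1);
    int jhi = clampi((int)std::floor(*std::max_element(vy, vy + 4) + tol), 0, D2 - 1);
    int klo = clampi((int)std::ceil(*std::min_element(vz, vz + 4) - tol), 0, D3 - 1);
    int khi = clampi((int)std::floor(*std::max_element(vz, vz + 4) + tol), 0, D3 - 1);
    if (ilo > ihi || jlo > jhi || klo > khi) continue;
    // invert the 3x3 edge matrix T = [v1-v0, v2-v0, v3-v0]
    double a11 = vx[1] - vx[0], a12 = vx[2] - vx[0], a13 = vx[3] - vx[0];
    double a21 = vy[1] - vy[0], a22 = vy[2] - vy[0], a23 = vy[3] - vy[0];
    double a31 = vz[1] - vz[0], a32 = vz[2] - vz[0], a33 = vz[3] - vz[0];
    double det = a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
                 a13 * (a21 * a32 - a22 * a31);
    if (std::fabs(det) < 1e-300) continue;  // degenerate tet: zero volume
    double b11 = (a22 * a33 - a23 * a32) / det, b12 = (a13 * a32 - a12 * a33) / det,
           b13 = (a12 * a23 - a13 * a22) / det;
    double b21 = (a23 * a31 - a21 * a33) / det, b22 = (a11 * a33 - a13 * a31) / det,
           b23 = (a13 * a21 - a11 * a23) / det;
    double b31 = (a21 * a32 - a22 * a31) / det, b32 = (a12 * a31 - a11 * a32) / det,
           b33 = (a11 * a22 - a12 * a21) / det;
    for (int k = klo; k <= khi; ++k)
      for (int j = jlo; j <= jhi; ++j)
        for (int i = ilo; i <= ihi; ++i) {
          double px = i - vx[0], py = j - vy[0], pz = k - vz[0];
          double l1 = b11 * px + b12 * py + b13 * pz;
          double l2 = b21 * px + b22 * py + b23 * pz;
          double l3 = b31 * px + b32 * py + b33 * pz;
          double l0 = 1.0 - l1 - l2 - l3;
          if (l0 >= -tol && l1 >= -tol && l2 >= -tol && l3 >= -tol)
            mask[(size_t)(k * D2 + j) * D1 + i] = 1;
        }
  }
  mask.attr("dim") = IntegerVector::create(D1, D2, D3);
  return mask;
}

// nearest row of B for each row of A (1-based indices)
// [[Rcpp::export(name = ".cpp_nn_index")]]
IntegerVector cpp_nn_index(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  IntegerVector idx(n);
  for (int i = 0; i < n; ++i) {
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = std::numeric_limits<double>::infinity();
    int bj = 0;
    for (int j = 0; j < m; ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bj = j; }
    }
    idx[i] = bj + 1;
  }
  return idx;
}

// closest distance from each point to a triangle soup (Ericson's algorithm)
// tri: ntri x 9 matrix, rows = (ax,ay,az, bx,by,bz, cx,cy,cz)
// [[Rcpp::export(name = ".cpp_point_tri_dist")]]
NumericVector cpp_point_tri_dist(NumericMatrix P, NumericMatrix tri) {
  const int n = P.nrow(), m = tri.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double px = P(i, 0), py = P(i, 1), pz = P(i, 2);
    double best = std::numeric_limits<double>::infinity();
    for (int t = 0; t < m; ++t) {
      double ax = tri(t, 0), ay = tri(t, 1), az = tri(t, 2);
      double bx = tri(t, 3), by = tri(t, 4), bz = tri(t, 5);
      double cx = tri(t, 6), cy = tri(t, 7), cz = tri(t, 8);
      double abx = bx - ax, aby = by - ay, abz = bz - az;
      double acx = cx - ax, acy = cy - ay, acz = cz - az;
      double apx = px - ax, apy = py - ay, apz = pz - az;
      double d1 = abx * apx + aby * apy + abz * apz;
      double d2 = acx * apx + acy * apy + acz * apz;
      double qx, qy, qz;
      if (d1 <= 0 && d2 <= 0) { qx = ax; qy = ay; qz = az; }
      else {
        double bpx = px - bx, bpy = py - by, bpz = pz - bz;
        double d3 = abx * bpx + aby * bpy + abz * bpz;
        double d4 = acx * bpx + acy * bpy + acz * bpz;
        if (d3 >= 0 && d4 <= d3) { qx = bx; qy = by; qz = bz; }
        else {
          double vc = d1 * d4 - d3 * d2;
          if (vc <= 0 && d1 >= 0 && d3 <= 0) {
            double v = d1 / (d1 - d3);
            qx = ax + v * abx; qy = ay + v * aby; qz = az + v * abz;
          } else {
            double cpx = px - cx, cpy = py - cy, cpz = pz - cz;
            double d5 = abx * cpx + aby * cpy + abz * cpz;
            double d6 = acx * cpx + acy * cpy + acz * cpz;
            if (d6 >= 0 && d5 <= d6) { qx = cx; qy = cy; qz = cz; }
            else {
              double vb = d5 * d2 - d1 * d6;
              if (vb <= 0 && d2 >= 0 && d6 <= 0) {
                double w = d2 / (d2 - d6);
                qx = ax + w * acx; qy = ay + w * acy; qz = az + w * acz;
              } else {
                double va = d3 * d6 - d5 * d4;
                if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
                  double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
                  qx = bx + w * (cx - bx); qy = by + w * (cy - by); qz = bz + w * (cz - bz);
                } else {
                  double denom = 1.0 / (va + vb + vc);
                  double v = vb * denom, w = vc * denom;
                  qx = ax + abx * v + acx * w;
                  qy = ay + aby * v + acy * w;
                  qz = az + abz * v + acz * w;
                }
              }
            }
          }
        }
      }
      double dx = px - qx, dy = py - qy, dz = pz - qz;
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Locate containing tetrahedron for each query point (lowest tet index wins).
// Returns 1-based tet index (NA if outside) and barycentric coordinates.
// [[Rcpp::export(name = ".cpp_find_tet")]]
List cpp_find_tet(NumericMatrix nodes, IntegerMatrix tets, NumericMatrix q,
                  double tol) {
  const int M = tets.nrow(), K = q.nrow();
  // precompute inverse edge matrices and bounding boxes
  std::vector<double> inv(9 * M), x0(3 * M), blo(3 * M), bhi(3 * M);
  std::vector<bool> ok(M, true);
  for (int t = 0; t < M; ++t) {
    double vx[4], vy[4], vz[4];
    for (int a = 0; a < 4; ++a) {
      int id = tets(t, a);
      vx[a] = nodes(id, 0); vy[a] = nodes(id, 1); vz[a] = nodes(id, 2);
    }
    blo[3 * t] = *std::min_element(vx, vx + 4); bhi[3 * t] = *std::max_element(vx, vx + 4);
    blo[3 * t + 1] = *std::min_element(vy, vy + 4); bhi[3 * t + 1] = *std::max_element(vy, vy + 4);
    blo[3 * t + 2] = *std::min_element(vz, vz + 4); bhi[3 * t + 2] = *std::max_element(vz, vz + 4);
    double a11 = vx[1] - vx[0], a12 = vx[2] - vx[0], a13 = vx[3] - vx[0];
    double a21 = vy[1] - vy[0], a22 = vy[2] - vy[0], a23 = vy[3] - vy[0];
    double a31 = vz[1] - vz[0], a32 = vz[2] - vz[0], a33 = vz[3] - vz[0];
    double det = a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
                 a13 * (a21 * a32 - a22 * a31);
    if (std::fabs(det) < 1e-300) { ok[t] = false; continue; }
    double* B = &inv[9 * t];
    B[0] = (a22 * a33 - a23 * a32) / det; B[1] = (a13 * a32 - a12 * a33) / det;
    B[2] = (a12 * a23 - a13 * a22) / det;
    B[3] = (a23 * a31 - a21 * a33) / det; B[4] = (a11 * a33 - a13 * a31) / det;
    B[5] = (a13 * a21 - a11 * a23) / det;
    B[6] = (a21 * a32 - a22 * a31) / det; B[7] = (a12 * a31 - a11 * a32) / det;
    B[8] = (a11 * a22 - a12 * a21) / det;
    x0[3 * t] = vx[0]; x0[3 * t + 1] = vy[0]; x0[3 * t + 2] = vz[0];
  }
  IntegerVector hit(K, NA_INTEGER);
  NumericMatrix bary(K, 4);
  for (int p = 0; p < K; ++p) {
    double px = q(p, 0), py = q(p, 1), pz = q(p, 2);
    for (int t = 0; t < M; ++t) {
      if (!ok[t]) continue;
      if (px < blo[3 * t] - tol || px > bhi[3 * t] + tol ||
          py < blo[3 * t + 1] - tol || py > bhi[3 * t + 1] + tol ||
          pz < blo[3 * t + 2] - tol || pz > bhi[3 * t + 2] + tol) continue;
      const double* B = &inv[9 * t];
      double rx = px - x0[3 * t], ry = py - x0[3 * t + 1], rz = pz - x0[3 * t + 2];
      double l1 = B[0] * rx + B[1] * ry + B[2] * rz;
      double l2 = B[3] * rx + B[4] * ry + B[5] * rz;
      double l3 = B[6] * rx + B[7] * ry + B[8] * rz;
      double l0 = 1.0 - l1 - l2 - l3;
      if (l0 >= -tol && l1 >= -tol && l2 >= -tol && l3 >= -tol) {
        hit[p] = t + 1;
        bary(p, 0) = l0; bary(p, 1) = l1; bary(p, 2) = l2; bary(p, 3) = l3;
        break;  // lowest tet index wins
      }
    }
  }
  return List::create(_["tet"] = hit, _["bary"] = bary);
}
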