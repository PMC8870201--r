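#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 13 unique 3D offsets (half of the 26-neighbourhood) at Chebyshev distance 1.
static const int OFFS[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Merged-direction symmetric GLCM: pairs over all 13 offsets, each pair
// counted in both (i,j) and (j,i). Level 0 marks out-of-mask voxels.
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector levels, IntegerVector dims, int nb) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix M(nb, nb);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    int li = levels[idx3(x, y, z, nx, ny)];
    if (li <= 0) continue;
    for (int o = 0; o < 13; ++o) {
      int x2 = x + OFFS[o][0], y2 = y + OFFS[o][1], z2 = z + OFFS[o][2];
      if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
      int lj = levels[idx3(x2, y2, z2, nx, ny)];
      if (lj <= 0) continue;
      M(li - 1, lj - 1) += 1.0;
      M(lj - 1, li - 1) += 1.0;
    }
  }
  return M;
}

// Merged-direction GLRLM: maximal constant-level in-mask runs along each of
// the 13 direction lines, counts summed over directions.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector levels, IntegerVector dims, int nb) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int maxlen = std::max(nx, std::max(ny, nz));
  NumericMatrix M(nb, maxlen);
  for (int o = 0; o < 13; ++o) {
    int dx = OFFS[o][0], dy = OFFS[o][1], dz = OFFS[o][2];
    for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
      int li = levels[idx3(x, y, z, nx, ny)];
      if (li <= 0) continue;
      // run start: predecessor along -d is outside the grid or has a
      // different level (out-of-mask voxels break runs)
      int xp = x - dx, yp = y - dy, zp = z - dz;
      if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz &&
          levels[idx3(xp, yp, zp, nx, ny)] == li) continue;
      int len = 1;
      int xn = x + dx, yn = y + dy, zn = z + dz;
      while (xn >= 0 && xn < nx && yn >= 0 && yn < ny && zn >= 0 && zn < nz &&
             levels[idx3(xn, yn, zn, nx, ny)] == li) {
        ++len; xn += dx; yn += dy; zn += dz;
      }
      M(li - 1, len - 1) += 1.0;
    }
  }
  return M;
}

// GLSZM: 26-connected constant-level zones (single matrix, no directions).
// Columns are zone sizes 1..max observed size.
// [[Rcpp::export]]
NumericMatrix cpp_glszm(IntegerVector levels, IntegerVector dims, int nb) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<std::pair<int,int> > zones; // (level, size)
  std::vector<int> stack;
  int maxsize = 1;
  for (int start = 0; start < n; ++start) {
    if (seen[start] || levels[start] <= 0) continue;
    int lev = levels[start];
    int size = 0;
    stack.clear();
    stack.push_back(start);
    seen[start] = 1;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      ++size;
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int x2 = x + dx, y2 = y + dy, z2 = z + dz;
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
        int w = idx3(x2, y2, z2, nx, ny);
        if (!seen[w] && levels[w] == lev) { seen[w] = 1; stack.push_back(w); }
      }
    }
    zones.push_back(std::make_pair(lev, size));
    if (size > maxsize) maxsize = size;
  }
  NumericMatrix M(nb, maxsize);
  for (size_t i = 0; i < zones.size(); ++i)
    M(zones[i].first - 1, zones[i].second - 1) += 1.0;
  return M;
}

// NGTDM: per level, count of valid voxels and summed absolute difference to
// the mean of in-mask 26-neighbours. Returns nb x 2 matrix (n_i, s_i).
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dims, int nb) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix M(nb, 2);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    int li = levels[idx3(x, y, z, nx, ny)];
    if (li <= 0) continue;
    double sum = 0.0; int cnt = 0;
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
      if (!dx && !dy && !dz) continue;
      int x2 = x + dx, y2 = y + dy, z2 = z + dz;
      if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
      int lj = levels[idx3(x2, y2, z2, nx, ny)];
      if (lj > 0) { sum += lj; ++cnt; }
    }
    if (cnt > 0) {
      M(li - 1, 0) += 1.0;
      M(li - 1, 1) += std::fabs((double)li - sum / cnt);
    }
  }
  return M;
}

static inline double tri_area(const double a[3], const double b[3], const double c[3]) {
  double u[3] = { b[0]-a[0], b[1]-a[1], b[2]-a[2] };
  double v[3] = { c[0]-a[0], c[1]-a[1], c[2]-a[2] };
  double cx = u[1]*v[2] - u[2]*v[1];
  double cy = u[2]*v[0] - u[0]*v[2];
  double cz = u[0]*v[1] - u[1]*v[0];
  return 0.5 * std::sqrt(cx*cx + cy*cy + cz*cz);
}

static inline void edge_cross(const double a[3], const double b[3],
                              double va, double vb, double out[3]) {
  double t = (0.5 - va) / (vb - va);
  for (int d = 0; d < 3; ++d) out[d] = a[d] + t * (b[d] - a[d]);
}

// Surface area and enclosed volume of the 0.5-isosurface of a scalar field
// (e.g. a lightly smoothed binary mask) by marching tetrahedra on the
// voxel-centre node grid. Each cell is split into 6 tetrahedra sharing the
// main diagonal; crossings are linearly interpolated. Triangles are oriented
// outwards (away from the above-isolevel vertices), so the signed divergence
// sum gives the enclosed volume. The field must be 0 on its outer boundary.
// Returns c(area, volume).
// [[Rcpp::export]]
NumericVector cpp_mesh_props(NumericVector field, IntegerVector dims,
                             NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  static const int C[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
  };
  static const int TETS[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}
  };
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double area = 0.0, vol6 = 0.0;
  double m[4][3];
  for (int z = 0; z < nz - 1; ++z) for (int y = 0; y < ny - 1; ++y) for (int x = 0; x < nx - 1; ++x) {
    double val[8];
    double pos[8][3];
    int nabove = 0;
    for (int c = 0; c < 8; ++c) {
      int cx = x + C[c][0], cy = y + C[c][1], cz = z + C[c][2];
      val[c] = field[idx3(cx, cy, cz, nx, ny)];
      if (val[c] >= 0.5) ++nabove;
      pos[c][0] = cx * sx; pos[c][1] = cy * sy; pos[c][2] = cz * sz;
    }
    if (nabove == 0 || nabove == 8) continue;
    for (int t = 0; t < 6; ++t) {
      int vin[4], nin = 0, nout = 0, vout[4];
      for (int k = 0; k < 4; ++k) {
        int c = TETS[t][k];
        if (val[c] >= 0.5) vin[nin++] = c; else vout[nout++] = c;
      }
      if (nin == 0 || nin == 4) continue;
      int ntri = 0;
      double ref[3];
      if (nin == 1) {
        for (int k = 0; k < 3; ++k)
          edge_cross(pos[vin[0]], pos[vout[k]], val[vin[0]], val[vout[k]], m[k]);
        for (int d = 0; d < 3; ++d) ref[d] = pos[vin[0]][d];
        ntri = 1;
      } else if (nin == 3) {
        for (int k = 0; k < 3; ++k)
          edge_cross(pos[vin[k]], pos[vout[0]], val[vin[k]], val[vout[0]], m[k]);
        for (int d = 0; d < 3; ++d)
          ref[d] = (pos[vin[0]][d] + pos[vin[1]][d] + pos[vin[2]][d]) / 3.0;
        ntri = 1;
      } else { // 2 in / 2 out: quad across edges a-c, a-d, b-d, b-c
        int a = vin[0], b = vin[1], c = vout[0], d = vout[1];
        edge_cross(pos[a], pos[c], val[a], val[c], m[0]);
        edge_cross(pos[a], pos[d], val[a], val[d], m[1]);
        edge_cross(pos[b], pos[d], val[b], val[d], m[2]);
        edge_cross(pos[b], pos[c], val[b], val[c], m[3]);
        for (int dd = 0; dd < 3; ++dd) ref[dd] = 0.5 * (pos[a][dd] + pos[b][dd]);
        ntri = 2;
      }
      for (int tr = 0; tr < ntri; ++tr) {
        double *p0 = m[0], *p1 = m[tr + 1], *p2 = m[tr + 2];
        double u[3] = { p1[0]-p0[0], p1[1]-p0[1], p1[2]-p0[2] };
        double v[3] = { p2[0]-p0[0], p2[1]-p0[1], p2[2]-p0[2] };
        double nvec[3] = { u[1]*v[2]-u[2]*v[1], u[2]*v[0]-u[0]*v[2], u[0]*v[1]-u[1]*v[0] };
        double cen[3] = { (p0[0]+p1[0]+p2[0])/3.0 - ref[0],
                          (p0[1]+p1[1]+p2[1])/3.0 - ref[1],
                          (p0[2]+p1[2]+p2[2])/3.0 - ref[2] };
        double dot = nvec[0]*cen[0] + nvec[1]*cen[1] + nvec[2]*cen[2];
        double sgn = (dot >= 0) ? 1.0 : -1.0;  // outward orientation
        area += tri_area(p0, p1, p2);
        vol6 += sgn * (p0[0]*(p1[1]*p2[2]-p1[2]*p2[1])
                     - p0[1]*(p1[0]*p2[2]-p1[2]*p2[0])
                     + p0[2]*(p1[0]*p2[1]-p1[1]*p2[0]));
      }
    }
  }
  return NumericVector::create(area, std::fabs(vol6) / 6.0);
}

// Maximum pairwise Euclidean distance between points (rows of an n x 3 matrix).
// [[Rcpp::export]]
double cpp_max_pairwise_dist(NumericMatrix pts) {
  int n = pts.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i) {
    double xi = pts(i,0), yi = pts(i,1), zi = pts(i,2);
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(j,0) - xi, dy = pts(j,1) - yi, dz = pts(j,2) - zi;
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > best) best = d2;
    }
  }
  return std::sqrt(best);
}
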