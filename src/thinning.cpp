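#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 3D topological thinning and connected-component labelling for binary masks.
// Index convention: column-major (R array), voxel (x,y,z) -> x + nx*(y + ny*z).

namespace {

inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Foreground occupancy of the 3x3x3 neighbourhood of p, centre excluded.
// nb[dz+1][dy+1][dx+1], out-of-volume treated as background.
void neighbourhood(const std::vector<char> &img, int nx, int ny, int nz,
                   int x, int y, int z, char nb[3][3][3]) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        char v = 0;
        if (xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny && zz < nz)
          v = img[idx3(xx, yy, zz, nx, ny)];
        nb[dz + 1][dy + 1][dx + 1] = v;
      }
  nb[1][1][1] = 0; // centre ignored
}

int count_fg_neighbours(const char nb[3][3][3]) {
  int n = 0;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      for (int c = 0; c < 3; ++c) n += nb[a][b][c];
  return n;
}

// Number of 26-connected components of foreground within the 26-neighbourhood.
int fg_components_26(const char nb[3][3][3]) {
  char seen[3][3][3] = {{{0}}};
  int comps = 0;
  int stack[26][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      for (int c = 0; c < 3; ++c) {
        if (!nb[a][b][c] || seen[a][b][c]) continue;
        ++comps;
        int top = 0;
        stack[top][0] = a; stack[top][1] = b; stack[top][2] = c;
        seen[a][b][c] = 1;
        ++top;
        while (top > 0) {
          --top;
          int pa = stack[top][0], pb = stack[top][1], pc = stack[top][2];
          for (int da = -1; da <= 1; ++da)
            for (int db = -1; db <= 1; ++db)
              for (int dc = -1; dc <= 1; ++dc) {
                int qa = pa + da, qb = pb + db, qc = pc + dc;
                if (qa < 0 || qb < 0 || qc < 0 || qa > 2 || qb > 2 || qc > 2)
                  continue;
                if (nb[qa][qb][qc] && !seen[qa][qb][qc]) {
                  seen[qa][qb][qc] = 1;
                  stack[top][0] = qa; stack[top][1] = qb; stack[top][2] = qc;
                  ++top;
                }
              }
        }
      }
  return comps;
}

// Number of 6-connected components of background within the 18-neighbourhood
// that touch a face neighbour of the centre.
int bg_components_6(const char nb[3][3][3]) {
  // member of N18: |da|+|db|+|dc| <= 2, not the centre
  char in18[3][3][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      for (int c = 0; c < 3; ++c) {
        int m = std::abs(a - 1) + std::abs(b - 1) + std::abs(c - 1);
        in18[a][b][c] = (m >= 1 && m <= 2);
      }
  char seen[3][3][3] = {{{0}}};
  int comps = 0;
  int stack[18][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      for (int c = 0; c < 3; ++c) {
        // seeds are background FACE neighbours only
        int m = std::abs(a - 1) + std::abs(b - 1) + std::abs(c - 1);
        if (m != 1 || nb[a][b][c] || seen[a][b][c]) continue;
        ++comps;
        int top = 0;
        stack[top][0] = a; stack[top][1] = b; stack[top][2] = c;
        seen[a][b][c] = 1;
        ++top;
        while (top > 0) {
          --top;
          int pa = stack[top][0], pb = stack[top][1], pc = stack[top][2];
          const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
          for (int k = 0; k < 6; ++k) {
            int qa = pa + d6[k][0], qb = pb + d6[k][1], qc = pc + d6[k][2];
            if (qa < 0 || qb < 0 || qc < 0 || qa > 2 || qb > 2 || qc > 2)
              continue;
            if (in18[qa][qb][qc] && !nb[qa][qb][qc] && !seen[qa][qb][qc]) {
              seen[qa][qb][qc] = 1;
              stack[top][0] = qa; stack[top][1] = qb; stack[top][2] = qc;
              ++top;
            }
          }
        }
      }
  return comps;
}

// Simple point: deletion preserves topology (one fg 26-component in N26,
// one bg 6-component in N18 touching a face neighbour).
inline bool is_simple(const std::vector<char> &img, int nx, int ny, int nz,
                      int x, int y, int z) {
  char nb[3][3][3];
  neighbourhood(img, nx, ny, nz, x, y, z, nb);
  int nfg = count_fg_neighbours(nb);
  if (nfg == 0) return false;
  if (fg_components_26(nb) != 1) return false;
  if (bg_components_6(nb) != 1) return false;
  return true;
}

inline bool is_endpoint(const std::vector<char> &img, int nx, int ny, int nz,
                        int x, int y, int z) {
  char nb[3][3][3];
  neighbourhood(img, nx, ny, nz, x, y, z, nb);
  return count_fg_neighbours(nb) <= 1;
}

} // namespace

// [[Rcpp::export(name = ".thin3d_cpp")]]
LogicalVector thin3d_cpp(LogicalVector voxels, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> img(n);
  for (R_xlen_t i = 0; i < n; ++i) img[i] = voxels[i] ? 1 : 0;

  // six face directions; a subiteration deletes only points whose neighbour
  // in that direction is background, which keeps erosion symmetric
  const int dirs[6][3] = {{0,0,1},{0,0,-1},{0,1,0},{0,-1,0},{1,0,0},{-1,0,0}};
  bool changed = true;
  std::vector<int> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            int i = idx3(x, y, z, nx, ny);
            if (!img[i]) continue;
            int xx = x + dirs[d][0], yy = y + dirs[d][1], zz = z + dirs[d][2];
            char border = 1;
            if (xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny && zz < nz)
              border = img[idx3(xx, yy, zz, nx, ny)] ? 0 : 1;
            if (!border) continue;
            if (is_endpoint(img, nx, ny, nz, x, y, z)) continue;
            if (is_simple(img, nx, ny, nz, x, y, z)) cand.push_back(i);
          }
      // sequential re-check: earlier deletions may make later candidates
      // non-simple or endpoints
      for (size_t k = 0; k < cand.size(); ++k) {
        int i = cand[k];
        int z = i / (nx * ny), rem = i % (nx * ny);
        int y = rem / nx, x = rem % nx;
        if (is_endpoint(img, nx, ny, nz, x, y, z)) continue;
        if (!is_simple(img, nx, ny, nz, x, y, z)) continue;
        img[i] = 0;
        changed = true;
      }
    }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = img[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export(name = ".cc_label26_cpp")]]
IntegerVector cc_label26_cpp(LogicalVector voxels, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!voxels[s] || lab[s] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t i = stack.back();
      stack.pop_back();
      int z = (int)(i / ((R_xlen_t)nx * ny));
      int rem = (int)(i % ((R_xlen_t)nx * ny));
      int y = rem / nx, x = rem % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            R_xlen_t j = idx3(xx, yy, zz, nx, ny);
            if (voxels[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
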