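#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a binary 3D grid by iterative flood fill.
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, int connectivity) {
  IntegerVector dm = mask.attr("dim");
  const int nx = dm[0], ny = dm[1], nz = dm[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  lab.attr("dim") = dm;
  std::vector<int> offs_x, offs_y, offs_z;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs_x.push_back(dx); offs_y.push_back(dy); offs_z.push_back(dz);
      }
  const int no = offs_x.size();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int vx = v % nx, vy = (v / nx) % ny, vz = v / ((R_xlen_t)nx * ny);
      for (int o = 0; o < no; ++o) {
        int ux = vx + offs_x[o], uy = vy + offs_y[o], uz = vz + offs_z[o];
        if (ux < 0 || ux >= nx || uy < 0 || uy >= ny || uz < 0 || uz >= nz) continue;
        R_xlen_t u = ux + (R_xlen_t)nx * (uy + (R_xlen_t)ny * uz);
        if (mask[u] && !lab[u]) { lab[u] = next; stack.push_back(u); }
      }
    }
  }
  return lab;
}

// Binary erosion with an axis-aligned box structuring element of per-axis
// radii (rx, ry, rz) voxels; separable min filter, three passes.
// 'pad' is the value assumed outside the grid: 0 for plain erosion, 1 when
// eroding a complement to realize dilation (background extends outward).
static void erode_axis(std::vector<int>& a, int nx, int ny, int nz, int axis,
                       int r, int pad) {
  if (r <= 0) return;
  std::vector<int> out(a.size(), 0);
  const int n[3] = {nx, ny, nz};
  const R_xlen_t str[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int la = n[axis];
  const R_xlen_t sa = str[axis];
  // iterate over lines along 'axis'
  int b1 = (axis == 0) ? 1 : 0;
  int b2 = (axis == 2) ? 1 : 2;
  for (int j = 0; j < n[b2]; ++j)
    for (int i = 0; i < n[b1]; ++i) {
      R_xlen_t base = str[b1] * i + str[b2] * j;
      for (int k = 0; k < la; ++k) {
        int ok = 1;
        for (int d = -r; d <= r; ++d) {
          int kk = k + d;
          int v = (kk < 0 || kk >= la) ? pad : a[base + sa * kk];
          if (!v) { ok = 0; break; }
        }
        out[base + sa * k] = ok;
      }
    }
  a.swap(out);
}

// [[Rcpp::export]]
IntegerVector cpp_erode_box(IntegerVector mask, IntegerVector radii) {
  IntegerVector dm = mask.attr("dim");
  const int nx = dm[0], ny = dm[1], nz = dm[2];
  std::vector<int> a(mask.begin(), mask.end());
  erode_axis(a, nx, ny, nz, 0, radii[0], 0);
  erode_axis(a, nx, ny, nz, 1, radii[1], 0);
  erode_axis(a, nx, ny, nz, 2, radii[2], 0);
  IntegerVector out(a.begin(), a.end());
  out.attr("dim") = dm;
  return out;
}

// Binary dilation with the same box element (erosion of the complement).
// [[Rcpp::export]]
IntegerVector cpp_dilate_box(IntegerVector mask, IntegerVector radii) {
  IntegerVector dm = mask.attr("dim");
  const int nx = dm[0], ny = dm[1], nz = dm[2];
  std::vector<int> a(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) a[i] = mask[i] ? 0 : 1;
  erode_axis(a, nx, ny, nz, 0, radii[0], 1);
  erode_axis(a, nx, ny, nz, 1, radii[1], 1);
  erode_axis(a, nx, ny, nz, 2, radii[2], 1);
  IntegerVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = a[i] ? 0 : 1;
  out.attr("dim") = dm;
  return out;
}
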