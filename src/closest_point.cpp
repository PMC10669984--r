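// Point-to-surface distance queries against a triangle soup, accelerated by
// a uniform grid.  Used by the Hausdorff-distance QC and by the remesher's
// back-projection step.  Distances are exact per triangle (Ericson's
// closest-point-on-triangle construction); only the candidate set is pruned.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static inline void closest_pt_triangle(const double *p, const double *a,
                                       const double *b, const double *c,
                                       double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }

  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }

  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

struct TriGrid {
  int nx, ny, nz;
  double ox, oy, oz, h;
  std::vector<int> cell_start;   // CSR offsets, length nx*ny*nz + 1
  std::vector<int> cell_tris;
};

static void build_grid(const NumericMatrix &V, const IntegerMatrix &F,
                       TriGrid &g) {
  int nf = F.nrow();
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) {
    lo[k] = std::numeric_limits<double>::infinity();
    hi[k] = -std::numeric_limits<double>::infinity();
  }
  int nv = V.nrow();
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) {
      double x = V(i, k);
      if (x < lo[k]) lo[k] = x;
      if (x > hi[k]) hi[k] = x;
    }
  double ext[3] = {hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2]};
  double vol = std::max(ext[0], 1e-9) * std::max(ext[1], 1e-9) *
               std::max(ext[2], 1e-9);
  double h = std::cbrt(vol / std::max(nf, 1));
  double maxext = std::max(ext[0], std::max(ext[1], ext[2]));
  if (h <= 0.0 || !std::isfinite(h)) h = std::max(maxext, 1.0);
  h = std::max(h, maxext / 128.0);
  g.h = h;
  g.ox = lo[0]; g.oy = lo[1]; g.oz = lo[2];
  g.nx = std::max(1, (int)std::ceil(ext[0] / h));
  g.ny = std::max(1, (int)std::ceil(ext[1] / h));
  g.nz = std::max(1, (int)std::ceil(ext[2] / h));

  int ncell = g.nx * g.ny * g.nz;
  std::vector<int> counts(ncell, 0);
  std::vector<int> tlo(3 * nf), thi(3 * nf);
  for (int t = 0; t < nf; ++t) {
    double blo[3], bhi[3];
    for (int k = 0; k < 3; ++k) {
      double a = V(F(t, 0), k), b = V(F(t, 1), k), c = V(F(t, 2), k);
      blo[k] = std::min(a, std::min(b, c));
      bhi[k] = std::max(a, std::max(b, c));
    }
    int il = std::min(g.nx - 1, std::max(0, (int)((blo[0] - g.ox) / h)));
    int ih = std::min(g.nx - 1, std::max(0, (int)((bhi[0] - g.ox) / h)));
    int jl = std::min(g.ny - 1, std::max(0, (int)((blo[1] - g.oy) / h)));
    int jh = std::min(g.ny - 1, std::max(0, (int)((bhi[1] - g.oy) / h)));
    int kl = std::min(g.nz - 1, std::max(0, (int)((blo[2] - g.oz) / h)));
    int kh = std::min(g.nz - 1, std::max(0, (int)((bhi[2] - g.oz) / h)));
    tlo[3 * t] = il; tlo[3 * t + 1] = jl; tlo[3 * t + 2] = kl;
    thi[3 * t] = ih; thi[3 * t + 1] = jh; thi[3 * t + 2] = kh;
    for (int i = il; i <= ih; ++i)
      for (int j = jl; j <= jh; ++j)
        for (int k = kl; k <= kh; ++k)
          counts[(i * g.ny + j) * g.nz + k]++;
  }
  g.cell_start.assign(ncell + 1, 0);
  for (int c = 0; c < ncell; ++c) g.cell_start[c + 1] = g.cell_start[c] + counts[c];
  g.cell_tris.assign(g.cell_start[ncell], 0);
  std::vector<int> cur(g.cell_start.begin(), g.cell_start.end() - 1);
  for (int t = 0; t < nf; ++t) {
    for (int i = tlo[3 * t]; i <= thi[3 * t]; ++i)
      for (int j = tlo[3 * t + 1]; j <= thi[3 * t + 1]; ++j)
        for (int k = tlo[3 * t + 2]; k <= thi[3 * t + 2]; ++k)
          g.cell_tris[cur[(i * g.ny + j) * g.nz + k]++] = t;
  }
}

// Closest point on the mesh for each query point.  Returns squared-distance
// lower-bound-pruned exact nearest point.
// [[Rcpp::export]]
List cpp_project_points(NumericMatrix pts, NumericMatrix V, IntegerMatrix F0) {
  int nf = F0.nrow(), np = pts.nrow();
  if (nf == 0) stop("mesh has no faces");
  IntegerMatrix F(clone(F0));
  for (int t = 0; t < nf; ++t)
    for (int k = 0; k < 3; ++k) F(t, k) = F0(t, k) - 1;  // 1-based -> 0-based

  TriGrid g;
  build_grid(V, F, g);

  NumericVector dist(np);
  NumericMatrix proj(np, 3);
  std::vector<double> tv(9 * nf);
  for (int t = 0; t < nf; ++t)
    for (int c = 0; c < 3; ++c)
      for (int k = 0; k < 3; ++k) tv[9 * t + 3 * c + k] = V(F(t, c), k);

  int maxr = g.nx + g.ny + g.nz + 2;
  std::vector<char> seen(nf, 0);
  std::vector<int> touched;
  touched.reserve(256);

  for (int q = 0; q < np; ++q) {
    double p[3] = {pts(q, 0), pts(q, 1), pts(q, 2)};
    int ci = std::min(g.nx - 1, std::max(0, (int)((p[0] - g.ox) / g.h)));
    int cj = std::min(g.ny - 1, std::max(0, (int)((p[1] - g.oy) / g.h)));
    int ck = std::min(g.nz - 1, std::max(0, (int)((p[2] - g.oz) / g.h)));
    double best = std::numeric_limits<double>::infinity();
    double bp[3] = {p[0], p[1], p[2]};
    touched.clear();

    for (int r = 0; r <= maxr; ++r) {
      bool any_cell = false;
      int il = ci - r, ih = ci + r, jl = cj - r, jh = cj + r,
          kl = ck - r, kh = ck + r;
      for (int i = std::max(0, il); i <= std::min(g.nx - 1, ih); ++i)
        for (int j = std::max(0, jl); j <= std::min(g.ny - 1, jh); ++j)
          for (int k = std::max(0, kl); k <= std::min(g.nz - 1, kh); ++k) {
            // only the shell at Chebyshev radius r
            if (r > 0 && i != il && i != ih && j != jl && j != jh &&
                k != kl && k != kh)
              continue;
            any_cell = true;
            int c = (i * g.ny + j) * g.nz + k;
            for (int s = g.cell_start[c]; s < g.cell_start[c + 1]; ++s) {
              int t = g.cell_tris[s];
              if (seen[t]) continue;
              seen[t] = 1;
              touched.push_back(t);
              double out[3];
              closest_pt_triangle(p, &tv[9 * t], &tv[9 * t + 3], &tv[9 * t + 6],
                                  out);
              double d2 = 0;
              for (int k2 = 0; k2 < 3; ++k2) {
                double d = p[k2] - out[k2];
                d2 += d * d;
              }
              if (d2 < best) {
                best = d2;
                bp[0] = out[0]; bp[1] = out[1]; bp[2] = out[2];
              }
            }
          }
      if (std::isfinite(best)) {
        // distance from p to the outside of the scanned cell box: if it
        // exceeds the current best, no unscanned cell can do better
        double blo[3] = {g.ox + il * g.h, g.oy + jl * g.h, g.oz + kl * g.h};
        double bhi[3] = {g.ox + (ih + 1) * g.h, g.oy + (jh + 1) * g.h,
                         g.oz + (kh + 1) * g.h};
        double m = std::numeric_limits<double>::infinity();
        for (int k2 = 0; k2 < 3; ++k2) {
          m = std::min(m, p[k2] - blo[k2]);
          m = std::min(m, bhi[k2] - p[k2]);
        }
        if (m > 0 && m * m >= best) break;
      }
      if (!any_cell && r > 0 && il < 0 && jl < 0 && kl < 0 && ih >= g.nx &&
          jh >= g.ny && kh >= g.nz)
        break;  // whole grid scanned
    }
    for (size_t s = 0; s < touched.size(); ++s) seen[touched[s]] = 0;
    dist[q] = std::sqrt(best);
    proj(q, 0) = bp[0]; proj(q, 1) = bp[1]; proj(q, 2) = bp[2];
  }
  return List::create(_["dist"] = dist, _["points"] = proj);
}
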