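#include <Rcpp.h>
#include <unordered_map>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Signed distance field to the union of probe-inflated atom spheres:
// f(x) = min_i( |x - c_i| - r_i ), sampled on a regular grid.
// Only grid points inside each atom's bounding box (half-width r_i + 2h)
// are updated; points outside every box keep a large positive value, which
// is sign-correct everywhere and magnitude-correct within 2h of the surface.
// [[Rcpp::export]]
NumericVector cpp_distance_field(NumericMatrix centers, NumericVector radii,
                                 NumericVector origin, double spacing,
                                 IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  NumericVector field(ntot, 1e9);
  const int na = centers.nrow();
  for (int a = 0; a < na; ++a) {
    const double cx = centers(a, 0), cy = centers(a, 1), cz = centers(a, 2);
    const double r = radii[a], pad = r + 2.0 * spacing;
    int ix0 = (int)std::floor((cx - pad - origin[0]) / spacing);
    int ix1 = (int)std::ceil((cx + pad - origin[0]) / spacing);
    int iy0 = (int)std::floor((cy - pad - origin[1]) / spacing);
    int iy1 = (int)std::ceil((cy + pad - origin[1]) / spacing);
    int iz0 = (int)std::floor((cz - pad - origin[2]) / spacing);
    int iz1 = (int)std::ceil((cz + pad - origin[2]) / spacing);
    if (ix0 < 0) ix0 = 0; if (iy0 < 0) iy0 = 0; if (iz0 < 0) iz0 = 0;
    if (ix1 > nx - 1) ix1 = nx - 1;
    if (iy1 > ny - 1) iy1 = ny - 1;
    if (iz1 > nz - 1) iz1 = nz - 1;
    for (int iz = iz0; iz <= iz1; ++iz) {
      const double dz = origin[2] + iz * spacing - cz;
      for (int iy = iy0; iy <= iy1; ++iy) {
        const double dy = origin[1] + iy * spacing - cy;
        const double dzy = dz * dz + dy * dy;
        R_xlen_t base = (R_xlen_t)iz * ny * nx + (R_xlen_t)iy * nx;
        for (int ix = ix0; ix <= ix1; ++ix) {
          const double dx = origin[0] + ix * spacing - cx;
          const double v = std::sqrt(dx * dx + dzy) - r;
          if (v < field[base + ix]) field[base + ix] = v;
        }
      }
    }
  }
  return field;
}

// --- marching tetrahedra ----------------------------------------------------
// Each grid cube is split into 6 tetrahedra sharing the main diagonal
// (corner 0 to corner 7); the split is identical in every cube, so faces of
// neighbouring cubes are triangulated consistently and the extracted
// isosurface is watertight. Isosurface vertices are welded via the grid edge
// they sit on.

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
};

static inline int mt_edge_vertex(MTState &st, R_xlen_t ga, R_xlen_t gb,
                                 double fa, double fb,
                                 const double *pa, const double *pb) {
  if (ga > gb) { std::swap(ga, gb); std::swap(fa, fb); const double *t = pa; pa = pb; pb = t; }
  // grids here have < 2^32 points, so packing both endpoints is collision-free
  const uint64_t key = ((uint64_t)ga << 32) | (uint64_t)gb;
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double t = fa / (fa - fb);
  if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  st.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
  st.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
  st.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
  int id = (int)st.vx.size() - 1;
  st.edge_vertex.emplace(key, id);
  return id;
}

// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector field, IntegerVector dims,
                        NumericVector origin, double spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // 6 tetrahedra around the 0-7 diagonal (cube corners bit-coded x|y<<1|z<<2)
  static const int TETS[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  MTState st;
  double corner[8][3];
  double fval[8];
  R_xlen_t gidx[8];

  for (int iz = 0; iz + 1 < nz; ++iz) {
    for (int iy = 0; iy + 1 < ny; ++iy) {
      for (int ix = 0; ix + 1 < nx; ++ix) {
        bool anyin = false, anyout = false;
        for (int c = 0; c < 8; ++c) {
          const int cx = ix + (c & 1), cy = iy + ((c >> 1) & 1), cz = iz + ((c >> 2) & 1);
          R_xlen_t g = (R_xlen_t)cz * ny * nx + (R_xlen_t)cy * nx + cx;
          double f = field[g];
          if (f == 0.0) f = 1e-12;  // nudge: treat exact zeros as outside
          gidx[c] = g; fval[c] = f;
          corner[c][0] = origin[0] + cx * spacing;
          corner[c][1] = origin[1] + cy * spacing;
          corner[c][2] = origin[2] + cz * spacing;
          if (f < 0) anyin = true; else anyout = true;
        }
        if (!anyin || !anyout) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          int in[4], nin = 0, out[4], nout = 0;
          for (int k = 0; k < 4; ++k) {
            if (fval[T[k]] < 0) in[nin++] = T[k]; else out[nout++] = T[k];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            const int apex = (nin == 1) ? in[0] : out[0];
            const int *oth = (nin == 1) ? out : in;
            int v[3];
            for (int k = 0; k < 3; ++k)
              v[k] = mt_edge_vertex(st, gidx[apex], gidx[oth[k]],
                                    fval[apex], fval[oth[k]],
                                    corner[apex], corner[oth[k]]);
            if (v[0] != v[1] && v[0] != v[2] && v[1] != v[2]) {
              st.tri.push_back(v[0]); st.tri.push_back(v[1]); st.tri.push_back(v[2]);
            }
          } else {  // 2 in, 2 out: quad split into two triangles
            int e00 = mt_edge_vertex(st, gidx[in[0]], gidx[out[0]], fval[in[0]], fval[out[0]], corner[in[0]], corner[out[0]]);
            int e01 = mt_edge_vertex(st, gidx[in[0]], gidx[out[1]], fval[in[0]], fval[out[1]], corner[in[0]], corner[out[1]]);
            int e11 = mt_edge_vertex(st, gidx[in[1]], gidx[out[1]], fval[in[1]], fval[out[1]], corner[in[1]], corner[out[1]]);
            int e10 = mt_edge_vertex(st, gidx[in[1]], gidx[out[0]], fval[in[1]], fval[out[0]], corner[in[1]], corner[out[0]]);
            if (e00 != e01 && e00 != e11 && e01 != e11) {
              st.tri.push_back(e00); st.tri.push_back(e01); st.tri.push_back(e11);
            }
            if (e00 != e11 && e00 != e10 && e11 != e10) {
              st.tri.push_back(e00); st.tri.push_back(e11); st.tri.push_back(e10);
            }
          }
        }
      }
    }
  }
  const int nv = (int)st.vx.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i, 0) = st.vx[i]; V(i, 1) = st.vy[i]; V(i, 2) = st.vz[i]; }
  const int nf = (int)st.tri.size() / 3;
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = st.tri[3 * i] + 1;     // 1-based for R
    F(i, 1) = st.tri[3 * i + 1] + 1;
    F(i, 2) = st.tri[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// --- quadric edge collapse --------------------------------------------------
// Garland-Heckbert error quadrics, area-weighted, greedy edge contraction
// with a lazy heap. Candidate positions per edge: the two endpoints and the
// midpoint (cheapest wins). A normal-flip guard rejects collapses that would
// invert an incident face.

struct Quadric {
  double q[10];  // upper triangle of symmetric 4x4: 11 12 13 14 22 23 24 33 34 44
  Quadric() { for (int i = 0; i < 10; ++i) q[i] = 0.0; }
  void add_plane(double a, double b, double c, double d, double w) {
    q[0] += w * a * a; q[1] += w * a * b; q[2] += w * a * c; q[3] += w * a * d;
    q[4] += w * b * b; q[5] += w * b * c; q[6] += w * b * d;
    q[7] += w * c * c; q[8] += w * c * d; q[9] += w * d * d;
  }
  void add(const Quadric &o) { for (int i = 0; i < 10; ++i) q[i] += o.q[i]; }
  double eval(const double *p) const {
    const double x = p[0], y = p[1], z = p[2];
    return q[0] * x * x + 2 * q[1] * x * y + 2 * q[2] * x * z + 2 * q[3] * x +
           q[4] * y * y + 2 * q[5] * y * z + 2 * q[6] * y +
           q[7] * z * z + 2 * q[8] * z + q[9];
  }
};

struct HeapEntry {
  double cost;
  int a, b, va, vb;  // vertex ids + their versions at push time
  bool operator<(const HeapEntry &o) const { return cost > o.cost; }  // min-heap
};

static inline void face_normal(const std::vector<double> &P, int i, int j, int k,
                               double *n) {
  const double ax = P[3 * j] - P[3 * i], ay = P[3 * j + 1] - P[3 * i + 1], az = P[3 * j + 2] - P[3 * i + 2];
  const double bx = P[3 * k] - P[3 * i], by = P[3 * k + 1] - P[3 * i + 1], bz = P[3 * k + 2] - P[3 * i + 2];
  n[0] = ay * bz - az * by; n[1] = az * bx - ax * bz; n[2] = ax * by - ay * bx;
}

// [[Rcpp::export]]
List cpp_simplify_qem(NumericMatrix V, IntegerMatrix F, int target_faces) {
  const int nv = V.nrow(), nf = F.nrow();
  std::vector<double> P(3 * nv);
  for (int i = 0; i < nv; ++i) { P[3 * i] = V(i, 0); P[3 * i + 1] = V(i, 1); P[3 * i + 2] = V(i, 2); }
  std::vector<int> fv(3 * nf);
  std::vector<bool> face_live(nf, true);
  for (int i = 0; i < nf; ++i) { fv[3 * i] = F(i, 0) - 1; fv[3 * i + 1] = F(i, 1) - 1; fv[3 * i + 2] = F(i, 2) - 1; }

  std::vector<Quadric> Q(nv);
  std::vector<std::vector<int>> vfaces(nv);
  for (int f = 0; f < nf; ++f) {
    const int i = fv[3 * f], j = fv[3 * f + 1], k = fv[3 * f + 2];
    double n[3];
    face_normal(P, i, j, k, n);
    const double len = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
    if (len > 1e-12) {
      const double area = 0.5 * len;
      const double a = n[0] / len, b = n[1] / len, c = n[2] / len;
      const double d = -(a * P[3 * i] + b * P[3 * i + 1] + c * P[3 * i + 2]);
      Q[i].add_plane(a, b, c, d, area);
      Q[j].add_plane(a, b, c, d, area);
      Q[k].add_plane(a, b, c, d, area);
    }
    vfaces[i].push_back(f); vfaces[j].push_back(f); vfaces[k].push_back(f);
  }

  std::vector<int> version(nv, 0);
  std::vector<bool> dead(nv, false);
  std::priority_queue<HeapEntry> heap;

  auto edge_cost = [&](int a, int b, double *best_pos) {
    Quadric s = Q[a]; s.add(Q[b]);
    const double *pa = &P[3 * a], *pb = &P[3 * b];
    double mid[3] = {0.5 * (pa[0] + pb[0]), 0.5 * (pa[1] + pb[1]), 0.5 * (pa[2] + pb[2])};
    double best = s.eval(mid);
    best_pos[0] = mid[0]; best_pos[1] = mid[1]; best_pos[2] = mid[2];
    const double ca = s.eval(pa);
    if (ca < best) { best = ca; best_pos[0] = pa[0]; best_pos[1] = pa[1]; best_pos[2] = pa[2]; }
    const double cb = s.eval(pb);
    if (cb < best) { best = cb; best_pos[0] = pb[0]; best_pos[1] = pb[1]; best_pos[2] = pb[2]; }
    // optimal placement: minimize the quadric, v = -A^{-1} b (3x3 solve);
    // fall back to the candidate points when A is near-singular
    const double A11 = s.q[0], A12 = s.q[1], A13 = s.q[2];
    const double A22 = s.q[4], A23 = s.q[5], A33 = s.q[7];
    const double r1 = -s.q[3], r2 = -s.q[6], r3 = -s.q[8];
    const double det = A11 * (A22 * A33 - A23 * A23)
                     - A12 * (A12 * A33 - A23 * A13)
                     + A13 * (A12 * A23 - A22 * A13);
    const double scale = std::fabs(A11) + std::fabs(A22) + std::fabs(A33);
    if (std::fabs(det) > 1e-9 * scale * scale * scale) {
      double opt[3];
      opt[0] = (r1 * (A22 * A33 - A23 * A23) - A12 * (r2 * A33 - A23 * r3) +
                A13 * (r2 * A23 - A22 * r3)) / det;
      opt[1] = (A11 * (r2 * A33 - A23 * r3) - r1 * (A12 * A33 - A23 * A13) +
                A13 * (A12 * r3 - r2 * A13)) / det;
      opt[2] = (A11 * (A22 * r3 - r2 * A23) - A12 * (A12 * r3 - r2 * A13) +
                r1 * (A12 * A23 - A22 * A13)) / det;
      // guard against wild solutions far from the edge
      const double elen2 = (pa[0] - pb[0]) * (pa[0] - pb[0]) +
                           (pa[1] - pb[1]) * (pa[1] - pb[1]) +
                           (pa[2] - pb[2]) * (pa[2] - pb[2]);
      const double dm2 = (opt[0] - mid[0]) * (opt[0] - mid[0]) +
                         (opt[1] - mid[1]) * (opt[1] - mid[1]) +
                         (opt[2] - mid[2]) * (opt[2] - mid[2]);
      if (dm2 <= 4.0 * elen2) {
        const double co = s.eval(opt);
        if (co < best) {
          best = co;
          best_pos[0] = opt[0]; best_pos[1] = opt[1]; best_pos[2] = opt[2];
        }
      }
    }
    return best;
  };

  auto push_edges_of = [&](int a) {
    for (int f : vfaces[a]) {
      if (!face_live[f]) continue;
      for (int s = 0; s < 3; ++s) {
        const int b = fv[3 * f + s];
        if (b == a || dead[b]) continue;
        double pos[3];
        const double c = edge_cost(a, b, pos);
        heap.push({c, a, b, version[a], version[b]});
      }
    }
  };
  for (int a = 0; a < nv; ++a) if (!vfaces[a].empty()) push_edges_of(a);

  int live = 0;
  for (int f = 0; f < nf; ++f) if (face_live[f]) ++live;

  std::vector<int> scratch;
  while (live > target_faces && !heap.empty()) {
    HeapEntry e = heap.top(); heap.pop();
    const int a = e.a, b = e.b;
    if (dead[a] || dead[b] || version[a] != e.va || version[b] != e.vb) continue;
    double pos[3];
    edge_cost(a, b, pos);

    // normal-flip guard: faces keeping exactly one of {a,b} must not invert
    bool flip = false;
    scratch.clear();
    for (int f : vfaces[a]) if (face_live[f]) scratch.push_back(f);
    for (int f : vfaces[b]) if (face_live[f]) scratch.push_back(f);
    double keep_a[3] = {P[3 * a], P[3 * a + 1], P[3 * a + 2]};
    double keep_b[3] = {P[3 * b], P[3 * b + 1], P[3 * b + 2]};
    for (int f : scratch) {
      int id[3] = {fv[3 * f], fv[3 * f + 1], fv[3 * f + 2]};
      bool hasa = (id[0] == a || id[1] == a || id[2] == a);
      bool hasb = (id[0] == b || id[1] == b || id[2] == b);
      if (hasa && hasb) continue;  // will degenerate and be removed
      double n0[3];
      face_normal(P, id[0], id[1], id[2], n0);
      // temporarily move
      P[3 * a] = pos[0]; P[3 * a + 1] = pos[1]; P[3 * a + 2] = pos[2];
      P[3 * b] = pos[0]; P[3 * b + 1] = pos[1]; P[3 * b + 2] = pos[2];
      double n1[3];
      face_normal(P, id[0], id[1], id[2], n1);
      P[3 * a] = keep_a[0]; P[3 * a + 1] = keep_a[1]; P[3 * a + 2] = keep_a[2];
      P[3 * b] = keep_b[0]; P[3 * b + 1] = keep_b[1]; P[3 * b + 2] = keep_b[2];
      if (n0[0] * n1[0] + n0[1] * n1[1] + n0[2] * n1[2] < 0) { flip = true; break; }
    }
    // rejected collapses are simply dropped; the edge re-enters the heap
    // whenever either endpoint is touched by a later collapse
    if (flip) continue;

    // perform collapse b -> a at pos
    P[3 * a] = pos[0]; P[3 * a + 1] = pos[1]; P[3 * a + 2] = pos[2];
    Q[a].add(Q[b]);
    dead[b] = true;
    for (int f : vfaces[b]) {
      if (!face_live[f]) continue;
      for (int s = 0; s < 3; ++s) if (fv[3 * f + s] == b) fv[3 * f + s] = a;
      const int i = fv[3 * f], j = fv[3 * f + 1], k = fv[3 * f + 2];
      if (i == j || j == k || i == k) {
        face_live[f] = false; --live;
      } else {
        vfaces[a].push_back(f);
      }
    }
    vfaces[b].clear();
    ++version[a]; ++version[b];
    push_edges_of(a);
  }

  // compact
  std::vector<int> vmap(nv, -1);
  int nvo = 0;
  for (int f = 0; f < nf; ++f) {
    if (!face_live[f]) continue;
    for (int s = 0; s < 3; ++s) {
      const int v = fv[3 * f + s];
      if (vmap[v] < 0) vmap[v] = nvo++;
    }
  }
  NumericMatrix Vo(nvo, 3);
  for (int v = 0; v < nv; ++v) {
    if (vmap[v] >= 0) {
      Vo(vmap[v], 0) = P[3 * v]; Vo(vmap[v], 1) = P[3 * v + 1]; Vo(vmap[v], 2) = P[3 * v + 2];
    }
  }
  int nfo = 0;
  for (int f = 0; f < nf; ++f) if (face_live[f]) ++nfo;
  IntegerMatrix Fo(nfo, 3);
  int fo = 0;
  for (int f = 0; f < nf; ++f) {
    if (!face_live[f]) continue;
    Fo(fo, 0) = vmap[fv[3 * f]] + 1;
    Fo(fo, 1) = vmap[fv[3 * f + 1]] + 1;
    Fo(fo, 2) = vmap[fv[3 * f + 2]] + 1;
    ++fo;
  }
  return List::create(_["vertices"] = Vo, _["faces"] = Fo);
}

// --- point to mesh distance -------------------------------------------------
// Minimum Euclidean distance from each query point to any triangle of the
// mesh (exact point-triangle distance, brute force over faces).

static double point_tri_dist2(const double *p, const double *a,
                              const double *b, const double *c) {
  // Eberly-style closest point on triangle
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  const double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  const double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double u, v;
  if (d1 <= 0 && d2 <= 0) { u = 0; v = 0; }
  else {
    double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
    const double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    const double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    if (d3 >= 0 && d4 <= d3) { u = 1; v = 0; }
    else {
      double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
      const double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
      const double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
      if (d6 >= 0 && d5 <= d6) { u = 0; v = 1; }
      else {
        const double vc = d1 * d4 - d3 * d2;
        if (vc <= 0 && d1 >= 0 && d3 <= 0) { u = d1 / (d1 - d3); v = 0; }
        else {
          const double vb = d5 * d2 - d1 * d6;
          if (vb <= 0 && d2 >= 0 && d6 <= 0) { u = 0; v = d2 / (d2 - d6); }
          else {
            const double va = d3 * d6 - d5 * d4;
            if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
              const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              u = 1 - w; v = w;
            } else {
              // interior: barycentric weights along ab and ac
              const double den = va + vb + vc;
              u = vb / den;
              v = vc / den;
            }
          }
        }
      }
    }
  }
  double q[3] = {a[0] + u * ab[0] + v * ac[0],
                 a[1] + u * ab[1] + v * ac[1],
                 a[2] + u * ab[2] + v * ac[2]};
  const double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
  return dx * dx + dy * dy + dz * dz;
}

// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix P, NumericMatrix V,
                                  IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  std::vector<double> vp(3 * V.nrow());
  for (int i = 0; i < V.nrow(); ++i) {
    vp[3 * i] = V(i, 0); vp[3 * i + 1] = V(i, 1); vp[3 * i + 2] = V(i, 2);
  }
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double pt[3] = {P(p, 0), P(p, 1), P(p, 2)};
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      const double d2 = point_tri_dist2(pt, &vp[3 * (F(f, 0) - 1)],
                                        &vp[3 * (F(f, 1) - 1)],
                                        &vp[3 * (F(f, 2) - 1)]);
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}
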