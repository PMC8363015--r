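// Core geometry and ray-tracing engine.
//
// Triangle meshes are stored as flat arrays; an octree (axis-aligned,
// centre-split, triangles duplicated into every overlapping child) accelerates
// nearest-hit queries.  The octree is an accelerator only: results are
// required to be identical to a brute-force scan over all triangles.
//
// Tracing follows geometric optics: Snell refraction at every surface
// crossing (no Fresnel losses), optional specular reflection on total
// internal reflection, and incremental Beer-Lambert absorption marched along
// every path segment that lies inside a retinal volume.  Volume membership is
// tracked by crossing parity (a bitmask over meshes), which is initialised
// to "outside everything" because source rays always start outside the eye.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const double EPS_ADV = 1e-6;   // advance along ray after a surface event (um)
static const double EPS_T   = 1e-9;   // minimum accepted hit parameter
static const double EPS_BARY = 1e-9;  // inclusive barycentric tolerance (shared edges)

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
};
static inline V3 operator+(V3 a, V3 b) { return V3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator-(V3 a, V3 b) { return V3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator*(V3 a, double s) { return V3(a.x * s, a.y * s, a.z * s); }
static inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(V3 a, V3 b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm3(V3 a) { return std::sqrt(dot(a, a)); }
static inline V3 unit(V3 a) { double n = norm3(a); return V3(a.x / n, a.y / n, a.z / n); }

struct Node {
  double lo[3], hi[3];
  int child[8];                 // -1 when absent
  std::vector<int> tris;        // leaf triangle indices (empty for internal)
  bool leaf;
};

struct Hit {
  double t, u, v;
  int face;                     // -1 = none
};

struct Mesh3 {
  // per-face precomputed data
  std::vector<V3> v0, e1, e2, fn;     // origin vertex, edges, unit face normal
  std::vector<V3> vn0, vn1, vn2;      // vertex normals (for smoothed option)
  std::vector<int> mesh_id;           // 0-based volume id per face
  int n_mesh;
  std::vector<Node> nodes;
  int leaf_capacity, max_depth;

  void build_tree(int cap, int maxd);
  Hit nearest(const V3& o, const V3& d, double tmin) const;
  Hit nearest_brute(const V3& o, const V3& d, double tmin) const;
  void crossings(const V3& o, const V3& d, std::vector<int>& count_per_mesh) const;

  bool mt(int f, const V3& o, const V3& d, double tmin, double& t, double& u, double& v) const {
    V3 pv = cross(d, e2[f]);
    double det = dot(e1[f], pv);
    if (std::fabs(det) < 1e-14) return false;
    double inv = 1.0 / det;
    V3 tv = o - v0[f];
    u = dot(tv, pv) * inv;
    if (u < -EPS_BARY || u > 1.0 + EPS_BARY) return false;
    V3 qv = cross(tv, e1[f]);
    v = dot(d, qv) * inv;
    if (v < -EPS_BARY || u + v > 1.0 + EPS_BARY) return false;
    t = dot(e2[f], qv) * inv;
    return t >= tmin;
  }
};

// ---- octree -----------------------------------------------------------------

static inline bool box_overlap(const double lo1[3], const double hi1[3],
                               const double lo2[3], const double hi2[3]) {
  for (int k = 0; k < 3; ++k)
    if (lo1[k] > hi2[k] || lo2[k] > hi1[k]) return false;
  return true;
}

static void tri_bbox(const Mesh3& m, int f, double lo[3], double hi[3]) {
  V3 a = m.v0[f], b = m.v0[f] + m.e1[f], c = m.v0[f] + m.e2[f];
  lo[0] = std::min({a.x, b.x, c.x}); hi[0] = std::max({a.x, b.x, c.x});
  lo[1] = std::min({a.y, b.y, c.y}); hi[1] = std::max({a.y, b.y, c.y});
  lo[2] = std::min({a.z, b.z, c.z}); hi[2] = std::max({a.z, b.z, c.z});
}

static int build_node(Mesh3& m, const double lo[3], const double hi[3],
                      std::vector<int>& tris, int depth) {
  int id = (int)m.nodes.size();
  m.nodes.push_back(Node());
  Node& nd = m.nodes[id];
  for (int k = 0; k < 3; ++k) { nd.lo[k] = lo[k]; nd.hi[k] = hi[k]; }
  for (int k = 0; k < 8; ++k) nd.child[k] = -1;
  if ((int)tris.size() <= m.leaf_capacity || depth >= m.max_depth) {
    nd.leaf = true;
    nd.tris = tris;
    return id;
  }
  nd.leaf = false;
  double mid[3] = { 0.5 * (lo[0] + hi[0]), 0.5 * (lo[1] + hi[1]), 0.5 * (lo[2] + hi[2]) };
  for (int c = 0; c < 8; ++c) {
    double clo[3], chi[3];
    for (int k = 0; k < 3; ++k) {
      if (c & (1 << k)) { clo[k] = mid[k]; chi[k] = hi[k]; }
      else              { clo[k] = lo[k];  chi[k] = mid[k]; }
    }
    std::vector<int> sub;
    for (int f : tris) {
      double tlo[3], thi[3];
      tri_bbox(m, f, tlo, thi);
      if (box_overlap(tlo, thi, clo, chi)) sub.push_back(f);
    }
    if (sub.empty()) continue;
    if ((int)sub.size() == (int)tris.size() && depth > 0) {
      // no reduction possible; collapsing into a leaf avoids pathological splits
      m.nodes[id].leaf = true;
      m.nodes[id].tris = tris;
      for (int k = 0; k < 8; ++k) m.nodes[id].child[k] = -1;
      return id;
    }
    int cid = build_node(m, clo, chi, sub, depth + 1);
    m.nodes[id].child[c] = cid;
  }
  return id;
}

void Mesh3::build_tree(int cap, int maxd) {
  leaf_capacity = cap;
  max_depth = maxd;
  nodes.clear();
  double lo[3] = { 1e300, 1e300, 1e300 }, hi[3] = { -1e300, -1e300, -1e300 };
  int nf = (int)v0.size();
  for (int f = 0; f < nf; ++f) {
    double tlo[3], thi[3];
    tri_bbox(*this, f, tlo, thi);
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], tlo[k]);
      hi[k] = std::max(hi[k], thi[k]);
    }
  }
  for (int k = 0; k < 3; ++k) {        // small margin around the root bounds
    double pad = 1e-6 + 1e-9 * (hi[k] - lo[k]);
    lo[k] -= pad; hi[k] += pad;
  }
  std::vector<int> all(nf);
  for (int f = 0; f < nf; ++f) all[f] = f;
  build_node(*this, lo, hi, all, 0);
}

static inline bool slab(const Node& nd, const V3& o, const V3& d,
                        double& t0, double& t1) {
  t0 = 0.0; t1 = 1e300;
  const double* lo = nd.lo; const double* hi = nd.hi;
  const double ov[3] = { o.x, o.y, o.z };
  const double dv[3] = { d.x, d.y, d.z };
  for (int k = 0; k < 3; ++k) {
    if (std::fabs(dv[k]) < 1e-300) {
      if (ov[k] < lo[k] || ov[k] > hi[k]) return false;
    } else {
      double inv = 1.0 / dv[k];
      double a = (lo[k] - ov[k]) * inv, b = (hi[k] - ov[k]) * inv;
      if (a > b) std::swap(a, b);
      if (a > t0) t0 = a;
      if (b < t1) t1 = b;
      if (t0 > t1) return false;
    }
  }
  return true;
}

Hit Mesh3::nearest(const V3& o, const V3& d, double tmin) const {
  Hit best; best.face = -1; best.t = 1e300; best.u = best.v = 0;
  if (nodes.empty()) return best;
  struct El { int node; double t0; };
  std::vector<El> stack;
  stack.reserve(64);
  double t0, t1;
  if (!slab(nodes[0], o, d, t0, t1)) return best;
  stack.push_back({0, t0});
  while (!stack.empty()) {
    El e = stack.back(); stack.pop_back();
    if (e.t0 > best.t) continue;
    const Node& nd = nodes[e.node];
    if (nd.leaf) {
      for (int f : nd.tris) {
        double t, u, v;
        if (mt(f, o, d, tmin, t, u, v) && t < best.t) {
          best.t = t; best.u = u; best.v = v; best.face = f;
        }
      }
    } else {
      El kids[8]; int nk = 0;
      for (int c = 0; c < 8; ++c) {
        int cid = nd.child[c];
        if (cid < 0) continue;
        if (slab(nodes[cid], o, d, t0, t1) && t0 <= best.t)
          kids[nk++] = {cid, t0};
      }
      std::sort(kids, kids + nk, [](const El& a, const El& b) { return a.t0 > b.t0; });
      for (int i = 0; i < nk; ++i) stack.push_back(kids[i]);
    }
  }
  if (best.face < 0) best.t = NA_REAL;
  return best;
}

Hit Mesh3::nearest_brute(const V3& o, const V3& d, double tmin) const {
  Hit best; best.face = -1; best.t = 1e300; best.u = best.v = 0;
  int nf = (int)v0.size();
  for (int f = 0; f < nf; ++f) {
    double t, u, v;
    if (mt(f, o, d, tmin, t, u, v) && t < best.t) {
      best.t = t; best.u = u; best.v = v; best.face = f;
    }
  }
  if (best.face < 0) best.t = NA_REAL;
  return best;
}

// count, per mesh id, the surface crossings along the ray (t > EPS_T).
// Triangles duplicated across leaves are de-duplicated with a visit stamp.
void Mesh3::crossings(const V3& o, const V3& d, std::vector<int>& cnt) const {
  cnt.assign(n_mesh, 0);
  static thread_local std::vector<int> stamp;
  static thread_local int stamp_id = 0;
  if ((int)stamp.size() != (int)v0.size()) { stamp.assign(v0.size(), 0); stamp_id = 0; }
  ++stamp_id;
  std::vector<int> stack;
  stack.reserve(64);
  double t0, t1;
  if (nodes.empty() || !slab(nodes[0], o, d, t0, t1)) return;
  stack.push_back(0);
  while (!stack.empty()) {
    int id = stack.back(); stack.pop_back();
    const Node& nd = nodes[id];
    if (nd.leaf) {
      for (int f : nd.tris) {
        if (stamp[f] == stamp_id) continue;
        stamp[f] = stamp_id;
        double t, u, v;
        if (mt(f, o, d, EPS_T, t, u, v)) cnt[mesh_id[f]]++;
      }
    } else {
      for (int c = 0; c < 8; ++c) {
        int cid = nd.child[c];
        if (cid >= 0 && slab(nodes[cid], o, d, t0, t1)) stack.push_back(cid);
      }
    }
  }
}

// ---- mesh assembly ----------------------------------------------------------

static void fill_mesh(Mesh3& m, const NumericMatrix& verts, const IntegerMatrix& faces,
                      const IntegerVector& mesh_id, int n_mesh) {
  int nf = faces.nrow();
  m.v0.resize(nf); m.e1.resize(nf); m.e2.resize(nf); m.fn.resize(nf);
  m.mesh_id.resize(nf);
  m.n_mesh = n_mesh;
  // area-weighted vertex normals (used only when smoothing is requested)
  int nv = verts.nrow();
  std::vector<V3> vnorm(nv, V3());
  for (int f = 0; f < nf; ++f) {
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    V3 va(verts(a, 0), verts(a, 1), verts(a, 2));
    V3 vb(verts(b, 0), verts(b, 1), verts(b, 2));
    V3 vc(verts(c, 0), verts(c, 1), verts(c, 2));
    m.v0[f] = va;
    m.e1[f] = vb - va;
    m.e2[f] = vc - va;
    V3 n = cross(m.e1[f], m.e2[f]);
    m.fn[f] = unit(n);
    vnorm[a] = vnorm[a] + n; vnorm[b] = vnorm[b] + n; vnorm[c] = vnorm[c] + n;
    m.mesh_id[f] = mesh_id.size() ? mesh_id[f] - 1 : 0;
  }
  m.vn0.resize(nf); m.vn1.resize(nf); m.vn2.resize(nf);
  for (int f = 0; f < nf; ++f) {
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    m.vn0[f] = unit(vnorm[a]); m.vn1[f] = unit(vnorm[b]); m.vn2[f] = unit(vnorm[c]);
  }
}

// ---- standalone octree index (geometry module) ------------------------------

// [[Rcpp::export]]
SEXP cpp_octree_build(NumericMatrix verts, IntegerMatrix faces, IntegerVector mesh_id,
                      int leaf_capacity, int max_depth) {
  if (faces.nrow() < 1) stop("octree requires at least one triangle");
  Mesh3* m = new Mesh3();
  int nm = mesh_id.size() ? Rcpp::max(mesh_id) : 1;
  fill_mesh(*m, verts, faces, mesh_id, nm);
  m->build_tree(leaf_capacity, max_depth);
  XPtr<Mesh3> p(m, true);
  return p;
}

// [[Rcpp::export]]
List cpp_octree_stats(SEXP xp) {
  XPtr<Mesh3> m(xp);
  int n_leaf = 0, max_in_leaf = 0;
  for (const Node& nd : m->nodes)
    if (nd.leaf) { n_leaf++; max_in_leaf = std::max(max_in_leaf, (int)nd.tris.size()); }
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) { lo[k] = m->nodes[0].lo[k]; hi[k] = m->nodes[0].hi[k]; }
  return List::create(_["n_nodes"] = (int)m->nodes.size(), _["n_leaves"] = n_leaf,
                      _["max_leaf_size"] = max_in_leaf, _["n_triangles"] = (int)m->v0.size(),
                      _["root_lo"] = NumericVector::create(lo[0], lo[1], lo[2]),
                      _["root_hi"] = NumericVector::create(hi[0], hi[1], hi[2]));
}

// [[Rcpp::export]]
IntegerVector cpp_octree_query_box(SEXP xp, NumericVector lo, NumericVector hi) {
  XPtr<Mesh3> m(xp);
  double qlo[3] = { lo[0], lo[1], lo[2] }, qhi[3] = { hi[0], hi[1], hi[2] };
  std::vector<char> seen(m->v0.size(), 0);
  std::vector<int> stack;
  std::vector<int> out;
  if (m->nodes.empty()) return IntegerVector(0);
  if (box_overlap(m->nodes[0].lo, m->nodes[0].hi, qlo, qhi)) stack.push_back(0);
  while (!stack.empty()) {
    int id = stack.back(); stack.pop_back();
    const Node& nd = m->nodes[id];
    if (nd.leaf) {
      for (int f : nd.tris) {
        if (seen[f]) continue;
        seen[f] = 1;
        double tlo[3], thi[3];
        tri_bbox(*m, f, tlo, thi);
        if (box_overlap(tlo, thi, qlo, qhi)) out.push_back(f + 1);
      }
    } else {
      for (int c = 0; c < 8; ++c) {
        int cid = nd.child[c];
        if (cid >= 0 && box_overlap(m->nodes[cid].lo, m->nodes[cid].hi, qlo, qhi))
          stack.push_back(cid);
      }
    }
  }
  std::sort(out.begin(), out.end());
  return wrap(out);
}

// nearest hit per ray; brute = ignore the octree (oracle path)
// [[Rcpp::export]]
NumericMatrix cpp_intersect(SEXP xp, NumericMatrix origins, NumericMatrix dirs,
                            double tmin, bool brute) {
  XPtr<Mesh3> m(xp);
  int n = origins.nrow();
  NumericMatrix out(n, 5);  // t, u, v, face(1-based), mesh(1-based)
  colnames(out) = CharacterVector::create("t", "u", "v", "face", "mesh");
  for (int i = 0; i < n; ++i) {
    V3 o(origins(i, 0), origins(i, 1), origins(i, 2));
    V3 d(dirs(i, 0), dirs(i, 1), dirs(i, 2));
    Hit h = brute ? m->nearest_brute(o, d, tmin) : m->nearest(o, d, tmin);
    if (h.face < 0) {
      out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; out(i, 2) = NA_REAL;
      out(i, 3) = NA_REAL; out(i, 4) = NA_REAL;
    } else {
      out(i, 0) = h.t; out(i, 1) = h.u; out(i, 2) = h.v;
      out(i, 3) = h.face + 1; out(i, 4) = m->mesh_id[h.face] + 1;
    }
  }
  return out;
}

// parity crossing counts per mesh for each point (generic oblique test ray)
// [[Rcpp::export]]
IntegerMatrix cpp_crossing_counts(SEXP xp, NumericMatrix points) {
  XPtr<Mesh3> m(xp);
  V3 d = unit(V3(0.5377397, 0.2843553, 0.7949298));
  int n = points.nrow();
  IntegerMatrix out(n, m->n_mesh);
  std::vector<int> cnt;
  for (int i = 0; i < n; ++i) {
    V3 o(points(i, 0), points(i, 1), points(i, 2));
    m->crossings(o, d, cnt);
    for (int k = 0; k < m->n_mesh; ++k) out(i, k) = cnt[k];
  }
  return out;
}

// exact point-to-triangle distances (boundary tie rule support)
// [[Rcpp::export]]
NumericVector cpp_min_tri_dist(SEXP xp, NumericMatrix points) {
  XPtr<Mesh3> m(xp);
  int n = points.nrow(), nf = (int)m->v0.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    V3 p(points(i, 0), points(i, 1), points(i, 2));
    double best = 1e300;
    for (int f = 0; f < nf; ++f) {
      // Ericson-style closest point on triangle
      V3 a = m->v0[f], b = a + m->e1[f], c = a + m->e2[f];
      V3 ab = b - a, ac = c - a, ap = p - a;
      double d1 = dot(ab, ap), d2 = dot(ac, ap);
      V3 q;
      if (d1 <= 0 && d2 <= 0) q = a;
      else {
        V3 bp = p - b;
        double d3 = dot(ab, bp), d4 = dot(ac, bp);
        if (d3 >= 0 && d4 <= d3) q = b;
        else {
          double vc = d1 * d4 - d3 * d2;
          if (vc <= 0 && d1 >= 0 && d3 <= 0) q = a + ab * (d1 / (d1 - d3));
          else {
            V3 cp = p - c;
            double d5 = dot(ab, cp), d6 = dot(ac, cp);
            if (d6 >= 0 && d5 <= d6) q = c;
            else {
              double vb = d5 * d2 - d1 * d6;
              if (vb <= 0 && d2 >= 0 && d6 <= 0) q = a + ac * (d2 / (d2 - d6));
              else {
                double va = d3 * d6 - d5 * d4;
                if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
                  q = b + (c - b) * ((d4 - d3) / ((d4 - d3) + (d5 - d6)));
                else {
                  double denom = 1.0 / (va + vb + vc);
                  q = a + ab * (vb * denom) + ac * (vc * denom);
                }
              }
            }
          }
        }
      }
      best = std::min(best, norm3(p - q));
      if (best == 0) break;
    }
    out[i] = best;
  }
  return out;
}

// ---- optical scene ----------------------------------------------------------

struct Receptors {
  std::vector<V3> base, apex, axis;   // axis = unit(base - apex)
  std::vector<double> len, rb, ra, rc;
  // uniform grid hash
  double glo[3], cell;
  int gn[3];
  std::vector<std::vector<int>> cells;
  bool ready = false;

  int cell_index(int ix, int iy, int iz) const { return (iz * gn[1] + iy) * gn[0] + ix; }

  bool contains(int r, const V3& p) const {
    V3 w = p - apex[r];
    double h = dot(w, axis[r]);
    if (h < 0 || h > len[r]) return false;
    double rad2 = dot(w, w) - h * h;
    double R = ra[r] + (rb[r] - ra[r]) * h / len[r];
    if (rad2 > R * R) return false;
    if (rad2 < rc[r] * rc[r]) return false;   // non-absorbing core (strictly inside)
    return true;
  }

  int query(const V3& p, int* out, int maxn) const {
    if (!ready) return 0;
    int ix = (int)std::floor((p.x - glo[0]) / cell);
    int iy = (int)std::floor((p.y - glo[1]) / cell);
    int iz = (int)std::floor((p.z - glo[2]) / cell);
    if (ix < 0 || iy < 0 || iz < 0 || ix >= gn[0] || iy >= gn[1] || iz >= gn[2]) return 0;
    const std::vector<int>& cand = cells[cell_index(ix, iy, iz)];
    int k = 0;
    for (int r : cand) {
      if (contains(r, p)) { if (k < maxn) out[k] = r; ++k; }
    }
    return k;
  }
};

struct Scene {
  Mesh3 mesh;
  std::vector<int> role;          // per mesh: 0 refract, 1 retina, 2 absorber
  std::vector<double> nidx;       // per mesh refractive index
  std::vector<int> priority;      // per mesh; larger wins when volumes overlap
  std::vector<int> window_from;   // per mesh (retina role): mesh id allowed to enter
                                  // from (-1 = none/air only blocked, -2 = any medium)
  double n_air;
  bool smooth_normals;
  Receptors rec;
  double alpha, step;
};

// [[Rcpp::export]]
SEXP cpp_scene_build(NumericMatrix verts, IntegerMatrix faces, IntegerVector mesh_id,
                     IntegerVector role, NumericVector nidx, IntegerVector priority,
                     IntegerVector window_from, double n_air,
                     int leaf_capacity, int max_depth, bool smooth_normals) {
  Scene* sc = new Scene();
  int nm = role.size();
  fill_mesh(sc->mesh, verts, faces, mesh_id, nm);
  sc->mesh.build_tree(leaf_capacity, max_depth);
  sc->role.assign(role.begin(), role.end());
  sc->nidx.assign(nidx.begin(), nidx.end());
  sc->priority.assign(priority.begin(), priority.end());
  sc->window_from.assign(window_from.begin(), window_from.end());
  sc->n_air = n_air;
  sc->smooth_normals = smooth_normals;
  sc->alpha = 0.0;
  sc->step = 0.25;
  XPtr<Scene> p(sc, true);
  return p;
}

// [[Rcpp::export]]
void cpp_scene_set_receptors(SEXP xp, NumericMatrix base, NumericMatrix apex,
                             NumericVector rb, NumericVector ra, NumericVector rc,
                             double alpha, double step) {
  XPtr<Scene> sc(xp);
  Receptors& R = sc->rec;
  int n = base.nrow();
  R.base.resize(n); R.apex.resize(n); R.axis.resize(n);
  R.len.resize(n); R.rb.resize(n); R.ra.resize(n); R.rc.resize(n);
  double lo[3] = { 1e300, 1e300, 1e300 }, hi[3] = { -1e300, -1e300, -1e300 };
  double maxr = 0.5;
  for (int i = 0; i < n; ++i) {
    R.base[i] = V3(base(i, 0), base(i, 1), base(i, 2));
    R.apex[i] = V3(apex(i, 0), apex(i, 1), apex(i, 2));
    V3 ax = R.base[i] - R.apex[i];
    R.len[i] = norm3(ax);
    R.axis[i] = unit(ax);
    R.rb[i] = rb[i]; R.ra[i] = ra[i]; R.rc[i] = rc[i];
    double r = std::max(rb[i], ra[i]);
    maxr = std::max(maxr, r);
    double blo[3] = { std::min(R.base[i].x, R.apex[i].x) - r,
                      std::min(R.base[i].y, R.apex[i].y) - r,
                      std::min(R.base[i].z, R.apex[i].z) - r };
    double bhi[3] = { std::max(R.base[i].x, R.apex[i].x) + r,
                      std::max(R.base[i].y, R.apex[i].y) + r,
                      std::max(R.base[i].z, R.apex[i].z) + r };
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], blo[k]); hi[k] = std::max(hi[k], bhi[k]);
    }
  }
  R.cell = std::max(2.0 * maxr, 2.0);
  for (int k = 0; k < 3; ++k) {
    R.glo[k] = lo[k] - 1e-6;
    R.gn[k] = std::max(1, (int)std::ceil((hi[k] - R.glo[k]) / R.cell) + 1);
    R.gn[k] = std::min(R.gn[k], 256);
  }
  R.cells.assign((size_t)R.gn[0] * R.gn[1] * R.gn[2], {});
  for (int i = 0; i < n; ++i) {
    double r = std::max(rb[i], ra[i]);
    int i0[3], i1[3];
    double blo[3] = { std::min(R.base[i].x, R.apex[i].x) - r,
                      std::min(R.base[i].y, R.apex[i].y) - r,
                      std::min(R.base[i].z, R.apex[i].z) - r };
    double bhi[3] = { std::max(R.base[i].x, R.apex[i].x) + r,
                      std::max(R.base[i].y, R.apex[i].y) + r,
                      std::max(R.base[i].z, R.apex[i].z) + r };
    for (int k = 0; k < 3; ++k) {
      i0[k] = std::max(0, (int)std::floor((blo[k] - R.glo[k]) / R.cell));
      i1[k] = std::min(R.gn[k] - 1, (int)std::floor((bhi[k] - R.glo[k]) / R.cell));
    }
    for (int iz = i0[2]; iz <= i1[2]; ++iz)
      for (int iy = i0[1]; iy <= i1[1]; ++iy)
        for (int ix = i0[0]; ix <= i1[0]; ++ix)
          R.cells[R.cell_index(ix, iy, iz)].push_back(i);
  }
  R.ready = true;
  sc->alpha = alpha;
  sc->step = step;
}

static inline int medium_of(const Scene& sc, uint32_t mask) {
  int best = -1, bp = -1000000;
  for (int m = 0; m < (int)sc.role.size(); ++m)
    if (mask & (1u << m))
      if (sc.priority[m] > bp) { bp = sc.priority[m]; best = m; }
  return best;   // -1 = air
}

static inline double index_of(const Scene& sc, int med) {
  return med < 0 ? sc.n_air : sc.nidx[med];
}

// march Beer-Lambert absorption along [a,b]; returns remaining power,
// credits absorbed power into absorb[]
static double march_absorb(const Scene& sc, const V3& a, const V3& b, double power,
                           double* absorb, double& absorbed_total) {
  V3 seg = b - a;
  double L = norm3(seg);
  if (L <= 0 || sc.alpha <= 0 || !sc.rec.ready) return power;
  V3 d = seg * (1.0 / L);
  int nstep = (int)std::ceil(L / sc.step);
  double ds = L / nstep;
  double f = std::exp(-sc.alpha * ds);
  int ids[64];
  for (int i = 0; i < nstep; ++i) {
    double s = (i + 0.5) * ds;
    V3 mid = a + d * s;
    int k = sc.rec.query(mid, ids, 64);
    if (k > 0) {
      double dA = power * (1.0 - f);
      power *= f;
      double share = dA / k;
      int kk = std::min(k, 64);
      for (int j = 0; j < kk; ++j) absorb[ids[j]] += share;
      absorbed_total += dA;
    }
  }
  return power;
}

// trace one parallel beam through the scene.
// Returns summed per-receptor absorption (power units of the input rays),
// bookkeeping sums, and optionally full per-ray paths.
// [[Rcpp::export]]
List cpp_trace_beam(SEXP xp, NumericMatrix origins, NumericVector dir, double ray_power,
                    int max_events, bool record_paths, int tir_mode) {
  XPtr<Scene> sc(xp);
  const Scene& S = *sc;
  int n = origins.nrow();
  int nrec = (int)S.rec.base.size();
  std::vector<double> absorb(nrec, 0.0);
  double p_exit = 0, p_pigment = 0, p_lost = 0, p_absorbed = 0;
  int n_hit = 0, n_entered = 0, n_tir_term = 0, n_maxev = 0;
  List paths(record_paths ? n : 0);
  V3 d0 = unit(V3(dir[0], dir[1], dir[2]));

  for (int i = 0; i < n; ++i) {
    V3 pos(origins(i, 0), origins(i, 1), origins(i, 2));
    V3 d = d0;
    uint32_t mask = 0;
    double power = ray_power;
    bool hit_any = false, entered = false;
    int reason = 0;  // 1 exited, 2 pigment, 3 tir-terminated, 4 max-events
    std::vector<double> segrec;   // x0 y0 z0 x1 y1 z1 medium
    std::vector<double> evrec;    // t_global? face mesh kind (0 refract,1 tir,2 noop,3 terminate)
    int ev = 0;
    for (ev = 0; ev < max_events; ++ev) {
      Hit h = S.mesh.nearest(pos, d, EPS_T);
      int med = medium_of(S, mask);
      if (h.face < 0) {
        if (med >= 0 && S.role[med] == 1)   // retina medium: march to nothing? (shouldn't occur)
          power = march_absorb(S, pos, pos + d * 1e4, power, absorb.data(), p_absorbed);
        p_exit += power;
        reason = 1;
        if (record_paths) {
          V3 e = pos + d * 1e4;
          double sr[7] = { pos.x, pos.y, pos.z, e.x, e.y, e.z, (double)(med + 1) };
          segrec.insert(segrec.end(), sr, sr + 7);
        }
        break;
      }
      hit_any = true;
      V3 hp = pos + d * h.t;
      if (med >= 0 && S.role[med] == 1)
        power = march_absorb(S, pos, hp, power, absorb.data(), p_absorbed);
      if (record_paths) {
        double sr[7] = { pos.x, pos.y, pos.z, hp.x, hp.y, hp.z, (double)(med + 1) };
        segrec.insert(segrec.end(), sr, sr + 7);
      }
      int m = S.mesh.mesh_id[h.face];
      bool inside_m = (mask >> m) & 1u;
      if (S.role[m] == 2 ||                                    // absorber shell
          (S.role[m] == 1 && inside_m) ||                      // retina exit: screening pigment
          (S.role[m] == 1 && !inside_m &&
           !(S.window_from[m] == -2 || S.window_from[m] == med))) {  // pigment from outside
        p_pigment += power;
        reason = 2;
        if (record_paths) {
          double er[4] = { (double)(h.face + 1), (double)(m + 1), 3, h.t };
          evrec.insert(evrec.end(), er, er + 4);
        }
        break;
      }
      // refraction (or no-op when indices match)
      V3 nrm;
      if (S.smooth_normals) {
        V3 vn = S.mesh.vn0[h.face] * (1.0 - h.u - h.v) + S.mesh.vn1[h.face] * h.u +
                S.mesh.vn2[h.face] * h.v;
        nrm = unit(vn);
      } else {
        nrm = S.mesh.fn[h.face];
      }
      double ci = -dot(d, nrm);
      if (ci < 0) { nrm = nrm * (-1.0); ci = -ci; }
      uint32_t mask2 = mask ^ (1u << m);
      int med2 = medium_of(S, mask2);
      double n1 = index_of(S, med);
      double n2 = index_of(S, med2);
      double eta = n1 / n2;
      double k2 = 1.0 - eta * eta * (1.0 - ci * ci);
      int kind;
      if (k2 < 0) {
        if (tir_mode == 1) {
          reason = 3;
          n_tir_term++;
          p_lost += power;
          if (record_paths) {
            double er[4] = { (double)(h.face + 1), (double)(m + 1), 1, h.t };
            evrec.insert(evrec.end(), er, er + 4);
          }
          break;
        }
        d = unit(d + nrm * (2.0 * ci));   // specular reflection, medium unchanged
        kind = 1;
      } else {
        d = unit(d * eta + nrm * (eta * ci - std::sqrt(k2)));
        mask = mask2;
        kind = (n1 == n2) ? 2 : 0;
        if (med2 >= 0 && S.role[med2] == 1 && !entered) { entered = true; n_entered++; }
      }
      if (record_paths) {
        double er[4] = { (double)(h.face + 1), (double)(m + 1), (double)kind, h.t };
        evrec.insert(evrec.end(), er, er + 4);
      }
      pos = hp + d * EPS_ADV;
    }
    if (ev == max_events && reason == 0) { reason = 4; n_maxev++; p_lost += power; }
    if (hit_any) n_hit++;
    if (record_paths) {
      int ns = (int)segrec.size() / 7;
      NumericMatrix segm(ns, 7);
      for (int s = 0; s < ns; ++s)
        for (int c = 0; c < 7; ++c) segm(s, c) = segrec[s * 7 + c];
      colnames(segm) = CharacterVector::create("x0", "y0", "z0", "x1", "y1", "z1", "medium");
      int ne = (int)evrec.size() / 4;
      NumericMatrix evm(ne, 4);
      for (int s = 0; s < ne; ++s)
        for (int c = 0; c < 4; ++c) evm(s, c) = evrec[s * 4 + c];
      colnames(evm) = CharacterVector::create("face", "mesh", "kind", "t");
      paths[i] = List::create(_["segments"] = segm, _["events"] = evm,
                              _["reason"] = reason, _["power_remaining"] = power);
    }
  }
  List out = List::create(_["absorption"] = wrap(absorb), _["n_rays"] = n,
                          _["n_hit"] = n_hit, _["n_entered_retina"] = n_entered,
                          _["power_exited"] = p_exit, _["power_pigment"] = p_pigment,
                          _["power_absorbed"] = p_absorbed, _["power_lost"] = p_lost,
                          _["n_tir_terminated"] = n_tir_term, _["n_max_events"] = n_maxev);
  if (record_paths) out["paths"] = paths;
  return out;
}

// receptor shell membership for arbitrary points (exposed for the R-level op)
// [[Rcpp::export]]
List cpp_cone_membership(NumericMatrix points, NumericMatrix base, NumericMatrix apex,
                         NumericVector rb, NumericVector ra, NumericVector rc) {
  int np = points.nrow(), nr = base.nrow();
  List out(np);
  for (int i = 0; i < np; ++i) {
    V3 p(points(i, 0), points(i, 1), points(i, 2));
    std::vector<int> ids;
    for (int r = 0; r < nr; ++r) {
      V3 a(apex(r, 0), apex(r, 1), apex(r, 2));
      V3 b(base(r, 0), base(r, 1), base(r, 2));
      V3 ax = b - a;
      double L = norm3(ax);
      V3 u = ax * (1.0 / L);
      V3 w = p - a;
      double h = dot(w, u);
      if (h < 0 || h > L) continue;
      double rad2 = dot(w, w) - h * h;
      double R = ra[r] + (rb[r] - ra[r]) * h / L;
      if (rad2 > R * R) continue;
      if (rad2 < rc[r] * rc[r]) continue;
      ids.push_back(r + 1);
    }
    out[i] = wrap(ids);
  }
  return out;
}
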