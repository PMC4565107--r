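// 3D power (Laguerre) diagram by direct half-space clipping.
//
// The cell of weighted site i is the set of points p with
//   |p - c_i|^2 - w_i <= |p - c_j|^2 - w_j  for all j,
// intersected with an axis-aligned bounding box.  Each bisector is a plane
// (the radical plane), so every cell is the box polyhedron successively
// clipped by n-1 half-spaces.  Cells are convex; faces are tracked with the
// index of the neighbouring site (or a boundary marker) and their exact
// polygon area, so that face areas and cell volumes are analytic, not
// sampled.  O(n^2) overall, which is ample for the problem sizes this
// package targets (tens to a few thousand atoms).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
};

inline V3 operator-(const V3 &a, const V3 &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline V3 operator+(const V3 &a, const V3 &b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline V3 operator*(double s, const V3 &a) { return {s * a.x, s * a.y, s * a.z}; }
inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(const V3 &a, const V3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double norm(const V3 &a) { return std::sqrt(dot(a, a)); }

struct Face {
  int neighbor;            // >= 0: site index; -1..-6: box wall id
  V3 n;                    // outward unit normal
  std::vector<V3> verts;   // ordered polygon vertices
};

typedef std::vector<Face> Poly;

// Polygon area for a planar (convex) polygon via the cross-product sum.
double face_area(const std::vector<V3> &v) {
  if (v.size() < 3) return 0.0;
  V3 s = {0.0, 0.0, 0.0};
  for (size_t k = 1; k + 1 < v.size(); ++k)
    s = s + cross(v[k] - v[0], v[k + 1] - v[0]);
  return 0.5 * norm(s);
}

// Clip convex polyhedron by half-space dot(n, p) <= c.  If the plane cuts,
// a new cap face with the given neighbor id and outward normal n/|n| is
// appended.  eps is an absolute geometric tolerance.
Poly clip_halfspace(const Poly &poly, const V3 &n, double c, int neighbor, double eps) {
  double nn = norm(n);
  V3 nu = (1.0 / nn) * n;
  double cu = c / nn;  // signed-distance form: dot(nu, p) - cu

  bool any_out = false, any_in = false;
  for (const Face &f : poly)
    for (const V3 &v : f.verts) {
      double d = dot(nu, v) - cu;
      if (d > eps) any_out = true;
      if (d < -eps) any_in = true;
    }
  if (!any_out) return poly;      // plane does not cut: unchanged
  if (!any_in) return Poly();     // cell entirely removed

  Poly out;
  std::vector<V3> cap_pts;
  for (const Face &f : poly) {
    const std::vector<V3> &v = f.verts;
    size_t m = v.size();
    std::vector<V3> kept;
    kept.reserve(m + 2);
    for (size_t a = 0; a < m; ++a) {
      size_t b = (a + 1) % m;
      double da = dot(nu, v[a]) - cu;
      double db = dot(nu, v[b]) - cu;
      bool ina = da <= eps, inb = db <= eps;
      if (ina) {
        kept.push_back(v[a]);
        if (std::fabs(da) <= eps) cap_pts.push_back(v[a]);
      }
      if (ina != inb && std::fabs(da) > eps && std::fabs(db) > eps) {
        double t = da / (da - db);
        V3 p = v[a] + t * (v[b] - v[a]);
        kept.push_back(p);
        cap_pts.push_back(p);
      }
    }
    if (kept.size() >= 3 && face_area(kept) > 1e-14) {
      Face nf;
      nf.neighbor = f.neighbor;
      nf.n = f.n;
      nf.verts = std::move(kept);
      out.push_back(std::move(nf));
    }
  }

  // Build the cap polygon: dedupe collected intersection points, then order
  // them by angle around their centroid in the cutting plane.
  std::vector<V3> uniq;
  for (const V3 &p : cap_pts) {
    bool dup = false;
    for (const V3 &q : uniq)
      if (norm(p - q) < 10.0 * eps) { dup = true; break; }
    if (!dup) uniq.push_back(p);
  }
  if (uniq.size() >= 3) {
    V3 cen = {0, 0, 0};
    for (const V3 &p : uniq) cen = cen + p;
    cen = (1.0 / uniq.size()) * cen;
    // in-plane basis
    V3 ref = std::fabs(nu.x) < 0.9 ? V3{1, 0, 0} : V3{0, 1, 0};
    V3 u = cross(nu, ref);
    u = (1.0 / norm(u)) * u;
    V3 w = cross(nu, u);
    std::vector<std::pair<double, V3>> ang;
    ang.reserve(uniq.size());
    for (const V3 &p : uniq) {
      V3 d = p - cen;
      ang.push_back({std::atan2(dot(d, w), dot(d, u)), p});
    }
    std::sort(ang.begin(), ang.end(),
              [](const std::pair<double, V3> &a, const std::pair<double, V3> &b) {
                return a.first < b.first;
              });
    Face cap;
    cap.neighbor = neighbor;
    cap.n = nu;
    for (auto &pr : ang) cap.verts.push_back(pr.second);
    if (face_area(cap.verts) > 1e-14) out.push_back(std::move(cap));
  }
  return out;
}

Poly box_poly(double x0, double x1, double y0, double y1, double z0, double z1) {
  V3 v000{x0, y0, z0}, v100{x1, y0, z0}, v010{x0, y1, z0}, v110{x1, y1, z0};
  V3 v001{x0, y0, z1}, v101{x1, y0, z1}, v011{x0, y1, z1}, v111{x1, y1, z1};
  Poly p;
  p.push_back({-1, {-1, 0, 0}, {v000, v001, v011, v010}});  // x = x0
  p.push_back({-2, {1, 0, 0}, {v100, v110, v111, v101}});   // x = x1
  p.push_back({-3, {0, -1, 0}, {v000, v100, v101, v001}});  // y = y0
  p.push_back({-4, {0, 1, 0}, {v010, v011, v111, v110}});   // y = y1
  p.push_back({-5, {0, 0, -1}, {v000, v010, v110, v100}});  // z = z0
  p.push_back({-6, {0, 0, 1}, {v001, v101, v111, v011}});   // z = z1
  return p;
}

// Divergence-theorem volume: V = (1/3) sum_f area_f * dot(n_f, centroid_f),
// valid for a closed surface with outward unit normals, in absolute coords.
double poly_volume(const Poly &poly) {
  double v = 0.0;
  for (const Face &f : poly) {
    double a = face_area(f.verts);
    V3 cen = {0, 0, 0};
    for (const V3 &p : f.verts) cen = cen + p;
    cen = (1.0 / f.verts.size()) * cen;
    v += a * dot(f.n, cen);
  }
  return v / 3.0;
}

}  // namespace

// [[Rcpp::export]]
List power_cells_cpp(NumericMatrix centers, NumericVector weights, NumericVector box) {
  int n = centers.nrow();
  double diag = std::sqrt(std::pow(box[1] - box[0], 2) + std::pow(box[3] - box[2], 2) +
                          std::pow(box[5] - box[4], 2));
  double eps = 1e-10 * std::max(diag, 1.0);

  std::vector<V3> c(n);
  std::vector<double> c2(n);
  for (int i = 0; i < n; ++i) {
    c[i] = {centers(i, 0), centers(i, 1), centers(i, 2)};
    c2[i] = dot(c[i], c[i]);
  }

  List cells(n);
  for (int i = 0; i < n; ++i) {
    Poly poly = box_poly(box[0], box[1], box[2], box[3], box[4], box[5]);
    // clip nearer sites first: shrinks the cell early, later planes miss it
    std::vector<int> order;
    order.reserve(n - 1);
    for (int j = 0; j < n; ++j)
      if (j != i) order.push_back(j);
    std::sort(order.begin(), order.end(), [&](int a, int b) {
      return dot(c[a] - c[i], c[a] - c[i]) < dot(c[b] - c[i], c[b] - c[i]);
    });
    for (int j : order) {
      if (poly.empty()) break;
      // power_i(p) <= power_j(p)  <=>  dot(2(c_j - c_i), p) <= |c_j|^2 - |c_i|^2 + w_i - w_j
      V3 nrm = 2.0 * (c[j] - c[i]);
      double rhs = c2[j] - c2[i] + weights[i] - weights[j];
      poly = clip_halfspace(poly, nrm, rhs, j, eps);
    }

    int nf = (int)poly.size();
    IntegerVector nb(nf);
    NumericVector area(nf);
    for (int k = 0; k < nf; ++k) {
      nb[k] = poly[k].neighbor >= 0 ? poly[k].neighbor + 1 : poly[k].neighbor;  // 1-based sites
      area[k] = face_area(poly[k].verts);
    }
    cells[i] = List::create(_["volume"] = poly.empty() ? 0.0 : poly_volume(poly),
                            _["neighbor"] = nb, _["area"] = area);
  }
  return cells;
}
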