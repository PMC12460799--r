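// Exact 3-D Voronoi cell of one generator by half-space clipping of a
// bounding box against the bisector planes of candidate neighbors.
#include <Rcpp.h>
#include <array>
#include <vector>
#include <map>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Cell {
  std::vector<std::array<double, 3>> V;
  std::vector<std::vector<int>> faces;   // vertex index rings
  std::vector<int> src;                  // 0 = box, otherwise neighbor id
};

Cell box_cell(const double* lo, const double* hi) {
  Cell c;
  c.V = {{lo[0], lo[1], lo[2]}, {hi[0], lo[1], lo[2]},
         {hi[0], hi[1], lo[2]}, {lo[0], hi[1], lo[2]},
         {lo[0], lo[1], hi[2]}, {hi[0], lo[1], hi[2]},
         {hi[0], hi[1], hi[2]}, {lo[0], hi[1], hi[2]}};
  c.faces = {{0, 3, 2, 1}, {4, 5, 6, 7}, {0, 1, 5, 4},
             {1, 2, 6, 5}, {2, 3, 7, 6}, {3, 0, 4, 7}};
  c.src = {0, 0, 0, 0, 0, 0};
  return c;
}

// clip cell by half-space {x : nrm.x <= b}; returns false if cell empty
bool clip_cell(Cell& c, const double nrm[3], double b, int source) {
  const size_t nv = c.V.size();
  std::vector<double> s(nv);
  double smax = 1.0;
  for (size_t i = 0; i < nv; ++i) {
    s[i] = c.V[i][0] * nrm[0] + c.V[i][1] * nrm[1] + c.V[i][2] * nrm[2] - b;
    smax = std::max(smax, std::fabs(s[i]));
  }
  const double tol = 1e-9 * smax;
  bool all_keep = true, any_keep = false;
  std::vector<char> keep(nv);
  for (size_t i = 0; i < nv; ++i) {
    keep[i] = s[i] <= tol;
    all_keep = all_keep && keep[i];
    any_keep = any_keep || keep[i];
  }
  if (all_keep) return true;
  if (!any_keep) return false;

  std::map<std::pair<int, int>, int> edge_vertex;
  auto cut_edge = [&](int i, int j) -> int {
    std::pair<int, int> key = i < j ? std::make_pair(i, j)
                                    : std::make_pair(j, i);
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = s[i] / (s[i] - s[j]);
    std::array<double, 3> p;
    for (int a = 0; a < 3; ++a)
      p[a] = c.V[i][a] + t * (c.V[j][a] - c.V[i][a]);
    c.V.push_back(p);
    int id = (int)c.V.size() - 1;
    edge_vertex[key] = id;
    return id;
  };

  std::vector<std::vector<int>> new_faces;
  std::vector<int> new_src;
  std::vector<int> cut_pts;
  for (size_t f = 0; f < c.faces.size(); ++f) {
    const std::vector<int>& ring = c.faces[f];
    std::vector<int> out;
    const size_t m = ring.size();
    for (size_t e = 0; e < m; ++e) {
      int i = ring[e], j = ring[(e + 1) % m];
      if (keep[i]) out.push_back(i);
      if (keep[i] != keep[j]) {
        int id = cut_edge(i, j);
        out.push_back(id);
        cut_pts.push_back(id);
      }
    }
    if (out.size() >= 3) {
      new_faces.push_back(out);
      new_src.push_back(c.src[f]);
    }
  }
  std::sort(cut_pts.begin(), cut_pts.end());
  cut_pts.erase(std::unique(cut_pts.begin(), cut_pts.end()), cut_pts.end());
  if (cut_pts.size() >= 3) {
    // order the new planar convex face by angle about its centroid
    double ctr[3] = {0, 0, 0};
    for (int id : cut_pts)
      for (int a = 0; a < 3; ++a) ctr[a] += c.V[id][a];
    for (int a = 0; a < 3; ++a) ctr[a] /= cut_pts.size();
    double nn2 = std::sqrt(nrm[0] * nrm[0] + nrm[1] * nrm[1] +
                           nrm[2] * nrm[2]);
    double un[3] = {nrm[0] / nn2, nrm[1] / nn2, nrm[2] / nn2};
    double a1[3] = {1, 0, 0};
    if (std::fabs(un[0]) > 0.9) { a1[0] = 0; a1[1] = 1; }
    double dot = a1[0] * un[0] + a1[1] * un[1] + a1[2] * un[2];
    double e1[3] = {a1[0] - dot * un[0], a1[1] - dot * un[1],
                    a1[2] - dot * un[2]};
    double e1n = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
    for (int a = 0; a < 3; ++a) e1[a] /= e1n;
    double e2[3] = {un[1] * e1[2] - un[2] * e1[1],
                    un[2] * e1[0] - un[0] * e1[2],
                    un[0] * e1[1] - un[1] * e1[0]};
    std::vector<std::pair<double, int>> ang;
    for (int id : cut_pts) {
      double r[3] = {c.V[id][0] - ctr[0], c.V[id][1] - ctr[1],
                     c.V[id][2] - ctr[2]};
      double u = r[0] * e1[0] + r[1] * e1[1] + r[2] * e1[2];
      double v = r[0] * e2[0] + r[1] * e2[1] + r[2] * e2[2];
      ang.push_back({std::atan2(v, u), id});
    }
    std::sort(ang.begin(), ang.end());
    std::vector<int> ring;
    for (auto& a : ang) ring.push_back(a.second);
    new_faces.push_back(ring);
    new_src.push_back(source);
  }
  // compact unused vertices
  std::vector<int> remap(c.V.size(), -1);
  std::vector<std::array<double, 3>> V2;
  for (auto& ring : new_faces)
    for (int& id : ring) {
      if (remap[id] < 0) {
        remap[id] = (int)V2.size();
        V2.push_back(c.V[id]);
      }
      id = remap[id];
    }
  c.V = std::move(V2);
  c.faces = std::move(new_faces);
  c.src = std::move(new_src);
  return true;
}

double rmax2_of(const Cell& c, const double* p) {
  double r = 0;
  for (auto& v : c.V) {
    double d = (v[0] - p[0]) * (v[0] - p[0]) +
               (v[1] - p[1]) * (v[1] - p[1]) +
               (v[2] - p[2]) * (v[2] - p[2]);
    r = std::max(r, d);
  }
  return r;
}

double cell_volume(const Cell& c, const double* p) {
  double vol = 0;
  for (auto& ring : c.faces) {
    for (size_t e = 1; e + 1 < ring.size(); ++e) {
      const double* a = c.V[ring[0]].data();
      const double* b = c.V[ring[e]].data();
      const double* d = c.V[ring[e + 1]].data();
      double u[3] = {a[0] - p[0], a[1] - p[1], a[2] - p[2]};
      double v[3] = {b[0] - p[0], b[1] - p[1], b[2] - p[2]};
      double w[3] = {d[0] - p[0], d[1] - p[1], d[2] - p[2]};
      vol += std::fabs(u[0] * (v[1] * w[2] - v[2] * w[1]) -
                       u[1] * (v[0] * w[2] - v[2] * w[0]) +
                       u[2] * (v[0] * w[1] - v[1] * w[0])) / 6.0;
    }
  }
  return vol;
}

}  // namespace

// Computes the clipped Voronoi cell of pts[i0,] (1-based i0) against the
// sorted candidate neighbors cand (1-based row indices into pts, ascending
// distance cand_d). Returns volume, first-rank neighbor ids, whether the
// cell touches the bounding box, whether the early-stop rule proved the
// cell complete, and the squared max vertex distance.
// [[Rcpp::export(name = ".vor_cell_cpp")]]
List vor_cell_cpp(int i0, IntegerVector cand, NumericVector cand_d,
                  NumericMatrix pts, NumericVector lo, NumericVector hi) {
  const int nc = cand.size();
  double p[3] = {pts(i0 - 1, 0), pts(i0 - 1, 1), pts(i0 - 1, 2)};
  Cell cell = box_cell(REAL(lo), REAL(hi));
  double rmax2 = rmax2_of(cell, p);
  bool complete = false;
  for (int q = 0; q < nc; ++q) {
    if (cand_d[q] * cand_d[q] / 4.0 > rmax2) { complete = true; break; }
    int j = cand[q] - 1;
    double pj[3] = {pts(j, 0), pts(j, 1), pts(j, 2)};
    double nrm[3] = {pj[0] - p[0], pj[1] - p[1], pj[2] - p[2]};
    double b = (nrm[0] * (p[0] + pj[0]) + nrm[1] * (p[1] + pj[1]) +
                nrm[2] * (p[2] + pj[2])) / 2.0;
    if (!clip_cell(cell, nrm, b, cand[q]))
      stop("empty Voronoi cell (duplicate points?)");
    rmax2 = rmax2_of(cell, p);
  }
  if (!complete && nc > 0 &&
      cand_d[nc - 1] * cand_d[nc - 1] / 4.0 > rmax2)
    complete = true;
  std::vector<int> nb;
  bool boundary = false;
  for (int s : cell.src) {
    if (s == 0) boundary = true;
    else nb.push_back(s);
  }
  std::sort(nb.begin(), nb.end());
  nb.erase(std::unique(nb.begin(), nb.end()), nb.end());
  return List::create(_["volume"] = cell_volume(cell, p),
                      _["neighbors"] = wrap(nb),
                      _["boundary"] = boundary,
                      _["complete"] = complete,
                      _["rmax2"] = rmax2);
}
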