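// Quadric-error edge-collapse decimation for closed manifold triangle
// meshes. Collapses the cheapest valid edge (link condition + normal-flip
// guard) until the target face count is reached; each collapse on a closed
// surface removes exactly two faces.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <set>
#include <array>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

// Symmetric 4x4 quadric, upper triangle:
// [0]=aa [1]=ab [2]=ac [3]=ad [4]=bb [5]=bc [6]=bd [7]=cc [8]=cd [9]=dd
typedef std::array<double, 10> Quadric;

inline void addPlane(Quadric &q, double a, double b, double c, double d,
                     double w) {
  q[0] += w * a * a; q[1] += w * a * b; q[2] += w * a * c; q[3] += w * a * d;
  q[4] += w * b * b; q[5] += w * b * c; q[6] += w * b * d;
  q[7] += w * c * c; q[8] += w * c * d; q[9] += w * d * d;
}

inline double evalQuadric(const Quadric &q, const Vec3 &v) {
  return q[0] * v.x * v.x + 2 * q[1] * v.x * v.y + 2 * q[2] * v.x * v.z +
         2 * q[3] * v.x + q[4] * v.y * v.y + 2 * q[5] * v.y * v.z +
         2 * q[6] * v.y + q[7] * v.z * v.z + 2 * q[8] * v.z + q[9];
}

struct Cand {
  double cost;
  int u, v;
  unsigned su, sv;  // version stamps at push time
};
struct CandCmp {
  bool operator()(const Cand &a, const Cand &b) const {
    return a.cost > b.cost;
  }
};

}  // namespace

// [[Rcpp::export]]
List decimate_quadric(NumericMatrix vertices, IntegerMatrix faces,
                      int target_faces) {
  const int nv = vertices.nrow();
  const int nf = faces.nrow();
  std::vector<Vec3> V(nv);
  for (int i = 0; i < nv; ++i) {
    V[i] = {vertices(i, 0), vertices(i, 1), vertices(i, 2)};
  }
  std::vector<std::array<int, 3>> F(nf);
  std::vector<bool> faceAlive(nf, true);
  for (int i = 0; i < nf; ++i) {
    F[i] = {faces(i, 0) - 1, faces(i, 1) - 1, faces(i, 2) - 1};
  }

  std::vector<std::set<int>> vertFaces(nv);
  for (int i = 0; i < nf; ++i) {
    for (int k = 0; k < 3; ++k) vertFaces[F[i][k]].insert(i);
  }

  // initial per-vertex quadrics (area-weighted face planes)
  std::vector<Quadric> Q(nv);
  for (auto &q : Q) q.fill(0.0);
  for (int i = 0; i < nf; ++i) {
    const Vec3 &p0 = V[F[i][0]], &p1 = V[F[i][1]], &p2 = V[F[i][2]];
    Vec3 n = cross(sub(p1, p0), sub(p2, p0));
    double area2 = norm(n);
    if (area2 < 1e-300) continue;
    Vec3 un = {n.x / area2, n.y / area2, n.z / area2};
    double d = -dot(un, p0);
    double w = 0.5 * area2;
    for (int k = 0; k < 3; ++k) addPlane(Q[F[i][k]], un.x, un.y, un.z, d, w);
  }

  std::vector<unsigned> stamp(nv, 0);
  std::vector<bool> vertAlive(nv, true);

  std::priority_queue<Cand, std::vector<Cand>, CandCmp> pq;

  auto faceNormal = [&](int fi, int replace, const Vec3 &pos) -> Vec3 {
    Vec3 p[3];
    for (int k = 0; k < 3; ++k) {
      int vi = F[fi][k];
      p[k] = (vi == replace) ? pos : V[vi];
    }
    return cross(sub(p[1], p[0]), sub(p[2], p[0]));
  };

  auto pushEdge = [&](int u, int v) {
    if (u > v) std::swap(u, v);
    Quadric q;
    for (int k = 0; k < 10; ++k) q[k] = Q[u][k] + Q[v][k];
    Vec3 mid = {(V[u].x + V[v].x) / 2, (V[u].y + V[v].y) / 2,
                (V[u].z + V[v].z) / 2};
    double c = std::min({evalQuadric(q, V[u]), evalQuadric(q, V[v]),
                         evalQuadric(q, mid)});
    pq.push({c, u, v, stamp[u], stamp[v]});
  };

  {
    std::set<std::pair<int, int>> edges;
    for (int i = 0; i < nf; ++i) {
      for (int k = 0; k < 3; ++k) {
        int a = F[i][k], b = F[i][(k + 1) % 3];
        edges.insert({std::min(a, b), std::max(a, b)});
      }
    }
    for (const auto &e : edges) pushEdge(e.first, e.second);
  }

  int alive = nf;
  while (alive > target_faces && !pq.empty()) {
    Cand c = pq.top();
    pq.pop();
    int u = c.u, v = c.v;
    if (!vertAlive[u] || !vertAlive[v]) continue;
    if (stamp[u] != c.su || stamp[v] != c.sv) continue;

    // faces sharing the edge
    std::vector<int> shared;
    for (int f : vertFaces[u]) {
      if (vertFaces[v].count(f)) shared.push_back(f);
    }
    if (shared.size() != 2) continue;  // boundary or non-manifold: skip

    // link condition: common vertex neighbours of u and v must be exactly
    // the two vertices opposite the shared edge
    std::set<int> nu, nvv;
    for (int f : vertFaces[u]) {
      for (int k = 0; k < 3; ++k) {
        if (F[f][k] != u) nu.insert(F[f][k]);
      }
    }
    for (int f : vertFaces[v]) {
      for (int k = 0; k < 3; ++k) {
        if (F[f][k] != v) nvv.insert(F[f][k]);
      }
    }
    std::vector<int> common;
    std::set_intersection(nu.begin(), nu.end(), nvv.begin(), nvv.end(),
                          std::back_inserter(common));
    std::set<int> opposite;
    for (int f : shared) {
      for (int k = 0; k < 3; ++k) {
        if (F[f][k] != u && F[f][k] != v) opposite.insert(F[f][k]);
      }
    }
    if (common.size() != 2 || opposite.size() != 2) continue;
    if (!opposite.count(common[0]) || !opposite.count(common[1])) continue;

    // choose collapse position among {u, v, midpoint}, requiring no
    // triangle-normal flip in the one-ring
    Quadric q;
    for (int k = 0; k < 10; ++k) q[k] = Q[u][k] + Q[v][k];
    Vec3 mid = {(V[u].x + V[v].x) / 2, (V[u].y + V[v].y) / 2,
                (V[u].z + V[v].z) / 2};
    std::array<Vec3, 3> cands = {mid, V[u], V[v]};
    std::array<double, 3> costs;
    for (int k = 0; k < 3; ++k) costs[k] = evalQuadric(q, cands[k]);
    std::array<int, 3> ord = {0, 1, 2};
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return costs[a] < costs[b]; });

    bool done = false;
    for (int oi : ord) {
      const Vec3 &pos = cands[oi];
      bool flip = false;
      for (int w : {u, v}) {
        for (int f : vertFaces[w]) {
          if (std::find(shared.begin(), shared.end(), f) != shared.end()) {
            continue;
          }
          Vec3 n0 = faceNormal(f, -1, pos);  // current normal
          Vec3 n1;
          {
            Vec3 p[3];
            for (int k = 0; k < 3; ++k) {
              int vi = F[f][k];
              p[k] = (vi == u || vi == v) ? pos : V[vi];
            }
            n1 = cross(sub(p[1], p[0]), sub(p[2], p[0]));
          }
          if (dot(n0, n1) <= 0 || norm(n1) < 1e-14) {
            flip = true;
            break;
          }
        }
        if (flip) break;
      }
      if (flip) continue;

      // perform collapse: v merges into u at pos
      V[u] = pos;
      for (int k = 0; k < 10; ++k) Q[u][k] += Q[v][k];
      for (int f : shared) {
        faceAlive[f] = false;
        for (int k = 0; k < 3; ++k) vertFaces[F[f][k]].erase(f);
        --alive;
      }
      std::vector<int> vfaces(vertFaces[v].begin(), vertFaces[v].end());
      for (int f : vfaces) {
        for (int k = 0; k < 3; ++k) {
          if (F[f][k] == v) F[f][k] = u;
        }
        vertFaces[v].erase(f);
        vertFaces[u].insert(f);
      }
      vertAlive[v] = false;
      ++stamp[u];
      ++stamp[v];
      // re-seed edges around u
      std::set<int> nbrs;
      for (int f : vertFaces[u]) {
        for (int k = 0; k < 3; ++k) {
          if (F[f][k] != u) nbrs.insert(F[f][k]);
        }
      }
      for (int w : nbrs) pushEdge(u, w);
      done = true;
      break;
    }
    (void)done;
  }

  // compact output
  std::vector<int> vmap(nv, -1);
  int nvOut = 0;
  std::vector<std::array<int, 3>> fOut;
  fOut.reserve(alive);
  for (int i = 0; i < nf; ++i) {
    if (!faceAlive[i]) continue;
    for (int k = 0; k < 3; ++k) {
      if (vmap[F[i][k]] < 0) vmap[F[i][k]] = nvOut++;
    }
    fOut.push_back(F[i]);
  }
  NumericMatrix vOut(nvOut, 3);
  for (int i = 0; i < nv; ++i) {
    if (vmap[i] >= 0) {
      vOut(vmap[i], 0) = V[i].x;
      vOut(vmap[i], 1) = V[i].y;
      vOut(vmap[i], 2) = V[i].z;
    }
  }
  IntegerMatrix fMat(static_cast<int>(fOut.size()), 3);
  for (size_t i = 0; i < fOut.size(); ++i) {
    for (int k = 0; k < 3; ++k) fMat(i, k) = vmap[fOut[i][k]] + 1;
  }
  return List::create(Named("vertices") = vOut, Named("faces") = fMat);
}

// Even-odd point-in-polygon test for many points against one polygon.
// [[Rcpp::export]]
LogicalVector points_in_polygon(NumericVector px, NumericVector py,
                                NumericVector polyx, NumericVector polyy) {
  const int np = px.size();
  const int nv = polyx.size();
  LogicalVector out(np);
  for (int i = 0; i < np; ++i) {
    const double x = px[i], y = py[i];
    bool inside = false;
    for (int j = 0, k = nv - 1; j < nv; k = j++) {
      if (((polyy[j] > y) != (polyy[k] > y)) &&
          (x < (polyx[k] - polyx[j]) * (y - polyy[j]) /
                       (polyy[k] - polyy[j]) +
                   polyx[j])) {
        inside = !inside;
      }
    }
    out[i] = inside;
  }
  return out;
}
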