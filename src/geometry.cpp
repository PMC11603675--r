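#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <algorithm>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Iso-surface extraction by marching tetrahedra.
//
// Each grid cell is split into the six tetrahedra sharing the main diagonal
// (corner 0 -> corner 6); the decomposition is identical in every cell, so
// shared cube faces receive matching diagonals and the resulting surface is
// watertight wherever the iso-surface closes inside the grid. Surface
// vertices are linearly interpolated on crossing edges and deduplicated by
// global edge id, triangles are wound so normals point toward the low-value
// side (outside the segmented structure).
// ---------------------------------------------------------------------------

static const int CUBE_OFF[8][3] = {
  {0,0,0}, {1,0,0}, {1,1,0}, {0,1,0},
  {0,0,1}, {1,0,1}, {1,1,1}, {0,1,1}
};

static const int TETS[6][4] = {
  {0,1,2,6}, {0,2,3,6}, {0,3,7,6},
  {0,7,4,6}, {0,4,5,6}, {0,5,1,6}
};

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

static inline uint64_t edge_key(uint64_t a, uint64_t b) {
  if (a > b) std::swap(a, b);
  return (a << 32) | b;
}

// [[Rcpp::export(name = ".cpp_marching_tets")]]
List cpp_marching_tets(NumericVector values, IntegerVector dim,
                       NumericVector spacing, NumericVector origin,
                       double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double *v = REAL(values);
  const double eps = 1e-6 * (1.0 + std::abs(iso));

  MTState st;
  st.vx.reserve(1 << 16); st.f0.reserve(1 << 16);

  std::vector<double> cv(8);
  std::vector<uint64_t> gid(8);
  double px[8], py[8], pz[8];

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + CUBE_OFF[c][0];
          int cj = j + CUBE_OFF[c][1];
          int ck = k + CUBE_OFF[c][2];
          uint64_t g = (uint64_t)ci + (uint64_t)nx * ((uint64_t)cj + (uint64_t)ny * ck);
          gid[c] = g;
          double val = v[g];
          // nudge values landing exactly on the iso level off it, so edge
          // interpolation never produces coincident (degenerate) vertices
          if (val == iso) val = iso + eps;
          cv[c] = val;
          px[c] = ox + sx * ci;
          py[c] = oy + sy * cj;
          pz[c] = oz + sz * ck;
          if (val >= iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          int tc[4] = {TETS[t][0], TETS[t][1], TETS[t][2], TETS[t][3]};
          int ins[4], nin = 0, outs[4], nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (cv[tc[c]] >= iso) ins[nin++] = tc[c];
            else outs[nout++] = tc[c];
          }
          if (nin == 0 || nin == 4) continue;

          // interpolated vertex on edge (a inside, b outside)
          auto evert = [&](int a, int b) -> int {
            uint64_t key = edge_key(gid[a], gid[b]);
            auto it = st.edge_vertex.find(key);
            if (it != st.edge_vertex.end()) return it->second;
            double va = cv[a], vb = cv[b];
            double tt = (iso - va) / (vb - va);
            if (tt < 0.0) tt = 0.0;
            if (tt > 1.0) tt = 1.0;
            int id = (int)st.vx.size();
            st.vx.push_back(px[a] + tt * (px[b] - px[a]));
            st.vy.push_back(py[a] + tt * (py[b] - py[a]));
            st.vz.push_back(pz[a] + tt * (pz[b] - pz[a]));
            st.edge_vertex.emplace(key, id);
            return id;
          };

          // emit triangle wound so its normal points away from the inside
          auto emit = [&](int a, int b, int c) {
            double ax = st.vx[a], ay = st.vy[a], az = st.vz[a];
            double b1 = st.vx[b] - ax, b2 = st.vy[b] - ay, b3 = st.vz[b] - az;
            double c1 = st.vx[c] - ax, c2 = st.vy[c] - ay, c3 = st.vz[c] - az;
            double n1 = b2 * c3 - b3 * c2;
            double n2 = b3 * c1 - b1 * c3;
            double n3 = b1 * c2 - b2 * c1;
            double a2 = n1 * n1 + n2 * n2 + n3 * n3;
            if (a2 < 1e-24) return; // degenerate sliver, skip
            double qx = 0, qy = 0, qz = 0;
            for (int m = 0; m < nin; ++m) {
              qx += px[ins[m]]; qy += py[ins[m]]; qz += pz[ins[m]];
            }
            qx /= nin; qy /= nin; qz /= nin;
            double gx = (st.vx[a] + st.vx[b] + st.vx[c]) / 3.0;
            double gy = (st.vy[a] + st.vy[b] + st.vy[c]) / 3.0;
            double gz = (st.vz[a] + st.vz[b] + st.vz[c]) / 3.0;
            double d = n1 * (qx - gx) + n2 * (qy - gy) + n3 * (qz - gz);
            if (d > 0) { st.f0.push_back(a); st.f1.push_back(c); st.f2.push_back(b); }
            else       { st.f0.push_back(a); st.f1.push_back(b); st.f2.push_back(c); }
          };

          if (nin == 1) {
            emit(evert(ins[0], outs[0]), evert(ins[0], outs[1]), evert(ins[0], outs[2]));
          } else if (nin == 3) {
            emit(evert(ins[0], outs[0]), evert(ins[1], outs[0]), evert(ins[2], outs[0]));
          } else { // 2 in, 2 out -> quad as two triangles
            int e1 = evert(ins[0], outs[0]);
            int e2 = evert(ins[0], outs[1]);
            int e3 = evert(ins[1], outs[1]);
            int e4 = evert(ins[1], outs[0]);
            emit(e1, e2, e3);
            emit(e1, e3, e4);
          }
        }
      }
    }
  }

  int nv = (int)st.vx.size(), nf = (int)st.f0.size();
  NumericMatrix V(nv, 3);
  for (int m = 0; m < nv; ++m) { V(m,0) = st.vx[m]; V(m,1) = st.vy[m]; V(m,2) = st.vz[m]; }
  IntegerMatrix F(nf, 3);
  for (int m = 0; m < nf; ++m) { F(m,0) = st.f0[m]+1; F(m,1) = st.f1[m]+1; F(m,2) = st.f2[m]+1; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// 26-connected component labelling of a 3D logical mask (BFS flood fill).
// Labels are 1..n in decreasing order of component size; background is 0.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> lab(n, 0);
  std::vector<R_xlen_t> sizes_idx; // component sizes in discovery order
  std::vector<R_xlen_t> queue_buf;
  int next = 0;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    R_xlen_t size = 0;
    queue_buf.clear();
    queue_buf.push_back(s);
    lab[s] = next;
    while (!queue_buf.empty()) {
      R_xlen_t cur = queue_buf.back();
      queue_buf.pop_back();
      ++size;
      int ci = (int)(cur % nx);
      int cj = (int)((cur / nx) % ny);
      int ck = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk) {
        int zk = ck + dk; if (zk < 0 || zk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int yj = cj + dj; if (yj < 0 || yj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int xi = ci + di; if (xi < 0 || xi >= nx) continue;
            R_xlen_t nb = (R_xlen_t)xi + (R_xlen_t)nx * ((R_xlen_t)yj + (R_xlen_t)ny * zk);
            if (mask[nb] && !lab[nb]) { lab[nb] = next; queue_buf.push_back(nb); }
          }
        }
      }
    }
    sizes_idx.push_back(size);
  }

  // relabel so that 1 = largest component
  std::vector<int> order(next);
  for (int m = 0; m < next; ++m) order[m] = m;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    return sizes_idx[a] > sizes_idx[b];
  });
  std::vector<int> remap(next + 1, 0);
  for (int m = 0; m < next; ++m) remap[order[m] + 1] = m + 1;

  IntegerVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = remap[lab[s]];
  return out;
}

// ---------------------------------------------------------------------------
// Ray casting against a triangle soup with a median-split AABB BVH and
// Moller-Trumbore intersection. Returns the nearest hit (distance and face
// index) per ray, or a miss flag.
// ---------------------------------------------------------------------------

struct BVHNode {
  double bmin[3], bmax[3];
  int left, right;     // child node indices, -1 for leaf
  int begin, end;      // triangle index range for leaves
};

struct BVH {
  std::vector<BVHNode> nodes;
  std::vector<int> tri_order;
  const double *vx;
  const int *fa, *fb, *fc;
  int nv, nf;
  std::vector<double> cx, cy, cz; // centroids
  std::vector<double> tbmin, tbmax; // per-tri bounds, 3*nf each

  double vert(int vi, int axis) const { return vx[vi + nv * axis]; }

  void tri_bounds(int t, double *bmin, double *bmax) const {
    for (int a = 0; a < 3; ++a) {
      bmin[a] = tbmin[3 * t + a];
      bmax[a] = tbmax[3 * t + a];
    }
  }

  int build(int begin, int end) {
    BVHNode node;
    for (int a = 0; a < 3; ++a) { node.bmin[a] = R_PosInf; node.bmax[a] = R_NegInf; }
    for (int m = begin; m < end; ++m) {
      int t = tri_order[m];
      for (int a = 0; a < 3; ++a) {
        node.bmin[a] = std::min(node.bmin[a], tbmin[3 * t + a]);
        node.bmax[a] = std::max(node.bmax[a], tbmax[3 * t + a]);
      }
    }
    int id = (int)nodes.size();
    nodes.push_back(node);
    if (end - begin <= 8) {
      nodes[id].left = nodes[id].right = -1;
      nodes[id].begin = begin; nodes[id].end = end;
      return id;
    }
    // split on largest extent of centroids
    double cmin[3] = {R_PosInf, R_PosInf, R_PosInf};
    double cmax[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int m = begin; m < end; ++m) {
      int t = tri_order[m];
      double c[3] = {cx[t], cy[t], cz[t]};
      for (int a = 0; a < 3; ++a) {
        cmin[a] = std::min(cmin[a], c[a]);
        cmax[a] = std::max(cmax[a], c[a]);
      }
    }
    int axis = 0;
    double ext = cmax[0] - cmin[0];
    for (int a = 1; a < 3; ++a)
      if (cmax[a] - cmin[a] > ext) { ext = cmax[a] - cmin[a]; axis = a; }
    int mid = (begin + end) / 2;
    if (ext <= 0) {
      nodes[id].left = nodes[id].right = -1;
      nodes[id].begin = begin; nodes[id].end = end;
      return id;
    }
    const std::vector<double> &cc = (axis == 0 ? cx : (axis == 1 ? cy : cz));
    std::nth_element(tri_order.begin() + begin, tri_order.begin() + mid,
                     tri_order.begin() + end,
                     [&](int a, int b) { return cc[a] < cc[b]; });
    int l = build(begin, mid);
    int r = build(mid, end);
    nodes[id].left = l; nodes[id].right = r;
    nodes[id].begin = nodes[id].end = -1;
    return id;
  }
};

static inline bool slab_hit(const BVHNode &nd, const double *o,
                            const double *inv_d, double tmax) {
  double t0 = 0.0, t1 = tmax;
  for (int a = 0; a < 3; ++a) {
    double ta = (nd.bmin[a] - o[a]) * inv_d[a];
    double tb = (nd.bmax[a] - o[a]) * inv_d[a];
    if (ta > tb) std::swap(ta, tb);
    if (ta > t0) t0 = ta;
    if (tb < t1) t1 = tb;
    if (t0 > t1) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".cpp_ray_cast")]]
List cpp_ray_cast(NumericMatrix vertices, IntegerMatrix faces,
                  NumericMatrix origins, NumericMatrix directions,
                  double max_dist, double min_dist) {
  const int nf = faces.nrow();
  const int nr = origins.nrow();
  NumericVector tout(nr, NA_REAL);
  IntegerVector fout(nr, NA_INTEGER);
  LogicalVector hit(nr, false);
  if (nf == 0) {
    return List::create(_["hit"] = hit, _["distance"] = tout, _["face"] = fout);
  }

  BVH bvh;
  bvh.vx = REAL(vertices);
  bvh.nv = vertices.nrow();
  bvh.nf = nf;
  std::vector<int> A(nf), B(nf), C(nf);
  for (int t = 0; t < nf; ++t) {
    A[t] = faces(t,0) - 1; B[t] = faces(t,1) - 1; C[t] = faces(t,2) - 1;
  }
  bvh.cx.resize(nf); bvh.cy.resize(nf); bvh.cz.resize(nf);
  bvh.tbmin.resize(3 * (size_t)nf); bvh.tbmax.resize(3 * (size_t)nf);
  for (int t = 0; t < nf; ++t) {
    for (int a = 0; a < 3; ++a) {
      double v0 = bvh.vert(A[t], a), v1 = bvh.vert(B[t], a), v2 = bvh.vert(C[t], a);
      bvh.tbmin[3*t+a] = std::min(v0, std::min(v1, v2)) - 1e-9;
      bvh.tbmax[3*t+a] = std::max(v0, std::max(v1, v2)) + 1e-9;
    }
    bvh.cx[t] = (bvh.vert(A[t],0) + bvh.vert(B[t],0) + bvh.vert(C[t],0)) / 3.0;
    bvh.cy[t] = (bvh.vert(A[t],1) + bvh.vert(B[t],1) + bvh.vert(C[t],1)) / 3.0;
    bvh.cz[t] = (bvh.vert(A[t],2) + bvh.vert(B[t],2) + bvh.vert(C[t],2)) / 3.0;
  }
  bvh.tri_order.resize(nf);
  for (int t = 0; t < nf; ++t) bvh.tri_order[t] = t;
  bvh.nodes.reserve(2 * nf / 8 + 16);
  bvh.build(0, nf);

  std::vector<int> stack;
  stack.reserve(64);

  for (int r = 0; r < nr; ++r) {
    double o[3] = {origins(r,0), origins(r,1), origins(r,2)};
    double d[3] = {directions(r,0), directions(r,1), directions(r,2)};
    double inv_d[3];
    for (int a = 0; a < 3; ++a)
      inv_d[a] = (d[a] != 0.0) ? 1.0 / d[a] : (d[a] >= 0 ? R_PosInf : R_NegInf);
    double best = max_dist;
    int best_f = -1;
    stack.clear();
    stack.push_back(0);
    while (!stack.empty()) {
      int ni = stack.back(); stack.pop_back();
      const BVHNode &nd = bvh.nodes[ni];
      if (!slab_hit(nd, o, inv_d, best)) continue;
      if (nd.left < 0) {
        for (int m = nd.begin; m < nd.end; ++m) {
          int t = bvh.tri_order[m];
          // Moller-Trumbore
          double e1[3], e2[3];
          for (int a = 0; a < 3; ++a) {
            e1[a] = bvh.vert(B[t],a) - bvh.vert(A[t],a);
            e2[a] = bvh.vert(C[t],a) - bvh.vert(A[t],a);
          }
          double pv[3] = {
            d[1]*e2[2] - d[2]*e2[1],
            d[2]*e2[0] - d[0]*e2[2],
            d[0]*e2[1] - d[1]*e2[0]
          };
          double det = e1[0]*pv[0] + e1[1]*pv[1] + e1[2]*pv[2];
          if (std::abs(det) < 1e-14) continue;
          double inv = 1.0 / det;
          double tv[3] = {
            o[0] - bvh.vert(A[t],0),
            o[1] - bvh.vert(A[t],1),
            o[2] - bvh.vert(A[t],2)
          };
          double u = (tv[0]*pv[0] + tv[1]*pv[1] + tv[2]*pv[2]) * inv;
          if (u < -1e-9 || u > 1 + 1e-9) continue;
          double qv[3] = {
            tv[1]*e1[2] - tv[2]*e1[1],
            tv[2]*e1[0] - tv[0]*e1[2],
            tv[0]*e1[1] - tv[1]*e1[0]
          };
          double vv = (d[0]*qv[0] + d[1]*qv[1] + d[2]*qv[2]) * inv;
          if (vv < -1e-9 || u + vv > 1 + 1e-9) continue;
          double tt = (e2[0]*qv[0] + e2[1]*qv[1] + e2[2]*qv[2]) * inv;
          if (tt > min_dist && tt < best) { best = tt; best_f = t; }
        }
      } else {
        stack.push_back(nd.left);
        stack.push_back(nd.right);
      }
    }
    if (best_f >= 0) {
      hit[r] = true;
      tout[r] = best;
      fout[r] = best_f + 1;
    }
  }
  return List::create(_["hit"] = hit, _["distance"] = tout, _["face"] = fout);
}
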