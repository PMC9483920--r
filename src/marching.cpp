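// Iso-surface extraction from a regular scalar grid by marching tetrahedra
// (Kuhn subdivision of each cube into 6 tetrahedra).  Vertices are keyed by
// the grid edge they interpolate on, so shared vertices are welded and the
// mesh is watertight for level sets fully inside the grid; that makes the
// Euler characteristic (and hence genus) of the triangulation meaningful.
#include <Rcpp.h>
#include <map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct MeshBuilder {
  std::map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri; // triplets of 0-based vertex ids

  const double *val;
  double iso, ox, oy, oz, h;
  int nx, ny, nz;

  int gid(int i, int j, int k) const { return (k * ny + j) * nx + i; }
  double f(int g) const { return val[g]; }
  void coords(int g, double &px, double &py, double &pz) const {
    int i = g % nx, j = (g / nx) % ny, k = g / (nx * ny);
    px = ox + i * h; py = oy + j * h; pz = oz + k * h;
  }

  int edge_point(int ga, int gb) {
    if (ga > gb) std::swap(ga, gb);
    uint64_t key = ((uint64_t)ga << 32) | (uint64_t)gb;
    std::map<uint64_t, int>::iterator it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double fa = f(ga), fb = f(gb);
    double t = (iso - fa) / (fb - fa);
    if (t < 0) t = 0; if (t > 1) t = 1;
    double ax, ay, az, bx, by, bz;
    coords(ga, ax, ay, az);
    coords(gb, bx, by, bz);
    int id = (int)vx.size();
    vx.push_back(ax + t * (bx - ax));
    vy.push_back(ay + t * (by - ay));
    vz.push_back(az + t * (bz - az));
    edge_vertex[key] = id;
    return id;
  }

  void do_tet(int g0, int g1, int g2, int g3) {
    int g[4] = {g0, g1, g2, g3};
    int above = 0, idxA[4], idxB[4], na = 0, nb = 0;
    for (int a = 0; a < 4; ++a) {
      if (f(g[a]) > iso) { idxA[na++] = g[a]; ++above; }
      else idxB[nb++] = g[a];
    }
    if (above == 0 || above == 4) return;
    if (above == 1 || above == 3) {
      // one isolated vertex: triangle on the three edges leaving it
      int apex = (above == 1) ? idxA[0] : idxB[0];
      int *base = (above == 1) ? idxB : idxA;
      int p0 = edge_point(apex, base[0]);
      int p1 = edge_point(apex, base[1]);
      int p2 = edge_point(apex, base[2]);
      if (p0 != p1 && p1 != p2 && p0 != p2) {
        tri.push_back(p0); tri.push_back(p1); tri.push_back(p2);
      }
    } else {
      // 2-2 split: quad on the four crossing edges -> two triangles
      int p00 = edge_point(idxA[0], idxB[0]);
      int p01 = edge_point(idxA[0], idxB[1]);
      int p10 = edge_point(idxA[1], idxB[0]);
      int p11 = edge_point(idxA[1], idxB[1]);
      if (p00 != p01 && p01 != p10 && p00 != p10) {
        tri.push_back(p00); tri.push_back(p01); tri.push_back(p10);
      }
      if (p01 != p11 && p11 != p10 && p01 != p10) {
        tri.push_back(p01); tri.push_back(p11); tri.push_back(p10);
      }
    }
  }
};

} // namespace

// [[Rcpp::export]]
List marching_tetrahedra_cpp(NumericVector values, IntegerVector dim,
                             double iso, NumericVector origin, double spacing) {
  MeshBuilder mb;
  mb.val = values.begin();
  mb.iso = iso;
  mb.nx = dim[0]; mb.ny = dim[1]; mb.nz = dim[2];
  mb.ox = origin[0]; mb.oy = origin[1]; mb.oz = origin[2];
  mb.h = spacing;

  // Kuhn subdivision: six tetrahedra along the 6 monotone corner paths
  static const int perms[6][3] = {
    {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};

  for (int k = 0; k + 1 < mb.nz; ++k)
    for (int j = 0; j + 1 < mb.ny; ++j)
      for (int i = 0; i + 1 < mb.nx; ++i) {
        int base[3] = {i, j, k};
        for (int p = 0; p < 6; ++p) {
          int c[4][3];
          for (int a = 0; a < 3; ++a) c[0][a] = base[a];
          for (int step = 0; step < 3; ++step) {
            for (int a = 0; a < 3; ++a) c[step + 1][a] = c[step][a];
            c[step + 1][perms[p][step]] += 1;
          }
          mb.do_tet(mb.gid(c[0][0], c[0][1], c[0][2]),
                    mb.gid(c[1][0], c[1][1], c[1][2]),
                    mb.gid(c[2][0], c[2][1], c[2][2]),
                    mb.gid(c[3][0], c[3][1], c[3][2]));
        }
      }

  int nv = (int)mb.vx.size();
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; ++i) {
    verts(i, 0) = mb.vx[i]; verts(i, 1) = mb.vy[i]; verts(i, 2) = mb.vz[i];
  }
  int nt = (int)mb.tri.size() / 3;
  IntegerMatrix tris(nt, 3);
  for (int t = 0; t < nt; ++t) {
    tris(t, 0) = mb.tri[3 * t] + 1;     // 1-based for R
    tris(t, 1) = mb.tri[3 * t + 1] + 1;
    tris(t, 2) = mb.tri[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["triangles"] = tris);
}
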