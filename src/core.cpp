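#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// ---------------------------------------------------------------------------
// 3D connected-component labelling (26-connectivity), BFS flood fill.
// mask: integer/logical vector of length nx*ny*nz. Returns integer labels
// (0 = background, components numbered from 1).
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, int nx, int ny, int nz) {
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::queue<int> q;
  for (int z0 = 0; z0 < nz; ++z0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int x0 = 0; x0 < nx; ++x0) {
        int i0 = idx3(x0, y0, z0, nx, ny);
        if (!mask[i0] || lab[i0]) continue;
        ++next;
        lab[i0] = next;
        q.push(i0);
        while (!q.empty()) {
          int i = q.front(); q.pop();
          int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dx && !dy && !dz) continue;
                int xx = x + dx, yy = y + dy, zz = z + dz;
                if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
                  continue;
                int j = idx3(xx, yy, zz, nx, ny);
                if (mask[j] && !lab[j]) { lab[j] = next; q.push(j); }
              }
        }
      }
  lab.attr("n") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// 3-4-5 chamfer distance transform to the background, in units of
// voxels (divided by 3 at the end). Two-pass.
// [[Rcpp::export]]
NumericVector cpp_chamfer_dt(LogicalVector mask, int nx, int ny, int nz) {
  const double BIG = 1e9;
  std::vector<double> d(mask.size());
  for (int i = 0; i < (int)mask.size(); ++i) d[i] = mask[i] ? BIG : 0.0;
  // neighbour offsets with chamfer weights (face 3, edge 4, corner 5)
  struct Off { int dx, dy, dz; double w; };
  std::vector<Off> fwd;
  for (int dz = -1; dz <= 0; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && (dy > 0 || (dy == 0 && dx >= 0))) continue;
        int a = std::abs(dx) + std::abs(dy) + std::abs(dz);
        fwd.push_back({dx, dy, dz, a == 1 ? 3.0 : (a == 2 ? 4.0 : 5.0)});
      }
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (d[i] == 0) continue;
        for (auto &o : fwd) {
          int xx = x + o.dx, yy = y + o.dy, zz = z + o.dz;
          double nb = (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
                        ? 0.0 : d[idx3(xx, yy, zz, nx, ny)];
          if (nb + o.w < d[i]) d[i] = nb + o.w;
        }
      }
  for (int z = nz - 1; z >= 0; --z)
    for (int y = ny - 1; y >= 0; --y)
      for (int x = nx - 1; x >= 0; --x) {
        int i = idx3(x, y, z, nx, ny);
        if (d[i] == 0) continue;
        for (auto &o : fwd) {
          int xx = x - o.dx, yy = y - o.dy, zz = z - o.dz;
          double nb = (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
                        ? 0.0 : d[idx3(xx, yy, zz, nx, ny)];
          if (nb + o.w < d[i]) d[i] = nb + o.w;
        }
      }
  NumericVector out(mask.size());
  for (int i = 0; i < (int)mask.size(); ++i) out[i] = d[i] / 3.0;
  return out;
}

// ---------------------------------------------------------------------------
// Simple-point test (Bertrand & Malandain): a foreground voxel is simple iff
//   (a) its 26-neighbourhood foreground (centre removed) has exactly one
//       26-connected component, and
//   (b) the background within its 18-neighbourhood has exactly one
//       6-connected component that is 6-adjacent to the centre.
static bool is_simple(const std::vector<char> &fg, int x, int y, int z,
                      int nx, int ny, int nz) {
  char nb[27];
  int n = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        bool v = !(xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
                   && fg[idx3(xx, yy, zz, nx, ny)];
        nb[n++] = v ? 1 : 0;
      }
  nb[13] = 0; // remove centre
  // (a) count 26-CC of foreground among 26 neighbours
  int comp = 0;
  char seen[27] = {0};
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comp;
    if (comp > 1) return false;
    std::queue<int> q; q.push(s); seen[s] = 1;
    while (!q.empty()) {
      int i = q.front(); q.pop();
      int ix = i % 3, iy = (i / 3) % 3, iz = i / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int jx = ix + dx, jy = iy + dy, jz = iz + dz;
            if (jx < 0 || jy < 0 || jz < 0 || jx > 2 || jy > 2 || jz > 2) continue;
            int j = jx + 3 * jy + 9 * jz;
            if (j == 13 || !nb[j] || seen[j]) continue;
            seen[j] = 1; q.push(j);
          }
    }
  }
  if (comp != 1) return false;
  // (b) 6-CC of background in the 18-neighbourhood, 6-adjacent to centre
  auto in18 = [](int ix, int iy, int iz) {
    int a = std::abs(ix - 1) + std::abs(iy - 1) + std::abs(iz - 1);
    return a >= 1 && a <= 2;
  };
  char seenb[27] = {0};
  int compb = 0;
  // seeds: the six face neighbours that are background
  const int faces[6] = {4, 10, 12, 14, 16, 22};
  for (int fi = 0; fi < 6; ++fi) {
    int s = faces[fi];
    if (nb[s] || seenb[s]) continue;
    ++compb;
    if (compb > 1) return false;
    std::queue<int> q; q.push(s); seenb[s] = 1;
    while (!q.empty()) {
      int i = q.front(); q.pop();
      int ix = i % 3, iy = (i / 3) % 3, iz = i / 9;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int kk = 0; kk < 6; ++kk) {
        int jx = ix + d6[kk][0], jy = iy + d6[kk][1], jz = iz + d6[kk][2];
        if (jx < 0 || jy < 0 || jz < 0 || jx > 2 || jy > 2 || jz > 2) continue;
        if (!in18(jx, jy, jz)) continue;
        int j = jx + 3 * jy + 9 * jz;
        if (nb[j] || seenb[j]) continue;
        seenb[j] = 1; q.push(j);
      }
    }
  }
  return compb == 1;
}

static int count_fg_neighbours(const std::vector<char> &fg, int x, int y, int z,
                               int nx, int ny, int nz) {
  int c = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        if (fg[idx3(xx, yy, zz, nx, ny)]) ++c;
      }
  return c;
}

// ---------------------------------------------------------------------------
// Curve-skeleton by ordered topological thinning: iteratively delete simple
// border points in increasing distance-transform order, never deleting
// curve endpoints (<= 1 foreground neighbour). Returns logical skeleton.
// [[Rcpp::export]]
LogicalVector cpp_skeletonize3d(LogicalVector mask, NumericVector dt,
                                int nx, int ny, int nz) {
  std::vector<char> fg(mask.size());
  for (int i = 0; i < (int)mask.size(); ++i) fg[i] = mask[i] ? 1 : 0;
  bool changed = true;
  while (changed) {
    changed = false;
    // collect border foreground voxels
    std::vector<std::pair<double, int>> border;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = idx3(x, y, z, nx, ny);
          if (!fg[i]) continue;
          bool isborder = false;
          const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
          for (int kk = 0; kk < 6 && !isborder; ++kk) {
            int xx = x + d6[kk][0], yy = y + d6[kk][1], zz = z + d6[kk][2];
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              isborder = true;
            else if (!fg[idx3(xx, yy, zz, nx, ny)]) isborder = true;
          }
          if (isborder) border.push_back({dt[i], i});
        }
    std::sort(border.begin(), border.end());
    for (auto &pr : border) {
      int i = pr.second;
      if (!fg[i]) continue;
      int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
      int nn = count_fg_neighbours(fg, x, y, z, nx, ny, nz);
      if (nn <= 1) continue;            // endpoint: keep
      if (is_simple(fg, x, y, z, nx, ny, nz)) {
        fg[i] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(mask.size());
  for (int i = 0; i < (int)mask.size(); ++i) out[i] = fg[i] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Phased-array field: coherent sum of point-source elements with focusing
// delays, spherical spreading and a baffled cos element factor.
// px,py,pz: field points (N). ex,ey,ez: element centres (M).
// nxv,nyv,nzv: element (tile) normal. k: wavenumber (rad/mm).
// fx,fy,fz: focus. Returns intensity |p|^2 (relative).
// [[Rcpp::export]]
NumericVector cpp_beamsum(NumericVector px, NumericVector py, NumericVector pz,
                          NumericVector ex, NumericVector ey, NumericVector ez,
                          double nxv, double nyv, double nzv,
                          double k, double fx, double fy, double fz) {
  int N = px.size(), M = ex.size();
  // focusing delays: phase advance so all elements arrive in phase at focus
  std::vector<double> fr(M);
  for (int m = 0; m < M; ++m) {
    double dx = fx - ex[m], dy = fy - ey[m], dz = fz - ez[m];
    fr[m] = std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  NumericVector out(N);
  for (int n = 0; n < N; ++n) {
    double re = 0, im = 0;
    double x = px[n], y = py[n], z = pz[n];
    for (int m = 0; m < M; ++m) {
      double dx = x - ex[m], dy = y - ey[m], dz = z - ez[m];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-6) r = 1e-6;
      double cosang = (dx * nxv + dy * nyv + dz * nzv) / r;
      if (cosang <= 0) continue;        // baffled: no backward radiation
      double ph = k * (r - fr[m]);
      double a = cosang / r;
      re += a * std::cos(ph);
      im += a * std::sin(ph);
    }
    out[n] = re * re + im * im;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Explicit finite-difference Pennes bioheat stepper on a regular grid with
// Dirichlet (dT = 0) outer boundary.
//   dT <- dT + cdiff * laplacian(dT) - sink * dT + src
// cdiff = k*dt/(rho*c*h^2); sink = per-voxel rho_b*c_b*w_b*dt/(rho*c);
// src = q*dt/(rho*c) per voxel.
// track_idx: 0-based voxel indices whose dT is recorded every snap_every
// steps. Returns list(final, runmax, tracked, track_times_steps).
// [[Rcpp::export]]
List cpp_bioheat(NumericVector dT0, NumericVector src, NumericVector sink,
                 int nx, int ny, int nz, double cdiff, int nsteps,
                 int snap_every, IntegerVector track_idx) {
  std::vector<double> T(dT0.begin(), dT0.end());
  std::vector<double> Tn(T.size());
  NumericVector runmax(dT0.size());
  for (int i = 0; i < (int)T.size(); ++i) runmax[i] = T[i];
  int ntr = track_idx.size();
  int nsnap = (snap_every > 0) ? (nsteps / snap_every + 1) : 0;
  NumericMatrix tracked(std::max(nsnap, 0), ntr);
  IntegerVector snap_steps(std::max(nsnap, 0));
  int srow = 0;
  if (nsnap > 0) {
    for (int t = 0; t < ntr; ++t) tracked(0, t) = T[track_idx[t]];
    snap_steps[0] = 0;
    srow = 1;
  }
  for (int s = 1; s <= nsteps; ++s) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = idx3(x, y, z, nx, ny);
          if (x == 0 || y == 0 || z == 0 || x == nx - 1 || y == ny - 1 || z == nz - 1) {
            Tn[i] = 0.0;               // Dirichlet outer boundary
            continue;
          }
          double lap = T[i - 1] + T[i + 1] + T[i - nx] + T[i + nx]
                     + T[i - nx * ny] + T[i + nx * ny] - 6.0 * T[i];
          // diffusion/source explicit, sink implicit (unconditionally
          // stable for arbitrarily strong local sinks)
          Tn[i] = (T[i] + cdiff * lap + src[i]) / (1.0 + sink[i]);
        }
    std::swap(T, Tn);
    for (int i = 0; i < (int)T.size(); ++i)
      if (T[i] > runmax[i]) runmax[i] = T[i];
    if (snap_every > 0 && s % snap_every == 0 && srow < nsnap) {
      for (int t = 0; t < ntr; ++t) tracked(srow, t) = T[track_idx[t]];
      snap_steps[srow] = s;
      ++srow;
    }
  }
  NumericVector fin(dT0.size());
  for (int i = 0; i < (int)T.size(); ++i) fin[i] = T[i];
  return List::create(_["final"] = fin, _["runmax"] = runmax,
                      _["tracked"] = tracked, _["snap_steps"] = snap_steps);
}
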