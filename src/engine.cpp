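#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Lattice convention: sites are stored in an integer vector of length
// Lx*Ly*Lz in column-major (R array) order, 0-based linear index
//   i = x + Lx * (y + Ly * z),  x,y,z in [0, L).
// occ[i] holds the clone id of the occupying tumour voxel (0 = empty).

static const double INF = std::numeric_limits<double>::infinity();

// 26-neighbourhood offsets (all non-zero vectors with components in {-1,0,1})
static void neighbour_offsets(int off[26][3]) {
  int n = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        off[n][0] = dx; off[n][1] = dy; off[n][2] = dz; ++n;
      }
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform, 1-D lower envelope pass
// (Felzenszwalb & Huttenlocher). f: input squared distances along a line,
// d: output. n: line length.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1; // index of the rightmost parabola in the lower envelope
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue; // not a source parabola
    double s = 0.0;
    while (k >= 0) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) --k; else break;
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
    } else {
      ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
    }
  }
  if (k < 0) { // no sources on this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Depth field: exact Euclidean distance from every lattice site to the
// tumour surface, defined as the exterior empty region (empty sites
// 6-connected to the lattice boundary). Interior holes left by cell death
// are not tumour surface and do not act as distance sources.
// [[Rcpp::export]]
NumericVector cpp_depth_field(IntegerVector occ, IntegerVector dims) {
  const int Lx = dims[0], Ly = dims[1], Lz = dims[2];
  const int n = Lx * Ly * Lz;

  // flood fill the exterior empty region from the lattice boundary
  std::vector<char> ext(n, 0);
  std::vector<int> queue;
  queue.reserve(n / 4);
  for (int z = 0; z < Lz; ++z)
    for (int y = 0; y < Ly; ++y)
      for (int x = 0; x < Lx; ++x) {
        if (x > 0 && x < Lx - 1 && y > 0 && y < Ly - 1 &&
            z > 0 && z < Lz - 1) continue;
        const int i = x + Lx * (y + Ly * z);
        if (occ[i] == 0 && !ext[i]) { ext[i] = 1; queue.push_back(i); }
      }
  const int step6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (size_t h = 0; h < queue.size(); ++h) {
    const int i = queue[h];
    const int x = i % Lx, y = (i / Lx) % Ly, z = i / (Lx * Ly);
    for (int k = 0; k < 6; ++k) {
      const int nx = x + step6[k][0], ny = y + step6[k][1], nz = z + step6[k][2];
      if (nx < 0 || nx >= Lx || ny < 0 || ny >= Ly || nz < 0 || nz >= Lz)
        continue;
      const int j = nx + Lx * (ny + Ly * nz);
      if (occ[j] == 0 && !ext[j]) { ext[j] = 1; queue.push_back(j); }
    }
  }

  std::vector<double> g(n);
  for (int i = 0; i < n; ++i) g[i] = ext[i] ? 0.0 : INF;

  std::vector<double> f(std::max(Lx, std::max(Ly, Lz)));
  std::vector<double> d(f.size());

  // pass along x
  for (int z = 0; z < Lz; ++z)
    for (int y = 0; y < Ly; ++y) {
      const int base = Lx * (y + Ly * z);
      for (int x = 0; x < Lx; ++x) f[x] = g[base + x];
      dt1d(f, d, Lx);
      for (int x = 0; x < Lx; ++x) g[base + x] = d[x];
    }
  // pass along y
  for (int z = 0; z < Lz; ++z)
    for (int x = 0; x < Lx; ++x) {
      for (int y = 0; y < Ly; ++y) f[y] = g[x + Lx * (y + Ly * z)];
      dt1d(f, d, Ly);
      for (int y = 0; y < Ly; ++y) g[x + Lx * (y + Ly * z)] = d[y];
    }
  // pass along z
  for (int y = 0; y < Ly; ++y)
    for (int x = 0; x < Lx; ++x) {
      for (int z = 0; z < Lz; ++z) f[z] = g[x + Lx * (y + Ly * z)];
      dt1d(f, d, Lz);
      for (int z = 0; z < Lz; ++z) g[x + Lx * (y + Ly * z)] = d[z];
    }

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (g[i] == INF) ? R_PosInf : std::sqrt(g[i]);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_eligible_parents(IntegerVector occ, IntegerVector dims,
                                   int surfaceMode) {
  const int Lx = dims[0], Ly = dims[1], Lz = dims[2];
  int off[26][3];
  neighbour_offsets(off);
  std::vector<int> out;
  for (int z = 0; z < Lz; ++z)
    for (int y = 0; y < Ly; ++y)
      for (int x = 0; x < Lx; ++x) {
        const int i = x + Lx * (y + Ly * z);
        if (occ[i] == 0) continue;
        if (!surfaceMode) { out.push_back(i + 1); continue; }
        bool elig = false;
        for (int k = 0; k < 26 && !elig; ++k) {
          const int nx = x + off[k][0], ny = y + off[k][1], nz = z + off[k][2];
          if (nx < 0 || nx >= Lx || ny < 0 || ny >= Ly || nz < 0 || nz >= Lz)
            continue; // outside lattice: not usable space
          if (occ[nx + Lx * (ny + Ly * nz)] == 0) elig = true;
        }
        if (elig) out.push_back(i + 1);
      }
  return wrap(out);
}

// Fisher-Yates shuffle driven by R's RNG (single stream with the R side)
static void shuffle_int(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

// Proliferation phase over eligible parents in random order.
// mode: 0 = surface, 1 = volume. Returns cloned, updated lattices plus the
// list of daughter sites and their (inherited) parent clone ids. Daughter
// sites are tracked through later pushes so the returned positions are
// where the daughters actually sit at the end of the phase.
// forceSites (1-based, may be empty): process exactly these sites, in the
// given order, with growth probability 1 (single-placement op for tests).
// [[Rcpp::export]]
List cpp_growth_phase(IntegerVector occIn, IntegerVector birthIn,
                      IntegerVector founderIn, IntegerVector dims,
                      NumericVector depth, NumericVector cloneProb,
                      int mode, int stepNo, int nSample,
                      IntegerVector forceSites) {
  const int Lx = dims[0], Ly = dims[1], Lz = dims[2];
  const int nsite = Lx * Ly * Lz;
  IntegerVector occ = clone(occIn);
  IntegerVector birth = clone(birthIn);
  IntegerVector founder = clone(founderIn);
  int off[26][3];
  neighbour_offsets(off);
  const bool forced = forceSites.size() > 0;

  // parent site list (eligibility by the 26-neighbourhood at phase start;
  // emptiness is re-checked at placement time)
  std::vector<int> parents;
  if (forced) {
    for (int k = 0; k < forceSites.size(); ++k)
      parents.push_back(forceSites[k] - 1);
  } else {
    for (int z = 0; z < Lz; ++z)
      for (int y = 0; y < Ly; ++y)
        for (int x = 0; x < Lx; ++x) {
          const int i = x + Lx * (y + Ly * z);
          if (occ[i] == 0) continue;
          if (mode == 1) { parents.push_back(i); continue; }
          for (int k = 0; k < 26; ++k) {
            const int nx = x + off[k][0], ny = y + off[k][1], nz = z + off[k][2];
            if (nx < 0 || nx >= Lx || ny < 0 || ny >= Ly || nz < 0 || nz >= Lz)
              continue;
            if (occ[nx + Lx * (ny + Ly * nz)] == 0) { parents.push_back(i); break; }
          }
        }
    shuffle_int(parents);
  }

  std::vector<int> dSite, dClone;
  std::vector<int> dIdx(nsite, -1); // site -> daughter index, push-tracked
  std::string err = "";

  for (size_t pi = 0; pi < parents.size() && err.empty(); ++pi) {
    const int i = parents[pi];
    const int cl = occ[i];
    if (cl == 0) continue; // freed meanwhile (cannot happen, defensive)
    if (!forced) {
      const double p = cloneProb[cl - 1];
      if (unif_rand() >= p) continue;
    }
    const int x = i % Lx, y = (i / Lx) % Ly, z = i / (Lx * Ly);

    if (mode == 0) {
      // surface: uniformly chosen currently-empty neighbour
      int cand[26], ncand = 0;
      for (int k = 0; k < 26; ++k) {
        const int nx = x + off[k][0], ny = y + off[k][1], nz = z + off[k][2];
        if (nx < 0 || nx >= Lx || ny < 0 || ny >= Ly || nz < 0 || nz >= Lz)
          continue;
        const int j = nx + Lx * (ny + Ly * nz);
        if (occ[j] == 0) cand[ncand++] = j;
      }
      if (ncand == 0) continue; // enclosed since phase start: skip
      int pick = (int)std::floor(unif_rand() * ncand);
      if (pick >= ncand) pick = ncand - 1;
      const int j = cand[pick];
      occ[j] = cl; birth[j] = stepNo; founder[j] = 0;
      dIdx[j] = (int)dSite.size();
      dSite.push_back(j + 1); dClone.push_back(cl);
    } else {
      // volume: sample nSample of the 26 orientations without replacement,
      // take the candidate whose site lies closest to the tumour surface
      // (depth field; empty sites have depth 0), ties broken uniformly;
      // then push the occupied ray outward by one step.
      int ord[26];
      for (int k = 0; k < 26; ++k) ord[k] = k;
      const int m = nSample < 26 ? nSample : 26;
      for (int k = 0; k < m; ++k) {
        int j = k + (int)std::floor(unif_rand() * (26 - k));
        if (j > 25) j = 25;
        std::swap(ord[k], ord[j]);
      }
      double best = INF;
      int bestK = -1, nties = 0;
      bool oob = false;
      for (int k = 0; k < m; ++k) {
        const int o = ord[k];
        const int nx = x + off[o][0], ny = y + off[o][1], nz = z + off[o][2];
        if (nx < 0 || nx >= Lx || ny < 0 || ny >= Ly || nz < 0 || nz >= Lz) {
          oob = true; break;
        }
        const int j = nx + Lx * (ny + Ly * nz);
        const double dv = (occ[j] == 0) ? 0.0 : depth[j];
        if (dv < best) { best = dv; bestK = o; nties = 1; }
        else if (dv == best) {
          ++nties;
          if (unif_rand() < 1.0 / nties) bestK = o;
        }
      }
      if (oob) { err = "push would exit the lattice"; break; }
      const int dx = off[bestK][0], dy = off[bestK][1], dz = off[bestK][2];
      // walk outward to the first empty site
      int ex = x + dx, ey = y + dy, ez = z + dz, steps = 1;
      while (true) {
        if (ex < 0 || ex >= Lx || ey < 0 || ey >= Ly || ez < 0 || ez >= Lz) {
          err = "push would exit the lattice"; break;
        }
        if (occ[ex + Lx * (ey + Ly * ez)] == 0) break;
        ex += dx; ey += dy; ez += dz; ++steps;
      }
      if (!err.empty()) break;
      // shift occupants one step outward (far end first), preserving order
      for (int s = steps; s >= 2; --s) {
        const int tx = x + s * dx, ty = y + s * dy, tz = z + s * dz;
        const int fx = tx - dx, fy = ty - dy, fz = tz - dz;
        const int t = tx + Lx * (ty + Ly * tz);
        const int f = fx + Lx * (fy + Ly * fz);
        occ[t] = occ[f]; birth[t] = birth[f]; founder[t] = founder[f];
        if (dIdx[f] >= 0) { dSite[dIdx[f]] = t + 1; dIdx[t] = dIdx[f]; dIdx[f] = -1; }
      }
      const int candSite = (x + dx) + Lx * ((y + dy) + Ly * (z + dz));
      occ[candSite] = cl; birth[candSite] = stepNo; founder[candSite] = 0;
      dIdx[candSite] = (int)dSite.size();
      dSite.push_back(candSite + 1); dClone.push_back(cl);
    }
  }

  return List::create(_["occ"] = occ, _["birth"] = birth,
                      _["founder"] = founder,
                      _["daughter_site"] = wrap(dSite),
                      _["daughter_clone"] = wrap(dClone),
                      _["error"] = err);
}
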