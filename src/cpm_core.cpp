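// Lattice Monte Carlo core for the retinal Cellular Potts model.
//
// The lattice is a 3D integer array mapping voxels to generalized-cell ids
// (0 = Medium).  Cell attributes are flat vectors indexed by id.  Boundary
// conditions: periodic in x and y, fixed planes in z (no copies across the
// choroidal base or the outer limiting membrane).
//
// Energy terms: contact energies over the 26-neighborhood (unit weights),
// a quadratic volume constraint, breakable-spring links anchored at cell
// centers of mass, and contact-inhibited chemotaxis applied when an
// endothelial cell advances into a non-endothelial voxel.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <unordered_map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// cell type codes (keep in step with R/state.R)
static const int T_MEDIUM = 0, T_VASC = 1, T_STALK = 2, T_TIP = 3,
                 T_RPE = 4, T_POS = 5, T_PIS = 6, T_BRM = 7;

static inline bool is_ec(int ty) {
  return ty == T_VASC || ty == T_STALK || ty == T_TIP;
}

struct Lattice {
  int nx, ny, nz, nxy;
  inline int idx(int x, int y, int z) const { return x + nx * (y + ny * z); }
  inline int wrapx(int x) const { return (x % nx + nx) % nx; }
  inline int wrapy(int y) const { return (y % ny + ny) % ny; }
};

// 26-neighborhood offsets (contact), 6-neighborhood first (copy proposals)
static const int OFF6[6][3] = {
  {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}
};

static void make_off26(std::vector<std::array<int,3>>& off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        off.push_back({dx, dy, dz});
      }
}

// minimum-image displacement (voxel units) along a periodic axis
static inline double min_image(double d, double L) {
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

struct State {
  Lattice lat;
  IntegerVector site;
  IntegerVector cellType;   // by id (1-based ids; element id-1)
  IntegerVector volume;
  NumericVector targetVolume;
  LogicalVector frozen;
  NumericVector comx, comy, comz;   // voxel units, wrapped into [0, L)
  NumericMatrix J;                  // 8 x 8 by type code (+1)
  double lambdaVol;
  double temperature;
  // links
  IntegerVector la, lb;
  NumericVector llambda, lrest;
  LogicalVector lactive;
  double breakFactor;
  double springScale;
  // chemotaxis
  NumericMatrix lambdaChem;         // 8 x nFields by advancing cell type
  std::vector<NumericVector> fields;
  std::vector<std::vector<int>> linksOf;  // per id: link row indices
  std::vector<std::array<int,3>> off26;
  // hot-path caches
  std::vector<int> typeOfId;              // [0] = Medium
  double Jc[8][8];
  int nbr26[26];                          // linear offsets, lateral interior
  const int* S = nullptr;                 // raw site pointer

  std::vector<double> linkLen;            // cached current lengths
  const double *CX = nullptr, *CY = nullptr, *CZ = nullptr;
  const int *LA = nullptr, *LB = nullptr;
  const double *LL = nullptr, *LR = nullptr;
  const int *VOL = nullptr;
  const double *TV = nullptr;

  void buildLinkIndex(int nIds) {
    linksOf.assign(nIds + 1, {});
    for (int k = 0; k < la.size(); ++k) {
      if (!lactive[k]) continue;
      linksOf[la[k]].push_back(k);
      linksOf[lb[k]].push_back(k);
    }
    linkLen.resize(la.size());
    for (int k = 0; k < la.size(); ++k)
      linkLen[k] = lactive[k] ? linkLength2(k, -1, 0,0,0, -1, 0,0,0) : 0.0;
  }

  void buildCaches() {
    typeOfId.resize(cellType.size() + 1);
    typeOfId[0] = T_MEDIUM;
    for (int i = 0; i < cellType.size(); ++i) typeOfId[i + 1] = cellType[i];
    for (int a = 0; a < 8; ++a)
      for (int b = 0; b < 8; ++b) Jc[a][b] = J(a, b);
    int k = 0;
    for (auto& o : off26)
      nbr26[k++] = o[0] + lat.nx * (o[1] + lat.ny * o[2]);
    S = &site[0];
    if (comx.size()) {
      CX = &comx[0]; CY = &comy[0]; CZ = &comz[0];
      VOL = &volume[0]; TV = &targetVolume[0];
    }
    if (la.size()) {
      LA = &la[0]; LB = &lb[0]; LL = &llambda[0]; LR = &lrest[0];
    }
  }

  inline int typeOf(int id) const { return typeOfId[id]; }

  double linkLength(int k, int idMoved, double cx, double cy, double cz) const {
    // length of link k with cell idMoved's COM overridden by (cx,cy,cz)
    int a = la[k], b = lb[k];
    double ax, ay, az, bx, by, bz;
    if (a == idMoved) { ax = cx; ay = cy; az = cz; }
    else { ax = comx[a-1]; ay = comy[a-1]; az = comz[a-1]; }
    if (b == idMoved) { bx = cx; by = cy; bz = cz; }
    else { bx = comx[b-1]; by = comy[b-1]; bz = comz[b-1]; }
    double dx = min_image(ax - bx, lat.nx);
    double dy = min_image(ay - by, lat.ny);
    double dz = az - bz;
    return std::sqrt(dx*dx + dy*dy + dz*dz);
  }

  double linkLength2(int k, int idA, double ax0, double ay0, double az0,
                     int idB, double bx0, double by0, double bz0) const {
    // both endpoints possibly overridden
    int a = la[k], b = lb[k];
    double ax = comx[a-1], ay = comy[a-1], az = comz[a-1];
    double bx = comx[b-1], by = comy[b-1], bz = comz[b-1];
    if (a == idA) { ax = ax0; ay = ay0; az = az0; }
    if (a == idB) { ax = bx0; ay = by0; az = bz0; }
    if (b == idA) { bx = ax0; by = ay0; bz = az0; }
    if (b == idB) { bx = bx0; by = by0; bz = bz0; }
    double dx = min_image(ax - bx, lat.nx);
    double dy = min_image(ay - by, lat.ny);
    double dz = az - bz;
    return std::sqrt(dx*dx + dy*dy + dz*dz);
  }
};

// nearest periodic image of voxel center x relative to reference c
static inline double image_near(double x, double c, double L) {
  double d = x - c;
  if (d > 0.5 * L) x -= L;
  else if (d < -0.5 * L) x += L;
  return x;
}

static inline double wrap01(double x, double L) {
  while (x < 0) x += L;
  while (x >= L) x -= L;
  return x;
}

// Delta H of copying the id at voxel s onto voxel t.  Pure function of the
// current state; used both by the Metropolis loop and the exported
// single-proposal probe.
static double delta_energy(const State& st, int sx, int sy, int sz,
                           int tx, int ty, int tz) {
  const Lattice& L = st.lat;
  int s = L.idx(sx, sy, sz), t = L.idx(tx, ty, tz);
  int sigS = st.S[s], sigT = st.S[t];
  if (sigS == sigT) return 0.0;
  int tyS = st.typeOf(sigS), tyT = st.typeOf(sigT);
  double dH = 0.0;

  // contact term over 26-neighborhood of t
  const double* JS = st.Jc[tyS];
  const double* JT = st.Jc[tyT];
  if (tx >= 1 && tx < L.nx - 1 && ty >= 1 && ty < L.ny - 1 &&
      tz >= 1 && tz < L.nz - 1) {
    for (int k = 0; k < 26; ++k) {
      int sigN = st.S[t + st.nbr26[k]];
      int tyN = st.typeOfId[sigN];
      if (sigN != sigT) dH -= JT[tyN];
      if (sigN != sigS) dH += JS[tyN];
    }
  } else {
    for (size_t k = 0; k < st.off26.size(); ++k) {
      int nxp = tx + st.off26[k][0], nyp = ty + st.off26[k][1],
          nzp = tz + st.off26[k][2];
      if (nzp < 0 || nzp >= L.nz) continue;
      int n = L.idx(L.wrapx(nxp), L.wrapy(nyp), nzp);
      int sigN = st.S[n];
      int tyN = st.typeOfId[sigN];
      if (sigN != sigT) dH -= JT[tyN];
      if (sigN != sigS) dH += JS[tyN];
    }
  }

  // volume term (Medium unconstrained; frozen cells never appear here)
  if (sigS != 0) {
    double v = st.VOL[sigS - 1], vt = st.TV[sigS - 1];
    dH += st.lambdaVol * ((v + 1 - vt) * (v + 1 - vt) - (v - vt) * (v - vt));
  }
  if (sigT != 0) {
    double v = st.VOL[sigT - 1], vt = st.TV[sigT - 1];
    dH += st.lambdaVol * ((v - 1 - vt) * (v - 1 - vt) - (v - vt) * (v - vt));
  }

  // spring term via center-of-mass shifts
  bool anyLinks = (sigS != 0 && !st.linksOf[sigS].empty()) ||
                  (sigT != 0 && !st.linksOf[sigT].empty());
  if (anyLinks) {
    double sxN = 0, syN = 0, szN = 0, txN = 0, tyN2 = 0, tzN = 0;
    bool sMoves = false, tMoves = false;
    double xt = tx + 0.5, yt = ty + 0.5, zt = tz + 0.5;
    if (sigS != 0) {
      double v = st.VOL[sigS - 1];
      double cx = st.CX[sigS-1], cy = st.CY[sigS-1], cz = st.CZ[sigS-1];
      double xi = image_near(xt, cx, L.nx), yi = image_near(yt, cy, L.ny);
      sxN = wrap01((v * cx + xi) / (v + 1), L.nx);
      syN = wrap01((v * cy + yi) / (v + 1), L.ny);
      szN = (v * cz + zt) / (v + 1);
      sMoves = true;
    }
    if (sigT != 0 && st.VOL[sigT - 1] > 1) {
      double v = st.VOL[sigT - 1];
      double cx = st.CX[sigT-1], cy = st.CY[sigT-1], cz = st.CZ[sigT-1];
      double xi = image_near(xt, cx, L.nx), yi = image_near(yt, cy, L.ny);
      txN = wrap01((v * cx - xi) / (v - 1), L.nx);
      tyN2 = wrap01((v * cy - yi) / (v - 1), L.ny);
      tzN = (v * cz - zt) / (v - 1);
      tMoves = true;
    }
    // at most one link per unordered pair, so the only overlap between
    // the two cells' link lists is the link joining them: skip it on the
    // second pass
    bool tVanishes = (sigT != 0 && st.VOL[sigT - 1] == 1);
    const double* lenC = st.linkLen.data();
    for (int pass = 0; pass < 2; ++pass) {
      int id = pass == 0 ? sigS : sigT;
      if (id == 0) continue;
      const std::vector<int>& lk = st.linksOf[id];
      for (size_t qq = 0; qq < lk.size(); ++qq) {
        int k = lk[qq];
        if (pass == 1 && (st.LA[k] == sigS || st.LB[k] == sigS))
          continue;
        double l0 = lenC[k];
        double r = st.LR[k];
        int a = st.LA[k], b = st.LB[k];
        if (tVanishes && (a == sigT || b == sigT)) {
          dH -= 0.5 * st.springScale * st.LL[k] * (l0 - r) * (l0 - r);
          continue;
        }
        double ax, ay, az, bx, by, bz;
        if (a == sigS && sMoves) { ax = sxN; ay = syN; az = szN; }
        else if (a == sigT && tMoves) { ax = txN; ay = tyN2; az = tzN; }
        else { ax = st.CX[a-1]; ay = st.CY[a-1]; az = st.CZ[a-1]; }
        if (b == sigS && sMoves) { bx = sxN; by = syN; bz = szN; }
        else if (b == sigT && tMoves) { bx = txN; by = tyN2; bz = tzN; }
        else { bx = st.CX[b-1]; by = st.CY[b-1]; bz = st.CZ[b-1]; }
        double dx = min_image(ax - bx, L.nx);
        double dy = min_image(ay - by, L.ny);
        double dz = az - bz;
        double l1 = std::sqrt(dx*dx + dy*dy + dz*dz);
        dH += 0.5 * st.springScale * st.LL[k] * ((l1 - r) * (l1 - r) - (l0 - r) * (l0 - r));
      }
    }
  }

  // contact-inhibited chemotaxis: an EC advancing into a non-EC voxel
  if (is_ec(tyS) && !is_ec(tyT)) {
    for (size_t f = 0; f < st.fields.size(); ++f) {
      double lam = st.lambdaChem(tyS, f);
      if (lam != 0.0) dH += -lam * (st.fields[f][t] - st.fields[f][s]);
    }
  }
  return dH;
}

static State unpack(List state, bool clone_mutable = false) {
  State st;
  IntegerVector dims = state["dims"];
  st.lat.nx = dims[0]; st.lat.ny = dims[1]; st.lat.nz = dims[2];
  st.lat.nxy = st.lat.nx * st.lat.ny;
  st.site = state["site"];
  st.cellType = state["cell_type"];
  st.volume = state["volume"];
  st.targetVolume = state["target_volume"];
  st.frozen = state["frozen"];
  st.comx = state["comx"]; st.comy = state["comy"]; st.comz = state["comz"];
  if (clone_mutable) {
    st.site = clone(st.site);
    st.volume = clone(st.volume);
    st.comx = clone(st.comx); st.comy = clone(st.comy);
    st.comz = clone(st.comz);
  }
  st.J = as<NumericMatrix>(state["J"]);
  st.lambdaVol = as<double>(state["lambda_vol"]);
  st.temperature = as<double>(state["temperature"]);
  st.la = state["link_a"]; st.lb = state["link_b"];
  st.llambda = state["link_lambda"]; st.lrest = state["link_rest"];
  st.lactive = state["link_active"];
  if (clone_mutable) st.lactive = clone(st.lactive);
  st.breakFactor = as<double>(state["break_factor"]);
  st.springScale = as<double>(state["spring_scale"]);
  st.lambdaChem = as<NumericMatrix>(state["lambda_chem"]);
  List fl = state["chem_fields"];
  for (int i = 0; i < fl.size(); ++i)
    st.fields.push_back(as<NumericVector>(fl[i]));
  make_off26(st.off26);
  st.buildLinkIndex(st.cellType.size());
  st.buildCaches();
  return st;
}

// [[Rcpp::export(name = ".delta_energy_cpp")]]
double delta_energy_cpp(List state, IntegerVector source_vox,
                        IntegerVector target_vox) {
  State st = unpack(state);
  return delta_energy(st, source_vox[0], source_vox[1], source_vox[2],
                      target_vox[0], target_vox[1], target_vox[2]);
}

static void apply_copy(State& st, int t, int tx, int ty, int tz,
                       int sigS, int sigT) {
  const Lattice& L = st.lat;
  double xt = tx + 0.5, yt = ty + 0.5, zt = tz + 0.5;
  st.site[t] = sigS;
  if (sigS != 0) {
    int i = sigS - 1;
    double v = st.volume[i];
    double xi = image_near(xt, st.comx[i], L.nx);
    double yi = image_near(yt, st.comy[i], L.ny);
    st.comx[i] = wrap01((v * st.comx[i] + xi) / (v + 1), L.nx);
    st.comy[i] = wrap01((v * st.comy[i] + yi) / (v + 1), L.ny);
    st.comz[i] = (v * st.comz[i] + zt) / (v + 1);
    st.volume[i] = v + 1;
  }
  if (sigT != 0) {
    int i = sigT - 1;
    double v = st.volume[i];
    if (v > 1) {
      double xi = image_near(xt, st.comx[i], L.nx);
      double yi = image_near(yt, st.comy[i], L.ny);
      st.comx[i] = wrap01((v * st.comx[i] - xi) / (v - 1), L.nx);
      st.comy[i] = wrap01((v * st.comy[i] - yi) / (v - 1), L.ny);
      st.comz[i] = (v * st.comz[i] - zt) / (v - 1);
    }
    st.volume[i] = v - 1;
    if (st.volume[i] == 0) {
      // vanished cell: deactivate its springs
      for (int k : st.linksOf[sigT]) st.lactive[k] = false;
      st.linksOf[sigT].clear();
    }
  }
  // refresh cached lengths and break overstretched springs
  for (int pass = 0; pass < 2; ++pass) {
    int id = pass == 0 ? sigS : sigT;
    if (id == 0) continue;
    std::vector<int>& lk = st.linksOf[id];
    for (size_t q = 0; q < lk.size();) {
      int k = lk[q];
      if (!st.lactive[k]) { lk.erase(lk.begin() + q); continue; }
      double len = st.linkLength2(k, -1, 0,0,0, -1, 0,0,0);
      st.linkLen[k] = len;
      if (len > st.breakFactor * st.lrest[k]) {
        st.lactive[k] = false;
        lk.erase(lk.begin() + q);
      } else ++q;
    }
  }
}

// [[Rcpp::export(name = ".run_mcs_cpp")]]
List run_mcs_cpp(List state, int n_mcs) {
  State st = unpack(state, true);
  const Lattice& L = st.lat;
  int nvox = L.nx * L.ny * L.nz;

  // attempts per MCS = number of non-frozen voxels
  std::vector<char> frz(st.cellType.size() + 1, 0);
  for (int i = 0; i < st.frozen.size(); ++i) frz[i + 1] = st.frozen[i];
  int nFrozenVox = 0;
  for (int i = 0; i < nvox; ++i)
    if (frz[st.S[i]]) ++nFrozenVox;
  int attemptsPerMcs = nvox - nFrozenVox;

  long attempts = 0, accepted = 0;
  RNGScope scope;
  for (int mcs = 0; mcs < n_mcs; ++mcs) {
    for (int a = 0; a < attemptsPerMcs; ++a) {
      ++attempts;
      int t = (int)(unif_rand() * nvox);
      if (t >= nvox) t = nvox - 1;
      int tz = t / L.nxy, rem = t % L.nxy, ty = rem / L.nx, tx = rem % L.nx;
      int sigT = st.S[t];
      if (frz[sigT]) continue;                         // frozen target
      int d = (int)(unif_rand() * 6); if (d > 5) d = 5;
      int szp = tz + OFF6[d][2];
      if (szp < 0 || szp >= L.nz) continue;            // fixed z planes
      int sxp = L.wrapx(tx + OFF6[d][0]), syp = L.wrapy(ty + OFF6[d][1]);
      int s = L.idx(sxp, syp, szp);
      int sigS = st.S[s];
      if (sigS == sigT) continue;
      if (frz[sigS]) continue;                         // frozen source
      double dH = delta_energy(st, sxp, syp, szp, tx, ty, tz);
      if (dH <= 0.0 || unif_rand() < std::exp(-dH / st.temperature)) {
        apply_copy(st, t, tx, ty, tz, sigS, sigT);
        ++accepted;
      }
    }
  }
  return List::create(_["site"] = st.site, _["volume"] = st.volume,
                      _["comx"] = st.comx, _["comy"] = st.comy,
                      _["comz"] = st.comz, _["link_active"] = st.lactive,
                      _["attempts"] = (double)attempts,
                      _["accepted"] = (double)accepted,
                      _["attempts_per_mcs"] = attemptsPerMcs);
}

// Contact areas between cells.  order = 6 counts voxel faces (morphometric
// areas, link formation); order = 26 matches the energy neighborhood.
// [[Rcpp::export(name = ".contact_areas_cpp")]]
DataFrame contact_areas_cpp(IntegerVector site, IntegerVector dims,
                            int order) {
  Lattice L; L.nx = dims[0]; L.ny = dims[1]; L.nz = dims[2];
  L.nxy = L.nx * L.ny;
  std::vector<std::array<int,3>> off;
  if (order == 6) {
    off.push_back({1,0,0}); off.push_back({0,1,0}); off.push_back({0,0,1});
  } else {
    // forward half of the 26-neighborhood (13 offsets)
    std::vector<std::array<int,3>> all;
    make_off26(all);
    for (auto& o : all)
      if (o[2] > 0 || (o[2] == 0 && (o[1] > 0 || (o[1] == 0 && o[0] > 0))))
        off.push_back(o);
  }
  std::unordered_map<long long, int> acc;
  acc.reserve(4096);
  const int* S = &site[0];
  for (int z = 0; z < L.nz; ++z)
    for (int y = 0; y < L.ny; ++y)
      for (int x = 0; x < L.nx; ++x) {
        int a = S[L.idx(x, y, z)];
        for (auto& o : off) {
          int zz = z + o[2];
          if (zz < 0 || zz >= L.nz) continue;
          int b = S[L.idx(L.wrapx(x + o[0]), L.wrapy(y + o[1]), zz)];
          if (a == b) continue;
          long long key = a < b ? ((long long)a << 24) | b
                                : ((long long)b << 24) | a;
          acc[key] += 1;
        }
      }
  // deterministic output order (sorted by pair)
  std::vector<std::pair<long long,int>> rows(acc.begin(), acc.end());
  std::sort(rows.begin(), rows.end());
  int n = rows.size();
  IntegerVector ca(n), cb(n), area(n);
  for (int i = 0; i < n; ++i) {
    ca[i] = (int)(rows[i].first >> 24);
    cb[i] = (int)(rows[i].first & 0xFFFFFF);
    area[i] = rows[i].second;
  }
  return DataFrame::create(_["a"] = ca, _["b"] = cb, _["area"] = area);
}

// Per-cell boundary statistics over voxel faces: total heterotypic boundary
// area and the part of it shared with endothelial cells (for
// contact-inhibited growth).
// [[Rcpp::export(name = ".boundary_stats_cpp")]]
List boundary_stats_cpp(IntegerVector site, IntegerVector dims,
                        IntegerVector cellType) {
  Lattice L; L.nx = dims[0]; L.ny = dims[1]; L.nz = dims[2];
  L.nxy = L.nx * L.ny;
  int nIds = cellType.size();
  IntegerVector btot(nIds), bec(nIds);
  for (int z = 0; z < L.nz; ++z)
    for (int y = 0; y < L.ny; ++y)
      for (int x = 0; x < L.nx; ++x) {
        int a = site[L.idx(x, y, z)];
        for (int d = 0; d < 6; ++d) {
          int zz = z + OFF6[d][2];
          if (zz < 0 || zz >= L.nz) continue;
          int b = site[L.idx(L.wrapx(x + OFF6[d][0]), L.wrapy(y + OFF6[d][1]), zz)];
          if (a == b) continue;
          if (a != 0) {
            btot[a - 1] += 1;
            if (b != 0 && is_ec(cellType[b - 1])) bec[a - 1] += 1;
          }
        }
      }
  return List::create(_["boundary"] = btot, _["ec_contact"] = bec);
}

// Mean field value over each cell's voxels.
// [[Rcpp::export(name = ".field_mean_by_cell_cpp")]]
NumericVector field_mean_by_cell_cpp(IntegerVector site, NumericVector field,
                                     int n_ids) {
  NumericVector sum(n_ids);
  IntegerVector cnt(n_ids);
  for (int i = 0; i < site.size(); ++i) {
    int id = site[i];
    if (id > 0 && id <= n_ids) { sum[id - 1] += field[i]; cnt[id - 1] += 1; }
  }
  for (int i = 0; i < n_ids; ++i)
    sum[i] = cnt[i] > 0 ? sum[i] / cnt[i] : NA_REAL;
  return sum;
}

// One explicit diffusion-decay step:
//   c' = c + dt * (D lap(c) - kloc c + src), then clamp at 0.
// kloc and src are per-voxel (first-order loss incl. decay and uptake;
// constant sources/sinks).  z faces are Dirichlet when the corresponding
// value is finite, zero-flux otherwise; x,y periodic.
// [[Rcpp::export(name = ".step_field_cpp")]]
NumericVector step_field_cpp(NumericVector field, IntegerVector dims,
                             double D, double dt, double h,
                             NumericVector kloc, NumericVector src,
                             double dirichlet_lo, double dirichlet_hi) {
  Lattice L; L.nx = dims[0]; L.ny = dims[1]; L.nz = dims[2];
  L.nxy = L.nx * L.ny;
  NumericVector out(clone(field));
  double ih2 = 1.0 / (h * h);
  bool dlo = R_finite(dirichlet_lo), dhi = R_finite(dirichlet_hi);
  for (int z = 0; z < L.nz; ++z)
    for (int y = 0; y < L.ny; ++y)
      for (int x = 0; x < L.nx; ++x) {
        int i = L.idx(x, y, z);
        if ((z == 0 && dlo) || (z == L.nz - 1 && dhi)) {
          out[i] = z == 0 ? dirichlet_lo : dirichlet_hi;
          continue;
        }
        double c = field[i];
        double lap = 0.0;
        lap += field[L.idx(L.wrapx(x+1), y, z)] - c;
        lap += field[L.idx(L.wrapx(x-1), y, z)] - c;
        lap += field[L.idx(x, L.wrapy(y+1), z)] - c;
        lap += field[L.idx(x, L.wrapy(y-1), z)] - c;
        lap += (z + 1 < L.nz ? field[L.idx(x, y, z+1)] - c : 0.0);
        lap += (z > 0 ? field[L.idx(x, y, z-1)] - c : 0.0);
        double v = c + dt * (D * lap * ih2 - kloc[i] * c + src[i]);
        out[i] = v > 0.0 ? v : 0.0;
      }
  return out;
}

// Steady state of D lap(c) - kloc c + src = 0 by Gauss-Seidel with
// over-relaxation.  Same boundary conventions as step_field.
// [[Rcpp::export(name = ".steady_field_cpp")]]
List steady_field_cpp(NumericVector init, IntegerVector dims,
                      double D, double h, NumericVector kloc,
                      NumericVector src, double dirichlet_lo,
                      double dirichlet_hi, double tol, int max_iter) {
  Lattice L; L.nx = dims[0]; L.ny = dims[1]; L.nz = dims[2];
  L.nxy = L.nx * L.ny;
  NumericVector c(clone(init));
  double ih2 = D / (h * h);
  bool dlo = R_finite(dirichlet_lo), dhi = R_finite(dirichlet_hi);
  const double omega = 1.7;
  double maxdel = 0.0;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    maxdel = 0.0;
    for (int z = 0; z < L.nz; ++z)
      for (int y = 0; y < L.ny; ++y)
        for (int x = 0; x < L.nx; ++x) {
          int i = L.idx(x, y, z);
          if ((z == 0 && dlo) || (z == L.nz - 1 && dhi)) {
            c[i] = z == 0 ? dirichlet_lo : dirichlet_hi;
            continue;
          }
          double nb = 0.0; int nnb = 4;
          nb += c[L.idx(L.wrapx(x+1), y, z)];
          nb += c[L.idx(L.wrapx(x-1), y, z)];
          nb += c[L.idx(x, L.wrapy(y+1), z)];
          nb += c[L.idx(x, L.wrapy(y-1), z)];
          if (z + 1 < L.nz) { nb += c[L.idx(x, y, z+1)]; ++nnb; }
          if (z > 0)        { nb += c[L.idx(x, y, z-1)]; ++nnb; }
          double denom = nnb * ih2 + kloc[i];
          if (denom <= 0.0) continue;
          double cn = (ih2 * nb + src[i]) / denom;
          double upd = c[i] + omega * (cn - c[i]);
          if (upd < 0.0 && src[i] >= 0.0) upd = 0.0;  // SOR overshoot
          double del = std::fabs(upd - c[i]);
          if (del > maxdel) maxdel = del;
          c[i] = upd;
        }
    if (maxdel < tol) break;
  }
  return List::create(_["field"] = c, _["iterations"] = it + 1,
                      _["max_delta"] = maxdel);
}

// Stochastic degradation of frozen Bruch's-membrane voxels by the MMP field:
// each BrM voxel converts to Medium with probability min(1, rate*c*dt).
// Returns the removed voxel indices (1-based) so R can update ledgers.
// [[Rcpp::export(name = ".degrade_brm_cpp")]]
IntegerVector degrade_brm_cpp(IntegerVector site, IntegerVector cellType,
                              NumericVector mmp, double rate, double dt) {
  std::vector<int> removed;
  RNGScope scope;
  for (int i = 0; i < site.size(); ++i) {
    int id = site[i];
    if (id == 0 || cellType[id - 1] != T_BRM) continue;
    double p = rate * mmp[i] * dt;
    if (p <= 0.0) continue;
    if (p > 1.0) p = 1.0;
    if (unif_rand() < p) removed.push_back(i + 1);
  }
  return wrap(removed);
}
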