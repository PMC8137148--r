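// Lattice core of the cellular Potts model: Metropolis kernel, incremental
// and global Hamiltonian, neighbour-graph scan, fragment cleanup, division
// relabeling. Cell ids are 1-based lattice labels; 0 is free space. All
// per-cell vectors passed from R are indexed by id (element id-1) and are
// modified in place where noted -- the R wrapper owns those vectors and
// guarantees they are not shared.
//
// Randomness comes from R's generator (unif_rand), so a single set.seed()
// on the R side makes whole simulations reproducible.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Fast counter-based RNG for the attempt loop (xoshiro256+), seeded from
// R's generator at kernel entry so a single set.seed() still fixes the
// whole simulation.
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9e3779b97f4a7c15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix(seed);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// Neighbourhood offsets. order 1 = von Neumann (4), order 2 = Moore (8).
static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DR4V[4] = {-1, 1, 0, 0};
static const int DC4V[4] = {0, 0, -1, 1};

struct Grid {
  int *lab;
  int H, W;
  bool periodic;
  inline bool wrap(int &r, int &c) const {
    // returns false if the site falls outside a fixed frame (wall)
    if (periodic) {
      if (r < 0) r += H; else if (r >= H) r -= H;
      if (c < 0) c += W; else if (c >= W) c -= W;
      return true;
    }
    return r >= 0 && r < H && c >= 0 && c < W;
  }
  inline int at(int r, int c) const { return lab[r + (long)c * H]; }
  inline void set(int r, int c, int v) { lab[r + (long)c * H] = v; }
};

static inline int type_of(int label, const int *typ) {
  return label == 0 ? 0 : typ[label - 1];
}

// Adhesion + elastic part of the energy change for copying label `cand`
// onto site (tr, tc). J is a flat (ntp x ntp) row-major type matrix;
// out-of-frame neighbours behave as free space (type 0, label 0).
static double flip_dh(const Grid &g, int tr, int tc, int cand,
                      const int *A, const double *AT, const double *lam,
                      const int *typ, const double *J, int ntp,
                      const int *dr, const int *dc, int nb) {
  int old = g.at(tr, tc);
  double dh = 0.0;
  int tc_cand = type_of(cand, typ), tc_old = type_of(old, typ);
  for (int k = 0; k < nb; ++k) {
    int r = tr + dr[k], c = tc + dc[k];
    int ln, lt;
    if (g.wrap(r, c)) { ln = g.at(r, c); lt = type_of(ln, typ); }
    else { ln = 0; lt = 0; }
    if (cand != ln) dh += J[tc_cand * ntp + lt];
    if (old != ln)  dh -= J[tc_old * ntp + lt];
  }
  // elastic: free space (label 0) carries no target area
  if (old > 0)  dh += lam[old - 1]  * (1.0 - 2.0 * (A[old - 1]  - AT[old - 1]));
  if (cand > 0) dh += lam[cand - 1] * (1.0 + 2.0 * (A[cand - 1] - AT[cand - 1]));
  return dh;
}

static void pick_offsets(int order, const int *&dr, const int *&dc, int &nb) {
  if (order <= 1) { dr = DR4V; dc = DC4V; nb = 4; }
  else { dr = DR8; dc = DC8; nb = 8; }
}

// [[Rcpp::export]]
List cpp_run_mcs(IntegerMatrix labels, int n_mcs,
                 IntegerVector A, NumericVector AT, NumericVector lam,
                 IntegerVector typ, NumericVector polx, NumericVector poly,
                 NumericVector lamm, NumericMatrix J,
                 double temp, bool periodic, int neighbor_order) {
  Grid g{labels.begin(), labels.nrow(), labels.ncol(), periodic};
  const int *dr, *dc; int nb;
  pick_offsets(neighbor_order, dr, dc, nb);
  int *a = A.begin();
  double *at = AT.begin(); double *lm = lam.begin();
  int *tp = typ.begin();
  double *px = polx.begin(), *py = poly.begin(), *lmm = lamm.begin();
  int ntp = J.nrow();
  std::vector<double> Jflat((size_t)ntp * ntp);
  for (int i = 0; i < ntp; ++i)
    for (int j = 0; j < ntp; ++j) Jflat[(size_t)i * ntp + j] = J(i, j);
  const double *Jf = Jflat.data();
  const double inv_sqrt2 = 1.0 / std::sqrt(2.0);

  uint64_t seed64;
  {
    RNGScope scope;
    seed64 = ((uint64_t)(unif_rand() * 4294967296.0) << 32) ^
             (uint64_t)(unif_rand() * 4294967296.0);
  }
  Xoshiro rng(seed64);
  long HW = (long)g.H * g.W;
  double attempts = 0, accepts = 0, dh_sum = 0;
  for (int s = 0; s < n_mcs; ++s) {
    for (long t = 0; t < HW; ++t) {
      attempts += 1;
      long idx = (long)(rng.unif() * HW);
      if (idx >= HW) idx = HW - 1;
      int tr = (int)(idx % g.H), tcc = (int)(idx / g.H);
      int k = (int)(rng.next() & 0xffff) % nb;
      int sr = tr + dr[k], sc = tcc + dc[k];
      if (!g.wrap(sr, sc)) continue;      // wall cannot be copied from
      int cand = g.at(sr, sc);
      int old = g.lab[idx];
      if (cand == old) continue;
      double dh = flip_dh(g, tr, tcc, cand, a, at, lm, tp, Jf, ntp, dr, dc, nb);
      if (cand > 0 && lmm[cand - 1] != 0.0) {
        // motion of the advancing cell along its polarity lowers the energy
        double sx = (double)(tcc - sc), sy = (double)(tr - sr);
        if (sx != 0.0 && sy != 0.0) { sx *= inv_sqrt2; sy *= inv_sqrt2; }
        dh -= lmm[cand - 1] * (px[cand - 1] * sx + py[cand - 1] * sy);
      }
      bool acc = dh <= 0.0 || rng.unif() < std::exp(-dh / temp);
      if (acc) {
        g.lab[idx] = cand;
        if (old > 0) a[old - 1] -= 1;
        if (cand > 0) a[cand - 1] += 1;
        dh_sum += dh;
        accepts += 1;
      }
    }
  }
  return List::create(_["attempts"] = attempts, _["accepts"] = accepts,
                      _["dh_sum"] = dh_sum);
}

// [[Rcpp::export]]
double cpp_total_energy(IntegerMatrix labels, IntegerVector A,
                        NumericVector AT, NumericVector lam, IntegerVector typ,
                        NumericMatrix J, bool periodic, int neighbor_order) {
  Grid g{labels.begin(), labels.nrow(), labels.ncol(), periodic};
  const int *dr, *dc; int nb;
  pick_offsets(neighbor_order, dr, dc, nb);
  int ntp = J.nrow();
  double e_pair = 0, e_wall = 0;
  for (int c = 0; c < g.W; ++c) {
    for (int r = 0; r < g.H; ++r) {
      int l0 = g.at(r, c), t0 = type_of(l0, typ.begin());
      for (int k = 0; k < nb; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (g.wrap(rr, cc)) {
          int l1 = g.at(rr, cc);
          if (l1 != l0) e_pair += J(t0, type_of(l1, typ.begin()));
        } else if (l0 != 0) {
          e_wall += J(t0, 0); // fixed-frame wall behaves as free space
        }
      }
    }
  }
  double e = 0.5 * e_pair + e_wall;
  for (int i = 0; i < A.size(); ++i)
    if (typ[i] > 0) e += lam[i] * (A[i] - AT[i]) * (A[i] - AT[i]);
  return e;
}

// [[Rcpp::export]]
double cpp_delta_energy(IntegerMatrix labels, IntegerVector A,
                        NumericVector AT, NumericVector lam, IntegerVector typ,
                        NumericMatrix J, bool periodic, int neighbor_order,
                        int tr, int tc, int cand,
                        int sr, int sc,
                        NumericVector polx, NumericVector poly,
                        NumericVector lamm) {
  Grid g{labels.begin(), labels.nrow(), labels.ncol(), periodic};
  const int *dr, *dc; int nb;
  pick_offsets(neighbor_order, dr, dc, nb);
  int ntp = J.nrow();
  std::vector<double> Jflat((size_t)ntp * ntp);
  for (int i = 0; i < ntp; ++i)
    for (int j = 0; j < ntp; ++j) Jflat[(size_t)i * ntp + j] = J(i, j);
  if (cand == g.at(tr, tc)) return 0.0;
  double dh = flip_dh(g, tr, tc, cand, A.begin(), AT.begin(), lam.begin(),
                      typ.begin(), Jflat.data(), ntp, dr, dc, nb);
  if (sr >= 0 && cand > 0 && lamm[cand - 1] != 0.0) {
    double sx = (double)(tc - sc), sy = (double)(tr - sr);
    double n = std::sqrt(sx * sx + sy * sy);
    if (n > 0) { sx /= n; sy /= n; }
    dh -= lamm[cand - 1] * (polx[cand - 1] * sx + poly[cand - 1] * sy);
  }
  return dh;
}

// [[Rcpp::export]]
void cpp_apply_flip(IntegerMatrix labels, IntegerVector A, int tr, int tc,
                    int cand) {
  int old = labels(tr, tc);
  labels(tr, tc) = cand;
  if (old > 0) A[old - 1] -= 1;
  if (cand > 0) A[cand - 1] += 1;
}

// Neighbour graph scan. Edges are unordered cell pairs with the count of
// adjacent pixel pairs along their interface; perimeter is the per-cell
// count of (site, neighbour) pairs whose labels differ, including free
// space and fixed-frame walls.
// [[Rcpp::export]]
List cpp_neighbor_graph(IntegerMatrix labels, int adjacency, bool periodic) {
  Grid g{labels.begin(), labels.nrow(), labels.ncol(), periodic};
  const int *dr, *dc; int nb;
  pick_offsets(adjacency == 8 ? 2 : 1, dr, dc, nb);
  int maxid = 0;
  long HW = (long)g.H * g.W;
  for (long i = 0; i < HW; ++i) if (g.lab[i] > maxid) maxid = g.lab[i];
  std::vector<double> perim(maxid + 1, 0.0);
  std::unordered_map<long long, long> edges;
  for (int c = 0; c < g.W; ++c) {
    for (int r = 0; r < g.H; ++r) {
      int l0 = g.at(r, c);
      if (l0 == 0) continue;
      for (int k = 0; k < nb; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        int l1 = g.wrap(rr, cc) ? g.at(rr, cc) : 0;
        if (l1 == l0) continue;
        perim[l0] += 1;
        if (l1 > 0 && l1 > l0) {
          long long key = (long long)l0 * (maxid + 1) + l1;
          edges[key] += 1;
        }
      }
    }
  }
  int ne = edges.size();
  IntegerVector ea(ne), eb(ne), ew(ne);
  int i = 0;
  for (auto &kv : edges) {
    ea[i] = (int)(kv.first / (maxid + 1));
    eb[i] = (int)(kv.first % (maxid + 1));
    ew[i] = (int)kv.second;
    ++i;
  }
  return List::create(_["edge_a"] = ea, _["edge_b"] = eb,
                      _["shared_boundary"] = ew,
                      _["perimeter"] = NumericVector(perim.begin() + 1, perim.end()));
}

// Per-id pixel counts and centroid sums (pixel-centre coordinates,
// 0-based row/col + 0.5).
// [[Rcpp::export]]
List cpp_centroids(IntegerMatrix labels, int maxid) {
  int H = labels.nrow(), W = labels.ncol();
  std::vector<double> sx(maxid + 1, 0.0), sy(maxid + 1, 0.0);
  std::vector<int> n(maxid + 1, 0);
  const int *lab = labels.begin();
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      int l = lab[r + (long)c * H];
      if (l > 0 && l <= maxid) {
        sx[l] += c + 0.5; sy[l] += r + 0.5; n[l] += 1;
      }
    }
  return List::create(
      _["n"] = IntegerVector(n.begin() + 1, n.end()),
      _["sum_x"] = NumericVector(sx.begin() + 1, sx.end()),
      _["sum_y"] = NumericVector(sy.begin() + 1, sy.end()));
}

// Free minor disconnected fragments (< min_px pixels, and never the largest
// component of a cell) back to free space; updates A in place. 4-connected
// components define a fragment. Returns the number of pixels freed per id.
// [[Rcpp::export]]
IntegerVector cpp_fragment_cleanup(IntegerMatrix labels, IntegerVector A,
                                   int min_px, bool periodic) {
  Grid g{labels.begin(), labels.nrow(), labels.ncol(), periodic};
  long HW = (long)g.H * g.W;
  std::vector<int> comp(HW, -1);
  std::vector<int> comp_size, comp_label;
  std::vector<long> stack;
  int ncomp = 0;
  for (long i = 0; i < HW; ++i) {
    if (g.lab[i] == 0 || comp[i] >= 0) continue;
    int lab0 = g.lab[i];
    int cid = ncomp++;
    comp_label.push_back(lab0);
    int size = 0;
    stack.clear();
    stack.push_back(i);
    comp[i] = cid;
    while (!stack.empty()) {
      long p = stack.back(); stack.pop_back();
      ++size;
      int r = (int)(p % g.H), c = (int)(p / g.H);
      for (int k = 0; k < 4; ++k) {
        int rr = r + DR4V[k], cc = c + DC4V[k];
        if (!g.wrap(rr, cc)) continue;
        long q = rr + (long)cc * g.H;
        if (comp[q] < 0 && g.lab[q] == lab0) { comp[q] = cid; stack.push_back(q); }
      }
    }
    comp_size.push_back(size);
  }
  // largest component per label survives unconditionally
  std::unordered_map<int, int> best; // label -> comp id
  for (int c = 0; c < ncomp; ++c) {
    auto it = best.find(comp_label[c]);
    if (it == best.end() || comp_size[c] > comp_size[it->second])
      best[comp_label[c]] = c;
  }
  IntegerVector freed(A.size(), 0);
  for (long i = 0; i < HW; ++i) {
    int c = comp[i];
    if (c < 0) continue;
    if (c != best[comp_label[c]] && comp_size[c] < min_px) {
      int l = comp_label[c];
      g.lab[i] = 0;
      A[l - 1] -= 1;
      freed[l - 1] += 1;
    }
  }
  return freed;
}

// Split each cell in `ids` along the line through its centroid perpendicular
// to the major axis of its pixel second-moment tensor; pixels on the
// positive side take the corresponding new id. Degenerate (isotropic)
// moment tensors fall back to the supplied random angle. Areas are updated
// in place. Returns per-cell daughter areas and a success flag.
// [[Rcpp::export]]
List cpp_divide_cells(IntegerMatrix labels, IntegerVector A,
                      IntegerVector ids, IntegerVector new_ids,
                      NumericVector fallback_angle) {
  int H = labels.nrow(), W = labels.ncol();
  int *lab = labels.begin();
  std::unordered_map<int, int> pos; // id -> index in ids
  for (int i = 0; i < ids.size(); ++i) pos[ids[i]] = i;
  std::vector<std::vector<long>> px(ids.size());
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      long p = r + (long)c * H;
      auto it = pos.find(lab[p]);
      if (it != pos.end()) px[it->second].push_back(p);
    }
  IntegerVector a1(ids.size()), a2(ids.size());
  LogicalVector ok(ids.size());
  for (int i = 0; i < ids.size(); ++i) {
    auto &pts = px[i];
    int n = pts.size();
    if (n < 2) { ok[i] = false; continue; }
    double cx = 0, cy = 0;
    for (long p : pts) { cx += (double)(p / H); cy += (double)(p % H); }
    cx /= n; cy /= n;
    double sxx = 0, syy = 0, sxy = 0;
    for (long p : pts) {
      double dx = (double)(p / H) - cx, dy = (double)(p % H) - cy;
      sxx += dx * dx; syy += dy * dy; sxy += dx * dy;
    }
    double theta;
    if (std::sqrt((sxx - syy) * (sxx - syy) + 4 * sxy * sxy) < 1e-9 * (sxx + syy + 1e-12))
      theta = fallback_angle[i];
    else
      theta = 0.5 * std::atan2(2 * sxy, sxx - syy); // major axis direction
    double ux = std::cos(theta), uy = std::sin(theta);
    int n2 = 0;
    for (long p : pts) {
      double proj = ((double)(p / H) - cx) * ux + ((double)(p % H) - cy) * uy;
      if (proj > 1e-9) { lab[p] = new_ids[i]; ++n2; }
    }
    if (n2 == 0 || n2 == n) {
      // pathological partition: revert and defer
      for (long p : pts) lab[p] = ids[i];
      ok[i] = false;
      continue;
    }
    a1[i] = n - n2; a2[i] = n2;
    A[ids[i] - 1] = n - n2;
    A[new_ids[i] - 1] = n2;
    ok[i] = true;
  }
  return List::create(_["area1"] = a1, _["area2"] = a2, _["ok"] = ok);
}

// [[Rcpp::export]]
void cpp_erase_cells(IntegerMatrix labels, IntegerVector A, IntegerVector ids) {
  int H = labels.nrow(), W = labels.ncol();
  int *lab = labels.begin();
  std::vector<bool> kill;
  int maxid = 0;
  for (int i = 0; i < ids.size(); ++i) if (ids[i] > maxid) maxid = ids[i];
  kill.assign(maxid + 1, false);
  for (int i = 0; i < ids.size(); ++i) kill[ids[i]] = true;
  for (long p = 0; p < (long)H * W; ++p) {
    int l = lab[p];
    if (l > 0 && l <= maxid && kill[l]) { lab[p] = 0; A[l - 1] -= 1; }
  }
}
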