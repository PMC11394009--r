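#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Molecular graphs arrive as a bond matrix (m x 3: i, j, order; 1-based atom
// indices). All heavy lifting that would be quartic/exponential in R lives here.

namespace {

struct Graph {
  int n;
  std::vector<std::vector<int> > adj;      // neighbour atom ids
  std::vector<std::vector<int> > adjBond;  // parallel bond ids
  std::vector<int> bi, bj, border;
  Graph(int n_, const IntegerMatrix &bonds) : n(n_), adj(n_), adjBond(n_) {
    int m = bonds.nrow();
    bi.resize(m); bj.resize(m); border.resize(m);
    for (int e = 0; e < m; ++e) {
      int i = bonds(e, 0) - 1, j = bonds(e, 1) - 1;
      bi[e] = i; bj[e] = j;
      border[e] = bonds.ncol() > 2 ? bonds(e, 2) : 1;
      adj[i].push_back(j); adjBond[i].push_back(e);
      adj[j].push_back(i); adjBond[j].push_back(e);
    }
  }
  int nbonds() const { return (int)bi.size(); }
};

// ---------------------------------------------------------------------------
// Chi indices: enumerate connected edge subgraphs of size 1..kmax via ESU on
// the line graph, classify (path / chain / cluster / path-cluster), accumulate
// sum over subgraphs of prod(weight)^-1/2 for each supplied weight column.
// ---------------------------------------------------------------------------

struct ChiAcc {
  // sums[w][type][order], counts[type][order]; type 0=p,1=ch,2=c,3=pc
  std::vector<std::vector<std::vector<double> > > sums;
  std::vector<std::vector<int> > counts;
  ChiAcc(int nw, int kmax)
      : sums(nw, std::vector<std::vector<double> >(4, std::vector<double>(kmax + 1, 0.0))),
        counts(4, std::vector<int>(kmax + 1, 0)) {}
};

class ChiEnum {
public:
  ChiEnum(const Graph &g, const NumericMatrix &w, int kmax)
      : g_(g), w_(w), kmax_(kmax), acc_((int)w.ncol(), kmax),
        ladj_(g.nbonds()), inSub_(g.nbonds(), false), blocked_(g.nbonds(), 0) {
    // line graph adjacency: bonds sharing an atom
    for (int a = 0; a < g_.n; ++a) {
      const std::vector<int> &bs = g_.adjBond[a];
      for (size_t x = 0; x < bs.size(); ++x)
        for (size_t y = x + 1; y < bs.size(); ++y) {
          ladj_[bs[x]].push_back(bs[y]);
          ladj_[bs[y]].push_back(bs[x]);
        }
    }
  }

  void run() {
    int m = g_.nbonds();
    for (int v = 0; v < m; ++v) {
      sub_.clear(); sub_.push_back(v); inSub_[v] = true;
      record();
      std::vector<int> ext;
      for (size_t t = 0; t < ladj_[v].size(); ++t)
        if (ladj_[v][t] > v) { ext.push_back(ladj_[v][t]); }
      std::sort(ext.begin(), ext.end());
      ext.erase(std::unique(ext.begin(), ext.end()), ext.end());
      extend(ext, v);
      inSub_[v] = false;
    }
  }

  const ChiAcc &acc() const { return acc_; }

private:
  void extend(std::vector<int> ext, int root) {
    if ((int)sub_.size() == kmax_) return;
    while (!ext.empty()) {
      int w = ext.back(); ext.pop_back();
      std::vector<int> ext2 = ext;
      for (size_t t = 0; t < ladj_[w].size(); ++t) {
        int u = ladj_[w][t];
        if (u <= root || inSub_[u]) continue;
        bool isNbrOfSub = false;
        for (size_t s = 0; s < sub_.size(); ++s) {
          const std::vector<int> &ns = ladj_[sub_[s]];
          if (std::find(ns.begin(), ns.end(), u) != ns.end()) { isNbrOfSub = true; break; }
        }
        if (!isNbrOfSub && std::find(ext2.begin(), ext2.end(), u) == ext2.end())
          ext2.push_back(u);
      }
      sub_.push_back(w); inSub_[w] = true;
      record();
      extend(ext2, root);
      sub_.pop_back(); inSub_[w] = false;
    }
  }

  void record() {
    int k = (int)sub_.size();
    int atoms[16]; int deg[16]; int na = 0;
    for (int e = 0; e < k; ++e) {
      int ends[2] = { g_.bi[sub_[e]], g_.bj[sub_[e]] };
      for (int s = 0; s < 2; ++s) {
        int a = ends[s], pos = -1;
        for (int t = 0; t < na; ++t) if (atoms[t] == a) { pos = t; break; }
        if (pos < 0) { atoms[na] = a; deg[na] = 1; ++na; }
        else ++deg[pos];
      }
    }
    int type;
    if (na == k) type = 1;                       // contains a cycle -> chain
    else {                                       // tree
      int maxdeg = 0; bool has2 = false;
      for (int t = 0; t < na; ++t) { maxdeg = std::max(maxdeg, deg[t]); if (deg[t] == 2) has2 = true; }
      if (maxdeg <= 2) type = 0;                 // path
      else type = has2 ? 3 : 2;                  // path-cluster / cluster
    }
    acc_.counts[type][k] += 1;
    for (int wcol = 0; wcol < w_.ncol(); ++wcol) {
      double prod = 1.0; bool ok = true;
      for (int t = 0; t < na; ++t) {
        double d = w_(atoms[t], wcol);
        if (d <= 0) { ok = false; break; }
        prod *= d;
      }
      if (ok) acc_.sums[wcol][type][k] += 1.0 / std::sqrt(prod);
    }
  }

  const Graph &g_;
  const NumericMatrix &w_;
  int kmax_;
  ChiAcc acc_;
  std::vector<std::vector<int> > ladj_;
  std::vector<bool> inSub_;
  std::vector<int> blocked_;
  std::vector<int> sub_;
};

}  // namespace

// [[Rcpp::export]]
List cpp_chi_subgraphs(int natoms, IntegerMatrix bonds, NumericMatrix weights, int kmax) {
  Graph g(natoms, bonds);
  ChiEnum en(g, weights, kmax);
  en.run();
  const ChiAcc &a = en.acc();
  CharacterVector types = CharacterVector::create("p", "ch", "c", "pc");
  List sums(weights.ncol());
  for (int wcol = 0; wcol < weights.ncol(); ++wcol) {
    NumericMatrix s(4, kmax + 1);
    for (int t = 0; t < 4; ++t)
      for (int k = 0; k <= kmax; ++k) s(t, k) = a.sums[wcol][t][k];
    rownames(s) = types;
    sums[wcol] = s;
  }
  IntegerMatrix cnt(4, kmax + 1);
  for (int t = 0; t < 4; ++t)
    for (int k = 0; k <= kmax; ++k) cnt(t, k) = a.counts[t][k];
  rownames(cnt) = types;
  return List::create(_["sums"] = sums, _["counts"] = cnt);
}

// ---------------------------------------------------------------------------
// Detour matrix: longest simple path (in bonds) between every atom pair.
// DFS over simple paths with a global step budget; returns -1 on overflow.
// ---------------------------------------------------------------------------

namespace {
struct DetourDFS {
  const Graph &g;
  std::vector<int> best;
  std::vector<bool> vis;
  long long steps, budget;
  bool overflow;
  DetourDFS(const Graph &g_, long long budget_)
      : g(g_), vis(g_.n, false), steps(0), budget(budget_), overflow(false) {}
  void dfs(int v, int depth) {
    if (overflow) return;
    if (++steps > budget) { overflow = true; return; }
    vis[v] = true;
    if (depth > best[v]) best[v] = depth;
    for (size_t t = 0; t < g.adj[v].size(); ++t) {
      int u = g.adj[v][t];
      if (!vis[u]) dfs(u, depth + 1);
    }
    vis[v] = false;
  }
};
}

// [[Rcpp::export]]
IntegerMatrix cpp_detour_matrix(int natoms, IntegerMatrix bonds, double budget = 2e7) {
  Graph g(natoms, bonds);
  IntegerMatrix D(natoms, natoms);
  long long spent = 0;
  for (int s = 0; s < natoms; ++s) {
    DetourDFS d(g, (long long)budget - spent);
    d.best.assign(natoms, 0);
    d.dfs(s, 0);
    spent += d.steps;
    if (d.overflow) { D(0, 0) = -1; return D; }
    for (int t = 0; t < natoms; ++t) D(s, t) = d.best[t];
  }
  return D;
}

// ---------------------------------------------------------------------------
// SiRMS simplexes: every 4-atom subset keyed by the canonical labelled induced
// subgraph. mode 0 = single structure (origins ignored, unit counts);
// mode 1 = mixture (molar-fraction weighting, doubled-minor rule, fragment cap).
// ---------------------------------------------------------------------------

namespace {

static const int PERM4[24][4] = {
  {0,1,2,3},{0,1,3,2},{0,2,1,3},{0,2,3,1},{0,3,1,2},{0,3,2,1},
  {1,0,2,3},{1,0,3,2},{1,2,0,3},{1,2,3,0},{1,3,0,2},{1,3,2,0},
  {2,0,1,3},{2,0,3,1},{2,1,0,3},{2,1,3,0},{2,3,0,1},{2,3,1,0},
  {3,0,1,2},{3,0,2,1},{3,1,0,2},{3,1,2,0},{3,2,0,1},{3,2,1,0}};
// pair order for adjacency bits
static const int PAIRS[6][2] = {{0,1},{0,2},{0,3},{1,2},{1,3},{2,3}};

inline uint64_t canon_key(const int lab[4], const int ori[4], const bool adj[4][4]) {
  uint64_t best = ~0ULL;
  for (int p = 0; p < 24; ++p) {
    const int *pm = PERM4[p];
    uint64_t key = 0;
    for (int i = 0; i < 4; ++i) {
      uint64_t v = ((uint64_t)lab[pm[i]] << 2) | (uint64_t)ori[pm[i]];
      key = (key << 14) | v;
    }
    uint64_t bits = 0;
    for (int q = 0; q < 6; ++q)
      bits = (bits << 1) | (adj[pm[PAIRS[q][0]]][pm[PAIRS[q][1]]] ? 1u : 0u);
    key = (key << 6) | bits;
    if (key < best) best = key;
  }
  return best;
}

inline int ncomp4(const bool adj[4][4]) {
  int parent[4] = {0, 1, 2, 3};
  for (int i = 0; i < 4; ++i)
    for (int j = i + 1; j < 4; ++j)
      if (adj[i][j]) {
        int ri = i, rj = j;
        while (parent[ri] != ri) ri = parent[ri];
        while (parent[rj] != rj) rj = parent[rj];
        if (ri != rj) parent[std::max(ri, rj)] = std::min(ri, rj);
      }
  int nc = 0;
  for (int i = 0; i < 4; ++i) {
    int r = i; while (parent[r] != r) r = parent[r];
    if (r == i) ++nc;
  }
  return nc;
}

}  // namespace

// [[Rcpp::export]]
DataFrame cpp_simplexes(int natoms, IntegerMatrix bonds, IntegerVector labels,
                        IntegerVector origin, NumericVector fracByOrigin,
                        int mode, int fragCap = 3, bool capSingle = false) {
  std::vector<std::vector<bool> > A(natoms, std::vector<bool>(natoms, false));
  for (int e = 0; e < bonds.nrow(); ++e) {
    int i = bonds(e, 0) - 1, j = bonds(e, 1) - 1;
    A[i][j] = A[j][i] = true;
  }
  std::unordered_map<uint64_t, double> table;
  std::unordered_map<uint64_t, int> comps;  // key -> ncomp (redundant w/ bits, cached)
  int lab[4], ori[4];
  bool adj[4][4];
  for (int a = 0; a < natoms; ++a)
    for (int b = a + 1; b < natoms; ++b)
      for (int c = b + 1; c < natoms; ++c)
        for (int d = c + 1; d < natoms; ++d) {
          int idx[4] = {a, b, c, d};
          int omask = 0;
          for (int i = 0; i < 4; ++i) {
            lab[i] = labels[idx[i]];
            ori[i] = mode == 1 ? origin[idx[i]] : 0;
            omask |= 1 << ori[i];
          }
          for (int i = 0; i < 4; ++i) {
            adj[i][i] = false;
            for (int j = i + 1; j < 4; ++j)
              adj[i][j] = adj[j][i] = A[idx[i]][idx[j]];
          }
          int nc = ncomp4(adj);
          double wgt = 1.0;
          if (mode == 1) {
            int nOri = 0; double minf = 1e300;
            for (int o = 0; o < (int)fracByOrigin.size(); ++o)
              if (omask & (1 << o)) { ++nOri; minf = std::min(minf, (double)fracByOrigin[o]); }
            if (nOri == 1) {
              if (capSingle && nc > fragCap) continue;
              wgt = minf;  // SiRMS-S: the component's own molar fraction
            } else {
              if (nc > fragCap) continue;
              wgt = 2.0 * minf;  // SiRMS-M: doubled minor fraction
            }
          }
          uint64_t key = canon_key(lab, ori, adj);
          table[key] += wgt;
          comps[key] = nc;
        }
  int nk = (int)table.size();
  CharacterVector keys(nk);
  NumericVector counts(nk);
  IntegerVector ncv(nk);
  int r = 0;
  for (std::unordered_map<uint64_t, double>::const_iterator it = table.begin();
       it != table.end(); ++it, ++r) {
    uint64_t key = it->first;
    uint64_t bits = key & 0x3F;
    char buf[96];
    int l[4], o[4];
    uint64_t rest = key >> 6;
    for (int i = 3; i >= 0; --i) {
      uint64_t v = rest & 0x3FFF;
      l[i] = (int)(v >> 2); o[i] = (int)(v & 3);
      rest >>= 14;
    }
    snprintf(buf, sizeof(buf), "%d.%d.%d.%d|%c%c%c%c%c%c|%d%d%d%d",
             l[0], l[1], l[2], l[3],
             (char)('0' + ((bits >> 5) & 1)), (char)('0' + ((bits >> 4) & 1)),
             (char)('0' + ((bits >> 3) & 1)), (char)('0' + ((bits >> 2) & 1)),
             (char)('0' + ((bits >> 1) & 1)), (char)('0' + (bits & 1)),
             o[0], o[1], o[2], o[3]);
    keys[r] = buf;
    counts[r] = it->second;
    ncv[r] = comps[key];
  }
  return DataFrame::create(_["key"] = keys, _["count"] = counts,
                           _["nfrag"] = ncv, _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Count fingerprints
// ---------------------------------------------------------------------------

namespace {
inline uint64_t fnv1a(const std::vector<uint32_t> &items) {
  uint64_t h = 1469598103934665603ULL;
  for (size_t i = 0; i < items.size(); ++i) {
    uint32_t x = items[i];
    for (int b = 0; b < 4; ++b) {
      h ^= (x >> (8 * b)) & 0xFF;
      h *= 1099511628211ULL;
    }
  }
  return h;
}

struct PathFP {
  const Graph &g;
  const IntegerVector &atype;
  int minlen, maxlen, width;
  std::vector<int> counts;
  std::vector<bool> vis;
  std::vector<int> pathAtoms, pathBonds;
  PathFP(const Graph &g_, const IntegerVector &at, int mn, int mx, int w)
      : g(g_), atype(at), minlen(mn), maxlen(mx), width(w),
        counts(w, 0), vis(g_.n, false) {}
  void record() {
    int np = (int)pathBonds.size();
    // canonical direction: lexicographically smaller item sequence
    std::vector<uint32_t> fwd, rev;
    for (size_t i = 0; i < pathAtoms.size(); ++i) {
      fwd.push_back((uint32_t)atype[pathAtoms[i]]);
      if (i < pathBonds.size()) fwd.push_back(0x80000000u | (uint32_t)g.border[pathBonds[i]]);
    }
    for (int i = (int)pathAtoms.size() - 1; i >= 0; --i) {
      rev.push_back((uint32_t)atype[pathAtoms[i]]);
      if (i > 0) rev.push_back(0x80000000u | (uint32_t)g.border[pathBonds[i - 1]]);
    }
    std::vector<uint32_t> &canon = (fwd <= rev) ? fwd : rev;
    canon.insert(canon.begin(), (uint32_t)np);
    counts[(int)(fnv1a(canon) % (uint64_t)width)] += 1;
  }
  void dfs(int v) {
    vis[v] = true;
    pathAtoms.push_back(v);
    int np = (int)pathBonds.size();
    if (np >= minlen) record();
    if (np < maxlen) {
      for (size_t t = 0; t < g.adj[v].size(); ++t) {
        int u = g.adj[v][t];
        if (vis[u]) continue;
        pathBonds.push_back(g.adjBond[v][t]);
        dfs(u);
        pathBonds.pop_back();
      }
    }
    pathAtoms.pop_back();
    vis[v] = false;
  }
};
}

// [[Rcpp::export]]
IntegerVector cpp_path_fp(int natoms, IntegerMatrix bonds, IntegerVector atomType,
                          int minPath, int maxPath, int width) {
  Graph g(natoms, bonds);
  PathFP fp(g, atomType, minPath, maxPath, width);
  for (int v = 0; v < natoms; ++v) fp.dfs(v);
  // every undirected path was visited once from each end
  IntegerVector out(width);
  for (int b = 0; b < width; ++b) out[b] = fp.counts[b] / 2;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_morgan_fp(int natoms, IntegerMatrix bonds, IntegerVector invariants,
                            int radius, int width) {
  Graph g(natoms, bonds);
  IntegerVector out(width);
  std::vector<uint64_t> id(natoms), nid(natoms);
  for (int a = 0; a < natoms; ++a) {
    std::vector<uint32_t> it;
    it.push_back((uint32_t)invariants[a]);
    id[a] = fnv1a(it);
    out[(int)(id[a] % (uint64_t)width)] += 1;
  }
  for (int r = 1; r <= radius; ++r) {
    for (int a = 0; a < natoms; ++a) {
      std::vector<std::pair<uint64_t, uint64_t> > nbr;
      for (size_t t = 0; t < g.adj[a].size(); ++t)
        nbr.push_back(std::make_pair((uint64_t)g.border[g.adjBond[a][t]], id[g.adj[a][t]]));
      std::sort(nbr.begin(), nbr.end());
      std::vector<uint32_t> items;
      items.push_back((uint32_t)r);
      items.push_back((uint32_t)(id[a] & 0xFFFFFFFF));
      items.push_back((uint32_t)(id[a] >> 32));
      for (size_t t = 0; t < nbr.size(); ++t) {
        items.push_back((uint32_t)nbr[t].first);
        items.push_back((uint32_t)(nbr[t].second & 0xFFFFFFFF));
        items.push_back((uint32_t)(nbr[t].second >> 32));
      }
      nid[a] = fnv1a(items);
      out[(int)(nid[a] % (uint64_t)width)] += 1;
    }
    id = nid;
  }
  return out;
}
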