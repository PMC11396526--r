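// Combinatorial kernels: ring-spiral windup/enumeration of fullerene duals,
// canonical spiral search, and the memoized Zhang-Zhang polynomial recursion.
// Counts are kept in 64-bit integers (exact far beyond the C20-C70 range)
// and returned to R as doubles.

#include <Rcpp.h>
#include <cstdint>
#include <deque>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// 128-bit vertex-subset keys (graphs up to 128 vertices)

struct Key {
  uint64_t lo, hi;
  bool operator==(const Key& o) const { return lo == o.lo && hi == o.hi; }
};

struct KeyHash {
  size_t operator()(const Key& k) const {
    uint64_t h = k.lo * 0x9E3779B97F4A7C15ULL;
    h ^= k.hi + 0x9E3779B97F4A7C15ULL + (h << 6) + (h >> 2);
    h ^= h >> 29;
    h *= 0xBF58476D1CE4E5B9ULL;
    h ^= h >> 32;
    return static_cast<size_t>(h);
  }
};

static inline bool key_empty(const Key& k) { return k.lo == 0 && k.hi == 0; }
static inline bool key_has(const Key& k, int v) {
  return v < 64 ? (k.lo >> v) & 1ULL : (k.hi >> (v - 64)) & 1ULL;
}
static inline void key_clear(Key& k, int v) {
  if (v < 64) k.lo &= ~(1ULL << v); else k.hi &= ~(1ULL << (v - 64));
}
static inline void key_set(Key& k, int v) {
  if (v < 64) k.lo |= 1ULL << v; else k.hi |= 1ULL << (v - 64);
}
static inline bool key_subset(const Key& a, const Key& b) {
  return (a.lo & ~b.lo) == 0 && (a.hi & ~b.hi) == 0;
}
static inline Key key_minus(const Key& a, const Key& b) {
  Key r; r.lo = a.lo & ~b.lo; r.hi = a.hi & ~b.hi; return r;
}

// ---------------------------------------------------------------------------
// Zhang-Zhang polynomial by vertex-branching decomposition.
//
// Every recursion state is an induced subgraph identified by its live-vertex
// set S, so the memo key is exact and collision-free.  For the pivot u (live
// vertex with fewest live neighbours, smallest index on ties):
//   ZZ(S) = sum_{v in N(u) ∩ S} ZZ(S \ {u,v})
//         + x * sum_{rings h: u in h, h ⊆ S} ZZ(S \ V(h))
// with ZZ(empty) = 1 and ZZ = 0 when u cannot be covered.

struct ZZCtx {
  int n;
  std::vector<std::vector<int>> adj;
  std::vector<std::vector<int>> vrings;  // ring indices through each vertex
  std::vector<Key> ringmask;
  std::unordered_map<Key, std::vector<int64_t>, KeyHash> memo;
};

static void poly_add(std::vector<int64_t>& dst,
                     const std::vector<int64_t>& src, int shift) {
  if (src.empty()) return;
  if (dst.size() < src.size() + shift) dst.resize(src.size() + shift, 0);
  for (size_t i = 0; i < src.size(); ++i) dst[i + shift] += src[i];
}

static const std::vector<int64_t>& zz_rec(ZZCtx& C, const Key& S) {
  static const std::vector<int64_t> one(1, 1);
  if (key_empty(S)) return one;
  auto it = C.memo.find(S);
  if (it != C.memo.end()) return it->second;

  // pivot: live vertex with fewest live neighbours
  int best = -1, bestd = 1 << 30;
  for (int v = 0; v < C.n; ++v) {
    if (!key_has(S, v)) continue;
    int d = 0;
    for (int w : C.adj[v]) if (key_has(S, w)) ++d;
    if (d < bestd) { bestd = d; best = v; if (d == 0) break; }
  }
  std::vector<int64_t> res;
  int u = best;
  for (int w : C.adj[u]) {
    if (!key_has(S, w)) continue;
    Key T = S; key_clear(T, u); key_clear(T, w);
    poly_add(res, zz_rec(C, T), 0);
  }
  for (int r : C.vrings[u]) {
    if (!key_subset(C.ringmask[r], S)) continue;
    poly_add(res, zz_rec(C, key_minus(S, C.ringmask[r])), 1);
  }
  auto ins = C.memo.emplace(S, std::move(res));
  return ins.first->second;
}

// edges: m x 2 (1-based); rings: list of 1-based vertex vectors;
// masks: list of 1-based live-vertex sets (empty list => one full mask).
// Returns a list of numeric coefficient vectors (length 0 = zero polynomial);
// the memo table is shared across all masks of one call.
// [[Rcpp::export]]
List zz_multi_cpp(int n, IntegerMatrix edges, List rings, List masks) {
  if (n > 128) stop("graphs with more than 128 vertices are not supported");
  ZZCtx C;
  C.n = n;
  C.adj.assign(n, {});
  for (int i = 0; i < edges.nrow(); ++i) {
    int u = edges(i, 0) - 1, v = edges(i, 1) - 1;
    if (u < 0 || v < 0 || u >= n || v >= n || u == v) stop("bad edge");
    C.adj[u].push_back(v);
    C.adj[v].push_back(u);
  }
  C.vrings.assign(n, {});
  for (int r = 0; r < rings.size(); ++r) {
    IntegerVector rv = rings[r];
    Key m{0, 0};
    for (int i = 0; i < rv.size(); ++i) {
      int v = rv[i] - 1;
      if (v < 0 || v >= n) stop("bad ring vertex");
      key_set(m, v);
      C.vrings[v].push_back(r);
    }
    C.ringmask.push_back(m);
  }
  int nm = masks.size();
  List out(std::max(nm, 1));
  if (nm == 0) {
    Key full{0, 0};
    for (int v = 0; v < n; ++v) key_set(full, v);
    const auto& p = zz_rec(C, full);
    out[0] = NumericVector(p.begin(), p.end());
  } else {
    for (int i = 0; i < nm; ++i) {
      IntegerVector mv = masks[i];
      Key S{0, 0};
      for (int j = 0; j < mv.size(); ++j) key_set(S, mv[j] - 1);
      const auto& p = zz_rec(C, S);
      out[i] = NumericVector(p.begin(), p.end());
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Independent perfect-matching oracle: plain edge branching on the
// lowest-index live vertex, no memoization and no ring logic.

static int64_t match_rec(const std::vector<std::vector<int>>& adj, Key S) {
  int u = -1;
  if (S.lo) {
#ifdef _MSC_VER
    for (int v = 0; v < 64; ++v) if ((S.lo >> v) & 1ULL) { u = v; break; }
#else
    u = __builtin_ctzll(S.lo);
#endif
  } else if (S.hi) {
#ifdef _MSC_VER
    for (int v = 0; v < 64; ++v) if ((S.hi >> v) & 1ULL) { u = v + 64; break; }
#else
    u = 64 + __builtin_ctzll(S.hi);
#endif
  } else {
    return 1;
  }
  int64_t tot = 0;
  for (int w : adj[u]) {
    if (!key_has(S, w)) continue;
    Key T = S; key_clear(T, u); key_clear(T, w);
    tot += match_rec(adj, T);
  }
  return tot;
}

// [[Rcpp::export]]
double matching_count_cpp(int n, IntegerMatrix edges) {
  if (n > 128) stop("graphs with more than 128 vertices are not supported");
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < edges.nrow(); ++i) {
    adj[edges(i, 0) - 1].push_back(edges(i, 1) - 1);
    adj[edges(i, 1) - 1].push_back(edges(i, 0) - 1);
  }
  Key S{0, 0};
  for (int v = 0; v < n; ++v) key_set(S, v);
  return static_cast<double>(match_rec(adj, S));
}

// ---------------------------------------------------------------------------
// Ring-spiral windup (dual bookkeeping).
//
// Faces are attached one at a time; the open spiral boundary is the deque of
// faces that still have unused valences.  Each new face fuses to the tail
// (previous face) and to the head (earliest open face); whenever a boundary
// face fills up it leaves the boundary and the fusion wraps to its
// neighbour.  The last face must close every remaining valence exactly.

struct WS {
  std::vector<int> open;
  std::deque<int> bd;
  std::vector<uint64_t> dadj;  // F <= 64 rows of adjacency bits
};

static void ws_init(WS& st, int F) {
  st.open.assign(F, 0);
  st.bd.clear();
  st.dadj.assign(F, 0);
}

static bool add_face(WS& st, int j, int sz, int F) {
  st.open[j] = sz;
  auto connect = [&st, j](int a) -> bool {
    if ((st.dadj[j] >> a) & 1ULL) return false;  // shorted: double fusion
    if (st.open[a] <= 0 || st.open[j] <= 0) return false;
    st.dadj[j] |= 1ULL << a;
    st.dadj[a] |= 1ULL << j;
    --st.open[a];
    --st.open[j];
    return true;
  };
  if (j == 0) { st.bd.push_back(0); return true; }
  if (j < F - 1) {
    if (st.bd.empty()) return false;
    if (!connect(st.bd.back())) return false;          // fuse to tail
    while (st.open[st.bd.back()] == 0) {               // tail wrap
      st.bd.pop_back();
      if (st.bd.empty()) return false;
      if (!connect(st.bd.back())) return false;
    }
    int h = st.bd.front();
    if (!((st.dadj[j] >> h) & 1ULL)) {
      if (!connect(h)) return false;                   // fuse to head
    }
    while (st.open[st.bd.front()] == 0) {              // head wrap
      st.bd.pop_front();
      if (st.bd.empty()) return false;
      if (!connect(st.bd.front())) return false;
    }
    if (st.open[j] <= 0) return false;                 // closed too early
    st.bd.push_back(j);
    return true;
  }
  // final face: one fusion to every remaining boundary face, closing all
  std::deque<int> b = st.bd;
  for (int f : b) if (!connect(f)) return false;
  if (st.open[j] != 0) return false;
  for (int f : b) if (st.open[f] != 0) return false;
  st.bd.clear();
  return true;
}

// sizes: face sizes (5/6) in spiral order.  Returns list(ok, fail_pos, dual)
// where dual is the F x F dual (face) adjacency matrix on success and
// fail_pos the 1-based spiral position at which the windup failed.
// [[Rcpp::export]]
List windup_cpp(IntegerVector sizes) {
  int F = sizes.size();
  if (F < 4 || F > 64) stop("face count out of supported range (4..64)");
  WS st;
  ws_init(st, F);
  for (int j = 0; j < F; ++j) {
    if (sizes[j] != 5 && sizes[j] != 6) stop("face sizes must be 5 or 6");
    if (!add_face(st, j, sizes[j], F)) {
      return List::create(_["ok"] = false, _["fail_pos"] = j + 1);
    }
  }
  IntegerMatrix D(F, F);
  for (int a = 0; a < F; ++a)
    for (int b = 0; b < F; ++b)
      D(a, b) = (st.dadj[a] >> b) & 1ULL ? 1 : 0;
  return List::create(_["ok"] = true, _["fail_pos"] = -1, _["dual"] = D);
}

// ---------------------------------------------------------------------------
// Spiral unwind: reconstruct a face spiral of a wound dual from a start
// triple of mutually adjacent faces.  open[f] counts dual valences of f not
// yet consumed by the spiral prefix; the next face is the unique common
// neighbour (outside the prefix) of the tail face and the earliest open face.
//
// When ref != NULL the produced size sequence is compared on the fly with
// ref: return -1 as soon as it becomes lexicographically greater; cmp is set
// to -1 if it becomes smaller.  Return 1 on completion, 0 on a dead end.

static int unwind_from(const std::vector<std::vector<int>>& nb,
                       const std::vector<uint64_t>& am,
                       const std::vector<int>& deg, int F,
                       int f1, int f2, int f3,
                       const int* ref, int& cmp, std::vector<int>& ord) {
  std::vector<int> open(F);
  std::vector<char> in(F, 0);
  ord.clear();
  cmp = 0;
  auto place = [&](int f) -> bool {
    if (ref && cmp == 0) {
      int s = deg[f], r = ref[ord.size()];
      if (s > r) return false;
      if (s < r) cmp = -1;
    }
    in[f] = 1;
    open[f] = deg[f];
    for (int w : nb[f]) if (in[w]) { --open[f]; --open[w]; }
    ord.push_back(f);
    return true;
  };
  if (!place(f1)) return -1;
  if (!place(f2)) return -1;
  if (!place(f3)) return -1;
  int h = 0;
  for (int k = 3; k < F; ++k) {
    while (open[ord[h]] == 0) {
      ++h;
      if (h >= k) return 0;  // boundary exhausted with faces remaining
    }
    int H = ord[h], T = ord[k - 1];
    if (!((am[T] >> H) & 1ULL)) return 0;  // spiral broken
    int cand = -1, cnt = 0;
    for (int w : nb[T]) {
      if (!in[w] && ((am[w] >> H) & 1ULL)) { cand = w; ++cnt; }
    }
    if (cnt != 1) return 0;
    if (!place(cand)) return -1;
  }
  return 1;
}

static void build_nb(const std::vector<uint64_t>& am, int F,
                     std::vector<std::vector<int>>& nb,
                     std::vector<int>& deg) {
  nb.assign(F, {});
  deg.assign(F, 0);
  for (int a = 0; a < F; ++a) {
    for (int b = 0; b < F; ++b)
      if ((am[a] >> b) & 1ULL) nb[a].push_back(b);
    deg[a] = static_cast<int>(nb[a].size());
  }
}

// True iff no spiral start of the wound dual yields a size sequence
// lexicographically smaller than `sizes` (i.e. `sizes` is canonical).
static bool is_canonical(const std::vector<uint64_t>& am,
                         const std::vector<int>& sizes) {
  int F = static_cast<int>(sizes.size());
  std::vector<std::vector<int>> nb;
  std::vector<int> deg;
  build_nb(am, F, nb, deg);
  std::vector<int> ord;
  int cmp;
  for (int f1 = 0; f1 < F; ++f1) {
    if (deg[f1] > sizes[0]) continue;
    for (int f2 : nb[f1]) {
      for (int f3 : nb[f1]) {
        if (f3 == f2 || !((am[f2] >> f3) & 1ULL)) continue;
        int r = unwind_from(nb, am, deg, F, f1, f2, f3, sizes.data(), cmp, ord);
        if (r == 1 && cmp < 0) return false;
      }
    }
  }
  return true;
}

// Canonical (lexicographically smallest) spiral of a fullerene dual given as
// a 0/1 adjacency matrix.  Returns the 1-based pentagon positions.
// [[Rcpp::export]]
IntegerVector canonical_spiral_cpp(IntegerMatrix dual) {
  int F = dual.nrow();
  if (F > 64) stop("face count out of supported range");
  std::vector<uint64_t> am(F, 0);
  for (int a = 0; a < F; ++a)
    for (int b = 0; b < F; ++b)
      if (dual(a, b)) am[a] |= 1ULL << b;
  std::vector<std::vector<int>> nb;
  std::vector<int> deg;
  build_nb(am, F, nb, deg);
  std::vector<int> best, ord;
  int cmp;
  for (int f1 = 0; f1 < F; ++f1) {
    for (int f2 : nb[f1]) {
      for (int f3 : nb[f1]) {
        if (f3 == f2 || !((am[f2] >> f3) & 1ULL)) continue;
        int r = unwind_from(nb, am, deg, F, f1, f2, f3,
                            best.empty() ? nullptr : best.data(), cmp, ord);
        if (r != 1) continue;
        if (best.empty() || cmp < 0) {
          best.resize(F);
          for (int k = 0; k < F; ++k) best[k] = deg[ord[k]];
        }
      }
    }
  }
  if (best.empty()) stop("no face spiral exists for this graph");
  IntegerVector pent;
  for (int k = 0; k < F; ++k) if (best[k] == 5) pent.push_back(k + 1);
  return pent;
}

// ---------------------------------------------------------------------------
// Exhaustive generation: depth-first search over face-size prefixes (5 before
// 6, hence lexicographic pentagon-position order) with incremental windup so
// that failures prune whole subtrees; a completed spiral is kept only if it
// equals its own canonical spiral (cheap isomorph rejection).

struct EnumCtx {
  int F;
  long limit;           // stop after this many isomers (-1 = all)
  std::vector<std::vector<int>> codes;
  std::vector<int> sizes;
  unsigned long steps;
};

static bool enum_dfs(EnumCtx& E, const WS& st, int j, int pens_left) {
  if (++E.steps % 65536 == 0) Rcpp::checkUserInterrupt();
  if (j == E.F) {
    if (is_canonical(st.dadj, E.sizes)) {
      std::vector<int> pent;
      for (int k = 0; k < E.F; ++k)
        if (E.sizes[k] == 5) pent.push_back(k + 1);
      E.codes.push_back(pent);
      if (E.limit >= 0 && static_cast<long>(E.codes.size()) >= E.limit)
        return true;
    }
    return false;
  }
  int slots = E.F - j;
  for (int s = 5; s <= 6; ++s) {
    if (s == 5 && pens_left == 0) continue;
    if (s == 6 && slots <= pens_left) continue;
    WS ns = st;
    E.sizes[j] = s;
    if (add_face(ns, j, s, E.F)) {
      if (enum_dfs(E, ns, j + 1, pens_left - (s == 5 ? 1 : 0))) return true;
    }
  }
  return false;
}

// All canonical spiral codes of the (5,6)-fullerene C_n in lexicographic
// order, one row of 1-based pentagon positions per isomer.
// [[Rcpp::export]]
IntegerMatrix enumerate_spirals_cpp(int n, long limit = -1) {
  if (n < 20 || n % 2 != 0) stop("n must be even and >= 20");
  int F = n / 2 + 2;
  if (F > 64) stop("face count out of supported range");
  EnumCtx E;
  E.F = F;
  E.limit = limit;
  E.sizes.assign(F, 0);
  E.steps = 0;
  WS st;
  ws_init(st, F);
  enum_dfs(E, st, 0, 12);
  IntegerMatrix out(static_cast<int>(E.codes.size()), 12);
  for (size_t i = 0; i < E.codes.size(); ++i)
    for (int k = 0; k < 12; ++k)
      out(i, k) = E.codes[i][k];
  return out;
}
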