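// Core maximum-parsimony kernels: Fitch scoring on bitmask-encoded state
// sets, stepwise addition, TBR branch swapping with an equally-best tree
// pool, exhaustive topology enumeration, per-branch minimum lengths (the
// MINBRLEN collapse rule) and ACCTRAN branch step counts.
//
// Conventions: tips are 0..nTip-1, internal nodes nTip..2*nTip-3 (unrooted
// binary trees); leaf state sets are uint32 bitmasks with missing data
// pre-expanded to the full state set; taxon sets are uint64 bitmasks, which
// caps analyses at 64 taxa (enforced on the R side).

#include <Rcpp.h>
#include <cstdint>
#include <array>
#include <vector>
#include <string>
#include <set>
#include <algorithm>
#include <climits>

using namespace Rcpp;

struct UTree {
  int nTip;
  // neighbor lists; -1 = empty slot. Leaves use slot 0 only.
  std::vector<std::array<int, 3>> nb;

  explicit UTree(int n) : nTip(n), nb(2 * n - 2, {-1, -1, -1}) {}

  void link(int a, int b) {
    add_nb(a, b);
    add_nb(b, a);
  }
  void unlink(int a, int b) {
    drop_nb(a, b);
    drop_nb(b, a);
  }
  void add_nb(int a, int b) {
    for (int k = 0; k < 3; ++k)
      if (nb[a][k] == -1) { nb[a][k] = b; return; }
    stop("internal error: node degree overflow");
  }
  void drop_nb(int a, int b) {
    for (int k = 0; k < 3; ++k)
      if (nb[a][k] == b) { nb[a][k] = -1; return; }
    stop("internal error: neighbor not found");
  }
  int degree(int a) const {
    int d = 0;
    for (int k = 0; k < 3; ++k) d += nb[a][k] != -1;
    return d;
  }
};

// ---- conversions -----------------------------------------------------------

static UTree tree_from_edge(const IntegerMatrix& edge, int nTip) {
  UTree t(nTip);
  for (int i = 0; i < edge.nrow(); ++i) {
    int p = edge(i, 0) - 1, c = edge(i, 1) - 1;
    // ape may number internal nodes beyond 2*nTip-3 for rooted trees; the R
    // layer unroots first, so ids fit the unrooted range.
    t.link(p, c);
  }
  return t;
}

// Emit an ape-style edge matrix rooted at the internal node adjacent to tip 0.
static IntegerMatrix tree_to_edge(const UTree& t) {
  int nTip = t.nTip, nNodes = 2 * nTip - 2;
  std::vector<int> newid(nNodes, -1);
  for (int i = 0; i < nTip; ++i) newid[i] = i + 1;
  int nextInternal = nTip + 1;

  int root = t.nb[0][0];
  std::vector<std::pair<int, int>> edges;
  std::vector<int> stack = {root};
  std::vector<int> parent(nNodes, -1);
  parent[root] = root;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    if (v >= nTip) newid[v] = nextInternal++;
    for (int k = 0; k < 3; ++k) {
      int w = t.nb[v][k];
      if (w == -1 || w == parent[v]) continue;
      parent[w] = v;
      edges.push_back({v, w});
      if (w >= nTip) stack.push_back(w);
    }
  }
  // re-walk in recorded order; parents appear before children so ids exist
  IntegerMatrix out(edges.size(), 2);
  for (size_t i = 0; i < edges.size(); ++i) {
    out(i, 0) = newid[edges[i].first];
    out(i, 1) = newid[edges[i].second];
  }
  return out;
}

// ---- Fitch scoring ---------------------------------------------------------

struct Traversal {
  std::vector<int> post;    // postorder node sequence (root last)
  std::vector<int> parent;  // parent per node (-1 for root)
};

static void build_traversal(const UTree& t, int root, Traversal& tr) {
  int nNodes = 2 * t.nTip - 2;
  tr.post.clear();
  tr.parent.assign(nNodes, -2);  // -2 = not visited
  std::vector<int> stack = {root};
  tr.parent[root] = -1;
  std::vector<int> pre;
  pre.reserve(nNodes);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    pre.push_back(v);
    for (int k = 0; k < 3; ++k) {
      int w = t.nb[v][k];
      if (w == -1 || w == tr.parent[v]) continue;
      tr.parent[w] = v;
      stack.push_back(w);
    }
  }
  tr.post.assign(pre.rbegin(), pre.rend());
}

// Total weighted Fitch length; returns a value > cutoff early when exceeded.
static int fitch_score(const UTree& t, const uint32_t* M, const int* w,
                       int nPat, int cutoff, Traversal& tr,
                       std::vector<uint32_t>& S, int root = -1) {
  if (root < 0) root = t.nb[0][0];
  build_traversal(t, root, tr);
  int nNodes = 2 * t.nTip - 2;
  if ((int)S.size() < nNodes * nPat) S.resize((size_t)nNodes * nPat);
  int total = 0;
  for (int idx = 0; idx < (int)tr.post.size(); ++idx) {
    int v = tr.post[idx];
    uint32_t* Sv = &S[(size_t)v * nPat];
    if (v < t.nTip) {
      const uint32_t* Mv = &M[(size_t)v * nPat];
      std::copy(Mv, Mv + nPat, Sv);
      continue;
    }
    bool first = true;
    for (int k = 0; k < 3; ++k) {
      int c = t.nb[v][k];
      if (c == -1 || c == tr.parent[v]) continue;
      const uint32_t* Sc = &S[(size_t)c * nPat];
      if (first) {
        std::copy(Sc, Sc + nPat, Sv);
        first = false;
      } else {
        for (int p = 0; p < nPat; ++p) {
          uint32_t inter = Sv[p] & Sc[p];
          if (inter) {
            Sv[p] = inter;
          } else {
            Sv[p] |= Sc[p];
            total += w[p];
          }
        }
        if (total > cutoff) return total;
      }
    }
  }
  return total;
}

static std::vector<uint32_t> masks_from_R(const IntegerMatrix& masks) {
  int nTip = masks.nrow(), nPat = masks.ncol();
  std::vector<uint32_t> M((size_t)nTip * nPat);
  for (int i = 0; i < nTip; ++i)
    for (int p = 0; p < nPat; ++p)
      M[(size_t)i * nPat + p] = (uint32_t)masks(i, p);
  return M;
}

// [[Rcpp::export]]
IntegerVector fitch_per_pattern_cpp(IntegerMatrix edge, int nTip,
                                    IntegerMatrix masks) {
  int nPat = masks.ncol();
  UTree t = tree_from_edge(edge, nTip);
  std::vector<uint32_t> M = masks_from_R(masks);
  Traversal tr;
  int root = t.nb[0][0];
  build_traversal(t, root, tr);
  int nNodes = 2 * nTip - 2;
  std::vector<uint32_t> S((size_t)nNodes * nPat);
  IntegerVector out(nPat);
  for (int idx = 0; idx < (int)tr.post.size(); ++idx) {
    int v = tr.post[idx];
    uint32_t* Sv = &S[(size_t)v * nPat];
    if (v < nTip) {
      std::copy(&M[(size_t)v * nPat], &M[(size_t)v * nPat] + nPat, Sv);
      continue;
    }
    bool first = true;
    for (int k = 0; k < 3; ++k) {
      int c = t.nb[v][k];
      if (c == -1 || c == tr.parent[v]) continue;
      const uint32_t* Sc = &S[(size_t)c * nPat];
      if (first) {
        std::copy(Sc, Sc + nPat, Sv);
        first = false;
      } else {
        for (int p = 0; p < nPat; ++p) {
          uint32_t inter = Sv[p] & Sc[p];
          if (inter) {
            Sv[p] = inter;
          } else {
            Sv[p] |= Sc[p];
            out[p] += 1;
          }
        }
      }
    }
  }
  return out;
}

// ---- splits & constraints --------------------------------------------------

static void subtree_masks(const UTree& t, int root, std::vector<uint64_t>& tipmask,
                          Traversal& tr) {
  build_traversal(t, root, tr);
  tipmask.assign(2 * t.nTip - 2, 0);
  for (int idx = 0; idx < (int)tr.post.size(); ++idx) {
    int v = tr.post[idx];
    if (v < t.nTip) {
      tipmask[v] = 1ULL << v;
      continue;
    }
    for (int k = 0; k < 3; ++k) {
      int c = t.nb[v][k];
      if (c == -1 || c == tr.parent[v]) continue;
      tipmask[v] |= tipmask[c];
    }
  }
}

static inline uint64_t norm_split(uint64_t s, uint64_t full) {
  return (s & 1ULL) ? ((~s) & full) : s;
}

// All nontrivial splits of the (possibly partial) tree containing tip `anchor`.
static std::vector<uint64_t> tree_splits_internal(const UTree& t, int anchor,
                                                  uint64_t present) {
  Traversal tr;
  std::vector<uint64_t> tm;
  int root = t.nb[anchor][0];
  subtree_masks(t, root, tm, tr);
  std::vector<uint64_t> out;
  int npres = __builtin_popcountll(present);
  for (int v = 0; v < (int)tm.size(); ++v) {
    if (tr.parent[v] < 0 || v < t.nTip) continue;
    uint64_t s = tm[v];
    int pc = __builtin_popcountll(s);
    if (pc < 2 || pc > npres - 2) continue;
    out.push_back(norm_split(s, present));
  }
  return out;
}

// Does the tree (restricted to `present` taxa) display the clade?
static bool contains_clade(const UTree& t, int anchor, uint64_t present,
                           uint64_t clade) {
  uint64_t cl = clade & present;
  int pc = __builtin_popcountll(cl);
  int npres = __builtin_popcountll(present);
  if (pc < 2 || pc > npres - 2) return true;  // trivial on this taxon set
  uint64_t want = norm_split(cl, present);
  std::vector<uint64_t> sp = tree_splits_internal(t, anchor, present);
  for (uint64_t s : sp)
    if (s == want) return true;
  return false;
}

static bool constraint_ok(const UTree& t, int anchor, uint64_t present,
                          uint64_t clade, bool hasClade, bool converse) {
  if (!hasClade) return true;
  bool has = contains_clade(t, anchor, present, clade);
  return converse ? !has : has;
}

static std::string tree_key(const UTree& t, uint64_t full) {
  std::vector<uint64_t> sp = tree_splits_internal(t, 0, full);
  std::sort(sp.begin(), sp.end());
  return std::string((const char*)sp.data(), sp.size() * sizeof(uint64_t));
}

// [[Rcpp::export]]
CharacterVector tree_key_cpp(IntegerMatrix edge, int nTip) {
  UTree t = tree_from_edge(edge, nTip);
  uint64_t full = (nTip == 64) ? ~0ULL : ((1ULL << nTip) - 1);
  std::string k = tree_key(t, full);
  // hex-encode for safe transport
  static const char* hex = "0123456789abcdef";
  std::string out;
  out.reserve(k.size() * 2);
  for (unsigned char c : k) {
    out.push_back(hex[c >> 4]);
    out.push_back(hex[c & 15]);
  }
  return CharacterVector::create(out);
}

// ---- TBR search ------------------------------------------------------------

struct SearchCtx {
  const uint32_t* M;
  const int* w;
  int nPat;
  uint64_t full;
  uint64_t clade;
  bool hasClade;
  bool converse;
  Traversal tr;
  std::vector<uint32_t> S;

  int score(const UTree& t, int cutoff) {
    return fitch_score(t, M, w, nPat, cutoff, tr, S);
  }
  bool ok(const UTree& t) {
    return constraint_ok(t, 0, full, clade, hasClade, converse);
  }
};

static void collect_edges(const UTree& t, int start,
                          std::vector<std::pair<int, int>>& edges) {
  edges.clear();
  std::vector<int> stack = {start};
  std::vector<char> seen(2 * t.nTip - 2, 0);
  seen[start] = 1;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    for (int k = 0; k < 3; ++k) {
      int u = t.nb[v][k];
      if (u == -1) continue;
      if (v < u) edges.push_back({v, u});
      if (!seen[u]) {
        seen[u] = 1;
        stack.push_back(u);
      }
    }
  }
  std::sort(edges.begin(), edges.end());
}

// Enumerate TBR neighbors of `t`, invoking fn(candidate) on each candidate
// (the candidate is a fully valid tree; fn must not retain the reference).
template <typename F>
static void tbr_enumerate(UTree& t, F fn) {
  std::vector<std::pair<int, int>> all_edges, edgesA, edgesB;
  collect_edges(t, 0, all_edges);

  for (auto E : all_edges) {
    int u = E.first, v = E.second;
    t.unlink(u, v);

    // suppress degree-2 attachment nodes, remembering how to restore
    int pA = -1, qA = -1, pB = -1, qB = -1;
    bool leafA = u < t.nTip, leafB = v < t.nTip;
    if (!leafA) {
      int nbs[2], n = 0;
      for (int k = 0; k < 3; ++k)
        if (t.nb[u][k] != -1) nbs[n++] = t.nb[u][k];
      pA = nbs[0]; qA = nbs[1];
      t.unlink(u, pA);
      t.unlink(u, qA);
      t.link(pA, qA);
    }
    if (!leafB) {
      int nbs[2], n = 0;
      for (int k = 0; k < 3; ++k)
        if (t.nb[v][k] != -1) nbs[n++] = t.nb[v][k];
      pB = nbs[0]; qB = nbs[1];
      t.unlink(v, pB);
      t.unlink(v, qB);
      t.link(pB, qB);
    }

    if (leafA) {
      edgesA.clear();
    } else {
      collect_edges(t, pA, edgesA);
    }
    if (leafB) {
      edgesB.clear();
    } else {
      collect_edges(t, pB, edgesB);
    }

    size_t nA = leafA ? 1 : edgesA.size();
    size_t nB = leafB ? 1 : edgesB.size();
    for (size_t ia = 0; ia < nA; ++ia) {
      int a1 = -1, a2 = -1;
      if (!leafA) {
        a1 = edgesA[ia].first;
        a2 = edgesA[ia].second;
        t.unlink(a1, a2);
        t.link(a1, u);
        t.link(a2, u);
      }
      for (size_t ib = 0; ib < nB; ++ib) {
        int b1 = -1, b2 = -1;
        if (!leafB) {
          b1 = edgesB[ib].first;
          b2 = edgesB[ib].second;
          // skip the reconstruction of the original tree
          bool origA = leafA || (std::minmax(a1, a2) == std::minmax(pA, qA));
          bool origB = std::minmax(b1, b2) == std::minmax(pB, qB);
          if (origA && origB) continue;
          t.unlink(b1, b2);
          t.link(b1, v);
          t.link(b2, v);
        } else if (leafA || (std::minmax(a1, a2) == std::minmax(pA, qA))) {
          continue;  // original tree
        }
        t.link(u, v);
        fn(t);
        t.unlink(u, v);
        if (!leafB) {
          t.unlink(b1, v);
          t.unlink(b2, v);
          t.link(b1, b2);
        }
      }
      if (!leafA) {
        t.unlink(a1, u);
        t.unlink(a2, u);
        t.link(a1, a2);
      }
    }

    // restore suppressed nodes and the bisected edge
    if (!leafB) {
      t.unlink(pB, qB);
      t.link(v, pB);
      t.link(v, qB);
    }
    if (!leafA) {
      t.unlink(pA, qA);
      t.link(u, pA);
      t.link(u, qA);
    }
    t.link(u, v);
  }
}

// [[Rcpp::export]]
List tbr_search_cpp(IntegerMatrix edge, int nTip, IntegerMatrix masks,
                    IntegerVector weights, IntegerVector cladeTips,
                    bool converse, bool firstImprovement, int maxTrees) {
  UTree start = tree_from_edge(edge, nTip);
  std::vector<uint32_t> M = masks_from_R(masks);
  std::vector<int> w(weights.begin(), weights.end());

  SearchCtx ctx;
  ctx.M = M.data();
  ctx.w = w.data();
  ctx.nPat = masks.ncol();
  ctx.full = (nTip == 64) ? ~0ULL : ((1ULL << nTip) - 1);
  ctx.clade = 0;
  ctx.hasClade = cladeTips.size() > 0;
  ctx.converse = converse;
  for (int i = 0; i < cladeTips.size(); ++i)
    ctx.clade |= 1ULL << (cladeTips[i] - 1);

  int best = ctx.score(start, INT_MAX);
  bool capped = false;

  std::vector<UTree> pool;
  std::set<std::string> seen;
  pool.push_back(start);
  seen.insert(tree_key(start, ctx.full));
  size_t next = 0;

  while (next < pool.size()) {
    Rcpp::checkUserInterrupt();
    UTree t = pool[next];  // working copy
    int bestNb = INT_MAX;
    UTree bestNbTree(nTip);
    bool restarted = false;

    tbr_enumerate(t, [&](UTree& cand) {
      if (restarted) return;
      if (!ctx.ok(cand)) return;
      int s = ctx.score(cand, best);
      if (s < best) {
        if (firstImprovement) {
          pool.clear();
          seen.clear();
          pool.push_back(cand);
          seen.insert(tree_key(cand, ctx.full));
          best = s;
          next = 0;
          restarted = true;
        } else if (s < bestNb) {
          bestNb = s;
          bestNbTree = cand;
        }
      } else if (s == best) {
        std::string k = tree_key(cand, ctx.full);
        if (!seen.count(k)) {
          if ((int)pool.size() < maxTrees) {
            pool.push_back(cand);
            seen.insert(k);
          } else {
            capped = true;
          }
        }
      }
    });

    if (restarted) continue;
    if (bestNb < best) {
      pool.clear();
      seen.clear();
      pool.push_back(bestNbTree);
      seen.insert(tree_key(bestNbTree, ctx.full));
      best = bestNb;
      next = 0;
      continue;
    }
    ++next;
  }

  List trees(pool.size());
  for (size_t i = 0; i < pool.size(); ++i) trees[i] = tree_to_edge(pool[i]);
  return List::create(_["best_length"] = best, _["trees"] = trees,
                      _["capped"] = capped);
}

// ---- stepwise addition -----------------------------------------------------

// Break a forbidden clade by an NNI across its stem edge (used to repair a
// converse-constrained starting tree).
static void break_clade(UTree& t, uint64_t clade, uint64_t full) {
  Traversal tr;
  std::vector<uint64_t> tm;
  int root = t.nb[0][0];
  subtree_masks(t, root, tm, tr);
  uint64_t want = norm_split(clade, full);
  for (int v = (int)tm.size() - 1; v >= t.nTip; --v) {
    if (tr.parent[v] < 0) continue;
    if (norm_split(tm[v], full) != want) continue;
    int u = tr.parent[v];
    // first neighbor of v besides u, first of u besides v
    int a = -1, b = -1;
    for (int k = 0; k < 3; ++k)
      if (t.nb[v][k] != -1 && t.nb[v][k] != u) { a = t.nb[v][k]; break; }
    for (int k = 0; k < 3; ++k)
      if (t.nb[u][k] != -1 && t.nb[u][k] != v) { b = t.nb[u][k]; break; }
    if (a == -1 || b == -1) return;
    t.unlink(v, a);
    t.unlink(u, b);
    t.link(v, b);
    t.link(u, a);
    return;
  }
}

// [[Rcpp::export]]
List stepwise_addition_cpp(int nTip, IntegerMatrix masks, IntegerVector weights,
                           IntegerVector order, IntegerVector cladeTips,
                           bool converse) {
  std::vector<uint32_t> M = masks_from_R(masks);
  std::vector<int> w(weights.begin(), weights.end());
  int nPat = masks.ncol();
  uint64_t full = (nTip == 64) ? ~0ULL : ((1ULL << nTip) - 1);
  uint64_t clade = 0;
  bool hasClade = cladeTips.size() > 0;
  for (int i = 0; i < cladeTips.size(); ++i) clade |= 1ULL << (cladeTips[i] - 1);

  std::vector<int> ord(order.begin(), order.end());
  for (auto& x : ord) x -= 1;

  UTree t(nTip);
  int firstInternal = nTip;
  t.link(ord[0], firstInternal);
  t.link(ord[1], firstInternal);
  t.link(ord[2], firstInternal);
  uint64_t present = (1ULL << ord[0]) | (1ULL << ord[1]) | (1ULL << ord[2]);

  Traversal tr;
  std::vector<uint32_t> S;
  std::vector<std::pair<int, int>> edges;

  for (int i = 3; i < nTip; ++i) {
    int x = ord[i];
    int nodeNew = nTip + i - 2;
    collect_edges(t, ord[0], edges);
    int bestScore = INT_MAX, bestA = -1, bestB = -1;
    bool finalStep = (i == nTip - 1);
    uint64_t presNew = present | (1ULL << x);
    for (auto e : edges) {
      t.unlink(e.first, e.second);
      t.link(e.first, nodeNew);
      t.link(e.second, nodeNew);
      t.link(x, nodeNew);
      bool ok = true;
      if (hasClade) {
        if (converse) {
          // partial trees cannot pre-judge the final split; enforce at the end
          if (finalStep) ok = constraint_ok(t, x, presNew, clade, true, true);
        } else {
          ok = constraint_ok(t, x, presNew, clade, true, false);
        }
      }
      if (ok) {
        int s = fitch_score(t, M.data(), w.data(), nPat, bestScore, tr, S,
                            firstInternal);
        if (s < bestScore) {
          bestScore = s;
          bestA = e.first;
          bestB = e.second;
        }
      }
      t.unlink(x, nodeNew);
      t.unlink(e.first, nodeNew);
      t.unlink(e.second, nodeNew);
      t.link(e.first, e.second);
    }
    if (bestA == -1) {
      // every placement violated; place greedily and repair afterwards
      for (auto e : edges) {
        t.unlink(e.first, e.second);
        t.link(e.first, nodeNew);
        t.link(e.second, nodeNew);
        t.link(x, nodeNew);
        int s = fitch_score(t, M.data(), w.data(), nPat, bestScore, tr, S,
                            firstInternal);
        if (s < bestScore) {
          bestScore = s;
          bestA = e.first;
          bestB = e.second;
        }
        t.unlink(x, nodeNew);
        t.unlink(e.first, nodeNew);
        t.unlink(e.second, nodeNew);
        t.link(e.first, e.second);
      }
    }
    t.unlink(bestA, bestB);
    t.link(bestA, nodeNew);
    t.link(bestB, nodeNew);
    t.link(x, nodeNew);
    present = presNew;
  }

  if (hasClade && converse && contains_clade(t, 0, full, clade)) {
    break_clade(t, clade, full);
  }

  int finalScore = fitch_score(t, M.data(), w.data(), nPat, INT_MAX, tr, S);
  return List::create(_["edge"] = tree_to_edge(t), _["length"] = finalScore);
}

// ---- exhaustive enumeration ------------------------------------------------

struct ExhCtx {
  const uint32_t* M;
  const int* w;
  int nPat;
  int nTip;
  int best;
  std::vector<IntegerMatrix> optima;
  Traversal tr;
  std::vector<uint32_t> S;
  long long scored;
};

static void exhaustive_recurse(UTree& t, int i, ExhCtx& ctx) {
  if (i == ctx.nTip) {
    int s = fitch_score(t, ctx.M, ctx.w, ctx.nPat, ctx.best, ctx.tr, ctx.S);
    ctx.scored++;
    if (s < ctx.best) {
      ctx.best = s;
      ctx.optima.clear();
      ctx.optima.push_back(tree_to_edge(t));
    } else if (s == ctx.best) {
      ctx.optima.push_back(tree_to_edge(t));
    }
    return;
  }
  // prune: adding taxa never decreases length
  int partial = fitch_score(t, ctx.M, ctx.w, ctx.nPat, ctx.best, ctx.tr, ctx.S);
  if (partial > ctx.best) return;

  std::vector<std::pair<int, int>> edges;
  collect_edges(t, 0, edges);
  int nodeNew = ctx.nTip + i - 2;
  for (auto e : edges) {
    t.unlink(e.first, e.second);
    t.link(e.first, nodeNew);
    t.link(e.second, nodeNew);
    t.link(i, nodeNew);
    exhaustive_recurse(t, i + 1, ctx);
    t.unlink(i, nodeNew);
    t.unlink(e.first, nodeNew);
    t.unlink(e.second, nodeNew);
    t.link(e.first, e.second);
  }
}

// [[Rcpp::export]]
List exhaustive_search_cpp(int nTip, IntegerMatrix masks, IntegerVector weights) {
  std::vector<uint32_t> M = masks_from_R(masks);
  std::vector<int> w(weights.begin(), weights.end());
  ExhCtx ctx;
  ctx.M = M.data();
  ctx.w = w.data();
  ctx.nPat = masks.ncol();
  ctx.nTip = nTip;
  ctx.best = INT_MAX;
  ctx.scored = 0;

  UTree t(nTip);
  t.link(0, nTip);
  t.link(1, nTip);
  t.link(2, nTip);
  exhaustive_recurse(t, 3, ctx);

  List trees(ctx.optima.size());
  for (size_t i = 0; i < ctx.optima.size(); ++i) trees[i] = ctx.optima[i];
  return List::create(_["best_length"] = ctx.best, _["trees"] = trees,
                      _["n_scored"] = (double)ctx.scored);
}

// ---- per-branch minimum lengths (MINBRLEN) ---------------------------------

// Minimum changes an edge must carry over all most-parsimonious
// reconstructions. For unordered characters on a binary tree the Sankoff
// cost vector of any sub-component takes at most three values, L, L+1, L+2;
// the tier-0 set is the Fitch set S and the tier-1 set T follows from the S
// sets of the two parts joined at the component's interface node
// (symmetric difference when they intersect, complement of the union when
// they are disjoint). An edge can be change-free in some MPR iff the states
// of its two sides can agree at combined cost L: S_below and S_above
// intersect, or one side's tier-0 set meets the other side's tier-1 set
// when the Fitch sets are disjoint.
struct TierSet {
  uint32_t S;
  uint32_t T;
};

static inline TierSet tier_combine(uint32_t Sa, uint32_t Sb, uint32_t full) {
  TierSet out;
  uint32_t inter = Sa & Sb;
  if (inter) {
    out.S = inter;
    out.T = (Sa | Sb) & ~inter;
  } else {
    out.S = Sa | Sb;
    out.T = full & ~out.S;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector branch_min_cpp(IntegerMatrix edge, int nTip, IntegerMatrix masks,
                             IntegerVector weights) {
  int nPat = masks.ncol();
  int nNodes = 0;
  for (int i = 0; i < edge.nrow(); ++i)
    nNodes = std::max(nNodes, std::max(edge(i, 0), edge(i, 1)));

  std::vector<std::vector<int>> children(nNodes + 1);
  std::vector<int> parent(nNodes + 1, 0);
  for (int i = 0; i < edge.nrow(); ++i) {
    children[edge(i, 0)].push_back(edge(i, 1));
    parent[edge(i, 1)] = edge(i, 0);
  }
  int root = edge(0, 0);
  while (parent[root] != 0) root = parent[root];

  std::vector<uint32_t> full(nPat, 0);
  for (int i = 0; i < nTip; ++i)
    for (int p = 0; p < nPat; ++p) full[p] |= (uint32_t)masks(i, p);

  // postorder
  std::vector<int> post, stack = {root};
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    post.push_back(v);
    for (int c : children[v]) stack.push_back(c);
  }
  std::reverse(post.begin(), post.end());

  std::vector<uint32_t> dS((size_t)(nNodes + 1) * nPat);
  std::vector<uint32_t> dT((size_t)(nNodes + 1) * nPat);
  std::vector<uint32_t> uS((size_t)(nNodes + 1) * nPat);
  std::vector<uint32_t> uT((size_t)(nNodes + 1) * nPat);

  for (int v : post) {
    size_t off = (size_t)v * nPat;
    if (children[v].empty()) {
      for (int p = 0; p < nPat; ++p) {
        dS[off + p] = (uint32_t)masks(v - 1, p);
        dT[off + p] = 0;  // leaf states are fixed to the observed set
      }
      continue;
    }
    if (children[v].size() == 2) {
      size_t a = (size_t)children[v][0] * nPat;
      size_t b = (size_t)children[v][1] * nPat;
      for (int p = 0; p < nPat; ++p) {
        TierSet ts = tier_combine(dS[a + p], dS[b + p], full[p]);
        dS[off + p] = ts.S;
        dT[off + p] = ts.T;
      }
    } else {
      // root trifurcation: fold pairwise (exact for degree-3 root of an
      // unrooted binary tree); only S is needed at the root itself
      size_t a = (size_t)children[v][0] * nPat;
      for (int p = 0; p < nPat; ++p) {
        dS[off + p] = dS[a + p];
      }
      for (size_t ci = 1; ci < children[v].size(); ++ci) {
        size_t b = (size_t)children[v][ci] * nPat;
        for (int p = 0; p < nPat; ++p) {
          TierSet ts = tier_combine(dS[off + p], dS[b + p], full[p]);
          dS[off + p] = ts.S;
          dT[off + p] = ts.T;
        }
      }
    }
  }

  // preorder up-sets: the above-component of child c is rooted at its parent
  // v and joins the above-component of v with c's siblings
  for (auto it = post.rbegin(); it != post.rend(); ++it) {
    int v = *it;
    for (int c : children[v]) {
      size_t oc = (size_t)c * nPat;
      bool first = true;
      if (v != root) {
        size_t ov = (size_t)v * nPat;
        std::copy(&uS[ov], &uS[ov] + nPat, &uS[oc]);
        std::copy(&uT[ov], &uT[ov] + nPat, &uT[oc]);
        first = false;
      }
      for (int sib : children[v]) {
        if (sib == c) continue;
        size_t os = (size_t)sib * nPat;
        if (first) {
          std::copy(&dS[os], &dS[os] + nPat, &uS[oc]);
          if (v == root && children[v].size() == 2) {
            // degree-2 root: the above component is the sibling subtree seen
            // through the root, so its tier-1 set is everything outside S
            for (int p = 0; p < nPat; ++p) uT[oc + p] = full[p] & ~dS[os + p];
          } else {
            std::copy(&dT[os], &dT[os] + nPat, &uT[oc]);
          }
          first = false;
        } else {
          for (int p = 0; p < nPat; ++p) {
            TierSet ts = tier_combine(uS[oc + p], dS[os + p], full[p]);
            uS[oc + p] = ts.S;
            uT[oc + p] = ts.T;
          }
        }
      }
    }
  }

  IntegerVector out(edge.nrow());
  for (int i = 0; i < edge.nrow(); ++i) {
    int c = edge(i, 1);
    size_t oc = (size_t)c * nPat;
    int steps = 0;
    for (int p = 0; p < nPat; ++p) {
      uint32_t Sb = dS[oc + p], Tb = dT[oc + p];
      uint32_t Sa = uS[oc + p], Ta = uT[oc + p];
      if (Sb & Sa) continue;
      if ((Sb & Ta) || (Sa & Tb)) continue;
      steps += weights[p];
    }
    out[i] = steps;
  }
  return out;
}

// ---- ACCTRAN branch steps --------------------------------------------------

// Root the unrooted binary tree at the designated outgroup tip, Fitch
// down-pass, then a preorder pass assigning final states that places changes
// as early (rootward) as possible: a node keeps its parent's state only when
// that state is in its Fitch set; otherwise it changes, to the lowest-index
// member of its Fitch set.
// [[Rcpp::export]]
List acctran_cpp(IntegerMatrix edge, int nTip, IntegerMatrix masks,
                 IntegerVector weights, int outgroupTip) {
  UTree t = tree_from_edge(edge, nTip);
  int nPat = masks.ncol();
  int og = outgroupTip - 1;
  int r0 = t.nb[og][0];

  Traversal tr;
  build_traversal(t, r0, tr);
  // exclude the outgroup leaf's subtree orientation: r0's parent is -1; the
  // outgroup becomes a child of r0 in this traversal, which is fine — we just
  // must not descend through it when assigning finals from the root side.
  int nNodes = 2 * nTip - 2;
  std::vector<uint32_t> S((size_t)nNodes * nPat);
  std::vector<int> L(nPat, 0);
  for (int idx = 0; idx < (int)tr.post.size(); ++idx) {
    int v = tr.post[idx];
    uint32_t* Sv = &S[(size_t)v * nPat];
    if (v < nTip) {
      for (int p = 0; p < nPat; ++p) Sv[p] = (uint32_t)masks(v, p);
      continue;
    }
    bool first = true;
    for (int k = 0; k < 3; ++k) {
      int c = t.nb[v][k];
      if (c == -1 || c == tr.parent[v]) continue;
      if (v == r0 && c == og) continue;  // handled at the root edge
      uint32_t* Sc = &S[(size_t)c * nPat];
      if (first) {
        std::copy(Sc, Sc + nPat, Sv);
        first = false;
      } else {
        for (int p = 0; p < nPat; ++p) {
          uint32_t inter = Sv[p] & Sc[p];
          if (inter) {
            Sv[p] = inter;
          } else {
            Sv[p] |= Sc[p];
            L[p] += 1;
          }
        }
      }
    }
  }

  // per-edge step counts, indexed like the input edge matrix
  std::vector<int> stepsByPair((size_t)nNodes * 3, 0);
  auto slot_of = [&](int a, int b) {
    for (int k = 0; k < 3; ++k)
      if (t.nb[a][k] == b) return (size_t)a * 3 + k;
    stop("internal error: edge not found");
    return (size_t)0;
  };

  std::vector<uint32_t> finals((size_t)nNodes * nPat);
  // root edge (og, r0)
  {
    size_t sl = slot_of(std::min(og, r0), std::max(og, r0));
    uint32_t* Sr = &S[(size_t)r0 * nPat];
    uint32_t* F = &finals[(size_t)r0 * nPat];
    for (int p = 0; p < nPat; ++p) {
      uint32_t m = (uint32_t)masks(og, p);
      uint32_t inter = Sr[p] & m;
      if (inter) {
        F[p] = inter & (~inter + 1);  // lowest set bit
      } else {
        F[p] = Sr[p] & (~Sr[p] + 1);
        stepsByPair[sl] += weights[p];
      }
    }
  }
  // preorder over the ingroup side
  std::vector<int> pre(tr.post.rbegin(), tr.post.rend());
  for (int v : pre) {
    if (v == r0) {
      // children handled below in common loop
    }
    uint32_t* Fv = &finals[(size_t)v * nPat];
    for (int k = 0; k < 3; ++k) {
      int c = t.nb[v][k];
      if (c == -1 || c == tr.parent[v]) continue;
      if (v == r0 && c == og) continue;
      size_t sl = slot_of(std::min(v, c), std::max(v, c));
      uint32_t* Fc = &finals[(size_t)c * nPat];
      if (c < nTip) {
        for (int p = 0; p < nPat; ++p) {
          uint32_t m = (uint32_t)masks(c, p);
          if (Fv[p] & m) {
            Fc[p] = Fv[p];
          } else {
            Fc[p] = m & (~m + 1);
            stepsByPair[sl] += weights[p];
          }
        }
      } else {
        uint32_t* Sc = &S[(size_t)c * nPat];
        for (int p = 0; p < nPat; ++p) {
          if (Fv[p] & Sc[p]) {
            Fc[p] = Fv[p];
          } else {
            Fc[p] = Sc[p] & (~Sc[p] + 1);
            stepsByPair[sl] += weights[p];
          }
        }
      }
    }
  }

  IntegerVector out(edge.nrow());
  int total = 0;
  for (int i = 0; i < edge.nrow(); ++i) {
    int a = edge(i, 0) - 1, b = edge(i, 1) - 1;
    out[i] = stepsByPair[slot_of(std::min(a, b), std::max(a, b))];
    total += out[i];
  }
  return List::create(_["steps"] = out, _["total"] = total);
}
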