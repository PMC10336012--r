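// Canonical atom ranking: iterative neighborhood refinement with
// individualization.  Returns every discrete coloring reachable by the
// individualization-refinement tree; the SMILES writer picks the
// lexicographically smallest string over these colorings.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <utility>

using namespace Rcpp;

typedef std::vector<std::vector<std::pair<int, int> > > AdjList;

// One round of stable refinement: colors become ranks of
// (old color, sorted multiset of (bond type, neighbor color)).
static std::vector<int> refine(int n, const AdjList &adj, std::vector<int> col) {
  int ndistinct = 0;
  {
    std::vector<int> tmp(col);
    std::sort(tmp.begin(), tmp.end());
    ndistinct = (int)(std::unique(tmp.begin(), tmp.end()) - tmp.begin());
  }
  std::vector<std::vector<long long> > key(n);
  std::vector<int> idx(n);
  for (;;) {
    for (int v = 0; v < n; ++v) {
      key[v].clear();
      key[v].push_back(col[v]);
      std::vector<long long> nb;
      nb.reserve(adj[v].size());
      for (size_t k = 0; k < adj[v].size(); ++k)
        nb.push_back((long long)adj[v][k].first * (n + 2) + col[adj[v][k].second]);
      std::sort(nb.begin(), nb.end());
      key[v].insert(key[v].end(), nb.begin(), nb.end());
    }
    for (int v = 0; v < n; ++v) idx[v] = v;
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      return key[a] < key[b];
    });
    std::vector<int> newcol(n);
    int c = 1;
    newcol[idx[0]] = c;
    for (int i = 1; i < n; ++i) {
      if (key[idx[i]] != key[idx[i - 1]]) ++c;
      newcol[idx[i]] = c;
    }
    if (c == ndistinct) return newcol;
    ndistinct = c;
    col.swap(newcol);
  }
}

static void enumerate_colorings(int n, const AdjList &adj, std::vector<int> col,
                                std::vector<std::vector<int> > &out, int cap) {
  col = refine(n, adj, col);
  // first cell (smallest color value) with multiplicity > 1
  std::vector<int> cnt(n + 2, 0);
  for (int v = 0; v < n; ++v) cnt[col[v]]++;
  int cell = -1;
  for (int c = 1; c <= n; ++c)
    if (cnt[c] > 1) { cell = c; break; }
  if (cell < 0) {
    out.push_back(col);
    return;
  }
  for (int v = 0; v < n; ++v) {
    if (col[v] != cell) continue;
    std::vector<int> c2(col);
    for (int w = 0; w < n; ++w) c2[w] *= 2;
    c2[v] -= 1;
    enumerate_colorings(n, adj, c2, out, cap);
    if ((int)out.size() > cap)
      stop("canonical labeling branch limit exceeded");
  }
}

// [[Rcpp::export]]
List cpp_discrete_colorings(int n, IntegerVector a1, IntegerVector a2,
                            IntegerVector bond_type, IntegerVector init,
                            int cap = 5000) {
  AdjList adj(n);
  for (int r = 0; r < a1.size(); ++r) {
    int a = a1[r] - 1, b = a2[r] - 1;
    adj[a].push_back(std::make_pair(bond_type[r], b));
    adj[b].push_back(std::make_pair(bond_type[r], a));
  }
  std::vector<int> col(init.begin(), init.end());
  std::vector<std::vector<int> > out;
  enumerate_colorings(n, adj, col, out, cap);
  List res(out.size());
  for (size_t i = 0; i < out.size(); ++i)
    res[i] = IntegerVector(out[i].begin(), out[i].end());
  return res;
}

// Deterministic depth-first SMILES emission.  Neighbor visiting order
// follows `rank` (ties by atom index); atom and per-bond tokens are
// precomputed on the R side.  Ring-closure digits are assigned in
// preorder-interval order with reuse, and the (possibly explicit) bond
// symbol is written at both mentions of a ring digit.

struct Writer {
  int n, m;
  const int *a1, *a2;
  std::vector<std::vector<int> > adj;     // bond rows per atom
  const IntegerVector *rank;
  std::vector<bool> visited;
  std::vector<int> pre;
  std::vector<std::vector<int> > children;
  std::vector<int> ringbonds;
  std::vector<bool> is_ring;
  int cnt;

  int other(int r, int v) const {
    return (a1[r] - 1 == v) ? a2[r] - 1 : a1[r] - 1;
  }

  void dfs(int v, int from_row) {
    visited[v] = true;
    pre[v] = ++cnt;
    std::vector<std::pair<std::pair<int, int>, int> > nb;  // ((rank,idx),row)
    for (size_t k = 0; k < adj[v].size(); ++k) {
      int r = adj[v][k];
      if (r == from_row) continue;
      int w = other(r, v);
      nb.push_back(std::make_pair(std::make_pair((*rank)[w], w), r));
    }
    std::sort(nb.begin(), nb.end());
    for (size_t k = 0; k < nb.size(); ++k) {
      int r = nb[k].second, w = nb[k].first.second;
      if (visited[w]) {
        if (!is_ring[r]) { is_ring[r] = true; ringbonds.push_back(r); }
      } else {
        children[v].push_back(r);
        dfs(w, r);
      }
    }
  }
};

// [[Rcpp::export]]
std::string cpp_write_smiles(int n, IntegerVector a1, IntegerVector a2,
                             std::vector<std::string> atok,
                             std::vector<std::string> btok,
                             int start, IntegerVector rank) {
  Writer W;
  W.n = n; W.m = a1.size();
  W.a1 = a1.begin(); W.a2 = a2.begin();
  W.adj.assign(n, std::vector<int>());
  for (int r = 0; r < W.m; ++r) {
    W.adj[a1[r] - 1].push_back(r);
    W.adj[a2[r] - 1].push_back(r);
  }
  W.rank = &rank;
  W.visited.assign(n, false);
  W.pre.assign(n, 0);
  W.children.assign(n, std::vector<int>());
  W.is_ring.assign(W.m, false);
  W.cnt = 0;
  W.dfs(start - 1, -1);
  if (W.cnt < n) stop("molecule is not connected");

  // ring digit assignment with reuse, by (open,close) preorder intervals
  int nr = (int)W.ringbonds.size();
  std::vector<int> digit_of(nr, 0);
  {
    std::vector<std::pair<std::pair<int, int>, int> > iv(nr);
    for (int k = 0; k < nr; ++k) {
      int r = W.ringbonds[k];
      int p1 = W.pre[a1[r] - 1], p2 = W.pre[a2[r] - 1];
      iv[k] = std::make_pair(std::make_pair(std::min(p1, p2), std::max(p1, p2)), k);
    }
    std::sort(iv.begin(), iv.end());
    std::vector<int> busy_until(100, 0);
    for (int i = 0; i < nr; ++i) {
      int lo = iv[i].first.first, hi = iv[i].first.second, k = iv[i].second;
      int d = 1;
      while (busy_until[d] > lo) ++d;
      digit_of[k] = d;
      busy_until[d] = hi;
    }
  }
  std::vector<std::vector<std::pair<int, int> > > ring_at(n);  // (digit,row)
  for (int k = 0; k < nr; ++k) {
    int r = W.ringbonds[k];
    ring_at[a1[r] - 1].push_back(std::make_pair(digit_of[k], r));
    ring_at[a2[r] - 1].push_back(std::make_pair(digit_of[k], r));
  }
  for (int v = 0; v < n; ++v) std::sort(ring_at[v].begin(), ring_at[v].end());

  // emission
  struct Emit {
    Writer *W;
    std::vector<std::vector<std::pair<int, int> > > *ring_at;
    const std::vector<std::string> *atok, *btok;
    std::string out;
    void emit(int v) {
      out += (*atok)[v];
      for (size_t k = 0; k < (*ring_at)[v].size(); ++k) {
        int d = (*ring_at)[v][k].first, r = (*ring_at)[v][k].second;
        out += (*btok)[r];
        if (d <= 9) out += char('0' + d);
        else { out += '%'; out += char('0' + d / 10); out += char('0' + d % 10); }
      }
      const std::vector<int> &ch = W->children[v];
      for (size_t k = 0; k < ch.size(); ++k) {
        int r = ch[k];
        int w = W->other(r, v);
        if (k + 1 < ch.size()) {
          out += '(';
          out += (*btok)[r];
          emit(w);
          out += ')';
        } else {
          out += (*btok)[r];
          emit(w);
        }
      }
    }
  } E;
  E.W = &W; E.ring_at = &ring_at; E.atok = &atok; E.btok = &btok;
  E.emit(start - 1);
  return E.out;
}

// Small graph utilities for the hot path (connectivity, BFS backbone
// path, bridge detection).  1-based vertex/bond indexing at the interface.

// [[Rcpp::export]]
IntegerVector cpp_components(int n, IntegerVector a1, IntegerVector a2) {
  std::vector<std::vector<int> > adj(n);
  for (int r = 0; r < a1.size(); ++r) {
    adj[a1[r] - 1].push_back(a2[r] - 1);
    adj[a2[r] - 1].push_back(a1[r] - 1);
  }
  IntegerVector memb(n, 0);
  int c = 0;
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    if (memb[s]) continue;
    ++c;
    stack.push_back(s);
    memb[s] = c;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      for (size_t k = 0; k < adj[v].size(); ++k)
        if (!memb[adj[v][k]]) { memb[adj[v][k]] = c; stack.push_back(adj[v][k]); }
    }
  }
  return memb;
}

// Shortest path (BFS, deterministic by bond insertion order); empty when
// unreachable.
// [[Rcpp::export]]
IntegerVector cpp_bfs_path(int n, IntegerVector a1, IntegerVector a2,
                           int from, int to) {
  std::vector<std::vector<int> > adj(n);
  for (int r = 0; r < a1.size(); ++r) {
    adj[a1[r] - 1].push_back(a2[r] - 1);
    adj[a2[r] - 1].push_back(a1[r] - 1);
  }
  std::vector<int> parent(n, -2);
  std::vector<int> queue;
  int s = from - 1, t = to - 1;
  parent[s] = -1;
  queue.push_back(s);
  for (size_t qi = 0; qi < queue.size(); ++qi) {
    int v = queue[qi];
    if (v == t) break;
    for (size_t k = 0; k < adj[v].size(); ++k) {
      int w = adj[v][k];
      if (parent[w] == -2) { parent[w] = v; queue.push_back(w); }
    }
  }
  if (parent[t] == -2) return IntegerVector(0);
  std::vector<int> path;
  for (int v = t; v != -1; v = parent[v]) path.push_back(v + 1);
  std::reverse(path.begin(), path.end());
  return IntegerVector(path.begin(), path.end());
}

// Bond rows lying on at least one cycle (i.e., non-bridges), via DFS
// low-link bridge detection.
// [[Rcpp::export]]
IntegerVector cpp_cycle_bonds(int n, IntegerVector a1, IntegerVector a2) {
  int m = a1.size();
  std::vector<std::vector<std::pair<int, int> > > adj(n);  // (w, bond row)
  for (int r = 0; r < m; ++r) {
    adj[a1[r] - 1].push_back(std::make_pair(a2[r] - 1, r));
    adj[a2[r] - 1].push_back(std::make_pair(a1[r] - 1, r));
  }
  std::vector<int> disc(n, -1), low(n, 0);
  std::vector<bool> is_bridge(m, false);
  int timer = 0;
  // iterative DFS: stack of (v, parent bond row, adjacency position)
  for (int s = 0; s < n; ++s) {
    if (disc[s] != -1) continue;
    std::vector<int> vstack, bstack, pstack;
    vstack.push_back(s); bstack.push_back(-1); pstack.push_back(0);
    disc[s] = low[s] = timer++;
    while (!vstack.empty()) {
      int v = vstack.back();
      int pos = pstack.back();
      if (pos < (int)adj[v].size()) {
        pstack.back()++;
        int w = adj[v][pos].first, r = adj[v][pos].second;
        if (r == bstack.back()) continue;
        if (disc[w] == -1) {
          disc[w] = low[w] = timer++;
          vstack.push_back(w); bstack.push_back(r); pstack.push_back(0);
        } else {
          low[v] = std::min(low[v], disc[w]);
        }
      } else {
        int r = bstack.back();
        vstack.pop_back(); bstack.pop_back(); pstack.pop_back();
        if (!vstack.empty()) {
          int u = vstack.back();
          low[u] = std::min(low[u], low[v]);
          if (low[v] > disc[u]) is_bridge[r] = true;
        }
      }
    }
  }
  std::vector<int> out;
  for (int r = 0; r < m; ++r)
    if (!is_bridge[r]) out.push_back(r + 1);
  return IntegerVector(out.begin(), out.end());
}
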