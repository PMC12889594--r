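// Left-right (de Fraysseix--Rosenstiehl) planarity test, following the
// formulation in Brandes, "The Left-Right Planarity Test" (2009): DFS
// orientation with lowpoints and nesting order, then a second DFS
// maintaining a stack of conflict pairs of edge intervals. Only the
// boolean planarity decision is computed (no embedding). Also provides
// the greedy planar-filtered-network builder: edges arrive sorted by
// descending |rho| and each is kept iff the graph stays planar.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

namespace {

struct Interval {
  int low, high;                       // directed edge ids; -1 = none
  Interval() : low(-1), high(-1) {}
  Interval(int l, int h) : low(l), high(h) {}
  bool empty() const { return low == -1 && high == -1; }
};

struct ConflictPair {
  Interval L, R;
};

class LRPlanarity {
public:
  int n, m;
  std::vector<std::vector<std::pair<int,int> > > adj;  // (neighbor, edge id)
  std::vector<int> height, parent_edge;
  // per-edge state; an undirected edge gets exactly one orientation, so
  // the undirected edge id doubles as the directed edge id
  std::vector<int> eu, ev, lowpt, lowpt2, nesting_depth;
  std::vector<bool> oriented;
  std::vector<int> ref_, side, lowpt_edge, stack_bottom;
  std::vector<std::vector<int> > ordered;
  std::vector<ConflictPair> S;

  LRPlanarity(int n_, const std::vector<std::pair<int,int> >& edges)
      : n(n_), m((int)edges.size()) {
    adj.assign(n, std::vector<std::pair<int,int> >());
    for (int i = 0; i < m; ++i) {
      adj[edges[i].first].push_back(std::make_pair(edges[i].second, i));
      adj[edges[i].second].push_back(std::make_pair(edges[i].first, i));
    }
    height.assign(n, -1);
    parent_edge.assign(n, -1);
    eu.assign(m, -1); ev.assign(m, -1);
    lowpt.assign(m, 0); lowpt2.assign(m, 0); nesting_depth.assign(m, 0);
    oriented.assign(m, false);
    ref_.assign(m, -1); side.assign(m, 1);
    lowpt_edge.assign(m, -1); stack_bottom.assign(m, -2);
  }

  bool is_planar() {
    if (n > 2 && (long)m > 3L * n - 6L) return false;
    for (int v = 0; v < n; ++v)
      if (height[v] == -1) { height[v] = 0; dfs_orientation(v); }
    ordered.assign(n, std::vector<int>());
    for (int e = 0; e < m; ++e)
      if (eu[e] >= 0) ordered[eu[e]].push_back(e);
    for (int v = 0; v < n; ++v)
      std::sort(ordered[v].begin(), ordered[v].end(), NestCmp(this));
    for (int v = 0; v < n; ++v)
      if (parent_edge[v] == -1 && height[v] == 0)
        if (!dfs_testing(v)) return false;
    return true;
  }

private:
  struct NestCmp {
    LRPlanarity* p;
    NestCmp(LRPlanarity* p_) : p(p_) {}
    bool operator()(int a, int b) const {
      return p->nesting_depth[a] < p->nesting_depth[b];
    }
  };

  void dfs_orientation(int v) {
    int e = parent_edge[v];
    for (size_t i = 0; i < adj[v].size(); ++i) {
      int w = adj[v][i].first, id = adj[v][i].second;
      if (oriented[id]) continue;
      oriented[id] = true;
      eu[id] = v; ev[id] = w;
      lowpt[id] = height[v]; lowpt2[id] = height[v];
      if (height[w] == -1) {              // tree edge
        parent_edge[w] = id;
        height[w] = height[v] + 1;
        dfs_orientation(w);
      } else {                            // back edge
        lowpt[id] = height[w];
      }
      nesting_depth[id] = 2 * lowpt[id];
      if (lowpt2[id] < height[v]) nesting_depth[id] += 1;   // chordal
      if (e != -1) {                      // update parent edge lowpoints
        if (lowpt[id] < lowpt[e]) {
          lowpt2[e] = std::min(lowpt[e], lowpt2[id]);
          lowpt[e] = lowpt[id];
        } else if (lowpt[id] > lowpt[e]) {
          lowpt2[e] = std::min(lowpt2[e], lowpt[id]);
        } else {
          lowpt2[e] = std::min(lowpt2[e], lowpt2[id]);
        }
      }
    }
  }

  bool conflicting(const Interval& I, int b) const {
    return !I.empty() && lowpt[I.high] > lowpt[b];
  }

  int lowest(const ConflictPair& P) const {
    if (P.L.empty() && P.R.empty()) return -2;
    if (P.L.empty()) return lowpt[P.R.low];
    if (P.R.empty()) return lowpt[P.L.low];
    return std::min(lowpt[P.L.low], lowpt[P.R.low]);
  }

  bool dfs_testing(int v) {
    int e = parent_edge[v];
    for (size_t i = 0; i < ordered[v].size(); ++i) {
      int ei = ordered[v][i];
      int w = ev[ei];
      stack_bottom[ei] = (int)S.size() - 1;
      if (ei == parent_edge[w]) {         // tree edge
        if (!dfs_testing(w)) return false;
      } else {                            // back edge
        lowpt_edge[ei] = ei;
        ConflictPair P;
        P.R = Interval(ei, ei);
        S.push_back(P);
      }
      if (lowpt[ei] < height[v]) {        // ei has a return edge
        if (ei == ordered[v][0]) {
          if (e != -1) lowpt_edge[e] = lowpt_edge[ei];
        } else if (!add_constraints(ei, e)) {
          return false;
        }
      }
    }
    if (e != -1) remove_back_edges(e);
    return true;
  }

  bool add_constraints(int ei, int e) {
    ConflictPair P;
    if ((int)S.size() - 1 == stack_bottom[ei]) return true;  // nothing pushed
    // merge return edges of ei into P.R
    do {
      ConflictPair Q = S.back(); S.pop_back();
      if (!Q.L.empty()) std::swap(Q.L, Q.R);
      if (!Q.L.empty()) return false;     // not planar
      if (Q.R.low != -1 && lowpt[Q.R.low] > lowpt[e]) {
        if (P.R.empty()) P.R = Q.R;       // topmost interval
        else ref_[P.R.low] = Q.R.high;
        P.R.low = Q.R.low;
      } else if (Q.R.low != -1) {         // align
        ref_[Q.R.low] = lowpt_edge[e];
      }
    } while ((int)S.size() - 1 != stack_bottom[ei]);
    // merge conflicting return edges of earlier siblings into P.L
    while (!S.empty() &&
           (conflicting(S.back().L, ei) || conflicting(S.back().R, ei))) {
      ConflictPair Q = S.back(); S.pop_back();
      if (conflicting(Q.R, ei)) std::swap(Q.L, Q.R);
      if (conflicting(Q.R, ei)) return false;   // not planar
      // merge interval below lowpt(ei) into P.R
      if (P.R.low != -1) ref_[P.R.low] = Q.R.high;
      if (Q.R.low != -1) P.R.low = Q.R.low;
      if (P.L.empty()) P.L = Q.L;         // topmost interval
      else ref_[P.L.low] = Q.L.high;
      P.L.low = Q.L.low;
    }
    if (!(P.L.empty() && P.R.empty())) S.push_back(P);
    return true;
  }

  void remove_back_edges(int e) {
    int u = eu[e];
    // drop entire conflict pairs returning to the parent
    while (!S.empty() && lowest(S.back()) == height[u]) {
      ConflictPair P = S.back(); S.pop_back();
      if (P.L.low != -1) side[P.L.low] = -1;
    }
    if (!S.empty()) {                     // trim one more conflict pair
      ConflictPair P = S.back(); S.pop_back();
      while (P.L.high != -1 && ev[P.L.high] == u) P.L.high = ref_[P.L.high];
      if (P.L.high == -1 && P.L.low != -1) {    // just emptied
        ref_[P.L.low] = P.R.low;
        side[P.L.low] = -1;
        P.L.low = -1;
      }
      while (P.R.high != -1 && ev[P.R.high] == u) P.R.high = ref_[P.R.high];
      if (P.R.high == -1 && P.R.low != -1) {    // just emptied
        ref_[P.R.low] = P.L.low;
        side[P.R.low] = -1;
        P.R.low = -1;
      }
      S.push_back(P);
    }
    // side of e is the side of a highest return edge
    if (lowpt[e] < height[u] && !S.empty()) {
      int hl = S.back().L.high, hr = S.back().R.high;
      if (hl != -1 && (hr == -1 || lowpt[hl] > lowpt[hr])) ref_[e] = hl;
      else ref_[e] = hr;
    }
  }
};

bool planar_check(int n, const std::vector<std::pair<int,int> >& edges) {
  LRPlanarity lr(n, edges);
  return lr.is_planar();
}

} // namespace

// [[Rcpp::export(name = ".is_planar_cpp")]]
bool is_planar_cpp(int n_vertices, Rcpp::IntegerVector from,
                   Rcpp::IntegerVector to) {
  std::vector<std::pair<int,int> > es(from.size());
  for (int i = 0; i < from.size(); ++i) {
    if (from[i] == to[i]) Rcpp::stop("self-loops are not allowed");
    es[i] = std::make_pair(from[i] - 1, to[i] - 1);
  }
  return planar_check(n_vertices, es);
}

// Greedy planar filtered network: edges pre-sorted by descending |rho|;
// each edge is added iff the graph stays planar; construction stops once
// 3(V-2) edges are held (the maximal planar edge count).
// [[Rcpp::export(name = ".build_pfn_cpp")]]
Rcpp::LogicalVector build_pfn_cpp(int n_vertices, Rcpp::IntegerVector from,
                                  Rcpp::IntegerVector to) {
  int m = from.size();
  Rcpp::LogicalVector keep(m);
  std::vector<std::pair<int,int> > held;
  long cap = (n_vertices >= 3) ? 3L * (n_vertices - 2L)
                               : (n_vertices == 2 ? 1L : 0L);
  for (int i = 0; i < m; ++i) {
    keep[i] = false;
    if ((long)held.size() >= cap) continue;
    held.push_back(std::make_pair(from[i] - 1, to[i] - 1));
    if (planar_check(n_vertices, held)) keep[i] = true;
    else held.pop_back();
  }
  return keep;
}
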