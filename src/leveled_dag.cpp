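// Leveled-DAG engine for the exact MLCS problem.
//
// The graph is built level by level over match points. A node whose
// in-degree drops to zero after it has been expanded is "outdated":
// its partial LCS strings are bequeathed to its successors (appending
// each successor's own symbol) and the node is deleted. When only the
// end sentinel survives, its partial LCS set is the complete MLCS set.

#include <Rcpp.h>
#include <unordered_map>
#include <memory>

#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct PtHash {
  std::size_t operator()(const std::vector<int>& v) const {
    std::size_t h = 1469598103934665603ULL;
    for (int x : v)
      h ^= static_cast<std::size_t>(x) + 0x9e3779b97f4a7c15ULL +
           (h << 6) + (h >> 2);
    return h;
  }
};

// A partial-LCS set, stored structurally: the explicit strings in
// `base` plus, for each (src, delta) part, every string of the dead
// precursor's frozen set with delta appended ('\0' = append nothing,
// used by the end node). All represented strings share length `len`.
// Sharing makes a bequeathing step O(1); the strings themselves are
// only materialized on inspection and at final extraction, where the
// reachable sets are exactly those on maximum-length paths.
struct PlcsSet {
  int len = 0;
  std::vector<std::string> base;
  std::vector<std::pair<std::shared_ptr<PlcsSet>, char>> parts;
};

inline void normalizePlcs(std::vector<std::string>& v) {
  std::sort(v.begin(), v.end());
  v.erase(std::unique(v.begin(), v.end()), v.end());
}

const std::vector<std::string>& materialize(
    const std::shared_ptr<PlcsSet>& ps,
    std::unordered_map<const PlcsSet*, std::vector<std::string>>& memo) {
  static const std::vector<std::string> empty;
  if (!ps) return empty;
  auto hit = memo.find(ps.get());
  if (hit != memo.end()) return hit->second;
  std::vector<std::string> out = ps->base;
  for (const auto& pr : ps->parts) {
    // references into a node-based map stay valid across inserts
    const std::vector<std::string>& src = materialize(pr.first, memo);
    for (const std::string& w : src)
      out.push_back(pr.second ? w + pr.second : w);
  }
  normalizePlcs(out);
  return memo.emplace(ps.get(), std::move(out)).first->second;
}

struct Node {
  std::vector<int> pt;
  char sym = '\0';                // corresponding symbol C(p)
  std::vector<int> suc;           // successor ids, insertion order
  int inc = 0;                    // live incoming-edge counter
  bool expanded = false;
  bool live = true;
  std::shared_ptr<PlcsSet> plcs;  // null = empty set
};

struct Dag {
  int d = 0, ns = 0;
  // st[k][i][j]: first position of symbol i in sequence k strictly
  // after column j; 0 encodes "none". Columns 0..n_k.
  std::vector<std::vector<std::vector<int>>> st;
  std::vector<char> symbols;
  std::vector<int> order;         // symbol generation order (0-based)
  bool reversePass = false;

  std::vector<Node> nodes;        // id 0 = source, id 1 = end
  std::unordered_map<std::vector<int>, int, PtHash> map;  // live internals + source
  std::vector<int> cur, nxt;

  double nodesCreated = 0, candGen = 0;
  double removedInternal = 0;
  int liveInternal = 0, peakLive = 0, levels = 0, passes = 0;
  bool finished = false;

  static constexpr int END_ID = 1;

  Dag(const List& tables, const CharacterVector& syms,
      const IntegerVector& symbolOrder, bool revPass) {
    d = tables.size();
    ns = syms.size();
    reversePass = revPass;
    for (int i = 0; i < ns; ++i)
      symbols.push_back(Rcpp::as<std::string>(syms[i])[0]);
    for (int i = 0; i < symbolOrder.size(); ++i)
      order.push_back(symbolOrder[i] - 1);
    st.resize(d);
    for (int k = 0; k < d; ++k) {
      IntegerMatrix m = tables[k];
      if (m.nrow() != ns)
        stop("successor table %d has %d rows, expected %d", k + 1,
             m.nrow(), ns);
      st[k].assign(ns, std::vector<int>());
      for (int i = 0; i < ns; ++i) {
        st[k][i].resize(m.ncol());
        for (int j = 0; j < m.ncol(); ++j) st[k][i][j] = m(i, j);
      }
    }
    Node source;
    source.pt.assign(d, 0);
    Node end;
    end.pt.assign(d, -1);          // sentinel key, conceptually (Inf,...,Inf)
    end.expanded = true;           // the end node is never expanded
    nodes.push_back(source);
    nodes.push_back(end);
    map[nodes[0].pt] = 0;
    cur.push_back(0);
  }

  // Expand every unexpanded node of the current level in queue order,
  // then advance the queues (Cur_Level <- Next_Level).
  int expandLevel() {
    if (cur.empty()) stop("no nodes to expand: current level is empty");
    for (int id : cur)
      if (nodes[id].expanded)
        stop("internal inconsistency: node already expanded");
    int created = 0;
    for (int id : cur) {
      bool any = false;
      for (int oi : order) {
        std::vector<int> q(d);
        bool ok = true;
        for (int k = 0; k < d; ++k) {
          int v = st[k][oi][nodes[id].pt[k]];
          if (v == 0) { ok = false; break; }
          q[k] = v;
        }
        if (!ok) continue;
        any = true;
        candGen += 1;
        int sid;
        auto it = map.find(q);
        if (it == map.end()) {
          sid = static_cast<int>(nodes.size());
          Node nn;
          nn.pt = q;
          nn.sym = symbols[oi];
          // first-level nodes carry their single-character partial LCS
          if (id == 0) {
            nn.plcs = std::make_shared<PlcsSet>();
            nn.plcs->len = 1;
            nn.plcs->base.push_back(std::string(1, symbols[oi]));
          }
          nodes.push_back(std::move(nn));
          map[q] = sid;
          nxt.push_back(sid);
          nodesCreated += 1;
          ++liveInternal;
          ++created;
        } else {
          sid = it->second;
        }
        // one expansion per node and one candidate per symbol, and the
        // symbol is determined by the match point, so the edge id->sid
        // cannot repeat: Suc(t) stays duplicate-free by construction.
        nodes[id].suc.push_back(sid);
        nodes[sid].inc += 1;
      }
      if (!any) {  // childless: the end node becomes the only successor
        nodes[id].suc.push_back(END_ID);
        nodes[END_ID].inc += 1;
      }
      nodes[id].expanded = true;
    }
    ++levels;
    if (liveInternal > peakLive) peakLive = liveInternal;
    cur.swap(nxt);
    nxt.clear();
    return created;
  }

  // One remove-outdated pass: snapshot the zero in-degree expanded
  // live nodes, bequeath their partial LCSs, delete them. Nodes whose
  // in-degree drops to zero during the pass wait for a later pass.
  int removePass() {
    ++passes;
    std::vector<int> Z;
    for (std::size_t i = 0; i < nodes.size(); ++i) {
      if (static_cast<int>(i) == END_ID) continue;
      const Node& nd = nodes[i];
      if (nd.live && nd.expanded && nd.inc == 0)
        Z.push_back(static_cast<int>(i));
    }
    if (reversePass) std::reverse(Z.begin(), Z.end());
    for (int pi : Z) {
      Node& p = nodes[pi];
      // p is dead after this pass: its set is frozen and can be shared
      // by reference with every inheriting successor.
      int lp = p.plcs ? p.plcs->len : 0;
      for (int si : p.suc) {
        Node& s = nodes[si];
        char delta = (si == END_ID) ? '\0' : s.sym;
        int ls = s.plcs ? s.plcs->len : 0;
        // Compare on the length the bequeathed strings will have after
        // appending the successor's symbol (nothing for the end node):
        // longer replaces, equal unions, shorter is discarded. For
        // internal successors this is exactly the classical
        // "|p| >= |s| replace / |p| + 1 = |s| union" rule; for the end
        // node it keeps equal-length MLCS arriving from distinct
        // precursors instead of overwriting them.
        int newLen = lp + (delta ? 1 : 0);
        if (!s.plcs || newLen > ls) {
          if (!p.plcs) {
            s.plcs.reset();        // bequeathing an empty set
          } else {
            s.plcs = std::make_shared<PlcsSet>();
            s.plcs->len = newLen;
            s.plcs->parts.emplace_back(p.plcs, delta);
          }
        } else if (newLen == ls) {
          // s owns its PlcsSet exclusively while alive, so in-place
          // union is safe
          if (p.plcs) s.plcs->parts.emplace_back(p.plcs, delta);
        }
        // newLen < ls: too short to matter, discard
        s.inc -= 1;
      }
      map.erase(p.pt);
      p.live = false;
      std::vector<int>().swap(p.suc);
      p.plcs.reset();              // successors keep the frozen set alive
      if (pi != 0) { --liveInternal; removedInternal += 1; }
    }
    return static_cast<int>(Z.size());
  }

  void run() {
    while (!cur.empty()) {
      expandLevel();
      removePass();
    }
    while (liveInternal > 0 || nodes[0].live) {
      if (removePass() == 0)
        stop("internal inconsistency: removal stalled before completion");
      Rcpp::checkUserInterrupt();
    }
    finished = true;
  }
};

Dag* get(SEXP xp) {
  Rcpp::XPtr<Dag> p(xp);
  if (!p) stop("invalid leveled-DAG handle");
  return p.get();
}

}  // namespace

// [[Rcpp::export(name = ".dagCreate")]]
SEXP dagCreate(List tables, CharacterVector symbols,
               IntegerVector symbolOrder, bool reversePass) {
  Rcpp::XPtr<Dag> p(new Dag(tables, symbols, symbolOrder, reversePass),
                    true);
  return p;
}

// [[Rcpp::export(name = ".dagExpandLevel")]]
int dagExpandLevel(SEXP xp) { return get(xp)->expandLevel(); }

// [[Rcpp::export(name = ".dagRemovePass")]]
int dagRemovePass(SEXP xp) { return get(xp)->removePass(); }

// [[Rcpp::export(name = ".dagRun")]]
void dagRun(SEXP xp) { get(xp)->run(); }

// [[Rcpp::export(name = ".dagCurLevelSize")]]
int dagCurLevelSize(SEXP xp) {
  return static_cast<int>(get(xp)->cur.size());
}

// [[Rcpp::export(name = ".dagLiveInternal")]]
int dagLiveInternal(SEXP xp) { return get(xp)->liveInternal; }

// [[Rcpp::export(name = ".dagLivePoints")]]
List dagLivePoints(SEXP xp) {
  Dag* g = get(xp);
  List out;
  for (std::size_t i = 2; i < g->nodes.size(); ++i) {
    if (!g->nodes[i].live) continue;
    IntegerVector pt(g->d);
    for (int k = 0; k < g->d; ++k) pt[k] = g->nodes[i].pt[k];
    out.push_back(pt);
  }
  return out;
}

// [[Rcpp::export(name = ".dagNodePlcs")]]
CharacterVector dagNodePlcs(SEXP xp, IntegerVector point) {
  Dag* g = get(xp);
  std::vector<int> key(point.begin(), point.end());
  auto it = g->map.find(key);
  if (it == g->map.end()) stop("no live node at the given match point");
  std::unordered_map<const PlcsSet*, std::vector<std::string>> memo;
  const std::vector<std::string>& v =
      materialize(g->nodes[it->second].plcs, memo);
  return CharacterVector(v.begin(), v.end());
}

// [[Rcpp::export(name = ".dagNodeInfo")]]
List dagNodeInfo(SEXP xp, IntegerVector point) {
  Dag* g = get(xp);
  std::vector<int> key(point.begin(), point.end());
  auto it = g->map.find(key);
  if (it == g->map.end()) stop("no live node at the given match point");
  const Node& nd = g->nodes[it->second];
  std::unordered_map<const PlcsSet*, std::vector<std::string>> memo;
  const std::vector<std::string>& v = materialize(nd.plcs, memo);
  List sucs;
  for (int si : nd.suc) {
    const Node& s = g->nodes[si];
    if (si == Dag::END_ID) {
      sucs.push_back(R_NilValue);
    } else {
      IntegerVector pt(s.pt.begin(), s.pt.end());
      sucs.push_back(pt);
    }
  }
  return List::create(
      _["symbol"] = std::string(1, nd.sym),
      _["incoming"] = nd.inc,
      _["expanded"] = nd.expanded,
      _["plcs"] = CharacterVector(v.begin(), v.end()),
      _["successors"] = sucs);
}

// [[Rcpp::export(name = ".dagEndPlcs")]]
CharacterVector dagEndPlcs(SEXP xp) {
  Dag* g = get(xp);
  std::unordered_map<const PlcsSet*, std::vector<std::string>> memo;
  const std::vector<std::string>& v =
      materialize(g->nodes[Dag::END_ID].plcs, memo);
  return CharacterVector(v.begin(), v.end());
}

// [[Rcpp::export(name = ".dagIsFinished")]]
bool dagIsFinished(SEXP xp) {
  Dag* g = get(xp);
  return g->liveInternal == 0 && !g->nodes[0].live && g->cur.empty();
}

// [[Rcpp::export(name = ".dagStats")]]
List dagStats(SEXP xp) {
  Dag* g = get(xp);
  return List::create(
      _["nodesCreated"] = g->nodesCreated,
      _["peakLive"] = static_cast<double>(g->peakLive),
      _["levels"] = static_cast<double>(g->levels),
      _["candidatesGenerated"] = g->candGen,
      _["removalPasses"] = static_cast<double>(g->passes),
      _["liveInternal"] = static_cast<double>(g->liveInternal),
      _["nodesRemoved"] = g->removedInternal);
}
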