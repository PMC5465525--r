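// Popcount-binned forest of split-half multibit trees over sparse bit
// vectors (CLKs), with exact Tanimoto threshold retrieval.
//
// Records are stored as sorted 0-based positions of set bits.  Trees are
// built per popcount bin by recursively splitting on the bit whose set/unset
// counts are closest to half of the current members (ties: lowest bit
// index).  Queries prune (i) whole bins via the popcount bound
// min(a,b)/max(a,b) and (ii) subtrees via the accumulated match-bit bound
// i_max/(a+b-i_max); both bounds dominate the true Tanimoto of every
// descendant, so pruning is lossless.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int split_bit;             // -1 at leaves
  int c0, c1;                // children (members with bit unset / set)
  std::vector<int> members;  // record indices, leaves only
};

struct Forest {
  int l;
  int leaf_limit;
  int n;
  std::vector<std::vector<int>> fps;     // sorted set-bit positions
  std::vector<int> pop;                  // popcount per record
  std::vector<std::pair<int, int>> bins; // (popcount, root node id)
  std::vector<Node> nodes;
};

inline bool has_bit(const std::vector<int> &fp, int bit) {
  return std::binary_search(fp.begin(), fp.end(), bit);
}

// Lowest non-constant bit with member count closest to n/2, or -1.
// Bits already split on along the path are constant within `members`
// (every member agrees with the ancestor match bits), so no explicit
// used-set is needed.
int choose_split(const std::vector<std::vector<int>> &fps,
                 const std::vector<int> &members, int l,
                 std::vector<int> &cnt) {
  std::fill(cnt.begin(), cnt.end(), 0);
  const int n = static_cast<int>(members.size());
  for (int m : members)
    for (int p : fps[m]) cnt[p]++;
  int best = -1;
  long best_bal = -1;
  for (int p = 0; p < l; ++p) {
    const int c = cnt[p];
    if (c == 0 || c == n) continue;  // constant bit cannot split
    const long bal = std::labs(2L * c - n);
    if (best < 0 || bal < best_bal) {
      best = p;
      best_bal = bal;
    }
  }
  return best;
}

int build_node(Forest &f, std::vector<int> members, std::vector<int> &cnt) {
  const int id = static_cast<int>(f.nodes.size());
  f.nodes.push_back(Node{-1, -1, -1, {}});
  if (static_cast<int>(members.size()) <= f.leaf_limit) {
    f.nodes[id].members = std::move(members);
    return id;
  }
  const int bit = choose_split(f.fps, members, f.l, cnt);
  if (bit < 0) {  // all members bit-identical: oversized leaf allowed
    f.nodes[id].members = std::move(members);
    return id;
  }
  std::vector<int> m0, m1;
  for (int m : members) (has_bit(f.fps[m], bit) ? m1 : m0).push_back(m);
  f.nodes[id].split_bit = bit;
  members.clear();
  const int c0 = build_node(f, std::move(m0), cnt);
  const int c1 = build_node(f, std::move(m1), cnt);
  f.nodes[id].c0 = c0;
  f.nodes[id].c1 = c1;
  return id;
}

struct QueryHit {
  int idx;
  double sim;
};

struct QueryStats {
  long nodes_visited = 0;
  long comparisons = 0;
};

// Exact threshold query; appends hits (0-based record indices).
void run_query(const Forest &f, const std::vector<int> &qpos,
               const std::vector<char> &qbit, double threshold,
               std::vector<QueryHit> &hits, QueryStats &stats) {
  const int a = static_cast<int>(qpos.size());
  if (a == 0) return;  // all-zero query matches nothing at threshold > 0
  struct Frame {
    int node, a_def, b_def;
  };
  std::vector<Frame> stack;
  for (const auto &bin : f.bins) {
    const int b = bin.first;
    if (b == 0) continue;
    const double pop_bound =
        static_cast<double>(std::min(a, b)) / static_cast<double>(std::max(a, b));
    if (pop_bound < threshold) continue;
    stack.clear();
    stack.push_back(Frame{bin.second, 0, 0});
    while (!stack.empty()) {
      const Frame fr = stack.back();
      stack.pop_back();
      stats.nodes_visited++;
      const int i_max = std::min(a - fr.a_def, b - fr.b_def);
      if (i_max <= 0) continue;
      const double bound =
          static_cast<double>(i_max) / static_cast<double>(a + b - i_max);
      if (bound < threshold) continue;
      const Node &nd = f.nodes[fr.node];
      if (nd.split_bit < 0) {
        for (int m : nd.members) {
          stats.comparisons++;
          int inter = 0;
          for (int p : f.fps[m]) inter += qbit[p];
          const int uni = a + b - inter;
          const double sim =
              uni == 0 ? 0.0
                       : static_cast<double>(inter) / static_cast<double>(uni);
          if (sim >= threshold) hits.push_back(QueryHit{m, sim});
        }
      } else {
        const bool qset = qbit[nd.split_bit] != 0;
        // child 0: members have the bit unset; a set query bit is unmatchable
        stack.push_back(Frame{nd.c0, fr.a_def + (qset ? 1 : 0), fr.b_def});
        // child 1: members have the bit set; an unset query bit costs b
        stack.push_back(Frame{nd.c1, fr.a_def, fr.b_def + (qset ? 0 : 1)});
      }
    }
  }
}

Forest *get_forest(SEXP ptr) {
  Rcpp::XPtr<Forest> xp(ptr);
  if (!xp) stop("invalid multibit tree pointer");
  return xp.get();
}

std::vector<int> as_positions(SEXP v, int l) {
  IntegerVector iv(v);
  std::vector<int> out(iv.begin(), iv.end());
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  if (!out.empty() && (out.front() < 0 || out.back() >= l))
    stop("bit position out of range [0, l)");
  return out;
}

}  // namespace

// [[Rcpp::export]]
SEXP mbt_build(List positions, int l, int leaf_limit) {
  if (l < 1) stop("l must be >= 1");
  if (leaf_limit < 1) stop("leaf_limit must be >= 1");
  Forest *f = new Forest();
  f->l = l;
  f->leaf_limit = leaf_limit;
  f->n = positions.size();
  f->fps.resize(f->n);
  f->pop.resize(f->n);
  std::map<int, std::vector<int>> by_pop;
  for (int i = 0; i < f->n; ++i) {
    f->fps[i] = as_positions(positions[i], l);
    f->pop[i] = static_cast<int>(f->fps[i].size());
    by_pop[f->pop[i]].push_back(i);
  }
  std::vector<int> cnt(l, 0);
  for (auto &kv : by_pop) {
    const int root = build_node(*f, std::move(kv.second), cnt);
    f->bins.push_back({kv.first, root});
  }
  Rcpp::XPtr<Forest> xp(f, true);
  return xp;
}

// [[Rcpp::export]]
List mbt_info(SEXP ptr) {
  Forest *f = get_forest(ptr);
  return List::create(_["n"] = f->n, _["l"] = f->l,
                      _["leaf_limit"] = f->leaf_limit,
                      _["n_bins"] = static_cast<int>(f->bins.size()),
                      _["n_nodes"] = static_cast<int>(f->nodes.size()));
}

// Flat description of the forest for structural audits: one row per node.
// match_bit/match_value describe the edge from the parent (NA at roots).
// [[Rcpp::export]]
List mbt_describe(SEXP ptr) {
  Forest *f = get_forest(ptr);
  const int nn = static_cast<int>(f->nodes.size());
  IntegerVector node(nn), parent(nn), split_bit(nn), c0(nn), c1(nn),
      bin_popcount(nn), match_bit(nn), match_value(nn);
  List members(nn);
  std::fill(parent.begin(), parent.end(), NA_INTEGER);
  std::fill(match_bit.begin(), match_bit.end(), NA_INTEGER);
  std::fill(match_value.begin(), match_value.end(), NA_INTEGER);
  std::vector<int> binpop(nn, NA_INTEGER);
  for (const auto &bin : f->bins) {
    // propagate bin popcount down from each root
    std::vector<int> st{bin.second};
    while (!st.empty()) {
      int id = st.back();
      st.pop_back();
      binpop[id] = bin.first;
      const Node &nd = f->nodes[id];
      if (nd.split_bit >= 0) {
        st.push_back(nd.c0);
        st.push_back(nd.c1);
      }
    }
  }
  for (int id = 0; id < nn; ++id) {
    const Node &nd = f->nodes[id];
    node[id] = id + 1;
    bin_popcount[id] = binpop[id];
    split_bit[id] = nd.split_bit < 0 ? NA_INTEGER : nd.split_bit;
    c0[id] = nd.split_bit < 0 ? NA_INTEGER : nd.c0 + 1;
    c1[id] = nd.split_bit < 0 ? NA_INTEGER : nd.c1 + 1;
    if (nd.split_bit >= 0) {
      parent[nd.c0] = id + 1;
      parent[nd.c1] = id + 1;
      match_bit[nd.c0] = nd.split_bit;
      match_value[nd.c0] = 0;
      match_bit[nd.c1] = nd.split_bit;
      match_value[nd.c1] = 1;
    }
    IntegerVector mem(nd.members.size());
    for (size_t k = 0; k < nd.members.size(); ++k) mem[k] = nd.members[k] + 1;
    members[id] = mem;
  }
  return List::create(_["node"] = node, _["parent"] = parent,
                      _["bin_popcount"] = bin_popcount,
                      _["split_bit"] = split_bit, _["child0"] = c0,
                      _["child1"] = c1, _["match_bit"] = match_bit,
                      _["match_value"] = match_value,
                      _["members"] = members);
}

// [[Rcpp::export]]
List mbt_query(SEXP ptr, IntegerVector qpos, double threshold) {
  Forest *f = get_forest(ptr);
  std::vector<int> q = as_positions(qpos, f->l);
  std::vector<char> qbit(f->l, 0);
  for (int p : q) qbit[p] = 1;
  std::vector<QueryHit> hits;
  QueryStats stats;
  run_query(*f, q, qbit, threshold, hits, stats);
  const int nh = static_cast<int>(hits.size());
  IntegerVector idx(nh);
  NumericVector sim(nh);
  for (int i = 0; i < nh; ++i) {
    idx[i] = hits[i].idx + 1;
    sim[i] = hits[i].sim;
  }
  return List::create(_["idx"] = idx, _["sim"] = sim,
                      _["nodes_visited"] = static_cast<double>(stats.nodes_visited),
                      _["comparisons"] = static_cast<double>(stats.comparisons));
}

// Self de-duplication: query every indexed record, keep hits j > i.
// [[Rcpp::export]]
List mbt_query_self(SEXP ptr, double threshold) {
  Forest *f = get_forest(ptr);
  std::vector<int> ia, ja;
  std::vector<double> sa;
  QueryStats stats;
  std::vector<char> qbit(f->l, 0);
  std::vector<QueryHit> hits;
  for (int i = 0; i < f->n; ++i) {
    for (int p : f->fps[i]) qbit[p] = 1;
    hits.clear();
    run_query(*f, f->fps[i], qbit, threshold, hits, stats);
    for (const QueryHit &h : hits) {
      if (h.idx > i) {
        ia.push_back(i + 1);
        ja.push_back(h.idx + 1);
        sa.push_back(h.sim);
      }
    }
    for (int p : f->fps[i]) qbit[p] = 0;
  }
  return List::create(_["i"] = wrap(ia), _["j"] = wrap(ja),
                      _["sim"] = wrap(sa),
                      _["nodes_visited"] = static_cast<double>(stats.nodes_visited),
                      _["comparisons"] = static_cast<double>(stats.comparisons));
}

// Two-file linkage: query each external record against the indexed forest.
// [[Rcpp::export]]
List mbt_query_batch(SEXP ptr, List qpositions, double threshold) {
  Forest *f = get_forest(ptr);
  std::vector<int> qi, ji;
  std::vector<double> sa;
  QueryStats stats;
  std::vector<char> qbit(f->l, 0);
  std::vector<QueryHit> hits;
  const int nq = qpositions.size();
  for (int q = 0; q < nq; ++q) {
    std::vector<int> qp = as_positions(qpositions[q], f->l);
    for (int p : qp) qbit[p] = 1;
    hits.clear();
    run_query(*f, qp, qbit, threshold, hits, stats);
    for (const QueryHit &h : hits) {
      qi.push_back(q + 1);
      ji.push_back(h.idx + 1);
      sa.push_back(h.sim);
    }
    for (int p : qp) qbit[p] = 0;
  }
  return List::create(_["qi"] = wrap(qi), _["j"] = wrap(ji),
                      _["sim"] = wrap(sa),
                      _["nodes_visited"] = static_cast<double>(stats.nodes_visited),
                      _["comparisons"] = static_cast<double>(stats.comparisons));
}

// Split-half bit choice on an arbitrary member set, excluding `used`
// (0-based) positions; exposed for testing against a brute-force oracle.
// [[Rcpp::export]]
int mbt_choose_split_bit(List positions, int l, IntegerVector used) {
  std::vector<std::vector<int>> fps(positions.size());
  std::vector<int> members(positions.size());
  for (int i = 0; i < positions.size(); ++i) {
    fps[i] = as_positions(positions[i], l);
    members[i] = i;
  }
  if (members.empty()) stop("members must be non-empty");
  std::vector<char> excl(l, 0);
  for (int u : used) {
    if (u < 0 || u >= l) stop("used position out of range");
    excl[u] = 1;
  }
  std::vector<int> cnt(l, 0);
  const int n = static_cast<int>(members.size());
  for (int m : members)
    for (int p : fps[m]) cnt[p]++;
  int best = -1;
  long best_bal = -1;
  for (int p = 0; p < l; ++p) {
    if (excl[p]) continue;
    const int c = cnt[p];
    if (c == 0 || c == n) continue;
    const long bal = std::labs(2L * c - n);
    if (best < 0 || bal < best_bal) {
      best = p;
      best_bal = bal;
    }
  }
  return best;  // -1 => NONE
}
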