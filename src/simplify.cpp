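// Tree sequence simplification by backwards-in-time propagation of
// ancestral segments.
//
// The state is one lineage per input node: a sorted chain of disjoint
// ancestral segments (l, r, u) meaning that output node u inherits the
// genomic interval [l, r) through this input node.  Sample lineages start
// as a single segment (0, L, sample index).  Input parents are processed in
// chronological order (the canonical edge sort guarantees grouping and
// ordering); for each parent the overlapping portions of its children's
// chains are merged with a sweep over a min-heap of segments:
//
//   * where exactly one segment covers a point, it passes through unchanged
//     (unary ancestry is elided);
//   * where two or more overlap, a coalescence is recorded: an output node
//     for the parent is allocated on first use (so all coalescing segments
//     in one parent share the same output node), one output edge is emitted
//     per overlapping segment, and the merged segment carries the parent's
//     output node upwards.
//
// A parent that is itself a sample contributes its own chain to the merge,
// so children attach to the sample node wherever they share material with
// it, and samples are retained even where unary.  Mutations are mapped at
// the end: a mutation on input node u at position x survives iff u's final
// chain covers x, and is re-assigned to the output node found there.
//
// Work is linear in input edges plus segments processed; the `ops` counter
// reports the number of basic segment operations for empirical scaling
// checks.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Seg {
  double l, r;
  int node;
};

struct SegCmp {
  // min-heap on left endpoint; ties broken by node then right for
  // deterministic pop order
  bool operator()(const Seg& a, const Seg& b) const {
    if (a.l != b.l) return a.l > b.l;
    if (a.node != b.node) return a.node > b.node;
    return a.r > b.r;
  }
};

struct OutEdge {
  double l, r;
  int parent, child;
};

}  // namespace

// [[Rcpp::export(name = ".simplify_cpp")]]
List simplify_cpp(NumericVector node_time,
                  NumericVector edge_left,
                  NumericVector edge_right,
                  IntegerVector edge_parent,
                  IntegerVector edge_child,
                  NumericVector mut_position,
                  IntegerVector mut_node,
                  IntegerVector samples,
                  double sequence_length) {
  const int M = node_time.size();
  const int E = edge_left.size();
  const int n = samples.size();

  std::vector<std::vector<Seg> > chains(M);
  std::vector<int> node_map(M, -1);
  std::vector<int> out_node_input;  // input id per output node
  out_node_input.reserve(2 * n);

  for (int i = 0; i < n; ++i) {
    int s = samples[i];
    node_map[s] = i;
    out_node_input.push_back(s);
    Seg seg;
    seg.l = 0.0;
    seg.r = sequence_length;
    seg.node = i;
    chains[s].push_back(seg);
  }

  std::vector<OutEdge> out_edges;
  out_edges.reserve(E);
  long long ops = 0;

  std::vector<bool> is_sample_in(M, false);
  for (int i = 0; i < n; ++i) is_sample_in[samples[i]] = true;

  int e = 0;
  std::priority_queue<Seg, std::vector<Seg>, SegCmp> Q;
  std::vector<Seg> X;
  while (e < E) {
    const int p = edge_parent[e];
    // gather overlapping child material for all edges of this parent
    while (e < E && edge_parent[e] == p) {
      const double el = edge_left[e];
      const double er = edge_right[e];
      const std::vector<Seg>& ch = chains[edge_child[e]];
      for (size_t k = 0; k < ch.size(); ++k) {
        ++ops;
        if (ch[k].r > el && ch[k].l < er) {
          Seg seg;
          seg.l = std::max(ch[k].l, el);
          seg.r = std::min(ch[k].r, er);
          seg.node = ch[k].node;
          Q.push(seg);
        }
      }
      ++e;
    }
    if (is_sample_in[p]) {
      // the parent's own material takes part in the merge
      const std::vector<Seg>& ch = chains[p];
      for (size_t k = 0; k < ch.size(); ++k) Q.push(ch[k]);
    }
    std::vector<Seg> merged;
    while (!Q.empty()) {
      const double l = Q.top().l;
      X.clear();
      while (!Q.empty() && Q.top().l == l) {
        X.push_back(Q.top());
        Q.pop();
        ++ops;
      }
      const double next_l = Q.empty() ? INFINITY : Q.top().l;
      Seg alpha;
      if (X.size() == 1) {
        alpha = X[0];
        if (next_l < alpha.r) {
          Seg rest;
          rest.l = next_l;
          rest.r = alpha.r;
          rest.node = alpha.node;
          Q.push(rest);
          alpha.r = next_l;
        }
      } else {
        if (node_map[p] == -1) {
          node_map[p] = (int)out_node_input.size();
          out_node_input.push_back(p);
        }
        const int u = node_map[p];
        double r = next_l;
        for (size_t k = 0; k < X.size(); ++k) r = std::min(r, X[k].r);
        alpha.l = l;
        alpha.r = r;
        alpha.node = u;
        for (size_t k = 0; k < X.size(); ++k) {
          if (X[k].node != u) {
            OutEdge oe;
            oe.l = l;
            oe.r = r;
            oe.parent = u;
            oe.child = X[k].node;
            out_edges.push_back(oe);
            ++ops;
          }
          if (X[k].r > r) {
            Seg rest;
            rest.l = r;
            rest.r = X[k].r;
            rest.node = X[k].node;
            Q.push(rest);
          }
        }
      }
      if (!merged.empty() && merged.back().node == alpha.node &&
          merged.back().r == alpha.l) {
        merged.back().r = alpha.r;  // defragment abutting same-colour pieces
      } else {
        merged.push_back(alpha);
      }
    }
    chains[p].swap(merged);
  }

  // canonical sort of output edges; output node ids are allocated in
  // processing order, i.e. nondecreasing time with input-id tie-break, but
  // sample parents may be young, so sort on output node time first
  const int out_n = (int)out_node_input.size();
  std::vector<double> out_time(out_n);
  for (int i = 0; i < out_n; ++i) out_time[i] = node_time[out_node_input[i]];
  std::sort(out_edges.begin(), out_edges.end(),
            [&](const OutEdge& a, const OutEdge& b) {
              if (out_time[a.parent] != out_time[b.parent])
                return out_time[a.parent] < out_time[b.parent];
              if (a.parent != b.parent) return a.parent < b.parent;
              if (a.child != b.child) return a.child < b.child;
              return a.l < b.l;
            });
  // squash adjacent same-(parent, child) edges
  std::vector<OutEdge> squashed;
  squashed.reserve(out_edges.size());
  for (size_t i = 0; i < out_edges.size(); ++i) {
    if (!squashed.empty() && squashed.back().parent == out_edges[i].parent &&
        squashed.back().child == out_edges[i].child &&
        squashed.back().r == out_edges[i].l) {
      squashed.back().r = out_edges[i].r;
    } else {
      squashed.push_back(out_edges[i]);
    }
  }

  // map mutations through the final chains
  const int nmut = mut_position.size();
  std::vector<int> keep;
  std::vector<int> mapped;
  for (int j = 0; j < nmut; ++j) {
    const double x = mut_position[j];
    const std::vector<Seg>& ch = chains[mut_node[j]];
    for (size_t k = 0; k < ch.size(); ++k) {
      if (ch[k].l <= x && x < ch[k].r) {
        keep.push_back(j);
        mapped.push_back(ch[k].node);
        break;
      }
      if (ch[k].l > x) break;
    }
  }

  const int ne = (int)squashed.size();
  NumericVector rl(ne), rr(ne);
  IntegerVector rp(ne), rc(ne);
  for (int i = 0; i < ne; ++i) {
    rl[i] = squashed[i].l;
    rr[i] = squashed[i].r;
    rp[i] = squashed[i].parent;
    rc[i] = squashed[i].child;
  }
  return List::create(
      _["node_map"] = IntegerVector(node_map.begin(), node_map.end()),
      _["out_node_input"] = IntegerVector(out_node_input.begin(),
                                          out_node_input.end()),
      _["edge_left"] = rl, _["edge_right"] = rr, _["edge_parent"] = rp,
      _["edge_child"] = rc,
      _["mut_keep"] = IntegerVector(keep.begin(), keep.end()),
      _["mut_out_node"] = IntegerVector(mapped.begin(), mapped.end()),
      _["ops"] = (double)ops);
}
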