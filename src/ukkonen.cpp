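// Suffix tree construction (Ukkonen's online algorithm) and canonical
// annotation pass.  The tree is returned to R as flat integer vectors over
// node ids 1..N, where the canonical id of a node is its preorder rank in a
// DFS that visits children in ascending byte order of the first edge
// character (the sentinel '$' sorts before A-Z, so it comes first).
//
// All invariants needed downstream are computed here in one pass:
// string depth, node depth (nodes on the root path, root = 1), suffix
// links remapped to canonical ids, leaf suffix indexes, DFS subtree
// intervals, leaf ranges in DFS leaf order, and CSR child adjacency.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>

using namespace Rcpp;

namespace {

const int INF = std::numeric_limits<int>::max();

struct UNode {
  int start;   // edge label T[start, end) on the edge entering this node
  int end;     // INF for leaves until construction finishes
  int link;    // suffix link (0 = root / unset)
  std::map<unsigned char, int> next;
  UNode(int s, int e) : start(s), end(e), link(0) {}
};

class Builder {
public:
  std::vector<UNode> t;
  const unsigned char* text;
  int n;
  int root, need_link, remainder, active_node, active_e, active_len, pos;

  Builder(const unsigned char* txt, int len) : text(txt), n(len) {
    t.reserve(2 * static_cast<size_t>(len) + 4);
    root = new_node(-1, -1);
    need_link = 0;
    remainder = 0;
    active_node = root;
    active_e = 0;
    active_len = 0;
    pos = -1;
    for (int i = 0; i < n; ++i) extend(i);
    if (remainder != 0) stop("suffix tree construction left implicit suffixes; text must end with a unique sentinel");
  }

  int new_node(int s, int e) {
    t.emplace_back(s, e);
    return static_cast<int>(t.size()) - 1;
  }
  void add_link(int node) {
    if (need_link > 0) t[need_link].link = node;
    need_link = node;
  }
  int edge_length(int v) const {
    return std::min(t[v].end == INF ? pos + 1 : t[v].end, pos + 1) - t[v].start;
  }
  bool walk_down(int v) {
    int el = edge_length(v);
    if (active_len >= el) {
      active_e += el;
      active_len -= el;
      active_node = v;
      return true;
    }
    return false;
  }
  void extend(int i) {
    pos = i;
    need_link = 0;
    ++remainder;
    unsigned char c = text[pos];
    while (remainder > 0) {
      if (active_len == 0) active_e = pos;
      std::map<unsigned char, int>::iterator it = t[active_node].next.find(text[active_e]);
      if (it == t[active_node].next.end()) {
        int leaf = new_node(pos, INF);
        t[active_node].next[text[active_e]] = leaf;
        add_link(active_node);
      } else {
        int nxt = it->second;
        if (walk_down(nxt)) continue;
        if (text[t[nxt].start + active_len] == c) {
          ++active_len;
          add_link(active_node);
          break;
        }
        int split = new_node(t[nxt].start, t[nxt].start + active_len);
        t[active_node].next[text[active_e]] = split;
        int leaf = new_node(pos, INF);
        t[split].next[c] = leaf;
        t[nxt].start += active_len;
        t[split].next[text[t[nxt].start]] = nxt;
        add_link(split);
      }
      --remainder;
      if (active_node == root && active_len > 0) {
        --active_len;
        active_e = pos - remainder + 1;
      } else {
        active_node = t[active_node].link > 0 ? t[active_node].link : root;
      }
    }
  }
};

struct Frame {
  int old_id;
  int parent_new;
  int sdepth;   // string depth at this node
  int ndepth;   // nodes on root path including this one
};

} // namespace

// [[Rcpp::export(name = ".build_suffix_tree_cpp")]]
List build_suffix_tree_cpp(RawVector txt) {
  const int n = txt.size();
  if (n < 2) stop("text must have length >= 2 (content plus sentinel)");
  const unsigned char* text = RAW(txt);

  Builder b(text, n);
  const int total = static_cast<int>(b.t.size());

  // Canonical preorder renumbering with an explicit stack; children of the
  // internal std::map are already in ascending byte order.
  std::vector<int> new_id(total, 0);
  std::vector<int> parent(total + 1, NA_INTEGER);
  std::vector<int> edge_start(total + 1, NA_INTEGER);
  std::vector<int> edge_end(total + 1, NA_INTEGER);
  std::vector<int> sdepth(total + 1, 0);
  std::vector<int> ndepth(total + 1, 0);
  std::vector<int> is_leaf(total + 1, 0);
  std::vector<int> dfs_out(total + 1, 0);
  std::vector<int> suffix_index(total + 1, NA_INTEGER);
  std::vector<int> first_leaf(total + 1, 0);
  std::vector<int> last_leaf(total + 1, 0);
  std::vector<int> leaf_count(total + 1, 0);
  std::vector<int> path_first_char(total + 1, NA_INTEGER);
  std::vector<int> old_of_new(total + 1, 0);

  std::vector<Frame> stack;
  stack.push_back(Frame{b.root, NA_INTEGER, 0, 1});
  int next_new = 0;
  int leaf_rank = 0;
  // post-processing order: record nodes in preorder, fix subtree stats after
  std::vector<int> order;
  order.reserve(total);

  while (!stack.empty()) {
    Frame f = stack.back();
    stack.pop_back();
    int id = ++next_new;
    new_id[f.old_id] = id;
    old_of_new[id] = f.old_id;
    order.push_back(id);
    UNode& nd = b.t[f.old_id];
    parent[id] = f.parent_new;
    sdepth[id] = f.sdepth;
    ndepth[id] = f.ndepth;
    if (nd.start >= 0) {
      edge_start[id] = nd.start;
      edge_end[id] = (nd.end == INF) ? n : nd.end;
      if (f.parent_new == NA_INTEGER) stop("internal error: non-root without parent");
      int pfc = path_first_char[f.parent_new];
      path_first_char[id] = (pfc == NA_INTEGER) ? static_cast<int>(text[nd.start]) : pfc;
    }
    if (nd.next.empty()) {
      is_leaf[id] = 1;
      suffix_index[id] = n - f.sdepth;
      first_leaf[id] = last_leaf[id] = ++leaf_rank;
    } else {
      // push children in reverse so ascending-char child is popped first
      for (std::map<unsigned char, int>::reverse_iterator it = nd.next.rbegin();
           it != nd.next.rend(); ++it) {
        UNode& ch = b.t[it->second];
        int el = ((ch.end == INF) ? n : ch.end) - ch.start;
        stack.push_back(Frame{it->second, id, f.sdepth + el, f.ndepth + 1});
      }
    }
  }
  if (next_new != total) stop("internal error: DFS did not reach every node");

  // Subtree aggregates in reverse preorder (children have larger ids).
  for (int k = total - 1; k >= 0; --k) {
    int id = order[k];
    dfs_out[id] = id;
    if (!is_leaf[id]) {
      first_leaf[id] = INF;
      last_leaf[id] = 0;
    }
    // aggregate children: scan done below via parent accumulation
  }
  for (int id = total; id >= 2; --id) {
    int p = parent[id];
    if (dfs_out[id] > dfs_out[p]) dfs_out[p] = dfs_out[id];
    leaf_count[p] += is_leaf[id] ? 1 : leaf_count[id];
    int fl = is_leaf[id] ? first_leaf[id] : first_leaf[id];
    int ll = last_leaf[id];
    if (fl != 0 && fl < first_leaf[p]) first_leaf[p] = fl;
    if (ll > last_leaf[p]) last_leaf[p] = ll;
  }
  for (int id = 1; id <= total; ++id) {
    if (is_leaf[id]) leaf_count[id] = 1;
    if (first_leaf[id] == INF) stop("internal error: internal node without leaves");
  }

  // Suffix links remapped to canonical ids (internal non-root nodes only).
  std::vector<int> slink(total + 1, NA_INTEGER);
  int height = 1;
  for (int id = 2; id <= total; ++id) {
    if (is_leaf[id]) continue;
    if (ndepth[id] > height) height = ndepth[id];
    int old_target = b.t[old_of_new[id]].link;
    int tgt = new_id[old_target]; // link 0 => root, which renumbers to 1
    slink[id] = tgt;
    if (sdepth[tgt] != sdepth[id] - 1)
      stop("suffix link depth invariant violated during construction (node %d)", id);
  }

  // Leaf bookkeeping: DFS leaf order and lookup by suffix index.
  std::vector<int> leaves_by_rank(leaf_rank, 0);
  std::vector<int> leaf_id_by_suffix(n, 0);
  {
    int r = 0;
    for (int k = 0; k < total; ++k) {
      int id = order[k];
      if (is_leaf[id]) {
        leaves_by_rank[r++] = suffix_index[id];
        leaf_id_by_suffix[suffix_index[id]] = id;
      }
    }
  }
  if (leaf_rank != n) stop("leaf count %d does not match text length %d", leaf_rank, n);

  // CSR children (already canonical order: child ids ascending = char order).
  std::vector<int> children_ptr(total + 2, 0);
  for (int id = 2; id <= total; ++id) children_ptr[parent[id] + 1]++;
  for (int i = 1; i <= total + 1; ++i) children_ptr[i] += children_ptr[i - 1];
  std::vector<int> children_ids(total - 1, 0);
  std::vector<int> fill(children_ptr.begin(), children_ptr.end());
  for (int id = 2; id <= total; ++id) children_ids[fill[parent[id]]++] = id;
  std::vector<int> children_char(total - 1, 0);
  for (int i = 0; i < total - 1; ++i)
    children_char[i] = static_cast<int>(text[edge_start[children_ids[i]]]);

  auto iv = [](std::vector<int>& v, int from) {
    return IntegerVector(v.begin() + from, v.end());
  };
  List out = List::create(
    _["n_nodes"] = total,
    _["height"] = height,
    _["parent"] = iv(parent, 1),
    _["edge_start"] = iv(edge_start, 1),
    _["edge_end"] = iv(edge_end, 1),
    _["depth"] = iv(sdepth, 1),
    _["node_depth"] = iv(ndepth, 1),
    _["is_leaf"] = iv(is_leaf, 1),
    _["suffix_link"] = iv(slink, 1),
    _["suffix_index"] = iv(suffix_index, 1),
    _["dfs_out"] = iv(dfs_out, 1),
    _["leaf_count"] = iv(leaf_count, 1),
    _["first_leaf"] = iv(first_leaf, 1),
    _["last_leaf"] = iv(last_leaf, 1),
    _["path_first_char"] = iv(path_first_char, 1),
    _["leaves_by_rank"] = IntegerVector(leaves_by_rank.begin(), leaves_by_rank.end()),
    _["leaf_id_by_suffix"] = IntegerVector(leaf_id_by_suffix.begin(), leaf_id_by_suffix.end())
  );
  out.push_back(IntegerVector(children_ptr.begin(), children_ptr.end()), "children_ptr");
  out.push_back(IntegerVector(children_ids.begin(), children_ids.end()), "children_ids");
  out.push_back(IntegerVector(children_char.begin(), children_char.end()), "children_char");
  return out;
}
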