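// Motif core: connected k-subgraph enumeration (ESU), typed-motif validity,
// canonical labeling of vertex- and edge-labeled multigraphs, census counting,
// and tentative-edge candidate search. Node/edge type codes arriving from R
// are 0-based and assigned in sorted label order, which makes the canonical
// minimisation consistent across graphs with different type vocabularies.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <set>
#include <algorithm>
#include <functional>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct TGraph {
  int n;
  size_t W;                                          // 64-bit words per bitmap row
  std::vector<int> ntype;
  std::vector<std::vector<int>> adj;                 // distinct neighbours, ascending
  std::vector<uint64_t> amat;                        // n x W adjacency bitmap
  std::unordered_map<int64_t, std::vector<int>> pet; // unordered pair -> sorted etype codes

  int64_t pkey(int a, int b) const {
    if (a > b) std::swap(a, b);
    return static_cast<int64_t>(a) * n + b;
  }
  bool adjq(int a, int b) const {
    return (amat[static_cast<size_t>(a) * W + (b >> 6)] >> (b & 63)) & 1u;
  }
  void link(int a, int b) {
    amat[static_cast<size_t>(a) * W + (b >> 6)] |= static_cast<uint64_t>(1) << (b & 63);
    amat[static_cast<size_t>(b) * W + (a >> 6)] |= static_cast<uint64_t>(1) << (a & 63);
  }
  void unlink(int a, int b) {
    amat[static_cast<size_t>(a) * W + (b >> 6)] &= ~(static_cast<uint64_t>(1) << (b & 63));
    amat[static_cast<size_t>(b) * W + (a >> 6)] &= ~(static_cast<uint64_t>(1) << (a & 63));
  }
};

TGraph build_graph(int n, const IntegerVector& ntype, const IntegerVector& efrom,
                   const IntegerVector& eto, const IntegerVector& etype) {
  if (n > 50000)
    stop("graphs larger than 50000 nodes are not supported by the motif core");
  TGraph g;
  g.n = n;
  g.W = static_cast<size_t>((n + 63) / 64);
  g.ntype.assign(ntype.begin(), ntype.end());
  g.adj.assign(n, {});
  g.amat.assign(static_cast<size_t>(n) * g.W, 0);
  for (R_xlen_t i = 0; i < efrom.size(); ++i) {
    int a = efrom[i], b = eto[i];
    auto& v = g.pet[g.pkey(a, b)];
    if (v.empty()) {
      g.adj[a].push_back(b);
      g.adj[b].push_back(a);
      g.link(a, b);
    }
    v.push_back(etype[i]);
  }
  for (auto& kv : g.pet) std::sort(kv.second.begin(), kv.second.end());
  for (auto& v : g.adj) std::sort(v.begin(), v.end());
  return g;
}

// k >= 3, every node with >= 2 distinct neighbours inside the induced
// subgraph, and >= min_types distinct node types.
bool valid_tnm(const TGraph& g, const std::vector<int>& S, int min_types) {
  const int k = static_cast<int>(S.size());
  if (k < 3) return false;
  for (int i = 0; i < k; ++i) {
    int deg = 0;
    for (int j = 0; j < k; ++j)
      if (j != i && g.adjq(S[i], S[j])) ++deg;
    if (deg < 2) return false;
  }
  int tmask = 0, tcount = 0;  // type codes can exceed 31 in principle; fall back
  if (*std::max_element(g.ntype.begin(), g.ntype.end()) < 31) {
    for (int v : S) tmask |= (1 << g.ntype[v]);
    tcount = __builtin_popcount(tmask);
  } else {
    std::vector<int> t;
    for (int v : S) t.push_back(g.ntype[v]);
    std::sort(t.begin(), t.end());
    tcount = static_cast<int>(std::unique(t.begin(), t.end()) - t.begin());
  }
  return tcount >= min_types;
}

// Lexicographically minimal encoding over all node permutations. The code is
// the type sequence followed by, for each position pair (a<b) in fixed order,
// the parallel-edge count then the sorted edge-type codes. First-difference
// positions always align on the same field category, so flat comparison is
// a well-defined total order on labelings.
std::vector<int> canon_code(const TGraph& g, const std::vector<int>& S) {
  const int k = static_cast<int>(S.size());
  std::vector<std::vector<const std::vector<int>*>> lp(k,
      std::vector<const std::vector<int>*>(k, nullptr));
  static const std::vector<int> kEmpty;
  for (int i = 0; i < k; ++i)
    for (int j = i + 1; j < k; ++j) {
      auto it = g.pet.find(g.pkey(S[i], S[j]));
      const std::vector<int>* p = (it == g.pet.end()) ? &kEmpty : &it->second;
      lp[i][j] = lp[j][i] = p;
    }
  std::vector<int> perm(k);
  for (int i = 0; i < k; ++i) perm[i] = i;
  std::vector<int> best, code;
  bool first = true;
  do {
    code.clear();
    for (int pos = 0; pos < k; ++pos) code.push_back(g.ntype[S[perm[pos]]]);
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b) {
        const auto& ets = *lp[perm[a]][perm[b]];
        code.push_back(static_cast<int>(ets.size()));
        for (int e : ets) code.push_back(e);
      }
    if (first || code < best) {
      best = code;
      first = false;
    }
  } while (std::next_permutation(perm.begin(), perm.end()));
  return best;
}

std::string code_to_key(const std::vector<int>& code, int k,
                        const std::vector<std::string>& nlab,
                        const std::vector<std::string>& elab) {
  std::string s;
  for (int i = 0; i < k; ++i) {
    if (i) s += ",";
    s += nlab[code[i]];
  }
  size_t p = k;
  for (int a = 0; a < k; ++a)
    for (int b = a + 1; b < k; ++b) {
      int c = code[p++];
      for (int e = 0; e < c; ++e) {
        s += "|";
        s += std::to_string(a + 1) + "-" + std::to_string(b + 1) + ":" + elab[code[p]];
        ++p;
      }
    }
  return s;
}

std::string set_key(const TGraph& g, const std::vector<int>& S,
                    const std::vector<std::string>& nlab,
                    const std::vector<std::string>& elab) {
  return code_to_key(canon_code(g, S), static_cast<int>(S.size()), nlab, elab);
}

// Wernicke's ESU: emits every connected k-node set exactly once.
struct ESU {
  const TGraph& g;
  int k, root;
  std::vector<int> S;
  std::vector<char> nbh;  // marks Vsub + N(Vsub) during a root's expansion
  const std::function<void(const std::vector<int>&)>& emit;

  ESU(const TGraph& gg, int kk, const std::function<void(const std::vector<int>&)>& em)
      : g(gg), k(kk), root(0), nbh(gg.n, 0), emit(em) {}

  void run() {
    if (k == 1) {
      for (int v = 0; v < g.n; ++v) {
        S.assign(1, v);
        emit(S);
      }
      return;
    }
    for (int v = 0; v < g.n; ++v) {
      root = v;
      std::fill(nbh.begin(), nbh.end(), 0);
      nbh[v] = 1;
      std::vector<int> ext;
      for (int u : g.adj[v]) {
        nbh[u] = 1;
        if (u > v) ext.push_back(u);
      }
      S.assign(1, v);
      extend(ext);
    }
  }

  void extend(std::vector<int>& ext) {
    while (!ext.empty()) {
      int w = ext.back();
      ext.pop_back();
      if (static_cast<int>(S.size()) + 1 == k) {
        S.push_back(w);
        emit(S);
        S.pop_back();
        continue;
      }
      std::vector<int> ext2 = ext;
      std::vector<int> marked;
      for (int u : g.adj[w]) {
        if (!nbh[u]) {
          nbh[u] = 1;
          marked.push_back(u);
          if (u > root) ext2.push_back(u);
        }
      }
      S.push_back(w);
      extend(ext2);
      S.pop_back();
      for (int u : marked) nbh[u] = 0;
    }
  }
};

std::vector<std::string> as_strings(const CharacterVector& x) {
  std::vector<std::string> out;
  out.reserve(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out.push_back(as<std::string>(x[i]));
  return out;
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_enumerate_ksets(int n, IntegerVector ntype, IntegerVector efrom,
                                  IntegerVector eto, IntegerVector etype, int k) {
  TGraph g = build_graph(n, ntype, efrom, eto, etype);
  std::vector<int> rows;
  std::function<void(const std::vector<int>&)> emit = [&](const std::vector<int>& S) {
    std::vector<int> s = S;
    std::sort(s.begin(), s.end());
    rows.insert(rows.end(), s.begin(), s.end());
  };
  ESU esu(g, k, emit);
  esu.run();
  const int m = static_cast<int>(rows.size()) / k;
  IntegerMatrix out(m, k);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < k; ++j) out(i, j) = rows[static_cast<size_t>(i) * k + j];
  return out;
}

// [[Rcpp::export]]
bool cpp_valid_tnm(int n, IntegerVector ntype, IntegerVector efrom, IntegerVector eto,
                   IntegerVector etype, IntegerVector set0, int min_types) {
  TGraph g = build_graph(n, ntype, efrom, eto, etype);
  std::vector<int> S(set0.begin(), set0.end());
  return valid_tnm(g, S, min_types);
}

// [[Rcpp::export]]
std::string cpp_canonical_key(int n, IntegerVector ntype, IntegerVector efrom,
                              IntegerVector eto, IntegerVector etype, IntegerVector set0,
                              CharacterVector node_labels, CharacterVector edge_labels) {
  TGraph g = build_graph(n, ntype, efrom, eto, etype);
  std::vector<int> S(set0.begin(), set0.end());
  return set_key(g, S, as_strings(node_labels), as_strings(edge_labels));
}

// [[Rcpp::export]]
List cpp_build_census(int n, IntegerVector ntype, IntegerVector efrom, IntegerVector eto,
                      IntegerVector etype, int k, int min_types,
                      CharacterVector node_labels, CharacterVector edge_labels) {
  TGraph g = build_graph(n, ntype, efrom, eto, etype);
  std::vector<std::string> nlab = as_strings(node_labels);
  std::vector<std::string> elab = as_strings(edge_labels);
  std::unordered_map<std::string, double> freq;
  std::function<void(const std::vector<int>&)> emit = [&](const std::vector<int>& S) {
    if (!valid_tnm(g, S, min_types)) return;
    freq[set_key(g, S, nlab, elab)] += 1.0;
  };
  ESU esu(g, k, emit);
  esu.run();
  const R_xlen_t m = static_cast<R_xlen_t>(freq.size());
  CharacterVector keys(m);
  NumericVector counts(m);
  R_xlen_t i = 0;
  for (const auto& kv : freq) {
    keys[i] = kv.first;
    counts[i] = kv.second;
    ++i;
  }
  return List::create(_["key"] = keys, _["count"] = counts);
}

// [[Rcpp::export]]
CharacterVector cpp_canonical_keys(int n, IntegerVector ntype, IntegerVector efrom,
                                   IntegerVector eto, IntegerVector etype,
                                   IntegerMatrix sets0, int min_types,
                                   CharacterVector node_labels,
                                   CharacterVector edge_labels) {
  TGraph g = build_graph(n, ntype, efrom, eto, etype);
  std::vector<std::string> nlab = as_strings(node_labels);
  std::vector<std::string> elab = as_strings(edge_labels);
  const int m = sets0.nrow(), k = sets0.ncol();
  CharacterVector out(m);
  std::vector<int> S(k);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < k; ++j) S[j] = sets0(i, j);
    if (!valid_tnm(g, S, min_types))
      stop("node set %d is not a valid typed network motif instance", i + 1);
    out[i] = set_key(g, S, nlab, elab);
  }
  return out;
}

// For every (drug, candidate edge type) pair whose typed edge to the target is
// absent, tentatively add the edge and collect the canonical keys of all valid
// k-node motif instances that contain both endpoints and exist in the census.
// [[Rcpp::export]]
List cpp_find_candidates(int n, IntegerVector ntype, IntegerVector efrom, IntegerVector eto,
                         IntegerVector etype, int k, int min_types,
                         CharacterVector node_labels, CharacterVector edge_labels,
                         int target0, IntegerVector drugs0, IntegerVector cand_etypes0,
                         CharacterVector census_keys) {
  if (k != 3 && k != 4)
    stop("single-edge motif completion is implemented for k = 3 and k = 4");
  TGraph g = build_graph(n, ntype, efrom, eto, etype);
  std::vector<std::string> nlab = as_strings(node_labels);
  std::vector<std::string> elab = as_strings(edge_labels);
  std::unordered_set<std::string> census;
  for (R_xlen_t i = 0; i < census_keys.size(); ++i)
    census.insert(as<std::string>(census_keys[i]));

  const int s = target0;
  std::vector<int> out_drug, out_et;
  std::vector<std::vector<std::string>> out_ref;
  std::vector<char> base_mark(n, 0);

  for (R_xlen_t di = 0; di < drugs0.size(); ++di) {
    const int d = drugs0[di];
    if (d == s) continue;
    for (R_xlen_t ti = 0; ti < cand_etypes0.size(); ++ti) {
      const int t = cand_etypes0[ti];
      const int64_t pk = g.pkey(d, s);
      {
        auto it = g.pet.find(pk);
        if (it != g.pet.end() &&
            std::binary_search(it->second.begin(), it->second.end(), t))
          continue;  // this typed edge already exists: nothing new to infer
      }
      // tentatively add (d, s, t)
      const bool pair_existed = g.pet.count(pk) > 0;
      {
        auto& vec = g.pet[pk];
        vec.insert(std::lower_bound(vec.begin(), vec.end(), t), t);
        if (!pair_existed) {
          g.adj[d].insert(std::lower_bound(g.adj[d].begin(), g.adj[d].end(), s), s);
          g.adj[s].insert(std::lower_bound(g.adj[s].begin(), g.adj[s].end(), d), d);
          g.link(d, s);
        }
      }

      std::set<std::string> refs;  // ordered -> deterministic output
      auto consider = [&](std::vector<int> S) {
        std::sort(S.begin(), S.end());
        if (!valid_tnm(g, S, min_types)) return;
        std::string key = set_key(g, S, nlab, elab);
        if (census.count(key)) refs.insert(key);
      };

      // base = (N(d) u N(s)) \ {d, s}; every connected k-set containing the
      // tentative edge is {d, s} plus nodes drawn from base or from a base
      // node's neighbourhood.
      std::vector<int> base;
      std::merge(g.adj[d].begin(), g.adj[d].end(), g.adj[s].begin(), g.adj[s].end(),
                 std::back_inserter(base));
      base.erase(std::unique(base.begin(), base.end()), base.end());
      base.erase(std::remove_if(base.begin(), base.end(),
                                [&](int u) { return u == d || u == s; }),
                 base.end());

      if (k == 3) {
        for (int u : base) consider({d, s, u});
      } else {
        for (int u : base) base_mark[u] = 1;
        for (size_t i = 0; i < base.size(); ++i) {
          const int u = base[i];
          for (size_t j = i + 1; j < base.size(); ++j)
            consider({d, s, u, base[j]});
          for (int v : g.adj[u]) {
            if (v == d || v == s || base_mark[v]) continue;
            // v attaches only through base; emit once, from its smallest
            // base neighbour (adj is ascending so the first marked hit wins)
            int mn = -1;
            for (int w : g.adj[v])
              if (base_mark[w]) { mn = w; break; }
            if (mn == u) consider({d, s, u, v});
          }
        }
        for (int u : base) base_mark[u] = 0;
      }

      // roll back the tentative edge
      {
        auto& vec = g.pet[pk];
        vec.erase(std::lower_bound(vec.begin(), vec.end(), t));
        if (vec.empty()) {
          g.pet.erase(pk);
          g.adj[d].erase(std::lower_bound(g.adj[d].begin(), g.adj[d].end(), s));
          g.adj[s].erase(std::lower_bound(g.adj[s].begin(), g.adj[s].end(), d));
          g.unlink(d, s);
        }
      }

      if (!refs.empty()) {
        out_drug.push_back(d);
        out_et.push_back(t);
        out_ref.emplace_back(refs.begin(), refs.end());
      }
    }
  }

  const R_xlen_t m = static_cast<R_xlen_t>(out_drug.size());
  IntegerVector rd(m), rt(m);
  List rr(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    rd[i] = out_drug[i];
    rt[i] = out_et[i];
    rr[i] = wrap(out_ref[i]);
  }
  return List::create(_["drug"] = rd, _["etype"] = rt, _["referenced"] = rr);
}
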