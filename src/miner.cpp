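#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<int> Elem;            // sorted ascending event ids
typedef std::vector<Elem> Sequence;       // ordered elements

// does sorted `big` contain all of sorted `small`?
static bool elem_contains(const Elem& big, const Elem& small) {
  size_t i = 0, j = 0;
  while (i < big.size() && j < small.size()) {
    if (big[i] == small[j]) { ++i; ++j; }
    else if (big[i] < small[j]) ++i;
    else return false;
  }
  return j == small.size();
}

// greedy earliest-match subsequence containment (pattern element must be a
// subset of a sequence element; matched positions strictly increasing)
static bool seq_contains(const Sequence& s, const Sequence& p) {
  size_t pos = 0;
  for (const Elem& pe : p) {
    bool found = false;
    while (pos < s.size()) {
      if (elem_contains(s[pos], pe)) { found = true; ++pos; break; }
      ++pos;
    }
    if (!found) return false;
  }
  return true;
}

static Sequence as_sequence(const List& seq) {
  Sequence s;
  s.reserve(seq.size());
  for (int j = 0; j < seq.size(); ++j) {
    IntegerVector e = seq[j];
    Elem el(e.begin(), e.end());
    std::sort(el.begin(), el.end());
    s.push_back(el);
  }
  return s;
}

struct Miner {
  std::vector<Sequence> db;
  int min_count;
  int max_len;
  std::vector<int> items;                  // frequent single items, sorted
  std::vector<Sequence> out_patterns;
  std::vector<int> out_supports;

  // projection state per containing sequence: (sid, prevpos, pos) where
  // prevpos = earliest element index after matching prefix-minus-last,
  // pos = earliest element index after matching the full prefix
  struct Proj { int sid, prevpos, pos; };

  void record(const Sequence& pat, int sup) {
    out_patterns.push_back(pat);
    out_supports.push_back(sup);
  }

  void expand(Sequence& prefix, const std::vector<Proj>& projs, int n_items) {
    if (max_len > 0 && n_items >= max_len) return;
    // s-extensions: append a new singleton element {x}
    for (int x : items) {
      std::vector<Proj> nproj;
      for (const Proj& pr : projs) {
        const Sequence& s = db[pr.sid];
        for (size_t e = pr.pos; e < s.size(); ++e) {
          if (std::binary_search(s[e].begin(), s[e].end(), x)) {
            nproj.push_back({pr.sid, pr.pos, (int)e + 1});
            break;
          }
        }
      }
      if ((int)nproj.size() >= min_count) {
        prefix.push_back(Elem{x});
        record(prefix, (int)nproj.size());
        expand(prefix, nproj, n_items + 1);
        prefix.pop_back();
      }
    }
    // i-extensions: grow the last element with x > its max item
    if (prefix.empty()) return;
    Elem& last = prefix.back();
    int lo = last.back();
    for (int x : items) {
      if (x <= lo) continue;
      Elem grown = last;
      grown.push_back(x);
      std::vector<Proj> nproj;
      for (const Proj& pr : projs) {
        const Sequence& s = db[pr.sid];
        for (size_t e = pr.prevpos; e < s.size(); ++e) {
          if (elem_contains(s[e], grown)) {
            nproj.push_back({pr.sid, pr.prevpos, (int)e + 1});
            break;
          }
        }
      }
      if ((int)nproj.size() >= min_count) {
        Elem saved = last;
        last = grown;
        record(prefix, (int)nproj.size());
        expand(prefix, nproj, n_items + 1);
        last = saved;
      }
    }
  }

  void run() {
    // frequent items
    std::map<int, int> item_sup;
    for (const Sequence& s : db) {
      std::vector<int> seen;
      for (const Elem& e : s)
        for (int x : e) seen.push_back(x);
      std::sort(seen.begin(), seen.end());
      seen.erase(std::unique(seen.begin(), seen.end()), seen.end());
      for (int x : seen) item_sup[x]++;
    }
    for (auto& kv : item_sup)
      if (kv.second >= min_count) items.push_back(kv.first);
    std::vector<Proj> root;
    for (int i = 0; i < (int)db.size(); ++i) root.push_back({i, 0, 0});
    Sequence prefix;
    expand(prefix, root, 0);
  }
};

// [[Rcpp::export]]
List cpp_mine_frequent(List db, int min_count, int max_len) {
  Miner m;
  m.min_count = min_count;
  m.max_len = max_len;
  m.db.reserve(db.size());
  for (int i = 0; i < db.size(); ++i)
    m.db.push_back(as_sequence(db[i]));
  m.run();
  List pats(m.out_patterns.size());
  for (size_t i = 0; i < m.out_patterns.size(); ++i) {
    List p(m.out_patterns[i].size());
    for (size_t j = 0; j < m.out_patterns[i].size(); ++j)
      p[j] = IntegerVector(m.out_patterns[i][j].begin(),
                           m.out_patterns[i][j].end());
    pats[i] = p;
  }
  return List::create(_["patterns"] = pats,
                      _["supports"] = IntegerVector(m.out_supports.begin(),
                                                    m.out_supports.end()));
}

// closed = no other pattern with equal support strictly contains it
// [[Rcpp::export]]
LogicalVector cpp_filter_closed(List patterns, IntegerVector supports) {
  int n = patterns.size();
  std::vector<Sequence> pats(n);
  std::vector<int> n_items(n, 0);
  for (int i = 0; i < n; ++i) {
    pats[i] = as_sequence(patterns[i]);
    for (const Elem& e : pats[i]) n_items[i] += (int)e.size();
  }
  std::map<int, std::vector<int>> by_sup;
  for (int i = 0; i < n; ++i) by_sup[supports[i]].push_back(i);
  LogicalVector closed(n, true);
  for (auto& kv : by_sup) {
    std::vector<int>& grp = kv.second;
    for (int a : grp) {
      for (int b : grp) {
        if (n_items[b] <= n_items[a]) continue;
        if (seq_contains(pats[b], pats[a])) { closed[a] = false; break; }
      }
    }
  }
  return closed;
}

// support counts for a list of patterns against a database
// [[Rcpp::export]]
IntegerVector cpp_pattern_support(List db, List patterns) {
  std::vector<Sequence> d(db.size());
  for (int i = 0; i < db.size(); ++i) d[i] = as_sequence(db[i]);
  IntegerVector out(patterns.size());
  for (int j = 0; j < patterns.size(); ++j) {
    Sequence p = as_sequence(patterns[j]);
    int c = 0;
    for (const Sequence& s : d)
      if (seq_contains(s, p)) ++c;
    out[j] = c;
  }
  return out;
}
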