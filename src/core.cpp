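// Core combinatorics for sorting signed permutations by reversals:
// Hannenhalli-Pevzner breakpoint-graph statistics, optimal 1-sequences,
// Cartier-Foata normalization, depth-first trace enumeration, solution
// counting, linear-extension counting, and search-based distance oracles.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <unordered_map>
#include <unordered_set>
#include <chrono>
#include <cstdint>
#include <functional>

using namespace Rcpp;

typedef std::vector<int> ivec;

// ---------------------------------------------------------------------------
// Breakpoint graph of a signed permutation framed by 0 and n+1.
// Each element x is split into two points (2x-1, 2x), order swapped when x<0.
// Black edges join consecutive positions (2b, 2b+1); gray edges join values
// (2g, 2g+1). Cycles alternate black/gray.
// ---------------------------------------------------------------------------
struct HPGraph {
  int n;
  ivec pts;              // framed point sequence, length 2n+2
  ivec pos;              // pos[value] = index in pts
  int ncyc;
  ivec grayCycle;        // cycle id per gray edge g = 0..n
  std::vector<bool> grayOriented; // endpoints at same-parity positions
  ivec grayL, grayR;     // position span of each gray edge
  ivec comp;             // component id per gray edge (interleaving closure)
  int ncomp;
  std::vector<bool> compOriented; // has an oriented gray edge
  std::vector<bool> compTrivial;  // all edges are adjacencies (span 1)
  ivec hurdleComp;       // component ids that are hurdles
  int h;
  int f;
  int d;
};

static void build_graph(const ivec &p, HPGraph &G) {
  int n = (int)p.size();
  G.n = n;
  int M = 2 * n + 2;
  G.pts.assign(M, 0);
  G.pts[0] = 0;
  G.pts[M - 1] = 2 * n + 1;
  for (int i = 0; i < n; i++) {
    int v = p[i];
    if (v > 0) { G.pts[2 * i + 1] = 2 * v - 1; G.pts[2 * i + 2] = 2 * v; }
    else       { G.pts[2 * i + 1] = -2 * v;    G.pts[2 * i + 2] = -2 * v - 1; }
  }
  G.pos.assign(M, 0);
  for (int i = 0; i < M; i++) G.pos[G.pts[i]] = i;

  int E = n + 1; // gray (and black) edge count
  G.grayCycle.assign(E, -1);
  G.grayOriented.assign(E, false);
  G.grayL.assign(E, 0); G.grayR.assign(E, 0);
  for (int g = 0; g < E; g++) {
    int a = G.pos[2 * g], b = G.pos[2 * g + 1];
    G.grayL[g] = std::min(a, b);
    G.grayR[g] = std::max(a, b);
    G.grayOriented[g] = ((G.grayR[g] - G.grayL[g]) % 2 == 0);
  }
  // cycle traversal over black edges b = 0..n (positions 2b, 2b+1)
  std::vector<bool> visB(E, false);
  G.ncyc = 0;
  for (int b = 0; b < E; b++) {
    if (visB[b]) continue;
    int cyc = G.ncyc++;
    int start = 2 * b, pcur = start;
    do {
      visB[pcur / 2] = true;
      int q = (pcur % 2 == 0) ? pcur + 1 : pcur - 1; // black partner
      int gid = G.pts[q] / 2;
      G.grayCycle[gid] = cyc;
      pcur = G.pos[G.pts[q] ^ 1];                    // gray partner
    } while (pcur != start);
  }
}

static void build_components(HPGraph &G) {
  int E = G.n + 1;
  // union-find over gray edges; union interleaving pairs
  ivec par(E);
  for (int i = 0; i < E; i++) par[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (par[x] != x) { par[x] = par[par[x]]; x = par[x]; }
    return x;
  };
  for (int a = 0; a < E; a++)
    for (int b = a + 1; b < E; b++) {
      bool il = (G.grayL[a] < G.grayL[b] && G.grayL[b] < G.grayR[a] &&
                 G.grayR[a] < G.grayR[b]) ||
                (G.grayL[b] < G.grayL[a] && G.grayL[a] < G.grayR[b] &&
                 G.grayR[b] < G.grayR[a]);
      if (il) { int ra = find(a), rb = find(b); if (ra != rb) par[ra] = rb; }
    }
  std::unordered_map<int, int> relab;
  G.comp.assign(E, -1);
  G.ncomp = 0;
  for (int g = 0; g < E; g++) {
    int r = find(g);
    auto it = relab.find(r);
    if (it == relab.end()) { relab[r] = G.ncomp; G.comp[g] = G.ncomp++; }
    else G.comp[g] = it->second;
  }
  G.compOriented.assign(G.ncomp, false);
  G.compTrivial.assign(G.ncomp, true);
  for (int g = 0; g < E; g++) {
    if (G.grayOriented[g]) G.compOriented[G.comp[g]] = true;
    if (G.grayR[g] - G.grayL[g] > 1) G.compTrivial[G.comp[g]] = false;
  }
}

// circular "does not separate the others" hurdle test on position sets
static std::vector<int> hurdles_of(const std::vector<ivec> &uposRaw,
                                   const std::vector<int> &ids, int M) {
  std::vector<int> out;
  size_t k = ids.size();
  for (size_t ui = 0; ui < k; ui++) {
    const ivec &P = uposRaw[ids[ui]];
    ivec Q;
    for (size_t vj = 0; vj < k; vj++)
      if (vj != ui)
        Q.insert(Q.end(), uposRaw[ids[vj]].begin(), uposRaw[ids[vj]].end());
    if (Q.empty()) { out.push_back(ids[ui]); continue; }
    bool isH = false;
    size_t m = P.size();
    for (size_t i = 0; i < m && !isH; i++) {
      int a = P[i], b = P[(i + 1) % m]; // circular gap (a, b)
      bool all = true;
      for (int x : Q) {
        bool in = (a < b) ? (x > a && x < b) : (x > a || x < b);
        if (!in) { all = false; break; }
      }
      if (all) isH = true;
    }
    if (isH) out.push_back(ids[ui]);
  }
  return out;
}

static void classify_hurdles(HPGraph &G) {
  int E = G.n + 1, M = 2 * G.n + 2;
  // position sets per unoriented nontrivial component
  std::vector<ivec> upos(G.ncomp);
  std::vector<int> uids;
  for (int c = 0; c < G.ncomp; c++)
    if (!G.compOriented[c] && !G.compTrivial[c]) uids.push_back(c);
  for (int g = 0; g < E; g++) {
    int c = G.comp[g];
    if (!G.compOriented[c] && !G.compTrivial[c]) {
      upos[c].push_back(G.grayL[g]);
      upos[c].push_back(G.grayR[g]);
    }
  }
  for (int c : uids) std::sort(upos[c].begin(), upos[c].end());

  std::vector<int> H = hurdles_of(upos, uids, M);
  G.hurdleComp = H;
  G.h = (int)H.size();
  // fortress: odd number of hurdles, all of them super-hurdles
  G.f = 0;
  if (G.h > 0 && G.h % 2 == 1) {
    std::unordered_set<int> hset(H.begin(), H.end());
    bool allSuper = true;
    for (int hcomp : H) {
      std::vector<int> rest;
      for (int c : uids) if (c != hcomp) rest.push_back(c);
      std::vector<int> H2 = hurdles_of(upos, rest, M);
      bool super = false;
      for (int c : H2) if (!hset.count(c)) { super = true; break; }
      if (!super) { allSuper = false; break; }
    }
    if (allSuper) G.f = 1;
  }
  G.d = (G.n + 1) - G.ncyc + G.h + G.f;
}

static void hp_full(const ivec &p, HPGraph &G) {
  build_graph(p, G);
  build_components(G);
  classify_hurdles(G);
}

static int hp_distance(const ivec &p) {
  HPGraph G;
  hp_full(p, G);
  return G.d;
}

// ---------------------------------------------------------------------------
// helpers
// ---------------------------------------------------------------------------
static ivec as_ivec(const IntegerVector &v) {
  return ivec(v.begin(), v.end());
}

static void check_perm(const ivec &p) {
  int n = (int)p.size();
  if (n < 1) stop("permutation must have at least one element");
  std::vector<bool> seen(n + 1, false);
  for (int v : p) {
    int a = v < 0 ? -v : v;
    if (a < 1 || a > n || seen[a])
      stop("invalid signed permutation: magnitudes must be 1..n exactly once");
    seen[a] = true;
  }
}

// relabel perm so that `target` becomes the identity
static ivec relabel(const ivec &p, const ivec &t) {
  int n = (int)p.size();
  if ((int)t.size() != n) stop("permutation and target must have equal size");
  ivec map(n + 1);
  for (int k = 0; k < n; k++) {
    int v = t[k];
    int a = v < 0 ? -v : v;
    map[a] = (v > 0) ? (k + 1) : -(k + 1);
  }
  ivec r(n);
  for (int i = 0; i < n; i++) {
    int v = p[i];
    int a = v < 0 ? -v : v;
    r[i] = (v > 0) ? map[a] : -map[a];
  }
  return r;
}

static void rev_inplace(ivec &p, int i, int j) { // 1-based inclusive
  int a = i - 1, b = j - 1;
  while (a < b) { int t = p[a]; p[a] = -p[b]; p[b] = -t; a++; b--; }
  if (a == b) p[a] = -p[a];
}

// overlap of two ascending integer sets: intersect, neither contains the other
static bool overlap_sets(const ivec &a, const ivec &b) {
  size_t i = 0, j = 0, inter = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) { inter++; i++; j++; }
    else if (a[i] < b[j]) i++;
    else j++;
  }
  return inter > 0 && inter < a.size() && inter < b.size();
}

// dependence relation of the trace monoid: two reversals depend on each
// other when they overlap or are equal (dependence is reflexive, so equal
// occurrences stay ordered)
static bool dependent(const ivec &a, const ivec &b) {
  return a == b || overlap_sets(a, b);
}

static bool lex_less(const ivec &a, const ivec &b) {
  return std::lexicographical_compare(a.begin(), a.end(), b.begin(), b.end());
}

// greedy Cartier-Foata level of each letter: 1 + max level of an earlier
// non-commuting letter
static ivec cf_levels_of(const std::vector<ivec> &word) {
  ivec lv(word.size(), 1);
  for (size_t k = 0; k < word.size(); k++) {
    int best = 0;
    for (size_t j = 0; j < k; j++)
      if (lv[j] > best && dependent(word[j], word[k])) best = lv[j];
    lv[k] = best + 1;
  }
  return lv;
}

static std::string canon_string(const std::vector<ivec> &word, const ivec &lv) {
  int m = 0;
  for (int l : lv) m = std::max(m, l);
  std::string out;
  for (int lev = 1; lev <= m; lev++) {
    std::vector<const ivec *> sub;
    for (size_t k = 0; k < word.size(); k++)
      if (lv[k] == lev) sub.push_back(&word[k]);
    std::sort(sub.begin(), sub.end(),
              [](const ivec *a, const ivec *b) { return lex_less(*a, *b); });
    if (lev > 1) out += "|";
    for (const ivec *s : sub) {
      out += "{";
      for (size_t i = 0; i < s->size(); i++) {
        if (i) out += ",";
        out += std::to_string((*s)[i]);
      }
      out += "}";
    }
  }
  return out;
}

static std::string key_of(const ivec &p) {
  std::string k(p.size(), ' ');
  int n = (int)p.size();
  for (size_t i = 0; i < p.size(); i++) k[i] = (char)(p[i] + n + 1);
  return k;
}

// all position intervals (i,j) whose reversal decreases distance by one;
// perm given relative to identity target
static std::vector<std::pair<int, int> > opt1_positions(const ivec &r, int d) {
  std::vector<std::pair<int, int> > out;
  int n = (int)r.size();
  ivec w = r;
  for (int i = 1; i <= n; i++)
    for (int j = i; j <= n; j++) {
      rev_inplace(w, i, j);
      if (hp_distance(w) == d - 1) out.push_back(std::make_pair(i, j));
      rev_inplace(w, i, j);
    }
  return out;
}

// ---------------------------------------------------------------------------
// exported: breakpoint-graph statistics
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_hp_stats(IntegerVector perm) {
  ivec p = as_ivec(perm);
  check_perm(p);
  HPGraph G;
  hp_full(p, G);
  return IntegerVector::create(_["d"] = G.d, _["c"] = G.ncyc, _["h"] = G.h,
                               _["f"] = G.f);
}

// [[Rcpp::export]]
List cpp_hp_detail(IntegerVector perm) {
  ivec p = as_ivec(perm);
  check_perm(p);
  HPGraph G;
  hp_full(p, G);
  int E = G.n + 1;
  List cycles(G.ncyc);
  for (int c = 0; c < G.ncyc; c++) {
    ivec g;
    for (int e = 0; e < E; e++)
      if (G.grayCycle[e] == c) g.push_back(e + 1); // 1-based gray edge ids
    cycles[c] = wrap(g);
  }
  LogicalVector cycOri(G.ncyc, false);
  for (int e = 0; e < E; e++)
    if (G.grayOriented[e]) cycOri[G.grayCycle[e]] = true;
  return List::create(
      _["points"] = wrap(G.pts), _["nCycles"] = G.ncyc, _["cycles"] = cycles,
      _["cycleOriented"] = cycOri, _["grayComponent"] = wrap(G.comp),
      _["componentOriented"] = wrap(G.compOriented),
      _["componentTrivial"] = wrap(G.compTrivial),
      _["hurdleComponents"] = wrap(G.hurdleComp), _["hurdles"] = G.h,
      _["fortress"] = G.f, _["distance"] = G.d);
}

// [[Rcpp::export]]
IntegerVector cpp_relabel(IntegerVector perm, IntegerVector target) {
  ivec p = as_ivec(perm), t = as_ivec(target);
  check_perm(p); check_perm(t);
  return wrap(relabel(p, t));
}

// [[Rcpp::export]]
IntegerMatrix cpp_opt1_positions(IntegerVector relPerm) {
  ivec r = as_ivec(relPerm);
  check_perm(r);
  int d = hp_distance(r);
  std::vector<std::pair<int, int> > v = opt1_positions(r, d);
  IntegerMatrix out((int)v.size(), 2);
  for (size_t k = 0; k < v.size(); k++) {
    out(k, 0) = v[k].first;
    out(k, 1) = v[k].second;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_cf_levels(List word) {
  std::vector<ivec> w;
  for (int i = 0; i < word.size(); i++)
    w.push_back(as_ivec(as<IntegerVector>(word[i])));
  return wrap(cf_levels_of(w));
}

// [[Rcpp::export]]
bool cpp_overlap(IntegerVector a, IntegerVector b) {
  return overlap_sets(as_ivec(a), as_ivec(b));
}

// ---------------------------------------------------------------------------
// depth-first trace enumeration (DFA), with optional stop criteria
// ---------------------------------------------------------------------------
struct DfaCtx {
  std::vector<std::string> out;
  double maxTraces;           // <0: unlimited
  double timeLimit;           // seconds, <0: unlimited
  std::chrono::steady_clock::time_point t0;
  bool stopped;
  int d;
  ivec orig, rel;             // current permutations (original labels / relative)
  std::vector<ivec> word;     // current i-trace letters (original magnitudes)
  ivec levels;
  std::unordered_map<std::string, std::vector<std::pair<int, int> > > memo;
};

static bool dfa_should_stop(DfaCtx &C) {
  if (C.maxTraces >= 0 && (double)C.out.size() >= C.maxTraces) return true;
  if (C.timeLimit >= 0) {
    double el = std::chrono::duration<double>(
                    std::chrono::steady_clock::now() - C.t0).count();
    if (el >= C.timeLimit) return true;
  }
  return false;
}

static void dfa_rec(DfaCtx &C, int depth) {
  if (C.stopped) return;
  if (depth == C.d) {
    C.out.push_back(canon_string(C.word, C.levels));
    if (dfa_should_stop(C)) C.stopped = true;
    return;
  }
  std::string key = key_of(C.rel);
  auto it = C.memo.find(key);
  if (it == C.memo.end())
    it = C.memo.insert(std::make_pair(
        key, opt1_positions(C.rel, C.d - depth))).first;
  std::vector<std::pair<int, int> > cand = it->second;
  // candidate reversal sets (original magnitudes), lexicographic order
  std::vector<std::pair<ivec, std::pair<int, int> > > cs;
  for (auto &ij : cand) {
    ivec s;
    for (int x = ij.first; x <= ij.second; x++)
      s.push_back(std::abs(C.orig[x - 1]));
    std::sort(s.begin(), s.end());
    cs.push_back(std::make_pair(s, ij));
  }
  std::sort(cs.begin(), cs.end(),
            [](const std::pair<ivec, std::pair<int, int> > &a,
               const std::pair<ivec, std::pair<int, int> > &b) {
              return lex_less(a.first, b.first);
            });
  for (auto &c : cs) {
    const ivec &S = c.first;
    // greedy level of S over the current word
    int lvl = 0;
    for (size_t k = 0; k < C.word.size(); k++)
      if (C.levels[k] > lvl && dependent(C.word[k], S)) lvl = C.levels[k];
    lvl += 1;
    // is_last: S falls in the last subword and is lexicographically last there
    bool ok = true;
    for (size_t k = 0; k < C.word.size() && ok; k++) {
      if (C.levels[k] > lvl) ok = false;
      else if (C.levels[k] == lvl && lex_less(S, C.word[k])) ok = false;
    }
    if (!ok) continue;
    int i = c.second.first, j = c.second.second;
    C.word.push_back(S);
    C.levels.push_back(lvl);
    rev_inplace(C.orig, i, j);
    rev_inplace(C.rel, i, j);
    dfa_rec(C, depth + 1);
    rev_inplace(C.rel, i, j);
    rev_inplace(C.orig, i, j);
    C.word.pop_back();
    C.levels.pop_back();
    if (C.stopped) return;
  }
}

// [[Rcpp::export]]
List cpp_dfa(IntegerVector perm, IntegerVector target, double maxTraces,
             double timeLimit) {
  DfaCtx C;
  C.orig = as_ivec(perm);
  check_perm(C.orig);
  ivec t = as_ivec(target);
  check_perm(t);
  C.rel = relabel(C.orig, t);
  C.d = hp_distance(C.rel);
  C.maxTraces = maxTraces;
  C.timeLimit = timeLimit;
  C.t0 = std::chrono::steady_clock::now();
  C.stopped = false;
  if (C.d == 0) {
    if (!(maxTraces >= 0 && maxTraces < 1))
      C.out.push_back("");
  } else {
    dfa_rec(C, 0);
  }
  double el = std::chrono::duration<double>(
                  std::chrono::steady_clock::now() - C.t0).count();
  return List::create(_["traces"] = wrap(C.out),
                      _["complete"] = !C.stopped,
                      _["distance"] = C.d,
                      _["elapsed"] = el);
}

// ---------------------------------------------------------------------------
// number of optimal sorting words: path-count DP on the level DAG of
// distinct intermediate permutations
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_count_solutions(IntegerVector perm, IntegerVector target) {
  ivec p = as_ivec(perm);
  check_perm(p);
  ivec t = as_ivec(target);
  ivec r = relabel(p, t);
  int d = hp_distance(r);
  std::unordered_map<std::string, std::pair<ivec, double> > level;
  level[key_of(r)] = std::make_pair(r, 1.0);
  for (int step = 0; step < d; step++) {
    std::unordered_map<std::string, std::pair<ivec, double> > nxt;
    int drem = d - step;
    for (auto &kv : level) {
      ivec cur = kv.second.first;
      double w = kv.second.second;
      std::vector<std::pair<int, int> > ops = opt1_positions(cur, drem);
      for (auto &ij : ops) {
        rev_inplace(cur, ij.first, ij.second);
        std::string k = key_of(cur);
        auto it = nxt.find(k);
        if (it == nxt.end()) nxt[k] = std::make_pair(cur, w);
        else it->second.second += w;
        rev_inplace(cur, ij.first, ij.second);
      }
    }
    level.swap(nxt);
  }
  ivec id(r.size());
  for (size_t i = 0; i < id.size(); i++) id[i] = (int)i + 1;
  auto it = level.find(key_of(id));
  return it == level.end() ? 0.0 : it->second.second;
}

// ---------------------------------------------------------------------------
// linear extensions of the commutation poset of a word (trace size):
// DP over order ideals, memoized on the placed-element bitmask
// ---------------------------------------------------------------------------
static double linext_rec(uint32_t placed, uint32_t full,
                         const std::vector<uint32_t> &preds,
                         std::unordered_map<uint32_t, double> &memo) {
  if (placed == full) return 1.0;
  auto it = memo.find(placed);
  if (it != memo.end()) return it->second;
  double tot = 0.0;
  int m = (int)preds.size();
  for (int e = 0; e < m; e++) {
    uint32_t bit = 1u << e;
    if ((placed & bit) || ((preds[e] & placed) != preds[e])) continue;
    tot += linext_rec(placed | bit, full, preds, memo);
  }
  memo[placed] = tot;
  return tot;
}

// [[Rcpp::export]]
double cpp_linext_count(List word) {
  int m = word.size();
  if (m == 0) return 1.0;
  if (m > 25) stop("linear-extension counting supports at most 25 reversals");
  std::vector<ivec> w;
  for (int i = 0; i < m; i++)
    w.push_back(as_ivec(as<IntegerVector>(word[i])));
  ivec lv = cf_levels_of(w);
  // process in level order; preds accumulate transitively
  std::vector<int> idx(m);
  for (int i = 0; i < m; i++) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return lv[a] < lv[b]; });
  std::vector<uint32_t> preds(m, 0u);
  for (int a = 0; a < m; a++)
    for (int b = 0; b < m; b++) {
      int ia = idx[a], ib = idx[b];
      if (lv[ia] < lv[ib] && dependent(w[ia], w[ib]))
        preds[ib] |= (1u << ia) | preds[ia];
    }
  uint32_t full = (m == 32) ? 0xffffffffu : ((1u << m) - 1u);
  std::unordered_map<uint32_t, double> memo;
  return linext_rec(0u, full, preds, memo);
}

// ---------------------------------------------------------------------------
// brute-force oracle: enumerate ALL optimal words (no trace pruning), group
// by Cartier-Foata normal form
// ---------------------------------------------------------------------------
struct BruteCtx {
  std::unordered_map<std::string, double> groups;
  double total;
  double maxWords;
  int d;
  ivec orig, rel;
  std::vector<ivec> word;
  std::unordered_map<std::string, std::vector<std::pair<int, int> > > memo;
};

static void brute_rec(BruteCtx &C, int depth) {
  if (C.total >= C.maxWords)
    stop("brute-force word enumeration exceeded the word cap");
  if (depth == C.d) {
    ivec lv = cf_levels_of(C.word);
    C.groups[canon_string(C.word, lv)] += 1.0;
    C.total += 1.0;
    return;
  }
  std::string key = key_of(C.rel);
  auto it = C.memo.find(key);
  if (it == C.memo.end())
    it = C.memo.insert(std::make_pair(
        key, opt1_positions(C.rel, C.d - depth))).first;
  std::vector<std::pair<int, int> > ops = it->second;
  for (auto &ij : ops) {
    ivec s;
    for (int x = ij.first; x <= ij.second; x++)
      s.push_back(std::abs(C.orig[x - 1]));
    std::sort(s.begin(), s.end());
    C.word.push_back(s);
    rev_inplace(C.orig, ij.first, ij.second);
    rev_inplace(C.rel, ij.first, ij.second);
    brute_rec(C, depth + 1);
    rev_inplace(C.rel, ij.first, ij.second);
    rev_inplace(C.orig, ij.first, ij.second);
    C.word.pop_back();
  }
}

// [[Rcpp::export]]
List cpp_brute_force(IntegerVector perm, IntegerVector target,
                     int maxDistance, double maxWords) {
  BruteCtx C;
  C.orig = as_ivec(perm);
  check_perm(C.orig);
  ivec t = as_ivec(target);
  check_perm(t);
  C.rel = relabel(C.orig, t);
  C.d = hp_distance(C.rel);
  if (C.d > maxDistance)
    stop("distance %d exceeds the brute-force guard (%d)", C.d, maxDistance);
  C.total = 0.0;
  C.maxWords = maxWords;
  if (C.d == 0) { C.groups[""] = 1.0; C.total = 1.0; }
  else brute_rec(C, 0);
  std::vector<std::string> keys;
  keys.reserve(C.groups.size());
  for (auto &kv : C.groups) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  NumericVector counts((int)keys.size());
  CharacterVector traces((int)keys.size());
  for (size_t i = 0; i < keys.size(); i++) {
    traces[i] = keys[i];
    counts[i] = C.groups[keys[i]];
  }
  return List::create(_["traces"] = traces, _["sizes"] = counts,
                      _["totalWords"] = C.total, _["distance"] = C.d);
}

// ---------------------------------------------------------------------------
// search-based distance oracles (independent of the HP component/hurdle
// classification): full-group BFS for n <= 7, bidirectional BFS for n <= 8,
// IDA* with the cycle lower bound as fallback
// ---------------------------------------------------------------------------
static uint64_t encode_perm(const ivec &p) {
  uint64_t k = 0;
  for (size_t i = 0; i < p.size(); i++) {
    uint64_t v = (uint64_t)(p[i] + 16); // n <= 15 fits in 5 bits + sign margin
    k = (k << 6) | v;
  }
  return k;
}

// [[Rcpp::export]]
IntegerVector cpp_bfs_distances(int n, IntegerMatrix queries) {
  if (n < 1 || n > 7) stop("full-group BFS supports n in 1..7");
  ivec id(n);
  for (int i = 0; i < n; i++) id[i] = i + 1;
  std::unordered_map<uint64_t, int> dist;
  std::vector<ivec> frontier;
  dist[encode_perm(id)] = 0;
  frontier.push_back(id);
  int depth = 0;
  while (!frontier.empty()) {
    std::vector<ivec> nxt;
    for (ivec &p : frontier) {
      for (int i = 1; i <= n; i++)
        for (int j = i; j <= n; j++) {
          rev_inplace(p, i, j);
          uint64_t k = encode_perm(p);
          if (dist.find(k) == dist.end()) {
            dist[k] = depth + 1;
            nxt.push_back(p);
          }
          rev_inplace(p, i, j);
        }
    }
    frontier.swap(nxt);
    depth++;
  }
  IntegerVector out(queries.nrow());
  for (int q = 0; q < queries.nrow(); q++) {
    ivec p(n);
    for (int i = 0; i < n; i++) p[i] = queries(q, i);
    check_perm(p);
    auto it = dist.find(encode_perm(p));
    if (it == dist.end()) stop("query permutation not reached by BFS");
    out[q] = it->second;
  }
  return out;
}

// [[Rcpp::export]]
int cpp_bidir_distance(IntegerVector perm) {
  ivec p = as_ivec(perm);
  check_perm(p);
  int n = (int)p.size();
  if (n > 10) stop("bidirectional BFS supports n <= 10");
  ivec id(n);
  for (int i = 0; i < n; i++) id[i] = i + 1;
  uint64_t kid = encode_perm(id), kp = encode_perm(p);
  if (kid == kp) return 0;
  std::unordered_map<uint64_t, int> dA, dB;
  std::vector<ivec> fA, fB;
  dA[kp] = 0; fA.push_back(p);
  dB[kid] = 0; fB.push_back(id);
  int depthA = 0, depthB = 0, best = INT32_MAX;
  while (!fA.empty() && !fB.empty()) {
    if (best <= depthA + depthB + 1) return best;
    bool expandA = fA.size() <= fB.size();
    std::vector<ivec> &fr = expandA ? fA : fB;
    std::unordered_map<uint64_t, int> &dme = expandA ? dA : dB;
    std::unordered_map<uint64_t, int> &dot = expandA ? dB : dA;
    int depth = expandA ? depthA : depthB;
    std::vector<ivec> nxt;
    for (ivec &q : fr) {
      for (int i = 1; i <= n; i++)
        for (int j = i; j <= n; j++) {
          rev_inplace(q, i, j);
          uint64_t k = encode_perm(q);
          if (dme.find(k) == dme.end()) {
            dme[k] = depth + 1;
            nxt.push_back(q);
            auto it = dot.find(k);
            if (it != dot.end())
              best = std::min(best, depth + 1 + it->second);
          }
          rev_inplace(q, i, j);
        }
    }
    fr.swap(nxt);
    if (expandA) depthA++; else depthB++;
  }
  if (best == INT32_MAX) stop("bidirectional BFS failed to meet");
  return best;
}
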