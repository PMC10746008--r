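#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// pairwise difference counts with pairwise deletion
// ---------------------------------------------------------------------------

// Columns where either sequence carries a gap or an ambiguity code are
// excluded; only unambiguous A/C/G/T columns are compared.
// [[Rcpp::export]]
List cpp_pdist_counts(CharacterVector seqs) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  const size_t L = s.empty() ? 0 : s[0].size();
  for (int i = 0; i < n; ++i)
    if (s[i].size() != L) stop("sequences have unequal lengths");

  // encode: 0..3 = ACGT, 255 = excluded symbol
  std::vector<std::vector<uint8_t>> code(n, std::vector<uint8_t>(L));
  for (int i = 0; i < n; ++i) {
    for (size_t j = 0; j < L; ++j) {
      switch (toupper(s[i][j])) {
        case 'A': code[i][j] = 0; break;
        case 'C': code[i][j] = 1; break;
        case 'G': code[i][j] = 2; break;
        case 'T': code[i][j] = 3; break;
        default:  code[i][j] = 255;
      }
    }
  }

  IntegerMatrix ndiff(n, n), ncomp(n, n);
  for (int a = 0; a < n; ++a) {
    for (int b = a; b < n; ++b) {
      int d = 0, c = 0;
      for (size_t j = 0; j < L; ++j) {
        uint8_t x = code[a][j], y = code[b][j];
        if (x == 255 || y == 255) continue;
        ++c;
        if (x != y) ++d;
      }
      ndiff(a, b) = ndiff(b, a) = d;
      ncomp(a, b) = ncomp(b, a) = c;
    }
  }
  return List::create(_["ndiff"] = ndiff, _["ncomp"] = ncomp);
}

// ---------------------------------------------------------------------------
// complete-linkage merge heights
// ---------------------------------------------------------------------------

// Naive O(n^3) complete-linkage agglomeration on a distance matrix.
// Tie-break: the merge with the lexicographically smallest (i, j) cluster
// representative pair is taken first, so output is deterministic.
// Returns the n-1 merge heights in merge order (non-decreasing).
// [[Rcpp::export]]
NumericVector cpp_complete_linkage_heights(NumericMatrix d) {
  const int n = d.nrow();
  if (n < 2) return NumericVector(0);
  // working copy of inter-cluster complete-linkage distances
  std::vector<std::vector<double>> D(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) D[i][j] = d(i, j);
  std::vector<int> alive(n, 1), rep(n);
  for (int i = 0; i < n; ++i) rep[i] = i; // smallest original index in cluster
  NumericVector heights(n - 1);

  for (int step = 0; step < n - 1; ++step) {
    double best = R_PosInf;
    int bi = -1, bj = -1;
    for (int i = 0; i < n; ++i) {
      if (!alive[i]) continue;
      for (int j = i + 1; j < n; ++j) {
        if (!alive[j]) continue;
        double v = D[i][j];
        if (v < best - 1e-15) {
          best = v; bi = i; bj = j;
        } else if (std::abs(v - best) <= 1e-15) {
          int ri = std::min(rep[i], rep[j]), rj = std::max(rep[i], rep[j]);
          int rbi = std::min(rep[bi], rep[bj]), rbj = std::max(rep[bi], rep[bj]);
          if (ri < rbi || (ri == rbi && rj < rbj)) { bi = i; bj = j; }
        }
      }
    }
    heights[step] = best;
    // merge bj into bi; complete linkage takes the max distance
    for (int k = 0; k < n; ++k) {
      if (!alive[k] || k == bi || k == bj) continue;
      double v = std::max(D[bi][k], D[bj][k]);
      D[bi][k] = D[k][bi] = v;
    }
    rep[bi] = std::min(rep[bi], rep[bj]);
    alive[bj] = 0;
  }
  return heights;
}

// ---------------------------------------------------------------------------
// Stable Ecotype Model coalescent simulator
// ---------------------------------------------------------------------------

static inline int unif_int(int k) { // uniform on 0..k-1
  int v = (int)(unif_rand() * k);
  return v >= k ? k - 1 : v;
}

// 2-bit packed difference count between two coded sequences
static inline int packed_diff(const std::vector<uint64_t>& x,
                              const std::vector<uint64_t>& y) {
  int d = 0;
  for (size_t w = 0; w < x.size(); ++w) {
    uint64_t g = x[w] ^ y[w];
    uint64_t m = (g | (g >> 1)) & 0x5555555555555555ULL;
    d += __builtin_popcountll(m);
  }
  return d;
}

// Simulate one replicate of the Stable Ecotype Model backward in time and
// return its binning curve (and, if full = true, the genealogy and alignment).
//
// Model: n sampled lineages are assigned to npop ecotypes (uniformly,
// conditioned on no ecotype being empty); each ecotype with >= 2 lineages
// suffers periodic selection at rate sigma (all its lineages coalesce);
// each ecotype merges into another at rate omega while >= 2 remain
// (backward view of an ecotype formation event). Rates are per unit branch
// length (expected substitutions/site). The process stops at time `depth`,
// where all remaining lineages join at the root. Sequences of length L then
// evolve down the genealogy under Jukes-Cantor.
// [[Rcpp::export]]
List cpp_sim_replicate(double omega, double sigma, int npop, int n,
                       double depth, int L, NumericVector criteria,
                       bool full) {
  if (n < 2) stop("sample size must be >= 2");
  if (depth <= 0) stop("depth must be positive");
  if (L < 1) stop("sequence length must be >= 1");
  if (npop < 1) stop("npop must be >= 1");
  const int k = std::min(npop, n);

  // --- initial assignment: uniform conditioned on no empty ecotype ---------
  std::vector<int> eco(n);
  bool ok = false;
  for (int tries = 0; tries < 10000 && !ok; ++tries) {
    std::vector<int> cnt(k, 0);
    for (int i = 0; i < n; ++i) { eco[i] = unif_int(k); ++cnt[eco[i]]; }
    ok = true;
    for (int e = 0; e < k; ++e) if (cnt[e] == 0) { ok = false; break; }
  }
  if (!ok) {
    // occupancy guarantee: one lineage per ecotype, rest uniform
    std::vector<int> perm(n);
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) std::swap(perm[i], perm[unif_int(i + 1)]);
    for (int e = 0; e < k; ++e) eco[perm[e]] = e;
    for (int i = k; i < n; ++i) eco[perm[i]] = unif_int(k);
  }

  // --- genealogy containers ------------------------------------------------
  const int max_nodes = 2 * n + 2;
  std::vector<int> parent(max_nodes, -1);
  std::vector<double> node_time(max_nodes, 0.0);
  int n_nodes = n; // leaves are 0..n-1 at time 0

  // live lineages: node id + ecotype id
  std::vector<int> lin_node(n), lin_eco(n);
  for (int i = 0; i < n; ++i) { lin_node[i] = i; lin_eco[i] = eco[i]; }
  int n_lin = n;

  auto eco_counts = [&](std::vector<int>& cnt, std::vector<int>& ids) {
    std::unordered_map<int, int> m;
    for (int i = 0; i < n_lin; ++i) m[lin_eco[i]]++;
    ids.clear();
    for (auto& kv : m) ids.push_back(kv.first);
    std::sort(ids.begin(), ids.end()); // deterministic order
    cnt.clear();
    for (int id : ids) cnt.push_back(m[id]);
  };

  double t = 0.0;
  while (true) {
    std::vector<int> cnt, ids;
    eco_counts(cnt, ids);
    const int n_eco = (int)ids.size();
    int n_ps = 0;
    for (int c : cnt) if (c >= 2) ++n_ps;
    const double r_ps = sigma * n_ps;
    const double r_form = (n_eco >= 2) ? omega * n_eco : 0.0;
    const double total = r_ps + r_form;
    if (total <= 0.0) break;
    t += exp_rand() / total;
    if (t >= depth) break;
    if (unif_rand() * total < r_ps) {
      // periodic selection: pick an ecotype with >= 2 lineages (uniform,
      // deterministic scan order over ids sorted for reproducibility)
      std::vector<int> elig;
      for (int e = 0; e < n_eco; ++e) if (cnt[e] >= 2) elig.push_back(e);
      int pick = elig[unif_int((int)elig.size())];
      int target = ids[pick];
      // coalesce all lineages of `target` into a new node at time t
      int node = n_nodes++;
      node_time[node] = t;
      std::vector<int> keep_node, keep_eco;
      for (int i = 0; i < n_lin; ++i) {
        if (lin_eco[i] == target) {
          parent[lin_node[i]] = node;
        } else {
          keep_node.push_back(lin_node[i]);
          keep_eco.push_back(lin_eco[i]);
        }
      }
      keep_node.push_back(node);
      keep_eco.push_back(target);
      n_lin = (int)keep_node.size();
      for (int i = 0; i < n_lin; ++i) { lin_node[i] = keep_node[i]; lin_eco[i] = keep_eco[i]; }
    } else {
      // ecotype formation (backward: ecotype merges into another)
      int src = unif_int(n_eco);
      int dst = unif_int(n_eco - 1);
      if (dst >= src) ++dst;
      int from = ids[src], to = ids[dst];
      for (int i = 0; i < n_lin; ++i)
        if (lin_eco[i] == from) lin_eco[i] = to;
    }
  }

  // root joins whatever remains at time depth
  int root;
  if (n_lin > 1) {
    root = n_nodes++;
    node_time[root] = depth;
    for (int i = 0; i < n_lin; ++i) parent[lin_node[i]] = root;
  } else {
    // single remaining lineage: stretch it to the root at `depth`
    root = n_nodes++;
    node_time[root] = depth;
    parent[lin_node[0]] = root;
  }

  // --- sequence evolution down the genealogy --------------------------------
  const int words = (L + 31) / 32;
  std::vector<std::vector<uint64_t>> seq(n_nodes, std::vector<uint64_t>(words, 0));
  // root sequence uniform over ACGT
  for (int j = 0; j < L; ++j) {
    int b = unif_int(4);
    seq[root][j >> 5] |= ((uint64_t)b) << ((j & 31) * 2);
  }
  // process nodes in order of decreasing time (parents strictly older than
  // children except the stretched-root chain, which is handled by index order)
  std::vector<int> order(n_nodes);
  for (int i = 0; i < n_nodes; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (node_time[a] != node_time[b]) return node_time[a] > node_time[b];
    return a > b; // internal nodes (higher ids) before leaves at equal times
  });
  for (int oi = 0; oi < n_nodes; ++oi) {
    int v = order[oi];
    if (v == root) continue;
    int p = parent[v];
    double b = node_time[p] - node_time[v];
    if (b < 0) b = 0;
    seq[v] = seq[p];
    double psub = 0.75 * (1.0 - std::exp(-4.0 * b / 3.0));
    int nmut = (int)R::rbinom((double)L, psub);
    for (int m = 0; m < nmut; ++m) {
      int pos = unif_int(L);
      int shift = (pos & 31) * 2;
      uint64_t cur = (seq[v][pos >> 5] >> shift) & 3ULL;
      uint64_t nb = (cur + 1 + unif_int(3)) & 3ULL;
      seq[v][pos >> 5] &= ~(3ULL << shift);
      seq[v][pos >> 5] |= nb << shift;
    }
  }

  // --- p-distance matrix of the leaves and binning curve -------------------
  NumericMatrix pd(n, n);
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      double p = (double)packed_diff(seq[a], seq[b]) / L;
      pd(a, b) = pd(b, a) = p;
    }
  NumericVector heights = cpp_complete_linkage_heights(pd);
  const int nc = criteria.size();
  IntegerVector bins(nc);
  for (int c = 0; c < nc; ++c) {
    double h = 1.0 - criteria[c] + 1e-12;
    int merged = 0;
    for (int s = 0; s < heights.size(); ++s) if (heights[s] <= h) ++merged;
    bins[c] = n - merged;
  }

  if (!full) return List::create(_["bins"] = bins);

  // full outputs: genealogy edges + alignment strings
  IntegerVector par_out(n_nodes);
  NumericVector time_out(n_nodes);
  for (int i = 0; i < n_nodes; ++i) {
    par_out[i] = parent[i] < 0 ? NA_INTEGER : parent[i] + 1; // 1-based
    time_out[i] = node_time[i];
  }
  const char* bases = "ACGT";
  CharacterVector aln(n);
  std::string buf(L, 'A');
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < L; ++j)
      buf[j] = bases[(seq[i][j >> 5] >> ((j & 31) * 2)) & 3ULL];
    aln[i] = buf;
  }
  return List::create(_["bins"] = bins, _["parent"] = par_out,
                      _["time"] = time_out, _["n_leaves"] = n,
                      _["root"] = root + 1, _["alignment"] = aln);
}

// ---------------------------------------------------------------------------
// fragment mapping for ANI: k-mer seeded, banded glocal alignment
// ---------------------------------------------------------------------------

static inline int base_code(char c) {
  switch (toupper(c)) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (toupper(c)) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: c = 'N';
    }
  }
  return r;
}

struct AlnScore { double identity; double coverage; };

// Banded alignment: fragment global, reference window local in the start/end
// (free end gaps on the window). Linear gap penalty. Returns identity as
// matches / fragment length (percent) and coverage as the fraction of
// fragment positions aligned to a reference base.
static AlnScore banded_glocal(const std::string& frag, const std::string& win,
                              int band) {
  const int m = (int)frag.size(), W = (int)win.size();
  const int width = 2 * band + 1;
  const double NEG = -1e18, GAP = -2.0;
  // column c of the band maps to window position j = i + (c - band)
  std::vector<double> prev(width, NEG), cur(width, NEG);
  std::vector<std::vector<int16_t>> mc((size_t)m + 1, std::vector<int16_t>(width, 0));
  std::vector<std::vector<int16_t>> cv((size_t)m + 1, std::vector<int16_t>(width, 0));
  // row 0: free start anywhere in window (j = c - band must be in [0, W])
  for (int c = 0; c < width; ++c) {
    int j = 0 + c - band;
    if (j >= 0 && j <= W) prev[c] = 0.0;
  }

  for (int i = 1; i <= m; ++i) {
    for (int c = 0; c < width; ++c) cur[c] = NEG;
    for (int c = 0; c < width; ++c) {
      int j = i + c - band;
      if (j < 0 || j > W) continue;
      double best = NEG; int move = -1; bool ismatch = false;
      // diagonal: consume frag[i-1] vs win[j-1]; same band column c
      if (j >= 1 && prev[c] > NEG / 2) {
        bool match = base_code(frag[i - 1]) >= 0 &&
                     base_code(frag[i - 1]) == base_code(win[j - 1]);
        double v = prev[c] + (match ? 1.0 : -1.0);
        if (v > best) { best = v; move = 1; ismatch = match; }
      }
      // gap in window (frag base vs '-'): from (i-1, j) -> column c+1 of prev row
      if (c + 1 < width && prev[c + 1] > NEG / 2) {
        double v = prev[c + 1] + GAP;
        if (v > best) { best = v; move = 2; ismatch = false; }
      }
      // gap in fragment ('-' vs win base): from (i, j-1) -> column c-1, same row
      if (c - 1 >= 0 && cur[c - 1] > NEG / 2) {
        double v = cur[c - 1] + GAP;
        if (v > best) { best = v; move = 3; ismatch = false; }
      }
      cur[c] = best;
      if (move == 1) {
        mc[i][c] = (int16_t)(mc[i - 1][c] + (ismatch ? 1 : 0));
        cv[i][c] = (int16_t)(cv[i - 1][c] + 1);
      } else if (move == 2) {
        mc[i][c] = mc[i - 1][c + 1];
        cv[i][c] = cv[i - 1][c + 1];
      } else if (move == 3) {
        mc[i][c] = mc[i][c - 1];
        cv[i][c] = cv[i][c - 1];
      }
    }
    std::swap(prev, cur);
  }
  // best over final row (free end in window)
  double best = NEG; int bc = -1;
  for (int c = 0; c < width; ++c) {
    int j = m + c - band;
    if (j < 0 || j > W) continue;
    if (prev[c] > best) { best = prev[c]; bc = c; }
  }
  AlnScore out{0.0, 0.0};
  if (bc < 0 || best <= NEG / 2) return out;
  out.identity = 100.0 * (double)mc[m][bc] / m;
  out.coverage = (double)cv[m][bc] / m;
  return out;
}

// Map each fragment onto a reference genome: hash all reference k-mers, vote
// on alignment diagonals with fragment k-mers (both strands), align the best
// few diagonals with a banded aligner and keep the highest-identity hit.
// [[Rcpp::export]]
NumericMatrix cpp_ani_map(CharacterVector frags, std::string ref,
                          int k, int step, double band_frac, int max_diags) {
  const int R = (int)ref.size();
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::unordered_multimap<uint64_t, int> index;
  index.reserve(R > k ? R - k + 1 : 0);
  {
    uint64_t h = 0; int run = 0;
    for (int j = 0; j < R; ++j) {
      int b = base_code(ref[j]);
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++run >= k) index.emplace(h, j - k + 1);
    }
  }
  const int nf = frags.size();
  NumericMatrix out(nf, 2);
  for (int f = 0; f < nf; ++f) {
    std::string fr = as<std::string>(frags[f]);
    const int m = (int)fr.size();
    const int band = std::max(8, (int)(band_frac * m));
    AlnScore best{0.0, 0.0};
    for (int strand = 0; strand < 2; ++strand) {
      std::string q = strand == 0 ? fr : revcomp(fr);
      // diagonal votes, bucketed to tolerate indel drift; each bucket keeps
      // an exact representative diagonal to anchor the alignment window
      std::unordered_map<int, std::pair<int, int>> votes; // bucket -> (count, rep diag)
      uint64_t h = 0; int run = 0;
      for (int j = 0; j < m; ++j) {
        int b = base_code(q[j]);
        if (b < 0) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)b) & mask;
        ++run;
        int qpos = j - k + 1;
        if (run >= k && (qpos % step) == 0) {
          auto range = index.equal_range(h);
          for (auto it = range.first; it != range.second; ++it) {
            int diff = it->second - qpos;
            int bucket = (diff >= 0) ? diff / band : -(((-diff) + band - 1) / band);
            auto ins = votes.emplace(bucket, std::make_pair(0, diff));
            ins.first->second.first++;
          }
        }
      }
      if (votes.empty()) continue;
      std::vector<std::pair<int, std::pair<int, int>>> vv(votes.begin(), votes.end());
      std::sort(vv.begin(), vv.end(), [](const std::pair<int, std::pair<int,int>>& a,
                                         const std::pair<int, std::pair<int,int>>& b) {
        return a.second.first > b.second.first ||
               (a.second.first == b.second.first && a.first < b.first);
      });
      int ndiag = std::min((int)vv.size(), max_diags);
      for (int dd = 0; dd < ndiag; ++dd) {
        // window anchored on the representative diagonal: the fragment is
        // expected near j - i = diag - lo, within the band
        int diag = vv[dd].second.second;
        int lo = std::max(0, diag - band / 2);
        int hi = std::min(R, diag + m + band);
        if (hi - lo < k) continue;
        std::string win = ref.substr(lo, hi - lo);
        AlnScore sc = banded_glocal(q, win, band);
        if (sc.identity > best.identity ||
            (sc.identity == best.identity && sc.coverage > best.coverage))
          best = sc;
      }
    }
    out(f, 0) = best.identity;
    out(f, 1) = best.coverage;
  }
  return out;
}
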