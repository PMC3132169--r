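// Desk-scale local alignment engine.
//
// Two stages, BLAST-style:
//  * exact-word seeds on a diagonal are extended ungapped with an x-drop
//    bound (fast path; sufficient for substitution-divergent homology);
//  * an exact affine-gap local DP (Smith-Waterman with traceback) scores
//    and aligns candidate pairs when gaps may matter.
//
// Sequences are encoded A=0 C=1 G=2 T=3, anything else (incl. N) = 4.
// Code 4 never matches, not even against itself, so hard-masked regions
// can neither seed nor contribute matching columns.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static inline std::vector<uint8_t> encode(const std::string &s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': case 'a': v[i] = 0; break;
      case 'C': case 'c': v[i] = 1; break;
      case 'G': case 'g': v[i] = 2; break;
      case 'T': case 't': v[i] = 3; break;
      default: v[i] = 4;
    }
  }
  return v;
}

static inline std::vector<uint8_t> revcomp(const std::vector<uint8_t> &v) {
  std::vector<uint8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t b = v[v.size() - 1 - i];
    r[i] = (b < 4) ? (3 - b) : 4;
  }
  return r;
}

struct Seed { int qpos, spos; };  // 0-based start of an exact word match

// All exact shared words between q and s, found by hashing subject words.
static std::vector<Seed> find_seeds(const std::vector<uint8_t> &q,
                                    const std::vector<uint8_t> &s,
                                    int word) {
  std::vector<Seed> seeds;
  if ((int)q.size() < word || (int)s.size() < word) return seeds;
  std::unordered_map<uint64_t, std::vector<int>> index;
  uint64_t key = 0, mask = (word >= 32) ? ~0ULL : ((1ULL << (2 * word)) - 1);
  int run = 0;
  for (int j = 0; j < (int)s.size(); ++j) {
    if (s[j] > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | s[j]) & mask;
    if (++run >= word) index[key].push_back(j - word + 1);
  }
  key = 0; run = 0;
  for (int i = 0; i < (int)q.size(); ++i) {
    if (q[i] > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | q[i]) & mask;
    if (++run >= word) {
      auto it = index.find(key);
      if (it != index.end())
        for (int j : it->second) seeds.push_back({i - word + 1, j});
    }
  }
  return seeds;
}

struct Ungapped { int qs, qe, ss, se, score; };  // 0-based inclusive

// Extend one seed ungapped in both directions with an x-drop bound.
static Ungapped extend_seed(const std::vector<uint8_t> &q,
                            const std::vector<uint8_t> &s,
                            int qpos, int spos, int word,
                            int match, int mismatch, int xdrop) {
  int score = word * match;
  // right
  int best = score, besti = qpos + word - 1;
  int i = qpos + word, j = spos + word, cur = score;
  while (i < (int)q.size() && j < (int)s.size()) {
    cur += (q[i] < 4 && q[i] == s[j]) ? match : mismatch;
    if (cur > best) { best = cur; besti = i; }
    if (cur < best - xdrop) break;
    ++i; ++j;
  }
  int right_ext = besti - (qpos + word - 1);
  score = best;
  // left
  best = score; int bestl = qpos;
  i = qpos - 1; j = spos - 1; cur = score;
  while (i >= 0 && j >= 0) {
    cur += (q[i] < 4 && q[i] == s[j]) ? match : mismatch;
    if (cur > best) { best = cur; bestl = i; }
    if (cur < best - xdrop) break;
    --i; --j;
  }
  Ungapped u;
  u.qs = bestl; u.qe = qpos + word - 1 + right_ext;
  u.ss = spos - (qpos - bestl); u.se = spos + (u.qe - qpos);
  u.score = best;
  return u;
}

// Sliding-window identity rule on a match vector: every `w`-column window
// must contain at least `k` matches; alignments shorter than `w` fail.
static bool window_pass(const std::vector<char> &mv, int w, int k) {
  int n = mv.size();
  if (n < w) return false;
  int sum = 0;
  for (int i = 0; i < w; ++i) sum += mv[i];
  if (sum < k) return false;
  for (int i = w; i < n; ++i) {
    sum += mv[i] - mv[i - w];
    if (sum < k) return false;
  }
  return true;
}

// Ungapped hits for one (q, s) orientation: extend seeds, skipping seeds
// already covered by an accepted extension on the same diagonal.
static std::vector<Ungapped> ungapped_hits(const std::vector<uint8_t> &q,
                                           const std::vector<uint8_t> &s,
                                           int word, int match, int mismatch,
                                           int xdrop, int min_score) {
  std::vector<Seed> seeds = find_seeds(q, s, word);
  std::vector<Ungapped> hits;
  if (seeds.empty()) return hits;
  // group by diagonal, remember covered query span per diagonal
  std::unordered_map<int, int> covered_to;  // diag -> last covered q index
  std::sort(seeds.begin(), seeds.end(), [](const Seed &a, const Seed &b) {
    int da = a.qpos - a.spos, db = b.qpos - b.spos;
    return da != db ? da < db : a.qpos < b.qpos;
  });
  for (const Seed &sd : seeds) {
    int diag = sd.qpos - sd.spos;
    auto it = covered_to.find(diag);
    if (it != covered_to.end() && sd.qpos <= it->second) continue;
    Ungapped u = extend_seed(q, s, sd.qpos, sd.spos, word,
                             match, mismatch, xdrop);
    covered_to[diag] = u.qe;
    if (u.score >= min_score) hits.push_back(u);
  }
  return hits;
}

// ---------------------------------------------------------------------------
// Exact affine-gap local DP with traceback.

struct SWHit {
  int qs, qe, ss, se, score;
  std::vector<char> mv;  // per-column: 1 match, 0 mismatch/gap
};

static const int NEG = -1000000000;

static bool sw_best(const std::vector<uint8_t> &q,
                    const std::vector<uint8_t> &s,
                    int match, int mismatch, int gap_open, int gap_ext,
                    SWHit &out) {
  int n = q.size(), m = s.size();
  if (n == 0 || m == 0) return false;
  int oe = gap_open + gap_ext;
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0), F(m + 1, NEG);
  // traceback: tbH 0=stop 1=diag 2=fromE 3=fromF; tbE/tbF 1=open 0=extend
  std::vector<uint8_t> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> tbE((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> tbF((size_t)(n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int E = NEG;
    Hcur[0] = 0;
    size_t row = (size_t)i * (m + 1);
    for (int j = 1; j <= m; ++j) {
      int sub = (q[i - 1] < 4 && q[i - 1] == s[j - 1]) ? match : mismatch;
      int diag = Hprev[j - 1] + sub;
      int e_open = Hcur[j - 1] - oe, e_ext = E - gap_ext;
      E = std::max(e_open, e_ext);
      tbE[row + j] = (e_open >= e_ext) ? 1 : 0;
      int f_open = Hprev[j] - oe, f_ext = F[j] - gap_ext;
      F[j] = std::max(f_open, f_ext);
      tbF[row + j] = (f_open >= f_ext) ? 1 : 0;
      int h = 0; uint8_t dir = 0;
      if (diag > h) { h = diag; dir = 1; }
      if (E > h) { h = E; dir = 2; }
      if (F[j] > h) { h = F[j]; dir = 3; }
      Hcur[j] = h; tbH[row + j] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }
  if (best <= 0) return false;
  // traceback
  std::vector<char> mv;
  int i = bi, j = bj, state = 0;  // 0=H 1=E 2=F
  int qe = bi - 1, se = bj - 1, qs = bi - 1, ss = bj - 1;
  while (true) {
    size_t idx = (size_t)i * (m + 1) + j;
    if (state == 0) {
      uint8_t d = tbH[idx];
      if (d == 0) break;
      if (d == 1) {
        mv.push_back((q[i - 1] < 4 && q[i - 1] == s[j - 1]) ? 1 : 0);
        qs = i - 1; ss = j - 1;
        --i; --j;
      } else if (d == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      mv.push_back(0);
      ss = j - 1;
      uint8_t d = tbE[idx];
      --j;
      state = d ? 0 : 1;
    } else {
      mv.push_back(0);
      qs = i - 1;
      uint8_t d = tbF[idx];
      --i;
      state = d ? 0 : 2;
    }
  }
  std::reverse(mv.begin(), mv.end());
  out.qs = qs; out.qe = qe; out.ss = ss; out.se = se;
  out.score = best; out.mv = mv;
  return true;
}

// Best local hits, extracted iteratively by masking used residues.
static std::vector<SWHit> sw_hits(std::vector<uint8_t> q,
                                  std::vector<uint8_t> s,
                                  int match, int mismatch, int gap_open,
                                  int gap_ext, int min_score, int max_hits) {
  std::vector<SWHit> hits;
  for (int h = 0; h < max_hits; ++h) {
    SWHit hit;
    if (!sw_best(q, s, match, mismatch, gap_open, gap_ext, hit)) break;
    if (hit.score < min_score) break;
    hits.push_back(hit);
    for (int i = hit.qs; i <= hit.qe; ++i) q[i] = 4;
    for (int j = hit.ss; j <= hit.se; ++j) s[j] = 4;
  }
  return hits;
}

// ---------------------------------------------------------------------------
// R entry points

// Hits of query vs subject on one orientation (subject as given).
// Returns a list of hits: qs, qe, ss, se, score, match vector (0-based
// conversion to 1-based happens here).
// [[Rcpp::export(name = ".cpp_align_one_strand")]]
List cpp_align_one_strand(std::string query, std::string subject,
                          int word, int match, int mismatch,
                          int gap_open, int gap_ext, int xdrop,
                          int min_score, int max_hits, bool gapped) {
  std::vector<uint8_t> q = encode(query), s = encode(subject);
  List out;
  if (find_seeds(q, s, word).empty()) return out;
  if (gapped) {
    std::vector<SWHit> hits = sw_hits(q, s, match, mismatch, gap_open,
                                      gap_ext, min_score, max_hits);
    for (const SWHit &h : hits) {
      out.push_back(List::create(
        _["q_start"] = h.qs + 1, _["q_end"] = h.qe + 1,
        _["s_start"] = h.ss + 1, _["s_end"] = h.se + 1,
        _["score"] = h.score,
        _["match_vector"] = LogicalVector(h.mv.begin(), h.mv.end())));
    }
  } else {
    std::vector<Ungapped> hits = ungapped_hits(q, s, word, match, mismatch,
                                               xdrop, min_score);
    std::sort(hits.begin(), hits.end(),
              [](const Ungapped &a, const Ungapped &b) {
                return a.score > b.score;
              });
    int kept = 0;
    for (const Ungapped &h : hits) {
      if (kept++ >= max_hits) break;
      std::vector<char> mv(h.qe - h.qs + 1);
      for (int t = 0; t <= h.qe - h.qs; ++t)
        mv[t] = (q[h.qs + t] < 4 && q[h.qs + t] == s[h.ss + t]) ? 1 : 0;
      out.push_back(List::create(
        _["q_start"] = h.qs + 1, _["q_end"] = h.qe + 1,
        _["s_start"] = h.ss + 1, _["s_end"] = h.se + 1,
        _["score"] = h.score,
        _["match_vector"] = LogicalVector(mv.begin(), mv.end())));
    }
  }
  return out;
}

// Sorted (word, position) list of a sequence, for merge-based seeding.
typedef std::vector<std::pair<uint64_t, int>> WordList;

static WordList word_list(const std::vector<uint8_t> &u, int word) {
  WordList out;
  uint64_t key = 0, mask = (word >= 32) ? ~0ULL : ((1ULL << (2 * word)) - 1);
  int run = 0;
  for (int i = 0; i < (int)u.size(); ++i) {
    if (u[i] > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | u[i]) & mask;
    if (++run >= word) out.push_back({key, i - word + 1});
  }
  std::sort(out.begin(), out.end());
  return out;
}

// Seeds between two sequences via merge-intersection of sorted word lists.
static std::vector<Seed> seeds_from_lists(const WordList &a,
                                          const WordList &b) {
  std::vector<Seed> seeds;
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i].first < b[j].first) ++i;
    else if (a[i].first > b[j].first) ++j;
    else {
      size_t i2 = i, j2 = j;
      while (i2 < a.size() && a[i2].first == a[i].first) ++i2;
      while (j2 < b.size() && b[j2].first == a[i].first) ++j2;
      for (size_t x = i; x < i2; ++x)
        for (size_t y = j; y < j2; ++y)
          seeds.push_back({a[x].second, b[y].second});
      i = i2; j = j2;
    }
  }
  return seeds;
}

// Ungapped hits given precomputed seeds (same diagonal dedup as
// ungapped_hits).
static std::vector<Ungapped> ungapped_from_seeds(
    std::vector<Seed> seeds, const std::vector<uint8_t> &q,
    const std::vector<uint8_t> &s, int word, int match, int mismatch,
    int xdrop, int min_score) {
  std::vector<Ungapped> hits;
  if (seeds.empty()) return hits;
  std::unordered_map<int, int> covered_to;
  std::sort(seeds.begin(), seeds.end(), [](const Seed &a, const Seed &b) {
    int da = a.qpos - a.spos, db = b.qpos - b.spos;
    return da != db ? da < db : a.qpos < b.qpos;
  });
  for (const Seed &sd : seeds) {
    int diag = sd.qpos - sd.spos;
    auto it = covered_to.find(diag);
    if (it != covered_to.end() && sd.qpos <= it->second) continue;
    Ungapped u = extend_seed(q, s, sd.qpos, sd.spos, word,
                             match, mismatch, xdrop);
    covered_to[diag] = u.qe;
    if (u.score >= min_score) hits.push_back(u);
  }
  return hits;
}

// Does any alignment between pair members pass the sliding-window identity
// rule?  Vectorized over candidate pairs (i, j are 1-based indices into
// seqs).  Fast path: ungapped x-drop extensions; exact DP only when an
// ungapped hit reaches min_score without passing the window rule.
// [[Rcpp::export(name = ".cpp_pairs_window_pass")]]
LogicalVector cpp_pairs_window_pass(CharacterVector seqs,
                                    IntegerVector ii, IntegerVector jj,
                                    int word, int match, int mismatch,
                                    int gap_open, int gap_ext, int xdrop,
                                    int min_score, int w, int k,
                                    int max_hits) {
  int nseq = seqs.size();
  std::vector<std::vector<uint8_t>> fwd(nseq), rev(nseq);
  std::vector<WordList> fwd_w(nseq), rev_w(nseq);
  for (int t = 0; t < nseq; ++t) {
    fwd[t] = encode(as<std::string>(seqs[t]));
    rev[t] = revcomp(fwd[t]);
    fwd_w[t] = word_list(fwd[t], word);
    rev_w[t] = word_list(rev[t], word);
  }
  int npair = ii.size();
  LogicalVector res(npair);
  for (int p = 0; p < npair; ++p) {
    int a = ii[p] - 1, b = jj[p] - 1;
    bool pass = false;
    for (int strand = 0; strand < 2 && !pass; ++strand) {
      const std::vector<uint8_t> &q = fwd[a];
      const std::vector<uint8_t> &s = (strand == 0) ? fwd[b] : rev[b];
      std::vector<Ungapped> hits = ungapped_from_seeds(
        seeds_from_lists(fwd_w[a], (strand == 0) ? fwd_w[b] : rev_w[b]),
        q, s, word, match, mismatch, xdrop, 0);
      int strong = 0, total_len = 0;
      for (const Ungapped &h : hits) {
        int len = h.qe - h.qs + 1;
        total_len += len;
        if (h.score >= min_score) ++strong;
        if (len < w) continue;
        std::vector<char> mv(len);
        for (int t = 0; t < len; ++t)
          mv[t] = (q[h.qs + t] < 4 && q[h.qs + t] == s[h.ss + t]) ? 1 : 0;
        if (window_pass(mv, w, k)) { pass = true; break; }
      }
      // Gapped DP can only rescue a pair when an indel split one
      // homologous stretch across diagonals: several ungapped runs, at
      // least one strong, jointly long enough to span a window.
      bool need_dp = hits.size() >= 2 && strong >= 1 && total_len >= w;
      if (!pass && need_dp) {
        std::vector<SWHit> dp = sw_hits(q, s, match, mismatch, gap_open,
                                        gap_ext, min_score, max_hits);
        for (const SWHit &h : dp)
          if (window_pass(h.mv, w, k)) { pass = true; break; }
      }
    }
    res[p] = pass;
  }
  return res;
}

// Candidate read pairs for all-vs-all self-comparison: unordered pairs
// (i < j, 1-based) sharing at least one exact word on either orientation.
// [[Rcpp::export(name = ".cpp_candidate_pairs")]]
IntegerMatrix cpp_candidate_pairs(CharacterVector seqs, int word) {
  int nseq = seqs.size();
  std::unordered_map<uint64_t, std::vector<int>> fwd_idx, rev_idx;
  uint64_t mask = (word >= 32) ? ~0ULL : ((1ULL << (2 * word)) - 1);
  for (int t = 0; t < nseq; ++t) {
    std::vector<uint8_t> v = encode(as<std::string>(seqs[t]));
    std::vector<uint8_t> r = revcomp(v);
    for (int pass = 0; pass < 2; ++pass) {
      const std::vector<uint8_t> &u = pass == 0 ? v : r;
      auto &idx = pass == 0 ? fwd_idx : rev_idx;
      uint64_t key = 0; int run = 0; int last = -1;
      for (int i = 0; i < (int)u.size(); ++i) {
        if (u[i] > 3) { run = 0; key = 0; continue; }
        key = ((key << 2) | u[i]) & mask;
        if (++run >= word) {
          std::vector<int> &v2 = idx[key];
          if (v2.empty() || v2.back() != t) v2.push_back(t);
          (void)last;
        }
      }
    }
  }
  std::unordered_map<uint64_t, char> pairs;
  for (auto &kv : fwd_idx) {
    const std::vector<int> &ids = kv.second;
    // same-strand sharers
    for (size_t a = 0; a < ids.size(); ++a)
      for (size_t b = a + 1; b < ids.size(); ++b)
        pairs[((uint64_t)ids[a] << 32) | (uint64_t)ids[b]] = 1;
    // opposite-strand sharers
    auto it = rev_idx.find(kv.first);
    if (it != rev_idx.end()) {
      for (int a : ids)
        for (int b : it->second) {
          if (a == b) continue;
          int lo = std::min(a, b), hi = std::max(a, b);
          pairs[((uint64_t)lo << 32) | (uint64_t)hi] = 1;
        }
    }
  }
  IntegerMatrix out(pairs.size(), 2);
  int r = 0;
  for (auto &kv : pairs) {
    out(r, 0) = (int)(kv.first >> 32) + 1;
    out(r, 1) = (int)(kv.first & 0xffffffffULL) + 1;
    ++r;
  }
  return out;
}

// Exact sliding-window identity check for an R logical match vector.
// [[Rcpp::export(name = ".cpp_window_pass")]]
bool cpp_window_pass(LogicalVector match_vector, int w, int k) {
  std::vector<char> mv(match_vector.size());
  for (int i = 0; i < match_vector.size(); ++i)
    mv[i] = match_vector[i] == TRUE ? 1 : 0;
  return window_pass(mv, w, k);
}
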