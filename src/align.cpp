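#include <Rcpp.h>
#include <unordered_set>
#include <unordered_map>
#include <cstring>
using namespace Rcpp;

// Local alignment engine used by the detection and flank-comparison stages.
// Affine-gap Smith-Waterman (Gotoh) over a subject window, with iterative
// masking so that every sufficiently scoring local alignment is reported,
// not just the best one.  Tie-breaking is fully deterministic: best score,
// then smallest subject end, then smallest query end; traceback prefers
// diagonal, then gap-in-query (consume subject), then gap-in-subject.

static const int NEG_BIG = -1000000;

struct ScoreTable {
  int tab[128][128];
  void init_nt(int match, int mismatch) {
    for (int i = 0; i < 128; ++i)
      for (int j = 0; j < 128; ++j) tab[i][j] = NEG_BIG;
    const char *b = "ACGT";
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j)
        tab[(int)b[i]][(int)b[j]] = (i == j) ? match : mismatch;
    // N aligns but never counts as a match
    const char *bn = "ACGTN";
    for (int i = 0; i < 5; ++i) {
      tab[(int)'N'][(int)bn[i]] = mismatch;
      tab[(int)bn[i]][(int)'N'] = mismatch;
    }
  }
  void init_matrix(const IntegerMatrix &m, const std::string &alpha,
                   int mismatch_default) {
    for (int i = 0; i < 128; ++i)
      for (int j = 0; j < 128; ++j) tab[i][j] = NEG_BIG;
    size_t n = alpha.size();
    for (size_t i = 0; i < n; ++i)
      for (size_t j = 0; j < n; ++j)
        tab[(int)alpha[i]][(int)alpha[j]] = m(i, j);
    (void)mismatch_default;
  }
};

// One pass of Gotoh SW over (query, subject) honouring a subject mask.
// Returns best score and fills traceback endpoints.
struct SWResult {
  int score, qs, qe, ss, se, identical, aligned;
  bool found;
};

static SWResult sw_best(const std::string &q, const std::string &s,
                        const std::vector<char> &masked, const ScoreTable &S,
                        int gap_open, int gap_ext, bool n_never_identical) {
  int m = q.size(), n = s.size();
  // rolling score rows + one byte of traceback state per cell:
  //   bits 0-1: H source (0 stop, 1 diagonal, 2 E, 3 F)
  //   bit  2  : E opened from H (else extends E)
  //   bit  3  : F opened from H (else extends F)
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), Fprev(n + 1, NEG_BIG),
      Fcur(n + 1, NEG_BIG), Ecur(n + 1, NEG_BIG);
  std::vector<unsigned char> dir((size_t)(m + 1) * (n + 1), 0);
  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0;
    Ecur[0] = NEG_BIG;
    unsigned char *drow = &dir[(size_t)i * (n + 1)];
    for (int j = 1; j <= n; ++j) {
      int e_open = Hcur[j - 1] + gap_open + gap_ext;
      int e_ext = Ecur[j - 1] + gap_ext;
      int e = e_open >= e_ext ? e_open : e_ext;
      unsigned char eb = e_open >= e_ext ? 4 : 0;
      int f_open = Hprev[j] + gap_open + gap_ext;
      int f_ext = Fprev[j] + gap_ext;
      int f = f_open >= f_ext ? f_open : f_ext;
      unsigned char fb = f_open >= f_ext ? 8 : 0;
      int sub = masked[j - 1] ? NEG_BIG
                              : S.tab[(int)q[i - 1]][(int)s[j - 1]];
      int d = Hprev[j - 1] + sub;
      // priority on ties: diagonal, then E (gap in query), then F
      int h = d;
      unsigned char hb = 1;
      if (e > h) { h = e; hb = 2; }
      if (f > h) { h = f; hb = 3; }
      if (h <= 0) { h = 0; hb = 0; }
      Ecur[j] = e;
      Fcur[j] = f;
      Hcur[j] = h;
      drow[j] = hb | eb | fb;
      if (h > 0) {
        if (h > best) { best = h; bi = i; bj = j; }
        else if (h == best && (j < bj || (j == bj && i < bi))) {
          bi = i; bj = j;
        }
      }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }
  SWResult r;
  r.found = best > 0;
  r.score = best;
  if (!r.found) return r;
  // traceback over the stored per-cell choices
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  int identical = 0, aligned = 0;
  while (i > 0 && j > 0) {
    unsigned char c = dir[(size_t)i * (n + 1) + j];
    if (state == 0) {
      unsigned char hb = c & 3;
      if (hb == 0) break;
      if (hb == 1) {
        aligned++;
        if (q[i - 1] == s[j - 1] &&
            !(n_never_identical && q[i - 1] == 'N')) identical++;
        i--; j--;
      } else if (hb == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      aligned++;
      state = (c & 4) ? 0 : 1;
      j--;
    } else {
      aligned++;
      state = (c & 8) ? 0 : 2;
      i--;
    }
  }
  r.qs = i + 1; r.qe = bi; r.ss = j + 1; r.se = bj;
  r.identical = identical; r.aligned = aligned;
  return r;
}

static DataFrame hits_frame(std::vector<SWResult> &hits) {
  int n = hits.size();
  IntegerVector qs(n), qe(n), ss(n), se(n), ident(n), aln(n), sc(n);
  for (int i = 0; i < n; ++i) {
    qs[i] = hits[i].qs; qe[i] = hits[i].qe; ss[i] = hits[i].ss;
    se[i] = hits[i].se; ident[i] = hits[i].identical;
    aln[i] = hits[i].aligned; sc[i] = hits[i].score;
  }
  return DataFrame::create(_["q_start"] = qs, _["q_end"] = qe,
                           _["s_start"] = ss, _["s_end"] = se,
                           _["identical"] = ident, _["aligned"] = aln,
                           _["score"] = sc);
}

static DataFrame sw_all_hits(const std::string &q, const std::string &s,
                             const ScoreTable &S, int gap_open, int gap_ext,
                             int min_score, bool n_never_identical,
                             int max_hits) {
  std::vector<char> masked(s.size(), 0);
  std::vector<SWResult> hits;
  size_t cap = max_hits > 0 ? (size_t)max_hits : 10000;
  for (;;) {
    SWResult r = sw_best(q, s, masked, S, gap_open, gap_ext,
                         n_never_identical);
    if (!r.found || r.score < min_score) break;
    hits.push_back(r);
    if (hits.size() >= cap) break;
    for (int j = r.ss - 1; j < r.se; ++j) masked[j] = 1;
  }
  return hits_frame(hits);
}

// [[Rcpp::export]]
DataFrame cpp_sw_hits_nt(std::string query, std::string subject, int match,
                         int mismatch, int gap_open, int gap_ext,
                         int min_score, int max_hits = -1) {
  ScoreTable S;
  S.init_nt(match, mismatch);
  return sw_all_hits(query, subject, S, gap_open, gap_ext, min_score, true,
                     max_hits);
}

// [[Rcpp::export]]
DataFrame cpp_sw_hits_matrix(std::string query, std::string subject,
                             IntegerMatrix score_matrix, std::string alphabet,
                             int gap_open, int gap_ext, int min_score,
                             int max_hits = -1) {
  ScoreTable S;
  S.init_matrix(score_matrix, alphabet, -4);
  return sw_all_hits(query, subject, S, gap_open, gap_ext, min_score, false,
                     max_hits);
}

// Exact k-mer seed windows: merged subject intervals (1-based, closed) around
// positions sharing a k-mer with the query.  Non-ACGT k-mers are skipped.
// [[Rcpp::export]]
IntegerMatrix cpp_seed_windows(std::string query, std::string subject, int k,
                               int margin) {
  int m = query.size(), n = subject.size();
  std::unordered_set<uint64_t> kmers;
  auto code = [](char c) -> int {
    switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2;
                 case 'T': return 3; default: return -1; }
  };
  if (m >= k) {
    uint64_t h = 0, maskbits = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int run = 0;
    for (int i = 0; i < m; ++i) {
      int c = code(query[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & maskbits;
      if (++run >= k) kmers.insert(h);
    }
  }
  std::vector<std::pair<int,int>> iv;
  if (n >= k && !kmers.empty()) {
    uint64_t h = 0, maskbits = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int c = code(subject[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & maskbits;
      if (++run >= k && kmers.count(h)) {
        int s = std::max(1, i - k + 2 - margin);
        int e = std::min(n, i + 1 + margin);
        if (!iv.empty() && s <= iv.back().second + 1)
          iv.back().second = std::max(iv.back().second, e);
        else
          iv.emplace_back(s, e);
      }
    }
  }
  IntegerMatrix out(iv.size(), 2);
  for (size_t i = 0; i < iv.size(); ++i) {
    out(i, 0) = iv[i].first;
    out(i, 1) = iv[i].second;
  }
  return out;
}

// Protein seed windows over arbitrary alphabet (exact k-mer string matches).
// [[Rcpp::export]]
IntegerMatrix cpp_seed_windows_aa(std::string query, std::string subject,
                                  int k, int margin) {
  int m = query.size(), n = subject.size();
  std::unordered_set<std::string> kmers;
  for (int i = 0; i + k <= m; ++i) kmers.insert(query.substr(i, k));
  std::vector<std::pair<int,int>> iv;
  for (int i = 0; i + k <= n; ++i) {
    if (kmers.count(subject.substr(i, k))) {
      int s = std::max(1, i + 1 - margin);
      int e = std::min(n, i + k + margin);
      if (!iv.empty() && s <= iv.back().second + 1)
        iv.back().second = std::max(iv.back().second, e);
      else
        iv.emplace_back(s, e);
    }
  }
  IntegerMatrix out(iv.size(), 2);
  for (size_t i = 0; i < iv.size(); ++i) {
    out(i, 0) = iv[i].first;
    out(i, 1) = iv[i].second;
  }
  return out;
}

// Rho-independent terminator scan on one strand.
// A hit is an inverted repeat (stem min_stem..max_stem bp, loop
// min_loop..max_loop nt, at most max_mismatch non-Watson-Crick/non-GU pairs,
// G:U wobble allowed) whose 3' arm is followed within tail_gap_max nt by a
// U-rich tract (>= tail_min_t of the next tail_window bases are T).
// [[Rcpp::export]]
DataFrame cpp_find_terminators(std::string seq, int min_stem, int max_stem,
                               int min_loop, int max_loop, int max_mismatch,
                               int tail_gap_max, int tail_window,
                               int tail_min_t) {
  int n = seq.size();
  auto pair_ok = [](char a, char b) -> bool {
    return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
           (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
           (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
  };
  // prefix sums of T for O(1) tail counts
  std::vector<int> tcum(n + 1, 0);
  for (int i = 0; i < n; ++i) tcum[i + 1] = tcum[i] + (seq[i] == 'T');
  std::vector<int> st, en, stem, loop, mism;
  std::vector<double> tail;
  for (int a = 0; a < n; ++a) {
    for (int s = min_stem; s <= max_stem; ++s) {
      for (int l = min_loop; l <= max_loop; ++l) {
        int end = a + 2 * s + l; // one past right arm
        if (end > n) break;
        int mm = 0;
        bool bad = false;
        for (int j = 0; j < s; ++j) {
          char x = seq[a + j], y = seq[end - 1 - j];
          if (x == 'N' || y == 'N' || !pair_ok(x, y)) {
            // the outermost and innermost stem pairs must be real pairs;
            // the mismatch budget applies to interior positions only
            if (j == 0 || j == s - 1 || ++mm > max_mismatch) {
              bad = true;
              break;
            }
          }
        }
        if (bad) continue;
        // tail
        int best_t = -1;
        for (int g = 0; g <= tail_gap_max; ++g) {
          if (end + g + tail_window > n) break;
          int ct = tcum[end + g + tail_window] - tcum[end + g];
          if (ct > best_t) best_t = ct;
        }
        if (best_t < tail_min_t) continue;
        st.push_back(a + 1);
        en.push_back(end);
        stem.push_back(s);
        loop.push_back(l);
        mism.push_back(mm);
        tail.push_back((double)best_t / tail_window);
      }
    }
  }
  // keep one hit per (start,end): fewest mismatches, then longest stem,
  // then highest tail score; then drop hits strictly contained in another.
  int h = st.size();
  std::vector<int> keep;
  std::vector<char> dead(h, 0);
  for (int i = 0; i < h; ++i) {
    if (dead[i]) continue;
    for (int j = i + 1; j < h; ++j) {
      if (dead[j]) continue;
      if (st[i] == st[j] && en[i] == en[j]) {
        bool i_better = (mism[i] < mism[j]) ||
          (mism[i] == mism[j] && stem[i] > stem[j]) ||
          (mism[i] == mism[j] && stem[i] == stem[j] && tail[i] >= tail[j]);
        dead[i_better ? j : i] = 1;
        if (!i_better) break;
      }
    }
  }
  for (int i = 0; i < h; ++i) {
    if (dead[i]) continue;
    bool contained = false;
    for (int j = 0; j < h; ++j) {
      if (j == i || dead[j]) continue;
      if (st[j] <= st[i] && en[j] >= en[i] &&
          (en[j] - st[j]) > (en[i] - st[i])) { contained = true; break; }
    }
    if (!contained) keep.push_back(i);
  }
  int kk = keep.size();
  IntegerVector ost(kk), oen(kk), ostem(kk), oloop(kk), omism(kk);
  NumericVector otail(kk);
  for (int i = 0; i < kk; ++i) {
    int id = keep[i];
    ost[i] = st[id]; oen[i] = en[id]; ostem[i] = stem[id];
    oloop[i] = loop[id]; omism[i] = mism[id]; otail[i] = tail[id];
  }
  return DataFrame::create(_["start"] = ost, _["end"] = oen,
                           _["stem_len"] = ostem, _["loop_len"] = oloop,
                           _["mismatches"] = omism,
                           _["u_tail_score"] = otail);
}

// Exact k-mer seed matches as (query_pos, subject_pos, diagonal) triples,
// used to build diagonal-tight subject windows for flank comparison.
// [[Rcpp::export]]
IntegerMatrix cpp_seed_positions(std::string query, std::string subject,
                                 int k) {
  int m = query.size(), n = subject.size();
  auto code = [](char c) -> int {
    switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2;
                 case 'T': return 3; default: return -1; }
  };
  std::unordered_map<uint64_t, std::vector<int>> kmers;
  uint64_t maskbits = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  if (m >= k) {
    uint64_t h = 0;
    int run = 0;
    for (int i = 0; i < m; ++i) {
      int c = code(query[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & maskbits;
      if (++run >= k) kmers[h].push_back(i - k + 2); // 1-based start
    }
  }
  std::vector<int> qp, sp;
  if (n >= k && !kmers.empty()) {
    uint64_t h = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int c = code(subject[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & maskbits;
      if (++run >= k) {
        auto it = kmers.find(h);
        if (it != kmers.end()) {
          for (int q : it->second) {
            qp.push_back(q);
            sp.push_back(i - k + 2);
          }
        }
      }
    }
  }
  IntegerMatrix out(qp.size(), 3);
  for (size_t i = 0; i < qp.size(); ++i) {
    out(i, 0) = qp[i];
    out(i, 1) = sp[i];
    out(i, 2) = sp[i] - qp[i];
  }
  return out;
}
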