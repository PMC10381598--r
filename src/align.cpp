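#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// 4-bit IUPAC encoding: A=1, C=2, G=4, T/U=8; ambiguity codes are unions.
// Two bases "match" iff their code sets intersect.
static inline int iupac_bits(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': case 'U': case 'u': return 8;
    case 'R': case 'r': return 1 | 4;
    case 'Y': case 'y': return 2 | 8;
    case 'S': case 's': return 2 | 4;
    case 'W': case 'w': return 1 | 8;
    case 'K': case 'k': return 4 | 8;
    case 'M': case 'm': return 1 | 2;
    case 'B': case 'b': return 2 | 4 | 8;
    case 'D': case 'd': return 1 | 4 | 8;
    case 'H': case 'h': return 1 | 2 | 8;
    case 'V': case 'v': return 1 | 2 | 4;
    case 'N': case 'n': return 15;
    default: return 0; // gap or unknown: never matches
  }
}

static inline bool iupac_match(char a, char b) {
  return (iupac_bits(a) & iupac_bits(b)) != 0;
}

// [[Rcpp::export]]
IntegerVector cpp_iupac_mismatches(CharacterVector seqs, std::string pattern,
                                   bool from_end = false) {
  // Count IUPAC-aware mismatches of `pattern` anchored at the start (or end)
  // of each sequence. Sequences shorter than the pattern count the missing
  // positions as mismatches.
  int n = seqs.size(), plen = pattern.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    std::string s = as<std::string>(seqs[i]);
    int slen = s.size(), mm = 0;
    for (int k = 0; k < plen; ++k) {
      int pos = from_end ? slen - plen + k : k;
      if (pos < 0 || pos >= slen || !iupac_match(s[pos], pattern[k])) ++mm;
    }
    out[i] = mm;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Semi-global (overlap) affine-gap alignment, Gotoh three-state DP.
// Terminal gaps in either sequence are free; a gap of length L costs
// gap_open + L * gap_extend. Scores are integers so ties are exact.
//
// Tie-breaking (canonical traceback): end cell scanned over the bottom row
// (j = 0..m) then the right column (i = 0..n-1), keeping strictly greater
// scores; state preference M > F > E; gap states close (reopen from M/F or
// M/E) as early as possible. Identity = 100 * matches / columns over the
// traced path, which excludes terminal-gap columns by construction.
// ---------------------------------------------------------------------------

struct AlnResult { double identity; int matches; int columns; int score; };

static const int NEG = INT_MIN / 4;

static AlnResult gotoh_overlap(const std::string &a, const std::string &b,
                               int match, int mismatch, int gap_open, int gap_extend) {
  int n = a.size(), m = b.size();
  size_t W = m + 1;
  std::vector<int> M((n + 1) * W, NEG), E((n + 1) * W, NEG), F((n + 1) * W, NEG);
  M[0] = 0;
  for (int j = 1; j <= m; ++j) E[j] = 0;        // free leading gap in query
  for (int i = 1; i <= n; ++i) F[i * W] = 0;    // free leading gap in reference
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      size_t c = i * W + j, d = (i - 1) * W + (j - 1), u = (i - 1) * W + j, l = i * W + (j - 1);
      int s = iupac_match(a[i - 1], b[j - 1]) ? match : mismatch;
      int vd = std::max(M[d], std::max(E[d], F[d]));
      M[c] = s + vd;
      int mfl = std::max(M[l], F[l]);
      E[c] = std::max(E[l] - gap_extend, mfl - gap_open - gap_extend);
      int meu = std::max(M[u], E[u]);
      F[c] = std::max(F[u] - gap_extend, meu - gap_open - gap_extend);
    }
  }
  // end cell: bottom row first (j ascending), then right column (i ascending)
  int bi = n, bj = 0, best = NEG;
  for (int j = 0; j <= m; ++j) {
    size_t c = n * W + j;
    int v = std::max(M[c], std::max(E[c], F[c]));
    if (v > best) { best = v; bi = n; bj = j; }
  }
  for (int i = 0; i < n; ++i) {
    size_t c = i * W + m;
    int v = std::max(M[c], std::max(E[c], F[c]));
    if (v > best) { best = v; bi = i; bj = m; }
  }
  // traceback
  int i = bi, j = bj, matches = 0, columns = 0;
  size_t c = (size_t)i * W + j;
  int state; // 0=M, 1=E (gap in query, consume b), 2=F (gap in ref, consume a)
  if (M[c] >= E[c] && M[c] >= F[c]) state = 0;
  else if (F[c] >= E[c]) state = 2;
  else state = 1;
  while (i > 0 && j > 0) {
    c = (size_t)i * W + j;
    if (state == 0) {
      ++columns;
      if (iupac_match(a[i - 1], b[j - 1])) ++matches;
      size_t d = (size_t)(i - 1) * W + (j - 1);
      int vd = M[c] - (iupac_match(a[i - 1], b[j - 1]) ? match : mismatch);
      if (M[d] == vd) state = 0;
      else if (F[d] == vd) state = 2;
      else state = 1;
      --i; --j;
    } else if (state == 1) {
      ++columns;
      size_t l = (size_t)i * W + (j - 1);
      int reopen = E[c] + gap_open + gap_extend;
      if (M[l] == reopen) state = 0;
      else if (F[l] == reopen) state = 2;
      else state = 1; // continue gap
      --j;
    } else {
      ++columns;
      size_t u = (size_t)(i - 1) * W + j;
      int reopen = F[c] + gap_open + gap_extend;
      if (M[u] == reopen) state = 0;
      else if (E[u] == reopen) state = 1;
      else state = 2;
      --i;
    }
  }
  AlnResult r;
  r.matches = matches; r.columns = columns; r.score = best;
  r.identity = columns > 0 ? 100.0 * matches / columns : 0.0;
  return r;
}

// [[Rcpp::export]]
List cpp_percent_identity(std::string a, std::string b,
                          int match = 1, int mismatch = -1,
                          int gap_open = 2, int gap_extend = 1) {
  AlnResult r = gotoh_overlap(a, b, match, mismatch, gap_open, gap_extend);
  return List::create(_["identity"] = r.identity, _["matches"] = r.matches,
                      _["columns"] = r.columns, _["score"] = r.score);
}

// [[Rcpp::export]]
NumericMatrix cpp_percent_identity_many(std::string query, CharacterVector refs,
                                        int match = 1, int mismatch = -1,
                                        int gap_open = 2, int gap_extend = 1) {
  int n = refs.size();
  NumericMatrix out(n, 3);
  colnames(out) = CharacterVector::create("identity", "score", "columns");
  for (int i = 0; i < n; ++i) {
    AlnResult r = gotoh_overlap(query, as<std::string>(refs[i]),
                                match, mismatch, gap_open, gap_extend);
    out(i, 0) = r.identity;
    out(i, 1) = r.score;
    out(i, 2) = r.columns;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Paired-end read merging: best ungapped overlap of revcomp(r2) against r1.
// Candidate layouts place rc(r2) starting at offset s in r1 coordinates
// (s = 0..len1 - min_overlap); overlap = min(len1 - s, len2). The accepted
// candidate maximises (overlap - 2 * mismatches), ties to the longer
// overlap; it must satisfy overlap >= min_overlap and
// mismatches / overlap <= max_mismatch_rate. Overlap disagreements resolve
// to the r1 base. Returns NA for pairs with no acceptable overlap.
// ---------------------------------------------------------------------------

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g'; case 'g': return 'c'; case 't': return 'a';
    case 'R': return 'Y'; case 'Y': return 'R'; case 'S': return 'S'; case 'W': return 'W';
    case 'K': return 'M'; case 'M': return 'K'; case 'B': return 'V'; case 'V': return 'B';
    case 'D': return 'H'; case 'H': return 'D'; case 'N': return 'N';
    default: return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp(r[i]);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_merge_pairs(CharacterVector r1, CharacterVector r2,
                                int min_overlap, double max_mismatch_rate) {
  int n = r1.size();
  if (r2.size() != n) stop("r1 and r2 must have equal length");
  CharacterVector out(n);
  for (int k = 0; k < n; ++k) {
    std::string s1 = as<std::string>(r1[k]);
    std::string s2 = revcomp(as<std::string>(r2[k]));
    int L1 = s1.size(), L2 = s2.size();
    int best_score = INT_MIN, best_s = -1, best_ov = -1;
    for (int s = 0; s <= L1 - min_overlap; ++s) {
      int ov = std::min(L1 - s, L2);
      if (ov < min_overlap) break;
      int mm = 0;
      for (int t = 0; t < ov; ++t) if (!iupac_match(s1[s + t], s2[t])) ++mm;
      if ((double)mm / ov > max_mismatch_rate) continue;
      int score = ov - 2 * mm;
      if (score > best_score || (score == best_score && ov > best_ov)) {
        best_score = score; best_s = s; best_ov = ov;
      }
    }
    if (best_s < 0) { out[k] = NA_STRING; continue; }
    std::string merged = s1.substr(0, best_s + best_ov); // r1 wins in overlap
    if (best_ov < L2) merged += s2.substr(best_ov);
    out[k] = merged;
  }
  return out;
}

// ---------------------------------------------------------------------------
// De novo two-parent chimera scan over abundance-sorted clusters.
// Cluster i (candidates evaluated in decreasing abundance order) is flagged
// when two distinct earlier, unflagged clusters A != B with abundance >=
// parent_ratio * abundance(i) exist together with a breakpoint k such that
// the prefix [0,k) matches A and the suffix [k,L) matches B at identity >=
// parent_identity (ungapped, left/right anchored; overhangs mismatch), while
// the best full-length identity of i to any single candidate parent stays
// below parent_identity.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_chimera_scan(CharacterVector seqs, NumericVector abundance,
                               double parent_identity, double parent_ratio) {
  int n = seqs.size();
  LogicalVector flagged(n);
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    int L = ss[i].size();
    if (L < 2) continue;
    std::vector<int> parents;
    for (int j = 0; j < i; ++j)
      if (!flagged[j] && abundance[j] >= parent_ratio * abundance[i]) parents.push_back(j);
    if (parents.size() < 2) continue;
    // per-breakpoint best prefix/suffix identity over parents (track top-2 ids)
    std::vector<double> bestPref(L + 1, -1), bestSuf(L + 1, -1), secPref(L + 1, -1), secSuf(L + 1, -1);
    std::vector<int> bestPrefIdx(L + 1, -1), bestSufIdx(L + 1, -1);
    double maxFull = -1;
    for (size_t pi = 0; pi < parents.size(); ++pi) {
      const std::string &p = ss[parents[pi]];
      int Lp = p.size();
      // prefix matches (left-anchored) and suffix matches (right-anchored)
      std::vector<int> pref(L + 1, 0), suf(L + 1, 0);
      for (int q = 0; q < L; ++q)
        pref[q + 1] = pref[q] + ((q < Lp && iupac_match(ss[i][q], p[q])) ? 1 : 0);
      for (int r = 0; r < L; ++r) {
        int ci = L - 1 - r, pj = Lp - 1 - r;
        suf[r + 1] = suf[r] + ((pj >= 0 && iupac_match(ss[i][ci], p[pj])) ? 1 : 0);
      }
      double full = (double)pref[L] / std::max(L, Lp);
      if (full > maxFull) maxFull = full;
      for (int k = 1; k < L; ++k) {
        double pid = (double)pref[k] / k;
        double sid = (double)suf[L - k] / (L - k);
        if (pid > bestPref[k]) { secPref[k] = bestPref[k]; bestPref[k] = pid; bestPrefIdx[k] = parents[pi]; }
        else if (pid > secPref[k]) secPref[k] = pid;
        if (sid > bestSuf[k]) { secSuf[k] = bestSuf[k]; bestSuf[k] = sid; bestSufIdx[k] = parents[pi]; }
        else if (sid > secSuf[k]) secSuf[k] = sid;
      }
    }
    if (maxFull >= parent_identity) continue;
    for (int k = 1; k < L; ++k) {
      bool segs = bestPref[k] >= parent_identity && bestSuf[k] >= parent_identity;
      if (!segs) continue;
      bool distinct = bestPrefIdx[k] != bestSufIdx[k] ||
                      secPref[k] >= parent_identity || secSuf[k] >= parent_identity;
      if (distinct) { flagged[i] = true; break; }
    }
  }
  return flagged;
}
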