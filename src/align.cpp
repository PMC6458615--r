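// Dynamic-programming alignment kernels shared by the orthology, ANI,
// BSR and center-star MSA stages. Linear gap penalties throughout.
#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

struct Aln {
  double score;
  int n_match, n_mismatch, n_gap_cols, columns;
  std::string a_aln, b_aln;
};

// Global Needleman-Wunsch, linear gap. Move preference on score ties is
// diagonal > up (gap in b) > left (gap in a): deterministic traceback.
static Aln nw_align(const std::string& a, const std::string& b,
                    double match, double mismatch, double gap,
                    bool traceback) {
  const size_t m = a.size(), n = b.size();
  std::vector<double> prev(n + 1), cur(n + 1);
  std::vector<char> tb;
  if (traceback) tb.assign((m + 1) * (n + 1), '0');
  for (size_t j = 0; j <= n; ++j) {
    prev[j] = gap * static_cast<double>(j);
    if (traceback && j > 0) tb[j] = 'L';
  }
  for (size_t i = 1; i <= m; ++i) {
    cur[0] = gap * static_cast<double>(i);
    if (traceback) tb[i * (n + 1)] = 'U';
    for (size_t j = 1; j <= n; ++j) {
      double sdiag = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      double sup = prev[j] + gap;
      double sleft = cur[j - 1] + gap;
      double best = sdiag;
      char dir = 'D';
      if (sup > best) { best = sup; dir = 'U'; }
      if (sleft > best) { best = sleft; dir = 'L'; }
      cur[j] = best;
      if (traceback) tb[i * (n + 1) + j] = dir;
    }
    std::swap(prev, cur);
  }
  Aln r;
  r.score = prev[n];
  r.n_match = r.n_mismatch = r.n_gap_cols = r.columns = 0;
  if (traceback) {
    size_t i = m, j = n;
    std::string aa, bb;
    while (i > 0 || j > 0) {
      char d = tb[i * (n + 1) + j];
      if (d == 'D') {
        aa.push_back(a[i - 1]); bb.push_back(b[j - 1]);
        if (a[i - 1] == b[j - 1]) ++r.n_match; else ++r.n_mismatch;
        --i; --j;
      } else if (d == 'U') {
        aa.push_back(a[i - 1]); bb.push_back('-');
        ++r.n_gap_cols; --i;
      } else {
        aa.push_back('-'); bb.push_back(b[j - 1]);
        ++r.n_gap_cols; --j;
      }
    }
    std::reverse(aa.begin(), aa.end());
    std::reverse(bb.begin(), bb.end());
    r.a_aln = aa; r.b_aln = bb;
    r.columns = r.n_match + r.n_mismatch + r.n_gap_cols;
  }
  return r;
}

// Banded global alignment around the main diagonal; the band is widened by
// the length difference so the corner stays reachable. Exact whenever the
// optimal path stays within the band (always true for substitution-
// dominated divergence with band >= the number of indels).
static Aln nw_banded(const std::string& a, const std::string& b,
                     double match, double mismatch, double gap,
                     int band, bool traceback) {
  const int m = static_cast<int>(a.size());
  const int n = static_cast<int>(b.size());
  int w1 = band + std::max(0, m - n);  // j >= i - w1
  int w2 = band + std::max(0, n - m);  // j <= i + w2
  const int width = w1 + w2 + 1;
  const double NEG = -1e18;
  std::vector<double> prev(width, NEG), cur(width, NEG);
  std::vector<char> tb;
  if (traceback) tb.assign(static_cast<size_t>(m + 1) * width, 'X');
  // col index c stores j = i - w1 + c
  for (int c = 0; c < width; ++c) {
    int j = -w1 + c;
    if (j >= 0 && j <= n) {
      prev[c] = gap * j;
      if (traceback) tb[c] = (j == 0) ? '0' : 'L';
    }
  }
  for (int i = 1; i <= m; ++i) {
    std::fill(cur.begin(), cur.end(), NEG);
    for (int c = 0; c < width; ++c) {
      int j = i - w1 + c;
      if (j < 0 || j > n) continue;
      double best = NEG; char dir = 'X';
      if (j >= 1 && prev[c] > NEG / 2) { // diag: (i-1, j-1) -> col c
        double s = prev[c] + (a[i - 1] == b[j - 1] ? match : mismatch);
        if (s > best) { best = s; dir = 'D'; }
      }
      if (c + 1 < width && prev[c + 1] > NEG / 2) { // up: (i-1, j) -> c+1
        double s = prev[c + 1] + gap;
        if (s > best) { best = s; dir = 'U'; }
      }
      if (c - 1 >= 0 && j >= 1 && cur[c - 1] > NEG / 2) { // left
        double s = cur[c - 1] + gap;
        if (s > best) { best = s; dir = 'L'; }
      }
      cur[c] = best;
      if (traceback) tb[static_cast<size_t>(i) * width + c] = dir;
    }
    std::swap(prev, cur);
  }
  Aln r;
  const int cend = n - m + w1;
  r.score = prev[cend];
  r.n_match = r.n_mismatch = r.n_gap_cols = r.columns = 0;
  if (traceback) {
    int i = m, c = cend;
    std::string aa, bb;
    while (i > 0 || (i - w1 + c) > 0) {
      char d = tb[static_cast<size_t>(i) * width + c];
      int j = i - w1 + c;
      if (d == 'D') {
        aa.push_back(a[i - 1]); bb.push_back(b[j - 1]);
        if (a[i - 1] == b[j - 1]) ++r.n_match; else ++r.n_mismatch;
        --i;
      } else if (d == 'U') {
        aa.push_back(a[i - 1]); bb.push_back('-');
        ++r.n_gap_cols; --i; ++c;
      } else if (d == 'L') {
        aa.push_back('-'); bb.push_back(b[j - 1]);
        ++r.n_gap_cols; --c;
      } else {
        break; // unreachable for a valid band
      }
    }
    std::reverse(aa.begin(), aa.end());
    std::reverse(bb.begin(), bb.end());
    r.a_aln = aa; r.b_aln = bb;
    r.columns = r.n_match + r.n_mismatch + r.n_gap_cols;
  }
  return r;
}

static Aln nw_dispatch(const std::string& a, const std::string& b,
                       double match, double mismatch, double gap,
                       int band, bool traceback) {
  if (band < 0) return nw_align(a, b, match, mismatch, gap, traceback);
  return nw_banded(a, b, match, mismatch, gap, band, traceback);
}

// [[Rcpp::export]]
List cpp_align_pair(std::string a, std::string b,
                    double match, double mismatch, double gap,
                    int band = -1) {
  Aln r = nw_dispatch(a, b, match, mismatch, gap, band, true);
  double identity = r.columns > 0 ?
    static_cast<double>(r.n_match) / r.columns : 0.0;
  return List::create(_["score"] = r.score,
                      _["identity"] = identity,
                      _["aligned_length"] = r.columns,
                      _["n_match"] = r.n_match,
                      _["a_aln"] = r.a_aln,
                      _["b_aln"] = r.b_aln);
}

// Symmetric matrix of pairwise global alignment scores (score only).
// [[Rcpp::export]]
NumericMatrix cpp_score_matrix(CharacterVector seqs,
                               double match, double mismatch, double gap,
                               int band = -1) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = match * static_cast<double>(s[i].size());
    for (int j = i + 1; j < n; ++j) {
      Aln r = nw_dispatch(s[i], s[j], match, mismatch, gap, band, false);
      out(i, j) = r.score;
      out(j, i) = r.score;
    }
  }
  return out;
}

// ---- k-mer machinery (5-bit packed, works for protein and DNA) ----

static bool encode_kmers(const std::string& s, int k,
                         std::vector<uint64_t>& out) {
  out.clear();
  if (static_cast<int>(s.size()) < k) return false;
  const uint64_t mask = (k * 5 >= 64) ? ~0ULL : ((1ULL << (k * 5)) - 1);
  uint64_t cur = 0;
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[i];
    int code;
    if (c >= 'A' && c <= 'Z') code = c - 'A';
    else if (c == '*') code = 26;
    else { run = 0; cur = 0; continue; }
    cur = ((cur << 5) | static_cast<uint64_t>(code)) & mask;
    if (++run >= k) out.push_back(cur);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return !out.empty();
}

// Inverted k-mer index over a sequence set: unique k-mer -> member indices.
static void build_kmer_index(const std::vector<std::vector<uint64_t> >& kmers,
                             std::unordered_map<uint64_t, std::vector<int> >& idx) {
  idx.clear();
  for (size_t j = 0; j < kmers.size(); ++j)
    for (size_t t = 0; t < kmers[j].size(); ++t)
      idx[kmers[j][t]].push_back(static_cast<int>(j));
}

// For one query k-mer set, count shared unique k-mers against every indexed
// sequence and return the indices meeting min_shared.
static void candidates_for(const std::vector<uint64_t>& q,
                           const std::unordered_map<uint64_t, std::vector<int> >& idx,
                           int nb, int min_shared, std::vector<int>& out) {
  std::vector<int> counts(nb, 0);
  for (size_t t = 0; t < q.size(); ++t) {
    std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
      idx.find(q[t]);
    if (it == idx.end()) continue;
    for (size_t h = 0; h < it->second.size(); ++h) ++counts[it->second[h]];
  }
  out.clear();
  for (int j = 0; j < nb; ++j) if (counts[j] >= min_shared) out.push_back(j);
}

// All-vs-all best hits between two sequence sets with a shared-k-mer
// prefilter. Pairs sharing fewer than min_shared k-mers are never aligned
// (treated as no hit). Ties on score keep the smallest index, so callers
// pass sequences sorted by identifier to get the lexicographic tie-break.
// [[Rcpp::export]]
List cpp_best_hits(CharacterVector A, CharacterVector B,
                   double match, double mismatch, double gap,
                   int k, int min_shared) {
  const int na = A.size(), nb = B.size();
  std::vector<std::string> sa(na), sb(nb);
  std::vector<std::vector<uint64_t> > ka(na), kb(nb);
  for (int i = 0; i < na; ++i) { sa[i] = as<std::string>(A[i]); encode_kmers(sa[i], k, ka[i]); }
  for (int j = 0; j < nb; ++j) { sb[j] = as<std::string>(B[j]); encode_kmers(sb[j], k, kb[j]); }
  std::unordered_map<uint64_t, std::vector<int> > idx;
  build_kmer_index(kb, idx);

  IntegerVector bestA(na, 0), bestB(nb, 0);
  NumericVector scoreA(na, NA_REAL), scoreB(nb, NA_REAL);
  NumericVector identA(na, NA_REAL), identB(nb, NA_REAL);

  std::vector<int> cand;
  for (int i = 0; i < na; ++i) {
    if (min_shared > 0) {
      candidates_for(ka[i], idx, nb, min_shared, cand);
    } else {
      cand.resize(nb);
      for (int j = 0; j < nb; ++j) cand[j] = j;
    }
    for (size_t c = 0; c < cand.size(); ++c) {
      int j = cand[c];
      Aln r = nw_align(sa[i], sb[j], match, mismatch, gap, false);
      if (bestA[i] == 0 || r.score > scoreA[i]) {
        bestA[i] = j + 1; scoreA[i] = r.score;
      }
      if (bestB[j] == 0 || r.score > scoreB[j]) {
        bestB[j] = i + 1; scoreB[j] = r.score;
      }
    }
  }
  // identity is only needed where an RBH edge is possible: align mutual
  // best pairs once more with traceback
  for (int i = 0; i < na; ++i) {
    int j = bestA[i] - 1;
    if (j < 0 || bestB[j] != i + 1) continue;
    Aln r = nw_align(sa[i], sb[j], match, mismatch, gap, true);
    double id = r.columns > 0 ?
      static_cast<double>(r.n_match) / r.columns : 0.0;
    identA[i] = id;
    identB[j] = id;
  }
  return List::create(
    _["best_a"] = bestA, _["score_a"] = scoreA, _["identity_a"] = identA,
    _["best_b"] = bestB, _["score_b"] = scoreB, _["identity_b"] = identB);
}

// Best alignment score of each query against a gene set (for BSR).
// Returns the best score per query (0 when no pair passes the prefilter).
// [[Rcpp::export]]
NumericVector cpp_best_scores(CharacterVector queries, CharacterVector genes,
                              double match, double mismatch, double gap,
                              int k, int min_shared) {
  const int nq = queries.size(), ng = genes.size();
  std::vector<std::string> sq(nq), sg(ng);
  std::vector<std::vector<uint64_t> > kq(nq), kg(ng);
  for (int i = 0; i < nq; ++i) { sq[i] = as<std::string>(queries[i]); encode_kmers(sq[i], k, kq[i]); }
  for (int j = 0; j < ng; ++j) { sg[j] = as<std::string>(genes[j]); encode_kmers(sg[j], k, kg[j]); }
  std::unordered_map<uint64_t, std::vector<int> > idx;
  build_kmer_index(kg, idx);
  NumericVector out(nq, 0.0);
  std::vector<int> cand;
  for (int i = 0; i < nq; ++i) {
    if (min_shared > 0) {
      candidates_for(kq[i], idx, ng, min_shared, cand);
    } else {
      cand.resize(ng);
      for (int j = 0; j < ng; ++j) cand[j] = j;
    }
    bool any = false;
    double best = 0.0;
    for (size_t c = 0; c < cand.size(); ++c) {
      Aln r = nw_align(sq[i], sg[cand[c]], match, mismatch, gap, false);
      if (!any || r.score > best) { best = r.score; any = true; }
    }
    out[i] = any ? best : 0.0;
  }
  return out;
}

// ---- ANI fragment alignment ----

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// Banded alignment of a fragment against a subject window (free end gaps in
// the window), then trimmed to the maximal-scoring contiguous segment of the
// alignment path (the local alignment a fragment-based ANI search reports).
// Identity counts exclude ambiguous columns; fragment coverage is the
// number of fragment bases inside the retained segment. Band is centered on
// diagonal `off` (fragment position i expected at window position i + off).
static bool banded_semiglobal(const std::string& f, const std::string& w,
                              int off, int band,
                              double match, double mismatch, double gap,
                              int& n_match, int& n_mismatch, int& n_ambig,
                              int& frag_covered, double& score) {
  const int m = static_cast<int>(f.size());
  const int n = static_cast<int>(w.size());
  const int width = 2 * band + 1;
  const double NEG = -1e18;
  std::vector<double> prev(width, NEG), cur(width, NEG);
  std::vector<char> tb(static_cast<size_t>(m + 1) * width, 'X');
  // row i stores j in [i + off - band, i + off + band]; col index = j - (i + off - band)
  // row 0: free leading window gap -> D[0][j] = 0 for valid j
  for (int c = 0; c < width; ++c) {
    int j = 0 + off - band + c;
    if (j >= 0 && j <= n) { prev[c] = 0.0; tb[c] = (j == 0) ? '0' : 'S'; } // S = skip window prefix
  }
  for (int i = 1; i <= m; ++i) {
    std::fill(cur.begin(), cur.end(), NEG);
    for (int c = 0; c < width; ++c) {
      int j = i + off - band + c;
      if (j < 0 || j > n) continue;
      double best = NEG; char dir = 'X';
      // diagonal: prev row, j-1 -> col index (j-1) - ((i-1)+off-band) = c
      if (j >= 1 && prev[c] > NEG / 2) {
        double s = prev[c] + (f[i - 1] == w[j - 1] ? match : mismatch);
        if (s > best) { best = s; dir = 'D'; }
      }
      // up: gap in window (consume fragment char): prev row, same j -> col c+1
      if (c + 1 < width && prev[c + 1] > NEG / 2) {
        double s = prev[c + 1] + gap;
        if (s > best) { best = s; dir = 'U'; }
      }
      // left: gap in fragment: cur row, j-1 -> col c-1
      if (c - 1 >= 0 && j >= 1 && cur[c - 1] > NEG / 2) {
        double s = cur[c - 1] + gap;
        if (s > best) { best = s; dir = 'L'; }
      }
      cur[c] = best;
      tb[static_cast<size_t>(i) * width + c] = dir;
    }
    std::swap(prev, cur);
  }
  // free trailing window gap: best over last row
  int bestc = -1;
  double best = NEG;
  for (int c = 0; c < width; ++c) {
    int j = m + off - band + c;
    if (j < 0 || j > n) continue;
    if (prev[c] > best) { best = prev[c]; bestc = c; }
  }
  if (bestc < 0 || best < NEG / 2) return false;
  score = best;
  // walk the path collecting per-column (score delta, kind)
  std::vector<double> col_score;
  std::vector<char> col_kind; // 'M' match, 'X' mismatch, 'N' ambiguous,
                              // 'G' gap column
  std::vector<char> col_frag; // 1 if the column consumes a fragment base
  int i = m, c = bestc;
  while (i > 0) {
    char d = tb[static_cast<size_t>(i) * width + c];
    if (d == 'D') {
      int j = i + off - band + c;
      int fa = base_code(f[i - 1]), wb = base_code(w[j - 1]);
      if (fa < 0 || wb < 0) {
        col_score.push_back(mismatch); col_kind.push_back('N');
      } else if (fa == wb) {
        col_score.push_back(match); col_kind.push_back('M');
      } else {
        col_score.push_back(mismatch); col_kind.push_back('X');
      }
      col_frag.push_back(1);
      --i; // c unchanged
    } else if (d == 'U') {
      col_score.push_back(gap); col_kind.push_back('G'); col_frag.push_back(1);
      --i; ++c;
    } else if (d == 'L') {
      col_score.push_back(gap); col_kind.push_back('G'); col_frag.push_back(0);
      --c;
    } else {
      return false;
    }
  }
  // maximal-sum contiguous segment (columns are in reverse order; contiguity
  // is direction-independent)
  size_t ncol = col_score.size();
  double run = 0, bestsum = -1.0;
  size_t run_start = 0, seg_lo = 0, seg_hi = 0; // [lo, hi)
  for (size_t t = 0; t < ncol; ++t) {
    if (run <= 0) { run = 0; run_start = t; }
    run += col_score[t];
    if (run > bestsum) { bestsum = run; seg_lo = run_start; seg_hi = t + 1; }
  }
  n_match = n_mismatch = n_ambig = 0;
  frag_covered = 0;
  if (bestsum <= 0) return true; // nothing alignable; zero coverage
  for (size_t t = seg_lo; t < seg_hi; ++t) {
    if (col_kind[t] == 'M') ++n_match;
    else if (col_kind[t] == 'X') ++n_mismatch;
    else if (col_kind[t] == 'N') ++n_ambig;
    frag_covered += col_frag[t];
  }
  return true;
}

// Cut query contigs into consecutive fragments, seed each fragment to its
// best diagonal in the subject via shared k-mers, align within a band, and
// report per-fragment identity (ACGT columns only) and coverage (aligned
// fragment fraction). Fragments with no seed are aligned by full-width DP
// only when the subject is at most full_dp_limit bases; otherwise unused.
// [[Rcpp::export]]
DataFrame cpp_ani_fragments(CharacterVector query_contigs,
                            CharacterVector subject_contigs,
                            int fragment_length, int kmer, int band,
                            double match, double mismatch, double gap,
                            int full_dp_limit) {
  std::vector<std::string> subj(subject_contigs.size());
  size_t subj_total = 0;
  for (int i = 0; i < subject_contigs.size(); ++i) {
    subj[i] = as<std::string>(subject_contigs[i]);
    subj_total += subj[i].size();
  }
  // k-mer index of the subject (2-bit encoding, ambiguous bases break runs)
  const uint64_t mask = (1ULL << (2 * kmer)) - 1;
  std::unordered_map<uint64_t, std::vector<uint64_t> > index;
  for (size_t s = 0; s < subj.size(); ++s) {
    uint64_t cur = 0; int run = 0;
    for (size_t p = 0; p < subj[s].size(); ++p) {
      int b = base_code(subj[s][p]);
      if (b < 0) { run = 0; cur = 0; continue; }
      cur = ((cur << 2) | static_cast<uint64_t>(b)) & mask;
      if (++run >= kmer)
        index[cur].push_back((static_cast<uint64_t>(s) << 40) |
                             static_cast<uint64_t>(p - kmer + 1));
    }
  }

  std::vector<double> identity, coverage;
  std::vector<int> used_contig, frag_index;
  for (int qc = 0; qc < query_contigs.size(); ++qc) {
    std::string q = as<std::string>(query_contigs[qc]);
    int n_frag = static_cast<int>(q.size()) / fragment_length;
    for (int fi = 0; fi < n_frag; ++fi) {
      std::string frag = q.substr(static_cast<size_t>(fi) * fragment_length,
                                  fragment_length);
      // vote per (subject contig, diagonal)
      std::unordered_map<int64_t, int> votes;
      uint64_t cur = 0; int run = 0;
      for (size_t p = 0; p < frag.size(); ++p) {
        int b = base_code(frag[p]);
        if (b < 0) { run = 0; cur = 0; continue; }
        cur = ((cur << 2) | static_cast<uint64_t>(b)) & mask;
        if (run + 1 >= kmer) {
          ++run;
          std::unordered_map<uint64_t, std::vector<uint64_t> >::iterator it =
            index.find(cur);
          if (it != index.end()) {
            size_t fpos = p - kmer + 1;
            for (size_t h = 0; h < it->second.size(); ++h) {
              int64_t sc = static_cast<int64_t>(it->second[h] >> 40);
              int64_t sp = static_cast<int64_t>(it->second[h] & ((1ULL << 40) - 1));
              int64_t diag = sp - static_cast<int64_t>(fpos);
              votes[(sc << 44) ^ (diag + (1LL << 42))] += 1;
            }
          }
        } else ++run;
      }
      int best_votes = 0; int64_t best_key = 0;
      for (std::unordered_map<int64_t, int>::iterator it = votes.begin();
           it != votes.end(); ++it) {
        if (it->second > best_votes ||
            (it->second == best_votes && best_votes > 0 && it->first < best_key)) {
          best_votes = it->second; best_key = it->first;
        }
      }
      bool ok = false;
      int nm = 0, nx = 0, namb = 0, ncov = 0; double sc_ = 0.0;
      if (best_votes > 0) {
        int scontig = static_cast<int>(best_key >> 44);
        int64_t diag = (best_key ^ (static_cast<int64_t>(scontig) << 44)) -
                       (1LL << 42);
        const std::string& S = subj[scontig];
        int64_t wstart = diag - band;
        if (wstart < 0) wstart = 0;
        int64_t wend = diag + fragment_length + band;
        if (wend > static_cast<int64_t>(S.size())) wend = S.size();
        if (wend > wstart) {
          std::string win = S.substr(wstart, wend - wstart);
          int off = static_cast<int>(diag - wstart);
          ok = banded_semiglobal(frag, win, off, band, match, mismatch, gap,
                                 nm, nx, namb, ncov, sc_);
        }
      } else if (subj_total <= static_cast<size_t>(full_dp_limit)) {
        // full-width DP against each contig, keep the best score
        double bs = -1e18; int bm = 0, bx = 0, ba = 0, bc = 0; bool bok = false;
        for (size_t s = 0; s < subj.size(); ++s) {
          int nm2, nx2, na2, nc2; double s2;
          int wide = static_cast<int>(
            std::max(subj[s].size(), frag.size()));
          if (banded_semiglobal(frag, subj[s], 0, wide, match, mismatch, gap,
                                nm2, nx2, na2, nc2, s2) && s2 > bs) {
            bs = s2; bm = nm2; bx = nx2; ba = na2; bc = nc2; bok = true;
          }
        }
        if (bok) { ok = true; nm = bm; nx = bx; namb = ba; ncov = bc; sc_ = bs; }
      }
      if (ok && nm + nx > 0) {
        identity.push_back(static_cast<double>(nm) / (nm + nx));
        coverage.push_back(static_cast<double>(ncov) / fragment_length);
      } else {
        identity.push_back(NA_REAL);
        coverage.push_back(0.0);
      }
      used_contig.push_back(qc + 1);
      frag_index.push_back(fi + 1);
    }
  }
  return DataFrame::create(_["contig"] = used_contig,
                           _["fragment"] = frag_index,
                           _["identity"] = identity,
                           _["coverage"] = coverage);
}
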