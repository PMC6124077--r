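#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

static inline char comp_base(char b) {
  switch (b) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    case 'N': return 'N'; case 'n': return 'n';
    default:  return 'N';
  }
}

static std::string revcomp_one(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) out[i] = comp_base(out[i]);
  return out;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(seqs[i])) { out[i] = NA_STRING; continue; }
    out[i] = revcomp_one(as<std::string>(seqs[i]));
  }
  return out;
}

// BWA-style 3' quality trim: keep prefix 1..p where p maximises
// sum_{i=p+1}^{L} (q_threshold - q_i); ties resolved toward the longest
// kept prefix, so reads at or above threshold are untouched.
// Returns kept length per read. Qualities are Phred+33.
// [[Rcpp::export]]
IntegerVector quality_trim_length_cpp(CharacterVector quals, int q_threshold) {
  R_xlen_t n = quals.size();
  IntegerVector out(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    const char* q = CHAR(STRING_ELT(quals, r));
    int L = (int) std::strlen(q);
    int best_pos = L;
    long best_sum = 0, s = 0;
    for (int i = L - 1; i >= 0; --i) {
      s += q_threshold - (q[i] - 33);
      if (s > best_sum) { best_sum = s; best_pos = i; }
    }
    out[r] = best_pos;
  }
  return out;
}

static int count_mismatch_prefix(const char* s, int L, const std::string& pat) {
  int m = (int) pat.size();
  if (m > L) return -1;
  int mm = 0;
  for (int i = 0; i < m; ++i) if (s[i] != pat[i]) ++mm;
  return mm;
}

static int count_mismatch_suffix(const char* s, int L, const std::string& pat) {
  int m = (int) pat.size();
  if (m > L) return -1;
  int mm = 0, off = L - m;
  for (int i = 0; i < m; ++i) if (s[off + i] != pat[i]) ++mm;
  return mm;
}

// Remove full-length occurrences of each pattern at the 5' end (pattern as
// given) and at the 3' end (reverse complement of the pattern), allowing
// max_error_rate mismatches per pattern length. Applied to every pattern in
// order; one removal per end per pattern.
// [[Rcpp::export]]
List trim_end_patterns_cpp(CharacterVector seqs, CharacterVector quals,
                           CharacterVector patterns, double max_error_rate) {
  R_xlen_t n = seqs.size();
  int npat = patterns.size();
  std::vector<std::string> pats(npat), pats_rc(npat);
  std::vector<int> allow(npat);
  for (int p = 0; p < npat; ++p) {
    pats[p] = as<std::string>(patterns[p]);
    pats_rc[p] = revcomp_one(pats[p]);
    allow[p] = (int) std::floor(max_error_rate * pats[p].size());
  }
  CharacterVector oseq(n), oqual(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    std::string q = as<std::string>(quals[r]);
    for (int p = 0; p < npat; ++p) {
      int L = (int) s.size();
      int m = (int) pats[p].size();
      int mm = count_mismatch_prefix(s.c_str(), L, pats[p]);
      if (mm >= 0 && mm <= allow[p]) {
        s = s.substr(m); q = q.substr(m); L -= m;
      }
      mm = count_mismatch_suffix(s.c_str(), L, pats_rc[p]);
      if (mm >= 0 && mm <= allow[p]) {
        s = s.substr(0, L - m); q = q.substr(0, L - m);
      }
    }
    oseq[r] = s; oqual[r] = q;
  }
  return List::create(_["seq"] = oseq, _["qual"] = oqual);
}

// Merge one read pair per element. Mate 2 is reverse-complemented here.
// All overlaps o in [min_overlap, min(n1,n2)] are scored as
// matches - mismatches (N never counts as a match); the best-scoring
// overlap wins, ties going to the longer overlap. Rejected when no
// admissible overlap exists (status 1) or the best overlap's mismatch
// fraction exceeds max_mismatch_frac (status 2).
// Merged base at a mismatch = higher-quality base (mate 1 on quality ties);
// merged quality = max at matches, absolute difference at mismatches.
// [[Rcpp::export]]
List merge_pairs_cpp(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2, CharacterVector qual2,
                     int min_overlap, double max_mismatch_frac) {
  R_xlen_t n = seq1.size();
  CharacterVector mseq(n), mqual(n);
  IntegerVector overlap(n), mismatches(n), status(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    std::string s1 = as<std::string>(seq1[r]);
    std::string q1 = as<std::string>(qual1[r]);
    std::string s2 = revcomp_one(as<std::string>(seq2[r]));
    std::string q2 = as<std::string>(qual2[r]);
    std::reverse(q2.begin(), q2.end());
    int n1 = (int) s1.size(), n2 = (int) s2.size();
    int omax = std::min(n1, n2);
    int best_o = -1, best_mm = 0;
    long best_score = LONG_MIN;
    for (int o = min_overlap; o <= omax; ++o) {
      int match = 0, mm = 0;
      const char* a = s1.c_str() + (n1 - o);
      const char* b = s2.c_str();
      for (int k = 0; k < o; ++k) {
        char ca = a[k], cb = b[k];
        if (ca == cb && ca != 'N') ++match; else ++mm;
      }
      long score = (long) match - mm;
      if (score >= best_score) { best_score = score; best_o = o; best_mm = mm; }
    }
    if (best_o < 0) {
      mseq[r] = NA_STRING; mqual[r] = NA_STRING;
      overlap[r] = NA_INTEGER; mismatches[r] = NA_INTEGER; status[r] = 1;
      continue;
    }
    if ((double) best_mm / best_o > max_mismatch_frac) {
      mseq[r] = NA_STRING; mqual[r] = NA_STRING;
      overlap[r] = best_o; mismatches[r] = best_mm; status[r] = 2;
      continue;
    }
    int o = best_o;
    int L = n1 + n2 - o;
    std::string ms(L, 'N'), mq(L, '!');
    for (int i = 0; i < n1 - o; ++i) { ms[i] = s1[i]; mq[i] = q1[i]; }
    for (int k = 0; k < o; ++k) {
      char ca = s1[n1 - o + k], cb = s2[k];
      char qa = q1[n1 - o + k], qb = q2[k];
      int i = n1 - o + k;
      if (ca == cb && ca != 'N') {
        ms[i] = ca;
        mq[i] = qa >= qb ? qa : qb;
      } else {
        if (qa >= qb) { ms[i] = ca; } else { ms[i] = cb; }
        int dq = qa >= qb ? qa - qb : qb - qa;
        if (dq > 41) dq = 41;
        mq[i] = (char) (33 + dq);
      }
    }
    for (int k = o; k < n2; ++k) { ms[n1 - o + k] = s2[k]; mq[n1 - o + k] = q2[k]; }
    mseq[r] = ms; mqual[r] = mq;
    overlap[r] = o; mismatches[r] = best_mm; status[r] = 0;
  }
  return List::create(_["seq"] = mseq, _["qual"] = mqual,
                      _["overlap_len"] = overlap,
                      _["mismatches_in_overlap"] = mismatches,
                      _["status"] = status);
}

// i.i.d. substitution errors at `rate` per base, using R's RNG so results
// are reproducible under set.seed(). Substituted base is uniform over the
// three alternatives.
// [[Rcpp::export]]
CharacterVector mutate_seqs_cpp(CharacterVector seqs, double rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  if (rate <= 0.0) return clone(seqs);
  for (R_xlen_t r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    for (size_t i = 0; i < s.size(); ++i) {
      if (R::unif_rand() < rate) {
        char cur = s[i];
        int k = (int) (R::unif_rand() * 3.0);
        if (k > 2) k = 2;
        int picked = 0;
        for (int b = 0; b < 4; ++b) {
          if (bases[b] == cur) continue;
          if (picked == k) { s[i] = bases[b]; break; }
          ++picked;
        }
      }
    }
    out[r] = s;
  }
  return out;
}

static inline int lcp_len(const std::string& a, const std::string& b) {
  int L = (int) std::min(a.size(), b.size());
  int i = 0;
  while (i < L && a[i] == b[i]) ++i;
  return i;
}

static inline int lcs_len(const std::string& a, const std::string& b) {
  int la = (int) a.size(), lb = (int) b.size();
  int L = std::min(la, lb);
  int i = 0;
  while (i < L && a[la - 1 - i] == b[lb - 1 - i]) ++i;
  return i;
}

static inline int ham(const std::string& a, const std::string& b) {
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) if (a[i] != b[i]) ++d;
  return d;
}

// Two-parent perfect-crossover chimera detector. Sequences must already be
// sorted by count descending. A sequence is flagged iff two earlier-accepted
// parents A != B of the same length exist, each with count >= skew * its own
// count, such that for some breakpoint p in [1, L-1]
// candidate == A[1..p] + B[p+1..L], and the candidate differs from each
// parent by >= min_diffs substitutions.
// [[Rcpp::export]]
LogicalVector chimera_flags_cpp(CharacterVector seqs, IntegerVector counts,
                                double skew, int min_diffs) {
  int n = seqs.size();
  LogicalVector flags(n);
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
  std::vector<int> accepted;
  accepted.reserve(n);
  std::vector<int> par, lcp_v, lcs_v, ham_v;
  for (int i = 0; i < n; ++i) {
    const std::string& c = ss[i];
    int L = (int) c.size();
    par.clear(); lcp_v.clear(); lcs_v.clear(); ham_v.clear();
    for (size_t a = 0; a < accepted.size(); ++a) {
      int j = accepted[a];
      if ((double) counts[j] >= skew * (double) counts[i] &&
          (int) ss[j].size() == L) par.push_back(j);
    }
    bool flagged = false;
    if (par.size() >= 2) {
      int max_lcp = 0, max_lcs = 0;
      for (size_t a = 0; a < par.size(); ++a) {
        int l1 = lcp_len(c, ss[par[a]]);
        int l2 = lcs_len(c, ss[par[a]]);
        lcp_v.push_back(l1); lcs_v.push_back(l2);
        ham_v.push_back(-1);
        if (l1 > max_lcp) max_lcp = l1;
        if (l2 > max_lcs) max_lcs = l2;
      }
      if (max_lcp + max_lcs >= L) {
        for (size_t a = 0; a < par.size() && !flagged; ++a) {
          if (lcp_v[a] < 1) continue;
          for (size_t b = 0; b < par.size() && !flagged; ++b) {
            if (a == b || lcs_v[b] < 1) continue;
            // breakpoint p with c[1..p]=A[1..p], c[p+1..L]=B[p+1..L]
            int lo = std::max(1, L - lcs_v[b]);
            int hi = std::min(lcp_v[a], L - 1);
            if (lo > hi) continue;
            if (ham_v[a] < 0) ham_v[a] = ham(c, ss[par[a]]);
            if (ham_v[a] < min_diffs) continue;
            if (ham_v[b] < 0) ham_v[b] = ham(c, ss[par[b]]);
            if (ham_v[b] < min_diffs) continue;
            flagged = true;
          }
        }
      }
    }
    flags[i] = flagged;
    if (!flagged) accepted.push_back(i);
  }
  return flags;
}

// Pairwise hamming distance matrix over equal-length sequences.
// [[Rcpp::export]]
IntegerMatrix hamming_matrix_cpp(CharacterVector seqs) {
  int n = seqs.size();
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) {
    ss[i] = as<std::string>(seqs[i]);
    if (i > 0 && ss[i].size() != ss[0].size())
      stop("sequences must have equal length");
  }
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int d = ham(ss[i], ss[j]);
      out(i, j) = d; out(j, i) = d;
    }
  return out;
}
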