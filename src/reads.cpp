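#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

// Mismatches between the prefix of each read and `pattern` (N counts as a
// mismatch). Returns pattern_length + 1 for reads shorter than the pattern;
// counting stops early once `cap` is exceeded.
// [[Rcpp::export]]
IntegerVector prefix_mismatch_cpp(CharacterVector reads, std::string pattern,
                                  int cap) {
  const int m = (int) pattern.size();
  const int n = reads.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    int len = (int) LENGTH(STRING_ELT(reads, r));
    if (len < m) { out[r] = m + 1; continue; }
    int d = 0;
    for (int p = 0; p < m; ++p) {
      if (s[p] != pattern[p]) {
        if (++d > cap) break;
      }
    }
    out[r] = d;
  }
  return out;
}

// Mismatch count of `read` against the same-length prefix of `ref`,
// early exit above cap. In T>C-aware mode a ref base `tol_ref` read as
// `tol_read` is not a mismatch (T->C on the forward strand appears as A->G
// on the reverse-complement mate).
static inline int mate_dist(const char *read, int rlen, const char *ref,
                            int reflen, int cap, bool tc, char tol_ref,
                            char tol_read) {
  int m = rlen < reflen ? rlen : reflen;
  int d = rlen > reflen ? rlen - reflen : 0; // overhang counts as mismatch
  for (int p = 0; p < m && d <= cap; ++p) {
    if (read[p] != ref[p]) {
      if (tc && ref[p] == tol_ref && read[p] == tol_read) continue;
      ++d;
    }
  }
  return d;
}

static void add_seed(std::unordered_map<std::string, std::vector<int> > &map,
                     const std::string &key, int idx) {
  map[key].push_back(idx);
}

static std::string collapse(const std::string &s, char from, char to) {
  std::string r = s;
  for (size_t i = 0; i < r.size(); ++i) if (r[i] == from) r[i] = to;
  return r;
}

// Assign trimmed read pairs to reference oligos by seeded near-exact
// matching. `fwd` must be prefixes of a variable region, `rev` prefixes of
// its reverse complement (UMI already removed). Per-mate Hamming distance
// must be <= max_mm; the unique best total-distance candidate wins.
// Returns 1-based oligo index, 0 for a tie, -1 for no acceptable candidate.
// [[Rcpp::export]]
IntegerVector assign_reads_cpp(CharacterVector fwd, CharacterVector rev,
                               CharacterVector ref_var,
                               CharacterVector ref_var_rc,
                               int max_mm, int seed_len, bool tc_aware) {
  const int n_ref = ref_var.size();
  const int n = fwd.size();
  std::unordered_map<std::string, std::vector<int> > sf1, sf2, sr1, sr2;
  for (int o = 0; o < n_ref; ++o) {
    std::string v = as<std::string>(ref_var[o]);
    std::string vr = as<std::string>(ref_var_rc[o]);
    if ((int) v.size() < 2 * seed_len || (int) vr.size() < 2 * seed_len)
      stop("reference shorter than two seeds");
    std::string f1 = v.substr(0, seed_len), f2 = v.substr(seed_len, seed_len);
    std::string r1 = vr.substr(0, seed_len), r2 = vr.substr(seed_len, seed_len);
    if (tc_aware) {
      f1 = collapse(f1, 'C', 'T'); f2 = collapse(f2, 'C', 'T');
      r1 = collapse(r1, 'G', 'A'); r2 = collapse(r2, 'G', 'A');
    }
    add_seed(sf1, f1, o); add_seed(sf2, f2, o);
    add_seed(sr1, r1, o); add_seed(sr2, r2, o);
  }

  IntegerVector out(n);
  std::vector<int> cand;
  std::vector<char> seen(n_ref, 0);
  for (int r = 0; r < n; ++r) {
    const char *fs = CHAR(STRING_ELT(fwd, r));
    int flen = (int) LENGTH(STRING_ELT(fwd, r));
    const char *rs = CHAR(STRING_ELT(rev, r));
    int rlen = (int) LENGTH(STRING_ELT(rev, r));
    cand.clear();
    if (flen >= 2 * seed_len && rlen >= 2 * seed_len) {
      std::string qf(fs, fs + 2 * seed_len), qr(rs, rs + 2 * seed_len);
      if (tc_aware) { qf = collapse(qf, 'C', 'T'); qr = collapse(qr, 'G', 'A'); }
      const std::string keys[4] = { qf.substr(0, seed_len),
                                    qf.substr(seed_len, seed_len),
                                    qr.substr(0, seed_len),
                                    qr.substr(seed_len, seed_len) };
      std::unordered_map<std::string, std::vector<int> > *maps[4] =
        { &sf1, &sf2, &sr1, &sr2 };
      for (int s = 0; s < 4; ++s) {
        std::unordered_map<std::string, std::vector<int> >::iterator it =
          maps[s]->find(keys[s]);
        if (it == maps[s]->end()) continue;
        for (size_t c = 0; c < it->second.size(); ++c) {
          int o = it->second[c];
          if (!seen[o]) { seen[o] = 1; cand.push_back(o); }
        }
      }
    }
    int best = -1, best_d = 2 * max_mm + 1, n_best = 0;
    for (size_t c = 0; c < cand.size(); ++c) {
      int o = cand[c];
      seen[o] = 0;
      const char *v = CHAR(STRING_ELT(ref_var, o));
      int vlen = (int) LENGTH(STRING_ELT(ref_var, o));
      int df = mate_dist(fs, flen, v, vlen, max_mm, tc_aware, 'T', 'C');
      if (df > max_mm) continue;
      const char *vr = CHAR(STRING_ELT(ref_var_rc, o));
      int dr = mate_dist(rs, rlen, vr, vlen, max_mm, tc_aware, 'A', 'G');
      if (dr > max_mm) continue;
      int d = df + dr;
      if (d < best_d) { best_d = d; best = o; n_best = 1; }
      else if (d == best_d) ++n_best;
    }
    out[r] = (best < 0) ? -1 : (n_best > 1 ? 0 : best + 1);
  }
  return out;
}

// Substitution sequencing errors at a per-base rate, using R's RNG.
// [[Rcpp::export]]
CharacterVector inject_errors_cpp(CharacterVector seqs, double rate) {
  static const char bases[4] = { 'A', 'C', 'G', 'T' };
  int n = seqs.size();
  CharacterVector out(n);
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    int len = (int) s.size();
    int k = (int) R::rbinom((double) len, rate);
    for (int e = 0; e < k; ++e) {
      int pos = (int) (R::unif_rand() * len);
      if (pos >= len) pos = len - 1;
      char cur = s[pos], sub;
      do {
        sub = bases[(int) (R::unif_rand() * 4) % 4];
      } while (sub == cur);
      s[pos] = sub;
    }
    out[r] = s;
  }
  return out;
}

// Per-molecule T>C conversion of reference sequences: read r comes from
// refs[idx[r]]; every T converts independently at rate_labeled for labeled
// molecules, rate_bg otherwise.
// [[Rcpp::export]]
CharacterVector slam_convert_cpp(CharacterVector refs, IntegerVector idx,
                                 LogicalVector labeled, double rate_labeled,
                                 double rate_bg) {
  int n = idx.size();
  CharacterVector out(n);
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(refs[idx[r] - 1]);
    double rate = labeled[r] ? rate_labeled : rate_bg;
    if (rate > 0) {
      for (size_t p = 0; p < s.size(); ++p)
        if (s[p] == 'T' && R::unif_rand() < rate) s[p] = 'C';
    }
    out[r] = s;
  }
  return out;
}

static inline char comp_base(char b) {
  switch (b) {
    case 'A': return 'T'; case 'T': return 'A';
    case 'G': return 'C'; case 'C': return 'G';
    default:  return 'N';
  }
}

// Tally T>C conversions over reference-T positions for assigned read pairs.
// The forward mate covers the 5' end of the variable region in sense
// orientation; the reverse mate covers the 3' end reverse-complemented, so
// rev position p maps to reference position L-1-p with complemented base.
// Positions with base quality below `min_phred` are skipped when quality
// strings are supplied (Sanger +33 encoding).
// [[Rcpp::export]]
List count_conversions_cpp(CharacterVector fwd, CharacterVector rev,
                           CharacterVector fwd_qual, CharacterVector rev_qual,
                           IntegerVector assign, CharacterVector ref_var,
                           int n_oligo, int min_phred) {
  NumericVector n_tc(n_oligo), n_t(n_oligo), other(n_oligo);
  bool have_q = fwd_qual.size() == fwd.size() && rev_qual.size() == rev.size();
  int n = fwd.size();
  for (int r = 0; r < n; ++r) {
    int o = assign[r];
    if (o <= 0) continue;
    const char *v = CHAR(STRING_ELT(ref_var, o - 1));
    int L = (int) LENGTH(STRING_ELT(ref_var, o - 1));
    const char *fs = CHAR(STRING_ELT(fwd, r));
    int flen = (int) LENGTH(STRING_ELT(fwd, r));
    const char *fq = have_q ? CHAR(STRING_ELT(fwd_qual, r)) : NULL;
    int m = flen < L ? flen : L;
    for (int p = 0; p < m; ++p) {
      if (fq && fq[p] - 33 < min_phred) continue;
      if (v[p] == 'T') {
        n_t[o - 1] += 1;
        if (fs[p] == 'C') n_tc[o - 1] += 1;
        else if (fs[p] != 'T') other[o - 1] += 1;
      } else if (fs[p] != v[p]) {
        other[o - 1] += 1;
      }
    }
    const char *rs = CHAR(STRING_ELT(rev, r));
    int rlen = (int) LENGTH(STRING_ELT(rev, r));
    const char *rq = have_q ? CHAR(STRING_ELT(rev_qual, r)) : NULL;
    m = rlen < L ? rlen : L;
    for (int p = 0; p < m; ++p) {
      if (rq && rq[p] - 33 < min_phred) continue;
      int refpos = L - 1 - p;
      char base = comp_base(rs[p]);
      if (v[refpos] == 'T') {
        n_t[o - 1] += 1;
        if (base == 'C') n_tc[o - 1] += 1;
        else if (base != 'T') other[o - 1] += 1;
      } else if (base != v[refpos]) {
        other[o - 1] += 1;
      }
    }
  }
  return List::create(_["n_TC"] = n_tc, _["n_T"] = n_t,
                      _["other_mismatch"] = other);
}
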