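#include <Rcpp.h>
#include <unordered_map>
#include <string>
using namespace Rcpp;

static inline char upcase(char c) {
  return (c >= 'a' && c <= 'z') ? c - 32 : c;
}

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline char complement(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
  }
  return 'N';
}

// lexicographic min of kmer and its reverse complement, written into out
static void canonical_kmer(const char *kmer, int k, std::string &out) {
  out.assign(kmer, k);
  std::string rc(k, 'N');
  for (int i = 0; i < k; ++i) rc[k - 1 - i] = complement(kmer[i]);
  if (rc < out) out = rc;
}

// Count overlapping k-mers in a set of sequences. Windows never span
// sequences; any window containing a non-ACGT base contributes nothing.
// When quals is given (Phred+offset ASCII strings aligned with seqs), a
// window is counted only if every base has quality >= qmin.
// [[Rcpp::export]]
List kmer_count_cpp(CharacterVector seqs, int k, bool canonical,
                    Nullable<CharacterVector> quals = R_NilValue,
                    int qmin = -1, int phred_offset = 33) {
  if (k < 1) stop("k must be >= 1");
  bool use_qual = quals.isNotNull() && qmin >= 0;
  CharacterVector qv;
  if (use_qual) {
    qv = CharacterVector(quals);
    if (qv.size() != seqs.size())
      stop("quality strings do not align with sequences");
  }

  std::unordered_map<std::string, double> counts;
  std::string key;
  std::string buf;
  double n_windows = 0.0;

  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char *raw = CHAR(STRING_ELT(seqs, s));
    int n = (int) LENGTH(STRING_ELT(seqs, s));
    if (n < k) continue;
    buf.assign(raw, n);
    for (int i = 0; i < n; ++i) buf[i] = upcase(buf[i]);

    const char *q = NULL;
    if (use_qual) {
      if (STRING_ELT(qv, s) == NA_STRING)
        stop("missing quality string");
      q = CHAR(STRING_ELT(qv, s));
      if ((int) LENGTH(STRING_ELT(qv, s)) != n)
        stop("quality string length differs from sequence length");
    }

    // last_bad: index of most recent base failing the base or quality test
    int last_bad = -1;
    for (int i = 0; i < n; ++i) {
      bool ok = is_acgt(buf[i]);
      if (ok && use_qual && (int)(q[i] - phred_offset) < qmin) ok = false;
      if (!ok) last_bad = i;
      int start = i - k + 1;
      if (start >= 0 && last_bad < start) {
        if (canonical) {
          canonical_kmer(buf.data() + start, k, key);
        } else {
          key.assign(buf.data() + start, k);
        }
        counts[key] += 1.0;
        n_windows += 1.0;
      }
    }
  }

  R_xlen_t m = (R_xlen_t) counts.size();
  CharacterVector kmers(m);
  NumericVector vals(m);
  R_xlen_t j = 0;
  for (std::unordered_map<std::string, double>::const_iterator it = counts.begin();
       it != counts.end(); ++it, ++j) {
    kmers[j] = it->first;
    vals[j] = it->second;
  }
  vals.attr("names") = kmers;
  return List::create(_["counts"] = vals, _["n_windows"] = n_windows);
}

// Overlapping occurrences of subword v in word w (exact, case-sensitive).
// [[Rcpp::export]]
double occ_cpp(std::string v, std::string w) {
  if (v.size() == 0) stop("subword must be nonempty");
  if (v.size() > w.size()) return 0.0;
  double cnt = 0.0;
  size_t pos = 0;
  while ((pos = w.find(v, pos)) != std::string::npos) {
    cnt += 1.0;
    ++pos;
  }
  return cnt;
}
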