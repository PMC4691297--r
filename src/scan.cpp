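#include <Rcpp.h>
using namespace Rcpp;

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// smallest p dividing k such that the k bases starting at s+a repeat with
// period p
static int smallest_period_k(const char *s, int a, int k) {
  for (int p = 1; p < k; ++p) {
    if (k % p != 0) continue;
    bool ok = true;
    for (int i = p; i < k; ++i) {
      if (s[a + i] != s[a + i - p]) { ok = false; break; }
    }
    if (ok) return p;
  }
  return k;
}

// Maximal perfect tandem-repeat runs for every period in k_range.
// A run of period k is anchored at the leftmost position a of a maximal
// interval where s[i] == s[i+k] with both bases in {A,C,G,T}; the reported
// extent keeps whole repeat units only.  Non-primitive motifs are skipped:
// the same tract is reported at its smallest period.
// [[Rcpp::export]]
List scan_runs_cpp(CharacterVector seqs, IntegerVector k_range) {
  std::vector<int> out_seq, out_start, out_period, out_rep;
  for (int si = 0; si < seqs.size(); ++si) {
    const char *s = CHAR(STRING_ELT(seqs, si));
    int L = LENGTH(STRING_ELT(seqs, si));
    for (int ki = 0; ki < k_range.size(); ++ki) {
      int k = k_range[ki];
      if (L < 2 * k) continue;
      int run_start = -1;
      for (int i = 0; i <= L - k; ++i) {
        bool match = (i < L - k) && s[i] == s[i + k] &&
                     is_acgt(s[i]) && is_acgt(s[i + k]);
        if (match) {
          if (run_start < 0) run_start = i;
        } else if (run_start >= 0) {
          // predicate interval [run_start, i-1]; region length (i-1-run_start+1)+k
          int region = (i - run_start) + k;
          int n = region / k;
          if (n >= 2 && smallest_period_k(s, run_start, k) == k) {
            out_seq.push_back(si + 1);
            out_start.push_back(run_start);
            out_period.push_back(k);
            out_rep.push_back(n);
          }
          run_start = -1;
        }
      }
    }
  }
  return List::create(
    Named("seq_index") = wrap(out_seq),
    Named("start") = wrap(out_start),
    Named("period") = wrap(out_period),
    Named("repeats") = wrap(out_rep));
}
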