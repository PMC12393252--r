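#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

static char comp2(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

// Exhaustive scan of ungapped antiparallel hairpin stems: base i pairs base
// j > i when complementary; maximal runs of consecutive pairs along an
// anti-diagonal (i + j constant) of length >= min_run, with a hairpin loop
// of at least min_loop nt, each form one configuration.
// [[Rcpp::export(name = ".self_scan_cpp")]]
DataFrame self_scan_cpp(std::string s, int min_run = 3, int min_loop = 3) {
  const int n = s.size();
  std::vector<int> i_start, j_end, len;
  for (int cc = 0; cc <= 2 * n - 2; ++cc) {
    int i_hi = (cc - min_loop - 1) / 2;
    int i_lo = cc - (n - 1) > 0 ? cc - (n - 1) : 0;
    if (i_hi < i_lo) continue;
    int run = 0;
    for (int i = i_lo; i <= i_hi + 1; ++i) {
      bool paired = false;
      if (i <= i_hi) {
        int j = cc - i;
        paired = (s[i] == comp2(s[j]) && s[i] != 'N');
      }
      if (paired) {
        ++run;
      } else {
        if (run >= min_run) {
          i_start.push_back(i - run);
          j_end.push_back(cc - (i - run));
          len.push_back(run);
        }
        run = 0;
      }
    }
  }
  return DataFrame::create(
    _["i_start"] = wrap(i_start),
    _["j_end"] = wrap(j_end),
    _["stem_length"] = wrap(len));
}
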