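#include <Rcpp.h>
#include <string>
using namespace Rcpp;

static char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

// Best ungapped pairing of strand a against strand b in one orientation.
// b is complemented (and reversed for the antiparallel orientation) so a
// position pairs where characters are equal; the score of an offset is the
// number of bases lying in complementary runs of length >= 2 (isolated
// pairs carry no stacking energy). Returns the best offset's aligned pair,
// or matched = 0 when no offset has a scoring run.
// [[Rcpp::export(name = ".dimer_scan_cpp")]]
List dimer_scan_cpp(std::string a, std::string b, bool antiparallel) {
  std::string bc(b.size(), 'N');
  for (size_t k = 0; k < b.size(); ++k) bc[k] = comp(b[k]);
  if (antiparallel) std::reverse(bc.begin(), bc.end());
  const int na = a.size(), nb = bc.size();
  int best_score = 0, best_off = 0, best_ia = 0, best_len = 0;
  for (int off = -(na - 2); off <= nb - 2; ++off) {
    int ia = off < 0 ? -off : 0;
    int ib = ia + off;
    int len = std::min(na - ia, nb - ib);
    if (len < 2) continue;
    int score = 0, run = 0;
    for (int k = 0; k < len; ++k) {
      if (a[ia + k] == bc[ib + k] && a[ia + k] != 'N') {
        ++run;
      } else {
        if (run >= 2) score += run;
        run = 0;
      }
    }
    if (run >= 2) score += run;
    if (score > best_score) {
      best_score = score; best_off = off; best_ia = ia; best_len = len;
    }
  }
  if (best_score == 0) {
    return List::create(_["matched"] = 0);
  }
  int ia = best_ia, ib = ia + best_off;
  return List::create(
    _["matched"] = best_score,
    _["a"] = a.substr(ia, best_len),
    _["b"] = bc.substr(ib, best_len));
}
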