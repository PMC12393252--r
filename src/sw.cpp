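#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps.
// A gap of length L costs gap_open + L * gap_ext, matching BLAST's
// gapopen/gapextend convention and Biostrings::pairwiseAlignment.
//
// Returns the single best-scoring local alignment with traceback.
// Ties are broken toward the smallest (end position in subject, end
// position in query), and within the traceback toward diagonal moves,
// which yields a deterministic alignment.

struct AlnResult {
  int score;
  int q_start, q_end; // 0-based half-open on query
  int s_start, s_end; // 0-based half-open on subject
  std::string q_aln, s_aln;
  int matched;
};

static AlnResult sw_core(const std::string& q, const std::string& s,
                         int match, int mismatch, int gap_open, int gap_ext) {
  const int n = q.size(), m = s.size();
  const int NEG = -1000000000;
  // H: best score ending at (i, j); E: gap in subject (consuming query);
  // F: gap in query (consuming subject). Rows over query.
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0);
  std::vector<int> Eprev(m + 1, NEG), Ecur(m + 1, NEG);
  std::vector<int> Fcur(m + 1, NEG);
  // traceback matrices: 0 stop, 1 diag, 2 up (E), 3 left (F)
  std::vector<signed char> tbH((n + 1) * (m + 1), 0);
  std::vector<signed char> tbE((n + 1) * (m + 1), 0); // 1: opened here, 0: extended
  std::vector<signed char> tbF((n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Fcur.assign(m + 1, NEG);
    Hcur[0] = 0; Ecur[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      size_t idx = (size_t)i * (m + 1) + j;
      // E: gap in subject (vertical move, consumes q[i-1])
      int e_open = Hprev[j] - gap_open - gap_ext;
      int e_ext  = Eprev[j] - gap_ext;
      if (e_open >= e_ext) { Ecur[j] = e_open; tbE[idx] = 1; }
      else                 { Ecur[j] = e_ext;  tbE[idx] = 0; }
      // F: gap in query (horizontal move, consumes s[j-1])
      int f_open = Hcur[j - 1] - gap_open - gap_ext;
      int f_ext  = Fcur[j - 1] - gap_ext;
      if (f_open >= f_ext) { Fcur[j] = f_open; tbF[idx] = 1; }
      else                 { Fcur[j] = f_ext;  tbF[idx] = 0; }
      int sub = (q[i - 1] == s[j - 1]) ? match : mismatch;
      int diag = Hprev[j - 1] + sub;
      int h = 0; signed char dir = 0;
      if (diag >= h) { h = diag; dir = 1; }
      if (Ecur[j] > h) { h = Ecur[j]; dir = 2; }
      if (Fcur[j] > h) { h = Fcur[j]; dir = 3; }
      Hcur[j] = h; tbH[idx] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  AlnResult res;
  res.score = best;
  if (best <= 0) {
    res.q_start = res.q_end = res.s_start = res.s_end = 0;
    res.matched = 0;
    return res;
  }
  // traceback
  std::string qa, sa;
  int i = bi, j = bj, matched = 0;
  int state = 0; // 0 in H, 2 in E, 3 in F
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (m + 1) + j;
    if (state == 0) {
      signed char d = tbH[idx];
      if (d == 0) break;
      if (d == 1) {
        qa.push_back(q[i - 1]); sa.push_back(s[j - 1]);
        if (q[i - 1] == s[j - 1]) ++matched;
        --i; --j;
      } else {
        state = d;
      }
    } else if (state == 2) {
      qa.push_back(q[i - 1]); sa.push_back('-');
      signed char opened = tbE[idx];
      --i;
      if (opened) state = 0;
    } else {
      qa.push_back('-'); sa.push_back(s[j - 1]);
      signed char opened = tbF[idx];
      --j;
      if (opened) state = 0;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  res.q_start = i; res.q_end = bi;
  res.s_start = j; res.s_end = bj;
  res.q_aln = qa; res.s_aln = sa;
  res.matched = matched;
  return res;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string subject,
                  int match = 1, int mismatch = -3,
                  int gap_open = 5, int gap_ext = 2) {
  AlnResult r = sw_core(query, subject, match, mismatch, gap_open, gap_ext);
  return List::create(
    _["score"] = r.score,
    _["q_start"] = r.q_start, _["q_end"] = r.q_end,
    _["s_start"] = r.s_start, _["s_end"] = r.s_end,
    _["q_aln"] = r.q_aln, _["s_aln"] = r.s_aln,
    _["matched_nt"] = r.matched);
}

// Batch form: one query against many subject windows. Returns a data frame.
// [[Rcpp::export(name = ".sw_align_batch_cpp")]]
DataFrame sw_align_batch_cpp(std::string query, CharacterVector subjects,
                             int match = 1, int mismatch = -3,
                             int gap_open = 5, int gap_ext = 2) {
  int k = subjects.size();
  IntegerVector score(k), qs(k), qe(k), ss(k), se(k), matched(k);
  CharacterVector qa(k), sa(k);
  for (int t = 0; t < k; ++t) {
    AlnResult r = sw_core(query, as<std::string>(subjects[t]),
                          match, mismatch, gap_open, gap_ext);
    score[t] = r.score; qs[t] = r.q_start; qe[t] = r.q_end;
    ss[t] = r.s_start; se[t] = r.s_end; matched[t] = r.matched;
    qa[t] = r.q_aln; sa[t] = r.s_aln;
  }
  return DataFrame::create(
    _["score"] = score,
    _["q_start"] = qs, _["q_end"] = qe,
    _["s_start"] = ss, _["s_end"] = se,
    _["matched_nt"] = matched,
    _["q_aln"] = qa, _["s_aln"] = sa,
    _["stringsAsFactors"] = false);
}
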