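#include <Rcpp.h>
#include <string>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh), full traceback.
// Scores: match/mismatch on identical/different bases; a gap of length L
// costs gap_open + L * gap_ext. Returns the best-scoring local alignment
// with 1-based inclusive end-points in both sequences plus match/column
// counts, which the R layer turns into identity and coverage.
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string a, std::string b,
              double match = 1.0, double mismatch = -1.0,
              double gap_open = 2.0, double gap_ext = 1.0) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0);
  // H: best ending in (i,j) with a[i] aligned to b[j]; E: gap in a (b
  // consumed); F: gap in b.
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Eprev(m + 1, R_NegInf), Ecur(m + 1, R_NegInf);
  std::vector<double> Fcur(m + 1, R_NegInf);
  // traceback matrices: 0 stop, 1 diag, 2 up(E: gap in b? see below), 3 left
  std::vector<unsigned char> tbH((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbE((n + 1) * (m + 1), 0); // 1: from H, 0: extend
  std::vector<unsigned char> tbF((n + 1) * (m + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Fcur.assign(m + 1, R_NegInf);
    Hcur[0] = 0.0; Ecur[0] = R_NegInf;
    for (int j = 1; j <= m; ++j) {
      // E: vertical move (consume a[i], gap in b)
      double e_open = Hprev[j] - (gap_open + gap_ext);
      double e_ext = Eprev[j] - gap_ext;
      if (e_open >= e_ext) { Ecur[j] = e_open; tbE[i * (m + 1) + j] = 1; }
      else { Ecur[j] = e_ext; tbE[i * (m + 1) + j] = 0; }
      // F: horizontal move (consume b[j], gap in a)
      double f_open = Hcur[j - 1] - (gap_open + gap_ext);
      double f_ext = Fcur[j - 1] - gap_ext;
      if (f_open >= f_ext) { Fcur[j] = f_open; tbF[i * (m + 1) + j] = 1; }
      else { Fcur[j] = f_ext; tbF[i * (m + 1) + j] = 0; }
      double sub = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? match : mismatch;
      double diag = Hprev[j - 1] + sub;
      double h = 0.0; unsigned char dir = 0;
      if (diag > h) { h = diag; dir = 1; }
      if (Ecur[j] > h) { h = Ecur[j]; dir = 2; }
      if (Fcur[j] > h) { h = Fcur[j]; dir = 3; }
      Hcur[j] = h; tbH[i * (m + 1) + j] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0);
  // traceback from (bi, bj)
  int i = bi, j = bj, matches = 0, columns = 0;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    if (state == 0) {
      unsigned char d = tbH[i * (m + 1) + j];
      if (d == 0) break;
      if (d == 1) {
        ++columns;
        if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ++matches;
        --i; --j;
      } else if (d == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++columns;
      unsigned char d = tbE[i * (m + 1) + j];
      --i;
      if (d == 1) state = 0;
    } else {
      ++columns;
      unsigned char d = tbF[i * (m + 1) + j];
      --j;
      if (d == 1) state = 0;
    }
  }
  return List::create(_["score"] = best,
                      _["a_start"] = i + 1, _["a_end"] = bi,
                      _["b_start"] = j + 1, _["b_end"] = bj,
                      _["matches"] = matches, _["columns"] = columns);
}

// Exact k-mer seed test: does any k-mer of the query occur in the target?
// [[Rcpp::export(name = ".has_kmer_seed")]]
bool has_kmer_seed(std::string query, std::string target, int k) {
  int nq = query.size(), nt = target.size();
  if (nq < k || nt < k) return false;
  std::unordered_set<std::string> kmers;
  for (int i = 0; i + k <= nq; ++i) kmers.insert(query.substr(i, k));
  for (int i = 0; i + k <= nt; ++i)
    if (kmers.count(target.substr(i, k))) return true;
  return false;
}
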