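#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Affine-gap Smith-Waterman returning up to max_hits locally optimal,
// non-overlapping (on the subject) alignments. After each traceback the
// subject positions used are masked and the DP is re-run, the standard
// iterative strategy for multi-HSP reporting.
//
// query / subject are 0-based integer encodings into the rows/cols of 'mat'.
// Gap of length k costs open + k * extend.
// Returned coordinates are 0-based half-open.
// [[Rcpp::export(name = ".sw_local_cpp")]]
List sw_local_cpp(IntegerVector query, IntegerVector subject,
                  NumericMatrix mat, double gap_open, double gap_extend,
                  double min_score, int max_hits) {
  const int m = query.size(), n = subject.size();
  std::vector<char> masked(n, 0);
  std::vector<double> qs, qe, ss, se, sc, nid, alen;
  std::vector<std::string> cigars;

  // DP rows: H, E (gap in subject / vertical), F (gap in query / horizontal)
  std::vector<double> H((m + 1) * (n + 1)), E((m + 1) * (n + 1)),
      F((m + 1) * (n + 1));
  // traceback: 0 stop, 1 diag, 2 up(E), 3 left(F); plus gap-state origins
  std::vector<uint8_t> TH((m + 1) * (n + 1)), TE((m + 1) * (n + 1)),
      TF((m + 1) * (n + 1));
  const double NEG = -1e30;

  for (int hit = 0; hit < max_hits; ++hit) {
    double best = 0.0;
    int bi = -1, bj = -1;
    for (int j = 0; j <= n; ++j) { H[j] = 0; E[j] = NEG; F[j] = NEG; }
    for (int i = 1; i <= m; ++i) {
      double *Hi = &H[i * (n + 1)], *Hp = &H[(i - 1) * (n + 1)];
      double *Ei = &E[i * (n + 1)], *Ep = &E[(i - 1) * (n + 1)];
      double *Fi = &F[i * (n + 1)];
      uint8_t *THi = &TH[i * (n + 1)], *TEi = &TE[i * (n + 1)],
              *TFi = &TF[i * (n + 1)];
      Hi[0] = 0; Ei[0] = NEG; Fi[0] = NEG;
      const int qi = query[i - 1];
      for (int j = 1; j <= n; ++j) {
        // E: gap in the subject (consume query letter), comes from row above
        double e_open = Hp[j] - gap_open - gap_extend;
        double e_ext = Ep[j] - gap_extend;
        if (e_open >= e_ext) { Ei[j] = e_open; TEi[j] = 1; }
        else { Ei[j] = e_ext; TEi[j] = 0; }
        // F: gap in the query (consume subject letter), comes from the left.
        // Moves consuming a masked subject position are forbidden, so no
        // alignment can enter or span a previously reported subject interval.
        if (masked[j - 1]) {
          Fi[j] = NEG; TFi[j] = 0;
          double h = 0.0; uint8_t t = 0;
          if (Ei[j] > h) { h = Ei[j]; t = 2; }
          Hi[j] = h; THi[j] = t;
          continue;
        }
        double f_open = Hi[j - 1] - gap_open - gap_extend;
        double f_ext = Fi[j - 1] - gap_extend;
        if (f_open >= f_ext) { Fi[j] = f_open; TFi[j] = 1; }
        else { Fi[j] = f_ext; TFi[j] = 0; }
        double diag = Hp[j - 1] + mat(qi, subject[j - 1]);
        double h = 0.0; uint8_t t = 0;
        if (diag > h) { h = diag; t = 1; }
        if (Ei[j] > h) { h = Ei[j]; t = 2; }
        if (Fi[j] > h) { h = Fi[j]; t = 3; }
        Hi[j] = h; THi[j] = t;
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
    if (best < min_score || bi < 0) break;
    // traceback
    int i = bi, j = bj, state = 0; // 0 = H
    int qend = bi, send = bj;
    int nident = 0, alnlen = 0;
    std::string ops;  // reversed: M = aligned pair, I = gap in subject
                      // (query consumed), D = gap in query (subject consumed)
    while (true) {
      if (state == 0) {
        uint8_t t = TH[i * (n + 1) + j];
        if (t == 0) break;
        if (t == 1) {
          ++alnlen; ops.push_back('M');
          if (query[i - 1] == subject[j - 1]) ++nident;
          --i; --j;
        } else if (t == 2) state = 2;
        else state = 3;
      } else if (state == 2) {
        uint8_t t = TE[i * (n + 1) + j];
        ++alnlen; ops.push_back('I'); --i;
        if (t == 1) state = 0;
      } else {
        uint8_t t = TF[i * (n + 1) + j];
        ++alnlen; ops.push_back('D'); --j;
        if (t == 1) state = 0;
      }
    }
    std::reverse(ops.begin(), ops.end());
    qs.push_back(i); qe.push_back(qend);
    ss.push_back(j); se.push_back(send);
    sc.push_back(best); nid.push_back(nident); alen.push_back(alnlen);
    cigars.push_back(ops);
    for (int k = j; k < send; ++k) masked[k] = 1;
  }
  return List::create(_["query_start"] = wrap(qs), _["query_end"] = wrap(qe),
                      _["subject_start"] = wrap(ss), _["subject_end"] = wrap(se),
                      _["score"] = wrap(sc), _["n_ident"] = wrap(nid),
                      _["aln_len"] = wrap(alen), _["cigar"] = wrap(cigars));
}

// Exact null distribution of a PSSM lattice score: distribution of the sum of
// per-position integer scores of a random word with i.i.d. background letters,
// by direct convolution across positions.
// scores: w x A integer matrix (lattice units); background: length-A probs.
// Returns list(min = minimal achievable sum, prob = probability vector over
// consecutive integer scores starting at min).
// [[Rcpp::export(name = ".pssm_null_cpp")]]
List pssm_null_cpp(IntegerMatrix scores, NumericVector background) {
  const int w = scores.nrow(), A = scores.ncol();
  long lo = 0, hi = 0;
  std::vector<double> cur(1, 1.0);
  for (int p = 0; p < w; ++p) {
    bool first = true;
    int smin = 0, smax = 0;
    for (int a = 0; a < A; ++a) {
      if (background[a] <= 0) continue;  // letter impossible under the null
      if (first) { smin = smax = scores(p, a); first = false; }
      else {
        if (scores(p, a) < smin) smin = scores(p, a);
        if (scores(p, a) > smax) smax = scores(p, a);
      }
    }
    long nlo = lo + smin, nhi = hi + smax;
    std::vector<double> nxt(nhi - nlo + 1, 0.0);
    for (int a = 0; a < A; ++a) {
      const double b = background[a];
      if (b <= 0) continue;
      const long off = lo + scores(p, a) - nlo;
      for (size_t s = 0; s < cur.size(); ++s) nxt[off + s] += cur[s] * b;
    }
    cur.swap(nxt); lo = nlo; hi = nhi;
  }
  return List::create(_["min"] = (double)lo, _["prob"] = wrap(cur));
}
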