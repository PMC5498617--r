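#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Gotoh three-state global alignment with free end gaps.
//
// Scoring: integer match/mismatch per column; a gap RUN costs gap_open on its
// first base and gap_extend on each further base. Among score-equal alignments
// the one with the fewest gap runs wins (lexicographic objective packed into a
// single int64: 4096*score - runs), and traceback ties prefer the diagonal,
// then a gap in b, then a gap in a. This keeps the optimum unique enough that
// indel lengths inferred from the traceback are reproducible.

static const int64_t NEG = INT64_MIN / 4;
static const int64_t SC = 4096; // score scale; |runs| < SC always holds here

// states
enum { SM = 0, SIA = 1, SIB = 2 }; // M: aligned pair; Ia: gap in b; Ib: gap in a
enum { PNONE = 0, PM = 1, PIA = 2, PIB = 3, PSTART = 4 };

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  const size_t W = (size_t)(m + 1);
  std::vector<int64_t> M((n + 1) * W, NEG), Ia((n + 1) * W, NEG), Ib((n + 1) * W, NEG);
  std::vector<unsigned char> bM((n + 1) * W, PNONE), bIa((n + 1) * W, PNONE),
      bIb((n + 1) * W, PNONE);
  // free leading end gaps: any (i,0)/(0,j) is a valid start in state M
  for (int i = 0; i <= n; ++i) { M[i * W] = 0; bM[i * W] = PSTART; }
  for (int j = 0; j <= m; ++j) { M[j] = 0; bM[j] = PSTART; }

  const int64_t OPEN = (int64_t)gap_open * SC - 1;
  const int64_t EXT  = (int64_t)gap_extend * SC;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = i * W + j, d = (i - 1) * W + (j - 1),
                   u = (i - 1) * W + j, l = i * W + (j - 1);
      const int64_t s = (a[i - 1] == b[j - 1] ? match : mismatch) * SC;
      // M: tie order M > Ia > Ib
      int64_t best = M[d]; unsigned char bp = PM;
      if (Ia[d] > best) { best = Ia[d]; bp = PIA; }
      if (Ib[d] > best) { best = Ib[d]; bp = PIB; }
      if (best <= NEG / 2) { M[c] = NEG; bM[c] = PNONE; }
      else { M[c] = best + s; bM[c] = bp; }
      // Ia: consume a[i-1] against a gap in b; open from M, extend from Ia
      int64_t vo = (M[u] <= NEG / 2) ? NEG : M[u] + OPEN;
      int64_t ve = (Ia[u] <= NEG / 2) ? NEG : Ia[u] + EXT;
      if (vo >= ve) { Ia[c] = vo; bIa[c] = PM; } else { Ia[c] = ve; bIa[c] = PIA; }
      // Ib: consume b[j-1] against a gap in a
      vo = (M[l] <= NEG / 2) ? NEG : M[l] + OPEN;
      ve = (Ib[l] <= NEG / 2) ? NEG : Ib[l] + EXT;
      if (vo >= ve) { Ib[c] = vo; bIb[c] = PM; } else { Ib[c] = ve; bIb[c] = PIB; }
    }
  }

  // free trailing end gaps: best over last row and last column, all states.
  int64_t best = NEG; int ei = n, ej = m, est = SM;
  for (int i = 0; i <= n; ++i) {
    const size_t c = i * W + m;
    const int64_t v[3] = { M[c], Ia[c], Ib[c] };
    for (int s = 0; s < 3; ++s)
      if (v[s] > best) { best = v[s]; ei = i; ej = m; est = s; }
  }
  for (int j = 0; j <= m; ++j) {
    const size_t c = n * W + j;
    const int64_t v[3] = { M[c], Ia[c], Ib[c] };
    for (int s = 0; s < 3; ++s)
      if (v[s] > best) { best = v[s]; ei = n; ej = j; est = s; }
  }

  // traceback
  std::string ra, rb;
  int i = ei, j = ej, st = est;
  while (true) {
    const size_t c = i * W + j;
    if (st == SM) {
      if (bM[c] == PSTART) break;
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      const unsigned char p = bM[c];
      --i; --j;
      st = (p == PM) ? SM : (p == PIA ? SIA : SIB);
    } else if (st == SIA) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      const unsigned char p = bIa[c];
      --i;
      st = (p == PM) ? SM : SIA;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      const unsigned char p = bIb[c];
      --j;
      st = (p == PM) ? SM : SIB;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  // recount gap runs in the traceback; combined = SC*score - runs
  int64_t runs = 0;
  for (size_t k = 0; k < ra.size(); ++k) {
    if (ra[k] == '-' && (k == 0 || ra[k - 1] != '-')) ++runs;
    if (rb[k] == '-' && (k == 0 || rb[k - 1] != '-')) ++runs;
  }
  const int64_t score = (best + runs) / SC;

  return List::create(
      _["score"] = (double)score,
      _["gap_runs"] = (int)runs,
      _["a_start"] = i + 1, _["a_end"] = ei,
      _["b_start"] = j + 1, _["b_end"] = ej,
      _["region_a"] = ra, _["region_b"] = rb);
}
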