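#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Semi-global affine-gap alignment: the query is aligned end-to-end, the
// reference contributes free end gaps (unaligned reference prefix/suffix
// costs nothing). Gap of length k costs gap_open + k * gap_extend.
// 'N' in either sequence is a wildcard: zero reward, never a mismatch.
//
// States: 0 = M (query base against reference base),
//         1 = I (gap in reference: extra query base, an insertion),
//         2 = D (gap in query: reference base skipped, a deletion).
// Deterministic tie-breaks: diagonal (mis)match preferred over gaps,
// deletion preferred over insertion, leftmost end column on final ties.

static inline double base_score(char q, char r, double match, double mismatch) {
  if (q == 'N' || r == 'N') return 0.0;
  return (q == r) ? match : -mismatch;
}

// [[Rcpp::export]]
List semiglobal_align_cpp(std::string query, std::string ref,
                          double match, double mismatch,
                          double gap_open, double gap_extend) {
  const int m = (int) query.size(), n = (int) ref.size();
  if (m == 0 || n == 0) stop("query and reference must be non-empty");
  const double NEG = -std::numeric_limits<double>::max() / 4.0;
  const int W = n + 1;
  std::vector<double> M((m + 1) * W, NEG), I((m + 1) * W, NEG), D((m + 1) * W, NEG);
  // traceback: predecessor state for each cell of each matrix (0/1/2; 3 = start)
  std::vector<unsigned char> tbM((m + 1) * W, 3), tbI((m + 1) * W, 3), tbD((m + 1) * W, 3);

  for (int j = 0; j <= n; ++j) M[j] = 0.0;        // free reference prefix
  for (int i = 1; i <= m; ++i) {                  // query overhang before reference
    I[i * W] = -(gap_open + i * gap_extend);
    tbI[i * W] = (i == 1) ? 0 : 1;
  }

  for (int i = 1; i <= m; ++i) {
    const char qc = query[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int c = i * W + j, dg = (i - 1) * W + (j - 1),
                up = (i - 1) * W + j, lf = i * W + (j - 1);
      // M: preference M > D > I on ties
      double best = M[dg]; unsigned char tb = 0;
      if (D[dg] > best) { best = D[dg]; tb = 2; }
      if (I[dg] > best) { best = I[dg]; tb = 1; }
      M[c] = best + base_score(qc, ref[j - 1], match, mismatch);
      tbM[c] = tb;
      // I (consume query base, gap in reference): prefer extension, then M, then D
      best = I[up] - gap_extend; tb = 1;
      if (M[up] - gap_open - gap_extend > best) { best = M[up] - gap_open - gap_extend; tb = 0; }
      if (D[up] - gap_open - gap_extend > best) { best = D[up] - gap_open - gap_extend; tb = 2; }
      I[c] = best; tbI[c] = tb;
      // D (consume reference base, gap in query): prefer extension, then M, then I
      best = D[lf] - gap_extend; tb = 2;
      if (M[lf] - gap_open - gap_extend > best) { best = M[lf] - gap_open - gap_extend; tb = 0; }
      if (I[lf] - gap_open - gap_extend > best) { best = I[lf] - gap_open - gap_extend; tb = 1; }
      D[c] = best; tbD[c] = tb;
    }
  }

  // best end cell on the last query row; free reference suffix
  double best = NEG; int endj = 0; unsigned char endstate = 0;
  for (int j = 0; j <= n; ++j) {
    const int c = m * W + j;
    if (M[c] > best) { best = M[c]; endj = j; endstate = 0; }
    if (D[c] > best) { best = D[c]; endj = j; endstate = 2; }
    if (I[c] > best) { best = I[c]; endj = j; endstate = 1; }
  }

  // traceback to per-step ops (reversed), 0=match 1=mismatch 2=ins 3=del
  std::vector<unsigned char> steps;
  int i = m, j = endj; unsigned char st = endstate;
  while (i > 0) {
    const int c = i * W + j;
    if (st == 0) {
      char qc = query[i - 1], rc = ref[j - 1];
      steps.push_back((qc == rc || qc == 'N' || rc == 'N') ? 0 : 1);
      st = tbM[c]; --i; --j;
    } else if (st == 1) {
      steps.push_back(2);
      st = tbI[c]; --i;
    } else {
      steps.push_back(3);
      st = tbD[c]; --j;
    }
  }
  // drop any trailing-deletion steps reached before the first query base
  // (cannot occur from this traceback since i==0 stops it; leading deletions
  // are forbidden by the NEG initialization of D on row 0)
  const int ref_start = j;
  std::reverse(steps.begin(), steps.end());

  // compress into runs with coordinates
  std::vector<int> op, len, ref_pos, query_pos;
  int rp = ref_start, qp = 0;
  for (size_t k = 0; k < steps.size(); ) {
    size_t k2 = k;
    while (k2 < steps.size() && steps[k2] == steps[k]) ++k2;
    const int L = (int)(k2 - k);
    op.push_back(steps[k]); len.push_back(L);
    ref_pos.push_back(rp); query_pos.push_back(qp);
    switch (steps[k]) {
      case 0: case 1: rp += L; qp += L; break;
      case 2: qp += L; break;
      case 3: rp += L; break;
    }
    k = k2;
  }

  return List::create(
    _["score"] = best,
    _["op"] = IntegerVector(op.begin(), op.end()),
    _["length"] = IntegerVector(len.begin(), len.end()),
    _["ref_pos"] = IntegerVector(ref_pos.begin(), ref_pos.end()),
    _["query_pos"] = IntegerVector(query_pos.begin(), query_pos.end()),
    _["ref_start"] = ref_start,
    _["ref_end"] = rp,
    _["flagged"] = (m > n));
}

// Per-family single-strand consensus: modal base per position among members,
// emitted only if its fraction among contributing members reaches the
// threshold, otherwise 'N'. Consensus length is the modal member length
// (ties resolved to the shorter); members contribute up to
// min(own length, modal length). 'N' in members counts toward the
// denominator but is never the consensus base. Order-invariant.
// [[Rcpp::export]]
List sscs_cpp(CharacterVector reads, double threshold) {
  const int nr = reads.size();
  if (nr == 0) stop("empty family");
  std::vector<std::string> rs(nr);
  std::map<int, int> lens;
  for (int i = 0; i < nr; ++i) {
    rs[i] = as<std::string>(reads[i]);
    lens[(int) rs[i].size()]++;
  }
  int L = 0, bestc = -1;
  for (std::map<int, int>::iterator it = lens.begin(); it != lens.end(); ++it)
    if (it->second > bestc) { bestc = it->second; L = it->first; }
  std::string cons(L, 'N');
  double agree_sum = 0.0;
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  for (int p = 0; p < L; ++p) {
    int cnt[5] = {0, 0, 0, 0, 0};  // A C G T other/N
    int contrib = 0;
    for (int i = 0; i < nr; ++i) {
      if ((int) rs[i].size() <= p) continue;
      ++contrib;
      switch (rs[i][p]) {
        case 'A': ++cnt[0]; break;
        case 'C': ++cnt[1]; break;
        case 'G': ++cnt[2]; break;
        case 'T': ++cnt[3]; break;
        default:  ++cnt[4];
      }
    }
    int mx = 0, mi = -1; bool tie = false;
    for (int b = 0; b < 4; ++b) {
      if (cnt[b] > mx) { mx = cnt[b]; mi = b; tie = false; }
      else if (cnt[b] == mx && mx > 0) tie = true;
    }
    double frac = (contrib > 0) ? (double) mx / contrib : 0.0;
    agree_sum += frac;
    if (mi >= 0 && !tie && frac >= threshold - 1e-12) cons[p] = bases[mi];
  }
  return List::create(_["consensus"] = cons,
                      _["agreement"] = (L > 0) ? agree_sum / L : 1.0,
                      _["length"] = L);
}

// Pairwise mismatch / comparable-position counts over min(length) positions;
// positions where either string has a non-ACGT character are not compared.
// 'b' is recycled if scalar.
// [[Rcpp::export]]
List mismatch_counts_cpp(CharacterVector a, CharacterVector b) {
  const int n = a.size(), nb = b.size();
  if (nb != n && nb != 1) stop("b must match a in length or be scalar");
  IntegerVector mm(n), comp(n);
  for (int i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[i]);
    std::string sb = as<std::string>(b[nb == 1 ? 0 : i]);
    const int L = (int) std::min(sa.size(), sb.size());
    int m = 0, c = 0;
    for (int p = 0; p < L; ++p) {
      char x = sa[p], y = sb[p];
      bool ok = (x=='A'||x=='C'||x=='G'||x=='T') && (y=='A'||y=='C'||y=='G'||y=='T');
      if (!ok) continue;
      ++c;
      if (x != y) ++m;
    }
    mm[i] = m; comp[i] = c;
  }
  return List::create(_["mismatches"] = mm, _["compared"] = comp);
}
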