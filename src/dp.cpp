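#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Gotoh global alignment over an arbitrary column-score matrix S (n x m).
// Gap of length L costs gap_open + L * gap_ext (Biostrings convention).
// Tie-break preference: diagonal (match state), then up (consume row/seq a),
// then left (consume column/seq b) -- fixed for reproducibility.
//
// Returns list(score, a, b): a and b are aligned index vectors, 0 = gap.
// [[Rcpp::export(name = ".dp_affine")]]
List dp_affine(NumericMatrix S, double gap_open, double gap_ext) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();
  const double go = gap_open + gap_ext; // cost of first gapped position

  // state 0 = M (diag), 1 = X (gap in b, consume a), 2 = Y (gap in a, consume b)
  std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  std::vector<unsigned char> pM((n + 1) * (m + 1), 0), pX((n + 1) * (m + 1), 0),
      pY((n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = -(gap_open + i * gap_ext);
    pX[at(i, 0)] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = -(gap_open + j * gap_ext);
    pY[at(0, j)] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: preference M > X > Y on ties
      {
        double vM = M[at(i - 1, j - 1)], vX = X[at(i - 1, j - 1)],
               vY = Y[at(i - 1, j - 1)];
        double best = vM;
        unsigned char p = 0;
        if (vX > best) { best = vX; p = 1; }
        if (vY > best) { best = vY; p = 2; }
        M[at(i, j)] = S(i - 1, j - 1) + best;
        pM[at(i, j)] = p;
      }
      // X: open from M or Y, extend from X
      {
        double vM = M[at(i - 1, j)] - go, vX = X[at(i - 1, j)] - gap_ext,
               vY = Y[at(i - 1, j)] - go;
        double best = vM;
        unsigned char p = 0;
        if (vX > best) { best = vX; p = 1; }
        if (vY > best) { best = vY; p = 2; }
        X[at(i, j)] = best;
        pX[at(i, j)] = p;
      }
      {
        double vM = M[at(i, j - 1)] - go, vX = X[at(i, j - 1)] - go,
               vY = Y[at(i, j - 1)] - gap_ext;
        double best = vM;
        unsigned char p = 0;
        if (vX > best) { best = vX; p = 1; }
        if (vY > best) { best = vY; p = 2; }
        Y[at(i, j)] = best;
        pY[at(i, j)] = p;
      }
    }
  }

  double score = M[at(n, m)];
  int state = 0;
  if (X[at(n, m)] > score) { score = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > score) { score = Y[at(n, m)]; state = 2; }

  std::vector<int> ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char p = pM[at(i, j)];
      ra.push_back(i); rb.push_back(j);
      --i; --j;
      state = p;
    } else if (state == 1) {
      unsigned char p = pX[at(i, j)];
      ra.push_back(i); rb.push_back(0);
      --i;
      state = p;
    } else {
      unsigned char p = pY[at(i, j)];
      ra.push_back(0); rb.push_back(j);
      --j;
      state = p;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score, _["a"] = wrap(ra), _["b"] = wrap(rb));
}

// Spliced alignment of a CDS onto a genomic sequence: every CDS base is
// aligned (match/mismatch), introns are free-length gaps in the CDS of at
// least min_intron bases costing intron_open, with a bonus for canonical
// GT...AG boundaries. Genomic flanks are free (local in the genomic axis).
//
// Returns list(score, path): path[i] = genomic position aligned to CDS base i.
// [[Rcpp::export(name = ".dp_spliced")]]
List dp_spliced(std::string cds, std::string genomic, int min_intron,
                double match, double mismatch, double intron_open,
                double splice_bonus) {
  const int n = cds.size(), m = genomic.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const double NEG = -std::numeric_limits<double>::infinity();

  // donor bonus if an intron starts at genomic position p (1-based)
  std::vector<double> donor(m + 2, 0.0), accept(m + 2, 0.0);
  for (int p = 1; p <= m - 1; ++p)
    if (genomic[p - 1] == 'G' && genomic[p] == 'T') donor[p] = splice_bonus / 2;
  // acceptor bonus if an intron ends at genomic position p (1-based)
  for (int p = 2; p <= m; ++p)
    if (genomic[p - 2] == 'A' && genomic[p - 1] == 'G')
      accept[p] = splice_bonus / 2;

  std::vector<double> Dprev(m + 1, NEG), Dcur(m + 1, NEG);
  // ptr(i,j): 0 diag, >0: intron from genomic column value (j' of previous row)
  std::vector<int> ptr((size_t)n * (m + 1), -1);
  // running best of Dprev[j'] + donor[j'+1] over j' <= j
  std::vector<double> run(m + 1, NEG);
  std::vector<int> runarg(m + 1, 0);

  for (int i = 1; i <= n; ++i) {
    if (i == 1) {
      for (int j = 1; j <= m; ++j) {
        Dcur[j] = (cds[0] == genomic[j - 1]) ? match : mismatch;
        ptr[(size_t)0 * (m + 1) + j] = 0;
      }
    } else {
      // running max over previous row
      double best = NEG;
      int bestarg = 0;
      for (int j = 0; j <= m; ++j) {
        if (j >= 1) {
          double cand = Dprev[j] + donor[j + 1];
          if (cand > best) { best = cand; bestarg = j; }
        }
        run[j] = best;
        runarg[j] = bestarg;
      }
      for (int j = 1; j <= m; ++j) {
        double s = (cds[i - 1] == genomic[j - 1]) ? match : mismatch;
        double diag = (j >= 2 || i == 1) ? Dprev[j - 1] : NEG;
        if (j == 1) diag = NEG;
        double via_intron = NEG;
        int arg = 0;
        int lim = j - min_intron - 1; // intron spans j'+1 .. j-1, length >= min
        if (lim >= 1) {
          via_intron = run[lim] - intron_open + accept[j - 1];
          arg = runarg[lim];
        }
        if (diag >= via_intron) {
          Dcur[j] = s + diag;
          ptr[(size_t)(i - 1) * (m + 1) + j] = 0;
        } else {
          Dcur[j] = s + via_intron;
          ptr[(size_t)(i - 1) * (m + 1) + j] = arg;
        }
      }
    }
    std::swap(Dprev, Dcur);
    std::fill(Dcur.begin(), Dcur.end(), NEG);
  }

  double score = NEG;
  int jend = 0;
  for (int j = 1; j <= m; ++j)
    if (Dprev[j] > score) { score = Dprev[j]; jend = j; }
  if (!std::isfinite(score)) stop("no spliced alignment found");

  IntegerVector path(n);
  int j = jend;
  for (int i = n; i >= 1; --i) {
    path[i - 1] = j;
    int p = ptr[(size_t)(i - 1) * (m + 1) + j];
    if (i > 1) j = (p == 0) ? j - 1 : p;
  }
  return List::create(_["score"] = score, _["path"] = path);
}
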