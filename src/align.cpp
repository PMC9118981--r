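#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh three-state
// recursion. Gap of length k costs open + k * extend. Traceback ties are
// broken deterministically: diagonal (match state) first, then up (gap in B),
// then left (gap in A).

static const double NEG = -1e18;

// [[Rcpp::export(name = ".nw_align")]]
List nw_align(std::string a, std::string b, NumericMatrix sub,
              CharacterVector alphabet, double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  // residue -> index in substitution matrix
  int idx[256];
  for (int i = 0; i < 256; ++i) idx[i] = -1;
  for (int i = 0; i < alphabet.size(); ++i) {
    std::string s = as<std::string>(alphabet[i]);
    idx[(unsigned char)s[0]] = i;
  }
  for (int i = 0; i < n; ++i)
    if (idx[(unsigned char)a[i]] < 0) stop("residue not in alphabet");
  for (int j = 0; j < m; ++j)
    if (idx[(unsigned char)b[j]] < 0) stop("residue not in alphabet");

  std::vector<double> M((n + 1) * (m + 1), NEG),
      Ix((n + 1) * (m + 1), NEG), Iy((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) Ix[at(i, 0)] = -(gap_open + i * gap_extend);
  for (int j = 1; j <= m; ++j) Iy[at(0, j)] = -(gap_open + j * gap_extend);

  for (int i = 1; i <= n; ++i) {
    const int ai = idx[(unsigned char)a[i - 1]];
    for (int j = 1; j <= m; ++j) {
      const double s = sub(ai, idx[(unsigned char)b[j - 1]]);
      double prev = std::max(M[at(i - 1, j - 1)],
                    std::max(Ix[at(i - 1, j - 1)], Iy[at(i - 1, j - 1)]));
      M[at(i, j)] = prev + s;
      Ix[at(i, j)] = std::max(
          std::max(M[at(i - 1, j)], Iy[at(i - 1, j)]) - gap_open - gap_extend,
          Ix[at(i - 1, j)] - gap_extend);
      Iy[at(i, j)] = std::max(
          std::max(M[at(i, j - 1)], Ix[at(i, j - 1)]) - gap_open - gap_extend,
          Iy[at(i, j - 1)] - gap_extend);
    }
  }

  // final state: prefer M, then Ix, then Iy
  int state;  // 0 = M, 1 = Ix (up, gap in b), 2 = Iy (left, gap in a)
  double score;
  {
    double fm = M[at(n, m)], fx = Ix[at(n, m)], fy = Iy[at(n, m)];
    if (fm >= fx && fm >= fy) { state = 0; score = fm; }
    else if (fx >= fy)        { state = 1; score = fx; }
    else                      { state = 2; score = fy; }
  }

  std::string ga, gb;
  std::vector<int> a2b(n, NA_INTEGER);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) stop("traceback error");
      ga += a[i - 1]; gb += b[j - 1];
      a2b[i - 1] = j;  // 1-based position in b
      const double target = M[at(i, j)] -
          sub(idx[(unsigned char)a[i - 1]], idx[(unsigned char)b[j - 1]]);
      if (M[at(i - 1, j - 1)] == target) state = 0;
      else if (Ix[at(i - 1, j - 1)] == target) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      if (i == 0) stop("traceback error");
      ga += a[i - 1]; gb += '-';
      const double cur = Ix[at(i, j)];
      if (M[at(i - 1, j)] - gap_open - gap_extend == cur) state = 0;
      else if (Ix[at(i - 1, j)] - gap_extend == cur) state = 1;
      else state = 2;
      --i;
    } else {
      if (j == 0) stop("traceback error");
      ga += '-'; gb += b[j - 1];
      const double cur = Iy[at(i, j)];
      if (M[at(i, j - 1)] - gap_open - gap_extend == cur) state = 0;
      else if (Iy[at(i, j - 1)] - gap_extend == cur) state = 2;
      else state = 1;
      --j;
    }
    if (i == 0 && j > 0) state = 2;
    if (j == 0 && i > 0) state = 1;
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());

  IntegerVector map(a2b.begin(), a2b.end());
  return List::create(_["score"] = score, _["aligned_a"] = ga,
                      _["aligned_b"] = gb, _["a_to_b"] = map);
}
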