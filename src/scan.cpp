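#include <Rcpp.h>
using namespace Rcpp;

// Window scanner over IUPAC bitmasks (A=1, C=2, G=4, T=8; ambiguity codes are
// unions). A subject position matches iff its expansion is a subset of the
// oligo position's expansion: (subj & ~pat & 15) == 0. A literal subject 'N'
// never matches; it is tallied separately and consumed by the N allowance.

// [[Rcpp::export(name = ".scan_windows_cpp")]]
IntegerMatrix scan_windows_cpp(IntegerVector pat, IntegerVector subj,
                               LogicalVector subj_is_n,
                               int max_mm, int max_n) {
  const int m = pat.size();
  const int n = subj.size();
  std::vector<int> starts, mms, nns;
  if (m == 0 || n < m) {
    return IntegerMatrix(0, 3);
  }
  for (int s = 0; s <= n - m; ++s) {
    int mm = 0, nn = 0;
    bool ok = true;
    for (int j = 0; j < m; ++j) {
      if (subj_is_n[s + j]) {
        if (++nn > max_n) { ok = false; break; }
      } else if ((subj[s + j] & ~pat[j] & 15) != 0) {
        if (++mm > max_mm) { ok = false; break; }
      }
    }
    if (ok) {
      starts.push_back(s);
      mms.push_back(mm);
      nns.push_back(nn);
    }
  }
  IntegerMatrix out(starts.size(), 3);
  for (size_t i = 0; i < starts.size(); ++i) {
    out(i, 0) = starts[i];
    out(i, 1) = mms[i];
    out(i, 2) = nns[i];
  }
  colnames(out) = CharacterVector::create("start", "mismatches", "n_positions");
  return out;
}

// Global Needleman-Wunsch with fixed scoring (match +1, mismatch -1, linear
// gap -2). Ties in the traceback resolve toward the upper-left: diagonal
// first, then up (gap in b), then left (gap in a). Returns the number of
// identically aligned symbol pairs alongside the alignment score.

// [[Rcpp::export(name = ".nw_identity_cpp")]]
List nw_identity_cpp(std::string a, std::string b) {
  const int la = a.size(), lb = b.size();
  const int GAP = -2;
  std::vector<int> prev(lb + 1), cur(lb + 1);
  // direction: 0 = diag, 1 = up, 2 = left
  std::vector<unsigned char> dir((la + 1) * (lb + 1));
  for (int j = 0; j <= lb; ++j) { prev[j] = j * GAP; if (j > 0) dir[j] = 2; }
  for (int i = 1; i <= la; ++i) {
    cur[0] = i * GAP;
    dir[i * (lb + 1)] = 1;
    for (int j = 1; j <= lb; ++j) {
      int sub = (a[i - 1] == b[j - 1]) ? 1 : -1;
      int d = prev[j - 1] + sub;
      int u = prev[j] + GAP;
      int l = cur[j - 1] + GAP;
      int best = d; unsigned char bd = 0;
      if (u > best) { best = u; bd = 1; }
      if (l > best) { best = l; bd = 2; }
      cur[j] = best;
      dir[i * (lb + 1) + j] = bd;
    }
    std::swap(prev, cur);
  }
  int score = prev[lb];
  int i = la, j = lb, ident = 0, alen = 0;
  while (i > 0 || j > 0) {
    unsigned char d = dir[i * (lb + 1) + j];
    ++alen;
    if (i > 0 && j > 0 && d == 0) {
      if (a[i - 1] == b[j - 1]) ++ident;
      --i; --j;
    } else if (i > 0 && (d == 1 || j == 0)) {
      --i;
    } else {
      --j;
    }
  }
  return List::create(_["score"] = score,
                      _["identical"] = ident,
                      _["alignment_length"] = alen);
}
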