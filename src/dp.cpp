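// Affine-gap Smith-Waterman with soft-clip semantics: the unaligned read
// prefix/suffix is reported as S ops, so clipping happens exactly when it
// improves the local score.
#include "snapvar.h"
using namespace Rcpp;

static const int NEG = -1000000000;

std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'C': c = 'G'; break;
      case 'G': c = 'C'; break; case 'T': c = 'A'; break;
      case 'a': c = 't'; break; case 'c': c = 'g'; break;
      case 'g': c = 'c'; break; case 't': c = 'a'; break;
      default: c = 'N';
    }
  }
  return r;
}

static inline int subst(char a, char b, const AlnParams &p) {
  if (a == 'N' || b == 'N') return p.mismatch;
  return (a == b) ? p.match : p.mismatch;
}

static void push_op(std::string &cig, char op, int len) {
  if (len <= 0) return;
  cig += std::to_string(len);
  cig += op;
}

AlnResult local_align(const std::string &read, const std::string &ref,
                      const AlnParams &p) {
  AlnResult res;
  const int n = (int)read.size(), m = (int)ref.size();
  if (n == 0 || m == 0) return res;
  const int go = p.gapOpen + p.gapExt; // cost of first gap base
  // DP rows over read (i), cols over ref (j); traceback matrices packed.
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  // tb codes for H: 0 stop, 1 diag, 2 from E (D op), 3 from F (I op)
  std::vector<uint8_t> tbH((n + 1) * (m + 1), 0), tbE((n + 1) * (m + 1), 0),
      tbF((n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int row = i * (m + 1), prow = (i - 1) * (m + 1);
    for (int j = 1; j <= m; ++j) {
      int eOpen = H[row + j - 1] - go, eExt = E[row + j - 1] - p.gapExt;
      if (eExt > eOpen) { E[row + j] = eExt; tbE[row + j] = 1; }
      else { E[row + j] = eOpen; tbE[row + j] = 0; }
      int fOpen = H[prow + j] - go, fExt = F[prow + j] - p.gapExt;
      if (fExt > fOpen) { F[row + j] = fExt; tbF[row + j] = 1; }
      else { F[row + j] = fOpen; tbF[row + j] = 0; }
      int diag = H[prow + j - 1] + subst(read[i - 1], ref[j - 1], p);
      int h = 0; uint8_t tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (E[row + j] > h) { h = E[row + j]; tb = 2; }
      if (F[row + j] > h) { h = F[row + j]; tb = 3; }
      H[row + j] = h; tbH[row + j] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) return res;
  // traceback
  std::vector<std::pair<char, int>> ops; // reversed
  int i = bi, j = bj;
  int state = 0; // 0 in H, 1 in E, 2 in F
  while (true) {
    int idx = i * (m + 1) + j;
    if (state == 0) {
      uint8_t tb = tbH[idx];
      if (tb == 0) break;
      if (tb == 1) {
        char op = (read[i - 1] == ref[j - 1] && read[i - 1] != 'N') ? '=' : 'X';
        if (!ops.empty() && ops.back().first == op) ops.back().second++;
        else ops.push_back({op, 1});
        --i; --j;
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // E: consumes ref -> D
      if (!ops.empty() && ops.back().first == 'D') ops.back().second++;
      else ops.push_back({'D', 1});
      uint8_t te = tbE[idx];
      --j;
      if (te == 0) state = 0;
    } else { // F: consumes read -> I
      if (!ops.empty() && ops.back().first == 'I') ops.back().second++;
      else ops.push_back({'I', 1});
      uint8_t tf = tbF[idx];
      --i;
      if (tf == 0) state = 0;
    }
  }
  res.score = best;
  res.refStart = j; // 0-based: first aligned ref base is ref[j]
  std::string cig;
  push_op(cig, 'S', i); // leading soft clip (read bases before alignment)
  for (auto it = ops.rbegin(); it != ops.rend(); ++it)
    push_op(cig, it->first, it->second);
  push_op(cig, 'S', n - bi);
  res.cigar = cig;
  res.ok = true;
  return res;
}

int local_align_score(const std::string &read, const std::string &ref,
                      const AlnParams &p) {
  const int n = (int)read.size(), m = (int)ref.size();
  if (n == 0 || m == 0) return 0;
  const int go = p.gapOpen + p.gapExt;
  std::vector<int> Hp(m + 1, 0), H(m + 1, 0), Fv(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int e = NEG;
    H[0] = 0;
    for (int j = 1; j <= m; ++j) {
      e = std::max(H[j - 1] - go, e - p.gapExt);
      Fv[j] = std::max(Hp[j] - go, Fv[j] - p.gapExt);
      int h = Hp[j - 1] + subst(read[i - 1], ref[j - 1], p);
      h = std::max(h, std::max(e, Fv[j]));
      h = std::max(h, 0);
      H[j] = h;
      if (h > best) best = h;
    }
    std::swap(H, Hp);
  }
  return best;
}

// [[Rcpp::export]]
List cpp_local_align(std::string read, std::string refwindow,
                     int match = 1, int mismatch = -4, int gapOpen = 6,
                     int gapExt = 1) {
  AlnParams p; p.match = match; p.mismatch = mismatch;
  p.gapOpen = gapOpen; p.gapExt = gapExt;
  AlnResult r = local_align(read, refwindow, p);
  return List::create(_["score"] = r.score, _["refStart"] = r.refStart,
                      _["cigar"] = r.cigar, _["ok"] = r.ok);
}

// Score every read against every haplotype (exhaustive read x haplotype).
// [[Rcpp::export]]
NumericMatrix cpp_score_matrix(CharacterVector reads, CharacterVector haps) {
  AlnParams p;
  const int n = reads.size(), h = haps.size();
  NumericMatrix out(n, h);
  std::vector<std::string> hs(h);
  for (int j = 0; j < h; ++j) hs[j] = as<std::string>(haps[j]);
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(reads[i]);
    for (int j = 0; j < h; ++j) out(i, j) = local_align_score(r, hs[j], p);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  return out;
}
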