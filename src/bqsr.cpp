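// Base quality score recalibration: tabulate (reported quality, machine
// cycle, dinucleotide) covariate cells over aligned non-clipped bases and
// replace reported qualities with smoothed empirical qualities.
#include "snapvar.h"
using namespace Rcpp;

struct CigWalk2 {
  const std::string &cig;
  size_t i = 0;
  CigWalk2(const std::string &c) : cig(c) {}
  bool next(int &len, char &op) {
    if (i >= cig.size()) return false;
    int num = 0;
    while (i < cig.size() && cig[i] >= '0' && cig[i] <= '9')
      num = num * 10 + (cig[i++] - '0');
    op = cig[i++];
    len = num;
    return true;
  }
};

static inline char comp(char c) {
  switch (c) { case 'A': return 'T'; case 'C': return 'G';
               case 'G': return 'C'; case 'T': return 'A'; }
  return 'N';
}

static inline int bIdx(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; }
  return -1;
}

// Dinucleotide covariate in sequencing orientation: prev*4 + cur, or 16 when
// the previous base is unavailable or N. seq is stored in reference
// orientation; for '-' strand reads the sequencing-orientation current base
// is the complement and the sequencing-previous base sits one position to
// the right in storage order.
static inline int dinucOf(const std::string &seq, int qp, bool isFwd) {
  char cur, prev;
  if (isFwd) {
    cur = seq[qp];
    prev = qp > 0 ? seq[qp - 1] : 'N';
  } else {
    cur = comp(seq[qp]);
    prev = qp + 1 < (int)seq.size() ? comp(seq[qp + 1]) : 'N';
  }
  int ci = bIdx(cur), pi = bIdx(prev);
  if (ci < 0) return -1;
  if (pi < 0) return 16;
  return pi * 4 + ci;
}

// cycle (1-based) in sequencing orientation
static inline int cycleOf(int qp, int readLen, bool isFwd) {
  return isFwd ? qp + 1 : readLen - qp;
}

// [[Rcpp::export]]
List cpp_bqsr_build(IntegerVector contig, IntegerVector pos, LogicalVector fwd,
                    CharacterVector cigar, CharacterVector seq,
                    CharacterVector qual, LogicalVector exclude,
                    CharacterVector refs, IntegerVector contigOffsets,
                    LogicalVector mask, int maxCycle, int minQ = 2) {
  std::vector<std::string> refSeqs(refs.size());
  for (int i = 0; i < refs.size(); ++i) refSeqs[i] = as<std::string>(refs[i]);
  const int NQ = 61, ND = 17;
  IntegerVector obs(NQ * maxCycle * ND, 0), mism(NQ * maxCycle * ND, 0);
  auto cell = [&](int q, int cyc, int dn) {
    return q + NQ * ((cyc - 1) + maxCycle * dn);
  };
  const int n = contig.size();
  long total = 0;
  for (int r = 0; r < n; ++r) {
    if (exclude[r] || contig[r] == NA_INTEGER) continue;
    std::string cg = as<std::string>(cigar[r]);
    std::string sq = as<std::string>(seq[r]);
    std::string qu = as<std::string>(qual[r]);
    const std::string &ref = refSeqs[contig[r] - 1];
    const long goff = contigOffsets[contig[r] - 1];
    const bool isFwd = fwd[r];
    const int rl = (int)sq.size();
    int rp = pos[r], qp = 0;
    CigWalk2 w(cg);
    int len; char op;
    while (w.next(len, op)) {
      if (op == 'S' || op == 'I') { qp += len; continue; }
      if (op == 'D') { rp += len; continue; }
      for (int t = 0; t < len; ++t) {
        int q = (int)qu[qp + t] - 33;
        char rb = ref[rp + t], qb = sq[qp + t];
        if (q >= minQ && q <= 60 && rb != 'N' && qb != 'N' &&
            !mask[goff + rp + t]) {
          int dn = dinucOf(sq, qp + t, isFwd);
          if (dn >= 0) {
            int cyc = cycleOf(qp + t, rl, isFwd);
            if (cyc >= 1 && cyc <= maxCycle) {
              int c = cell(q, cyc, dn);
              obs[c]++;
              if (qb != rb) mism[c]++;
              ++total;
            }
          }
        }
      }
      rp += len; qp += len;
    }
  }
  obs.attr("dim") = IntegerVector::create(NQ, maxCycle, ND);
  mism.attr("dim") = IntegerVector::create(NQ, maxCycle, ND);
  return List::create(_["obs"] = obs, _["mism"] = mism,
                      _["total"] = (double)total);
}

// Replace every base quality by its cell's empirical quality, falling back
// to the reported-quality marginal for unseen cells. empirical/marginal are
// precomputed in R from the smoothed counts.
// [[Rcpp::export]]
CharacterVector cpp_bqsr_apply(CharacterVector seq, CharacterVector qual,
                               LogicalVector fwd, IntegerVector obs,
                               NumericVector empirical,
                               NumericVector marginal, int maxCycle) {
  const int NQ = 61;
  const int n = qual.size();
  CharacterVector out(n);
  auto cell = [&](int q, int cyc, int dn) {
    return q + NQ * ((cyc - 1) + maxCycle * dn);
  };
  for (int r = 0; r < n; ++r) {
    std::string sq = as<std::string>(seq[r]);
    std::string qu = as<std::string>(qual[r]);
    const bool isFwd = fwd[r];
    const int rl = (int)sq.size();
    for (int t = 0; t < rl; ++t) {
      int q = (int)qu[t] - 33;
      if (q < 0) q = 0;
      if (q > 60) q = 60;
      int dn = dinucOf(sq, t, isFwd);
      int cyc = cycleOf(t, rl, isFwd);
      double nq = q;
      if (dn >= 0 && cyc >= 1 && cyc <= maxCycle &&
          obs[cell(q, cyc, dn)] > 0) {
        nq = empirical[cell(q, cyc, dn)];
      } else if (!Rcpp::NumericVector::is_na(marginal[q])) {
        nq = marginal[q];
      }
      int iq = (int)(nq + 0.5);
      if (iq < 0) iq = 0;
      if (iq > 60) iq = 60;
      qu[t] = (char)(iq + 33);
    }
    out[r] = qu;
  }
  return out;
}
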