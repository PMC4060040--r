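// The 16-genotype diploid model: 10 base-pair genotypes, 4 base/indel
// heterozygotes, homozygous indel and compound indel heterozygote. SNP and
// indel alleles compete in a single per-column likelihood: every counted
// observation at the column is either a base or an indel event, and
// contributes log( 0.5 P(obs|a1) + 0.5 P(obs|a2) ) with
// P(obs|a) = 1 - eps if the observation matches the allele, eps/3 otherwise,
// eps = 10^(-q/10) at the observation's mean quality.
#include "snapvar.h"
#include <cmath>
using namespace Rcpp;

// allele codes: 0..3 = A,C,G,T; 4 = I (top indel event); 5 = I' (second)
static const int GT_A1[16] = {0,0,0,0,1,1,1,2,2,3, 0,1,2,3, 4,4};
static const int GT_A2[16] = {0,1,2,3,1,2,3,2,3,3, 4,4,4,4, 4,5};

static inline double pObs(int obsAllele, int gtAllele, double eps) {
  return (obsAllele == gtAllele) ? (1.0 - eps) : (eps / 3.0);
}

static inline bool isTransition(int a, int b) {
  return (a == 0 && b == 2) || (a == 2 && b == 0) ||
         (a == 1 && b == 3) || (a == 3 && b == 1);
}

// [[Rcpp::export]]
List cpp_genotype_batch(IntegerMatrix counts, IntegerVector refCode,
                        IntegerVector ev1type, IntegerVector ev1n,
                        NumericVector ev1q, IntegerVector ev2type,
                        IntegerVector ev2n, NumericVector ev2q,
                        double thetaSnp, double thetaIndel, double tsRatio,
                        double delQual = 30.0, bool full = false) {
  const int n = counts.nrow();
  IntegerVector argmax(n, NA_INTEGER);
  NumericVector qual(n, NA_REAL), postMax(n, NA_REAL),
      postHomRef(n, NA_REAL);
  NumericMatrix postM, likM, priorM;
  if (full) {
    postM = NumericMatrix(n, 16);
    likM = NumericMatrix(n, 16);
    priorM = NumericMatrix(n, 16);
    std::fill(postM.begin(), postM.end(), 0.0);
    std::fill(likM.begin(), likM.end(), R_NegInf);
    std::fill(priorM.begin(), priorM.end(), R_NegInf);
  }
  const double wTs = tsRatio / (tsRatio + 1.0);
  const double wTv = 1.0 / (2.0 * (tsRatio + 1.0));

  for (int r = 0; r < n; ++r) {
    const int rc = refCode[r];
    if (rc < 0) continue;
    // observation classes: up to 4 bases + 2 indel events. A read is one
    // observation: reads carrying an indel event also deposited a base at
    // the anchor column, so event support is subtracted from the reference
    // base count before forming the base observations.
    bool hasE1 = ev1type[r] > 0 && ev1n[r] > 0;
    bool hasE2 = ev2type[r] > 0 && ev2n[r] > 0;
    int evTotal = (hasE1 ? ev1n[r] : 0) + (hasE2 ? ev2n[r] : 0);
    int obsAllele[6]; double obsN[6], obsQ[6];
    int nObs = 0; double depthObs = 0;
    int depthCol = counts(r, 18);
    bool strongIndel = evTotal >= 3 && depthCol > 0 &&
                       (double)evTotal / depthCol >= 0.2;
    for (int b = 0; b < 4; ++b) {
      int cnt = counts(r, b) + counts(r, b + 4);
      if (cnt > 0) {
        double q = (double)counts(r, b + 8) / cnt;
        if (b == rc) {
          cnt = std::max(0, cnt - evTotal);
          // at a strong indel column, residual reference-looking bases are
          // mostly reads that end too close to the event to exhibit it;
          // their evidence is alignment-limited, not base-quality-limited
          if (strongIndel) q = std::min(q, 10.0);
        }
        if (cnt == 0) continue;
        obsAllele[nObs] = b;
        obsN[nObs] = cnt;
        obsQ[nObs] = q;
        ++nObs; depthObs += cnt;
      }
    }
    if (hasE1) {
      obsAllele[nObs] = 4; obsN[nObs] = ev1n[r];
      obsQ[nObs] = ev1type[r] == 2 ? delQual : ev1q[r];
      ++nObs; depthObs += ev1n[r];
    }
    if (hasE2) {
      obsAllele[nObs] = 5; obsN[nObs] = ev2n[r];
      obsQ[nObs] = ev2type[r] == 2 ? delQual : ev2q[r];
      ++nObs; depthObs += ev2n[r];
    }
    if (depthObs <= 0) continue;

    // priors
    double prior[16];
    double others = 0.0;
    for (int g = 0; g < 16; ++g) {
      int a1 = GT_A1[g], a2 = GT_A2[g];
      double p;
      if (a1 == rc && a2 == rc) { prior[g] = -1; continue; } // hom-ref later
      bool i1 = (a1 == 4 || a2 == 4), i2 = (a1 == 5 || a2 == 5);
      auto wOf = [&](int b) { return isTransition(rc, b) ? wTs : wTv; };
      if (!i1 && !i2) {
        bool r1 = (a1 == rc), r2 = (a2 == rc);
        if (r1 || r2) {
          int alt = r1 ? a2 : a1;
          p = thetaSnp * wOf(alt);
        } else if (a1 == a2) {
          p = 0.5 * thetaSnp * wOf(a1);
        } else {
          p = thetaSnp * thetaSnp * wOf(a1) * wOf(a2);
        }
      } else if (i2) {            // I/I' compound het
        p = 0.25 * thetaIndel * thetaIndel;
      } else if (a1 == 4 && a2 == 4) { // I/I
        p = 0.5 * thetaIndel;
      } else {                    // base/I het
        int b = (a1 == 4) ? a2 : a1;
        p = (b == rc) ? thetaIndel : thetaSnp * thetaIndel * wOf(b);
      }
      prior[g] = p;
      others += p;
    }
    int homRefIdx = -1;
    for (int g = 0; g < 16; ++g)
      if (prior[g] < 0) { homRefIdx = g; prior[g] = 1.0 - others; }

    // log posterior over available genotypes
    double lp[16];
    double maxlp = R_NegInf;
    bool avail[16];
    for (int g = 0; g < 16; ++g) {
      int a1 = GT_A1[g], a2 = GT_A2[g];
      bool needs1 = (a1 == 4 || a2 == 4), needs2 = (a1 == 5 || a2 == 5);
      avail[g] = !((needs1 && !hasE1) || (needs2 && !hasE2));
      if (!avail[g]) { lp[g] = R_NegInf; continue; }
      double ll = 0.0;
      for (int o = 0; o < nObs; ++o) {
        double eps = std::pow(10.0, -obsQ[o] / 10.0);
        if (eps > 0.75) eps = 0.75;
        double p = 0.5 * pObs(obsAllele[o], a1, eps) +
                   0.5 * pObs(obsAllele[o], a2, eps);
        ll += obsN[o] * std::log(p);
      }
      if (full) {
        likM(r, g) = ll;
        priorM(r, g) = std::log(prior[g]);
      }
      lp[g] = std::log(prior[g]) + ll;
      if (lp[g] > maxlp) maxlp = lp[g];
    }
    double z = 0.0;
    for (int g = 0; g < 16; ++g)
      if (avail[g]) z += std::exp(lp[g] - maxlp);
    double lz = maxlp + std::log(z);
    int best = -1; double bestp = -1.0, pHomRef = 0.0;
    for (int g = 0; g < 16; ++g) {
      double post = avail[g] ? std::exp(lp[g] - lz) : 0.0;
      if (full) postM(r, g) = post;
      if (post > bestp) { bestp = post; best = g; }
      if (g == homRefIdx) pHomRef = post;
    }
    argmax[r] = best + 1;
    postMax[r] = bestp;
    postHomRef[r] = pHomRef;
    double q = pHomRef <= 0.0 ? 10000.0 : -10.0 * std::log10(pHomRef);
    if (q > 10000.0) q = 10000.0;
    if (q < 0.0) q = 0.0;
    qual[r] = q;
  }
  List out = List::create(_["argmax"] = argmax, _["qual"] = qual,
                          _["postMax"] = postMax,
                          _["postHomRef"] = postHomRef);
  if (full) {
    out["posterior"] = postM;
    out["loglik"] = likM;
    out["logprior"] = priorM;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_genotype_space() {
  IntegerVector a1(16), a2(16);
  for (int g = 0; g < 16; ++g) { a1[g] = GT_A1[g]; a2[g] = GT_A2[g]; }
  return List::create(_["a1"] = a1, _["a2"] = a2);
}
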