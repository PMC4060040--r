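// Batch glocal fit of reads against one selected haplotype (traceback kept),
// used when rewriting reads through a chosen indel hypothesis.
#include "snapvar.h"
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_fit_batch(CharacterVector reads, std::string hap) {
  AlnParams p;
  const int n = reads.size();
  IntegerVector score(n), hapStart(n);
  CharacterVector cigar(n);
  LogicalVector ok(n);
  for (int i = 0; i < n; ++i) {
    AlnResult r = local_align(as<std::string>(reads[i]), hap, p);
    ok[i] = r.ok;
    score[i] = r.score;
    hapStart[i] = r.refStart;
    cigar[i] = r.cigar;
  }
  return List::create(_["ok"] = ok, _["score"] = score,
                      _["hapStart"] = hapStart, _["cigar"] = cigar);
}
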