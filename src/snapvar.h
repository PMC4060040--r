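#ifndef SNAPVAR_H
#define SNAPVAR_H

#include <Rcpp.h>
#include <string>
#include <vector>
#include <cstdint>

// Alignment scoring used everywhere: match +1, mismatch -4,
// gap of length L costs gapOpen + L * gapExt (affine).
struct AlnParams {
  int match = 1;
  int mismatch = -4;
  int gapOpen = 6;
  int gapExt = 1;
};

struct AlnResult {
  int score = 0;
  int refStart = 0;        // 0-based offset of first aligned ref base in window
  std::string cigar;       // ops over {=, X, I, D, S}; read fully accounted for
  bool ok = false;
};

// Smith-Waterman local alignment with affine gaps and traceback.
AlnResult local_align(const std::string &read, const std::string &ref,
                      const AlnParams &p);

// Score-only variant (rolling rows), same optimum as local_align().
int local_align_score(const std::string &read, const std::string &ref,
                      const AlnParams &p);

std::string revcomp(const std::string &s);

#endif
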