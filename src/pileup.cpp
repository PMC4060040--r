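// Per-base evidence accumulation (the snapshot column builder) and small
// CIGAR / quality / indel-normalization utilities shared across modules.
#include "snapvar.h"
#include <map>
#include <tuple>
using namespace Rcpp;

struct CigWalker {
  const std::string &cig;
  size_t i = 0;
  CigWalker(const std::string &c) : cig(c) {}
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

// Per-alignment CIGAR summary: leading/trailing soft clip, reference span,
// read length consumed, match/mismatch/gap tallies and the DP score the
// current placement is worth.
// [[Rcpp::export]]
List cpp_cigar_stats(CharacterVector cigar, int match = 1, int mismatch = -4,
                     int gapOpen = 6, int gapExt = 1) {
  const int n = cigar.size();
  IntegerVector leadS(n), trailS(n), refSpan(n), readLen(n), nMatch(n),
      nMism(n), nIns(n), nDel(n), score(n);
  for (int r = 0; r < n; ++r) {
    std::string c = as<std::string>(cigar[r]);
    CigWalker w(c);
    int len; char op;
    bool first = true;
    int lead = 0, trail = 0, span = 0, rl = 0, nm = 0, nx = 0, ni = 0, nd = 0,
        sc = 0;
    while (w.next(len, op)) {
      switch (op) {
        case 'S':
          if (first) lead = len; else trail = len;
          rl += len; break;
        case '=': nm += len; span += len; rl += len; sc += match * len; break;
        case 'X': nx += len; span += len; rl += len; sc += mismatch * len; break;
        case 'M': nm += len; span += len; rl += len; sc += match * len; break;
        case 'I': ni++; rl += len; sc -= gapOpen + gapExt * len; break;
        case 'D': nd++; span += len; sc -= gapOpen + gapExt * len; break;
        default: stop("unknown CIGAR op '%s'", std::string(1, op).c_str());
      }
      if (op != 'S') first = false;
    }
    leadS[r] = lead; trailS[r] = trail; refSpan[r] = span; readLen[r] = rl;
    nMatch[r] = nm; nMism[r] = nx; nIns[r] = ni; nDel[r] = nd; score[r] = sc;
  }
  return List::create(_["leadClip"] = leadS, _["trailClip"] = trailS,
                      _["refSpan"] = refSpan, _["readLen"] = readLen,
                      _["nMatch"] = nMatch, _["nMism"] = nMism,
                      _["nIns"] = nIns, _["nDel"] = nDel, _["score"] = score);
}

// [[Rcpp::export]]
IntegerVector cpp_qualsum(CharacterVector qual) {
  IntegerVector out(qual.size());
  for (int i = 0; i < qual.size(); ++i) {
    std::string q = as<std::string>(qual[i]);
    int s = 0;
    for (char c : q) s += (int)c - 33;
    out[i] = s;
  }
  return out;
}

// rows of q are cycles, columns are reads; values are Phred scores
// [[Rcpp::export]]
CharacterVector cpp_encode_phred(IntegerMatrix q) {
  const int nc = q.ncol(), nr = q.nrow();
  CharacterVector out(nc);
  std::string buf(nr, '!');
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int v = q(i, j);
      if (v < 0) v = 0;
      if (v > 60) v = 60;
      buf[i] = (char)(v + 33);
    }
    out[j] = buf;
  }
  return out;
}

// FNV-1a over concatenated sequences, folded to a positive 31-bit value.
// [[Rcpp::export]]
int cpp_fnv(CharacterVector x) {
  uint64_t h = 1469598103934665603ULL;
  for (int i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    for (char c : s) { h ^= (uint8_t)c; h *= 1099511628211ULL; }
    h ^= (uint8_t)'\n'; h *= 1099511628211ULL;
  }
  return (int)((h ^ (h >> 32)) & 0x7fffffff);
}

static inline int baseIdx(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; }
  return -1;
}

// Region row lookup table: regions sorted by (contig, start), rows assigned
// cumulatively. Returns -1 when the position is outside declared regions.
struct RegionMap {
  std::vector<int> contig;   // 1-based contig index
  std::vector<int> start, end, rowStart;
  int rowOf(int ctg, int p) const {
    int lo = 0, hi = (int)contig.size() - 1, ans = -1;
    while (lo <= hi) {
      int mid = (lo + hi) / 2;
      if (contig[mid] < ctg || (contig[mid] == ctg && start[mid] <= p)) {
        ans = mid; lo = mid + 1;
      } else hi = mid - 1;
    }
    if (ans < 0) return -1;
    if (contig[ans] != ctg || p >= end[ans]) return -1;
    return rowStart[ans] + (p - start[ans]);
  }
};

static RegionMap makeRegionMap(IntegerVector regContig, IntegerVector regStart,
                               IntegerVector regEnd, IntegerVector regRowStart) {
  RegionMap rm;
  rm.contig.assign(regContig.begin(), regContig.end());
  rm.start.assign(regStart.begin(), regStart.end());
  rm.end.assign(regEnd.begin(), regEnd.end());
  rm.rowStart.assign(regRowStart.begin(), regRowStart.end());
  return rm;
}

// Column layout of the counts matrix (19 columns):
// 1-4 fwd counts A,C,G,T; 5-8 rev counts; 9-12 recal quality sums;
// 13-16 mapping quality sums; 17 N/other; 18 deletion-span; 19 depth.
// [[Rcpp::export]]
List cpp_pileup(IntegerVector contig, IntegerVector pos, LogicalVector fwd,
                CharacterVector cigar, CharacterVector seq,
                CharacterVector qual, IntegerVector mapq,
                LogicalVector exclude, IntegerVector regContig,
                IntegerVector regStart, IntegerVector regEnd,
                IntegerVector regRowStart, int nRows) {
  RegionMap rm = makeRegionMap(regContig, regStart, regEnd, regRowStart);
  IntegerMatrix counts(nRows, 19);
  // key: (row, type 1=I/2=D, payload) -> fwd, rev, qsum
  std::map<std::tuple<int, int, std::string>, std::array<long, 3>> events;
  const int n = contig.size();
  for (int r = 0; r < n; ++r) {
    if (exclude[r] || contig[r] == NA_INTEGER) continue;
    std::string cg = as<std::string>(cigar[r]);
    std::string sq = as<std::string>(seq[r]);
    std::string qu = as<std::string>(qual[r]);
    const int ctg = contig[r];
    const bool isFwd = fwd[r];
    const int mq = mapq[r];
    int rp = pos[r];   // reference cursor (0-based)
    int qp = 0;        // read cursor
    CigWalker w(cg);
    int len; char op;
    while (w.next(len, op)) {
      if (op == 'S') { qp += len; continue; }
      if (op == '=' || op == 'X' || op == 'M') {
        for (int t = 0; t < len; ++t) {
          int row = rm.rowOf(ctg, rp + t);
          if (row >= 0) {
            int b = baseIdx(sq[qp + t]);
            if (b < 0) counts(row, 16)++;             // N/other
            else {
              counts(row, b + (isFwd ? 0 : 4))++;
              counts(row, b + 8) += (int)qu[qp + t] - 33;
              counts(row, b + 12) += mq;
            }
            counts(row, 18)++;                        // depth
          }
        }
        rp += len; qp += len;
      } else if (op == 'I') {
        int arow = rm.rowOf(ctg, rp - 1);
        if (arow >= 0 && rp > 0) {
          std::string payload = sq.substr(qp, len);
          long qs = 0;
          for (int t = 0; t < len; ++t) qs += (int)qu[qp + t] - 33;
          auto &e = events[std::make_tuple(arow, 1, payload)];
          e[isFwd ? 0 : 1]++;
          e[2] += qs;
        }
        qp += len;
      } else if (op == 'D') {
        int arow = rm.rowOf(ctg, rp - 1);
        if (arow >= 0 && rp > 0) {
          auto &e = events[std::make_tuple(arow, 2, std::to_string(len))];
          e[isFwd ? 0 : 1]++;
        }
        for (int t = 0; t < len; ++t) {
          int row = rm.rowOf(ctg, rp + t);
          if (row >= 0) { counts(row, 17)++; counts(row, 18)++; }
        }
        rp += len;
      }
    }
  }
  const int ne = (int)events.size();
  IntegerVector erow(ne), efwd(ne), erev(ne), eqsum(ne);
  CharacterVector etype(ne), epayload(ne);
  int i = 0;
  for (auto &kv : events) {
    erow[i] = std::get<0>(kv.first) + 1; // 1-based row for R
    etype[i] = std::get<1>(kv.first) == 1 ? "I" : "D";
    epayload[i] = std::get<2>(kv.first);
    efwd[i] = (int)kv.second[0];
    erev[i] = (int)kv.second[1];
    eqsum[i] = (int)kv.second[2];
    ++i;
  }
  return List::create(
      _["counts"] = counts,
      _["events"] = DataFrame::create(
          _["row"] = erow, _["type"] = etype, _["payload"] = epayload,
          _["fwd"] = efwd, _["rev"] = erev, _["qsum"] = eqsum,
          _["stringsAsFactors"] = false));
}

// Extract every I/D edit op across alignments, with the anchor (0-based
// reference base immediately left of the event).
// [[Rcpp::export]]
DataFrame cpp_extract_indels(IntegerVector contig, IntegerVector pos,
                             CharacterVector cigar, CharacterVector seq,
                             LogicalVector exclude) {
  std::vector<int> oAln, oContig, oAnchor, oLen;
  std::vector<std::string> oType, oPayload;
  const int n = contig.size();
  for (int r = 0; r < n; ++r) {
    if (exclude[r] || contig[r] == NA_INTEGER) continue;
    std::string cg = as<std::string>(cigar[r]);
    std::string sq = as<std::string>(seq[r]);
    int rp = pos[r], qp = 0;
    CigWalker w(cg);
    int len; char op;
    while (w.next(len, op)) {
      if (op == 'S') qp += len;
      else if (op == '=' || op == 'X' || op == 'M') { rp += len; qp += len; }
      else if (op == 'I') {
        if (rp > 0) {
          oAln.push_back(r + 1); oContig.push_back(contig[r]);
          oAnchor.push_back(rp - 1); oType.push_back("I");
          oPayload.push_back(sq.substr(qp, len)); oLen.push_back(len);
        }
        qp += len;
      } else if (op == 'D') {
        if (rp > 0) {
          oAln.push_back(r + 1); oContig.push_back(contig[r]);
          oAnchor.push_back(rp - 1); oType.push_back("D");
          oPayload.push_back(std::to_string(len)); oLen.push_back(len);
        }
        rp += len;
      }
    }
  }
  return DataFrame::create(_["aln"] = wrap(oAln), _["contig"] = wrap(oContig),
                           _["anchor"] = wrap(oAnchor), _["type"] = wrap(oType),
                           _["payload"] = wrap(oPayload), _["len"] = wrap(oLen),
                           _["stringsAsFactors"] = false);
}

// Left-normalization through repeat context. anchor is the 0-based base left
// of the event; for D the payload is the deleted length, for I the inserted
// sequence. Returns shifted anchors and (for insertions) rotated payloads.
// [[Rcpp::export]]
List cpp_normalize_indels(std::string refseq, IntegerVector anchor,
                          CharacterVector type, CharacterVector payload) {
  const int n = anchor.size();
  IntegerVector oAnchor(n);
  CharacterVector oPayload(n);
  for (int i = 0; i < n; ++i) {
    int a = anchor[i];
    std::string ty = as<std::string>(type[i]);
    std::string pl = as<std::string>(payload[i]);
    if (ty == "D") {
      int len = 0;
      for (char c : pl) if (c >= '0' && c <= '9') len = len * 10 + (c - '0');
      // deleted run is refseq[a+1 .. a+len]; shift while base left of the
      // event equals the last deleted base
      while (a >= 1 && a + len < (int)refseq.size() &&
             refseq[a] == refseq[a + len])
        --a;
      oAnchor[i] = a;
      oPayload[i] = pl;
    } else {
      std::string s = pl;
      while (a >= 1 && !s.empty() && refseq[a] == s[s.size() - 1]) {
        s = std::string(1, refseq[a]) + s.substr(0, s.size() - 1);
        --a;
      }
      oAnchor[i] = a;
      oPayload[i] = s;
    }
  }
  return List::create(_["anchor"] = oAnchor, _["payload"] = oPayload);
}
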