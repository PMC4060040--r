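// Seed-and-extend paired-end aligner: k-mer hash index over the reference,
// candidate loci from clustered seed diagonals, windowed affine-gap DP
// extension, pair selection with an insert-size model and mate rescue.
#include "snapvar.h"
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

struct SeedIndex {
  int k = 16;
  int maxOcc = 64;
  std::vector<std::string> seqs;   // uppercase contig sequences
  std::vector<std::string> names;
  std::vector<long> offsets;       // global offset of each contig
  long total = 0;
  std::unordered_map<uint64_t, std::vector<uint32_t>> map; // fwd k-mers -> global pos
  std::unordered_set<uint64_t> repetitive;
};

static inline int baseCode(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; }
  return -1;
}

static bool encodeKmer(const std::string &s, size_t pos, int k, uint64_t &key) {
  uint64_t v = 0;
  for (int t = 0; t < k; ++t) {
    int c = baseCode(s[pos + t]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  key = v;
  return true;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int k,
                     int maxOcc) {
  if (k < 8 || k > 32) stop("k must be in [8, 32]");
  SeedIndex *idx = new SeedIndex();
  idx->k = k; idx->maxOcc = maxOcc;
  long off = 0;
  for (int i = 0; i < seqs.size(); ++i) {
    idx->seqs.push_back(as<std::string>(seqs[i]));
    idx->names.push_back(as<std::string>(names[i]));
    idx->offsets.push_back(off);
    off += idx->seqs.back().size();
  }
  idx->total = off;
  for (size_t ci = 0; ci < idx->seqs.size(); ++ci) {
    const std::string &s = idx->seqs[ci];
    if ((int)s.size() < k) continue;
    for (size_t p = 0; p + k <= s.size(); ++p) {
      uint64_t key;
      if (!encodeKmer(s, p, k, key)) continue;
      idx->map[key].push_back((uint32_t)(idx->offsets[ci] + p));
    }
  }
  // k-mers over maxOcc are flagged repetitive and skipped at query time
  for (auto it = idx->map.begin(); it != idx->map.end();) {
    if ((int)it->second.size() > idx->maxOcc) {
      idx->repetitive.insert(it->first);
      it = idx->map.erase(it);
    } else ++it;
  }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_lookup(SEXP xp, std::string kmer) {
  XPtr<SeedIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("kmer length != k");
  uint64_t key;
  if (!encodeKmer(kmer, 0, idx->k, key))
    return List::create(_["repetitive"] = false,
                        _["positions"] = IntegerVector(0));
  if (idx->repetitive.count(key))
    return List::create(_["repetitive"] = true,
                        _["positions"] = IntegerVector(0));
  auto it = idx->map.find(key);
  IntegerVector pos;
  if (it != idx->map.end()) pos = IntegerVector(it->second.begin(), it->second.end());
  return List::create(_["repetitive"] = false, _["positions"] = pos);
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
  XPtr<SeedIndex> idx(xp);
  return List::create(_["k"] = idx->k, _["maxOcc"] = idx->maxOcc,
                      _["nKmers"] = (double)idx->map.size(),
                      _["nRepetitive"] = (double)idx->repetitive.size(),
                      _["contigs"] = wrap(idx->names));
}

struct Candidate {
  int contig = -1;
  long pos = 0;        // 0-based contig start of alignment
  bool fwd = true;
  int score = 0;
  std::string cigar;   // over oriented read
};

static int contigOf(const SeedIndex &idx, long gpos) {
  int lo = 0, hi = (int)idx.offsets.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi + 1) / 2;
    if (idx.offsets[mid] <= gpos) lo = mid; else hi = mid - 1;
  }
  return lo;
}

// Gapless alignment on one diagonal with optimal end clipping =
// maximum-scoring subarray of per-base match/mismatch scores.
static bool kadane_align(const std::string &rd, const std::string &ctg,
                         long diag, const AlnParams &p, Candidate &cand) {
  const int n = (int)rd.size();
  int best = 0, cur = 0, curStart = 0, b0 = 0, b1 = -1;
  std::vector<int8_t> isMatch(n, 0);
  for (int t = 0; t < n; ++t) {
    long rp = diag + t;
    int v;
    if (rp < 0 || rp >= (long)ctg.size()) v = p.mismatch;
    else {
      char a = rd[t], b = ctg[rp];
      bool m = (a == b && a != 'N');
      isMatch[t] = m;
      v = m ? p.match : p.mismatch;
    }
    if (cur <= 0) { cur = v; curStart = t; } else cur += v;
    if (cur > best) { best = cur; b0 = curStart; b1 = t; }
  }
  if (best <= 0) return false;
  std::string cig;
  if (b0 > 0) { cig += std::to_string(b0); cig += 'S'; }
  int runLen = 0; char runOp = 0;
  for (int t = b0; t <= b1; ++t) {
    char op = isMatch[t] ? '=' : 'X';
    if (op == runOp) runLen++;
    else {
      if (runLen) { cig += std::to_string(runLen); cig += runOp; }
      runOp = op; runLen = 1;
    }
  }
  if (runLen) { cig += std::to_string(runLen); cig += runOp; }
  if (b1 < n - 1) { cig += std::to_string(n - 1 - b1); cig += 'S'; }
  cand.pos = diag + b0;
  cand.score = best;
  cand.cigar = cig;
  return true;
}

static void align_candidates(const SeedIndex &idx, const std::string &read,
                             const AlnParams &p, int maxCand,
                             std::vector<Candidate> &out) {
  const int k = idx.k;
  const int n = (int)read.size();
  out.clear();
  if (n < k) return;
  const int diagTol = 25;   // diagonal clustering tolerance (covers max indel)
  const int pad = 25;       // window padding for the DP extension
  for (int strand = 0; strand < 2; ++strand) {
    std::string s = strand == 0 ? read : revcomp(read);
    // non-overlapping seeds, plus one flush with the read end
    std::vector<int> offs;
    for (int o = 0; o + k <= n; o += k) offs.push_back(o);
    if (!offs.empty() && offs.back() != n - k) offs.push_back(n - k);
    std::vector<long> diags;
    for (int o : offs) {
      uint64_t key;
      if (!encodeKmer(s, o, k, key)) continue;
      if (idx.repetitive.count(key)) continue;
      auto it = idx.map.find(key);
      if (it == idx.map.end()) continue;
      for (uint32_t gp : it->second) diags.push_back((long)gp - o);
    }
    if (diags.empty()) continue;
    std::sort(diags.begin(), diags.end());
    // group diagonals
    struct Group { long dmin, dmax; int votes; };
    std::vector<Group> groups;
    for (size_t i = 0; i < diags.size(); ++i) {
      if (!groups.empty() && diags[i] - groups.back().dmax <= diagTol) {
        groups.back().dmax = diags[i];
        groups.back().votes++;
      } else groups.push_back({diags[i], diags[i], 1});
    }
    std::stable_sort(groups.begin(), groups.end(),
                     [](const Group &a, const Group &b) {
                       if (a.votes != b.votes) return a.votes > b.votes;
                       return a.dmin < b.dmin;
                     });
    int taken = 0;
    for (const Group &g : groups) {
      if (taken >= maxCand) break;
      ++taken;
      int ci = contigOf(idx, std::max(0L, g.dmin));
      const std::string &ctg = idx.seqs[ci];
      long coff = idx.offsets[ci];
      long dminL = g.dmin - coff, dmaxL = g.dmax - coff;
      Candidate cand;
      cand.contig = ci;
      cand.fwd = (strand == 0);
      bool done = false;
      if (dminL == dmaxL) {
        // fast path: gapless with optimal end clipping; fall back to DP
        // when an indel could still beat it (threshold = one clean 1 bp gap)
        Candidate kc = cand;
        if (kadane_align(s, ctg, dminL, p, kc) &&
            kc.score >= n * p.match - (p.gapOpen + p.gapExt)) {
          out.push_back(kc);
          done = true;
        }
      }
      if (!done) {
        long w0 = std::max(0L, dminL - pad);
        long w1 = std::min((long)ctg.size(), dmaxL + n + pad);
        if (w1 <= w0) continue;
        AlnResult r = local_align(s, ctg.substr(w0, w1 - w0), p);
        if (r.ok && r.score > 0) {
          cand.pos = w0 + r.refStart;
          cand.score = r.score;
          cand.cigar = r.cigar;
          out.push_back(cand);
        }
      }
    }
  }
  // dedupe identical placements keeping best score
  std::stable_sort(out.begin(), out.end(),
                   [](const Candidate &a, const Candidate &b) {
                     if (a.score != b.score) return a.score > b.score;
                     if (a.contig != b.contig) return a.contig < b.contig;
                     if (a.pos != b.pos) return a.pos < b.pos;
                     return a.fwd && !b.fwd; // + before -
                   });
  std::vector<Candidate> uniq;
  for (const Candidate &c : out) {
    bool dup = false;
    for (const Candidate &u : uniq)
      if (u.contig == c.contig && u.pos == c.pos && u.fwd == c.fwd) {
        dup = true; break;
      }
    if (!dup) uniq.push_back(c);
  }
  out.swap(uniq);
}

static int refSpanOfCigar(const std::string &cig) {
  int span = 0, num = 0;
  for (char c : cig) {
    if (c >= '0' && c <= '9') num = num * 10 + (c - '0');
    else {
      if (c == '=' || c == 'X' || c == 'D' || c == 'M') span += num;
      num = 0;
    }
  }
  return span;
}

static int mapqOf(const std::vector<Candidate> &cands) {
  if (cands.empty()) return 0;
  int best = cands[0].score;
  int second = cands.size() > 1 ? cands[1].score : 0;
  int d = best - second;
  if (d <= 0) return 0;
  if (d >= 10) return 60;
  return std::min(60, 6 * d);
}

static List candList(const std::vector<Candidate> &cands) {
  int n = (int)cands.size();
  IntegerVector contig(n), pos(n), score(n);
  LogicalVector fwd(n);
  CharacterVector cigar(n);
  for (int i = 0; i < n; ++i) {
    contig[i] = cands[i].contig + 1;
    pos[i] = (int)cands[i].pos;
    score[i] = cands[i].score;
    fwd[i] = cands[i].fwd;
    cigar[i] = cands[i].cigar;
  }
  return List::create(_["contig"] = contig, _["pos"] = pos,
                      _["strand"] = fwd, _["score"] = score,
                      _["cigar"] = cigar);
}

// [[Rcpp::export]]
List cpp_align_candidates(SEXP xp, std::string read, int maxCand = 8) {
  XPtr<SeedIndex> idx(xp);
  AlnParams p;
  std::vector<Candidate> cands;
  align_candidates(*idx, read, p, maxCand, cands);
  return candList(cands);
}

struct PairPick {
  bool ok1 = false, ok2 = false, proper = false;
  Candidate c1, c2;
  int mapq1 = 0, mapq2 = 0;
  bool rescued1 = false, rescued2 = false;
};

static bool properOrientation(const Candidate &a, const Candidate &b,
                              double imean, double isd, long &insert) {
  if (a.contig != b.contig) return false;
  if (a.fwd == b.fwd) return false;
  const Candidate &plus = a.fwd ? a : b;
  const Candidate &minus = a.fwd ? b : a;
  if (plus.pos > minus.pos) return false; // FR orientation
  long end = minus.pos + refSpanOfCigar(minus.cigar);
  insert = end - plus.pos;
  return insert >= (long)(imean - 4 * isd) && insert <= (long)(imean + 4 * isd);
}

static bool rescue_mate(const SeedIndex &idx, const std::string &mateRead,
                        const Candidate &anchor, double imean, double isd,
                        const AlnParams &p, Candidate &out) {
  const std::string &ctg = idx.seqs[anchor.contig];
  int n = (int)mateRead.size();
  long w0, w1;
  std::string s;
  if (anchor.fwd) {
    // mate expected downstream on - strand
    s = revcomp(mateRead);
    w0 = anchor.pos;
    w1 = anchor.pos + (long)(imean + 4 * isd) + n;
  } else {
    s = mateRead; // mate on + strand upstream
    long aend = anchor.pos + refSpanOfCigar(anchor.cigar);
    w0 = aend - (long)(imean + 4 * isd) - n;
    w1 = aend;
  }
  w0 = std::max(0L, w0);
  w1 = std::min((long)ctg.size(), w1);
  if (w1 - w0 < n / 2) return false;
  AlnResult r = local_align(s, ctg.substr(w0, w1 - w0), p);
  if (!r.ok || r.score < (int)(0.55 * n)) return false;
  out.contig = anchor.contig;
  out.pos = w0 + r.refStart;
  out.fwd = !anchor.fwd;
  out.score = r.score;
  out.cigar = r.cigar;
  return true;
}

static PairPick select_pair(const SeedIndex &idx,
                            const std::string &r1, const std::string &r2,
                            std::vector<Candidate> &c1,
                            std::vector<Candidate> &c2,
                            double imean, double isd, int pairBonus,
                            const AlnParams &p) {
  PairPick pick;
  pick.mapq1 = mapqOf(c1);
  pick.mapq2 = mapqOf(c2);
  if (c1.empty() && !c2.empty()) {
    Candidate r;
    if (rescue_mate(idx, r1, c2[0], imean, isd, p, r)) {
      c1.push_back(r);
      pick.rescued1 = true;
      pick.mapq1 = std::min(pick.mapq2, 40);
    }
  } else if (c2.empty() && !c1.empty()) {
    Candidate r;
    if (rescue_mate(idx, r2, c1[0], imean, isd, p, r)) {
      c2.push_back(r);
      pick.rescued2 = true;
      pick.mapq2 = std::min(pick.mapq1, 40);
    }
  }
  if (c1.empty() && c2.empty()) return pick;
  if (c2.empty()) { pick.ok1 = true; pick.c1 = c1[0]; return pick; }
  if (c1.empty()) { pick.ok2 = true; pick.c2 = c2[0]; return pick; }
  long bestTotal = -1000000000;
  int b1 = 0, b2 = 0; bool bprop = false;
  for (size_t i = 0; i < c1.size(); ++i)
    for (size_t j = 0; j < c2.size(); ++j) {
      long ins;
      bool prop = properOrientation(c1[i], c2[j], imean, isd, ins);
      long tot = (long)c1[i].score + c2[j].score + (prop ? pairBonus : 0);
      if (tot > bestTotal) {
        bestTotal = tot; b1 = (int)i; b2 = (int)j; bprop = prop;
      }
    }
  pick.ok1 = pick.ok2 = true;
  pick.c1 = c1[b1]; pick.c2 = c2[b2]; pick.proper = bprop;
  // ambiguity from pairing choice: if a non-selected candidate for a mate
  // ties the selected score, mapq reflects the per-read candidate gap already
  return pick;
}

// [[Rcpp::export]]
List cpp_pair_select(SEXP xp, std::string read1, std::string read2,
                     double insertMean, double insertSd, int pairBonus = 20,
                     int maxCand = 8) {
  XPtr<SeedIndex> idx(xp);
  AlnParams p;
  std::vector<Candidate> c1, c2;
  align_candidates(*idx, read1, p, maxCand, c1);
  align_candidates(*idx, read2, p, maxCand, c2);
  PairPick pk = select_pair(*idx, read1, read2, c1, c2, insertMean, insertSd,
                            pairBonus, p);
  auto one = [&](bool ok, const Candidate &c, int mapq, bool rescued) {
    return List::create(_["mapped"] = ok, _["contig"] = c.contig + 1,
                        _["pos"] = (int)c.pos, _["strand"] = c.fwd,
                        _["score"] = c.score, _["cigar"] = c.cigar,
                        _["mapq"] = mapq, _["rescued"] = rescued);
  };
  return List::create(_["mate1"] = one(pk.ok1, pk.c1, pk.mapq1, pk.rescued1),
                      _["mate2"] = one(pk.ok2, pk.c2, pk.mapq2, pk.rescued2),
                      _["properlyPaired"] = pk.proper);
}

static std::string reverseString(const std::string &s) {
  return std::string(s.rbegin(), s.rend());
}

// Batch paired-end alignment. Returns one row per read (2 * npairs rows,
// mate1 rows first then mate2 rows interleaved by pair index kept via
// pairId). Sequences/qualities are returned in reference orientation.
// [[Rcpp::export]]
List cpp_align_pairs(SEXP xp, CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2, CharacterVector qual2,
                     double insertMean, double insertSd, int pairBonus = 20,
                     int maxCand = 8) {
  XPtr<SeedIndex> idx(xp);
  AlnParams p;
  const int n = seq1.size();
  const int N = 2 * n;
  LogicalVector mapped(N), strandFwd(N), proper(N);
  IntegerVector contig(N), pos(N), mapq(N), score(N), pairId(N), mate(N);
  CharacterVector cigar(N), oseq(N), oqual(N);
  std::vector<Candidate> c1, c2;
  for (int i = 0; i < n; ++i) {
    std::string r1 = as<std::string>(seq1[i]);
    std::string r2 = as<std::string>(seq2[i]);
    align_candidates(*idx, r1, p, maxCand, c1);
    align_candidates(*idx, r2, p, maxCand, c2);
    PairPick pk = select_pair(*idx, r1, r2, c1, c2, insertMean, insertSd,
                              pairBonus, p);
    int i1 = 2 * i, i2 = 2 * i + 1;
    pairId[i1] = pairId[i2] = i + 1;
    mate[i1] = 1; mate[i2] = 2;
    proper[i1] = proper[i2] = pk.proper;
    auto fill = [&](int row, bool ok, const Candidate &c, int mq,
                    const std::string &rseq, const std::string &rqual) {
      mapped[row] = ok;
      if (!ok) { contig[row] = NA_INTEGER; pos[row] = NA_INTEGER;
                 oseq[row] = rseq; oqual[row] = rqual; return; }
      contig[row] = c.contig + 1;
      pos[row] = (int)c.pos;
      strandFwd[row] = c.fwd;
      mapq[row] = mq;
      score[row] = c.score;
      cigar[row] = c.cigar;
      if (c.fwd) { oseq[row] = rseq; oqual[row] = rqual; }
      else { oseq[row] = revcomp(rseq); oqual[row] = reverseString(rqual); }
    };
    fill(i1, pk.ok1, pk.c1, pk.mapq1, r1, as<std::string>(qual1[i]));
    fill(i2, pk.ok2, pk.c2, pk.mapq2, r2, as<std::string>(qual2[i]));
  }
  return List::create(_["pairId"] = pairId, _["mate"] = mate,
                      _["mapped"] = mapped, _["contig"] = contig,
                      _["pos"] = pos, _["strand"] = strandFwd,
                      _["mapq"] = mapq, _["score"] = score,
                      _["cigar"] = cigar, _["seq"] = oseq,
                      _["qual"] = oqual, _["proper"] = proper);
}
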