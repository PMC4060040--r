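#' Build a k-mer seed index over a reference
#'
#' Indexes every non-N k-mer of the forward strand; queries search the read
#' and its reverse complement, so both strands are reachable. K-mers
#' occurring more than \code{maxOcc} times are flagged repetitive and
#' skipped at query time.
#'
#' @param ref A \linkS4class{Reference}.
#' @param k Seed length, 8..32.
#' @param maxOcc Repetitive k-mer cutoff.
#' @return An opaque seed index handle (external pointer plus metadata).
#' @export
buildSeedIndex <- function(ref, k = 16L, maxOcc = 64L) {
  if (k < 8L || k > 32L) stop("k must be in [8, 32]")
  ptr <- cpp_build_index(refSequences(ref), refNames(ref), as.integer(k),
                         as.integer(maxOcc))
  structure(list(ptr = ptr, k = as.integer(k), maxOcc = as.integer(maxOcc),
                 contigs = refNames(ref), checksum = refChecksum(ref)),
            class = "SeedIndex")
}

#' @export
print.SeedIndex <- function(x, ...) {
  info <- cpp_index_info(x$ptr)
  cat("SeedIndex: k =", info$k, ";", info$nKmers, "k-mers indexed;",
      info$nRepetitive, "repetitive\n")
  invisible(x)
}

#' Look up a k-mer in a seed index
#' @param index A seed index from \code{\link{buildSeedIndex}}.
#' @param kmer A k-length string.
#' @return List with \code{positions} (0-based global offsets) and a
#'   \code{repetitive} flag.
#' @export
seedLookup <- function(index, kmer) cpp_index_lookup(index$ptr, kmer)

#' Align a single read, returning all candidate placements
#'
#' Seeds are taken at non-overlapping offsets (plus one flush with the read
#' end); seed hits are clustered by diagonal and each cluster is extended by
#' windowed affine-gap DP (match +1, mismatch -4, gap open 6, gap extend 1).
#' Ends are soft-clipped whenever clipping improves the local score.
#' Candidates are returned sorted by score, ties broken by
#' (contig, position, strand with + first).
#'
#' @param read Read sequence (A/C/G/T/N).
#' @param index Seed index.
#' @param maxCand Candidate loci evaluated per strand.
#' @return \code{data.frame} of candidates: contig index, 0-based pos,
#'   strand, score, CIGAR.
#' @export
alignRead <- function(read, index, maxCand = 8L) {
  if (nchar(read) < index$k) stop("read shorter than seed length k")
  cand <- cpp_align_candidates(index$ptr, toupper(read), maxCand)
  data.frame(contig = cand$contig, pos = cand$pos,
             strand = ifelse(cand$strand, "+", "-"), score = cand$score,
             cigar = cand$cigar, stringsAsFactors = FALSE)
}

#' Select and rescue a mate pair
#'
#' Chooses the candidate combination maximizing score1 + score2 + pair bonus,
#' where the bonus applies iff the mates are on opposite strands in FR
#' orientation with an insert within mean +/- 4 sd. When one mate has no
#' candidates, a DP rescue is attempted in the window implied by the placed
#' mate and the insert model. Mapping quality is 60 when the best candidate
#' beats the second best by >= 10 score points, otherwise 6 times the gap
#' (0 for ties).
#'
#' @param read1,read2 Mate sequences (sequencing orientation).
#' @param index Seed index.
#' @param insertMean,insertSd Insert size model (outer distance).
#' @param pairBonus Score bonus for a properly paired combination.
#' @return List with per-mate placements and \code{properlyPaired}.
#' @export
pairAndRescue <- function(read1, read2, index, insertMean = 500,
                          insertSd = 25, pairBonus = 20L) {
  cpp_pair_select(index$ptr, toupper(read1), toupper(read2), insertMean,
                  insertSd, pairBonus)
}

#' Align a full paired-end read set
#'
#' The batch driver behind the pipeline: per-pair candidate generation, pair
#' selection with rescue, and mapping quality assignment, all with the
#' semantics of \code{\link{alignRead}} and \code{\link{pairAndRescue}}.
#'
#' @param pairs A \linkS4class{ReadPairSet}.
#' @param index Seed index built from the same reference.
#' @param insertMean,insertSd Insert model.
#' @param pairBonus Proper-pair score bonus.
#' @return An \linkS4class{AlignedReads} (2 rows per pair; unmapped reads
#'   retained with \code{mapped = FALSE}).
#' @export
alignReadPairs <- function(pairs, index, insertMean = 500, insertSd = 25,
                           pairBonus = 20L) {
  res <- cpp_align_pairs(index$ptr, pairs@seq1, pairs@qual1, pairs@seq2,
                         pairs@qual2, insertMean, insertSd, pairBonus)
  d <- data.table::data.table(
    pairId = res$pairId, mate = res$mate,
    qname = rep(pairs@name, each = 2L),
    contig = res$contig, pos = res$pos,
    strand = ifelse(res$strand, "+", "-"),
    mapq = res$mapq, score = res$score, cigar = res$cigar,
    seq = res$seq, qual = res$qual, proper = res$proper,
    mapped = res$mapped, dup = FALSE)
  new("AlignedReads", data = d, contigs = index$contigs)
}

#' Alignment table accessor
#' @param aln An \linkS4class{AlignedReads}.
#' @return The underlying \code{data.table} (copy-on-modify semantics apply).
#' @export
alignmentData <- function(aln) aln@data

#' Reconstruct read bases from an edit script
#'
#' Applies a CIGAR to the reference span it covers and checks the result
#' against the stored read bases (soft-clips excluded); used by the
#' edit-script round-trip invariant.
#'
#' @param aln An \linkS4class{AlignedReads}.
#' @param ref The \linkS4class{Reference} aligned against.
#' @param rows Which alignment rows to check (default all mapped).
#' @return Logical vector: TRUE where aligned bases reproduce exactly from
#'   reference + edit script.
#' @export
checkEditScripts <- function(aln, ref, rows = NULL) {
  d <- aln@data
  if (is.null(rows)) rows <- which(d$mapped)
  seqs <- refSequences(ref)
  vapply(rows, function(i) {
    ops <- parseCigar(d$cigar[i])
    rp <- d$pos[i]
    qp <- 0L
    rs <- seqs[[d$contig[i]]]
    rd <- d$seq[i]
    okAll <- TRUE
    for (j in seq_len(nrow(ops))) {
      len <- ops$len[j]
      switch(ops$op[j],
        "S" = { qp <- qp + len },
        "=" = {
          okAll <- okAll &&
            substr(rd, qp + 1L, qp + len) == substr(rs, rp + 1L, rp + len)
          qp <- qp + len; rp <- rp + len
        },
        "X" = {
          a <- substr(rd, qp + 1L, qp + len)
          b <- substr(rs, rp + 1L, rp + len)
          okAll <- okAll && all(strsplit(a, "")[[1]] != strsplit(b, "")[[1]] |
                                  strsplit(a, "")[[1]] == "N" |
                                  strsplit(b, "")[[1]] == "N")
          qp <- qp + len; rp <- rp + len
        },
        "I" = { qp <- qp + len },
        "D" = { rp <- rp + len },
        "M" = { qp <- qp + len; rp <- rp + len })
    }
    okAll
  }, logical(1L))
}

# parse an extended CIGAR into a data.frame of (len, op)
parseCigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[=XIDSM]", cigar))[[1]]
  data.frame(len = lens, op = ops, stringsAsFactors = FALSE)
}

# per-read score implied by the current placement (same scoring as the DP)
placementScores <- function(aln) {
  cpp_cigar_stats(aln@data$cigar)$score
}
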