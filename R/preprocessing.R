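#' Mark duplicate read pairs in a single hash pass
#'
#' No external sort: pairs are keyed by the unclipped 5' positions and
#' strands of both mates (mate keys ordered canonically so the key is
#' orientation-invariant; soft-clipped bases are restored when computing the
#' 5' ends so trimmed duplicates still collide). Among pairs sharing a key,
#' the pair with the highest summed base quality is kept; ties keep the
#' first-seen pair in input order. Unpaired mapped reads are keyed by their
#' own position and strand.
#'
#' @param aln An \linkS4class{AlignedReads}.
#' @return The same object with duplicate flags set, plus a \code{"stats"}
#'   attribute (input/kept/flagged pair counts).
#' @export
markDuplicates <- function(aln) {
  d <- data.table::copy(aln@data)
  st <- cpp_cigar_stats(d$cigar)
  # unclipped 5' coordinate: for + strand the start minus the leading clip,
  # for - strand the end plus the trailing clip
  end5 <- ifelse(d$strand == "+",
                 d$pos - st$leadClip,
                 d$pos + st$refSpan - 1L + st$trailClip)
  qsum <- cpp_qualsum(d$qual)
  dt <- data.table::data.table(
    idx = seq_len(nrow(d)), pairId = d$pairId, mapped = d$mapped,
    keystr = paste(d$contig, end5, d$strand, sep = ":"), qsum = qsum)
  dtm <- dt[mapped == TRUE]
  # canonical mate order within each pair makes the key orientation-invariant
  data.table::setorder(dtm, pairId, keystr)
  dtm[, slot := seq_len(.N), by = "pairId"]
  w <- data.table::dcast(dtm, pairId ~ slot,
                         value.var = list("keystr", "qsum", "idx"))
  if (!"keystr_2" %in% names(w)) {
    w[, `:=`(keystr_2 = NA_character_, qsum_2 = NA_integer_,
             idx_2 = NA_integer_)]
  }
  byPair <- data.table::data.table(
    pairId = w$pairId,
    dkey = paste(w$keystr_1, data.table::fifelse(is.na(w$keystr_2), "",
                                                 w$keystr_2), sep = "|"),
    qsum = w$qsum_1 + data.table::fifelse(is.na(w$qsum_2), 0L, w$qsum_2),
    first = pmin(w$idx_1, w$idx_2, na.rm = TRUE))
  data.table::setorder(byPair, first)       # canonical input order
  byPair[, keep := FALSE]
  byPair[byPair[, .I[which.max(qsum)], by = "dkey"]$V1, keep := TRUE]
  dupPairs <- byPair$pairId[!byPair$keep]
  d[, dup := pairId %in% dupPairs & mapped]
  stats <- list(inputPairs = nrow(byPair),
                keptPairs = sum(byPair$keep),
                flaggedPairs = length(dupPairs))
  out <- new("AlignedReads", data = d, contigs = aln@contigs)
  attr(out, "stats") <- stats
  out
}

#' Build a base quality recalibration table
#'
#' Every aligned, non-clipped base with reported quality >= \code{minQ}
#' outside \code{maskSites} contributes one observation to its covariate
#' cell (reported quality, machine cycle, preceding+current dinucleotide in
#' sequencing orientation); a mismatch is counted when the read base differs
#' from the reference base. Cell empirical quality is
#' phred((mismatches+1)/(observations+2)), capped at 60. Duplicate-flagged
#' reads are excluded.
#'
#' Variant positions must be masked so true variation is not mistaken for
#' machine error: \code{\link{candidateVariantMask}} derives a mask from a
#' first-pass pileup (non-reference allele fraction >= 0.2) so no external
#' known-sites file is needed.
#'
#' @param aln Deduplicated \linkS4class{AlignedReads}.
#' @param ref Matching \linkS4class{Reference}.
#' @param maskSites Logical vector over concatenated genome positions
#'   (TRUE = excluded), or NULL for no masking.
#' @param minQ Minimum reported quality tabulated.
#' @return A \linkS4class{RecalTable}.
#' @export
buildRecalTable <- function(aln, ref, maskSites = NULL, minQ = 2L) {
  d <- aln@data
  use <- d$mapped & !d$dup
  if (!any(use)) stop("no usable alignments: cannot recalibrate")
  lens <- refLengths(ref)
  offsets <- cumsum(c(0L, utils::head(as.integer(lens), -1L)))
  if (is.null(maskSites)) maskSites <- rep(FALSE, sum(lens))
  maxCycle <- max(nchar(d$seq[use]))
  res <- cpp_bqsr_build(d$contig, d$pos, d$strand == "+", d$cigar, d$seq,
                        d$qual, !use, refSequences(ref), offsets, maskSites,
                        maxCycle, as.integer(minQ))
  if (res$total == 0) stop("no usable observations: cannot recalibrate")
  emp <- phredOf((res$mism + 1) / (res$obs + 2))
  margObs <- apply(res$obs, 1L, sum)
  margMism <- apply(res$mism, 1L, sum)
  marginal <- ifelse(margObs > 0, phredOf((margMism + 1) / (margObs + 2)),
                     NA_real_)
  new("RecalTable", obs = res$obs, mism = res$mism, empirical = emp,
      marginal = marginal, maxCycle = as.integer(maxCycle),
      total = res$total)
}

phredOf <- function(p) pmin(round(-10 * log10(p)), 60)

#' Mask of candidate variant positions for recalibration
#'
#' First-pass scan: positions where the non-reference fraction of the pileup
#' is at least \code{minFrac} are excluded from error tabulation.
#'
#' @param aln \linkS4class{AlignedReads} (pre-realignment is fine).
#' @param ref Matching \linkS4class{Reference}.
#' @param minFrac Non-reference fraction threshold.
#' @return Logical vector over concatenated genome positions.
#' @export
candidateVariantMask <- function(aln, ref, minFrac = 0.2) {
  snap <- buildSnapshot(aln, ref)
  counts <- snap@counts
  refCodes <- referenceCodes(ref)
  refN <- counts[cbind(seq_len(nrow(counts)), pmax(refCodes, 0L) + 1L)] +
    counts[cbind(seq_len(nrow(counts)), pmax(refCodes, 0L) + 5L)]
  depth <- counts[, 19L]
  mask <- depth > 0L & (depth - refN) / pmax(depth, 1L) >= minFrac
  mask[refCodes < 0L] <- TRUE
  mask
}

# 0..3 base code (A,C,G,T) per concatenated genome position, -1 for N
referenceCodes <- function(ref) {
  seqs <- refSequences(ref)
  unlist(lapply(seqs, function(s) {
    codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T")) - 1L
    codes[is.na(codes)] <- -1L
    codes
  }), use.names = FALSE)
}

#' Apply a recalibration table to read qualities
#'
#' Each base quality is replaced by its covariate cell's empirical quality;
#' bases in unseen cells fall back to the reported-quality marginal.
#' Deterministic: re-applying the same table to already-recalibrated reads
#' is a pure function of the (new) reported qualities.
#'
#' @param aln An \linkS4class{AlignedReads}.
#' @param table A \linkS4class{RecalTable}.
#' @return The alignments with replaced qualities.
#' @export
applyRecalibration <- function(aln, table) {
  d <- data.table::copy(aln@data)
  d$qual <- as.character(cpp_bqsr_apply(d$seq, d$qual, d$strand == "+",
                                        as.integer(table@obs),
                                        as.numeric(table@empirical),
                                        table@marginal, table@maxCycle))
  new("AlignedReads", data = d, contigs = aln@contigs)
}

#' Dump a recalibration table to TSV for inspection
#' @param table A \linkS4class{RecalTable}.
#' @param path Output TSV path.
#' @export
writeRecalTable <- function(table, path) {
  idx <- which(table@obs > 0, arr.ind = TRUE)
  dn <- c(paste0(rep(c("A", "C", "G", "T"), each = 4L),
                 rep(c("A", "C", "G", "T"), 4L)), "NX")
  df <- data.frame(reportedQ = idx[, 1L] - 1L, cycle = idx[, 2L],
                   dinuc = dn[idx[, 3L]],
                   observations = table@obs[idx],
                   mismatches = table@mism[idx],
                   empiricalQ = table@empirical[idx])
  df <- df[order(df$reportedQ, df$cycle, df$dinuc), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
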