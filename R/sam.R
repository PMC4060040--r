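#' Import alignments from a SAM file
#'
#' Lets callers bypass the internal aligner. Mapped records are converted to
#' the internal edit-script representation (M runs are split into =/X by
#' comparison with the reference); hard-clipped records are rejected,
#' soft-clips preserved, unmapped records skipped and counted.
#'
#' @param path SAM file path (text; @SQ lines must match the reference).
#' @param ref The \linkS4class{Reference} the file was aligned against.
#' @return An \linkS4class{AlignedReads}; the number of skipped unmapped
#'   records is attached as attribute \code{"unmapped"}.
#' @export
readSamAlignments <- function(path, ref) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required to read SAM input")
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  unknown <- setdiff(names(hdr), refNames(ref))
  if (length(unknown))
    stop("unknown contig in SAM header: ", paste(unknown, collapse = ", "))
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "mapq", "cigar", "seq", "qual"))
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  mappedSel <- !bitwAnd(b$flag, 4L)
  nUnmapped <- sum(!mappedSel)
  if (any(grepl("H", b$cigar[mappedSel])))
    stop("hard-clipped records are not supported")
  keep <- which(mappedSel)
  seqs <- as.character(b$seq[keep])
  quals <- as.character(b$qual[keep])
  cig <- b$cigar[keep]
  contig <- match(as.character(b$rname[keep]), refNames(ref))
  pos0 <- b$pos[keep] - 1L
  refseqs <- refSequences(ref)
  # verify CIGAR/sequence consistency and refine M into =/X
  st <- cpp_cigar_stats(cig)
  if (any(st$readLen != nchar(seqs)))
    stop("CIGAR/sequence length inconsistency at record ",
         keep[which(st$readLen != nchar(seqs))[1L]])
  lens <- refLengths(ref)
  if (any(pos0 + st$refSpan > lens[contig]))
    stop("alignment beyond contig end")
  cig <- vapply(seq_along(cig), function(i) {
    refineCigar(cig[i], seqs[i], refseqs[[contig[i]]], pos0[i])
  }, character(1L))
  flags <- b$flag[keep]
  d <- data.table::data.table(
    pairId = seq_along(keep), mate = ifelse(bitwAnd(flags, 128L) > 0L, 2L, 1L),
    qname = b$qname[keep], contig = contig, pos = pos0,
    strand = ifelse(bitwAnd(flags, 16L) > 0L, "-", "+"),
    mapq = b$mapq[keep], score = 0L, cigar = cig, seq = seqs, qual = quals,
    proper = bitwAnd(flags, 2L) > 0L, mapped = TRUE, dup = FALSE)
  # mates of one pair share a pairId
  d$pairId <- as.integer(factor(d$qname, levels = unique(d$qname)))
  d$score <- cpp_cigar_stats(d$cigar)$score
  out <- new("AlignedReads", data = d, contigs = refNames(ref))
  attr(out, "unmapped") <- nUnmapped
  out
}

# split M runs into =/X by comparing read and reference
refineCigar <- function(cigar, seq, refseq, pos0) {
  ops <- parseCigar(cigar)
  if (!any(ops$op == "M")) return(cigar)
  outOp <- character(0); outLen <- integer(0)
  push <- function(op, len) {
    n <- length(outOp)
    if (n && outOp[n] == op) outLen[n] <<- outLen[n] + len
    else { outOp[n + 1L] <<- op; outLen[n + 1L] <<- len }
  }
  qp <- 0L; rp <- pos0
  for (j in seq_len(nrow(ops))) {
    len <- ops$len[j]; op <- ops$op[j]
    if (op == "M") {
      a <- strsplit(substr(seq, qp + 1L, qp + len), "")[[1]]
      b <- strsplit(substr(refseq, rp + 1L, rp + len), "")[[1]]
      eq <- a == b & a != "N"
      r <- rle(eq)
      for (t in seq_along(r$lengths))
        push(if (r$values[t]) "=" else "X", r$lengths[t])
      qp <- qp + len; rp <- rp + len
    } else {
      push(op, len)
      if (op %in% c("=", "X")) { qp <- qp + len; rp <- rp + len }
      else if (op == "I" || op == "S") qp <- qp + len
      else if (op == "D") rp <- rp + len
    }
  }
  paste0(outLen, outOp, collapse = "")
}

#' Write alignments as SAM (debug output)
#'
#' Emits the selected alignments with bit-exact CIGAR derived from the edit
#' script (=/X merged into M, soft clips as S).
#'
#' @param aln An \linkS4class{AlignedReads}.
#' @param ref Matching \linkS4class{Reference}.
#' @param path Output SAM path.
#' @export
writeSamAlignments <- function(aln, ref, path) {
  d <- aln@data[aln@data$mapped]
  lens <- refLengths(ref)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens), con)
  samCig <- gsub("([0-9]+)[=X]", "\\1M", d$cigar)
  samCig <- vapply(samCig, mergeAdjacentM, character(1L), USE.NAMES = FALSE)
  flag <- 1L +
    ifelse(d$proper, 2L, 0L) +
    ifelse(d$strand == "-", 16L, 0L) +
    ifelse(d$mate == 1L, 64L, 128L) +
    ifelse(d$dup, 1024L, 0L)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                   d$qname, flag, aln@contigs[d$contig], d$pos + 1L, d$mapq,
                   samCig, d$seq, d$qual)
  writeLines(lines, con)
  invisible(path)
}

mergeAdjacentM <- function(cigar) {
  ops <- parseCigar(cigar)
  keepOp <- character(0); keepLen <- integer(0)
  for (j in seq_len(nrow(ops))) {
    n <- length(keepOp)
    if (n && keepOp[n] == ops$op[j]) keepLen[n] <- keepLen[n] + ops$len[j]
    else { keepOp <- c(keepOp, ops$op[j]); keepLen <- c(keepLen, ops$len[j]) }
  }
  paste0(keepLen, keepOp, collapse = "")
}
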