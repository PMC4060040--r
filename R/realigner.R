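#' Collect indel hypotheses from gapped alignments
#'
#' Every I/D edit op across the (deduplicated) reads becomes a candidate;
#' candidates are left-normalized through repeat context, identical
#' (anchor, type, payload) candidates merged with summed support, and
#' candidates below \code{minSupport} dropped. Soft-clip clusters of at
#' least \code{clipSupport} reads sharing a boundary seed an insertion
#' candidate whose payload is the consensus of the clipped bases.
#'
#' @param aln An \linkS4class{AlignedReads}.
#' @param ref Matching \linkS4class{Reference}.
#' @param minSupport Minimum supporting reads for a gapped-alignment
#'   candidate.
#' @param clipSupport Minimum clipped reads sharing a boundary.
#' @return \code{data.table}: contig, anchor (0-based base left of the
#'   event), type ("I"/"D"), payload, len, support.
#' @export
collectIndelHypotheses <- function(aln, ref, minSupport = 2L,
                                   clipSupport = 4L) {
  d <- aln@data
  exclude <- !d$mapped | d$dup
  raw <- data.table::as.data.table(
    cpp_extract_indels(d$contig, d$pos, d$cigar, d$seq, exclude))
  seqs <- refSequences(ref)
  hyp <- list()
  if (nrow(raw)) {
    for (ci in unique(raw$contig)) {
      sub <- raw[raw$contig == ci]
      nz <- cpp_normalize_indels(seqs[[ci]], sub$anchor, sub$type,
                                 sub$payload)
      sub$anchor <- nz$anchor
      sub$payload <- as.character(nz$payload)
      hyp[[length(hyp) + 1L]] <- sub
    }
  }
  merged <- if (length(hyp)) {
    data.table::rbindlist(hyp)[, .(support = .N, len = len[1L]),
                               by = c("contig", "anchor", "type", "payload")]
  } else {
    data.table::data.table(contig = integer(0), anchor = integer(0),
                           type = character(0), payload = character(0),
                           support = integer(0), len = integer(0))
  }
  merged <- merged[merged$support >= minSupport]
  merged[, origin := "gap"]
  clips <- clipSeededHypotheses(d, seqs, clipSupport)
  if (nrow(clips)) {
    clips[, origin := "clip"]
    # clips at the flank of an existing gap-derived hypothesis are already
    # explained by that event (reads ending at an indel boundary are
    # clipped); interpreting them as a separate insertion plants artifact
    # evidence, so such seeds are dropped
    if (nrow(merged)) {
      near <- vapply(seq_len(nrow(clips)), function(i) {
        any(merged$contig == clips$contig[i] &
              abs(merged$anchor - clips$anchor[i]) <= 30L)
      }, logical(1L))
      clips <- clips[!near]
    }
    clips <- clips[!merged, on = c("contig", "anchor", "type", "payload")]
    merged <- data.table::rbindlist(list(merged, clips), use.names = TRUE)
  }
  data.table::setorder(merged, contig, anchor, type, payload)
  merged[]
}

# soft-clip clusters: >= clipSupport reads whose aligned segment ends at the
# same reference boundary seed an insertion hypothesis resolved by the
# consensus of the clipped bases
clipSeededHypotheses <- function(d, seqs, clipSupport) {
  st <- cpp_cigar_stats(d$cigar)
  use <- d$mapped & !d$dup
  empty <- data.table::data.table(contig = integer(0), anchor = integer(0),
                                  type = character(0), payload = character(0),
                                  support = integer(0), len = integer(0))
  # right-side clips cluster at alignment end; left-side clips at start
  rsel <- which(use & st$trailClip >= 2L)
  lsel <- which(use & st$leadClip >= 2L)
  cl <- data.table::rbindlist(list(
    data.table::data.table(
      idx = rsel, contig = d$contig[rsel],
      boundary = d$pos[rsel] + st$refSpan[rsel], side = "R",
      clipLen = st$trailClip[rsel]),
    data.table::data.table(
      idx = lsel, contig = d$contig[lsel], boundary = d$pos[lsel],
      side = "L", clipLen = st$leadClip[lsel])))
  if (nrow(cl) == 0L) return(empty)
  grp <- cl[, .(support = .N, idxs = list(idx), clipLens = list(clipLen)),
            by = c("contig", "boundary", "side")]
  grp <- grp[grp$support >= clipSupport]
  if (nrow(grp) == 0L) return(empty)
  out <- list()
  for (i in seq_len(nrow(grp))) {
    idxs <- grp$idxs[[i]]
    side <- grp$side[i]
    clLens <- grp$clipLens[[i]]
    L <- min(clLens)
    L <- min(L, 20L)
    if (L < 1L) next
    segs <- vapply(seq_along(idxs), function(t) {
      s <- d$seq[idxs[t]]
      if (side == "R") substr(s, nchar(s) - clLens[t] + 1L,
                              nchar(s) - clLens[t] + L)
      else substr(s, clLens[t] - L + 1L, clLens[t])
    }, character(1L))
    cons <- consensusString(segs)
    if (grepl("N", cons)) next
    anchor <- if (side == "R") grp$boundary[i] - 1L else grp$boundary[i] - 1L
    if (anchor < 1L) next
    nz <- cpp_normalize_indels(seqs[[grp$contig[i]]], anchor, "I", cons)
    out[[length(out) + 1L]] <- data.table::data.table(
      contig = grp$contig[i], anchor = nz$anchor[1L], type = "I",
      payload = as.character(nz$payload[1L]), support = grp$support[i],
      len = nchar(cons))
  }
  if (!length(out)) return(empty)
  data.table::rbindlist(out)[, .(support = max(support), len = len[1L]),
                             by = c("contig", "anchor", "type", "payload")]
}

consensusString <- function(segs) {
  m <- do.call(rbind, strsplit(segs, ""))
  paste(apply(m, 2L, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    if (tb[1L] / length(col) >= 0.6) names(tb)[1L] else "N"
  }), collapse = "")
}

#' Realign reads against hypothetical indel haplotypes
#'
#' Hypotheses are grouped into windows (anchor +/- \code{flank}); each
#' window's haplotype set is the reference plus one single-event edit per
#' hypothesis (the \code{maxHyp} best-supported when more collide). Every
#' read overlapping the window is scored against every haplotype by the
#' same affine-gap DP the aligner uses — an exhaustive read-by-haplotype
#' evaluation. The haplotype maximizing the summed per-read scores is
#' selected; reads whose placement on the winning haplotype strictly beats
#' their current score are rewritten as reference-space alignments through
#' the chosen indel, others keep their original placement, so the summed
#' window score never decreases and re-realignment is a no-op.
#'
#' @param aln An \linkS4class{AlignedReads}.
#' @param ref Matching \linkS4class{Reference}.
#' @param hypotheses From \code{\link{collectIndelHypotheses}} (NULL to
#'   collect internally).
#' @param flank Window half-width around a hypothesis anchor.
#' @param maxWindow Maximum window width before splitting.
#' @param maxHyp Haplotypes per window beyond the reference.
#' @return The realigned \linkS4class{AlignedReads}; a per-window report is
#'   attached as attribute \code{"report"}.
#' @export
realignReads <- function(aln, ref, hypotheses = NULL, flank = 100L,
                         maxWindow = 400L, maxHyp = 8L) {
  if (is.null(hypotheses)) hypotheses <- collectIndelHypotheses(aln, ref)
  d <- data.table::copy(aln@data)
  if (nrow(hypotheses) == 0L) {
    out <- new("AlignedReads", data = d, contigs = aln@contigs)
    attr(out, "report") <- data.table::data.table()
    return(out)
  }
  seqs <- refSequences(ref)
  lens <- refLengths(ref)
  st <- cpp_cigar_stats(d$cigar)
  readEnd <- d$pos + st$refSpan
  origScore <- st$score
  # per-contig position-sorted read index for fast window overlap queries
  usable <- which(d$mapped & !d$dup)
  byContig <- split(usable, d$contig[usable])
  byContig <- lapply(byContig, function(ix) ix[order(d$pos[ix])])
  # snapshot of the sorted positions: rewrites move starts by at most the
  # indel length, absorbed by the query padding below
  posByContig <- lapply(byContig, function(ix) d$pos[ix])
  maxSpan <- if (length(usable)) max(st$refSpan[usable]) else 0L
  maxSpan <- maxSpan + 32L
  report <- list()
  hy <- data.table::copy(hypotheses)
  if (!"origin" %in% names(hy)) hy[, origin := "gap"]
  data.table::setorder(hy, contig, anchor)
  # group hypotheses whose flanked windows overlap
  hy[, wstart := pmax(0L, anchor - flank)]
  hy[, wend := pmin(lens[contig], anchor + len + flank)]
  hy[, grpLocal := cumsum(c(1L, as.integer(
    wstart[-1L] > cummax(wend[-.N])))), by = "contig"]
  hy[, grp := paste0(contig, ":", grpLocal)]
  for (g in unique(hy$grp)) {
    win <- hy[hy$grp == g]
    ci <- win$contig[1L]
    ws <- min(win$wstart); we <- max(win$wend)
    if (we - ws > maxWindow) {
      # split oversized windows at hypothesis boundaries, keeping overlap
      warning("realignment window ", ws, "-", we, " exceeds ", maxWindow,
              " bp; splitting")
      mid <- ws + (we - ws) %/% 2L
      if (any(win$anchor < mid)) win <- win[win$anchor < mid]
      else win <- win[1L]
      we <- min(we, max(win$wend))
    }
    if (nrow(win) > maxHyp) {
      data.table::setorder(win, -support, anchor)
      win <- win[seq_len(maxHyp)]
      data.table::setorder(win, anchor)
    }
    refWin <- substr(seqs[[ci]], ws + 1L, we)
    win[, ra := anchor - ws]                   # 0-based within window
    win[, evLen := nchar(payload)]
    win[type == "D", evLen := as.integer(payload)]
    hapDefs <- lapply(seq_len(nrow(win)), function(i) win[i])
    # one combined haplotype applying all mutually compatible hypotheses:
    # nearby co-occurring indels on one haplotype are otherwise unreachable
    # by single-event edits and leave mismatch artifacts behind
    if (sum(win$origin == "gap") >= 2L) {
      cand <- win[win$origin == "gap"][order(-support, ra)]
      acc <- list()
      occupied <- matrix(numeric(0), ncol = 2L)
      for (i in seq_len(nrow(cand))) {
        f0 <- cand$ra[i]
        f1 <- cand$ra[i] + (if (cand$type[i] == "D") cand$evLen[i] else 0L) + 1L
        if (nrow(occupied) == 0L ||
            all(f1 <= occupied[, 1L] | f0 >= occupied[, 2L])) {
          acc[[length(acc) + 1L]] <- cand[i]
          occupied <- rbind(occupied, c(f0, f1))
        }
      }
      if (length(acc) >= 2L) {
        joint <- data.table::rbindlist(acc)
        data.table::setorder(joint, ra)
        hapDefs[[length(hapDefs) + 1L]] <- joint
      }
    }
    built <- lapply(hapDefs, function(evs) buildEventHaplotype(refWin, evs))
    haps <- vapply(built, `[[`, character(1L), "seq")
    hapSegs <- lapply(built, `[[`, "segs")
    ix <- byContig[[as.character(ci)]]
    if (is.null(ix) || !length(ix)) next
    posC <- posByContig[[as.character(ci)]]
    lo <- findInterval(ws - maxSpan - 1L, posC) + 1L
    hi <- findInterval(we - 1L + 32L, posC)
    if (hi < lo) next
    rows <- ix[lo:hi]
    rows <- rows[d$pos[rows] < we & readEnd[rows] > ws]
    if (!length(rows)) next
    allHaps <- c(refWin, haps)
    sc <- cpp_score_matrix(d$seq[rows], allHaps)
    hapTotals <- colSums(sc)
    best <- which.max(hapTotals)               # ref haplotype wins ties
    nRewritten <- 0L
    # a read is rewritten iff its best placement on the selected haplotype
    # strictly beats its original score (ties keep the original placement);
    # the reference-space score of the rewritten alignment legitimately pays
    # the gap penalty of the chosen indel
    improved <- which(sc[, best] > origScore[rows])
    if (length(improved)) {
      fit <- cpp_fit_batch(d$seq[rows[improved]], allHaps[best])
      segs <- if (best == 1L) NULL else hapSegs[[best - 1L]]
      for (t in seq_along(improved)) {
        r <- rows[improved[t]]
        conv <- hapToRefAlignment(fit$cigar[t], fit$hapStart[t], ws, segs)
        if (is.null(conv)) next
        if (conv$pos == d$pos[r] && conv$cigar == d$cigar[r]) next
        newScore <- cpp_cigar_stats(conv$cigar)$score[1L]
        data.table::set(d, r, "pos", as.integer(conv$pos))
        data.table::set(d, r, "cigar", conv$cigar)
        data.table::set(d, r, "score", as.integer(newScore))
        origScore[r] <- newScore
        readEnd[r] <- conv$pos + cpp_cigar_stats(conv$cigar)$refSpan[1L]
        nRewritten <- nRewritten + 1L
      }
    }
    report[[length(report) + 1L]] <- data.table::data.table(
      contig = ci, windowStart = ws, windowEnd = we,
      nHypotheses = nrow(win), selected = best - 1L,
      readsInWindow = length(rows), readsRewritten = nRewritten)
  }
  out <- new("AlignedReads", data = d, contigs = aln@contigs)
  attr(out, "report") <- if (length(report)) data.table::rbindlist(report)
                         else data.table::data.table()
  out
}

# Build a haplotype by applying a set of non-overlapping indel events
# (window-relative anchors, sorted) to the reference window, together with
# the haplotype->reference segment table used to convert alignments back.
buildEventHaplotype <- function(refWin, events) {
  pieces <- character(0)
  segHap <- integer(0); segRef <- integer(0); segLen <- integer(0)
  hapCur <- 0L; refCur <- 0L
  addSeg <- function(str, refAt) {
    if (nchar(str) == 0L) return()
    pieces[length(pieces) + 1L] <<- str
    segHap[length(segHap) + 1L] <<- hapCur
    segRef[length(segRef) + 1L] <<- refAt
    segLen[length(segLen) + 1L] <<- nchar(str)
    hapCur <<- hapCur + nchar(str)
  }
  for (i in seq_len(nrow(events))) {
    ra <- events$ra[i]
    addSeg(substr(refWin, refCur + 1L, ra + 1L), refCur)
    refCur <- ra + 1L
    if (events$type[i] == "I") {
      addSeg(events$payload[i], NA_integer_)
    } else {
      refCur <- refCur + as.integer(events$payload[i])
    }
  }
  addSeg(substr(refWin, refCur + 1L, nchar(refWin)), refCur)
  list(seq = paste(pieces, collapse = ""),
       segs = data.table::data.table(hapStart = segHap, refStart = segRef,
                                     len = segLen))
}

# Convert an alignment against an event haplotype back to reference space.
# hapCigar aligns the read to the haplotype starting at hapStart (0-based);
# segs is the haplotype's segment table (NA refStart = inserted bases).
# Returns NULL when the placement cannot be expressed in reference
# coordinates (e.g. alignment confined to inserted bases).
hapToRefAlignment <- function(hapCigar, hapStart, windowStart, segs) {
  if (is.null(segs)) {
    return(list(pos = windowStart + hapStart, cigar = hapCigar))
  }
  ops <- parseCigar(hapCigar)
  outOp <- character(0); outLen <- integer(0)
  push <- function(op, len) {
    if (len <= 0L) return()
    n <- length(outOp)
    if (n && outOp[n] == op) outLen[n] <<- outLen[n] + len
    else { outOp[n + 1L] <<- op; outLen[n + 1L] <<- len }
  }
  hp <- hapStart
  started <- FALSE
  refPos <- NA_integer_
  lastRefEnd <- NA_integer_
  sH <- segs$hapStart; sR <- segs$refStart; sL <- segs$len
  for (j in seq_len(nrow(ops))) {
    len <- ops$len[j]; op <- ops$op[j]
    if (op == "S") { push("S", len); next }
    if (op == "I") { if (started) push("I", len) else push("S", len); next }
    h0 <- hp; h1 <- hp + len
    while (h0 < h1) {
      si <- findInterval(h0, sH)
      if (si < 1L) return(NULL)
      p1 <- min(h1, sH[si] + sL[si])
      if (p1 <= h0) return(NULL)
      if (is.na(sR[si])) {
        # read bases over inserted haplotype bases become an insertion
        if (op != "D") {
          if (started) push("I", p1 - h0) else push("S", p1 - h0)
        }
      } else {
        refAt <- sR[si] + (h0 - sH[si])
        if (started && refAt > lastRefEnd)
          push("D", refAt - lastRefEnd)       # deletion between segments
        if (!started && op != "D") {
          refPos <- windowStart + refAt
          started <- TRUE
        }
        if (started) {
          push(op, p1 - h0)
          lastRefEnd <- refAt + (p1 - h0)
        }
      }
      h0 <- p1
    }
    hp <- h1
  }
  if (!started) return(NULL)
  # an alignment must not start or end with an insertion in reference
  # space: boundary I runs become soft clips; a dangling boundary D is
  # dropped
  nonS <- which(outOp != "S")
  if (length(nonS)) {
    if (outOp[nonS[1L]] == "I") outOp[nonS[1L]] <- "S"
    nonS <- which(outOp != "S")
    if (length(nonS) && outOp[nonS[length(nonS)]] == "I")
      outOp[nonS[length(nonS)]] <- "S"
  }
  nonS <- which(outOp != "S")
  if (length(nonS) && outOp[nonS[length(nonS)]] == "D") {
    outLen <- outLen[-nonS[length(nonS)]]
    outOp <- outOp[-nonS[length(nonS)]]
  }
  if (!any(outOp %in% c("=", "X"))) return(NULL)
  # adjacent I/D pairs mean the read does not actually support the
  # haplotype's event structure there (a self-cancelling gap pair is never
  # optimal under affine scoring); such placements are rejected and the
  # read keeps its original alignment
  gapOps <- outOp[outOp != "S"]
  if (any(gapOps[-1L] %in% c("I", "D") &
            gapOps[-length(gapOps)] %in% c("I", "D") &
            gapOps[-1L] != gapOps[-length(gapOps)]))
    return(NULL)
  cig <- paste0(outLen, outOp, collapse = "")
  cig <- mergeAdjacentM(cig)
  list(pos = refPos, cigar = cig)
}
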