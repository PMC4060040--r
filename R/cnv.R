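#' Somatic CNV segmentation from a tumor-normal snapshot pair
#'
#' Per fixed-width window the depth ratio
#' r = log2( (tumor/tumor median) / (normal/normal median) ) is computed,
#' GC-corrected by subtracting the median ratio of the window's GC bin, and
#' segmented by recursive binary splitting on the two-sided t statistic:
#' a split is accepted when |difference in means| >= \code{minDelta} and
#' the Bonferroni-adjusted p value (within the current segment's candidate
#' splits) is below \code{alpha}. Segment states: GAIN when the mean ratio
#' is >= +0.3, LOSS when <= -0.3, else NEUTRAL.
#'
#' @param normal,tumor \linkS4class{Snapshot}s on the same reference.
#' @param ref The \linkS4class{Reference}.
#' @param window Window width in bp.
#' @param minNormalDepth Windows with lower mean normal depth are masked.
#' @param minDelta Minimum mean-shift accepted at a split.
#' @param alpha Split significance level (Bonferroni within recursion).
#' @param gcBinWidth GC fraction bin width for the correction.
#' @return A \linkS4class{CnvSegments}; the per-window table is attached as
#'   attribute \code{"windows"}.
#' @export
callCnv <- function(normal, tumor, ref, window = 1000L,
                    minNormalDepth = 10, minDelta = 0.2, alpha = 1e-4,
                    gcBinWidth = 0.025) {
  if (normal@checksum != tumor@checksum)
    stop("snapshots were built against different references")
  if (normal@checksum != refChecksum(ref))
    stop("reference does not match the snapshots")
  rg <- normal@regions
  seqs <- refSequences(ref)
  winTab <- list()
  for (i in seq_len(nrow(rg))) {
    len <- rg$end[i] - rg$start[i]
    nW <- len %/% window
    if (nW < 1L) next
    rows0 <- rg$rowStart[i]
    for (w in seq_len(nW)) {
      sel <- (rows0 + (w - 1L) * window + 1L):(rows0 + w * window)
      ws <- rg$start[i] + (w - 1L) * window
      gc <- gcFraction(substr(seqs[[rg$contig[i]]], ws + 1L, ws + window))
      winTab[[length(winTab) + 1L]] <- data.table::data.table(
        contig = rg$contig[i], start = ws, end = ws + window,
        normalDepth = mean(normal@counts[sel, 19L]),
        tumorDepth = mean(tumor@counts[sel, 19L]), gc = gc)
    }
  }
  wt <- data.table::rbindlist(winTab)
  wt[, masked := normalDepth < minNormalDepth]
  usable <- wt[masked == FALSE]
  if (nrow(usable) < 50L)
    stop("too little data: ", nrow(usable), " usable windows (need >= 50)")
  nMed <- stats::median(usable$normalDepth)
  tMed <- stats::median(usable$tumorDepth)
  usable[, ratio := log2((tumorDepth / tMed) / (normalDepth / nMed))]
  # GC correction: subtract per-GC-bin median ratio
  usable[, gcBin := floor(gc / gcBinWidth)]
  usable[, ratio := ratio - stats::median(ratio), by = "gcBin"]
  segs <- list()
  for (ctg in unique(usable$contig)) {
    sub <- usable[usable$contig == ctg]
    bounds <- segmentBinary(sub$ratio, minDelta, alpha)
    for (b in seq_len(nrow(bounds))) {
      sel <- bounds$from[b]:bounds$to[b]
      m <- mean(sub$ratio[sel])
      segs[[length(segs) + 1L]] <- data.table::data.table(
        contig = ctg, start = sub$start[bounds$from[b]],
        end = sub$end[bounds$to[b]], log2ratio = m,
        state = if (m >= 0.3) "GAIN" else if (m <= -0.3) "LOSS"
                else "NEUTRAL",
        nWindows = length(sel))
    }
  }
  st <- data.table::rbindlist(segs)
  st[, contig := refNames(ref)[contig]]
  out <- new("CnvSegments", segments = st)
  attr(out, "windows") <- usable[]
  out
}

gcFraction <- function(s) {
  v <- strsplit(s, "")[[1L]]
  n <- sum(v != "N")
  if (n == 0L) return(NA_real_)
  sum(v %in% c("G", "C")) / n
}

# recursive binary segmentation: best split by two-sided t statistic
segmentBinary <- function(x, minDelta, alpha) {
  n <- length(x)
  out <- list()
  recurse <- function(from, to) {
    len <- to - from + 1L
    if (len < 4L) {
      out[[length(out) + 1L]] <<- c(from, to)
      return()
    }
    xs <- x[from:to]
    bestP <- Inf; bestK <- NA_integer_; bestDelta <- 0
    nTests <- len - 3L
    for (k in 2L:(len - 2L)) {
      a <- xs[1L:k]; b <- xs[(k + 1L):len]
      d <- abs(mean(a) - mean(b))
      if (d < minDelta) next
      tt <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
      if (tt < bestP) { bestP <- tt; bestK <- k; bestDelta <- d }
    }
    if (!is.na(bestK) && bestP * nTests < alpha && bestDelta >= minDelta) {
      recurse(from, from + bestK - 1L)
      recurse(from + bestK, to)
    } else {
      out[[length(out) + 1L]] <<- c(from, to)
    }
  }
  recurse(1L, n)
  m <- do.call(rbind, out)
  data.table::data.table(from = m[, 1L], to = m[, 2L])
}

#' Write CNV segments as BED and TSV
#' @param segments A \linkS4class{CnvSegments}.
#' @param bedPath,tsvPath Output paths (either may be NULL).
#' @export
writeCnvSegments <- function(segments, bedPath = NULL, tsvPath = NULL) {
  s <- segments@segments
  if (!is.null(bedPath)) {
    writeLines(sprintf("%s\t%d\t%d\t%s", s$contig, s$start, s$end, s$state),
               bedPath)
  }
  if (!is.null(tsvPath)) {
    utils::write.table(s, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(segments)
}
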