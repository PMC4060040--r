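#' Build an in-memory pileup snapshot from alignments
#'
#' One column per reference position inside the declared regions. Aligned
#' bases increment their stranded base cell and the quality/mapping-quality
#' sums; N bases count only toward depth ("other"); an insertion registers
#' at the reference base to its left (matching VCF anchoring); a deletion
#' registers its length at the anchor and increments deletion-span counts
#' across the deleted positions; soft-clipped bases contribute nothing.
#' Duplicate-flagged and unmapped reads are excluded.
#'
#' @param aln An \linkS4class{AlignedReads} (deduplicated, recalibrated,
#'   realigned for the production pipeline; any alignments are accepted).
#' @param ref Matching \linkS4class{Reference}.
#' @param regions Optional target regions (\code{data.table} contig index /
#'   start / end, e.g. from \code{\link{readBedRegions}}); NULL means
#'   whole-genome.
#' @return A \linkS4class{Snapshot}.
#' @export
buildSnapshot <- function(aln, ref, regions = NULL) {
  d <- aln@data
  lens <- refLengths(ref)
  st <- cpp_cigar_stats(d$cigar[d$mapped])
  if (any(d$pos[d$mapped] + st$refSpan > lens[d$contig[d$mapped]]))
    stop("alignment extends beyond contig end")
  wholeGenome <- is.null(regions)
  rg <- if (wholeGenome) wholeGenomeRegions(ref)
        else normalizeRegions(data.table::copy(regions), ref)
  nRows <- sum(rg$end - rg$start)
  res <- cpp_pileup(d$contig, d$pos, d$strand == "+", d$cigar, d$seq,
                    d$qual, d$mapq, !d$mapped | d$dup,
                    rg$contig, rg$start, rg$end, rg$rowStart, nRows)
  ev <- data.table::as.data.table(res$events)
  new("Snapshot", contigs = refNames(ref),
      contigLengths = as.integer(lens), regions = rg, counts = res$counts,
      events = ev, checksum = refChecksum(ref),
      wholeGenome = wholeGenome)
}

#' Construct a snapshot from explicit column data
#'
#' Programmatic constructor used to assemble pileup states directly (e.g.
#' for modeling experiments); the pipeline path is
#' \code{\link{buildSnapshot}}.
#'
#' @param ref A \linkS4class{Reference}.
#' @param counts Integer matrix with 19 columns (see class docs).
#' @param events Optional indel event \code{data.table} (row, type,
#'   payload, fwd, rev, qsum).
#' @param regions Optional region table; defaults to whole-genome (counts
#'   must then cover every position).
#' @return A \linkS4class{Snapshot}.
#' @export
newSnapshot <- function(ref, counts, events = NULL, regions = NULL) {
  wholeGenome <- is.null(regions)
  rg <- if (wholeGenome) wholeGenomeRegions(ref)
        else normalizeRegions(data.table::copy(regions), ref)
  if (is.null(events))
    events <- data.table::data.table(row = integer(0), type = character(0),
                                     payload = character(0),
                                     fwd = integer(0), rev = integer(0),
                                     qsum = integer(0))
  new("Snapshot", contigs = refNames(ref),
      contigLengths = as.integer(refLengths(ref)), regions = rg,
      counts = counts, events = data.table::as.data.table(events),
      checksum = refChecksum(ref), wholeGenome = wholeGenome)
}

#' Extract one snapshot column in field form
#'
#' @param snapshot A \linkS4class{Snapshot}.
#' @param contig Contig name or index.
#' @param pos 0-based position.
#' @return List with per-base forward/reverse counts, quality and mapping
#'   quality sums, N/other count, deletion-span count, depth, and the
#'   insertion/deletion event tables.
#' @export
snapshotColumn <- function(snapshot, contig, pos) {
  ci <- if (is.character(contig)) match(contig, snapshot@contigs)
        else as.integer(contig)
  if (is.na(ci)) stop("unknown contig")
  if (pos < 0L || pos >= snapshot@contigLengths[ci])
    stop("position outside contig bounds")
  rowIdx <- regionRowOf(snapshot@regions, ci, as.integer(pos))
  if (is.na(rowIdx)) stop("position not covered by the snapshot's regions")
  rowIdx <- rowIdx + 1L
  cn <- snapshot@counts[rowIdx, ]
  ev <- snapshot@events[snapshot@events$row == rowIdx]
  list(contig = snapshot@contigs[ci], pos = as.integer(pos),
       fwd = stats::setNames(cn[1:4], c("A", "C", "G", "T")),
       rev = stats::setNames(cn[5:8], c("A", "C", "G", "T")),
       qualSum = stats::setNames(cn[9:12], c("A", "C", "G", "T")),
       mapqSum = stats::setNames(cn[13:16], c("A", "C", "G", "T")),
       nOther = cn[17], delSpan = cn[18], depth = cn[19],
       insertions = ev[ev$type == "I", c("payload", "fwd", "rev", "qsum")],
       deletions = ev[ev$type == "D", c("payload", "fwd", "rev")])
}

SNAPSHOT_MAGIC <- "SNP1"

#' Write a snapshot to its block-compressed indexed container
#'
#' Binary layout (little-endian): magic "SNP1", version, reference checksum,
#' contig table, declared regions, block size, block index
#' (byte offset + compressed sizes + payload checksum per block), then
#' per-block deflate-compressed column and event payloads. Every declared
#' position belongs to exactly one block of \code{blockSize} positions.
#'
#' @param snapshot A \linkS4class{Snapshot}.
#' @param path Output path.
#' @param blockSize Positions per block.
#' @export
writeSnapshot <- function(snapshot, path, blockSize = 65536L) {
  counts <- snapshot@counts
  ev <- snapshot@events
  nRows <- nrow(counts)
  nBlocks <- max(1L, as.integer(ceiling(nRows / blockSize)))
  data.table::setorder(ev, row, type, payload)
  blobs <- vector("list", nBlocks)
  eblobs <- vector("list", nBlocks)
  evBlock <- (ev$row - 1L) %/% blockSize + 1L
  for (b in seq_len(nBlocks)) {
    r0 <- (b - 1L) * blockSize + 1L
    r1 <- min(b * blockSize, nRows)
    raw <- writeBin(as.integer(t(counts[r0:r1, , drop = FALSE])),
                    raw(), size = 4L, endian = "little")
    blobs[[b]] <- memCompress(raw, type = "gzip")
    eb <- ev[evBlock == b]
    ec <- rawConnection(raw(0L), "wb")
    writeBin(nrow(eb), ec, size = 4L, endian = "little")
    if (nrow(eb)) for (i in seq_len(nrow(eb))) {
      writeBin(eb$row[i] - r0, ec, size = 4L, endian = "little")
      writeBin(as.integer(eb$type[i] == "D"), ec, size = 4L,
               endian = "little")
      pl <- charToRaw(eb$payload[i])
      writeBin(length(pl), ec, size = 4L, endian = "little")
      writeBin(pl, ec)
      writeBin(c(eb$fwd[i], eb$rev[i], eb$qsum[i]), ec, size = 4L,
               endian = "little")
    }
    eraw <- rawConnectionValue(ec)
    close(ec)
    eblobs[[b]] <- memCompress(eraw, type = "gzip")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(SNAPSHOT_MAGIC), con)
  writeBin(1L, con, size = 4L, endian = "little")              # version
  writeBin(snapshot@checksum, con, size = 4L, endian = "little")
  writeBin(length(snapshot@contigs), con, size = 4L, endian = "little")
  for (i in seq_along(snapshot@contigs)) {
    nm <- charToRaw(snapshot@contigs[i])
    writeBin(length(nm), con, size = 4L, endian = "little")
    writeBin(nm, con)
    writeBin(snapshot@contigLengths[i], con, size = 4L, endian = "little")
  }
  writeBin(as.integer(snapshot@wholeGenome), con, size = 4L,
           endian = "little")
  rg <- snapshot@regions
  writeBin(nrow(rg), con, size = 4L, endian = "little")
  writeBin(as.integer(rbind(rg$contig, rg$start, rg$end, rg$rowStart)),
           con, size = 4L, endian = "little")
  writeBin(as.integer(blockSize), con, size = 4L, endian = "little")
  writeBin(nRows, con, size = 4L, endian = "little")
  writeBin(nBlocks, con, size = 4L, endian = "little")
  # index: per block offset (relative to data start), sizes, checksum
  sizes <- vapply(blobs, length, integer(1L))
  esizes <- vapply(eblobs, length, integer(1L))
  offsets <- cumsum(c(0L, utils::head(sizes + esizes, -1L)))
  csums <- vapply(seq_len(nBlocks), function(b)
    blockChecksum(blobs[[b]], eblobs[[b]]), integer(1L))
  writeBin(as.integer(rbind(offsets, sizes, esizes, csums)), con,
           size = 4L, endian = "little")
  for (b in seq_len(nBlocks)) {
    writeBin(blobs[[b]], con)
    writeBin(eblobs[[b]], con)
  }
  invisible(path)
}

blockChecksum <- function(...) {
  x <- unlist(list(...))
  as.integer(sum(as.integer(x)) %% 2147483647L)
}

readSnapshotHeader <- function(con) {
  magic <- rawToChar(readBin(con, raw(), 4L))
  if (magic != SNAPSHOT_MAGIC) stop("not a snapshot file (bad magic)")
  version <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  if (version != 1L) stop("unsupported snapshot version ", version)
  checksum <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  nContig <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  contigs <- character(nContig)
  lens <- integer(nContig)
  for (i in seq_len(nContig)) {
    nl <- readBin(con, integer(), 1L, size = 4L, endian = "little")
    contigs[i] <- rawToChar(readBin(con, raw(), nl))
    lens[i] <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  }
  wholeGenome <- readBin(con, integer(), 1L, size = 4L,
                         endian = "little") == 1L
  nReg <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  rgv <- readBin(con, integer(), 4L * nReg, size = 4L, endian = "little")
  rgm <- matrix(rgv, nrow = 4L)
  rg <- data.table::data.table(contig = rgm[1L, ], start = rgm[2L, ],
                               end = rgm[3L, ], rowStart = rgm[4L, ])
  blockSize <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  nRows <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  nBlocks <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  idxv <- readBin(con, integer(), 4L * nBlocks, size = 4L,
                  endian = "little")
  idxm <- matrix(idxv, nrow = 4L)
  list(checksum = checksum, contigs = contigs, contigLengths = lens,
       wholeGenome = wholeGenome, regions = rg, blockSize = blockSize,
       nRows = nRows, nBlocks = nBlocks,
       offsets = idxm[1L, ], sizes = idxm[2L, ], esizes = idxm[3L, ],
       csums = idxm[4L, ], dataStart = seek(con))
}

#' Inspect a snapshot file header
#' @param path Snapshot file path.
#' @return List of header fields (contigs, regions, block index, checksum).
#' @export
snapshotFileInfo <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readSnapshotHeader(con)
}

#' Read a region from a snapshot file
#'
#' Decompresses only the blocks overlapping the requested region. A region
#' not fully inside the declared coverage raises an out-of-coverage error
#' (never an empty result); a reference checksum can be asserted.
#'
#' @param path Snapshot file path.
#' @param contig Contig name.
#' @param start,end 0-based half-open bounds.
#' @param checksum Optional reference checksum that must match.
#' @return A \linkS4class{Snapshot} restricted to the region; the number of
#'   block decompressions is attached as attribute \code{"blocksRead"}.
#' @export
readSnapshotRegion <- function(path, contig, start, end, checksum = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- readSnapshotHeader(con)
  if (!is.null(checksum) && checksum != h$checksum)
    stop("reference checksum mismatch: snapshot was built against a ",
         "different reference")
  ci <- match(contig, h$contigs)
  if (is.na(ci)) stop("unknown contig: ", contig)
  qs <- as.integer(start); qe <- as.integer(end)
  if (qs < 0L || qe > h$contigLengths[ci] || qs >= qe)
    stop("invalid region bounds")
  rg <- h$regions
  covering <- rg[rg$contig == ci & rg$start <= qs & rg$end >= qe, ]
  if (nrow(covering) == 0L)
    stop("region ", contig, ":", qs, "-", qe,
         " is outside the snapshot's declared coverage")
  row0 <- covering$rowStart[1L] + (qs - covering$start[1L])      # 0-based
  row1 <- row0 + (qe - qs)                                       # exclusive
  b0 <- row0 %/% h$blockSize
  b1 <- (row1 - 1L) %/% h$blockSize
  counts <- matrix(0L, nrow = end - start, ncol = 19L)
  evParts <- list()
  for (b in b0:b1) {
    blk <- readSnapshotBlock(con, h, b)
    blockRow0 <- b * h$blockSize                   # 0-based global row
    lo <- max(row0, blockRow0)
    hi <- min(row1, blockRow0 + nrow(blk$counts))
    counts[(lo - row0 + 1L):(hi - row0), ] <-
      blk$counts[(lo - blockRow0 + 1L):(hi - blockRow0), , drop = FALSE]
    ev <- blk$events
    if (nrow(ev)) {
      gr <- ev$row + blockRow0                     # 0-based global rows
      sel <- gr >= row0 & gr < row1
      if (any(sel)) {
        e <- ev[sel]
        e$row <- gr[sel] - row0 + 1L
        evParts[[length(evParts) + 1L]] <- e
      }
    }
  }
  events <- if (length(evParts)) data.table::rbindlist(evParts)
            else data.table::data.table(row = integer(0), type = character(0),
                                        payload = character(0),
                                        fwd = integer(0), rev = integer(0),
                                        qsum = integer(0))
  out <- new("Snapshot", contigs = h$contigs,
             contigLengths = h$contigLengths,
             regions = data.table::data.table(contig = ci, start = start,
                                              end = end, rowStart = 0L),
             counts = counts, events = events, checksum = h$checksum,
             wholeGenome = FALSE)
  attr(out, "blocksRead") <- b1 - b0 + 1L
  out
}

readSnapshotBlock <- function(con, h, b) {
  seek(con, h$dataStart + h$offsets[b + 1L])
  blob <- readBin(con, raw(), h$sizes[b + 1L])
  eblob <- readBin(con, raw(), h$esizes[b + 1L])
  if (blockChecksum(blob, eblob) != h$csums[b + 1L])
    stop("snapshot block ", b, " is corrupted (checksum mismatch)")
  raw <- memDecompress(blob, type = "gzip")
  vals <- readBin(raw, integer(), length(raw) / 4L, size = 4L,
                  endian = "little")
  counts <- matrix(vals, ncol = 19L, byrow = TRUE)
  eraw <- memDecompress(eblob, type = "gzip")
  ec <- rawConnection(eraw, "rb")
  ne <- readBin(ec, integer(), 1L, size = 4L, endian = "little")
  rows <- integer(ne); types <- character(ne); pls <- character(ne)
  fwd <- integer(ne); rev <- integer(ne); qsum <- integer(ne)
  for (i in seq_len(ne)) {
    rows[i] <- readBin(ec, integer(), 1L, size = 4L, endian = "little")
    types[i] <- if (readBin(ec, integer(), 1L, size = 4L,
                            endian = "little") == 1L) "D" else "I"
    nl <- readBin(ec, integer(), 1L, size = 4L, endian = "little")
    pls[i] <- rawToChar(readBin(ec, raw(), nl))
    v <- readBin(ec, integer(), 3L, size = 4L, endian = "little")
    fwd[i] <- v[1L]; rev[i] <- v[2L]; qsum[i] <- v[3L]
  }
  close(ec)
  list(counts = counts,
       events = data.table::data.table(row = rows, type = types,
                                       payload = pls, fwd = fwd, rev = rev,
                                       qsum = qsum))
}

#' Query a single position from a snapshot file
#'
#' Costs one block decompression.
#'
#' @param path Snapshot file path.
#' @param contig Contig name.
#' @param pos 0-based position.
#' @return A column as from \code{\link{snapshotColumn}}.
#' @export
querySnapshotPosition <- function(path, contig, pos) {
  snap <- readSnapshotRegion(path, contig, pos, pos + 1L)
  snapshotColumn(snap, contig, pos)
}

#' Load a full snapshot file into memory
#' @param path Snapshot file path.
#' @param checksum Optional reference checksum to assert.
#' @return A \linkS4class{Snapshot}.
#' @export
readSnapshot <- function(path, checksum = NULL) {
  h <- snapshotFileInfo(path)
  counts <- matrix(0L, nrow = h$nRows, ncol = 19L)
  con <- file(path, "rb")
  on.exit(close(con))
  if (!is.null(checksum) && checksum != h$checksum)
    stop("reference checksum mismatch")
  evParts <- list()
  for (b in seq_len(h$nBlocks) - 1L) {
    blk <- readSnapshotBlock(con, h, b)
    r0 <- b * h$blockSize
    counts[(r0 + 1L):(r0 + nrow(blk$counts)), ] <- blk$counts
    if (nrow(blk$events)) {
      e <- blk$events
      e$row <- e$row + r0 + 1L
      evParts[[length(evParts) + 1L]] <- e
    }
  }
  events <- if (length(evParts)) data.table::rbindlist(evParts)
            else data.table::data.table(row = integer(0), type = character(0),
                                        payload = character(0),
                                        fwd = integer(0), rev = integer(0),
                                        qsum = integer(0))
  new("Snapshot", contigs = h$contigs, contigLengths = h$contigLengths,
      regions = h$regions, counts = counts, events = events,
      checksum = h$checksum, wholeGenome = h$wholeGenome)
}

#' Render snapshot columns as a pileup-style TSV
#'
#' @param snapshot A \linkS4class{Snapshot}.
#' @param contig Contig name or index.
#' @param start,end 0-based half-open range.
#' @return \code{data.frame} with one row per position.
#' @export
snapshotView <- function(snapshot, contig, start, end) {
  rows <- lapply(start:(end - 1L), function(p) {
    col <- snapshotColumn(snapshot, contig, p)
    ins <- if (nrow(col$insertions))
      paste(sprintf("%s:%d", col$insertions$payload,
                    col$insertions$fwd + col$insertions$rev), collapse = ",")
      else "."
    del <- if (nrow(col$deletions))
      paste(sprintf("%s:%d", col$deletions$payload,
                    col$deletions$fwd + col$deletions$rev), collapse = ",")
      else "."
    data.frame(contig = col$contig, pos = col$pos,
               A = col$fwd["A"] + col$rev["A"], C = col$fwd["C"] + col$rev["C"],
               G = col$fwd["G"] + col$rev["G"], T = col$fwd["T"] + col$rev["T"],
               other = col$nOther, delSpan = col$delSpan, depth = col$depth,
               ins = ins, del = del)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
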