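mkReads <- function(df, contigs) {
  d <- data.table::as.data.table(df)
  new("AlignedReads", data = d, contigs = contigs)
}

test_that("pileup columns follow the counting rules", {
  ref <- toyReference()
  # 5 forward reads, all base A at position 50 (0-based), Q30
  seqA <- strrep("A", 10L)
  d <- data.table::data.table(
    pairId = 1:5, mate = 1L, qname = paste0("r", 1:5), contig = 1L,
    pos = 50L, strand = "+", mapq = 60L, score = 10L, cigar = "10=",
    seq = seqA, qual = strrep("?", 10L),          # '?' is Phred 30
    proper = FALSE, mapped = TRUE, dup = FALSE)
  snap <- buildSnapshot(mkReads(d, "toy"), ref)
  col <- snapshotColumn(snap, "toy", 50L)
  expect_equal(unname(col$fwd["A"]), 5L)
  expect_equal(unname(col$rev["A"]), 0L)
  expect_equal(unname(col$qualSum["A"]), 150L)
  expect_equal(unname(col$mapqSum["A"]), 300L)
  expect_equal(col$depth, 5L)
  # one read with a 2 bp deletion anchored at p: event at p, spans at p+1..2
  dDel <- data.table::copy(d[1L])
  dDel[, `:=`(cigar = "5=2D5=", pos = 100L)]
  snapD <- buildSnapshot(mkReads(dDel, "toy"), ref)
  colAnchor <- snapshotColumn(snapD, "toy", 104L)  # base left of deleted run
  expect_equal(colAnchor$deletions$payload, "2")
  expect_equal(colAnchor$deletions$fwd, 1L)
  colSpan1 <- snapshotColumn(snapD, "toy", 105L)
  colSpan2 <- snapshotColumn(snapD, "toy", 106L)
  expect_equal(colSpan1$delSpan, 1L)
  expect_equal(colSpan2$delSpan, 1L)
  expect_equal(colSpan1$depth, 1L)
  # insertion after p registers at p; inserted bases do not add depth
  dIns <- data.table::copy(d[1L])
  dIns[, `:=`(cigar = "5=2I3=", pos = 200L, seq = "AAAAAGGAAA")]
  snapI <- buildSnapshot(mkReads(dIns, "toy"), ref)
  colI <- snapshotColumn(snapI, "toy", 204L)
  expect_equal(colI$insertions$payload, "GG")
  expect_equal(colI$insertions$fwd, 1L)
  expect_equal(colI$depth, 1L)                   # anchor base only
  # soft-clipped bases contribute nothing
  dClip <- data.table::copy(d[1L])
  dClip[, `:=`(cigar = "4S6=", pos = 300L)]
  snapC <- buildSnapshot(mkReads(dClip, "toy"), ref)
  expect_equal(snapshotColumn(snapC, "toy", 299L)$depth, 0L)
  expect_equal(snapshotColumn(snapC, "toy", 300L)$depth, 1L)
})

test_that("depth equals base counts plus N and deletion spans everywhere", {
  st <- smallStudy()
  counts <- st$res$snapshot@counts
  expect_true(all(counts[, 19L] ==
                    rowSums(counts[, 1:8]) + counts[, 17L] + counts[, 18L]))
  expect_true(all(counts >= 0L))
})

test_that("snapshot files round-trip losslessly block by block", {
  st <- smallStudy()
  snap <- st$res$snapshot
  path <- tempfile(fileext = ".snapshot")
  writeSnapshot(snap, path, blockSize = 4096L)
  back <- readSnapshot(path, checksum = refChecksum(st$ref))
  expect_identical(back@counts, snap@counts)
  data.table::setorder(snap@events, row, type, payload)
  data.table::setorder(back@events, row, type, payload)
  expect_equal(back@events$row, snap@events$row)
  expect_equal(back@events$payload, snap@events$payload)
  expect_equal(back@events$fwd, snap@events$fwd)
  expect_equal(back@events$qsum, snap@events$qsum)
  expect_identical(back@regions$start, snap@regions$start)
  # a region query decompresses exactly the overlapped blocks
  rg <- readSnapshotRegion(path, "c1", 4000L, 4096L * 2L + 500L)
  expect_equal(attr(rg, "blocksRead"), 3L)
  expect_identical(rg@counts,
                   snap@counts[4001L:(4096L * 2L + 500L), , drop = FALSE])
  # single-position query equals the in-memory column
  col1 <- querySnapshotPosition(path, "c1", 12345L)
  col2 <- snapshotColumn(snap, "c1", 12345L)
  expect_identical(col1$fwd, col2$fwd)
  expect_identical(col1$qualSum, col2$qualSum)
  expect_identical(col1$depth, col2$depth)
})

test_that("snapshot queries fail loudly outside coverage or on corruption", {
  st <- smallStudy()
  snap <- st$res$snapshot
  path <- tempfile(fileext = ".snapshot")
  writeSnapshot(snap, path, blockSize = 4096L)
  lens <- refLengths(st$ref)
  expect_error(querySnapshotPosition(path, "c1", lens[[1]] + 5L),
               "invalid region|outside")
  expect_error(readSnapshotRegion(path, "nope", 0L, 10L), "unknown contig")
  expect_error(readSnapshot(path, checksum = 12345L), "checksum")
  # zero-depth position inside coverage is a present, all-zero column
  zero <- which(snap@counts[, 19L] == 0L)[1L]
  if (!is.na(zero)) {
    col <- querySnapshotPosition(path, "c1", zero - 1L)
    expect_equal(col$depth, 0L)
  }
  # flip one payload byte: the block checksum must catch it
  raw <- readBin(path, raw(), file.size(path))
  info <- snapshotFileInfo(path)
  off <- info$dataStart + info$offsets[2L] + 12L
  raw[off] <- as.raw(bitwXor(as.integer(raw[off]), 255L))
  bad <- tempfile(fileext = ".snapshot")
  writeBin(raw, bad)
  expect_error(readSnapshot(bad), "corrupt")
})

test_that("target-restricted snapshots declare only their regions", {
  st <- smallStudy()
  regions <- data.table::data.table(contig = 1L,
                                    start = c(10000L, 30000L),
                                    end = c(15000L, 32000L))
  snap <- buildSnapshot(st$res$alignments, st$ref, regions = regions)
  expect_false(snap@wholeGenome)
  expect_equal(nrow(snap@counts), 7000L)
  # on-target content matches the whole-genome snapshot
  whole <- st$res$snapshot
  expect_identical(snap@counts[1:5000, ], whole@counts[10001:15000, ])
  col <- snapshotColumn(snap, "c1", 10500L)
  colW <- snapshotColumn(whole, "c1", 10500L)
  expect_identical(col$fwd, colW$fwd)
  # off-target queries are an explicit out-of-coverage error
  expect_error(snapshotColumn(snap, "c1", 20000L), "not covered")
  path <- tempfile(fileext = ".snapshot")
  writeSnapshot(snap, path)
  expect_error(readSnapshotRegion(path, "c1", 20000L, 20010L),
               "outside")
})
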