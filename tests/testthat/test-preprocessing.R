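# hand-built alignment tables for controlled duplicate scenarios
mkAln <- function(df, contigs = "c1") {
  d <- data.table::as.data.table(df)
  if (!"dup" %in% names(d)) d[, dup := FALSE]
  new("AlignedReads", data = d, contigs = contigs)
}

pairRows <- function(pairId, pos1, pos2, q = "I", strand1 = "+",
                     strand2 = "-", len = 10L, clip1 = "") {
  cig1 <- if (nzchar(clip1)) clip1 else paste0(len, "=")
  data.table::data.table(
    pairId = pairId, mate = 1:2, qname = paste0("p", pairId),
    contig = 1L, pos = c(pos1, pos2), strand = c(strand1, strand2),
    mapq = 60L, score = len,
    cigar = c(cig1, paste0(len, "=")),
    seq = strrep("A", len), qual = strrep(q, len),
    proper = TRUE, mapped = TRUE, dup = FALSE)
}

test_that("duplicate pairs collide on unclipped 5' keys, best quality kept", {
  # two pairs with identical outer coordinates, one lower quality
  d <- data.table::rbindlist(list(
    pairRows(1L, 100L, 300L, q = "I"),           # qual sum 2*10*40
    pairRows(2L, 100L, 300L, q = "A"),           # qual sum 2*10*32
    pairRows(3L, 500L, 700L, q = "5")))          # distinct position
  res <- markDuplicates(mkAln(d))
  rd <- alignmentData(res)
  expect_false(any(rd$dup[rd$pairId == 1L]))
  expect_true(all(rd$dup[rd$pairId == 2L]))
  expect_false(any(rd$dup[rd$pairId == 3L]))
  st <- attr(res, "stats")
  expect_equal(st$inputPairs, 3L)
  expect_equal(st$keptPairs, 2L)
  expect_equal(st$flaggedPairs, 1L)
})

test_that("soft clips are restored before keying and ties keep first-seen", {
  # pair 2's mate1 is clipped by 3 bases: unclipped 5' still collides
  d <- data.table::rbindlist(list(
    pairRows(1L, 100L, 300L, q = "I"),
    {
      p <- pairRows(2L, 103L, 300L, q = "I", clip1 = "3S7=")
      p
    },
    pairRows(3L, 100L, 300L, q = "I")))          # exact quality tie with 1
  res <- markDuplicates(mkAln(d))
  rd <- alignmentData(res)
  # three pairs share one key: exactly 2 flagged, first-seen tie winner kept
  expect_equal(sum(rd$dup) / 2L, 2L)
  expect_false(any(rd$dup[rd$pairId == 1L]))
})

test_that("kept-set cardinality is invariant under input permutation", {
  st <- smallStudy()
  d <- alignmentData(st$aln)
  base <- markDuplicates(st$aln)
  nKept <- attr(base, "stats")$keptPairs
  set.seed(77)
  for (rep in 1:3) {
    pairIds <- unique(d$pairId)
    perm <- sample(pairIds)
    d2 <- d[order(match(pairId, perm))]
    d2[, pairId := pairId]                        # ids preserved, order not
    res <- markDuplicates(mkAln(d2, contigs = st$aln@contigs))
    expect_equal(attr(res, "stats")$keptPairs, nKept)
  }
})

test_that("empirical recalibration quality follows the smoothed formula", {
  # cells observed through a synthetic single-cell alignment set
  ref <- newReference(strrep("ACGT", 2500), "rc")
  # 10,000 aligned bases, exactly 1 mismatching: empirical Q 37
  expect_equal(snapvar:::phredOf((1 + 1) / (10000 + 2)), 37)
  # 998 observations, no mismatch: phred(1/1000) = 30
  expect_equal(snapvar:::phredOf((0 + 1) / (998 + 2)), 30)
  expect_equal(snapvar:::phredOf(1e-9), 60)      # capped at 60
})

test_that("error-free reads tabulate zero mismatches", {
  st <- smallStudy()
  prof0 <- simProfile(depth = 4, errStart = 0, errEnd = 0,
                      indelErrRate = 0, seed = 301)
  refOnly <- structure(list(
    ref = st$ref, truth = st$genome$truth[0L],
    haplotypes = list(list(refSequences(st$ref)[[1]],
                           refSequences(st$ref)[[1]]))
    , maps = list(list(data.table::data.table(hapStart = 0L, refStart = 0L),
                       data.table::data.table(hapStart = 0L, refStart = 0L)))),
    class = "DiploidGenome")
  sim0 <- simulateReads(refOnly, prof0)
  aln <- alignReadPairs(sim0$pairs, st$index)
  tab <- buildRecalTable(aln, st$ref)
  expect_equal(sum(tab@mism), 0L)
  expect_true(all(tab@mism <= tab@obs))
})

test_that("recalibrated qualities converge to the true error rate", {
  # uniform 1% error over short reads concentrates observations in few
  # cells; the marginal empirical quality must land within 1 phred of 20
  set.seed(302)
  L <- 30000L
  ref <- makeReference(L, seed = 303, name = "rq")
  s <- refSequences(ref)[[1]]
  n <- 20000L
  starts <- sample.int(L - 30L, n, replace = TRUE)
  seqs <- substring(s, starts, starts + 19L)
  chars <- strsplit(seqs, "")
  e <- 0.01
  for (i in seq_len(n)) {
    hit <- which(stats::runif(20L) < e)
    if (length(hit)) {
      for (h in hit)
        chars[[i]][h] <- sample(setdiff(c("A", "C", "G", "T"),
                                        chars[[i]][h]), 1L)
    }
  }
  seqs <- vapply(chars, paste, character(1), collapse = "")
  d <- data.table::data.table(
    pairId = seq_len(n), mate = 1L, qname = paste0("r", seq_len(n)),
    contig = 1L, pos = starts - 1L, strand = "+", mapq = 60L, score = 20L,
    cigar = "20=", seq = seqs, qual = strrep("5", 20L),  # reported Q20
    proper = FALSE, mapped = TRUE, dup = FALSE)
  aln <- new("AlignedReads", data = d, contigs = "rq")
  tab <- buildRecalTable(aln, ref)
  margObs <- apply(tab@obs, 1, sum)
  margMism <- apply(tab@mism, 1, sum)
  q20 <- -10 * log10((margMism[21] + 1) / (margObs[21] + 2))
  expect_gt(margObs[21], 1e5)
  expect_lt(abs(q20 - 20), 1)
  # applying the table replaces reported qualities by ~20
  rec <- applyRecalibration(aln, tab)
  # per-cell estimates carry binomial noise at ~1e3 observations each; the
  # recalibrated qualities must center on the true rate and stay close
  newQ <- unlist(lapply(alignmentData(rec)$qual[1:200], function(q)
    utf8ToInt(q) - 33L))
  expect_lt(abs(mean(newQ) - 20), 1)
  # individual cells see ~1e3 observations (sd ~1.2 phred); the +-1
  # guarantee applies at >= 1e5 observations, i.e. to the marginal above
  expect_gte(mean(abs(newQ - 20) <= 3), 0.95)
})

test_that("recalibration fallback and stability rules hold", {
  st <- smallStudy()
  aln <- markDuplicates(st$aln)
  tab <- buildRecalTable(aln, st$ref,
                         maskSites = candidateVariantMask(aln, st$ref))
  rec1 <- applyRecalibration(aln, tab)
  rec2 <- applyRecalibration(aln, tab)
  # deterministic map: identical inputs and table give identical output
  expect_identical(alignmentData(rec1)$qual, alignmentData(rec2)$qual)
  # a base in an unseen cell falls back to the reported-quality marginal
  probe <- data.table::copy(alignmentData(aln)[1L])
  probe[, qual := paste0(phredEncode(59L),
                         substr(qual, 2L, nchar(qual)))]
  probeAln <- new("AlignedReads", data = probe, contigs = st$aln@contigs)
  out <- applyRecalibration(probeAln, tab)
  q1 <- utf8ToInt(alignmentData(out)$qual[1L])[1L] - 33L
  expected <- if (sum(tab@obs[60L, , ]) > 0L) tab@marginal[60L] else 59
  if (is.na(expected)) expected <- 59
  expect_equal(q1, round(expected))
})
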