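mkColumn <- function(fwd = c(0L, 0L, 0L, 0L), rev = c(0L, 0L, 0L, 0L),
                     meanQ = 30L, ins = NULL, del = NULL, delSpan = 0L) {
  qs <- (fwd + rev) * meanQ
  insDt <- if (is.null(ins))
    data.table::data.table(payload = character(0), fwd = integer(0),
                           rev = integer(0), qsum = integer(0))
  else ins
  delDt <- if (is.null(del))
    data.table::data.table(payload = character(0), fwd = integer(0),
                           rev = integer(0))
  else del
  evN <- (if (nrow(insDt)) sum(insDt$fwd + insDt$rev) else 0L) +
    (if (nrow(delDt)) sum(delDt$fwd + delDt$rev) else 0L)
  list(contig = "c", pos = 0L,
       fwd = stats::setNames(fwd, c("A", "C", "G", "T")),
       rev = stats::setNames(rev, c("A", "C", "G", "T")),
       qualSum = stats::setNames(qs, c("A", "C", "G", "T")),
       mapqSum = stats::setNames((fwd + rev) * 60L, c("A", "C", "G", "T")),
       nOther = 0L, delSpan = delSpan,
       depth = sum(fwd + rev) + delSpan,
       insertions = insDt, deletions = delDt)
}

test_that("the genotype space enumerates exactly 16 genotypes", {
  sp <- snapvar:::cpp_genotype_space()
  expect_length(sp$a1, 16L)
  expect_length(sp$a2, 16L)
  labels <- snapvar:::GENOTYPE_LABELS
  expect_length(labels, 16L)
  expect_length(unique(labels), 16L)
  # composition: 10 base pairs, 4 base/indel hets, I/I, I1/I2
  expect_equal(sum(sp$a1 < 4 & sp$a2 < 4), 10L)
  expect_equal(sum(sp$a1 < 4 & sp$a2 == 4), 4L)
  expect_equal(sum(sp$a1 == 4 & sp$a2 == 4), 1L)
  expect_equal(sum(sp$a2 == 5), 1L)
})

test_that("clean columns give expected posterior-maximal genotypes", {
  # ref A, 10 A reads Q30: confident hom-ref
  gs <- genotypeSite(mkColumn(fwd = c(10L, 0L, 0L, 0L)), "A")
  expect_equal(gs$argmax, "AA")
  expect_gt(gs$posterior[1L], 0.999)
  # balanced A/G column: het
  gs2 <- genotypeSite(mkColumn(fwd = c(6L, 0L, 6L, 0L)), "A")
  expect_equal(gs2$argmax, "AG")
  # 5 reference-looking reads + 5 DEL(2) events: base/indel het; the 5
  # event-carrying reads also deposited their anchor base
  del <- data.table::data.table(payload = "2", fwd = 5L, rev = 0L)
  gs3 <- genotypeSite(mkColumn(fwd = c(10L, 0L, 0L, 0L), del = del), "A")
  expect_equal(gs3$argmax, "A/I")
  expect_equal(gs3$event1, "D:2")
  # no indel events: all 6 indel-bearing genotypes carry zero posterior
  expect_true(all(gs$posterior[11:16] == 0))
  expect_equal(sum(gs$posterior), 1, tolerance = 1e-9)
})

test_that("hom-ref columns yield no call and QUAL follows the posterior", {
  ref <- newReference(strrep("ACGT", 300), "cc")
  n <- 1200L
  counts <- matrix(0L, n, 19L)
  refCodes <- rep(c(0L, 1L, 2L, 3L), 300L)
  for (i in 1:n) {
    b <- refCodes[i]
    counts[i, b + 1L] <- 20L
    counts[i, b + 9L] <- 600L
    counts[i, b + 13L] <- 1200L
    counts[i, 19L] <- 20L
  }
  snap <- newSnapshot(ref, counts)
  calls <- callVariants(snap, ref)
  expect_equal(nrow(calls@calls), 0L)
  # QUAL is the phred of the hom-ref posterior mass
  gs <- genotypeSite(mkColumn(fwd = c(6L, 0L, 6L, 0L)), "A")
  expect_equal(gs$qual, -10 * log10(gs$posterior[1L]), tolerance = 1e-6)
})

test_that("called indel alleles expand to anchored VCF strings", {
  ref <- toyReference()
  s <- refSequences(ref)[[1]]
  p <- 499L                                      # 0-based anchor
  counts <- matrix(0L, nchar(s), 19L)
  # hom insertion: 20 reads all carrying INS "GG" (anchor bases deposited)
  rc <- match(substr(s, p + 1L, p + 1L), c("A", "C", "G", "T")) - 1L
  counts[p + 1L, rc + 1L] <- 20L
  counts[p + 1L, rc + 9L] <- 600L
  counts[p + 1L, rc + 13L] <- 1200L
  counts[p + 1L, 19L] <- 20L
  ev <- data.table::data.table(row = p + 1L, type = "I", payload = "GG",
                               fwd = 10L, rev = 10L, qsum = 1200L)
  snap <- newSnapshot(ref, counts, events = ev)
  calls <- callVariants(snap, ref)@calls
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$gt, "1/1")
  expect_equal(calls$class, "INS")
  # left-normalization may shift the anchor; REF stays the anchor base and
  # ALT appends the (possibly rotated) payload
  expect_equal(substr(calls$alt, 1L, 1L), calls$ref)
  expect_equal(nchar(calls$alt), 3L)
  expect_equal(calls$vcfPos, calls$pos + 1L)
})

test_that("posteriors match an independent brute-force evaluation", {
  rc <- randomColumns(1000L, seed = 404)
  res <- snapvar:::cpp_genotype_batch(
    rc$counts, rc$refCode, rc$ev1type, rc$ev1n, rc$ev1q, rc$ev2type,
    rc$ev2n, rc$ev2q, 1e-3, 1e-4, 2, 30, TRUE)
  for (i in seq_len(1000L)) {
    bf <- bruteForceGenotype(rc$counts[i, ], rc$refCode[i], rc$ev1type[i],
                             rc$ev1n[i], rc$ev1q[i], rc$ev2type[i],
                             rc$ev2n[i], rc$ev2q[i])
    if (is.null(bf)) next
    expect_equal(res$posterior[i, ], bf$posterior, tolerance = 1e-9)
    expect_equal(res$argmax[i], bf$argmax)
    expect_equal(res$qual[i], bf$qual, tolerance = 1e-6)
  }
})

test_that("posteriors are normalized at every site", {
  rc <- randomColumns(500L, seed = 405)
  res <- snapvar:::cpp_genotype_batch(
    rc$counts, rc$refCode, rc$ev1type, rc$ev1n, rc$ev1q, rc$ev2type,
    rc$ev2n, rc$ev2q, 1e-3, 1e-4, 2, 30, TRUE)
  sums <- rowSums(res$posterior)
  covered <- rc$counts[, 19L] > 0L
  expect_true(all(abs(sums[covered] - 1) < 1e-9))
})

test_that("planted genotypes are recovered at depth", {
  st <- smallStudy()
  cr <- snapvar:::decomposeCalls(st$res$calls, st$ref)
  tr <- data.table::copy(st$genome$truth)
  tr[, key := snapvar:::variantKey(contig, pos, class, payload)]
  cr[, key := snapvar:::variantKey(contig, pos, class, payload)]
  m <- merge(tr, cr, by = "key")
  expZ <- ifelse(m$zygosity == "hom", "hom", "het")
  obsZ <- ifelse(grepl("0", m$gt), "het", "hom")
  isSnp <- m$class.x == "SNP"
  expect_gte(mean((expZ == obsZ)[isSnp]), 0.995)
  expect_gte(mean((expZ == obsZ)[!isSnp]), 0.97)
  expect_gte(nrow(m) / nrow(tr), 0.99)
})
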