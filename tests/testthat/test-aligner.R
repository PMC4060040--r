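test_that("seed index stores k-mer positions and flags repetitive k-mers", {
  # one 8-mer repeated at two known offsets
  unit <- "ACGTTGCA"
  ref <- newReference(paste0(unit, "GGATCCAT", unit, "TTGACCTG"), "c1")
  idx <- buildSeedIndex(ref, k = 8L)
  hit <- seedLookup(idx, unit)
  expect_equal(sort(hit$positions), c(0L, 16L))
  expect_false(hit$repetitive)
  # homopolymer of 100 A: 93 occurrences of the 8-mer exceed maxOcc = 64
  hp <- newReference(strrep("A", 100), "hp")
  idxHp <- buildSeedIndex(hp, k = 8L, maxOcc = 64L)
  hitHp <- seedLookup(idxHp, strrep("A", 8))
  expect_true(hitHp$repetitive)
  expect_length(hitHp$positions, 0L)
  # all-N contig indexes nothing
  nn <- newReference(strrep("N", 50), "nn")
  idxN <- buildSeedIndex(nn, k = 8L)
  expect_equal(snapvar:::cpp_index_info(idxN$ptr)$nKmers, 0)
  expect_error(buildSeedIndex(ref, k = 4L), "k must be")
})

test_that("single-read alignment recovers exact, reverse and mutated reads", {
  st <- smallStudy()
  s <- refSequences(st$ref)[[1]]
  read <- substr(s, 101, 200)                    # reference[100:200], 0-based
  cand <- alignRead(read, st$index)
  expect_equal(cand$pos[1], 100L)
  expect_equal(cand$strand[1], "+")
  expect_equal(cand$score[1], 100L)
  expect_equal(cand$cigar[1], "100=")
  rc <- as.character(revComp(read))
  cand2 <- alignRead(rc, st$index)
  expect_equal(cand2$pos[1], 100L)
  expect_equal(cand2$strand[1], "-")
  # one substitution at read offset 50 (0-based): score 95, M(50) X M(49)
  mut <- read
  cur <- substr(mut, 51, 51)
  substr(mut, 51, 51) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  cand3 <- alignRead(mut, st$index)
  expect_equal(cand3$pos[1], 100L)
  expect_equal(cand3$score[1], 95L)
  expect_equal(cand3$cigar[1], "50=1X49=")
  # exhaustive gapless scan over every start position confirms the unique
  # optimum placement
  chars <- strsplit(s, "")[[1]]
  mutc <- strsplit(mut, "")[[1]]
  best <- -Inf; bestAt <- -1L
  for (p in 0:(nchar(s) - 100L)) {
    mm <- sum(chars[(p + 1L):(p + 100L)] != mutc)
    sc <- 100L - 5L * mm
    if (sc > best) { best <- sc; bestAt <- p }
  }
  expect_equal(bestAt, 100L)
  expect_equal(best, 95L)
})

test_that("windowed DP equals an independent local aligner on short instances", {
  skip_if_not_installed("Biostrings")
  set.seed(202)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -4,
                                                  baseOnly = TRUE)
  for (i in 1:20) {
    n1 <- sample(40:200, 1); n2 <- sample(40:200, 1)
    a <- paste(sample(c("A", "C", "G", "T"), n1, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), n2, TRUE), collapse = "")
    # half the cases: b contains a mutated copy of a (realistic optima)
    if (i %% 2 == 0) {
      bb <- strsplit(a, "")[[1]]
      k <- sample(seq_along(bb), max(1, n1 %/% 20))
      bb[k] <- sample(c("A", "C", "G", "T"), length(k), TRUE)
      b <- paste(c(bb, sample(c("A", "C", "G", "T"), 30, TRUE)),
                 collapse = "")
    }
    ours <- localAlign(a, b)$score
    theirs <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
      substitutionMatrix = mat, gapOpening = 6, gapExtension = 1,
      scoreOnly = TRUE)
    expect_equal(ours, max(0, theirs))
  }
})

test_that("pair selection enforces FR orientation and rescues seedless mates", {
  st <- smallStudy()
  s <- refSequences(st$ref)[[1]]
  r1 <- substr(s, 2001, 2100)
  r2 <- as.character(revComp(substr(s, 2401, 2500)))  # insert 500
  pk <- pairAndRescue(r1, r2, st$index, insertMean = 500, insertSd = 25)
  expect_true(pk$properlyPaired)
  expect_equal(pk$mate1$pos, 2000L)
  expect_equal(pk$mate2$pos, 2400L)
  # same-strand mates are never properly paired
  pk2 <- pairAndRescue(r1, substr(s, 2401, 2500), st$index)
  expect_false(pk2$properlyPaired)
  # mate2 with an error every 12 bp has no clean 16-mer seed, but lies 500
  # bp from mate1: rescued by DP in the insert window
  bad <- strsplit(substr(s, 2401, 2500), "")[[1]]
  for (p in seq(6, 94, by = 12)) {
    bad[p] <- setdiff(c("A", "C", "G", "T"), bad[p])[1]
  }
  badRead <- as.character(revComp(paste(bad, collapse = "")))
  expect_length(alignRead(badRead, st$index)$pos, 0L)
  pk3 <- pairAndRescue(r1, badRead, st$index)
  expect_true(pk3$mate2$rescued)
  expect_true(pk3$properlyPaired)
  expect_equal(pk3$mate2$pos, 2400L)
})

test_that("error-free read pairs align to their true origin", {
  st <- smallStudy()
  prof0 <- simProfile(depth = 8, errStart = 0, errEnd = 0,
                      indelErrRate = 0, seed = 210)
  refOnly <- structure(list(
    ref = st$ref, truth = st$genome$truth[0L],
    haplotypes = list(list(refSequences(st$ref)[[1]],
                           refSequences(st$ref)[[1]])),
    maps = list(list(data.table::data.table(hapStart = 0L, refStart = 0L),
                     data.table::data.table(hapStart = 0L, refStart = 0L)))),
    class = "DiploidGenome")
  sim0 <- simulateReads(refOnly, prof0)
  aln <- alignReadPairs(sim0$pairs, st$index)
  d <- alignmentData(aln)
  m1 <- d[d$mate == 1L]
  ok <- m1$mapped & m1$pos == sim0$origin$refStart1
  expect_gte(mean(ok), 0.999)
})

test_that("edit scripts reproduce read bases from the reference", {
  st <- smallStudy()
  d <- alignmentData(st$res$alignments)
  rows <- which(d$mapped)
  set.seed(33)
  rows <- sample(rows, 200L)
  expect_true(all(checkEditScripts(st$res$alignments, st$ref, rows)))
})

test_that("mapping quality reflects placement ambiguity", {
  # a read from an exact two-copy repeat must get MAPQ 0
  set.seed(55)
  core <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  ref <- newReference(paste0(pad(200), core, pad(200), core, pad(200)), "r")
  idx <- buildSeedIndex(ref)
  cand <- alignRead(substr(core, 51, 150), idx)
  expect_gte(nrow(cand), 2L)
  expect_equal(cand$score[1], cand$score[2])
  # unique read gets MAPQ 60 through the pair path
  st <- smallStudy()
  d <- alignmentData(st$aln)
  expect_true(all(d$mapq[d$mapped] <= 60L))
  expect_gt(mean(d$mapq[d$mapped] == 60L), 0.95)
})
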