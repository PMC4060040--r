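test_that("reference generation hits target GC and is seed-deterministic", {
  r1 <- makeReference(1e6, gc = 0.41, seed = 501)
  gc <- sum(Biostrings::letterFrequency(r1@sequences,
                                        c("G", "C"))) / 1e6
  expect_gte(gc, 0.40)
  expect_lte(gc, 0.42)
  r2 <- makeReference(1e6, gc = 0.41, seed = 501)
  expect_identical(refSequences(r1), refSequences(r2))
  expect_error(makeReference(1e6, gc = 1.5, seed = 1), "gc must be")
  expect_error(makeReference(500, seed = 1), ">= 10000")
  expect_error(makeReference(1e5, gc = 0.4), "seed")
})

test_that("planted variant counts follow the Poisson band", {
  g <- plantVariants(makeReference(1e6, seed = 502, name = "p"),
                     snpRate = 1e-3, indelRate = 1e-4, seed = 503)
  nSnp <- sum(g$truth$class == "SNP")
  # 99% band of Poisson(1000); the overlap guard drops a small fraction
  expect_gte(nSnp, stats::qpois(0.005, 1000) - 50L)
  expect_lte(nSnp, stats::qpois(0.995, 1000))
  nIndel <- sum(g$truth$class != "SNP")
  expect_gte(nIndel, 60L)
  expect_lte(nIndel, 140L)
})

test_that("haplotypes reproduce exactly from reference plus variant list", {
  ref <- makeReference(50000, seed = 504, name = "h")
  g <- plantVariants(ref, snpRate = 2e-3, indelRate = 5e-4, seed = 505)
  rebuilt <- snapvar:::buildHaplotypes(ref, g$truth)
  expect_identical(rebuilt$seqs[[1]][[1]], g$haplotypes[[1]][[1]])
  expect_identical(rebuilt$seqs[[1]][[2]], g$haplotypes[[1]][[2]])
  # het SNPs differ between haplotypes at the planted site
  hets <- g$truth[g$truth$class == "SNP" & g$truth$zygosity == "het"]
  for (i in utils::head(seq_len(nrow(hets)), 10L)) {
    p <- hets$pos[i]
    h <- as.integer(substr(hets$hap[i], 1L, 1L))
    other <- 3L - h
    m <- snapvar:::mapRefToHap(g$maps[[1]][[h]], p)
    mo <- snapvar:::mapRefToHap(g$maps[[1]][[other]], p)
    expect_equal(substr(g$haplotypes[[1]][[h]], m + 1L, m + 1L),
                 hets$payload[i])
    expect_equal(substr(g$haplotypes[[1]][[other]], mo + 1L, mo + 1L),
                 hets$vcfRef[i])
  }
})

test_that("read simulation is exact without errors and depth-calibrated", {
  ref <- makeReference(50000, seed = 506, name = "s")
  g <- plantVariants(ref, snpRate = 1e-3, indelRate = 1e-4, seed = 507)
  prof0 <- simProfile(depth = 10, errStart = 0, errEnd = 0,
                      indelErrRate = 0, seed = 508)
  sim <- simulateReads(g, prof0)
  # depth * L / (2 * readLength) pairs, within rounding
  expect_equal(length(sim$pairs), round(10 * 50000 / 200), tolerance = 1)
  # every read is an exact substring of its source haplotype
  o <- sim$origin
  set.seed(1)
  for (i in sample(nrow(o), 50L)) {
    hap <- g$haplotypes[[1]][[o$hap[i]]]
    r1 <- sim$pairs@seq1[i]
    want <- substr(hap, o$hapStart1[i] + 1L, o$hapStart1[i] + 100L)
    if (o$strand1[i] == "-") want <- as.character(revComp(want))
    expect_identical(r1, want)
  }
  # fixed seed gives byte-identical FASTQ
  prof <- simProfile(depth = 5, seed = 509)
  s1 <- simulateReads(g, prof)
  s2 <- simulateReads(g, prof)
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile(); f4 <- tempfile()
  writeFastqPairs(s1$pairs, f1, f2)
  writeFastqPairs(s2$pairs, f3, f4)
  expect_identical(readLines(f1), readLines(f3))
  expect_identical(readLines(f2), readLines(f4))
})

test_that("error profile rises across cycles and is quality-tracked", {
  ref <- makeReference(50000, seed = 510, name = "e")
  g <- plantVariants(ref, snpRate = 0.0001, indelRate = 0.00001, seed = 511)
  prof <- simProfile(depth = 20, seed = 512)
  sim <- simulateReads(g, prof)
  errs <- c(sim$origin$errPos1, sim$origin$errPos2)
  cycles <- as.integer(unlist(strsplit(errs[nzchar(errs)], ",")))
  # late cycles err ~5x more often than early ones
  early <- sum(cycles <= 20L)
  late <- sum(cycles > 80L)
  expect_gt(late, 2.5 * early)
  # reported qualities track the cycle error model within the jitter
  q1 <- utf8ToInt(sim$pairs@qual1[1L]) - 33L
  model <- round(-10 * log10(snapvar:::cycleErrorRates(100L, prof)))
  expect_true(all(abs(q1 - model) <= prof$qualJitter))
})

test_that("tumor pairs scale depth by copy number and stay truth-disjoint", {
  ref <- makeReference(120000, seed = 513, name = "t")
  germ <- plantVariants(ref, snpRate = 1e-3, indelRate = 1e-4, seed = 514)
  cnv <- data.table::data.table(contig = 1L, start = 30000L, end = 60000L,
                                cn = 4)
  prof <- simProfile(depth = 20, seed = 515)
  tp <- makeTumorPair(ref, germ, somaticSnvRate = 1e-4,
                      somaticIndelRate = 1e-5, cnvSpec = cnv,
                      profile = prof, seed = 516)
  # somatic truth disjoint from germline truth
  gk <- paste(germ$truth$contig, germ$truth$pos)
  sk <- paste(tp$somaticTruth$contig, tp$somaticTruth$pos)
  expect_length(intersect(gk, sk), 0L)
  expect_true(all(tp$somaticTruth$expectedAF == 0.5))
  # fragment density doubles inside the cn=4 region
  o <- tp$tumor$origin
  inside <- sum(o$refStart1 >= 30000L & o$refStart1 < 60000L)
  outside <- sum(o$refStart1 < 30000L | o$refStart1 >= 60000L)
  ratio <- (inside / 30000) / (outside / 90000)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
  expect_error(makeTumorPair(ref, germ, cnvSpec = data.table::data.table(
    contig = 1L, start = c(10L, 100L), end = c(200L, 300L), cn = c(3, 3)),
    profile = prof, seed = 1), "overlapping CNV")
})

test_that("trio inheritance is Mendelian by construction", {
  ref <- makeReference(60000, seed = 517, name = "f")
  prof <- simProfile(depth = 5, seed = 518)
  trio <- makeTrio(ref, snpRate = 1e-3, indelRate = 1e-4, profile = prof,
                   seed = 519)
  cu <- trio$child$genome$truth
  pk <- c(paste(trio$father$genome$truth$pos,
                trio$father$genome$truth$payload),
          paste(trio$mother$genome$truth$pos,
                trio$mother$genome$truth$payload))
  expect_true(all(paste(cu$pos, cu$payload) %in% pk))
  # forced de novo injection adds exactly n child-only variants
  trioDn <- makeTrio(ref, snpRate = 1e-3, indelRate = 1e-4, profile = prof,
                     seed = 519, deNovo = 10L)
  cd <- trioDn$child$genome$truth
  childOnly <- !(paste(cd$pos, cd$payload) %in% pk)
  expect_equal(sum(childOnly), 10L)
})
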