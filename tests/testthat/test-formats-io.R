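test_that("FASTA reading folds case, maps ambiguity codes to N and validates", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c1 descr", "ACGT", ">c2", "acgn", ">c3", "ACRYGT"), fa)
  ref <- readReference(fa)
  expect_equal(refNames(ref), c("c1", "c2", "c3"))
  expect_equal(unname(refSequences(ref)["c1"]), "ACGT")
  expect_equal(unname(refLengths(ref)["c1"]), 4L)
  expect_equal(unname(refSequences(ref)["c2"]), "ACGN")
  expect_equal(unname(refSequences(ref)["c3"]), "ACNNGT")

  dup <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "AC", ">c1", "GG"), dup)
  expect_error(readReference(dup), "duplicate")
  empty <- tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(readReference(empty))
  expect_error(readReference(tempfile()), "not found")
})

test_that("FASTQ pairs round-trip byte-identically and decode Phred+33", {
  pairs <- new("ReadPairSet", name = c("r1", "r2"),
               seq1 = c("ACGT", "GGCC"), qual1 = c("I!5A", "IIII"),
               seq2 = c("TTAA", "CCGG"), qual2 = c("AAAA", "!!!!"))
  f1 <- tempfile(fileext = ".fq"); f2 <- tempfile(fileext = ".fq")
  writeFastqPairs(pairs, f1, f2)
  back <- readFastqPairs(f1, f2)
  expect_identical(back@seq1, pairs@seq1)
  expect_identical(back@qual1, pairs@qual1)
  expect_identical(back@seq2, pairs@seq2)
  expect_identical(back@qual2, pairs@qual2)
  expect_identical(back@name, pairs@name)
  # "I" is Phred 40, "!" is Phred 0
  expect_equal(phredDecode("I!")[[1]], c(40L, 0L))
  expect_equal(phredEncode(c(40L, 0L)), "I!")
})

test_that("FASTQ pairing errors are reported", {
  f1 <- tempfile(fileext = ".fq"); f2 <- tempfile(fileext = ".fq")
  writeLines(c("@a/1", "ACGT", "+", "IIII", "@b/1", "ACGT", "+", "IIII",
               "@c/1", "ACGT", "+", "IIII"), f1)
  writeLines(c("@a/2", "ACGT", "+", "IIII", "@b/2", "ACGT", "+", "IIII"), f2)
  expect_error(readFastqPairs(f1, f2), "pairing error")
  writeLines(c("@a/2", "ACGT", "+", "IIII", "@x/2", "ACGT", "+", "IIII",
               "@c/2", "ACGT", "+", "IIII"), f2)
  expect_error(readFastqPairs(f1, f2), "name mismatch")
})

test_that("VCF writer anchors indels, shifts to 1-based, validates input", {
  ref <- toyReference()
  s <- refSequences(ref)[[1]]
  snp <- data.table::data.table(
    contig = "toy", pos = 9L, vcfPos = 10L,
    ref = substr(s, 10, 10), alt = "G", gt = "0/1", class = "SNP",
    qual = 50, depth = 30L, altFrac = 0.5, strandBias = 1, meanMQ = 60,
    meanAltQ = 30, homopolLen = 1L, distNearest = 100, indelLen = 0L,
    rfProb = NA_real_, filter = "PASS")
  if (snp$ref == "G") snp$alt <- "T"
  del <- data.table::copy(snp)
  del[, `:=`(pos = 19L, vcfPos = 20L, ref = substr(s, 20, 22),
             alt = substr(s, 20, 20), class = "DEL", indelLen = 2L)]
  calls <- new("VariantCallSet",
               calls = data.table::rbindlist(list(snp, del)),
               contigs = refNames(ref))
  out <- tempfile(fileext = ".vcf")
  writeVcf(calls, ref, out)
  lines <- readLines(out)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 2L)
  f <- strsplit(body[1], "\t")[[1]]
  expect_equal(as.integer(f[2]), 10L)            # 0-based 9 -> POS 10
  f2 <- strsplit(body[2], "\t")[[1]]
  expect_equal(nchar(f2[4]), 3L)                 # 2 bp deletion: REF "AXY"
  expect_equal(f2[5], substr(f2[4], 1, 1))       # ALT = shared anchor base
  # header-only VCF for an empty call set is still valid
  empty <- new("VariantCallSet", calls = snp[0L], contigs = refNames(ref))
  out2 <- tempfile(fileext = ".vcf")
  writeVcf(empty, ref, out2)
  expect_true(any(startsWith(readLines(out2), "#CHROM")))
  # unsorted input and N alleles are rejected
  unsorted <- new("VariantCallSet",
                  calls = data.table::rbindlist(list(del, snp)),
                  contigs = refNames(ref))
  expect_error(writeVcf(unsorted, ref, tempfile()), "sorted")
  bad <- data.table::copy(snp); bad[, alt := "N"]
  expect_error(writeVcf(new("VariantCallSet", calls = bad,
                            contigs = refNames(ref)), ref, tempfile()), "N")
})

test_that("VCF output parses under an independent VCF reader", {
  skip_if_not_installed("VariantAnnotation")
  st <- smallStudy()
  out <- tempfile(fileext = ".vcf")
  writeVcf(st$res$calls, st$ref, out)
  vcf <- VariantAnnotation::readVcf(out)
  expect_equal(length(vcf), nrow(st$res$calls@calls))
  expect_true(all(BiocGenerics::start(vcf) >= 1L))
  rr <- SummarizedExperiment::rowRanges(vcf)
  # indel records share a >= 1 bp anchor between REF and ALT
  refA <- as.character(rr$REF)
  altA <- vapply(rr$ALT, function(a) as.character(a)[1], character(1))
  indel <- nchar(refA) != nchar(altA)
  expect_true(all(substr(refA[indel], 1, 1) == substr(altA[indel], 1, 1)))
})

test_that("BED regions read as 0-based half-open with validation", {
  ref <- toyReference()
  bed <- tempfile(fileext = ".bed")
  writeLines(c("toy\t100\t200", "toy\t150\t300", "toy\t500\t600"), bed)
  rg <- readBedRegions(bed, ref)
  expect_equal(nrow(rg), 2L)                     # overlapping intervals merge
  expect_equal(rg$start, c(100L, 500L))
  expect_equal(rg$end, c(300L, 600L))
  bad <- tempfile(fileext = ".bed")
  writeLines("toy\t-5\t100", bad)
  expect_error(readBedRegions(bad, ref), "out of bounds")
})

test_that("SAM round-trips through an external SAM/BAM library", {
  skip_if_not_installed("Rsamtools")
  st <- smallStudy()
  d <- alignmentData(st$aln)
  sam <- tempfile(fileext = ".sam")
  writeSamAlignments(st$aln, st$ref, sam)
  back <- readSamAlignments(sam, st$ref)
  db <- alignmentData(back)
  expect_equal(nrow(db), sum(d$mapped))
  m <- d[d$mapped]
  # positions and spans survive the 1-based SAM round trip
  expect_equal(db$pos, m$pos)
  expect_equal(cigarStats(db$cigar)$refSpan,
               cigarStats(m$cigar)$refSpan)
  expect_equal(db$seq, m$seq)
})

test_that("SAM reader applies CIGAR arithmetic and rejects bad records", {
  skip_if_not_installed("Rsamtools")
  ref <- toyReference()
  s <- refSequences(ref)[[1]]
  sam <- tempfile(fileext = ".sam")
  rd1 <- substr(s, 6, 105)
  rd2 <- paste0(substr(s, 31, 40), substr(s, 43, 52))
  writeLines(c(
    "@HD\tVN:1.6",
    sprintf("@SQ\tSN:toy\tLN:%d", nchar(s)),
    sprintf("r1\t0\ttoy\t6\t60\t100M\t*\t0\t0\t%s\t%s", rd1,
            strrep("I", 100)),
    sprintf("r2\t0\ttoy\t31\t60\t10M2D10M\t*\t0\t0\t%s\t%s", rd2,
            strrep("I", 20)),
    sprintf("r3\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s", strrep("A", 20),
            strrep("I", 20))), sam)
  aln <- readSamAlignments(sam, ref)
  d <- alignmentData(aln)
  expect_equal(nrow(d), 2L)                      # unmapped record skipped
  expect_equal(attr(aln, "unmapped"), 1L)
  expect_equal(d$pos[1], 5L)                     # POS 6 -> 0-based 5
  expect_equal(cigarStats(d$cigar[1])$refSpan, 100L)
  expect_equal(cigarStats(d$cigar[2])$refSpan, 22L)
  # hard clips rejected
  sam2 <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    sprintf("@SQ\tSN:toy\tLN:%d", nchar(s)),
    sprintf("r1\t0\ttoy\t6\t60\t5H100M\t*\t0\t0\t%s\t%s", rd1,
            strrep("I", 100))), sam2)
  expect_error(readSamAlignments(sam2, ref), "ard-clip")
})
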