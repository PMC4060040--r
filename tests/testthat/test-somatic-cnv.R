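# snapshots assembled directly from column specifications
specSnapshot <- function(ref, spec) {
  # spec: data.table(pos, base (0..3), n, q) rows per site; positions not
  # listed stay hom-ref at depth 30
  n <- sum(refLengths(ref))
  counts <- matrix(0L, n, 19L)
  codes <- snapvar:::referenceCodes(ref)
  for (i in seq_len(n)) {
    b <- codes[i]
    if (b >= 0L) {
      counts[i, b + 1L] <- 15L
      counts[i, b + 5L] <- 15L
      counts[i, b + 9L] <- 900L
      counts[i, b + 13L] <- 1800L
      counts[i, 19L] <- 30L
    }
  }
  for (j in seq_len(nrow(spec))) {
    i <- spec$pos[j] + 1L
    counts[i, ] <- 0L
    tot <- 0L
    for (k in seq_along(spec$base[[j]])) {
      b <- spec$base[[j]][k]
      nn <- spec$n[[j]][k]
      nf <- nn %/% 2L
      counts[i, b + 1L] <- nf
      counts[i, b + 5L] <- nn - nf
      counts[i, b + 9L] <- nn * spec$q[j]
      counts[i, b + 13L] <- nn * 60L
      tot <- tot + nn
    }
    counts[i, 19L] <- tot
  }
  newSnapshot(ref, counts)
}

test_that("joint pair model separates somatic, germline and noise sites", {
  ref <- toyReference()
  codes <- snapvar:::referenceCodes(ref)
  # three probe sites with reference base A
  aSites <- which(codes == 0L) - 1L
  p1 <- aSites[10L]; p2 <- aSites[20L]; p3 <- aSites[30L]
  normal <- specSnapshot(ref, data.table::data.table(
    pos = c(p1, p2, p3),
    base = list(0L, c(0L, 2L), 0L),
    n = list(30L, c(15L, 15L), 30L), q = 30L))
  tumor <- specSnapshot(ref, data.table::data.table(
    pos = c(p1, p2, p3),
    base = list(c(0L, 2L), c(0L, 2L), c(0L, 2L)),
    n = list(c(15L, 15L), c(15L, 15L), c(29L, 1L)),
    q = c(30L, 30L, 10L)))
  som <- callSomatic(normal, tumor, ref)
  calls <- som@calls
  # A->G with clean normal: called, tumor genotype AG
  expect_true(p1 %in% calls$pos)
  expect_equal(calls$tumorGt[calls$pos == p1], "AG")
  expect_equal(calls$normalGt[calls$pos == p1], "AA")
  expect_gte(calls$score[calls$pos == p1], 30)
  # germline het in both samples: not somatic
  expect_false(p2 %in% calls$pos)
  # one low-quality alt read: below the score threshold
  expect_false(p3 %in% calls$pos)
})

test_that("joint posterior matches a brute-force 256-pair evaluation", {
  ref <- toyReference()
  codes <- snapvar:::referenceCodes(ref)
  p1 <- (which(codes == 0L) - 1L)[10L]
  normal <- specSnapshot(ref, data.table::data.table(
    pos = p1, base = list(0L), n = list(30L), q = 30L))
  tumor <- specSnapshot(ref, data.table::data.table(
    pos = p1, base = list(c(0L, 2L)), n = list(c(15L, 15L)), q = 30L))
  som <- callSomatic(normal, tumor, ref)
  score <- som@calls$score[som@calls$pos == p1]
  # independent evaluation: explicit loops over all 256 genotype pairs
  mu <- 1e-6
  bfN <- bruteForceGenotype(normal@counts[p1 + 1L, ], 0L, 0L, 0L, 0,
                            0L, 0L, 0)
  bfT <- bruteForceGenotype(tumor@counts[p1 + 1L, ], 0L, 0L, 0L, 0,
                            0L, 0L, 0)
  # the joint model: prior(Gn) P(Dn|Gn) T(Gt|Gn) P(Dt|Gt), assembled from
  # the independent brute-force prior/likelihood vectors
  lj <- matrix(-Inf, 16L, 16L)
  for (i in 1:16) for (j in 1:16) {
    tij <- if (i == j) log(1 - mu) else log(mu / 15)
    lj[i, j] <- bfN$logprior[i] + bfN$loglik[i] + tij + bfT$loglik[j]
  }
  J <- exp(lj - max(lj))
  J <- J / sum(J)
  sp <- snapvar:::cpp_genotype_space()
  novel <- vapply(1:16, function(g)
    any(!(c(sp$a1[g], sp$a2[g]) %in% 0L)), logical(1))
  M <- sum(J[1L, novel])                         # normal hom-ref = AA row
  expected <- -10 * log10(1 - M)
  expect_equal(score, expected, tolerance = 0.2)
})

test_that("identical snapshots produce zero somatic calls", {
  st <- smallStudy()
  som <- callSomatic(st$res$snapshot, st$res$snapshot, st$ref)
  expect_equal(nrow(som@calls), 0L)
  # mismatched references are rejected
  other <- makeReference(10000, seed = 99, name = "x")
  expect_error(callSomatic(st$res$snapshot,
                           depthSnapshot(other, rep(30L, 10000L)),
                           st$ref), "different references")
})

test_that("binary segmentation recovers planted gains and losses", {
  ref <- makeReference(300000, seed = 601, name = "w")
  set.seed(602)
  n <- 300000L
  base <- 40
  normalDepth <- stats::rpois(n, base)
  mult <- rep(1, n)
  mult[100001:150000] <- 1.5                     # 3 copies: log2 1.5 = 0.585
  mult[220001:250000] <- 0.5                     # hemizygous loss: log2 -1
  tumorDepth <- stats::rpois(n, base * mult)
  cn <- callCnv(depthSnapshot(ref, normalDepth),
                depthSnapshot(ref, tumorDepth), ref, window = 1000L)
  seg <- cn@segments
  gain <- seg[seg$state == "GAIN"]
  loss <- seg[seg$state == "LOSS"]
  expect_equal(nrow(gain), 1L)
  expect_equal(nrow(loss), 1L)
  expect_lte(abs(gain$start - 100000L), 2000L)   # within 2 windows
  expect_lte(abs(gain$end - 150000L), 2000L)
  expect_lte(abs(loss$start - 220000L), 2000L)
  expect_lte(abs(loss$end - 250000L), 2000L)
  expect_equal(gain$log2ratio, log2(1.5), tolerance = 0.1)
  expect_equal(loss$log2ratio, -1, tolerance = 0.15)
  # segments tile the windows without overlap
  data.table::setorder(seg, start)
  expect_true(all(seg$start[-1L] == seg$end[-nrow(seg)]))
})

test_that("flat coverage yields one neutral segment, thin data errors out", {
  ref <- makeReference(200000, seed = 603, name = "v")
  set.seed(604)
  d1 <- stats::rpois(200000L, 35)
  d2 <- stats::rpois(200000L, 35)
  cn <- callCnv(depthSnapshot(ref, d1), depthSnapshot(ref, d2), ref)
  expect_true(all(cn@segments$state == "NEUTRAL"))
  expect_lt(abs(cn@segments$log2ratio[1L]), 0.08)
  shallow <- depthSnapshot(ref, rep(2L, 200000L))
  expect_error(callCnv(shallow, shallow, ref), "too little data")
})
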