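# Shared fixtures, built once per test session and memoised. Everything is
# generated programmatically from fixed seeds; nothing is read from disk.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, builder(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

# 60 kb diploid study: reference, planted variants, 40x reads, and the full
# germline pipeline products — shared by aligner/realigner/caller tests
smallStudy <- function() {
  fixture("smallStudy", function() {
    ref <- makeReference(60000, seed = 101, name = "c1")
    genome <- plantVariants(ref, snpRate = 1e-3, indelRate = 1e-3,
                            seed = 102)
    prof <- simProfile(depth = 40, seed = 103)
    sim <- simulateReads(genome, prof)
    index <- buildSeedIndex(ref)
    aln <- alignReadPairs(sim$pairs, index)
    res <- suppressWarnings(runGermline(ref, pairs = sim$pairs))
    list(ref = ref, genome = genome, profile = prof, sim = sim,
         index = index, aln = aln, res = res)
  })
}

# deterministic toy reference with known content for exact-value tests
toyReference <- function() {
  fixture("toyReference", function() {
    set.seed(7)
    s <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
               collapse = "")
    # embed an exact homopolymer for normalization tests
    substr(s, 1001, 1012) <- "AAAAAAAAAAAA"
    newReference(s, "toy")
  })
}

# random pileup columns for likelihood-model tests: counts matrix rows plus
# bound events, drawn under a fixed seed
randomColumns <- function(n, seed = 11) {
  set.seed(seed)
  counts <- matrix(0L, n, 19L)
  ev1type <- integer(n); ev1n <- integer(n); ev1q <- numeric(n)
  ev2type <- integer(n); ev2n <- integer(n); ev2q <- numeric(n)
  refCode <- sample(0:3, n, replace = TRUE)
  for (i in seq_len(n)) {
    depth <- sample(1:60, 1L)
    alleles <- sample(0:3, sample(1:3, 1L))
    w <- stats::runif(length(alleles))
    nb <- as.vector(stats::rmultinom(1L, depth, w / sum(w)))
    for (k in seq_along(alleles)) {
      b <- alleles[k]
      nf <- stats::rbinom(1L, nb[k], 0.5)
      counts[i, b + 1L] <- nf
      counts[i, b + 5L] <- nb[k] - nf
      q <- sample(10:45, 1L)
      counts[i, b + 9L] <- nb[k] * q
      counts[i, b + 13L] <- nb[k] * 60L
    }
    if (stats::runif(1L) < 0.4) {
      ev1type[i] <- sample(1:2, 1L)
      ev1n[i] <- sample(1:20, 1L)
      ev1q[i] <- sample(10:40, 1L)
      if (stats::runif(1L) < 0.3) {
        ev2type[i] <- sample(1:2, 1L)
        ev2n[i] <- sample(1:5, 1L)
        ev2q[i] <- sample(10:40, 1L)
      }
    }
    counts[i, 19L] <- sum(counts[i, 1:8])
  }
  list(counts = counts, refCode = refCode, ev1type = ev1type, ev1n = ev1n,
       ev1q = ev1q, ev2type = ev2type, ev2n = ev2n, ev2q = ev2q)
}

# Independent brute-force evaluation of the 16-genotype model for one
# column: explicit loops over observation classes and genotype pairs, no
# shared code with the compiled implementation. Observations follow the
# model's definition: base counts (event support subtracted from the
# reference base, quality capped at 10 when the column is a strong indel
# candidate) plus up to two indel events.
bruteForceGenotype <- function(counts, refCode, ev1type, ev1n, ev1q,
                               ev2type, ev2n, ev2q,
                               thetaSnp = 1e-3, thetaIndel = 1e-4,
                               tsRatio = 2, delQual = 30) {
  pairs <- list(c(0, 0), c(0, 1), c(0, 2), c(0, 3), c(1, 1), c(1, 2),
                c(1, 3), c(2, 2), c(2, 3), c(3, 3), c(0, 4), c(1, 4),
                c(2, 4), c(3, 4), c(4, 4), c(4, 5))
  hasE1 <- ev1type > 0 && ev1n > 0
  hasE2 <- ev2type > 0 && ev2n > 0
  evTotal <- (if (hasE1) ev1n else 0) + (if (hasE2) ev2n else 0)
  depthCol <- counts[19]
  strongIndel <- evTotal >= 3 && depthCol > 0 && evTotal / depthCol >= 0.2
  obs <- list()
  for (b in 0:3) {
    cnt <- counts[b + 1] + counts[b + 5]
    if (cnt > 0) {
      q <- counts[b + 9] / cnt
      if (b == refCode) {
        cnt <- max(0, cnt - evTotal)
        if (strongIndel) q <- min(q, 10)
      }
      if (cnt > 0) obs[[length(obs) + 1]] <- list(a = b, n = cnt, q = q)
    }
  }
  if (hasE1) obs[[length(obs) + 1]] <-
      list(a = 4, n = ev1n, q = if (ev1type == 2) delQual else ev1q)
  if (hasE2) obs[[length(obs) + 1]] <-
      list(a = 5, n = ev2n, q = if (ev2type == 2) delQual else ev2q)
  if (!length(obs)) return(NULL)
  wTs <- tsRatio / (tsRatio + 1)
  wTv <- 1 / (2 * (tsRatio + 1))
  isTs <- function(a, b) (a == 0 && b == 2) || (a == 2 && b == 0) ||
    (a == 1 && b == 3) || (a == 3 && b == 1)
  wOf <- function(b) if (isTs(refCode, b)) wTs else wTv
  prior <- numeric(16)
  for (g in 1:16) {
    a1 <- pairs[[g]][1]; a2 <- pairs[[g]][2]
    if (a1 == refCode && a2 == refCode) { prior[g] <- NA; next }
    if (a1 < 4 && a2 < 4) {
      if (a1 == refCode || a2 == refCode) {
        alt <- if (a1 == refCode) a2 else a1
        prior[g] <- thetaSnp * wOf(alt)
      } else if (a1 == a2) prior[g] <- 0.5 * thetaSnp * wOf(a1)
      else prior[g] <- thetaSnp^2 * wOf(a1) * wOf(a2)
    } else if (a2 == 5) prior[g] <- 0.25 * thetaIndel^2
    else if (a1 == 4 && a2 == 4) prior[g] <- 0.5 * thetaIndel
    else {
      b <- if (a1 == 4) a2 else a1
      prior[g] <- if (b == refCode) thetaIndel
                  else thetaSnp * thetaIndel * wOf(b)
    }
  }
  prior[is.na(prior)] <- 1 - sum(prior, na.rm = TRUE)
  lp <- numeric(16)
  llv <- numeric(16)
  for (g in 1:16) {
    a1 <- pairs[[g]][1]; a2 <- pairs[[g]][2]
    if ((a1 == 4 || a2 == 4) && !hasE1) { lp[g] <- -Inf; llv[g] <- -Inf; next }
    if ((a1 == 5 || a2 == 5) && !hasE2) { lp[g] <- -Inf; llv[g] <- -Inf; next }
    ll <- 0
    for (o in obs) {
      eps <- min(10^(-o$q / 10), 0.75)
      pO <- function(a) if (o$a == a) 1 - eps else eps / 3
      ll <- ll + o$n * log(0.5 * pO(a1) + 0.5 * pO(a2))
    }
    llv[g] <- ll
    lp[g] <- log(prior[g]) + ll
  }
  m <- max(lp[is.finite(lp)])
  post <- ifelse(is.finite(lp), exp(lp - m), 0)
  post <- post / sum(post)
  homRefIdx <- which(vapply(pairs, function(p)
    p[1] == refCode && p[2] == refCode, logical(1)))
  list(posterior = post, argmax = which.max(post),
       loglik = llv, logprior = log(prior),
       qual = if (post[homRefIdx] <= 0) 10000
              else min(-10 * log10(post[homRefIdx]), 10000))
}

# snapshot with uniform synthetic depth per position, for CNV tests
depthSnapshot <- function(ref, depths) {
  n <- sum(refLengths(ref))
  stopifnot(length(depths) == n)
  counts <- matrix(0L, n, 19L)
  counts[, 1L] <- as.integer(depths)            # all-A forward evidence
  counts[, 9L] <- as.integer(depths) * 30L
  counts[, 13L] <- as.integer(depths) * 60L
  counts[, 19L] <- as.integer(depths)
  newSnapshot(ref, counts)
}

# internal helpers used across tests
cigarStats <- function(...) snapvar:::cpp_cigar_stats(...)
normIndels <- function(...) snapvar:::cpp_normalize_indels(...)
localAlign <- function(...) snapvar:::cpp_local_align(...)
revComp <- function(...) snapvar:::cpp_revcomp(...)
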