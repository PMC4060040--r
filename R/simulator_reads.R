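#' Simulate Illumina-style paired-end reads from a diploid genome
#'
#' Fragments are drawn uniformly (equal probability per haplotype) with a
#' Gaussian insert, FR mate orientation; substitution errors are injected
#' per the cycle profile and reported qualities follow the quality model
#' (phred of the cycle error rate with jitter). The origin table records
#' each read's true haplotype placement, its reference-projected interval
#' and the injected error cycles, so truth coverage and aligner accuracy
#' can be measured exactly.
#'
#' @param genome A \code{DiploidGenome} from \code{\link{plantVariants}}.
#' @param profile A \code{\link{simProfile}} (its seed drives everything).
#' @param cnvRegions Optional \code{data.table(contig, start, end, cn)} of
#'   copy-number regions (reference coordinates); fragment density scales
#'   by cn/2 inside them. Regions must not overlap.
#' @return List: \code{pairs} (a \linkS4class{ReadPairSet}) and
#'   \code{origin} (a \code{data.table}).
#' @export
simulateReads <- function(genome, profile, cnvRegions = NULL) {
  set.seed(profile$seed)
  ref <- genome$ref
  lens <- refLengths(ref)
  rl <- profile$readLength
  allSeq1 <- allSeq2 <- allQ1 <- allQ2 <- allName <- character(0)
  originParts <- list()
  for (ci in seq_along(lens)) {
    L <- as.integer(lens[ci])
    hapSeqs <- genome$haplotypes[[ci]]
    hapLens <- vapply(hapSeqs, nchar, integer(1L))
    maps <- genome$maps[[ci]]
    cnv <- if (!is.null(cnvRegions)) cnvRegions[cnvRegions$contig == ci]
           else NULL
    if (!is.null(cnv) && nrow(cnv) > 1L) {
      o <- order(cnv$start)
      if (any(cnv$start[o][-1L] < cnv$end[o][-nrow(cnv)]))
        stop("overlapping CNV regions")
    }
    basePairs <- round(profile$depth * L / (2 * rl))
    if (basePairs < 1L) next
    part <- cnvPartition(L, cnv)
    weights <- (part$end - part$start) * part$cn / 2
    nPairs <- round(basePairs * sum(weights) / L)
    regIdx <- sample.int(nrow(part), nPairs, replace = TRUE,
                         prob = weights)
    hapIdx <- sample.int(2L, nPairs, replace = TRUE)
    frag <- as.integer(round(stats::rnorm(nPairs, profile$insertMean,
                                          profile$insertSd)))
    frag <- pmax(frag, rl)
    # fragment start in reference coordinates within the drawn region,
    # then projected to the haplotype
    u <- stats::runif(nPairs)
    refStart <- part$start[regIdx] +
      floor(u * pmax(part$end[regIdx] - part$start[regIdx] - frag, 1))
    refStart <- pmax(refStart, 0L)
    hapStart <- integer(nPairs)
    for (h in 1:2) {
      sel <- hapIdx == h
      hapStart[sel] <- mapRefToHap(maps[[h]], refStart[sel])
    }
    bad <- hapStart + frag > hapLens[hapIdx] | hapStart < 0L
    # resample out-of-bounds fragments against the haplotype ends
    if (any(bad)) {
      hapStart[bad] <- floor(stats::runif(sum(bad)) *
                               (hapLens[hapIdx[bad]] - frag[bad]))
      hapStart <- pmax(hapStart, 0L)
    }
    fwd <- stats::runif(nPairs) < 0.5
    left <- right <- character(nPairs)
    for (h in 1:2) {
      sel <- hapIdx == h
      left[sel] <- substring(hapSeqs[[h]], hapStart[sel] + 1L,
                             hapStart[sel] + rl)
      right[sel] <- substring(hapSeqs[[h]], hapStart[sel] + frag[sel] - rl + 1L,
                              hapStart[sel] + frag[sel])
    }
    seq1 <- ifelse(fwd, left, cpp_revcomp(right))
    seq2 <- ifelse(fwd, cpp_revcomp(right), left)
    n2 <- 2L * nPairs
    seqs <- c(seq1, seq2)
    err <- injectSubstitutionErrors(seqs, rl, profile)
    seqs <- err$seqs
    quals <- makeQualityStrings(n2, rl, profile)
    ind <- injectReadIndels(seqs, rl, profile)
    seqs <- ind$seqs
    name <- sprintf("sv%s_%d", refNames(ref)[ci], seq_len(nPairs))
    allName <- c(allName, name)
    allSeq1 <- c(allSeq1, seqs[seq_len(nPairs)])
    allSeq2 <- c(allSeq2, seqs[nPairs + seq_len(nPairs)])
    allQ1 <- c(allQ1, quals[seq_len(nPairs)])
    allQ2 <- c(allQ2, quals[nPairs + seq_len(nPairs)])
    # true haplotype intervals per mate
    s1 <- ifelse(fwd, hapStart, hapStart + frag - rl)
    s2 <- ifelse(fwd, hapStart + frag - rl, hapStart)
    refS1 <- refE1 <- refS2 <- refE2 <- integer(nPairs)
    for (h in 1:2) {
      sel <- hapIdx == h
      refS1[sel] <- mapHapToRef(maps[[h]], s1[sel])
      refE1[sel] <- mapHapToRef(maps[[h]], s1[sel] + rl)
      refS2[sel] <- mapHapToRef(maps[[h]], s2[sel])
      refE2[sel] <- mapHapToRef(maps[[h]], s2[sel] + rl)
    }
    errPos <- err$errPos
    originParts[[length(originParts) + 1L]] <- data.table::data.table(
      qname = name, contig = ci, hap = hapIdx,
      hapStart1 = s1, hapStart2 = s2,
      strand1 = ifelse(fwd, "+", "-"), strand2 = ifelse(fwd, "-", "+"),
      refStart1 = refS1, refEnd1 = refE1, refStart2 = refS2,
      refEnd2 = refE2,
      errPos1 = errPos[seq_len(nPairs)],
      errPos2 = errPos[nPairs + seq_len(nPairs)],
      indelErr = ind$flag[seq_len(nPairs)] | ind$flag[nPairs + seq_len(nPairs)])
  }
  pairs <- new("ReadPairSet", name = allName, seq1 = allSeq1,
               qual1 = allQ1, seq2 = allSeq2, qual2 = allQ2)
  list(pairs = pairs, origin = data.table::rbindlist(originParts))
}

cnvPartition <- function(L, cnv) {
  if (is.null(cnv) || nrow(cnv) == 0L)
    return(data.table::data.table(start = 0L, end = L, cn = 2))
  cnv <- cnv[order(cnv$start)]
  starts <- integer(0); ends <- integer(0); cns <- numeric(0)
  cursor <- 0L
  for (i in seq_len(nrow(cnv))) {
    if (cnv$start[i] > cursor) {
      starts <- c(starts, cursor); ends <- c(ends, cnv$start[i])
      cns <- c(cns, 2)
    }
    starts <- c(starts, cnv$start[i]); ends <- c(ends, cnv$end[i])
    cns <- c(cns, cnv$cn[i])
    cursor <- cnv$end[i]
  }
  if (cursor < L) { starts <- c(starts, cursor); ends <- c(ends, L)
                    cns <- c(cns, 2) }
  data.table::data.table(start = starts, end = ends, cn = cns)
}

cycleErrorRates <- function(rl, profile) {
  profile$errStart +
    (profile$errEnd - profile$errStart) * (seq_len(rl) - 1L) / max(rl - 1L, 1L)
}

injectSubstitutionErrors <- function(seqs, rl, profile) {
  n <- length(seqs)
  rates <- cycleErrorRates(rl, profile)
  errRead <- integer(0); errCycle <- integer(0)
  bases <- c("A", "C", "G", "T")
  for (c in seq_len(rl)) {
    idx <- which(stats::runif(n) < rates[c])
    if (!length(idx)) next
    cur <- substring(seqs[idx], c, c)
    code <- match(cur, bases)
    valid <- !is.na(code)
    idx <- idx[valid]; code <- code[valid]
    if (!length(idx)) next
    off <- sample.int(3L, length(idx), replace = TRUE)
    newB <- bases[((code - 1L + off) %% 4L) + 1L]
    substr(seqs[idx], c, c) <- newB
    errRead <- c(errRead, idx); errCycle <- c(errCycle, rep(c, length(idx)))
  }
  errPos <- rep("", n)
  if (length(errRead)) {
    agg <- vapply(split(errCycle, errRead), paste, character(1L),
                  collapse = ",")
    errPos[as.integer(names(agg))] <- agg
  }
  list(seqs = seqs, errPos = errPos)
}

makeQualityStrings <- function(n, rl, profile) {
  rates <- cycleErrorRates(rl, profile)
  qBase <- as.integer(round(-10 * log10(pmax(rates, 1e-6))))
  j <- profile$qualJitter
  qm <- matrix(qBase, nrow = rl, ncol = n)
  if (j > 0L)
    qm <- qm + sample.int(2L * j + 1L, rl * n, replace = TRUE) - j - 1L
  qm[qm < 2L] <- 2L
  as.character(cpp_encode_phred(qm))
}

injectReadIndels <- function(seqs, rl, profile) {
  n <- length(seqs)
  flag <- rep(FALSE, n)
  pRead <- min(profile$indelErrRate * rl, 1)
  sel <- which(stats::runif(n) < pRead)
  bases <- c("A", "C", "G", "T")
  for (i in sel) {
    k <- sample.int(rl - 2L, 1L) + 1L
    if (stats::runif(1L) < 0.5) {
      # 1 bp deletion: drop cycle k, pad with a random base
      seqs[i] <- paste0(substr(seqs[i], 1L, k - 1L),
                        substr(seqs[i], k + 1L, rl),
                        sample(bases, 1L))
    } else {
      seqs[i] <- substr(paste0(substr(seqs[i], 1L, k),
                               sample(bases, 1L),
                               substr(seqs[i], k + 1L, rl)), 1L, rl)
    }
    flag[i] <- TRUE
  }
  list(seqs = seqs, flag = flag)
}

#' Simulate a tumor-normal pair with somatic events
#'
#' Tumor haplotypes are the germline haplotypes plus planted somatic SNVs
#' and indels (heterozygous, purity 1, expected alt fraction 0.5); CNV
#' regions scale tumor fragment density by cn/2. Somatic events colliding
#' with germline variants are dropped so the two truth sets stay disjoint.
#'
#' @param ref A \linkS4class{Reference}.
#' @param germline A \code{DiploidGenome} (the normal sample's variants).
#' @param somaticSnvRate,somaticIndelRate Per-base somatic rates.
#' @param cnvSpec Optional \code{data.table(contig, start, end, cn)}.
#' @param profile A \code{\link{simProfile}}.
#' @param seed Seed for somatic planting and the two read draws.
#' @return List: \code{normal}, \code{tumor} (each with pairs + origin),
#'   \code{somaticTruth}, \code{tumorGenome}.
#' @export
makeTumorPair <- function(ref, germline, somaticSnvRate = 1e-5,
                          somaticIndelRate = 2e-6, cnvSpec = NULL,
                          profile, seed) {
  if (missing(seed)) stop("seed is mandatory")
  som <- plantVariants(ref, snpRate = somaticSnvRate,
                       indelRate = somaticIndelRate, hetFraction = 1,
                       seed = seed + 1L)
  somTruth <- som$truth
  germTruth <- germline$truth
  # drop somatic draws colliding with germline footprints
  if (nrow(somTruth) && nrow(germTruth)) {
    germKey <- unlist(lapply(seq_len(nrow(germTruth)), function(i) {
      dl <- if (germTruth$class[i] == "DEL")
        as.integer(germTruth$payload[i]) else 0L
      paste(germTruth$contig[i],
            (germTruth$pos[i] - 1L):(germTruth$pos[i] + dl + 1L))
    }))
    somKey <- paste(somTruth$contig, somTruth$pos)
    somTruth <- somTruth[!somKey %in% germKey]
  }
  somTruth[, expectedAF := 0.5]
  tumorTruth <- data.table::rbindlist(list(
    germTruth, somTruth[, names(germTruth), with = FALSE]))
  data.table::setorder(tumorTruth, contig, pos)
  tumorHaps <- buildHaplotypes(ref, tumorTruth)
  tumorGenome <- structure(list(ref = ref, truth = tumorTruth,
                                haplotypes = tumorHaps$seqs,
                                maps = tumorHaps$maps),
                           class = "DiploidGenome")
  pN <- profile; pN$seed <- seed + 11L
  pT <- profile; pT$seed <- seed + 12L
  normal <- simulateReads(germline, pN)
  tumor <- simulateReads(tumorGenome, pT, cnvRegions = cnvSpec)
  list(normal = normal, tumor = tumor, somaticTruth = somTruth[],
       tumorGenome = tumorGenome)
}

#' Simulate a trio with Mendelian inheritance
#'
#' Parents are planted independently; the child inherits one haplotype from
#' each parent (no recombination at these scales), so with zero de novo
#' injections the child's variants are a subset of the parental union and
#' the truth genotypes have no Mendelian conflicts.
#'
#' @param ref A \linkS4class{Reference}.
#' @param snpRate,indelRate Variant densities for each parent.
#' @param profile A \code{\link{simProfile}}.
#' @param seed Master seed.
#' @param deNovo Number of de novo child SNVs to force-inject.
#' @return List with \code{father}, \code{mother}, \code{child} (genome,
#'   pairs, origin each) and the transmitted haplotype choices.
#' @export
makeTrio <- function(ref, snpRate = 1e-3, indelRate = 1e-4, profile, seed,
                     deNovo = 0L) {
  if (missing(seed)) stop("seed is mandatory")
  father <- plantVariants(ref, snpRate, indelRate, seed = seed + 1L)
  mother <- plantVariants(ref, snpRate, indelRate, seed = seed + 2L)
  set.seed(seed + 3L)
  nContig <- length(refNames(ref))
  fh <- sample.int(2L, nContig, replace = TRUE)
  mh <- sample.int(2L, nContig, replace = TRUE)
  childParts <- list()
  for (ci in seq_len(nContig)) {
    fv <- father$truth[father$truth$contig == ci &
                         grepl(as.character(fh[ci]), father$truth$hap)]
    mv <- mother$truth[mother$truth$contig == ci &
                         grepl(as.character(mh[ci]), mother$truth$hap)]
    fv <- data.table::copy(fv); fv[, hap := "1"]
    mv <- data.table::copy(mv); mv[, hap := "2"]
    both <- data.table::rbindlist(list(fv, mv))
    key <- paste(both$pos, both$class, both$payload)
    dupKeys <- key[duplicated(key)]
    both[, hap := data.table::fifelse(key %in% dupKeys, "12", hap)]
    both <- both[!duplicated(key)]
    childParts[[length(childParts) + 1L]] <- both
  }
  childTruth <- data.table::rbindlist(childParts)
  if (deNovo > 0L) {
    lens <- refLengths(ref)
    seqs <- refSequences(ref)
    dn <- list()
    tries <- 0L
    existing <- paste(childTruth$contig, childTruth$pos)
    while (length(dn) < deNovo && tries < deNovo * 100L) {
      tries <- tries + 1L
      ci <- sample.int(nContig, 1L)
      p <- sample.int(lens[ci] - 100L, 1L) + 50L
      refB <- substr(seqs[[ci]], p + 1L, p + 1L)
      if (refB == "N" || paste(ci, p) %in% existing) next
      alt <- sample(setdiff(c("A", "C", "G", "T"), refB), 1L)
      dn[[length(dn) + 1L]] <- data.table::data.table(
        contig = ci, pos = p, class = "SNP", payload = alt, len = 0L,
        vcfRef = refB, vcfAlt = alt, zygosity = "het",
        hap = sample(c("1", "2"), 1L), vcfPos = p + 1L)
      existing <- c(existing, paste(ci, p))
    }
    childTruth <- data.table::rbindlist(list(childTruth,
                                             data.table::rbindlist(dn)),
                                        use.names = TRUE)
  }
  data.table::setorder(childTruth, contig, pos)
  childTruth <- dropOverlaps(childTruth)
  childTruth[, zygosity := data.table::fifelse(hap == "12", "hom", "het")]
  haps <- buildHaplotypes(ref, childTruth)
  child <- structure(list(ref = ref, truth = childTruth,
                          haplotypes = haps$seqs, maps = haps$maps),
                     class = "DiploidGenome")
  mk <- function(genome, s) {
    p <- profile; p$seed <- s
    simulateReads(genome, p)
  }
  list(father = list(genome = father, reads = mk(father, seed + 11L)),
       mother = list(genome = mother, reads = mk(mother, seed + 12L)),
       child = list(genome = child, reads = mk(child, seed + 13L)),
       paternalHap = fh, maternalHap = mh)
}

#' One-call whole-genome simulation experiment
#'
#' Bundles reference generation, diploid variant planting and read
#' simulation under one master seed — the standard input protocol for
#' pipeline benchmarking: a synthetic genome with SNPs and indels, and
#' Illumina-style 100 bp paired-end reads at the requested depth with a
#' 500 +/- 25 bp insert.
#'
#' @param length Genome length (bp).
#' @param snpRate,indelRate Planted variant densities.
#' @param depth Sequencing depth.
#' @param seed Master seed; all stage seeds derive from it.
#' @param readLength,insertMean,insertSd Read geometry.
#' @return List: \code{ref}, \code{genome}, \code{profile}, \code{sim}
#'   (pairs + origin).
#' @export
wgsExperiment <- function(length = 1e6, snpRate = 1e-3, indelRate = 1e-3,
                          depth = 40, seed = 1L, readLength = 100L,
                          insertMean = 500, insertSd = 25) {
  seed <- as.integer(seed)
  ref <- makeReference(length, seed = seed, name = "sim1")
  genome <- plantVariants(ref, snpRate = snpRate, indelRate = indelRate,
                          seed = seed + 1000003L)
  prof <- simProfile(readLength = readLength, insertMean = insertMean,
                     insertSd = insertSd, depth = depth,
                     seed = seed + 2000003L)
  sim <- simulateReads(genome, prof)
  list(ref = ref, genome = genome, profile = prof, sim = sim)
}
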