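#' Generate a random reference genome
#'
#' Bases are drawn i.i.d. with the target GC content; optional repeat tracts
#' can be injected for aligner stress testing.
#'
#' @param length Contig length (>= 10000).
#' @param gc Target GC fraction in (0, 1).
#' @param seed RNG seed (mandatory: generation is a pure function of
#'   parameters + seed).
#' @param name Contig name.
#' @param repeatTracts Optional \code{data.frame(start, length, period)} of
#'   tandem repeats to inject (0-based starts).
#' @return A \linkS4class{Reference}.
#' @export
makeReference <- function(length, gc = 0.41, seed, name = "sim1",
                          repeatTracts = NULL) {
  if (length < 10000L) stop("reference length must be >= 10000")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p)
  if (!is.null(repeatTracts)) {
    for (i in seq_len(nrow(repeatTracts))) {
      s <- repeatTracts$start[i]; L <- repeatTracts$length[i]
      per <- repeatTracts$period[i]
      unit <- bases[(s + 1L):(s + per)]
      bases[(s + 1L):(s + L)] <- rep(unit, length.out = L)
    }
  }
  newReference(paste(bases, collapse = ""), name)
}

#' Illumina-style simulation profile
#'
#' Read length, insert model, depth, a per-cycle substitution error rate
#' rising linearly across the read, a reported-quality model (phred of the
#' cycle error rate with uniform integer jitter), and a per-base read indel
#' error rate.
#'
#' @param readLength Read length in bp.
#' @param insertMean,insertSd Insert (fragment) size model.
#' @param depth Haploid depth of coverage.
#' @param errStart,errEnd Substitution error rate at the first/last cycle.
#' @param qualJitter Reported-quality jitter half-width (phred units).
#' @param indelErrRate Per-base read indel error rate.
#' @param seed RNG seed (mandatory).
#' @export
simProfile <- function(readLength = 100L, insertMean = 500, insertSd = 25,
                       depth = 40, errStart = 0.001, errEnd = 0.005,
                       qualJitter = 3L, indelErrRate = 1e-5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(errStart >= 0, errStart <= 1, errEnd >= 0, errEnd <= 1,
            indelErrRate >= 0, indelErrRate <= 1, depth > 0)
  list(readLength = as.integer(readLength), insertMean = insertMean,
       insertSd = insertSd, depth = depth, errStart = errStart,
       errEnd = errEnd, qualJitter = as.integer(qualJitter),
       indelErrRate = indelErrRate, seed = as.integer(seed))
}

#' Plant germline variants and build diploid haplotypes
#'
#' SNPs and indels are placed by independent per-base Bernoulli draws
#' (Poisson-like at these rates); overlapping draws are resolved by
#' dropping the later one. Heterozygous variants go to one random
#' haplotype, homozygous to both; transitions are drawn with probability
#' tsRatio/(tsRatio+1); indel lengths are geometric, insertions uniform
#' random sequence. Indels are left-normalized at planting time so the
#' truth is directly comparable to normalized calls.
#'
#' @param ref A \linkS4class{Reference}.
#' @param snpRate,indelRate Per-base variant rates.
#' @param hetFraction Fraction of variants planted heterozygous.
#' @param indelGeomP Geometric length parameter.
#' @param maxIndel Maximum indel length.
#' @param tsRatio Transition:transversion draw ratio.
#' @param seed RNG seed (mandatory).
#' @return A \code{DiploidGenome}: truth table, per-contig haplotype
#'   sequences and haplotype-to-reference coordinate maps.
#' @export
plantVariants <- function(ref, snpRate = 1e-3, indelRate = 1e-4,
                          hetFraction = 2 / 3, indelGeomP = 0.4,
                          maxIndel = 20L, tsRatio = 2, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  seqs <- refSequences(ref)
  lens <- refLengths(ref)
  truthParts <- list()
  for (ci in seq_along(seqs)) {
    L <- lens[ci]
    s <- seqs[[ci]]
    bases <- strsplit(s, "")[[1L]]
    snpPos <- which(stats::runif(L) < snpRate) - 1L
    indelPos <- which(stats::runif(L) < indelRate) - 1L
    guard <- maxIndel + 2L
    snpPos <- snpPos[snpPos >= guard & snpPos < L - guard &
                       bases[snpPos + 1L] != "N"]
    indelPos <- indelPos[indelPos >= guard & indelPos < L - guard]
    tv <- list()
    if (length(snpPos)) {
      refB <- bases[snpPos + 1L]
      altB <- drawAltBases(refB, tsRatio)
      tv[[1L]] <- data.table::data.table(
        contig = ci, pos = snpPos, class = "SNP", payload = altB,
        len = 0L, vcfRef = refB, vcfAlt = altB)
    }
    if (length(indelPos)) {
      nI <- length(indelPos)
      isIns <- stats::runif(nI) < 0.5
      ilen <- pmin(stats::rgeom(nI, indelGeomP) + 1L, maxIndel)
      payload <- character(nI)
      ok <- rep(TRUE, nI)
      for (t in seq_len(nI)) {
        p <- indelPos[t]
        if (isIns[t]) {
          payload[t] <- paste(sample(c("A", "C", "G", "T"), ilen[t],
                                     replace = TRUE), collapse = "")
        } else {
          delSeq <- substr(s, p + 2L, p + 1L + ilen[t])
          if (grepl("N", delSeq) || bases[p + 1L] == "N") ok[t] <- FALSE
          payload[t] <- as.character(ilen[t])
        }
      }
      indelPos <- indelPos[ok]; isIns <- isIns[ok]
      ilen <- ilen[ok]; payload <- payload[ok]
      if (length(indelPos)) {
        nz <- cpp_normalize_indels(s, indelPos,
                                   ifelse(isIns, "I", "D"), payload)
        anchor <- nz$anchor
        payload <- as.character(nz$payload)
        keep <- anchor >= 1L
        tv[[length(tv) + 1L]] <- data.table::data.table(
          contig = ci, pos = anchor[keep], class = ifelse(isIns[keep],
                                                          "INS", "DEL"),
          payload = payload[keep], len = ilen[keep],
          vcfRef = NA_character_, vcfAlt = NA_character_)
      }
    }
    if (length(tv)) truthParts[[length(truthParts) + 1L]] <-
        data.table::rbindlist(tv, use.names = TRUE)
  }
  truth <- if (length(truthParts)) data.table::rbindlist(truthParts)
           else data.table::data.table(contig = integer(0), pos = integer(0),
                                       class = character(0),
                                       payload = character(0), len = integer(0),
                                       vcfRef = character(0),
                                       vcfAlt = character(0))
  data.table::setorder(truth, contig, pos)
  truth <- dropOverlaps(truth)
  n <- nrow(truth)
  zyg <- ifelse(stats::runif(n) < hetFraction, "het", "hom")
  hap <- ifelse(zyg == "hom", "12", ifelse(stats::runif(n) < 0.5, "1", "2"))
  truth[, zygosity := zyg]
  truth[, hap := hap]
  truth <- fillVcfAlleles(truth, seqs)
  haps <- buildHaplotypes(ref, truth)
  structure(list(ref = ref, truth = truth, haplotypes = haps$seqs,
                 maps = haps$maps), class = "DiploidGenome")
}

drawAltBases <- function(refB, tsRatio) {
  transitionOf <- c(A = "G", C = "T", G = "A", T = "C")
  tvOf <- list(A = c("C", "T"), C = c("A", "G"),
               G = c("C", "T"), T = c("A", "G"))
  pTs <- tsRatio / (tsRatio + 1)
  n <- length(refB)
  isTs <- stats::runif(n) < pTs
  alt <- character(n)
  alt[isTs] <- transitionOf[refB[isTs]]
  whichTv <- 1L + (stats::runif(n) < 0.5)
  for (i in which(!isTs)) alt[i] <- tvOf[[refB[i]]][whichTv[i]]
  alt
}

# Drop any variant whose footprint collides with an earlier-kept variant;
# "later draw" = later position in the sorted order. Around indels a guard
# band is enforced: an insertion/deletion pair within a few bases of each
# other edits the haplotype into a string that is exactly reproducible by a
# short run of substitutions, so the planted representation would not be
# uniquely recoverable under exact allele matching. The guard keeps every
# planted variant's minimal representation unique.
INDEL_GUARD <- 10L

dropOverlaps <- function(truth) {
  if (nrow(truth) < 2L) return(truth)
  keep <- logical(nrow(truth))
  lastEnd <- -100L; lastContig <- -1L; lastIndel <- FALSE
  for (i in seq_len(nrow(truth))) {
    isIndel <- truth$class[i] != "SNP"
    fp0 <- truth$pos[i]
    fp1 <- truth$pos[i] +
      (if (truth$class[i] == "DEL") as.integer(truth$payload[i]) else 0L) + 1L
    gap <- if (isIndel || lastIndel) INDEL_GUARD else 1L
    if (truth$contig[i] != lastContig || fp0 > lastEnd + gap) {
      keep[i] <- TRUE
      lastEnd <- fp1
      lastContig <- truth$contig[i]
      lastIndel <- isIndel
    }
  }
  truth[keep]
}

fillVcfAlleles <- function(truth, seqs) {
  for (i in which(is.na(truth$vcfRef))) {
    s <- seqs[[truth$contig[i]]]
    p <- truth$pos[i]
    anchorBase <- substr(s, p + 1L, p + 1L)
    if (truth$class[i] == "INS") {
      data.table::set(truth, i, "vcfRef", anchorBase)
      data.table::set(truth, i, "vcfAlt",
                      paste0(anchorBase, truth$payload[i]))
    } else {
      dl <- as.integer(truth$payload[i])
      data.table::set(truth, i, "vcfRef", substr(s, p + 1L, p + 1L + dl))
      data.table::set(truth, i, "vcfAlt", anchorBase)
    }
  }
  truth[, vcfPos := pos + 1L]
  truth
}

# apply a truth table to the reference, yielding per-contig haplotype pairs
# and hap->ref coordinate maps (piecewise linear)
buildHaplotypes <- function(ref, truth) {
  seqs <- refSequences(ref)
  hapSeqs <- list()
  hapMaps <- list()
  for (ci in seq_along(seqs)) {
    hapSeqs[[ci]] <- list()
    hapMaps[[ci]] <- list()
    for (h in 1:2) {
      tv <- truth[truth$contig == ci & grepl(as.character(h), truth$hap)]
      res <- applyVariantsToSeq(seqs[[ci]], tv)
      hapSeqs[[ci]][[h]] <- res$seq
      hapMaps[[ci]][[h]] <- res$map
    }
  }
  list(seqs = hapSeqs, maps = hapMaps)
}

applyVariantsToSeq <- function(s, tv) {
  if (nrow(tv) == 0L) {
    return(list(seq = s,
                map = data.table::data.table(hapStart = 0L, refStart = 0L)))
  }
  pieces <- character(0)
  mapHap <- integer(0); mapRef <- integer(0)
  cursor <- 0L          # 0-based ref position of next unconsumed base
  hapLen <- 0L
  addPiece <- function(str, refAt) {
    pieces[length(pieces) + 1L] <<- str
    mapHap[length(mapHap) + 1L] <<- hapLen
    mapRef[length(mapRef) + 1L] <<- refAt
    hapLen <<- hapLen + nchar(str)
  }
  for (i in seq_len(nrow(tv))) {
    p <- tv$pos[i]
    if (tv$class[i] == "SNP") {
      if (p > cursor) addPiece(substr(s, cursor + 1L, p), cursor)
      addPiece(tv$payload[i], p)
      cursor <- p + 1L
    } else if (tv$class[i] == "INS") {
      # insert after anchor p
      if (p + 1L > cursor) addPiece(substr(s, cursor + 1L, p + 1L), cursor)
      addPiece(tv$payload[i], NA_integer_)
      cursor <- p + 1L
    } else {
      dl <- as.integer(tv$payload[i])
      if (p + 1L > cursor) addPiece(substr(s, cursor + 1L, p + 1L), cursor)
      cursor <- p + 1L + dl
    }
  }
  if (cursor < nchar(s)) addPiece(substr(s, cursor + 1L, nchar(s)), cursor)
  hapSeq <- paste(pieces, collapse = "")
  # coordinate map: inserted pieces have no reference position of their own;
  # anchor them just past the previous piece so coverage mapping stays
  # monotone (drift bounded by the insertion length)
  for (i in which(is.na(mapRef))) {
    prev <- max(i - 1L, 1L)
    mapRef[i] <- mapRef[prev] + (mapHap[i] - mapHap[prev])
  }
  list(seq = hapSeq,
       map = data.table::data.table(hapStart = mapHap, refStart = mapRef))
}

mapHapToRef <- function(map, hapPos) {
  i <- findInterval(hapPos, map$hapStart)
  i[i < 1L] <- 1L
  map$refStart[i] + (hapPos - map$hapStart[i])
}

mapRefToHap <- function(map, refPos) {
  # inverse of mapHapToRef on segment starts; approximate within segments
  i <- findInterval(refPos, map$refStart)
  i[i < 1L] <- 1L
  map$hapStart[i] + (refPos - map$refStart[i])
}
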