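#' Prior model over the 16-genotype space
#'
#' SNP heterozygosity, indel heterozygosity and the transition:transversion
#' prior ratio; the per-genotype prior table is derived per site from the
#' reference base (hom-ref absorbs the remainder; the 16 priors sum to 1).
#'
#' @param thetaSnp Prior probability of a heterozygous SNP at a site.
#' @param thetaIndel Prior probability of a heterozygous indel at a site.
#' @param tsRatio Transition vs transversion prior ratio (2 gives the
#'   genome-wide Ti/Tv expectation of ~2).
#' @export
priorModel <- function(thetaSnp = 1e-3, thetaIndel = 1e-4, tsRatio = 2) {
  stopifnot(thetaSnp > 0, thetaSnp < 0.1, thetaIndel > 0, tsRatio > 0)
  structure(list(thetaSnp = thetaSnp, thetaIndel = thetaIndel,
                 tsRatio = tsRatio), class = "PriorModel")
}

GENOTYPE_LABELS <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT",
                     "TT", "A/I", "C/I", "G/I", "T/I", "I/I", "I1/I2")

# genotype index of hom-ref for ref code 0..3
HOMREF_IDX <- c(1L, 5L, 8L, 10L)

#' Per-site genotype state under the 16-genotype model
#'
#' Evaluates one snapshot column: 10 diploid base genotypes, 4 base/indel
#' heterozygotes, the homozygous indel and the compound indel heterozygote,
#' where I and I' are the two best-supported indel events at the site.
#' Genotypes referencing an absent indel allele carry posterior 0.
#'
#' @param column A column from \code{\link{snapshotColumn}}.
#' @param refBase Reference base at the column ("A"/"C"/"G"/"T").
#' @param priors A \code{\link{priorModel}}.
#' @param delQual Evidence quality assigned to deletion observations (the
#'   column stores no per-deletion quality).
#' @return List: genotype labels, log-likelihoods, posteriors (sum to 1),
#'   argmax label, QUAL, and the bound indel events.
#' @export
genotypeSite <- function(column, refBase, priors = priorModel(),
                         delQual = 30) {
  counts <- matrix(0L, 1L, 19L)
  counts[1L, 1:4] <- column$fwd
  counts[1L, 5:8] <- column$rev
  counts[1L, 9:12] <- column$qualSum
  counts[1L, 13:16] <- column$mapqSum
  counts[1L, 17L] <- column$nOther
  counts[1L, 18L] <- column$delSpan
  counts[1L, 19L] <- column$depth
  ev <- data.table::rbindlist(list(
    data.table::data.table(row = 1L, type = "I",
                           payload = column$insertions$payload,
                           fwd = column$insertions$fwd,
                           rev = column$insertions$rev,
                           qsum = column$insertions$qsum),
    data.table::data.table(row = 1L, type = "D",
                           payload = column$deletions$payload,
                           fwd = column$deletions$fwd,
                           rev = column$deletions$rev, qsum = 0L)),
    use.names = TRUE, fill = TRUE)
  bound <- bindTopEvents(ev, 1L)
  rc <- match(refBase, c("A", "C", "G", "T")) - 1L
  if (is.na(rc)) stop("refBase must be one of A/C/G/T")
  res <- cpp_genotype_batch(counts, rc, bound$ev1type, bound$ev1n,
                            bound$ev1q, bound$ev2type, bound$ev2n,
                            bound$ev2q, priors$thetaSnp, priors$thetaIndel,
                            priors$tsRatio, delQual, TRUE)
  if (is.na(res$argmax[1L])) return(NULL)   # depth 0: no-call sentinel
  list(genotypes = GENOTYPE_LABELS,
       logLik = res$loglik[1L, ], logPrior = res$logprior[1L, ],
       posterior = res$posterior[1L, ],
       argmax = GENOTYPE_LABELS[res$argmax[1L]], qual = res$qual[1L],
       event1 = bound$label1, event2 = bound$label2)
}

# top-2 indel events per row by stranded support; ties broken by
# (type, payload) for determinism
bindTopEvents <- function(ev, nRows) {
  out <- list(ev1type = integer(nRows), ev1n = integer(nRows),
              ev1q = numeric(nRows), ev1payload = rep(NA_character_, nRows),
              ev2type = integer(nRows), ev2n = integer(nRows),
              ev2q = numeric(nRows), ev2payload = rep(NA_character_, nRows),
              label1 = rep(NA_character_, nRows),
              label2 = rep(NA_character_, nRows))
  if (is.null(ev) || nrow(ev) == 0L) return(out)
  e <- data.table::copy(ev)
  e[, support := fwd + rev]
  data.table::setorder(e, row, -support, type, payload)
  e[, rank := seq_len(.N), by = "row"]
  top <- e[e$rank <= 2L]
  for (i in seq_len(nrow(top))) {
    r <- top$row[i]
    ty <- if (top$type[i] == "I") 1L else 2L
    qv <- if (ty == 1L)
      top$qsum[i] / max(top$support[i] * nchar(top$payload[i]), 1L) else 0
    lab <- paste0(top$type[i], ":", top$payload[i])
    if (top$rank[i] == 1L) {
      out$ev1type[r] <- ty; out$ev1n[r] <- top$support[i]; out$ev1q[r] <- qv
      out$ev1payload[r] <- top$payload[i]; out$label1[r] <- lab
    } else {
      out$ev2type[r] <- ty; out$ev2n[r] <- top$support[i]; out$ev2q[r] <- qv
      out$ev2payload[r] <- top$payload[i]; out$label2[r] <- lab
    }
  }
  out
}

# vectorized version used by the batch caller (no per-row R loop)
bindTopEventsFast <- function(ev, nRows) {
  out <- list(ev1type = integer(nRows), ev1n = integer(nRows),
              ev1q = numeric(nRows), ev1payload = rep(NA_character_, nRows),
              ev2type = integer(nRows), ev2n = integer(nRows),
              ev2q = numeric(nRows), ev2payload = rep(NA_character_, nRows),
              ev1fwd = integer(nRows), ev1rev = integer(nRows))
  if (is.null(ev) || nrow(ev) == 0L) return(out)
  e <- data.table::copy(ev)
  e[, support := fwd + rev]
  data.table::setorder(e, row, -support, type, payload)
  e[, rank := seq_len(.N), by = "row"]
  t1 <- e[e$rank == 1L]
  t2 <- e[e$rank == 2L]
  out$ev1type[t1$row] <- data.table::fifelse(t1$type == "I", 1L, 2L)
  out$ev1n[t1$row] <- t1$support
  out$ev1q[t1$row] <- data.table::fifelse(
    t1$type == "I", t1$qsum / pmax(t1$support * nchar(t1$payload), 1L), 0)
  out$ev1payload[t1$row] <- t1$payload
  out$ev1fwd[t1$row] <- t1$fwd
  out$ev1rev[t1$row] <- t1$rev
  out$ev2type[t2$row] <- data.table::fifelse(t2$type == "I", 1L, 2L)
  out$ev2n[t2$row] <- t2$support
  out$ev2q[t2$row] <- data.table::fifelse(
    t2$type == "I", t2$qsum / pmax(t2$support * nchar(t2$payload), 1L), 0)
  out$ev2payload[t2$row] <- t2$payload
  out
}

#' Call germline variants from a snapshot
#'
#' Runs the 16-genotype model at every covered position, emits a call
#' wherever the posterior-maximal genotype is not homozygous reference, and
#' assigns QUAL as the phred-scaled hom-ref posterior mass (capped at
#' 10000). Indel alleles are expanded to left-normalized, anchored VCF
#' REF/ALT strings; a site whose called genotype mixes a base and an indel
#' allele yields one record with two ALTs.
#'
#' @param snapshot A \linkS4class{Snapshot}.
#' @param ref Matching \linkS4class{Reference} (checksum-verified).
#' @param priors A \code{\link{priorModel}}.
#' @param delQual Deletion observation quality.
#' @return A \linkS4class{VariantCallSet} with filter status UNFILTERED.
#' @export
callVariants <- function(snapshot, ref, priors = priorModel(),
                         delQual = 30) {
  if (snapshot@checksum != refChecksum(ref))
    stop("reference checksum mismatch: snapshot was built against a ",
         "different reference")
  counts <- snapshot@counts
  nRows <- nrow(counts)
  rg <- snapshot@regions
  seqs <- refSequences(ref)
  # reference base code per snapshot row
  rowContig <- integer(nRows)
  rowPos <- integer(nRows)
  for (i in seq_len(nrow(rg))) {
    if (rg$end[i] > rg$start[i]) {
      sel <- (rg$rowStart[i] + 1L):(rg$rowStart[i] + rg$end[i] - rg$start[i])
      rowContig[sel] <- rg$contig[i]
      rowPos[sel] <- rg$start[i]:(rg$end[i] - 1L)
    }
  }
  refCodes <- integer(nRows)
  for (ci in unique(rowContig)) {
    sel <- rowContig == ci
    b <- strsplit(seqs[[ci]], "")[[1]][rowPos[sel] + 1L]
    cd <- match(b, c("A", "C", "G", "T")) - 1L
    cd[is.na(cd)] <- -1L
    refCodes[sel] <- cd
  }
  bound <- bindTopEventsFast(snapshot@events, nRows)
  res <- cpp_genotype_batch(counts, refCodes, bound$ev1type, bound$ev1n,
                            bound$ev1q, bound$ev2type, bound$ev2n,
                            bound$ev2q, priors$thetaSnp, priors$thetaIndel,
                            priors$tsRatio, delQual, FALSE)
  homRef <- ifelse(refCodes >= 0L, HOMREF_IDX[refCodes + 1L], NA_integer_)
  emit <- which(!is.na(res$argmax) & res$argmax != homRef)
  calls <- buildCallTable(emit, res, counts, refCodes, rowContig, rowPos,
                          bound, snapshot, ref, delQual)
  new("VariantCallSet", calls = calls, contigs = refNames(ref))
}

GT_SPACE <- NULL  # filled lazily from the compiled genotype table

genotypeAlleles <- function() {
  sp <- cpp_genotype_space()
  list(a1 = sp$a1, a2 = sp$a2)
}

buildCallTable <- function(emit, res, counts, refCodes, rowContig, rowPos,
                           bound, snapshot, ref, delQual) {
  cols <- c("contig", "pos", "vcfPos", "ref", "alt", "gt", "class", "qual",
            "depth", "altFrac", "strandBias", "meanMQ", "meanAltQ",
            "homopolLen", "distNearest", "indelLen", "rfProb", "filter")
  emptyCalls <- data.table::data.table(
    contig = character(0), pos = integer(0), vcfPos = integer(0),
    ref = character(0), alt = character(0), gt = character(0),
    class = character(0), qual = numeric(0), depth = integer(0),
    altFrac = numeric(0), strandBias = numeric(0), meanMQ = numeric(0),
    meanAltQ = numeric(0), homopolLen = integer(0), distNearest = numeric(0),
    indelLen = integer(0), rfProb = numeric(0), filter = character(0))
  if (!length(emit)) return(emptyCalls)
  sp <- genotypeAlleles()
  seqs <- refSequences(ref)
  lens <- refLengths(ref)
  baseChars <- c("A", "C", "G", "T")
  rows <- vector("list", length(emit))
  for (t in seq_along(emit)) {
    r <- emit[t]
    g <- res$argmax[r]
    a1 <- sp$a1[g]; a2 <- sp$a2[g]
    rc <- refCodes[r]
    ci <- rowContig[r]; p <- rowPos[r]
    ctgSeq <- seqs[[ci]]
    alleles <- unique(c(a1, a2))
    nonRef <- alleles[alleles != rc]
    if (!length(nonRef)) next
    # resolve indel payloads for I/I' alleles
    resolve <- function(a) {
      if (a <= 3L) list(kind = "base", base = baseChars[a + 1L])
      else if (a == 4L) list(kind = ifelse(bound$ev1type[r] == 1L, "INS",
                                           "DEL"),
                             payload = bound$ev1payload[r])
      else list(kind = ifelse(bound$ev2type[r] == 1L, "INS", "DEL"),
                payload = bound$ev2payload[r])
    }
    alts <- lapply(nonRef, resolve)
    kinds <- vapply(alts, `[[`, character(1L), "kind")
    dels <- vapply(alts, function(a)
      if (a$kind == "DEL") as.integer(a$payload) else 0L, integer(1L))
    maxDel <- max(dels)
    if (p + 1L + maxDel > lens[ci]) next      # event runs off the contig
    anchorBase <- substr(ctgSeq, p + 1L, p + 1L)
    tail <- if (maxDel > 0L) substr(ctgSeq, p + 2L, p + 1L + maxDel) else ""
    refAllele <- paste0(anchorBase, tail)
    altStr <- vapply(alts, function(a) {
      if (a$kind == "base") paste0(a$base, tail)
      else if (a$kind == "INS") paste0(anchorBase, a$payload, tail)
      else paste0(anchorBase, substr(tail, as.integer(a$payload) + 1L,
                                     maxDel))
    }, character(1L))
    if (any(altStr == refAllele)) next
    # genotype string in VCF allele indices
    gtIdx <- function(a) {
      if (a == rc) 0L
      else match(a, nonRef)
    }
    gtStr <- paste(sort(c(gtIdx(a1), gtIdx(a2))), collapse = "/")
    cls <- if (all(kinds == "base")) "SNP"
           else if (length(kinds) > 1L && any(kinds == "base")) "MIXED"
           else if (any(kinds == "INS")) "INS" else "DEL"
    # annotations against the primary (first) alt allele
    prim <- alts[[1L]]
    depth <- counts[r, 19L]
    baseTot <- sum(counts[r, 1:8])
    if (prim$kind == "base") {
      b <- match(prim$base, baseChars)
      altF <- counts[r, b]; altR <- counts[r, b + 4L]
      altN <- altF + altR
      meanAltQ <- if (altN > 0L) counts[r, b + 8L] / altN else 0
      indelLen <- 0L
    } else {
      if (nonRef[1L] == 4L) {
        altF <- bound$ev1fwd[r]; altR <- bound$ev1rev[r]
        altN <- bound$ev1n[r]
        meanAltQ <- if (bound$ev1type[r] == 1L) bound$ev1q[r] else delQual
      } else {
        altN <- bound$ev2n[r]; altF <- altN; altR <- 0L
        meanAltQ <- if (bound$ev2type[r] == 1L) bound$ev2q[r] else delQual
      }
      indelLen <- if (prim$kind == "INS") nchar(prim$payload)
                  else as.integer(prim$payload)
    }
    refF <- if (rc >= 0L) counts[r, rc + 1L] else 0L
    refR <- if (rc >= 0L) counts[r, rc + 5L] else 0L
    sb <- strandBiasPhred(refF, refR, altF, altR)
    meanMQ <- if (baseTot > 0L) sum(counts[r, 13:16]) / baseTot else 0
    rows[[t]] <- data.table::data.table(
      contig = snapshot@contigs[ci], pos = p, vcfPos = p + 1L,
      ref = refAllele, alt = paste(altStr, collapse = ","), gt = gtStr,
      class = cls, qual = res$qual[r], depth = as.integer(depth),
      altFrac = altN / max(depth, 1L), strandBias = sb, meanMQ = meanMQ,
      meanAltQ = meanAltQ,
      homopolLen = homopolymerLenAt(ctgSeq, p),
      distNearest = NA_real_, indelLen = indelLen, rfProb = NA_real_,
      filter = "UNFILTERED")
  }
  calls <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1L))])
  if (nrow(calls) == 0L) return(emptyCalls)
  # left-normalize emitted indel records and dedupe representations
  calls <- normalizeCallTable(calls, ref)
  ord <- order(match(calls$contig, refNames(ref)), calls$pos)
  calls <- calls[ord]
  calls[, distNearest := nearestCallDistance(calls)]
  calls[]
}

# phred-scaled Fisher exact strand bias (ref fwd/rev vs alt fwd/rev)
strandBiasPhred <- function(refF, refR, altF, altR) {
  m <- matrix(c(refF, refR, altF, altR), 2L)
  if (sum(m) == 0L) return(0)
  p <- stats::fisher.test(m)$p.value
  min(-10 * log10(max(p, 1e-30)), 300)
}

homopolymerLenAt <- function(ctgSeq, p) {
  # run length of the base immediately right of the anchor
  L <- nchar(ctgSeq)
  if (p + 2L > L) return(0L)
  b <- substr(ctgSeq, p + 2L, p + 2L)
  run <- 1L
  while (p + 2L + run <= L && substr(ctgSeq, p + 2L + run,
                                     p + 2L + run) == b)
    run <- run + 1L
  run
}

nearestCallDistance <- function(calls) {
  if (nrow(calls) < 2L) return(rep(1e6, nrow(calls)))
  d <- rep(1e6, nrow(calls))
  for (ctg in unique(calls$contig)) {
    sel <- which(calls$contig == ctg)
    if (length(sel) < 2L) next
    p <- calls$pos[sel]
    gaps <- diff(p)
    d[sel] <- pmin(c(gaps, 1e6), c(1e6, gaps))
  }
  d
}

# left-normalize indel records (SNPs are untouched) and merge duplicate
# normalized representations, keeping the higher-QUAL record
normalizeCallTable <- function(calls, ref) {
  seqs <- refSequences(ref)
  # single-allele indel records only: multi-ALT records were anchored as a
  # unit and each allele is normalized at comparison time instead
  isIndel <- calls$class %in% c("INS", "DEL") & !grepl(",", calls$alt,
                                                       fixed = TRUE)
  if (any(isIndel)) {
    for (ctg in unique(calls$contig[isIndel])) {
      sel <- which(isIndel & calls$contig == ctg)
      ci <- match(ctg, refNames(ref))
      type <- ifelse(calls$class[sel] == "INS", "I", "D")
      payload <- ifelse(calls$class[sel] == "INS",
                        substr(calls$alt[sel], 2L, nchar(calls$alt[sel])),
                        as.character(nchar(calls$ref[sel]) - 1L))
      nz <- cpp_normalize_indels(seqs[[ci]], calls$pos[sel], type, payload)
      newPos <- nz$anchor
      newPayload <- as.character(nz$payload)
      for (k in seq_along(sel)) {
        i <- sel[k]
        p <- newPos[k]
        anchorBase <- substr(seqs[[ci]], p + 1L, p + 1L)
        if (type[k] == "I") {
          data.table::set(calls, i, "ref", anchorBase)
          data.table::set(calls, i, "alt", paste0(anchorBase, newPayload[k]))
        } else {
          dl <- as.integer(newPayload[k])
          data.table::set(calls, i, "ref",
                          substr(seqs[[ci]], p + 1L, p + 1L + dl))
          data.table::set(calls, i, "alt", anchorBase)
        }
        data.table::set(calls, i, "pos", p)
        data.table::set(calls, i, "vcfPos", p + 1L)
      }
    }
  }
  data.table::setorder(calls, contig, pos, -qual)
  calls[!duplicated(calls[, c("contig", "pos", "ref", "alt")])]
}
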