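#' Call somatic SNVs and indels from a tumor-normal snapshot pair
#'
#' Per site, a joint posterior over the 16 x 16 normal/tumor genotype pairs:
#' prior(Gn) * P(Dn|Gn) * T(Gt|Gn) * P(Dt|Gt), where the somatic transition
#' T keeps the normal genotype with probability 1 - mu and spreads mu
#' uniformly over the 15 alternatives. The somatic score is
#' -10 log10(1 - M) with M the posterior mass of pairs in which the normal
#' genotype is homozygous reference and the tumor genotype carries an allele
#' absent from it. Indel alleles are bound per site from the combined
#' tumor+normal event support, so "I" denotes the same event in both
#' samples.
#'
#' @param normal,tumor \linkS4class{Snapshot}s built against the same
#'   reference (checksums must match); they must declare the same regions.
#' @param ref The \linkS4class{Reference}.
#' @param priors A \code{\link{priorModel}}.
#' @param mu Somatic transition rate.
#' @param minScore Minimum somatic score emitted.
#' @param minNormalDepth,minTumorDepth Depth guards.
#' @param maxNormalAF Maximum normal alt fraction.
#' @param requireBothStrands Require >= 1 alt read on each strand for SNVs.
#' @param delQual Deletion observation quality.
#' @return A \linkS4class{SomaticCallSet}.
#' @export
callSomatic <- function(normal, tumor, ref, priors = priorModel(),
                        mu = 1e-6, minScore = 30,
                        minNormalDepth = 8L, minTumorDepth = 8L,
                        maxNormalAF = 0.03, requireBothStrands = TRUE,
                        delQual = 30) {
  if (normal@checksum != tumor@checksum)
    stop("snapshots were built against different references")
  if (normal@checksum != refChecksum(ref))
    stop("reference does not match the snapshots")
  if (!identical(normal@regions[, c("contig", "start", "end")],
                 tumor@regions[, c("contig", "start", "end")]))
    stop("snapshots declare different regions")
  cn <- normal@counts; ct <- tumor@counts
  nRows <- nrow(cn)
  rg <- normal@regions
  rowContig <- integer(nRows); rowPos <- integer(nRows)
  for (i in seq_len(nrow(rg))) {
    sel <- (rg$rowStart[i] + 1L):(rg$rowStart[i] + rg$end[i] - rg$start[i])
    rowContig[sel] <- rg$contig[i]
    rowPos[sel] <- rg$start[i]:(rg$end[i] - 1L)
  }
  seqs <- refSequences(ref)
  refCodes <- integer(nRows)
  for (ci in unique(rowContig)) {
    sel <- rowContig == ci
    b <- strsplit(seqs[[ci]], "")[[1]][rowPos[sel] + 1L]
    cd <- match(b, c("A", "C", "G", "T")) - 1L
    cd[is.na(cd)] <- -1L
    refCodes[sel] <- cd
  }
  # candidate sites: tumor carries non-reference evidence
  tumorBase <- ct[, 1:4] + ct[, 5:8]
  refN <- ifelse(refCodes >= 0L,
                 tumorBase[cbind(seq_len(nRows), pmax(refCodes, 0L) + 1L)],
                 0L)
  nonRef <- rowSums(tumorBase) - refN
  evRows <- unique(c(tumor@events$row, normal@events$row))
  cand <- which((nonRef >= 2L | seq_len(nRows) %in% evRows) &
                  refCodes >= 0L & cn[, 19L] > 0L & ct[, 19L] > 0L)
  emptySet <- new("SomaticCallSet",
                  calls = data.table::data.table(
                    contig = character(0), pos = integer(0),
                    vcfPos = integer(0), ref = character(0),
                    alt = character(0), normalGt = character(0),
                    tumorGt = character(0), score = numeric(0),
                    class = character(0), normalDepth = integer(0),
                    tumorDepth = integer(0), normalAltReads = integer(0),
                    tumorAltReads = integer(0), normalAF = numeric(0),
                    tumorAF = numeric(0), filter = character(0)),
                  contigs = refNames(ref))
  if (!length(cand)) return(emptySet)
  # shared event binding from combined support
  combEv <- data.table::rbindlist(list(normal@events, tumor@events))
  combEv <- combEv[, .(fwd = sum(fwd), rev = sum(rev), qsum = sum(qsum)),
                   by = c("row", "type", "payload")]
  bound <- bindTopEventsFast(combEv, nRows)
  perSample <- function(counts, events) {
    # per-sample support for the bound events
    ev <- data.table::copy(events)
    key <- paste(ev$row, ev$type, ev$payload)
    k1 <- paste(seq_len(nRows), ifelse(bound$ev1type == 1L, "I", "D"),
                bound$ev1payload)
    k2 <- paste(seq_len(nRows), ifelse(bound$ev2type == 1L, "I", "D"),
                bound$ev2payload)
    m1 <- match(k1, key); m2 <- match(k2, key)
    list(ev1type = ifelse(is.na(m1), 0L, bound$ev1type),
         ev1n = ifelse(is.na(m1), 0L, ev$fwd[m1] + ev$rev[m1]),
         ev1q = ifelse(is.na(m1), 0,
                       ev$qsum[m1] / pmax((ev$fwd[m1] + ev$rev[m1]) *
                                            nchar(ev$payload[m1]), 1L)),
         ev1fwd = ifelse(is.na(m1), 0L, ev$fwd[m1]),
         ev1rev = ifelse(is.na(m1), 0L, ev$rev[m1]),
         ev2type = ifelse(is.na(m2), 0L, bound$ev2type),
         ev2n = ifelse(is.na(m2), 0L, ev$fwd[m2] + ev$rev[m2]),
         ev2q = ifelse(is.na(m2), 0,
                       ev$qsum[m2] / pmax((ev$fwd[m2] + ev$rev[m2]) *
                                            nchar(ev$payload[m2]), 1L)))
  }
  bn <- perSample(cn, normal@events)
  bt <- perSample(ct, tumor@events)
  sub <- function(x, rows) lapply(x, function(v) v[rows])
  bnC <- sub(bn, cand); btC <- sub(bt, cand)
  gn <- cpp_genotype_batch(cn[cand, , drop = FALSE], refCodes[cand],
                           bnC$ev1type, bnC$ev1n, bnC$ev1q, bnC$ev2type,
                           bnC$ev2n, bnC$ev2q, priors$thetaSnp,
                           priors$thetaIndel, priors$tsRatio, delQual, TRUE)
  gt <- cpp_genotype_batch(ct[cand, , drop = FALSE], refCodes[cand],
                           btC$ev1type, btC$ev1n, btC$ev1q, btC$ev2type,
                           btC$ev2n, btC$ev2q, priors$thetaSnp,
                           priors$thetaIndel, priors$tsRatio, delQual, TRUE)
  sp <- genotypeAlleles()
  logT <- matrix(log(mu / 15), 16L, 16L)
  diag(logT) <- log(1 - mu)
  rows <- list()
  for (t in seq_along(cand)) {
    r <- cand[t]
    rc <- refCodes[r]
    lpn <- gn$logprior[t, ] + gn$loglik[t, ]
    llt <- gt$loglik[t, ]
    J <- outer(lpn, llt, `+`) + logT
    m <- max(J)
    if (!is.finite(m)) next
    P <- exp(J - m)
    P <- P / sum(P)
    homRef <- HOMREF_IDX[rc + 1L]
    # somatic pairs: normal hom-ref, tumor introduces a novel allele
    novel <- vapply(seq_len(16L), function(g)
      any(!(c(sp$a1[g], sp$a2[g]) %in% c(rc))), logical(1L))
    M <- sum(P[homRef, novel])
    score <- if (M >= 1) 10000 else -10 * log10(max(1 - M, 1e-300))
    if (score < minScore) next
    tumorG <- which.max(colSums(P))
    normalG <- which.max(rowSums(P))
    novelAlleles <- setdiff(c(sp$a1[tumorG], sp$a2[tumorG]), rc)
    if (!length(novelAlleles)) next
    a <- novelAlleles[1L]
    call <- somaticCallRow(a, r, rc, rowContig[r], rowPos[r], cn, ct,
                           bn, bt, bound, normalG, tumorG, score, seqs,
                           normal@contigs, sp)
    if (is.null(call)) next
    # artifact guards
    if (call$normalDepth < minNormalDepth ||
        call$tumorDepth < minTumorDepth) next
    if (call$normalAF >= maxNormalAF) next
    if (requireBothStrands && call$class == "SNV" &&
        (call$altFwd < 1L || call$altRev < 1L)) next
    call$altFwd <- NULL; call$altRev <- NULL
    rows[[length(rows) + 1L]] <- data.table::as.data.table(call)
  }
  if (!length(rows)) return(emptySet)
  calls <- data.table::rbindlist(rows)
  data.table::setorder(calls, contig, pos)
  calls[, filter := "PASS"]
  new("SomaticCallSet", calls = calls, contigs = refNames(ref))
}

somaticCallRow <- function(a, r, rc, ci, p, cn, ct, bn, bt, bound, normalG,
                           tumorG, score, seqs, contigs, sp) {
  baseChars <- c("A", "C", "G", "T")
  anchorBase <- substr(seqs[[ci]], p + 1L, p + 1L)
  if (a <= 3L) {
    cls <- "SNV"
    refStr <- baseChars[rc + 1L]
    altStr <- baseChars[a + 1L]
    nAltF <- cn[r, a + 1L]; nAltR <- cn[r, a + 5L]
    tAltF <- ct[r, a + 1L]; tAltR <- ct[r, a + 5L]
  } else {
    # allele identity lives on the shared binding
    evType <- if (a == 4L) bound$ev1type[r] else bound$ev2type[r]
    payload <- if (a == 4L) bound$ev1payload[r] else bound$ev2payload[r]
    if (evType == 0L || is.na(payload)) return(NULL)
    if (evType == 1L) {
      cls <- "INS"
      refStr <- anchorBase
      altStr <- paste0(anchorBase, payload)
    } else {
      cls <- "DEL"
      dl <- as.integer(payload)
      if (p + 1L + dl > nchar(seqs[[ci]])) return(NULL)
      refStr <- substr(seqs[[ci]], p + 1L, p + 1L + dl)
      altStr <- anchorBase
    }
    if (a == 4L) {
      nAltF <- bn$ev1fwd[r]; nAltR <- bn$ev1rev[r]
      tAltF <- bt$ev1fwd[r]; tAltR <- bt$ev1rev[r]
    } else {
      nAltF <- bn$ev2n[r]; nAltR <- 0L
      tAltF <- bt$ev2n[r]; tAltR <- 0L
    }
  }
  nDepth <- cn[r, 19L]; tDepth <- ct[r, 19L]
  list(contig = contigs[ci], pos = p, vcfPos = p + 1L, ref = refStr,
       alt = altStr, normalGt = GENOTYPE_LABELS[normalG],
       tumorGt = GENOTYPE_LABELS[tumorG],
       score = score, class = cls, normalDepth = as.integer(nDepth),
       tumorDepth = as.integer(tDepth),
       normalAltReads = as.integer(nAltF + nAltR),
       tumorAltReads = as.integer(tAltF + tAltR),
       normalAF = (nAltF + nAltR) / max(nDepth, 1L),
       tumorAF = (tAltF + tAltR) / max(tDepth, 1L),
       altFwd = as.integer(tAltF), altRev = as.integer(tAltR))
}
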