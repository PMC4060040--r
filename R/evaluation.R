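#' Compare calls against a planted truth set
#'
#' SNPs match on (contig, position, alt allele); indels match on the
#' left-normalized (anchor, type, payload) exactly. When an origin table is
#' supplied, truth is restricted to variants covered by at least one
#' simulated read and per-variant simulated depth (DP) is recorded for
#' stratification. Multi-allelic call records are decomposed into
#' per-allele records before matching.
#'
#' @param truth Truth table from \code{\link{plantVariants}} (or a
#'   compatible \code{data.table}).
#' @param calls A \linkS4class{VariantCallSet}.
#' @param ref The shared \linkS4class{Reference}.
#' @param origin Optional origin table from \code{\link{simulateReads}}.
#' @param dpBreaks,aafBreaks Stratification bin edges.
#' @return A comparison report: per-class TP/FP/FN, sensitivity, FDR,
#'   genotype concordance, and stratified tables.
#' @export
matchCalls <- function(truth, calls, ref, origin = NULL,
                       dpBreaks = c(0, 10, 20, 30, Inf),
                       aafBreaks = c(0, 0.2, 0.3, 0.4, 0.6, 1)) {
  tr <- data.table::copy(truth)
  seqs <- refSequences(ref)
  # (re-)normalize truth indels; planting already normalizes but external
  # truth tables may not be
  tr <- normalizeTruth(tr, seqs)
  cr <- decomposeCalls(calls, ref)
  # coverage restriction and per-variant DP
  if (!is.null(origin)) {
    tr[, dp := truthDepth(tr, origin)]
    tr <- tr[tr$dp >= 1L]
  } else tr[, dp := NA_integer_]
  tr[, key := variantKey(contig, pos, class, payload)]
  cr[, key := variantKey(contig, pos, class, payload)]
  tp <- cr$key %in% tr$key
  matched <- tr$key %in% cr$key
  perClass <- function(isSnpT, isSnpC) {
    TP <- sum(tp & isSnpC)
    FP <- sum(!tp & isSnpC)
    FN <- sum(!matched & isSnpT)
    list(tp = TP, fp = FP, fn = FN,
         sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
         fdr = if (TP + FP > 0) FP / (TP + FP) else NA_real_)
  }
  snp <- perClass(tr$class == "SNP", cr$class == "SNP")
  indel <- perClass(tr$class != "SNP", cr$class != "SNP")
  # genotype concordance among matched truth/call pairs
  m <- merge(tr[matched, c("key", "zygosity")],
             unique(cr[tp, c("key", "gt")], by = "key"), by = "key")
  conc <- if (nrow(m)) {
    expected <- data.table::fifelse(m$zygosity == "hom", "hom", "het")
    observed <- data.table::fifelse(grepl("0", m$gt), "het", "hom")
    mean(expected == observed)
  } else NA_real_
  byDepth <- if (!is.null(origin)) {
    tr[, dpBin := cut(dp, dpBreaks, right = FALSE)]
    tr[, .(n = .N, detected = sum(key %in% cr$key),
           sensitivity = mean(key %in% cr$key)), by = c("class", "dpBin")]
  } else data.table::data.table()
  crm <- cr[tp]
  byAAF <- if (nrow(crm)) {
    crm[, aafBin := cut(altFrac, aafBreaks, right = FALSE)]
    crm[, .(n = .N), by = c("class", "aafBin")]
  } else data.table::data.table()
  list(snp = snp, indel = indel, genotypeConcordance = conc,
       byDepth = byDepth, byAAF = byAAF,
       falsePositives = cr[!tp],
       falseNegatives = tr[!matched])
}

variantKey <- function(contig, pos, class, payload) {
  cls <- c(SNP = "S", SNV = "S", INS = "I", DEL = "D")[class]
  paste(contig, pos, cls, payload, sep = "|")
}

normalizeTruth <- function(tr, seqs) {
  isIndel <- tr$class %in% c("INS", "DEL")
  if (!any(isIndel)) return(tr)
  for (ci in unique(tr$contig[isIndel])) {
    sel <- which(isIndel & tr$contig == ci)
    nz <- cpp_normalize_indels(seqs[[ci]], tr$pos[sel],
                               ifelse(tr$class[sel] == "INS", "I", "D"),
                               tr$payload[sel])
    data.table::set(tr, sel, "pos", nz$anchor)
    data.table::set(tr, sel, "payload", as.character(nz$payload))
  }
  tr
}

# calls -> one row per (site, alt allele) with class/payload in truth terms
decomposeCalls <- function(calls, ref) {
  cl <- calls@calls
  seqs <- refSequences(ref)
  contigIdx <- match(cl$contig, refNames(ref))
  rows <- list()
  for (i in seq_len(nrow(cl))) {
    alts <- strsplit(cl$alt[i], ",", fixed = TRUE)[[1L]]
    for (a in alts) {
      d <- decomposeAllele(cl$pos[i], cl$ref[i], a)
      if (is.null(d)) next
      rows[[length(rows) + 1L]] <- data.table::data.table(
        contig = contigIdx[i], pos = d$pos, class = d$class,
        payload = d$payload, gt = cl$gt[i], qual = cl$qual[i],
        altFrac = cl$altFrac[i], depth = cl$depth[i],
        filter = cl$filter[i])
    }
  }
  if (!length(rows))
    return(data.table::data.table(contig = integer(0), pos = integer(0),
                                  class = character(0), payload = character(0),
                                  gt = character(0), qual = numeric(0),
                                  altFrac = numeric(0), depth = integer(0),
                                  filter = character(0)))
  cr <- data.table::rbindlist(rows)
  # normalize indel records
  isIndel <- cr$class %in% c("INS", "DEL")
  for (ci in unique(cr$contig[isIndel])) {
    sel <- which(isIndel & cr$contig == ci)
    nz <- cpp_normalize_indels(seqs[[ci]], cr$pos[sel],
                               ifelse(cr$class[sel] == "INS", "I", "D"),
                               cr$payload[sel])
    data.table::set(cr, sel, "pos", nz$anchor)
    data.table::set(cr, sel, "payload", as.character(nz$payload))
  }
  unique(cr, by = c("contig", "pos", "class", "payload"))
}

# trim shared suffix/prefix, classify as SNP/INS/DEL in anchor terms
decomposeAllele <- function(pos, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  if (ref == alt) return(NULL)
  if (nchar(ref) == 1L && nchar(alt) == 1L)
    return(list(pos = pos, class = "SNP", payload = alt))
  if (nchar(ref) == 1L && nchar(alt) > 1L &&
      substr(alt, 1L, 1L) == ref)
    return(list(pos = pos, class = "INS",
                payload = substr(alt, 2L, nchar(alt))))
  if (nchar(alt) == 1L && nchar(ref) > 1L &&
      substr(ref, 1L, 1L) == alt)
    return(list(pos = pos, class = "DEL",
                payload = as.character(nchar(ref) - 1L)))
  # complex substitution: report as SNP at the first differing base
  list(pos = pos, class = "SNP", payload = substr(alt, 1L, 1L))
}

# simulated read depth at each truth site (reads overlapping the position)
truthDepth <- function(tr, origin) {
  dp <- integer(nrow(tr))
  for (ci in unique(tr$contig)) {
    o <- origin[origin$contig == ci]
    starts <- sort(c(o$refStart1, o$refStart2))
    ends <- sort(c(o$refEnd1, o$refEnd2))
    sel <- which(tr$contig == ci)
    p <- tr$pos[sel]
    dp[sel] <- findInterval(p, starts) - findInterval(p, ends)
  }
  dp
}

#' Write a comparison report as JSON plus a readable table
#' @param report From \code{\link{matchCalls}}.
#' @param jsonPath,tsvPath Output paths (either may be NULL).
#' @export
writeComparisonReport <- function(report, jsonPath = NULL, tsvPath = NULL) {
  if (!is.null(jsonPath)) {
    jsonlite::write_json(list(snp = report$snp, indel = report$indel,
                              genotypeConcordance = report$genotypeConcordance),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsvPath)) {
    df <- data.frame(class = c("SNP", "indel"),
                     tp = c(report$snp$tp, report$indel$tp),
                     fp = c(report$snp$fp, report$indel$fp),
                     fn = c(report$snp$fn, report$indel$fn),
                     sensitivity = c(report$snp$sensitivity,
                                     report$indel$sensitivity),
                     fdr = c(report$snp$fdr, report$indel$fdr))
    utils::write.table(df, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(report)
}
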