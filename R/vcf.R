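#' Write germline calls to VCF
#'
#' Emits a VCFv4.2 file with contig, FILTER (PASS/LowQual/RF_FAIL/UNFILTERED)
#' and INFO/FORMAT definitions. Positions convert from the internal 0-based
#' convention to 1-based here and only here; indels are written
#' left-normalized with the anchor base shared between REF and ALT.
#'
#' @param calls A \linkS4class{VariantCallSet}.
#' @param ref Matching \linkS4class{Reference}.
#' @param path Output path.
#' @param sample Sample name for the genotype column.
#' @export
writeVcf <- function(calls, ref, path, sample = "SAMPLE") {
  cl <- calls@calls
  lens <- refLengths(ref)
  ord <- match(cl$contig, names(lens))
  if (any(is.na(ord))) stop("call on unknown contig")
  if (nrow(cl) > 1L && !identical(order(ord, cl$pos), seq_len(nrow(cl))))
    stop("calls must be sorted by (contig order, position)")
  if (any(grepl("N", cl$ref)) || any(grepl("N", cl$alt)))
    stop("allele containing N cannot be written")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=snapvar",
    sprintf("##contig=<ID=%s,length=%d>", names(lens), lens),
    "##FILTER=<ID=LowQual,Description=\"Classifier probability >= 0.95 but QUAL < 30\">",
    "##FILTER=<ID=RF_FAIL,Description=\"Classifier probability < 0.95\">",
    "##FILTER=<ID=UNFILTERED,Description=\"No classifier applied\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth at site\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternative allele fraction\">",
    "##INFO=<ID=SB,Number=1,Type=Float,Description=\"Phred-scaled strand bias\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mean mapping quality\">",
    "##INFO=<ID=RFP,Number=1,Type=Float,Description=\"Random forest probability\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    sprintf("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t%s",
            sample)), con)
  if (nrow(cl)) {
    info <- sprintf("DP=%d;AF=%.4g;SB=%.4g;MQ=%.4g", cl$depth, cl$altFrac,
                    cl$strandBias, cl$meanMQ)
    hasRf <- !is.na(cl$rfProb)
    info[hasRf] <- paste0(info[hasRf],
                          sprintf(";RFP=%.4g", cl$rfProb[hasRf]))
    lines <- sprintf("%s\t%d\t.\t%s\t%s\t%.6g\t%s\t%s\tGT:DP\t%s:%d",
                     cl$contig, cl$vcfPos, cl$ref, cl$alt, cl$qual,
                     cl$filter, info, cl$gt, cl$depth)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a VCF written by this package back into a call table
#'
#' A deliberately small reader used for snapshot/re-call identity checks and
#' the trio utility; columns map back to the internal 0-based convention.
#'
#' @param path VCF path.
#' @return \code{data.table} of calls.
#' @export
readVcfCalls <- function(path) {
  ln <- readLines(path)
  body <- ln[!startsWith(ln, "#")]
  if (!length(body))
    return(data.table::data.table(contig = character(0), vcfPos = integer(0),
                                  ref = character(0), alt = character(0),
                                  qual = numeric(0), filter = character(0),
                                  gt = character(0)))
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  gt <- sub(":.*$", "", sapply(strsplit(body, "\t"), `[`, 10L))
  data.table::data.table(contig = f[[1]], vcfPos = as.integer(f[[2]]),
                         ref = f[[4]], alt = f[[5]],
                         qual = as.numeric(f[[6]]), filter = f[[7]],
                         gt = gt)
}

#' Write somatic calls as a two-sample VCF
#'
#' NORMAL/TUMOR columns with GT, DP, AD and AF; INFO carries the SOMATIC
#' flag and SSC (phred somatic score).
#'
#' @param calls A \linkS4class{SomaticCallSet}.
#' @param ref Matching \linkS4class{Reference}.
#' @param path Output path.
#' @export
writeSomaticVcf <- function(calls, ref, path) {
  cl <- calls@calls
  lens <- refLengths(ref)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=snapvar-somatic",
    sprintf("##contig=<ID=%s,length=%d>", names(lens), lens),
    "##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description=\"Somatic event\">",
    "##INFO=<ID=SSC,Number=1,Type=Float,Description=\"Somatic score (phred)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=1,Type=Integer,Description=\"Alt-supporting reads\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Alt allele fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORMAL\tTUMOR"),
    con)
  if (nrow(cl)) {
    lines <- sprintf(
      "%s\t%d\t.\t%s\t%s\t%.6g\t%s\tSOMATIC;SSC=%.6g\tGT:DP:AD:AF\t%s:%d:%d:%.4g\t%s:%d:%d:%.4g",
      cl$contig, cl$vcfPos, cl$ref, cl$alt, cl$score, cl$filter, cl$score,
      cl$normalGt, cl$normalDepth, cl$normalAltReads, cl$normalAF,
      cl$tumorGt, cl$tumorDepth, cl$tumorAltReads, cl$tumorAF)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write truth variants as VCF
#'
#' Lets the simulator's planted truth be consumed by standard tooling.
#'
#' @param truth Truth table from \code{\link{plantVariants}}.
#' @param ref Matching \linkS4class{Reference}.
#' @param path Output path.
#' @export
writeTruthVcf <- function(truth, ref, path) {
  lens <- refLengths(ref)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=snapvar-truth",
    sprintf("##contig=<ID=%s,length=%d>", names(lens), lens),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTRUTH"), con)
  if (nrow(truth)) {
    gt <- ifelse(truth$zygosity == "hom", "1/1", "0/1")
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                       names(lens)[truth$contig], truth$vcfPos, truth$vcfRef,
                       truth$vcfAlt, gt), con)
  }
  invisible(path)
}
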