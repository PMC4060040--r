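#' Run the full germline pipeline
#'
#' Executes align -> mark duplicates -> base quality recalibration ->
#' indel realignment -> snapshot -> 16-genotype calling -> optional
#' random-forest filtration, entirely in memory. Individual stages can be
#' skipped; a run report records per-stage counts. With target regions the
#' snapshot and calling are restricted to them (exome mode).
#'
#' @param ref A \linkS4class{Reference} (or FASTA path).
#' @param pairs A \linkS4class{ReadPairSet}; alternatively give
#'   \code{fastq1}/\code{fastq2} paths or a \code{sam} path that bypasses
#'   the internal aligner.
#' @param fastq1,fastq2,sam Alternative inputs.
#' @param regions Target regions: a BED path or a region \code{data.table};
#'   NULL for whole-genome.
#' @param outputPrefix When given, \code{<prefix>.vcf} and
#'   \code{<prefix>.snapshot} are written.
#' @param k,maxOcc Seed index parameters.
#' @param insertMean,insertSd Insert model for pairing.
#' @param dedup,bqsr,realign Stage switches.
#' @param priors A \code{\link{priorModel}}.
#' @param rfModel Optional \code{RfFilterModel}; NULL leaves calls
#'   UNFILTERED.
#' @param sampleName VCF sample column name.
#' @return List: \code{calls}, \code{snapshot}, \code{alignments},
#'   \code{report}, and output paths when written.
#' @export
runGermline <- function(ref, pairs = NULL, fastq1 = NULL, fastq2 = NULL,
                        sam = NULL, regions = NULL, outputPrefix = NULL,
                        k = 16L, maxOcc = 64L, insertMean = 500,
                        insertSd = 25, dedup = TRUE, bqsr = TRUE,
                        realign = TRUE, priors = priorModel(),
                        rfModel = NULL, sampleName = "SAMPLE") {
  if (is.character(ref)) ref <- readReference(ref)
  report <- list()
  if (is.character(regions)) regions <- readBedRegions(regions, ref)
  if (!is.null(sam)) {
    aln <- readSamAlignments(sam, ref)
    report$input <- list(source = "sam", reads = length(aln))
  } else {
    if (is.null(pairs)) {
      if (is.null(fastq1) || is.null(fastq2))
        stop("provide pairs, fastq1+fastq2, or sam input")
      pairs <- readFastqPairs(fastq1, fastq2)
    }
    index <- buildSeedIndex(ref, k = k, maxOcc = maxOcc)
    aln <- alignReadPairs(pairs, index, insertMean = insertMean,
                          insertSd = insertSd)
    report$input <- list(source = "fastq", pairs = length(pairs))
    report$alignment <- list(
      reads = length(aln), mapped = sum(aln@data$mapped),
      properlyPaired = sum(aln@data$proper & aln@data$mapped))
  }
  if (dedup) {
    aln <- markDuplicates(aln)
    report$dedup <- attr(aln, "stats")
  } else report$dedup <- list(skipped = TRUE)
  if (bqsr) {
    mask <- candidateVariantMask(aln, ref)
    recal <- buildRecalTable(aln, ref, maskSites = mask)
    aln <- applyRecalibration(aln, recal)
    report$bqsr <- list(observations = recal@total,
                        cells = sum(recal@obs > 0))
  } else report$bqsr <- list(skipped = TRUE)
  if (realign) {
    hyp <- collectIndelHypotheses(aln, ref)
    aln <- realignReads(aln, ref, hyp)
    rr <- attr(aln, "report")
    report$realign <- list(
      hypotheses = nrow(hyp), windows = nrow(rr),
      readsRewritten = if (nrow(rr)) sum(rr$readsRewritten) else 0L)
  } else report$realign <- list(skipped = TRUE)
  snapshot <- buildSnapshot(aln, ref, regions = regions)
  report$snapshot <- list(positions = nrow(snapshot@counts),
                          events = nrow(snapshot@events))
  calls <- callVariants(snapshot, ref, priors = priors)
  if (!is.null(rfModel)) calls <- rfFilter(calls, rfModel)
  report$calls <- list(
    total = nrow(calls@calls), snp = sum(calls@calls$class == "SNP"),
    indel = sum(calls@calls$class %in% c("INS", "DEL", "MIXED")))
  out <- list(calls = calls, snapshot = snapshot, alignments = aln,
              report = report)
  if (!is.null(outputPrefix)) {
    out$vcf <- paste0(outputPrefix, ".vcf")
    out$snapshotPath <- paste0(outputPrefix, ".snapshot")
    writeVcf(calls, ref, out$vcf, sample = sampleName)
    writeSnapshot(snapshot, out$snapshotPath)
  }
  out
}

#' Re-call variants from a stored snapshot
#'
#' Calling and filtration only: with identical parameters the output VCF is
#' byte-identical to the one produced by the full run that wrote the
#' snapshot (the store carries all evidence the caller uses).
#'
#' @param snapshotPath Snapshot file.
#' @param ref The \linkS4class{Reference} (checksum-verified).
#' @param priors A \code{\link{priorModel}}.
#' @param rfModel Optional filter model.
#' @param outputVcf Optional VCF path.
#' @param sampleName VCF sample column name.
#' @return List: \code{calls} and \code{vcf} when written.
#' @export
runFromSnapshot <- function(snapshotPath, ref, priors = priorModel(),
                            rfModel = NULL, outputVcf = NULL,
                            sampleName = "SAMPLE") {
  if (is.character(ref)) ref <- readReference(ref)
  snapshot <- readSnapshot(snapshotPath, checksum = refChecksum(ref))
  calls <- callVariants(snapshot, ref, priors = priors)
  if (!is.null(rfModel)) calls <- rfFilter(calls, rfModel)
  out <- list(calls = calls)
  if (!is.null(outputVcf)) {
    writeVcf(calls, ref, outputVcf, sample = sampleName)
    out$vcf <- outputVcf
  }
  out
}

#' Run the somatic pipeline on a snapshot pair
#'
#' Somatic SNV/indel calling plus CNV segmentation, both operating directly
#' on the stored snapshots.
#'
#' @param normalSnapshot,tumorSnapshot \linkS4class{Snapshot} objects or
#'   snapshot file paths.
#' @param ref The shared \linkS4class{Reference}.
#' @param outputPrefix When given, \code{<prefix>.somatic.vcf},
#'   \code{<prefix>.cnv.bed} and \code{<prefix>.cnv.tsv} are written.
#' @param cnvWindow CNV window width (bp).
#' @param ... Passed to \code{\link{callSomatic}}.
#' @return List: \code{somatic}, \code{cnv}, \code{report}.
#' @export
runSomatic <- function(normalSnapshot, tumorSnapshot, ref,
                       outputPrefix = NULL, cnvWindow = 1000L, ...) {
  if (is.character(ref)) ref <- readReference(ref)
  if (is.character(normalSnapshot)) {
    if (!file.exists(normalSnapshot))
      stop("normal snapshot not found: ", normalSnapshot)
    normalSnapshot <- readSnapshot(normalSnapshot,
                                   checksum = refChecksum(ref))
  }
  if (is.character(tumorSnapshot)) {
    if (!file.exists(tumorSnapshot))
      stop("tumor snapshot not found: ", tumorSnapshot)
    tumorSnapshot <- readSnapshot(tumorSnapshot,
                                  checksum = refChecksum(ref))
  }
  somatic <- callSomatic(normalSnapshot, tumorSnapshot, ref, ...)
  cnv <- callCnv(normalSnapshot, tumorSnapshot, ref, window = cnvWindow)
  report <- list(
    somaticCalls = nrow(somatic@calls),
    byClass = if (nrow(somatic@calls))
      as.list(table(somatic@calls$class)) else list(),
    cnvSegments = nrow(cnv@segments),
    gains = sum(cnv@segments$state == "GAIN"),
    losses = sum(cnv@segments$state == "LOSS"))
  out <- list(somatic = somatic, cnv = cnv, report = report)
  if (!is.null(outputPrefix)) {
    out$vcf <- paste0(outputPrefix, ".somatic.vcf")
    writeSomaticVcf(somatic, ref, out$vcf)
    writeCnvSegments(cnv, bedPath = paste0(outputPrefix, ".cnv.bed"),
                     tsvPath = paste0(outputPrefix, ".cnv.tsv"))
  }
  out
}
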