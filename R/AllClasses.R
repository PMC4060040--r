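#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib snapvar, .registration = TRUE
NULL

#' Reference genome container
#'
#' Holds the contig sequences (uppercase A/C/G/T/N), their ordered names and
#' lengths, and a content checksum used to guard snapshot/reference pairing.
#'
#' @slot sequences A \link[Biostrings]{DNAStringSet}, one entry per contig.
#' @slot checksum Integer content hash of the sequences.
#' @export
setClass("Reference",
  representation(sequences = "ANY", checksum = "integer"),
  validity = function(object) {
    nm <- names(object@sequences)
    if (is.null(nm) || anyDuplicated(nm))
      return("contig names must be present and unique")
    if (any(lengths(object@sequences) == 0L))
      return("contig sequences must be non-empty")
    TRUE
  })

#' Paired-end read set
#'
#' Mate sequences and Phred+33 quality strings in sequencing orientation.
#' The two mates of a pair share one read name.
#'
#' @slot name Read names, one per pair.
#' @slot seq1,qual1,seq2,qual2 Per-mate sequence and quality strings.
#' @export
setClass("ReadPairSet",
  representation(name = "character", seq1 = "character",
                 qual1 = "character", seq2 = "character",
                 qual2 = "character"),
  validity = function(object) {
    n <- length(object@name)
    if (length(object@seq1) != n || length(object@seq2) != n ||
        length(object@qual1) != n || length(object@qual2) != n)
      return("all slots must have one entry per pair")
    if (any(nchar(object@seq1) != nchar(object@qual1)) ||
        any(nchar(object@seq2) != nchar(object@qual2)))
      return("sequence and quality lengths differ")
    TRUE
  })

#' Aligned reads
#'
#' Columnar store of read placements: 0-based start, strand, extended CIGAR
#' over \{=, X, I, D, S\} in reference orientation, mapping quality,
#' alignment score, pairing and duplicate flags. Sequences and qualities are
#' stored in reference orientation (reverse-complemented for minus-strand
#' placements).
#'
#' @slot data A \code{data.table} with one row per read.
#' @slot contigs Ordered contig names the integer contig column indexes.
#' @export
setClass("AlignedReads",
  representation(data = "ANY", contigs = "character"))

#' Base quality recalibration table
#'
#' Observation and mismatch counts per covariate cell (reported quality,
#' machine cycle in sequencing orientation, preceding+current dinucleotide),
#' with smoothed empirical qualities phred((mismatches+1)/(observations+2)).
#'
#' @slot obs,mism Integer arrays \code{61 x maxCycle x 17}.
#' @slot empirical Numeric array of smoothed empirical qualities.
#' @slot marginal Reported-quality-only fallback qualities (length 61).
#' @slot maxCycle Largest machine cycle tabulated.
#' @slot total Total observations.
#' @export
setClass("RecalTable",
  representation(obs = "array", mism = "array", empirical = "array",
                 marginal = "numeric", maxCycle = "integer",
                 total = "numeric"),
  validity = function(object) {
    if (any(object@mism > object@obs))
      return("mismatches exceed observations in some cell")
    TRUE
  })

#' Per-base pileup snapshot
#'
#' The per-position aggregate the callers work from: stranded base counts,
#' recalibrated-quality and mapping-quality sums, N/other and deletion-span
#' counts, depth, plus indel event tables (inserted sequence or deletion
#' length, stranded support, summed quality). One row per reference position
#' inside the declared regions; whole-genome mode declares every contig.
#'
#' @slot contigs,contigLengths Reference layout.
#' @slot regions \code{data.table} of declared 0-based half-open regions with
#'   their cumulative row offsets.
#' @slot counts Integer matrix \code{nRows x 19} (see
#'   \code{\link{snapshotColumn}} for the field layout).
#' @slot events \code{data.table} of indel events keyed by row.
#' @slot checksum Reference checksum the snapshot was built against.
#' @slot wholeGenome TRUE unless restricted to target regions.
#' @export
setClass("Snapshot",
  representation(contigs = "character", contigLengths = "integer",
                 regions = "ANY", counts = "matrix", events = "ANY",
                 checksum = "integer", wholeGenome = "logical"),
  validity = function(object) {
    if (ncol(object@counts) != 19L) return("counts must have 19 columns")
    nRows <- sum(object@regions$end - object@regions$start)
    if (nrow(object@counts) != nRows)
      return("counts rows must cover declared regions exactly once")
    TRUE
  })

#' Germline variant calls
#'
#' One row per emitted (non-hom-ref) site with alleles, genotype, QUAL
#' (phred of the hom-ref posterior mass, capped at 10000), depth, allele
#' fraction, strand bias, mean mapping quality and filter annotations.
#'
#' @slot calls \code{data.table} of calls, sorted by (contig, position).
#' @slot contigs Ordered contig names (defines the sort order).
#' @export
setClass("VariantCallSet",
  representation(calls = "ANY", contigs = "character"))

#' Somatic calls from a tumor-normal pair
#' @slot calls \code{data.table} with normal/tumor genotypes, somatic score
#'   (phred), per-sample allele fractions and filter status.
#' @slot contigs Ordered contig names.
#' @export
setClass("SomaticCallSet",
  representation(calls = "ANY", contigs = "character"))

#' Copy-number segments
#' @slot segments \code{data.table} of segments tiling the analyzed windows:
#'   contig, start, end, mean log2 depth ratio, state, window count.
#' @export
setClass("CnvSegments", representation(segments = "ANY"))

setMethod("show", "Reference", function(object) {
  cat("Reference with", length(object@sequences), "contig(s),",
      sum(lengths(object@sequences)), "bp total; checksum",
      object@checksum, "\n")
})

setMethod("show", "ReadPairSet", function(object) {
  cat("ReadPairSet with", length(object@name), "read pairs\n")
})

setMethod("show", "AlignedReads", function(object) {
  d <- object@data
  cat("AlignedReads:", nrow(d), "reads;", sum(d$mapped), "mapped;",
      sum(d$dup), "duplicate-flagged\n")
})

setMethod("show", "RecalTable", function(object) {
  cat("RecalTable:", format(object@total, big.mark = ","),
      "observations over", sum(object@obs > 0), "covariate cells\n")
})

setMethod("show", "Snapshot", function(object) {
  cat("Snapshot:", nrow(object@counts), "positions in",
      nrow(object@regions), "region(s);", nrow(object@events),
      "indel events;", if (object@wholeGenome) "whole-genome"
      else "target-restricted", "\n")
})

setMethod("show", "VariantCallSet", function(object) {
  cl <- object@calls
  cat("VariantCallSet:", nrow(cl), "calls (",
      sum(cl$class == "SNP"), "SNP,", sum(cl$class != "SNP"), "indel )\n")
})

setMethod("show", "SomaticCallSet", function(object) {
  cat("SomaticCallSet:", nrow(object@calls), "somatic calls\n")
})

setMethod("show", "CnvSegments", function(object) {
  s <- object@segments
  cat("CnvSegments:", nrow(s), "segments (",
      sum(s$state == "GAIN"), "GAIN,", sum(s$state == "LOSS"), "LOSS )\n")
})

#' @export
setMethod("length", "ReadPairSet", function(x) length(x@name))

#' @export
setMethod("length", "AlignedReads", function(x) nrow(x@data))
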