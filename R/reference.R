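#' Load a reference genome from FASTA
#'
#' Reads all records, folds lowercase to uppercase and any non-ACGTN IUPAC
#' letter to N. Internal coordinates throughout the package are 0-based
#' half-open; conversion to 1-based happens only at the SAM/VCF text
#' boundary.
#'
#' @param path Path to a FASTA file.
#' @return A \linkS4class{Reference}.
#' @export
readReference <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop("FASTA parse error in '", path,
                                            "': ", conditionMessage(e)))
  if (length(seqs) == 0L) stop("FASTA parse error: no records in ", path)
  if (anyDuplicated(names(seqs)))
    stop("duplicate contig name(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  # header lines may carry descriptions after the first token
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) stop("duplicate contig name after header trim")
  chars <- as.character(seqs)
  chars <- toupper(chars)
  chars <- gsub("[^ACGTN]", "N", chars)
  newReference(chars, names(seqs))
}

#' Construct a Reference from character sequences
#' @param seqs Character vector of contig sequences.
#' @param names Contig names.
#' @return A \linkS4class{Reference}.
#' @export
newReference <- function(seqs, names) {
  seqs <- toupper(seqs)
  stopifnot(length(seqs) == length(names))
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- names
  new("Reference", sequences = dss,
      checksum = cpp_fnv(as.character(seqs)))
}

#' Contig names of a reference
#' @param ref A \linkS4class{Reference}.
#' @export
refNames <- function(ref) names(ref@sequences)

#' Contig lengths of a reference
#' @param ref A \linkS4class{Reference}.
#' @export
refLengths <- function(ref) {
  stats::setNames(Biostrings::width(ref@sequences), refNames(ref))
}

#' Contig sequences as plain character strings
#' @param ref A \linkS4class{Reference}.
#' @export
refSequences <- function(ref) {
  stats::setNames(as.character(ref@sequences), refNames(ref))
}

#' Reference content checksum
#' @param ref A \linkS4class{Reference}.
#' @export
refChecksum <- function(ref) ref@checksum

#' Write a reference to FASTA
#' @param ref A \linkS4class{Reference}.
#' @param path Output path.
#' @export
writeReferenceFasta <- function(ref, path) {
  Biostrings::writeXStringSet(ref@sequences, path)
  invisible(path)
}

# resolve a contig name or index to an index, with validation
contigIndex <- function(ref, contig) {
  if (is.character(contig)) {
    i <- match(contig, refNames(ref))
    if (any(is.na(i))) stop("unknown contig: ",
                            paste(contig[is.na(i)], collapse = ", "))
    i
  } else as.integer(contig)
}

#' Read 3-column BED target regions
#'
#' BED is 0-based half-open, matching the package's internal convention.
#' Intervals are validated against the reference, sorted and merged.
#'
#' @param path BED file path.
#' @param ref A \linkS4class{Reference}.
#' @return \code{data.table} with columns contig (index), start, end.
#' @export
readBedRegions <- function(path, ref) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED must have at least 3 columns")
  rg <- data.table::data.table(contig = contigIndex(ref, bed[[1L]]),
                               start = as.integer(bed[[2L]]),
                               end = as.integer(bed[[3L]]))
  normalizeRegions(rg, ref)
}

# sort, bound-check and merge overlapping regions; assign row offsets
normalizeRegions <- function(rg, ref) {
  lens <- refLengths(ref)
  if (any(rg$start < 0L) || any(rg$end > lens[rg$contig]) ||
      any(rg$start >= rg$end))
    stop("region out of bounds: need 0 <= start < end <= contig length")
  data.table::setorder(rg, contig, start)
  merged <- rg[, {
    s <- start; e <- end
    ks <- integer(0); ke <- integer(0)
    cs <- s[1L]; ce <- e[1L]
    if (length(s) > 1L) for (i in 2L:length(s)) {
      if (s[i] <= ce) ce <- max(ce, e[i])
      else { ks <- c(ks, cs); ke <- c(ke, ce); cs <- s[i]; ce <- e[i] }
    }
    list(start = c(ks, cs), end = c(ke, ce))
  }, by = "contig"]
  merged$rowStart <- cumsum(c(0L, head(merged$end - merged$start, -1L)))
  merged
}

# whole-genome region set
wholeGenomeRegions <- function(ref) {
  lens <- refLengths(ref)
  data.table::data.table(contig = seq_along(lens), start = 0L,
                         end = as.integer(lens),
                         rowStart = cumsum(c(0L, head(as.integer(lens), -1L))))
}

# row index of (contig index, 0-based pos) in a region table; NA if outside
regionRowOf <- function(regions, contig, pos) {
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(regions))) {
    hit <- contig == regions$contig[i] & pos >= regions$start[i] &
      pos < regions$end[i]
    out[hit] <- regions$rowStart[i] + (pos[hit] - regions$start[i])
  }
  out
}
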