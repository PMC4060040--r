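#' Read paired FASTQ files
#'
#' Decodes Phred+33 qualities. Mate names must agree after stripping a
#' trailing \code{/1} or \code{/2}; Phred+64 input (no quality character
#' below ';' and some above 'J') is rejected with a clear error rather than
#' silently mis-decoded.
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2.
#' @return A \linkS4class{ReadPairSet}.
#' @export
readFastqPairs <- function(path1, path2) {
  r1 <- readFastqOne(path1)
  r2 <- readFastqOne(path2)
  if (length(r1$name) != length(r2$name))
    stop("pairing error: ", length(r1$name), " records in ", path1, " vs ",
         length(r2$name), " in ", path2)
  n1 <- sub("/[12]$", "", r1$name)
  n2 <- sub("/[12]$", "", r2$name)
  bad <- which(n1 != n2)
  if (length(bad))
    stop("read name mismatch at record ", bad[1L], ": '", n1[bad[1L]],
         "' vs '", n2[bad[1L]], "'")
  new("ReadPairSet", name = n1, seq1 = r1$seq, qual1 = r1$qual,
      seq2 = r2$seq, qual2 = r2$qual)
}

readFastqOne <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  qual <- unname(as.character(S4Vectors::mcols(x)$qualities))
  # Phred+64 guard: +64 files sit entirely at or above '@' (64) and reach
  # characters no +33 file can ('_' and beyond for Q >= 62)
  qcat <- paste(utils::head(qual, 200L), collapse = "")
  if (nchar(qcat) > 0L) {
    codes <- utf8ToInt(qcat)
    if (min(codes) >= 64L && max(codes) >= 95L)
      stop("qualities look Phred+64 encoded; only Phred+33 is supported")
  }
  list(name = unname(sub("\\s.*$", "", names(x))),
       seq = unname(as.character(x)), qual = qual)
}

#' Write paired FASTQ files
#' @param pairs A \linkS4class{ReadPairSet}.
#' @param path1,path2 Output FASTQ paths.
#' @export
writeFastqPairs <- function(pairs, path1, path2) {
  writeFastqOne(paste0(pairs@name, "/1"), pairs@seq1, pairs@qual1, path1)
  writeFastqOne(paste0(pairs@name, "/2"), pairs@seq2, pairs@qual2, path2)
  invisible(c(path1, path2))
}

writeFastqOne <- function(name, seq, qual, path) {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- name
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
}

#' Decode a Phred+33 quality string to integer scores
#' @param qual Quality strings.
#' @return List of integer vectors.
#' @export
phredDecode <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Encode integer Phred scores to a +33 string
#' @param q Integer vector of scores.
#' @export
phredEncode <- function(q) {
  intToUtf8(pmin(pmax(q, 0L), 60L) + 33L)
}
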