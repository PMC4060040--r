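#' Count Mendelian SNP conflicts in a trio
#'
#' A conflict is a PASS SNP called in the child whose genotype cannot be
#' composed from one allele of each parent; sites absent from a parent's
#' call set are treated as homozygous reference. Calls must share one
#' reference.
#'
#' @param child,father,mother \linkS4class{VariantCallSet}s.
#' @param passOnly Restrict the child set to PASS (and UNFILTERED) SNPs.
#' @return List: \code{conflicts}, \code{checked}, \code{rate}, and the
#'   per-site conflict table.
#' @export
trioConflicts <- function(child, father, mother, passOnly = TRUE) {
  if (!identical(child@contigs, father@contigs) ||
      !identical(child@contigs, mother@contigs))
    stop("call sets come from different references")
  cc <- child@calls[child@calls$class == "SNP"]
  if (passOnly) cc <- cc[cc$filter %in% c("PASS", "UNFILTERED")]
  if (nrow(cc) == 0L)
    return(list(conflicts = 0L, checked = 0L, rate = NA_real_,
                table = data.table::data.table()))
  lookupTable <- function(calls) {
    s <- calls@calls[calls@calls$class == "SNP",
                     c("contig", "pos", "ref", "alt", "gt")]
    data.table::setkeyv(s, c("contig", "pos"))
    s
  }
  fat <- lookupTable(father)
  mot <- lookupTable(mother)
  getAlleles <- function(tab, ctg, p) {
    i <- tab[.(ctg, p), which = TRUE][1L]
    if (is.na(i)) return(NULL)                  # treated as hom-ref later
    splitGtAlleles(tab$ref[i], tab$alt[i], tab$gt[i])
  }
  conflict <- logical(nrow(cc))
  for (i in seq_len(nrow(cc))) {
    childAl <- splitGtAlleles(cc$ref[i], cc$alt[i], cc$gt[i])
    refAl <- substr(cc$ref[i], 1L, 1L)
    fa <- getAlleles(fat, cc$contig[i], cc$pos[i])
    mo <- getAlleles(mot, cc$contig[i], cc$pos[i])
    if (is.null(fa)) fa <- c(refAl, refAl)
    if (is.null(mo)) mo <- c(refAl, refAl)
    ok <- FALSE
    for (a in fa) for (b in mo)
      if (setequal(c(a, b), childAl) ||
          (childAl[1L] == childAl[2L] && a == childAl[1L] &&
           b == childAl[1L]))
        ok <- TRUE
    conflict[i] <- !ok
  }
  tab <- cc[, c("contig", "pos", "ref", "alt", "gt")]
  tab[, conflict := conflict]
  list(conflicts = sum(conflict), checked = nrow(cc),
       rate = sum(conflict) / nrow(cc), table = tab[])
}

# genotype string + alleles -> the two allele strings
splitGtAlleles <- function(ref, alt, gt) {
  alleles <- c(substr(ref, 1L, 1L), strsplit(alt, ",", fixed = TRUE)[[1L]])
  # compare SNP alleles at the site scale: use first base of each allele
  alleles <- substr(alleles, 1L, 1L)
  idx <- as.integer(strsplit(gt, "/", fixed = TRUE)[[1L]]) + 1L
  alleles[idx]
}

#' Write a trio conflict report to TSV
#' @param result From \code{\link{trioConflicts}}.
#' @param path Output path.
#' @export
writeTrioReport <- function(result, path) {
  utils::write.table(result$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
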