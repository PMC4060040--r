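RF_FEATURES <- c("qual", "depth", "altFrac", "strandBias", "meanMQ",
                 "meanAltQ", "homopolLen", "distNearest", "isIndel",
                 "indelLen")

#' Feature matrix for random-forest call filtration
#'
#' QUAL, depth, alt allele fraction, strand-bias score, mean mapping
#' quality, mean alt base quality, homopolymer run length at the site,
#' distance to the nearest other candidate, indel flag and indel length.
#'
#' @param calls A \linkS4class{VariantCallSet}.
#' @return \code{data.frame} of features, one row per call.
#' @export
rfFeatures <- function(calls) {
  cl <- calls@calls
  data.frame(qual = pmin(cl$qual, 10000), depth = cl$depth,
             altFrac = cl$altFrac, strandBias = cl$strandBias,
             meanMQ = cl$meanMQ, meanAltQ = cl$meanAltQ,
             homopolLen = cl$homopolLen,
             distNearest = pmin(cl$distNearest, 1e6),
             isIndel = as.integer(cl$class %in% c("INS", "DEL", "MIXED")),
             indelLen = cl$indelLen)
}

#' Train the random-forest call classifier
#'
#' A 200-tree seeded random forest over \code{\link{rfFeatures}}. Labels
#' come from simulator truth: planted variants are positives, unfiltered
#' caller output absent from the truth are negatives.
#'
#' @param calls A \linkS4class{VariantCallSet} of labeled calls.
#' @param labels Logical vector: TRUE for true variants.
#' @param ntree Number of trees.
#' @param seed RNG seed (the model is a pure function of data + seed).
#' @return Model object with the feature schema, version and out-of-bag
#'   accuracy attached.
#' @export
trainRfFilter <- function(calls, labels, ntree = 200L, seed = 99L) {
  x <- rfFeatures(calls)
  y <- factor(labels, levels = c(FALSE, TRUE))
  if (length(unique(y[!is.na(y)])) < 2L)
    stop("training requires both true and artifact calls")
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = y, ntree = ntree)
  oob <- sum(diag(fit$confusion[, 1:2])) / length(y)
  structure(list(fit = fit, features = RF_FEATURES, version = 1L,
                 oobAccuracy = oob, ntree = ntree, seed = seed),
            class = "RfFilterModel")
}

#' @export
print.RfFilterModel <- function(x, ...) {
  cat("RfFilterModel:", x$ntree, "trees; OOB accuracy",
      sprintf("%.4f", x$oobAccuracy), "\n")
  invisible(x)
}

#' Apply random-forest filtration to calls
#'
#' Filter semantics: PASS iff classifier probability >= \code{minProb} and
#' QUAL >= \code{minQual}; LowQual iff probability >= \code{minProb} but
#' QUAL < \code{minQual}; RF_FAIL otherwise. With no model every call is
#' passed through flagged UNFILTERED.
#'
#' @param calls A \linkS4class{VariantCallSet}.
#' @param model From \code{\link{trainRfFilter}}, or NULL.
#' @param minProb Probability threshold (default 0.95).
#' @param minQual QUAL threshold separating PASS from LowQual (default 30).
#' @return The call set with filter status and probability filled in.
#' @export
rfFilter <- function(calls, model, minProb = 0.95, minQual = 30) {
  cl <- data.table::copy(calls@calls)
  if (is.null(model)) {
    cl[, filter := "UNFILTERED"]
    return(new("VariantCallSet", calls = cl, contigs = calls@contigs))
  }
  if (!inherits(model, "RfFilterModel") ||
      !identical(model$features, RF_FEATURES))
    stop("model feature schema does not match this package version")
  if (nrow(cl)) {
    x <- rfFeatures(calls)
    prob <- stats::predict(model$fit, x, type = "prob")[, "TRUE"]
    cl[, rfProb := prob]
    cl[, filter := rfFilterStatus(rfProb, qual, minProb, minQual)]
  }
  new("VariantCallSet", calls = cl, contigs = calls@contigs)
}

#' Filter status rule
#'
#' PASS iff probability >= minProb and QUAL >= minQual; LowQual iff
#' probability >= minProb but QUAL < minQual; RF_FAIL otherwise.
#'
#' @param prob Classifier probabilities.
#' @param qual Call QUALs.
#' @param minProb,minQual Thresholds.
#' @return Character vector of filter statuses.
#' @export
rfFilterStatus <- function(prob, qual, minProb = 0.95, minQual = 30) {
  data.table::fifelse(prob >= minProb & qual >= minQual, "PASS",
                      data.table::fifelse(prob >= minProb, "LowQual",
                                          "RF_FAIL"))
}

#' Save / load a filter model with its schema
#' @param model An \code{RfFilterModel}.
#' @param path Destination file.
#' @export
saveRfFilter <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveRfFilter
#' @export
loadRfFilter <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "RfFilterModel") || model$version != 1L)
    stop("not a compatible filter model file")
  model
}
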