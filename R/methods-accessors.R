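#' @rdname ExpressionMatrix-class
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x@values))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("cellIds", "ExpressionMatrix", function(x) colnames(x@values))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

#' @rdname ExpressionMatrix-class
#' @export
setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

#' @rdname ExpressionMatrix-class
#' @param i gene (row) index or identifier vector.
#' @param j cell (column) index or identifier vector.
#' @param ... ignored.
#' @param drop ignored; subsetting always returns an ExpressionMatrix.
#' @export
setMethod("[", "ExpressionMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  ExpressionMatrix(v)
})

setMethod("show", "ExpressionMatrix", function(object) {
  d <- dim(object@values)
  cat(sprintf("ExpressionMatrix: %d genes x %d cells\n", d[1L], d[2L]))
  cat(sprintf("  genes: %s%s\n",
              paste(utils::head(geneIds(object), 4L), collapse = ", "),
              if (d[1L] > 4L) ", ..." else ""))
  cat(sprintf("  zero fraction: %.3f\n", mean(object@values == 0)))
})

#' @rdname PriorNetwork-class
#' @export
setMethod("genes", "PriorNetwork", function(x) x@genes)

#' @rdname PriorNetwork-class
#' @export
setMethod("edges", "PriorNetwork", function(x) x@edges)

#' @rdname PriorNetwork-class
#' @export
setMethod("tfSet", "PriorNetwork", function(x) x@tfSet)

#' @rdname PriorNetwork-class
#'
#' @details `networkDensity()` returns the fraction of possible directed
#' TF-to-target pairs that are observed edges,
#' |edges| / (|TFs| * (|genes| - 1)).
#' @export
setMethod("networkDensity", "PriorNetwork", function(x) {
  nrow(x@edges) / (length(x@tfSet) * (length(x@genes) - 1L))
})

setMethod("show", "PriorNetwork", function(object) {
  cat(sprintf("PriorNetwork: %d genes, %d TFs, %d directed edges (density %.4f)\n",
              length(object@genes), length(object@tfSet), nrow(object@edges),
              networkDensity(object)))
})

#' @rdname GeneSelection-class
#' @param object a GeneSelection.
setMethod("show", "GeneSelection", function(object) {
  cat(sprintf("GeneSelection: %d genes screened\n", length(object@geneIds)))
  cat(sprintf("  variance range: [%.4g, %.4g]\n",
              min(object@variance), max(object@variance)))
})

#' Sizes of the six edge-split compartments
#'
#' @param split an [EdgeSplit-class].
#' @return Named integer vector with the train/validation/test positive and
#'   negative counts.
#' @export
splitSizes <- function(split) {
  stopifnot(is(split, "EdgeSplit"))
  c(trainPos = nrow(split@trainPos), valPos = nrow(split@valPos),
    testPos = nrow(split@testPos), trainNeg = nrow(split@trainNeg),
    valNeg = nrow(split@valNeg), testNeg = nrow(split@testNeg))
}

setMethod("show", "EdgeSplit", function(object) {
  s <- splitSizes(object)
  cat("EdgeSplit (seed ", object@seed, ")\n", sep = "")
  cat(sprintf("  positives train/val/test: %d/%d/%d\n", s[1L], s[2L], s[3L]))
  cat(sprintf("  negatives train/val/test: %d/%d/%d\n", s[4L], s[5L], s[6L]))
})

setMethod("show", "GCNModel", function(object) {
  dims <- c(nrow(object@weights[[1L]]),
            vapply(object@weights, ncol, integer(1L)))
  cat(sprintf("GCNModel: %d layer(s), dims %s, lambda %.2f\n",
              length(object@weights), paste(dims, collapse = " -> "),
              object@lambdaMix))
})
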