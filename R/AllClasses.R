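#' @import methods
NULL

#' ExpressionMatrix: a gene-by-cell expression matrix
#'
#' Container for single-cell expression values with gene identifiers as rows
#' and cell identifiers as columns. Values are nonnegative: raw counts or
#' TPM before preprocessing, log-units after [logNormalize()].
#'
#' @slot values numeric matrix, genes in rows, cells in columns; dimnames
#'   carry the gene and cell identifiers.
#'
#' @seealso [readExpression()], [logNormalize()], [filterLowExpression()]
#' @export
setClass("ExpressionMatrix", representation(values = "matrix"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (nrow(v) < 1L || ncol(v) < 1L)
    msg <- c(msg, "need at least one gene and one cell")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "gene and cell identifiers (dimnames) are required")
  if (anyDuplicated(rownames(v)))
    msg <- c(msg, sprintf("duplicate gene identifier: %s",
                          rownames(v)[duplicated(rownames(v))][1L]))
  if (anyDuplicated(colnames(v)))
    msg <- c(msg, sprintf("duplicate cell identifier: %s",
                          colnames(v)[duplicated(colnames(v))][1L]))
  if (is.numeric(v)) {
    if (any(!is.finite(v))) msg <- c(msg, "all values must be finite")
    else if (any(v < 0)) msg <- c(msg, "expression values must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix with genes as rows and cells as columns.
#' @param geneIds,cellIds optional identifier vectors; defaults to the
#'   dimnames of `values`.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(0:5, nrow = 3, dimnames = list(paste0("G", 1:3), c("c1", "c2")))
#' ExpressionMatrix(m)
#' @export
ExpressionMatrix <- function(values, geneIds = rownames(values),
                             cellIds = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(as.character(geneIds), as.character(cellIds))
  new("ExpressionMatrix", values = values)
}

#' PriorNetwork: a directed TF-to-target edge set over a gene universe
#'
#' Holds the node set (genes), a deduplicated directed edge set, and the
#' subset of genes allowed to act as regulators (transcription factors).
#' Self-edges are never stored: the encoder adds its own self-loops, so
#' input self-edges would be double counted.
#'
#' @slot genes character vector, ordered unique gene identifiers (node set).
#' @slot edges data.frame with character columns `from`, `to`; directed
#'   TF-to-target pairs, no duplicates, no self-edges, endpoints in `genes`.
#' @slot tfSet character vector, subset of `genes` that may be edge sources.
#'
#' @seealso [readNetwork()], [simulateGRN()]
#' @export
setClass("PriorNetwork",
         representation(genes = "character", edges = "data.frame",
                        tfSet = "character"))

setValidity("PriorNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (!identical(colnames(e), c("from", "to")))
    msg <- c(msg, "edges must have columns 'from' and 'to'")
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate gene identifiers")
  if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self-edges are not allowed")
    if (!all(c(e$from, e$to) %in% object@genes))
      msg <- c(msg, "edge endpoints must be in the gene set")
    if (anyDuplicated(.edgeKey(e$from, e$to))) msg <- c(msg, "duplicate edges")
    if (!all(e$from %in% object@tfSet))
      msg <- c(msg, "every edge source must be in the TF set")
  }
  if (!all(object@tfSet %in% object@genes))
    msg <- c(msg, "TF set must be a subset of the gene set")
  if (length(msg)) msg else TRUE
})

#' Construct a PriorNetwork
#'
#' Edges are deduplicated; self-edges are dropped (with a message giving the
#' count). When `tfSet` is omitted it defaults to the set of edge sources.
#'
#' @param edges data.frame (or two-column matrix) of directed pairs, source
#'   then target.
#' @param genes gene universe; defaults to all endpoints.
#' @param tfSet regulator subset; defaults to observed edge sources.
#' @return A [PriorNetwork-class] object.
#' @examples
#' PriorNetwork(data.frame(from = c("A", "A"), to = c("B", "C")))
#' @export
PriorNetwork <- function(edges, genes = NULL, tfSet = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  colnames(edges) <- c("from", "to")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  nSelf <- sum(edges$from == edges$to)
  if (nSelf > 0L) {
    message(nSelf, " self-edge(s) dropped")
    edges <- edges[edges$from != edges$to, , drop = FALSE]
  }
  edges <- edges[!duplicated(.edgeKey(edges$from, edges$to)), , drop = FALSE]
  rownames(edges) <- NULL
  if (is.null(genes)) genes <- unique(c(edges$from, edges$to))
  if (is.null(tfSet)) tfSet <- unique(edges$from)
  new("PriorNetwork", genes = as.character(genes), edges = edges,
      tfSet = as.character(tfSet))
}

#' GeneSelection: per-gene variance statistics and selection parameters
#'
#' Result of the highly-variable-gene screen: each gene's sample variance and
#' the upper-tail chi-square dispersion p-value of that variance against the
#' dataset median variance.
#'
#' @slot geneIds character, genes the statistics refer to (order preserved).
#' @slot variance numeric, per-gene sample variance (denominator M-1).
#' @slot pValue numeric in \[0, 1\], per-gene dispersion p-value.
#' @slot params list with elements `minCellFraction`, `alpha`, `topK` as
#'   recorded by the pipeline steps that used this selection.
#'
#' @seealso [varianceSignificance()], [selectGenes()]
#' @export
setClass("GeneSelection",
         representation(geneIds = "character", variance = "numeric",
                        pValue = "numeric", params = "list"))

setValidity("GeneSelection", function(object) {
  msg <- character()
  n <- length(object@geneIds)
  if (length(object@variance) != n || length(object@pValue) != n)
    msg <- c(msg, "geneIds, variance and pValue lengths must match")
  if (any(object@variance < 0)) msg <- c(msg, "variances must be >= 0")
  if (any(object@pValue < 0 | object@pValue > 1))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' EdgeSplit: labeled positive/negative pairs in train/validation/test sets
#'
#' The positive sets partition the known edges 3:1:1 (train first on
#' remainders); negative sets are disjoint from all positives and from each
#' other, and every negative pair has a TF source.
#'
#' @slot trainPos,valPos,testPos data.frames (`from`, `to`) of label-1 pairs.
#' @slot trainNeg,valNeg,testNeg data.frames (`from`, `to`) of label-0 pairs.
#' @slot seed integer seed the split was drawn with.
#'
#' @seealso [makeEdgeSplit()], [splitPositives()]
#' @export
setClass("EdgeSplit",
         representation(trainPos = "data.frame", valPos = "data.frame",
                        testPos = "data.frame", trainNeg = "data.frame",
                        valNeg = "data.frame", testNeg = "data.frame",
                        seed = "integer"))

setValidity("EdgeSplit", function(object) {
  msg <- character()
  keys <- lapply(list(object@trainPos, object@valPos, object@testPos,
                      object@trainNeg, object@valNeg, object@testNeg),
                 function(d) .edgeKey(d$from, d$to))
  pos <- unlist(keys[1:3]); neg <- unlist(keys[4:6])
  if (anyDuplicated(pos)) msg <- c(msg, "positive sets must be disjoint")
  if (anyDuplicated(neg)) msg <- c(msg, "negative sets must be disjoint")
  if (length(intersect(pos, neg)))
    msg <- c(msg, "negatives must not appear among positives")
  if (length(msg)) msg else TRUE
})

#' GCNModel: parameters of the graph convolutional encoder
#'
#' Per-layer weight matrices and bias vectors of the encoder, plus the mixing
#' coefficient `lambdaMix` that blends the normalized prior-network adjacency
#' with the identity (1 = pure prior-network propagation, 0 = expression
#' features only).
#'
#' @slot weights list of numeric matrices; `weights[[l]]` has shape
#'   d_\{l-1\} x d_l with d_0 = number of cells (input feature dimension).
#' @slot biases list of numeric vectors, `biases[[l]]` of length d_l.
#' @slot lambdaMix numeric in \[0, 1\].
#'
#' @seealso [initGCNModel()], [gcnEncode()], [trainGCN()]
#' @export
setClass("GCNModel",
         representation(weights = "list", biases = "list",
                        lambdaMix = "numeric"))

setValidity("GCNModel", function(object) {
  msg <- character()
  L <- length(object@weights)
  if (L < 1L) msg <- c(msg, "at least one layer is required")
  if (length(object@biases) != L)
    msg <- c(msg, "weights and biases must have the same layer count")
  for (l in seq_len(L)) {
    W <- object@weights[[l]]
    if (!all(is.finite(W)) || !all(is.finite(object@biases[[l]])))
      msg <- c(msg, sprintf("non-finite parameters in layer %d", l))
    if (length(object@biases[[l]]) != ncol(W))
      msg <- c(msg, sprintf("bias length mismatch in layer %d", l))
    if (l > 1L && nrow(W) != ncol(object@weights[[l - 1L]]))
      msg <- c(msg, sprintf("weight shape chain broken at layer %d", l))
  }
  if (object@lambdaMix < 0 || object@lambdaMix > 1)
    msg <- c(msg, "lambdaMix must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
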