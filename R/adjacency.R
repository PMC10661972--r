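#' Build the symmetrically normalized message-passing adjacency
#'
#' Constructs the operator the graph convolutional encoder propagates
#' features with. The chosen edge subset (typically the training positives,
#' so that held-out labels never leak into the features) is symmetrized —
#' A_ij = A_ji = 1 if either direction is present — self-loops are added on
#' every node, and the result is normalized as D^(-1/2) A D^(-1/2) with
#' D_ii the row sums of A. Entries are A_ij / sqrt(d_i d_j); the spectral
#' radius of the result is at most 1. Isolated nodes get a pure self-loop
#' row.
#'
#' @param net a [PriorNetwork-class] (source of the node universe check).
#' @param nodes ordered character vector of node identifiers; must contain
#'   every endpoint of `edgeSubset`. This fixes the row/column order, which
#'   must match the expression matrix used for encoding.
#' @param edgeSubset data.frame (`from`, `to`) of edges to build the graph
#'   from; defaults to all edges of `net`.
#' @return A dense numeric `length(nodes)` x `length(nodes)` matrix with
#'   dimnames `nodes`.
#' @export
buildNormalizedAdjacency <- function(net, nodes = genes(net),
                                     edgeSubset = edges(net)) {
  stopifnot(is(net, "PriorNetwork"))
  edgeSubset <- as.data.frame(edgeSubset, stringsAsFactors = FALSE)
  if (nrow(edgeSubset)) {
    if (!all(.edgeKey(edgeSubset$from, edgeSubset$to) %in%
             .edgeKey(edges(net)$from, edges(net)$to)))
      .stopf("edgeSubset must be a subset of the network's edges")
    if (!all(c(edgeSubset$from, edgeSubset$to) %in% nodes))
      .stopf("every edge endpoint must be in `nodes`")
  }
  n <- length(nodes)
  A <- diag(1, n)
  dimnames(A) <- list(nodes, nodes)
  if (nrow(edgeSubset)) {
    i <- match(edgeSubset$from, nodes)
    j <- match(edgeSubset$to, nodes)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  d <- rowSums(A)
  A / sqrt(outer(d, d))
}
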