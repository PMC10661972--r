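#' Initialize a graph convolutional encoder
#'
#' Glorot-uniform initialization: each weight matrix W (fanIn x fanOut) is
#' drawn from U(-a, a) with a = sqrt(6 / (fanIn + fanOut)); biases start at
#' zero. The final layer is additionally scaled by `outputScale` so that the
#' decoder's initial dot-product scores sit below the 0/1 label scale:
#' with unscaled Glorot weights and nonnegative expression features the
#' initial scores are O(10^3), the first mean-squared-error steps then
#' drive every rectified unit to zero and training stalls permanently
#' (the ReLU subgradient at 0 is 0). Deterministic given the seed.
#'
#' @param inputDim input feature dimension d_0 (number of cells after
#'   preprocessing).
#' @param hiddenDims integer vector of layer output dimensions; the default
#'   `c(256, 128)` gives a two-layer encoder with a 128-dimensional final
#'   gene embedding.
#' @param lambdaMix mixing coefficient in \[0, 1\] between the normalized
#'   prior-network adjacency (1) and the identity (0); default 0.4.
#' @param seed integer seed for the weight draw.
#' @param outputScale multiplier on the final layer's initial weights
#'   (default 1; reduce if training with unnormalized features).
#' @return A [GCNModel-class].
#' @export
initGCNModel <- function(inputDim, hiddenDims = c(256L, 128L),
                         lambdaMix = 0.4, seed = 1L, outputScale = 1) {
  stopifnot(inputDim >= 1L, length(hiddenDims) >= 1L, all(hiddenDims >= 1L),
            outputScale > 0)
  dims <- c(inputDim, hiddenDims)
  L <- length(hiddenDims)
  .withSeed(.deriveSeed(seed, "glorot"), {
    weights <- lapply(seq_len(L), function(l) {
      fanIn <- dims[l]; fanOut <- dims[l + 1L]
      a <- sqrt(6 / (fanIn + fanOut)) * if (l == L) outputScale else 1
      matrix(stats::runif(fanIn * fanOut, -a, a), fanIn, fanOut)
    })
    biases <- lapply(hiddenDims, function(d) numeric(d))
    new("GCNModel", weights = weights, biases = biases,
        lambdaMix = lambdaMix)
  })
}

# The operator actually propagated with: lambda * Anorm + (1 - lambda) * I.
# At lambda = 1 this is the normalized prior-network adjacency; at lambda = 0
# the graph is ignored and each gene keeps its own features.
.mixedOperator <- function(Anorm, lambdaMix) {
  if (lambdaMix == 1) return(Anorm)
  lambdaMix * Anorm + diag(1 - lambdaMix, nrow(Anorm))
}

#' One graph convolutional layer
#'
#' Computes `ReLU(Ahat %*% H %*% W + b)` where
#' `Ahat = lambdaMix * Anorm + (1 - lambdaMix) * I`, `Anorm` the normalized
#' adjacency from [buildNormalizedAdjacency()], and the bias is broadcast
#' across nodes. At `lambdaMix = 1` this is the standard GCN propagation
#' rule: each node's new features are a degree-normalized average of its
#' neighbors' (and its own) features, linearly mapped and rectified.
#'
#' @param H numeric N x d matrix of node features.
#' @param Anorm numeric N x N normalized adjacency.
#' @param W numeric d x d' weight matrix.
#' @param b numeric length-d' bias vector.
#' @param lambdaMix mixing coefficient in \[0, 1\].
#' @return Numeric N x d' matrix of rectified features.
#' @export
gcnLayer <- function(H, Anorm, W, b, lambdaMix = 1) {
  stopifnot(ncol(H) == nrow(W), length(b) == ncol(W),
            nrow(H) == nrow(Anorm), lambdaMix >= 0, lambdaMix <= 1)
  Z <- .mixedOperator(Anorm, lambdaMix) %*% H %*% W
  Z <- sweep(Z, 2L, b, "+")
  if (any(!is.finite(Z)))
    .stopf("non-finite layer output (exploding weights?)")
  .relu(Z)
}

# Per-gene feature standardization: each gene's expression vector is
# centered across cells and scaled to unit L2 norm (constant genes map to
# zero rows). The Gram matrix of the standardized features is then exactly
# the gene-gene Pearson correlation matrix, so the rectified dot-product
# decoder scores co-expression rather than mean expression level (which
# would otherwise dominate every inner product of nonnegative profiles),
# and all downstream layer magnitudes stay O(1) under Glorot init.
.standardizeFeatures <- function(v) {
  vc <- v - rowMeans(v)
  nrm <- sqrt(rowSums(vc^2))
  nrm[nrm == 0] <- 1
  vc / nrm
}

#' Encode genes into embeddings
#'
#' Runs the full encoder: H^(0) is the (preprocessed) expression matrix
#' after per-gene standardization (see Details), then L stacked [gcnLayer()]
#' applications. The final layer's output is the gene embedding matrix H
#' (N genes x d_1 dimensions, entries >= 0).
#'
#' @details By default each gene's feature vector is standardized (zero
#' mean, unit variance across cells) before entering the first layer. This
#' makes the inner products the decoder ultimately measures reflect gene
#' co-expression instead of absolute expression level; without it the
#' encoder cannot separate a TF's true targets from other well-expressed
#' genes. Set `standardize = FALSE` to feed the raw values.
#'
#' @param x an [ExpressionMatrix-class]; its gene order must equal the
#'   adjacency's node order.
#' @param Anorm normalized adjacency with dimnames matching `geneIds(x)`.
#' @param model a [GCNModel-class].
#' @param standardize standardize features per gene first (default TRUE).
#' @return Numeric N x d_1 embedding matrix with gene identifiers as
#'   rownames.
#' @export
gcnEncode <- function(x, Anorm, model, standardize = TRUE) {
  stopifnot(is(x, "ExpressionMatrix"), is(model, "GCNModel"))
  if (!identical(geneIds(x), rownames(Anorm)))
    .stopf("gene order of expression matrix and adjacency differ")
  H <- exprValues(x)
  if (standardize) H <- .standardizeFeatures(H)
  for (l in seq_along(model@weights)) {
    if (ncol(H) != nrow(model@weights[[l]]))
      .stopf("dimension mismatch at layer %d: features %d vs weights %d",
             l, ncol(H), nrow(model@weights[[l]]))
    H <- gcnLayer(H, Anorm, model@weights[[l]], model@biases[[l]],
                  model@lambdaMix)
  }
  H
}

#' Co-expression profile features
#'
#' Featurizes each gene by its absolute co-expression profile: the vector of
#' absolute Pearson correlations with every gene in the matrix (the classic
#' relevance-network representation). Regulation manifests as co-variation
#' of either sign — repressed targets anti-correlate with their regulator —
#' and the rectified dot-product decoder scores feature *alignment*, so
#' feeding signed profiles would render repressive edges invisible (the
#' ReLU of a negative inner product is zero). Taking the modulus makes both
#' regulation signs equally visible: genes driven by the same regulators
#' have similar absolute-correlation profiles.
#'
#' @param x an [ExpressionMatrix-class] (typically preprocessed).
#' @return An [ExpressionMatrix-class] of dimension N x N whose "cell" axis
#'   holds one feature per gene (ids prefixed `r.`); entry (i, k) is
#'   |cor(gene i, gene k)|. Constant genes get zero profiles.
#' @seealso [gcnEncode()], [trainGCN()]
#' @export
coexpressionProfile <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  z <- .standardizeFeatures(exprValues(x))
  C <- abs(tcrossprod(z))
  ExpressionMatrix(C, geneIds = geneIds(x),
                   cellIds = paste0("r.", geneIds(x)))
}

#' Decode embeddings into a regulatory score matrix
#'
#' The rectified dot-product decoder: `R = ReLU(H %*% t(H))`. R is symmetric
#' and nonnegative; R\[i, j\] is the predicted regulatory association score
#' of genes i and j, with larger meaning stronger. Because embeddings are
#' themselves nonnegative, the ReLU only zeroes exact orthogonality.
#'
#' @param H numeric embedding matrix (genes x dimensions), e.g. from
#'   [gcnEncode()].
#' @return Numeric N x N score matrix with gene rownames/colnames.
#' @export
gcnDecode <- function(H) {
  stopifnot(is.matrix(H), all(is.finite(H)))
  .relu(tcrossprod(H))
}

#' Look up scores for gene pairs
#'
#' @param R score matrix from [gcnDecode()] with gene dimnames.
#' @param pairs data.frame (`from`, `to`) of query pairs.
#' @return Numeric vector of `R[from, to]`, in query order.
#' @export
scorePairs <- function(R, pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  i <- match(pairs$from, rownames(R))
  j <- match(pairs$to, colnames(R))
  if (anyNA(i) || anyNA(j)) {
    missingId <- c(pairs$from[is.na(i)], pairs$to[is.na(j)])[1L]
    .stopf("unknown gene in score query: %s", missingId)
  }
  R[cbind(i, j)]
}
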