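# Shared fixture builders. Everything is generated in code at test time.

# Tiny deterministic expression matrix.
tinyExpr <- function(values = matrix(0:5, nrow = 3),
                     genes = paste0("G", seq_len(nrow(values))),
                     cells = paste0("C", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, cells)
  ExpressionMatrix(values)
}

tinyNet <- function(edges = data.frame(from = c("A", "B"), to = c("B", "C")),
                    genes = NULL, tfs = NULL) {
  PriorNetwork(edges, genes = genes, tfSet = tfs)
}

# Random directed TF->target network over nTfs + extra target genes.
randomNet <- function(nTfs, nGenes, density, seed) {
  cfg <- syntheticConfig(nTfs = nTfs, nGenes = nGenes, density = density,
                         nCells = 4L, seed = seed)
  simulateGRN(cfg)
}

# Arbitrary directed graph with a guaranteed edge count, for operator
# oracles that only need *some* graph (not the generator's distribution).
randomGraphNet <- function(nNodes, nEdges, seed) {
  nodes <- paste0("G", seq_len(nNodes))
  tfs <- nodes[seq_len(max(1L, nNodes %/% 3L))]
  grid <- expand.grid(from = tfs, to = nodes, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, ]
  set.seed(seed)
  pick <- grid[sample.int(nrow(grid), min(nEdges, nrow(grid))), ]
  PriorNetwork(pick, genes = nodes, tfSet = tfs)
}

writeTempCsv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# Brute-force elementwise normalized adjacency: A_ij / sqrt(d_i d_j) on the
# symmetrized self-looped binary adjacency. Independent of the package's
# matrix implementation.
naiveNormalizedAdjacency <- function(edges, nodes) {
  n <- length(nodes)
  A <- diag(1, n)
  for (r in seq_len(nrow(edges))) {
    i <- match(edges$from[r], nodes); j <- match(edges$to[r], nodes)
    A[i, j] <- 1; A[j, i] <- 1
  }
  d <- rowSums(A)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- A[i, j] / sqrt(d[i] * d[j])
  dimnames(out) <- list(nodes, nodes)
  out
}

# Per-node aggregation oracle for one graph convolution layer:
# h_i = ReLU(sum_j Ahat_ij W^T h_j + b), looped over nodes.
naiveGcnLayer <- function(H, Anorm, W, b, lambdaMix = 1) {
  n <- nrow(H)
  Ahat <- lambdaMix * Anorm + diag(1 - lambdaMix, n)
  out <- matrix(0, n, ncol(W))
  for (i in seq_len(n)) {
    acc <- numeric(ncol(W))
    for (j in seq_len(n))
      acc <- acc + Ahat[i, j] * as.numeric(t(W) %*% H[j, ])
    out[i, ] <- pmax(acc + b, 0)
  }
  out
}

# Pairwise-comparison AUROC oracle (Mann-Whitney by enumeration).
naiveAuroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Step-wise AUPRC oracle: explicit sweep over distinct thresholds.
naiveAuprc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  nPos <- sum(labels == 1)
  area <- 0; prevRecall <- 0
  for (t in th) {
    sel <- scores >= t
    precision <- sum(labels[sel] == 1) / sum(sel)
    recall <- sum(labels[sel] == 1) / nPos
    area <- area + (recall - prevRecall) * precision
    prevRecall <- recall
  }
  area
}

# Cached end-to-end runs on the strong_signal conditions so that the
# stochastic acceptance properties can share them.
.runCache <- new.env(parent = emptyenv())

strongSignalRun <- function(seed, noiseSd = 0.1) {
  key <- sprintf("s%d_n%g", seed, noiseSd)
  if (!is.null(.runCache[[key]])) return(.runCache[[key]])
  cfg <- fixtureConfig("strong_signal")
  cfg$noiseSd <- noiseSd
  net <- simulateGRN(cfg)
  expr <- simulateExpression(net, cfg)
  d <- tempfile("ss")
  dir.create(d)
  writeExpression(expr, file.path(d, "e.csv"))
  writeNetwork(net, file.path(d, "n.csv"))
  writeLines(tfSet(net), file.path(d, "t.txt"))
  res <- suppressMessages(runExperiment(
    file.path(d, "e.csv"), file.path(d, "n.csv"), file.path(d, "t.txt"),
    config = trainConfig(seed = seed), outDir = tempfile(),
    writeArtifacts = FALSE))
  unlink(d, recursive = TRUE)
  .runCache[[key]] <- res[c("metrics", "history")]
  .runCache[[key]]
}
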