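#' Synthetic data configuration
#'
#' Parameters of the planted-network generator. The generator emulates the
#' benchmark regime the pipeline targets: a directed TF-to-target network at
#' a configurable density (benchmark ground truths span roughly 0.013-0.58)
#' and a nonnegative gene-by-cell expression matrix with dropout zeros.
#'
#' @param nTfs number of transcription factors.
#' @param nGenes total number of genes (TFs included); `nTfs <= nGenes`.
#' @param density edge probability over the TF x gene grid, in (0, 1).
#' @param nCells number of cells.
#' @param edgeWeightScale standard deviation of the per-edge regulatory
#'   weights (also the TF expression scale); larger means stronger
#'   TF-target co-variation. Default 2.
#' @param noiseSd standard deviation of the additive measurement noise.
#' @param dropoutRate probability an entry is zeroed (false-zero dropout),
#'   in \[0, 1).
#' @param seed integer seed.
#' @return A list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(nTfs = 10L, nGenes = 50L, density = 0.05,
                            nCells = 100L, edgeWeightScale = 2,
                            noiseSd = 0.1, dropoutRate = 0.1, seed = 1L) {
  stopifnot(nTfs >= 1L, nTfs <= nGenes, density > 0, density < 1,
            nCells >= 1L, edgeWeightScale > 0, noiseSd >= 0,
            dropoutRate >= 0, dropoutRate < 1)
  structure(list(nTfs = as.integer(nTfs), nGenes = as.integer(nGenes),
                 density = density, nCells = as.integer(nCells),
                 edgeWeightScale = edgeWeightScale, noiseSd = noiseSd,
                 dropoutRate = dropoutRate, seed = as.integer(seed)),
            class = "syntheticConfig")
}

#' Simulate a planted regulatory network
#'
#' Draws the total edge count as Binomial(nPairs, density) over the
#' TF x gene grid (self-pairs excluded), so the realized density
#' concentrates at the requested one, and places the edges by weighted
#' sampling without replacement with per-TF activity multipliers drawn
#' log-normal(0, 1). The multipliers tilt out-degrees heavy-tailed, so hub
#' TFs exist as in real regulatory networks. Deterministic given the seed.
#'
#' @param cfg a [syntheticConfig()].
#' @return A [PriorNetwork-class] over genes `G1..G<nGenes>` with TFs
#'   `G1..G<nTfs>`.
#' @export
simulateGRN <- function(cfg) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  gs <- sprintf("G%d", seq_len(cfg$nGenes))
  tfs <- gs[seq_len(cfg$nTfs)]
  from <- rep(tfs, each = cfg$nGenes)
  to <- rep(gs, times = cfg$nTfs)
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  nPairs <- length(from)
  .withSeed(.deriveSeed(cfg$seed, "grn"), {
    for (attempt in 1:2) {
      k <- stats::rbinom(1L, nPairs, cfg$density)
      if (k > 0L) break
    }
    if (k == 0L) .stopf("zero edges drawn at density %g; increase density",
                        cfg$density)
    mult <- stats::rlnorm(cfg$nTfs, 0, 1)
    names(mult) <- tfs
    idx <- sample.int(nPairs, k, prob = mult[from])
    PriorNetwork(data.frame(from = from[idx], to = to[idx],
                            stringsAsFactors = FALSE),
                 genes = gs, tfSet = tfs)
  })
}

#' Simulate a single-cell expression matrix from a planted network
#'
#' A linear-weights structural model with a softplus link: per cell, TF
#' activities are drawn |Normal(0, 1)|; each target's value is
#' `softplus(sum over regulators of w * activity) + |Normal(0, noiseSd)|`
#' with per-edge weights `w ~ Normal(0, edgeWeightScale^2)` fixed once per
#' edge; TFs express their own activity (scaled by `edgeWeightScale`) plus
#' noise. Each entry is then independently zeroed with probability
#' `dropoutRate`, modeling false-zero dropout. All values are nonnegative;
#' output is deterministic given the seed.
#'
#' @param net a [PriorNetwork-class], e.g. from [simulateGRN()].
#' @param cfg the matching [syntheticConfig()].
#' @return An [ExpressionMatrix-class] (genes of `net` x `nCells` cells).
#' @export
simulateExpression <- function(net, cfg) {
  stopifnot(is(net, "PriorNetwork"), inherits(cfg, "syntheticConfig"))
  gs <- genes(net); tfs <- tfSet(net)
  e <- edges(net)
  .withSeed(.deriveSeed(cfg$seed, "expression"), {
    w <- stats::rnorm(nrow(e), 0, cfg$edgeWeightScale)
    act <- abs(matrix(stats::rnorm(length(tfs) * cfg$nCells), length(tfs),
                      cfg$nCells, dimnames = list(tfs, NULL)))
    # regulatory input per target: sparse weighted sum of TF activities
    drive <- matrix(0, length(gs), cfg$nCells, dimnames = list(gs, NULL))
    if (nrow(e)) {
      for (r in seq_len(nrow(e)))
        drive[e$to[r], ] <- drive[e$to[r], ] + w[r] * act[e$from[r], ]
    }
    vals <- .softplus(drive)
    vals[tfs, ] <- cfg$edgeWeightScale * act
    vals <- vals + abs(matrix(stats::rnorm(length(vals), 0, cfg$noiseSd),
                              nrow(vals)))
    if (cfg$dropoutRate > 0) {
      drop <- matrix(stats::runif(length(vals)) < cfg$dropoutRate,
                     nrow(vals))
      vals[drop] <- 0
    }
    ExpressionMatrix(vals, geneIds = gs,
                     cellIds = sprintf("C%d", seq_len(cfg$nCells)))
  })
}

#' Named fixture presets
#'
#' Three pinned-seed study conditions used across the test suite:
#' `smoke` (10 TFs, 50 genes, 100 cells, density 0.05) for fast
#' plumbing checks; `strong_signal` (25 TFs, 200 genes, 300 cells, density
#' 0.05, noise 0.1, dropout 0.2) as the recovery benchmark; `dense`
#' (15 TFs, 100 genes, 200 cells, density 0.4), emulating the dense
#' cell-type-specific ground-truth regime.
#'
#' @param name one of `"smoke"`, `"strong_signal"`, `"dense"`.
#' @return The corresponding [syntheticConfig()].
#' @export
fixtureConfig <- function(name = c("smoke", "strong_signal", "dense")) {
  name <- match.arg(name)
  switch(name,
    smoke = syntheticConfig(nTfs = 10L, nGenes = 50L, nCells = 100L,
                            density = 0.05, noiseSd = 0.1,
                            dropoutRate = 0.1, seed = 101L),
    strong_signal = syntheticConfig(nTfs = 25L, nGenes = 200L,
                                    nCells = 300L, density = 0.05,
                                    noiseSd = 0.1, dropoutRate = 0.2,
                                    seed = 202L),
    dense = syntheticConfig(nTfs = 15L, nGenes = 100L, nCells = 200L,
                            density = 0.4, noiseSd = 0.1,
                            dropoutRate = 0.1, seed = 303L))
}

#' Write a named fixture to disk
#'
#' Generates the preset network and expression matrix and writes the three
#' standard files (`ExpressionData.csv`, `refNetwork.csv`, `TFs.txt`) in the
#' dialects read by [readExpression()], [readNetwork()] and [readTFList()].
#'
#' @param name preset name, see [fixtureConfig()].
#' @param dir output directory (created if needed).
#' @param seed optional seed overriding the preset's pinned seed.
#' @return Named character vector of the three file paths, invisibly.
#' @export
makeFixture <- function(name = c("smoke", "strong_signal", "dense"),
                        dir = tempfile("fixture"), seed = NULL) {
  cfg <- fixtureConfig(name)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  net <- simulateGRN(cfg)
  expr <- simulateExpression(net, cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "ExpressionData.csv"),
             network = file.path(dir, "refNetwork.csv"),
             tfs = file.path(dir, "TFs.txt"))
  writeExpression(expr, paths[["expression"]])
  writeNetwork(net, paths[["network"]])
  writeLines(tfSet(net), paths[["tfs"]])
  invisible(paths)
}
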