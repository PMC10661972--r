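#' Partition known edges into train/validation/test positives
#'
#' Uniform random 3:1:1 partition of the network's directed edges. Base
#' compartment sizes are floor(3n/5), floor(n/5), floor(n/5); any remainder
#' is assigned train-first (train, then validation, then test). Deterministic
#' given the seed.
#'
#' @param net a [PriorNetwork-class] with at least 5 edges.
#' @param seed integer seed.
#' @return An [EdgeSplit-class] with the positive compartments filled and
#'   empty negative compartments.
#' @seealso [makeEdgeSplit()] for the full labeled split.
#' @export
splitPositives <- function(net, seed = 1L) {
  stopifnot(is(net, "PriorNetwork"))
  e <- edges(net)
  n <- nrow(e)
  if (n < 5L) .stopf("need at least 5 positive edges to split 3:1:1, got %d", n)
  sizes <- c(train = n %/% 5L * 3L, val = n %/% 5L, test = n %/% 5L)
  rem <- n - sum(sizes)  # n %% 5, in 0..4
  if (rem > 0L) {
    extra <- tabulate(rep_len(1:3, rem), nbins = 3L)
    sizes <- sizes + extra
  }
  perm <- .withSeed(.deriveSeed(seed, "splitPositives"), sample.int(n))
  idx <- split(perm, rep(c("train", "val", "test"), times = sizes))
  emptyPairs <- data.frame(from = character(), to = character(),
                           stringsAsFactors = FALSE)
  take <- function(i) {
    d <- e[sort(i), , drop = FALSE]; rownames(d) <- NULL; d
  }
  new("EdgeSplit",
      trainPos = take(idx$train), valPos = take(idx$val),
      testPos = take(idx$test), trainNeg = emptyPairs, valNeg = emptyPairs,
      testNeg = emptyPairs, seed = as.integer(seed))
}

#' Sample hard negative pairs for training
#'
#' For each positive pair (g1, g2), draws `ceiling(ratio)` negatives
#' uniformly from the candidate pool restricted to source g1 — pairs
#' (g1, g3) with g3 a gene, g3 != g1, that are not edges of the network.
#' Sharing the source with a positive makes the negative "hard": the model
#' must separate a TF's true targets from its non-targets rather than
#' separating active TFs from silent genes. If the restricted pool is
#' exhausted the draw falls back to the unrestricted pool (any TF source).
#' The returned set has no duplicates, never intersects `allEdges` or
#' `exclude`, and is deterministic given the seed. If the pool runs out a
#' warning is issued and fewer pairs are returned.
#'
#' @param positives data.frame (`from`, `to`) of positive pairs to mirror.
#' @param net a [PriorNetwork-class]; its full edge set and TF set define the
#'   candidate pool `{(s, t): s in TFs, t in genes, t != s, (s, t) not an edge}`.
#' @param ratio negatives per positive (> 0); non-integers are ceiled per
#'   positive.
#' @param seed integer seed.
#' @param exclude optional data.frame (`from`, `to`) of pairs that must not
#'   be drawn (e.g. negatives already assigned to another compartment).
#' @return data.frame (`from`, `to`) of negative pairs.
#' @export
sampleHardNegatives <- function(positives, net, ratio = 1, seed = 1L,
                                exclude = NULL) {
  stopifnot(is(net, "PriorNetwork"), ratio > 0)
  positives <- as.data.frame(positives, stringsAsFactors = FALSE)
  allGenes <- genes(net)
  edgeKeys <- .edgeKey(edges(net)$from, edges(net)$to)
  used <- new.env(parent = emptyenv())
  for (k in edgeKeys) assign(k, TRUE, envir = used)
  if (!is.null(exclude) && nrow(exclude))
    for (k in .edgeKey(exclude$from, exclude$to)) assign(k, TRUE, envir = used)
  kPer <- ceiling(ratio)
  nWant <- kPer * nrow(positives)
  out <- character(nWant)
  nGot <- 0L
  .withSeed(.deriveSeed(seed, "hardNegatives"), {
    for (r in seq_len(nrow(positives))) {
      g1 <- positives$from[r]
      cand <- allGenes[allGenes != g1]
      cand <- cand[!vapply(.edgeKey(g1, cand), exists, TRUE, envir = used)]
      for (dummy in seq_len(kPer)) {
        if (length(cand)) {
          g3 <- cand[sample.int(length(cand), 1L)]
          key <- .edgeKey(g1, g3)
          cand <- cand[cand != g3]
        } else {
          key <- .sampleFromPool(net, used)
          if (is.na(key)) break
        }
        assign(key, TRUE, envir = used)
        nGot <- nGot + 1L
        out[nGot] <- key
      }
    }
  })
  if (nGot < nWant)
    warning(sprintf("negative pool exhausted: sampled %d of %d requested",
                    nGot, nWant))
  .keyToPairs(out[seq_len(nGot)])
}

# One uniform draw from the unrestricted candidate pool (TF source, non-edge,
# not yet used); NA when the pool is empty.
.sampleFromPool <- function(net, used) {
  pool <- unlist(lapply(tfSet(net), function(s) {
    t <- genes(net)[genes(net) != s]
    .edgeKey(s, t)
  }))
  pool <- pool[!vapply(pool, exists, TRUE, envir = used)]
  if (!length(pool)) return(NA_character_)
  pool[sample.int(length(pool), 1L)]
}

#' Density-matched negatives for the test set
#'
#' Draws uniform negatives (TF source, non-edge) so that the test-set
#' positive:negative ratio matches the network density rho =
#' |edges| / (|TFs| * (|genes| - 1)): the count is
#' round(|testPos| * (1 - rho) / rho). Evaluating at the natural class
#' imbalance keeps AUPRC comparable to what a screen of all candidate pairs
#' would face.
#'
#' @param testPos data.frame (`from`, `to`) of test positives.
#' @param net a [PriorNetwork-class].
#' @param seed integer seed.
#' @param exclude data.frame of pairs already used as negatives elsewhere.
#' @return data.frame (`from`, `to`) of negative pairs, disjoint from all
#'   edges and from `exclude`.
#' @export
densityMatchedTestNegatives <- function(testPos, net, seed = 1L,
                                        exclude = NULL) {
  stopifnot(is(net, "PriorNetwork"))
  rho <- networkDensity(net)
  if (rho <= 0 || rho >= 1) .stopf("network density %g outside (0,1)", rho)
  nNeg <- round(nrow(as.data.frame(testPos)) * (1 - rho) / rho)
  usedKeys <- .edgeKey(edges(net)$from, edges(net)$to)
  if (!is.null(exclude) && nrow(exclude))
    usedKeys <- c(usedKeys, .edgeKey(exclude$from, exclude$to))
  pool <- unlist(lapply(tfSet(net), function(s) {
    t <- genes(net)[genes(net) != s]
    .edgeKey(s, t)
  }))
  pool <- setdiff(pool, usedKeys)
  if (length(pool) < nNeg) {
    warning(sprintf("negative pool exhausted: sampled %d of %d requested",
                    length(pool), nNeg))
    nNeg <- length(pool)
  }
  keys <- .withSeed(.deriveSeed(seed, "testNegatives"),
                    sample(pool, nNeg))
  .keyToPairs(sort(keys))
}

#' Build the complete labeled edge split
#'
#' Convenience wrapper: 3:1:1 positive partition ([splitPositives()]), hard
#' training negatives at `negRatio` per positive, and density-matched
#' uniform negatives ([densityMatchedTestNegatives()]) for both the
#' validation and the test compartments. Hard negatives sharpen what the
#' model must learn during training; validation uses the same
#' density-matched protocol as the test evaluation so that checkpoint
#' selection optimizes the quantity actually reported. All negative
#' compartments are mutually disjoint and disjoint from every known edge.
#'
#' @param net a [PriorNetwork-class].
#' @param seed integer seed.
#' @param negRatio training negatives per training positive (default 1).
#' @return An [EdgeSplit-class] with all six compartments filled.
#' @export
makeEdgeSplit <- function(net, seed = 1L, negRatio = 1) {
  split <- splitPositives(net, seed)
  trainNeg <- sampleHardNegatives(split@trainPos, net, ratio = negRatio,
                                  seed = .deriveSeed(seed, "train"))
  valNeg <- densityMatchedTestNegatives(split@valPos, net,
                                        seed = .deriveSeed(seed, "val"),
                                        exclude = trainNeg)
  testNeg <- densityMatchedTestNegatives(split@testPos, net,
                                         seed = .deriveSeed(seed, "test"),
                                         exclude = rbind(trainNeg, valNeg))
  initialize(split, trainNeg = trainNeg, valNeg = valNeg, testNeg = testNeg)
}
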