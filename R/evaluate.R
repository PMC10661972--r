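#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a uniformly chosen
#' positive outscores a uniformly chosen negative, with ties counted as 1/2.
#' Computed from midranks, so it is exact under ties and invariant to any
#' strictly monotone transform of the scores.
#'
#' @param scores numeric vector of predicted scores.
#' @param labels 0/1 vector of the same length; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
aurocScore <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0L || nNeg == 0L)
    .stopf("AUROC needs both classes; got %d positives, %d negatives",
           nPos, nNeg)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve
#'
#' Step-wise (interpolation-free) area: scores are swept in descending order
#' with tied scores grouped into one threshold, and the area is
#' `sum((recall_k - recall_{k-1}) * precision_k)`. This matches the common
#' machine-learning "average precision" semantics; trapezoidal interpolation
#' in PR space is optimistically biased and is not used. The baseline value
#' for an uninformative ranker is the positive prevalence.
#'
#' @inheritParams aurocScore
#' @return AUPRC in (0, 1\].
#' @export
auprcScore <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  nPos <- sum(labels == 1)
  if (nPos == 0L || nPos == length(labels))
    .stopf("AUPRC needs both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores: cumulative counts at each distinct threshold
  lastOfGroup <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- cumsum(y)[lastOfGroup]
  nAbove <- seq_along(s)[lastOfGroup]
  precision <- tp / nAbove
  recall <- tp / nPos
  sum(diff(c(0, recall)) * precision)
}

#' Evaluate scores on a labeled pair set
#'
#' @param R score matrix from [gcnDecode()].
#' @param pos,neg data.frames (`from`, `to`) of positive and negative pairs.
#' @return A metrics report list: `auroc`, `auprc`, `nPos`, `nNeg`,
#'   `prevalence`.
#' @export
evaluatePairs <- function(R, pos, neg) {
  samples <- rbind(cbind(as.data.frame(pos), label = 1),
                   cbind(as.data.frame(neg), label = 0))
  scores <- scorePairs(R, samples)
  list(auroc = aurocScore(scores, samples$label),
       auprc = auprcScore(scores, samples$label),
       nPos = nrow(as.data.frame(pos)), nNeg = nrow(as.data.frame(neg)),
       prevalence = nrow(as.data.frame(pos)) / nrow(samples))
}

#' Rank all candidate TF-to-gene pairs
#'
#' Enumerates every directed (TF, gene) pair with TF in the network's TF
#' set, gene != TF and the pair not in `exclude` (typically the training
#' positives, which the model was fit on), and returns them sorted by score
#' descending with ties broken by (source, target) lexicographic order.
#'
#' @param R score matrix with gene dimnames covering the network's genes.
#' @param net a [PriorNetwork-class].
#' @param exclude data.frame (`from`, `to`) of pairs to omit, or NULL.
#' @return data.frame with columns `from`, `to`, `score`, ranked.
#' @seealso [writeRankedEdges()]
#' @export
rankCandidates <- function(R, net, exclude = NULL) {
  stopifnot(is(net, "PriorNetwork"))
  tfs <- tfSet(net); gs <- genes(net)
  from <- rep(tfs, each = length(gs))
  to <- rep(gs, times = length(tfs))
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  if (!is.null(exclude) && nrow(as.data.frame(exclude))) {
    exclude <- as.data.frame(exclude, stringsAsFactors = FALSE)
    keep <- !(.edgeKey(from, to) %in% .edgeKey(exclude$from, exclude$to))
    from <- from[keep]; to <- to[keep]
  }
  score <- scorePairs(R, data.frame(from = from, to = to,
                                    stringsAsFactors = FALSE))
  ord <- order(-score, from, to, method = "radix")
  data.frame(from = from[ord], to = to[ord], score = score[ord],
             stringsAsFactors = FALSE)
}
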