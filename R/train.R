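#' Training configuration
#'
#' Collects the tunable parameters of the full pipeline with the defaults
#' used throughout: 200 epochs of full-batch Adam at learning rate 0.005, a
#' two-layer encoder with hidden sizes 256 and 128, adjacency mixing
#' coefficient 0.4, Frobenius weight decay 5e-4, and one hard negative per
#' training positive.
#'
#' @param epochs number of training epochs (>= 1).
#' @param learningRate Adam step size (> 0).
#' @param lambdaMix encoder mixing coefficient in \[0, 1\]; 0 uses expression
#'   features only, 1 pure prior-network propagation.
#' @param weightDecay coefficient of the squared Frobenius norm of the
#'   weight matrices in the loss.
#' @param negRatio hard training negatives per positive.
#' @param seed integer seed; all randomness of a run flows from it.
#' @param hiddenDims encoder layer output dimensions.
#' @param features encoder input featurization: `"coexpression"` (default)
#'   feeds each gene's absolute co-expression profile
#'   ([coexpressionProfile()]); `"expression"` feeds the preprocessed
#'   expression values directly.
#' @param minCellFraction,alpha,topK,logBase preprocessing parameters, see
#'   [preprocessExpression()].
#' @return A list of class `trainConfig`.
#' @export
trainConfig <- function(epochs = 200L, learningRate = 0.005, lambdaMix = 0.4,
                        weightDecay = 5e-4, negRatio = 1, seed = 1L,
                        hiddenDims = c(256L, 128L),
                        features = c("coexpression", "expression"),
                        minCellFraction = 0.10,
                        alpha = 0.01, topK = 500L, logBase = 2) {
  stopifnot(epochs >= 1L, learningRate >= 0, lambdaMix >= 0, lambdaMix <= 1,
            weightDecay >= 0, negRatio > 0)
  features <- match.arg(features)
  structure(list(epochs = as.integer(epochs), learningRate = learningRate,
                 lambdaMix = lambdaMix, weightDecay = weightDecay,
                 negRatio = negRatio, seed = as.integer(seed),
                 hiddenDims = as.integer(hiddenDims), features = features,
                 minCellFraction = minCellFraction, alpha = alpha,
                 topK = as.integer(topK), logBase = logBase),
            class = "trainConfig")
}

#' Edge-reconstruction loss
#'
#' Mean squared error between predicted scores and binary edge labels over
#' the labeled sample set, plus Frobenius regularization of the encoder
#' weights: `mean((R[i,j] - y)^2) + weightDecay * sum_l ||W_l||_F^2`. The
#' label is the binary edge indicator (1 for a known edge, 0 for a sampled
#' negative), not a normalized quantity.
#'
#' @param R score matrix from [gcnDecode()].
#' @param samples data.frame with columns `from`, `to`, `label` (0/1).
#' @param model the [GCNModel-class] whose weights are regularized.
#' @param weightDecay regularization coefficient (>= 0).
#' @return Scalar loss.
#' @export
computeLoss <- function(R, samples, model, weightDecay = 0) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!nrow(samples)) .stopf("empty sample list")
  stopifnot(all(samples$label %in% c(0, 1)))
  s <- scorePairs(R, samples)
  data <- mean((s - samples$label)^2)
  reg <- sum(vapply(model@weights, function(W) sum(W^2), 0))
  data + weightDecay * reg
}

# Forward pass keeping per-layer intermediates for backprop.
# Returns list(H = list(H0..HL), Z = list(Z1..ZL), M = list(Ahat %*% H_{l-1})).
.gcnForward <- function(X, Anorm, model) {
  Ahat <- .mixedOperator(Anorm, model@lambdaMix)
  L <- length(model@weights)
  H <- vector("list", L + 1L); Z <- vector("list", L); M <- vector("list", L)
  H[[1L]] <- X
  for (l in seq_len(L)) {
    M[[l]] <- Ahat %*% H[[l]]
    Z[[l]] <- sweep(M[[l]] %*% model@weights[[l]], 2L, model@biases[[l]], "+")
    H[[l + 1L]] <- .relu(Z[[l]])
  }
  list(H = H, Z = Z, M = M, Ahat = Ahat)
}

#' Analytic gradients of the edge-reconstruction loss
#'
#' Backpropagates the loss of [computeLoss()] through the decoder and the
#' stacked graph convolution layers, returning exact gradients with respect
#' to every weight matrix and bias vector. Exposed so the gradients the
#' optimizer uses can be checked against finite differences.
#'
#' @param x an [ExpressionMatrix-class] (the encoder input H^(0)).
#' @param Anorm normalized adjacency aligned with `x`.
#' @param model a [GCNModel-class].
#' @param samples data.frame with columns `from`, `to`, `label`.
#' @param weightDecay regularization coefficient.
#' @param standardize standardize features per gene, as in [gcnEncode()].
#' @return List with `loss` (scalar), `weights` and `biases` (lists of
#'   gradients, same shapes as the model parameters).
#' @export
lossGradients <- function(x, Anorm, model, samples, weightDecay = 0,
                          standardize = TRUE) {
  stopifnot(is(x, "ExpressionMatrix"), is(model, "GCNModel"))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!nrow(samples)) .stopf("empty sample list")
  H0 <- exprValues(x)
  if (standardize) H0 <- .standardizeFeatures(H0)
  fwd <- .gcnForward(H0, Anorm, model)
  L <- length(model@weights)
  H <- fwd$H[[L + 1L]]
  P <- tcrossprod(H)
  R <- .relu(P)
  nodes <- geneIds(x)
  i <- match(samples$from, nodes); j <- match(samples$to, nodes)
  if (anyNA(i) || anyNA(j)) .stopf("sample pair references unknown gene")
  resid <- R[cbind(i, j)] - samples$label
  n <- nrow(samples)
  loss <- mean(resid^2) +
    weightDecay * sum(vapply(model@weights, function(W) sum(W^2), 0))
  # dL/dP at sampled positions; ReLU mask (P > 0) — P >= 0 always since H >= 0
  g <- (2 / n) * resid * (P[cbind(i, j)] > 0)
  G <- matrix(0, nrow(P), ncol(P))
  # accumulate (duplicates in (i,j) are not expected but summed correctly)
  for (k in seq_len(n)) G[i[k], j[k]] <- G[i[k], j[k]] + g[k]
  dH <- (G + t(G)) %*% H
  dW <- vector("list", L); db <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dZ <- dH * (fwd$Z[[l]] > 0)
    dW[[l]] <- unname(crossprod(fwd$M[[l]], dZ)) +
      2 * weightDecay * model@weights[[l]]
    db[[l]] <- unname(colSums(dZ))
    if (l > 1L) dH <- fwd$Ahat %*% tcrossprod(dZ, model@weights[[l]])
  }
  list(loss = loss, weights = dW, biases = db)
}

#' Train the encoder by full-batch Adam
#'
#' Optimizes the [computeLoss()] objective over the training positives and
#' hard negatives for `config$epochs` epochs with Adam (beta1 0.9, beta2
#' 0.999, eps 1e-8). Validation AUROC is computed every epoch on the
#' validation compartment of the split, and the returned model is the
#' checkpoint from the best-validation epoch (earliest on ties).
#' Deterministic given `config$seed`.
#'
#' @param x preprocessed [ExpressionMatrix-class]; genes must cover every
#'   split endpoint and match `Anorm`'s node order when supplied.
#' @param net [PriorNetwork-class] restricted to the genes of `x`.
#' @param split an [EdgeSplit-class] with all six compartments filled.
#' @param config a [trainConfig()].
#' @param Anorm optional precomputed normalized adjacency; by default built
#'   from the training positives only, so validation and test labels never
#'   enter the message-passing graph.
#' @return List with `model` (best-epoch [GCNModel-class]) and `history`
#'   (list: `trainLoss`, `valAuroc` per epoch, `bestEpoch`).
#' @export
trainGCN <- function(x, net, split, config = trainConfig(), Anorm = NULL) {
  stopifnot(is(x, "ExpressionMatrix"), is(net, "PriorNetwork"),
            is(split, "EdgeSplit"), inherits(config, "trainConfig"))
  if (is.null(Anorm))
    Anorm <- buildNormalizedAdjacency(net, nodes = geneIds(x),
                                      edgeSubset = split@trainPos)
  trainSamples <- rbind(
    cbind(split@trainPos, label = 1),
    cbind(split@trainNeg, label = 0))
  valSamples <- rbind(
    cbind(split@valPos, label = 1),
    cbind(split@valNeg, label = 0))
  model <- initGCNModel(ncol(exprValues(x)), hiddenDims = config$hiddenDims,
                        lambdaMix = config$lambdaMix, seed = config$seed)
  opt <- .adamInit(model)
  trainLoss <- numeric(config$epochs)
  valAuroc <- numeric(config$epochs)
  best <- list(auroc = -Inf, epoch = 1L, weights = model@weights,
               biases = model@biases)
  for (epoch in seq_len(config$epochs)) {
    gr <- lossGradients(x, Anorm, model, trainSamples, config$weightDecay)
    if (!is.finite(gr$loss))
      .stopf("non-finite training loss at epoch %d", epoch)
    trainLoss[epoch] <- gr$loss
    upd <- .adamStep(model, gr, opt, config$learningRate)
    model <- upd$model; opt <- upd$opt
    R <- gcnDecode(gcnEncode(x, Anorm, model))
    valAuroc[epoch] <- aurocScore(scorePairs(R, valSamples),
                                  valSamples$label)
    if (valAuroc[epoch] > best$auroc) {
      best <- list(auroc = valAuroc[epoch], epoch = epoch,
                   weights = model@weights, biases = model@biases)
    }
  }
  bestModel <- initialize(model, weights = best$weights, biases = best$biases)
  list(model = bestModel,
       history = list(trainLoss = trainLoss, valAuroc = valAuroc,
                      bestEpoch = best$epoch))
}

.adamInit <- function(model) {
  zero <- function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  }
  list(t = 0L,
       mW = lapply(model@weights, zero), vW = lapply(model@weights, zero),
       mB = lapply(model@biases, zero), vB = lapply(model@biases, zero))
}

.adamStep <- function(model, gr, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t; c2 <- 1 - beta2^opt$t
  W <- model@weights; B <- model@biases
  for (l in seq_along(W)) {
    opt$mW[[l]] <- beta1 * opt$mW[[l]] + (1 - beta1) * gr$weights[[l]]
    opt$vW[[l]] <- beta2 * opt$vW[[l]] + (1 - beta2) * gr$weights[[l]]^2
    W[[l]] <- W[[l]] - lr * (opt$mW[[l]] / c1) /
      (sqrt(opt$vW[[l]] / c2) + eps)
    opt$mB[[l]] <- beta1 * opt$mB[[l]] + (1 - beta1) * gr$biases[[l]]
    opt$vB[[l]] <- beta2 * opt$vB[[l]] + (1 - beta2) * gr$biases[[l]]^2
    B[[l]] <- B[[l]] - lr * (opt$mB[[l]] / c1) /
      (sqrt(opt$vB[[l]] / c2) + eps)
  }
  list(model = initialize(model, weights = W, biases = B), opt = opt)
}
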