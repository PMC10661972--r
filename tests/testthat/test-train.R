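# 3-node fixture shared by the loss/gradient tests
gradFixture <- function(seed = 42) {
  set.seed(seed)
  gs <- c("A", "B", "C")
  x <- tinyExpr(matrix(abs(rnorm(9)), 3, 3), genes = gs)
  net <- PriorNetwork(data.frame(from = c("A", "B"), to = c("B", "C")),
                      genes = gs, tfSet = c("A", "B"))
  A <- buildNormalizedAdjacency(net, nodes = gs)
  model <- initGCNModel(3, hiddenDims = c(3L, 2L), lambdaMix = 0.4, seed = 7)
  samples <- data.frame(from = c("A", "A", "B"), to = c("B", "C", "C"),
                        label = c(1, 0, 1))
  list(x = x, net = net, A = A, model = model, samples = samples)
}

test_that("loss reproduces analytic cases and ignores sample order", {
  R <- matrix(c(1, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"),
                                                   c("A", "B")))
  m <- initGCNModel(2, hiddenDims = 2L, seed = 1)
  perfect <- data.frame(from = "A", to = "B", label = 1)
  expect_equal(computeLoss(R, perfect, m, weightDecay = 0), 0)
  miss <- data.frame(from = "B", to = "B", label = 1)   # scored 0
  expect_equal(computeLoss(R, miss, m, weightDecay = 0), 1)
  # one positive and one negative both scored 0.5 -> mean squared error 0.25
  half <- data.frame(from = c("A", "A"), to = c("A", "A"),
                     label = c(1, 0))
  R2 <- matrix(0.5, 1, 1, dimnames = list("A", "A"))
  expect_equal(computeLoss(R2, half, m, weightDecay = 0), 0.25)
  # order invariance and the Frobenius term
  fx <- gradFixture()
  Rf <- gcnDecode(gcnEncode(fx$x, fx$A, fx$model))
  l1 <- computeLoss(Rf, fx$samples, fx$model, 0.01)
  l2 <- computeLoss(Rf, fx$samples[3:1, ], fx$model, 0.01)
  expect_equal(l1, l2)
  reg <- sum(sapply(fx$model@weights, function(W) sum(W^2)))
  expect_equal(l1 - computeLoss(Rf, fx$samples, fx$model, 0), 0.01 * reg)
  expect_error(computeLoss(Rf, fx$samples[0, ], fx$model, 0), "empty")
})

test_that("analytic gradients match central finite differences", {
  fx <- gradFixture()
  wd <- 0.01
  gr <- lossGradients(fx$x, fx$A, fx$model, fx$samples, weightDecay = wd)
  lossAt <- function(m) {
    computeLoss(gcnDecode(gcnEncode(fx$x, fx$A, m)), fx$samples, m, wd)
  }
  expect_equal(gr$loss, lossAt(fx$model), tolerance = 1e-12)
  eps <- 1e-6
  for (l in 1:2) {
    for (k in seq_along(fx$model@weights[[l]])) {
      up <- fx$model; up@weights[[l]][k] <- up@weights[[l]][k] + eps
      dn <- fx$model; dn@weights[[l]][k] <- dn@weights[[l]][k] - eps
      fd <- (lossAt(up) - lossAt(dn)) / (2 * eps)
      expect_equal(gr$weights[[l]][k], fd, tolerance = 1e-4)
    }
    for (k in seq_along(fx$model@biases[[l]])) {
      up <- fx$model; up@biases[[l]][k] <- up@biases[[l]][k] + eps
      dn <- fx$model; dn@biases[[l]][k] <- dn@biases[[l]][k] - eps
      fd <- (lossAt(up) - lossAt(dn)) / (2 * eps)
      expect_equal(gr$biases[[l]][k], fd, tolerance = 1e-4)
    }
  }
})

trainFixture <- function(seed = 1L) {
  cfg <- syntheticConfig(nTfs = 5, nGenes = 30, nCells = 50, density = 0.15,
                         noiseSd = 0.1, dropoutRate = 0.1, seed = 17)
  net <- simulateGRN(cfg)
  x <- logNormalize(simulateExpression(net, cfg))
  split <- makeEdgeSplit(net, seed = seed)
  list(x = coexpressionProfile(x), net = net, split = split)
}

test_that("zero learning rate leaves parameters bit-identical", {
  fx <- trainFixture()
  cfg <- trainConfig(epochs = 3L, learningRate = 0, seed = 2L,
                     hiddenDims = c(8L, 4L))
  fit <- trainGCN(fx$x, fx$net, fx$split, cfg)
  init <- initGCNModel(ncol(exprValues(fx$x)), hiddenDims = c(8L, 4L),
                       lambdaMix = cfg$lambdaMix, seed = 2L)
  expect_identical(fit$model@weights, init@weights)
  expect_identical(fit$model@biases, init@biases)
})

test_that("training is reproducible and reduces the loss", {
  fx <- trainFixture()
  cfg <- trainConfig(epochs = 30L, seed = 3L, hiddenDims = c(16L, 8L))
  f1 <- trainGCN(fx$x, fx$net, fx$split, cfg)
  f2 <- trainGCN(fx$x, fx$net, fx$split, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model@weights, f2$model@weights)
  expect_lt(tail(f1$history$trainLoss, 1), f1$history$trainLoss[1])
  expect_length(f1$history$trainLoss, 30L)
  expect_length(f1$history$valAuroc, 30L)
  expect_equal(f1$history$bestEpoch, which.max(f1$history$valAuroc))
})

test_that("weight decay shrinks embeddings under all-zero labels", {
  fx <- trainFixture()
  zeros <- rbind(fx$split@trainNeg,
                 setNames(fx$split@trainPos, c("from", "to")))
  zeros$label <- 0
  A <- buildNormalizedAdjacency(fx$net, nodes = geneIds(fx$x),
                                edgeSubset = fx$split@trainPos)
  model <- initGCNModel(ncol(exprValues(fx$x)), hiddenDims = c(8L, 4L),
                        lambdaMix = 0.4, seed = 4L)
  opt <- grnlink:::.adamInit(model)
  norms <- numeric(20)
  for (ep in 1:20) {
    gr <- lossGradients(fx$x, A, model, zeros, weightDecay = 0.01)
    u <- grnlink:::.adamStep(model, gr, opt, lr = 0.005)
    model <- u$model; opt <- u$opt
    norms[ep] <- sum(gcnEncode(fx$x, A, model)^2)
  }
  expect_true(all(diff(norms) <= 1e-10))
  expect_lt(norms[20], norms[1])
})
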