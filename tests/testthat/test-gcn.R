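test_that("gcn layer handles identity and clipping edge cases", {
  H <- matrix(abs(rnorm(6)), 3, 2)
  I3 <- diag(3)
  expect_equal(gcnLayer(H, I3, diag(2), c(0, 0), lambdaMix = 1), H)
  # zero weights with negative bias: ReLU clips everything
  out <- gcnLayer(H, I3, matrix(0, 2, 2), c(-1, -1))
  expect_true(all(out == 0))
})

test_that("matrix-form layer equals the per-node aggregation oracle", {
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(3:10, 1)
    net <- randomGraphNet(n, max(1L, round(0.5 * n)), seed = rep)
    A <- buildNormalizedAdjacency(net)
    H <- matrix(rnorm(n * 4), n)
    W <- matrix(rnorm(4 * 3), 4, 3)
    b <- rnorm(3)
    for (lam in c(1, 0.4)) {
      expect_equal(unname(gcnLayer(H, A, W, b, lambdaMix = lam)),
                   naiveGcnLayer(H, A, W, b, lambdaMix = lam),
                   tolerance = 1e-9)
    }
  }
})

test_that("encoding is permutation-equivariant and depth-consistent", {
  set.seed(5)
  net <- randomNet(2, 6, 0.4, seed = 8)
  x <- tinyExpr(matrix(runif(6 * 5, 0, 4), 6), genes = genes(net))
  A <- buildNormalizedAdjacency(net, nodes = geneIds(x))
  model <- initGCNModel(5, hiddenDims = c(4L, 3L), lambdaMix = 0.7, seed = 2)
  H <- gcnEncode(x, A, model)
  expect_true(all(H >= 0))
  # permuting genes of X and A together permutes embedding rows identically
  p <- sample(6)
  xp <- tinyExpr(exprValues(x)[p, ], genes = geneIds(x)[p])
  Hp <- gcnEncode(xp, A[p, p], model)
  expect_equal(unname(Hp), unname(H[p, ]), tolerance = 1e-12)
  # a one-layer model is exactly one gcnLayer call on standardized input
  m1 <- initGCNModel(5, hiddenDims = 4L, lambdaMix = 0.7, seed = 2)
  expect_equal(unname(gcnEncode(x, A, m1)),
               unname(gcnLayer(grnlink:::.standardizeFeatures(exprValues(x)),
                               A, m1@weights[[1]], m1@biases[[1]], 0.7)),
               tolerance = 1e-12)
  # dimension mismatch is caught with the layer named
  bad <- initGCNModel(3, hiddenDims = 4L)
  expect_error(gcnEncode(x, A, bad), "layer 1")
})

test_that("at lambda 0 the graph is ignored; at lambda 1 pure propagation", {
  net <- randomNet(2, 6, 0.5, seed = 4)
  x <- tinyExpr(matrix(runif(30, 0, 3), 6), genes = genes(net))
  A <- buildNormalizedAdjacency(net, nodes = geneIds(x))
  m0 <- initGCNModel(5, hiddenDims = c(4L, 3L), lambdaMix = 0, seed = 3)
  I6 <- diag(6); dimnames(I6) <- dimnames(A)
  expect_equal(gcnEncode(x, A, m0),
               gcnEncode(x, I6, m0), tolerance = 1e-12)
  # lambda 1: layer output is exactly ReLU(A H W + b)
  H <- matrix(abs(rnorm(24)), 6)
  W <- matrix(rnorm(4 * 2), 4); b <- rnorm(2)
  expect_equal(unname(gcnLayer(H, A, W, b, lambdaMix = 1)),
               unname(pmax(A %*% H %*% W + rep(1, 6) %o% b, 0)),
               tolerance = 1e-12)
})

test_that("decoder reproduces analytic cases and is symmetric nonnegative", {
  expect_equal(gcnDecode(diag(2)), diag(2))
  H0 <- rbind(c(1, 0), c(0, 0), c(0, 2))
  R0 <- gcnDecode(H0)
  expect_true(all(R0[2, ] == 0) && all(R0[, 2] == 0))
  # hand-computed signed case: H = [[1], [-2]]
  R <- gcnDecode(matrix(c(1, -2), 2, 1))
  expect_equal(unname(R), rbind(c(1, 0), c(0, 4)))
  set.seed(8)
  H <- matrix(rnorm(20), 5)
  Rr <- gcnDecode(H)
  expect_equal(Rr, t(Rr))
  expect_true(all(Rr >= 0))
  # diagonal equals squared row norms (ReLU inactive on the diagonal)
  expect_equal(diag(Rr), rowSums(H^2))
})

test_that("pair scoring is order-preserving and validates genes", {
  H <- diag(3)
  rownames(H) <- c("A", "B", "C")
  R <- gcnDecode(H)
  expect_equal(scorePairs(R, data.frame(from = "A", to = "A")), 1)
  q1 <- data.frame(from = c("A", "B"), to = c("B", "C"))
  expect_equal(scorePairs(R, q1), rev(scorePairs(R, q1[2:1, ])))
  expect_equal(scorePairs(R, data.frame(from = "A", to = "B")),
               scorePairs(R, data.frame(from = "B", to = "A")))
  expect_error(scorePairs(R, data.frame(from = "A", to = "Z")), "Z")
})

test_that("co-expression profile features are |cor| with correct shape", {
  set.seed(11)
  x <- tinyExpr(matrix(runif(5 * 30, 0, 4), 5))
  f <- coexpressionProfile(x)
  v <- exprValues(f)
  expect_equal(dim(v), c(5L, 5L))
  expect_equal(unname(v), unname(abs(cor(t(exprValues(x))))),
               tolerance = 1e-12)
  expect_true(all(v >= 0 & v <= 1 + 1e-12))
})

test_that("Glorot initialization is seeded and shape-consistent", {
  m <- initGCNModel(10, hiddenDims = c(8L, 4L), seed = 5)
  m2 <- initGCNModel(10, hiddenDims = c(8L, 4L), seed = 5)
  expect_identical(m@weights, m2@weights)
  expect_equal(dim(m@weights[[1]]), c(10L, 8L))
  expect_equal(dim(m@weights[[2]]), c(8L, 4L))
  a1 <- sqrt(6 / 18)
  expect_true(all(abs(m@weights[[1]]) <= a1))
  expect_true(all(m@biases[[1]] == 0))
  expect_true(validObject(m))
})
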