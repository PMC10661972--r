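test_that("low-expression filter uses a strict 'less than' boundary", {
  v <- rbind(allZero = rep(0, 10),
             oneOfTen = c(3, rep(0, 9)),     # exactly 10%: kept
             dense = rep(2, 10))
  colnames(v) <- paste0("C", 1:10)
  x <- ExpressionMatrix(v)
  kept <- filterLowExpression(x, 0.10)
  expect_identical(geneIds(kept), c("oneOfTen", "dense"))
  # all-positive matrix is untouched; the filter is idempotent
  allPos <- tinyExpr(matrix(1:12, 3))
  expect_identical(exprValues(filterLowExpression(allPos)),
                   exprValues(allPos))
  expect_identical(exprValues(filterLowExpression(kept)), exprValues(kept))
  expect_error(filterLowExpression(ExpressionMatrix(
    matrix(0, 1, 10, dimnames = list("G1", paste0("C", 1:10))))),
    "nothing left")
})

test_that("dispersion p-values follow the chi-square reference", {
  M <- 10L
  # every gene is a permutation of the same values, so every variance
  # equals the median variance and the statistic is exactly M - 1 = 9
  set.seed(3)
  v <- t(replicate(7, sample(1:10)))
  dimnames(v) <- list(paste0("G", 1:7), paste0("C", 1:M))
  sel <- varianceSignificance(ExpressionMatrix(v))
  # frozen expectation from an independent chi-square survival-function
  # oracle evaluated before the build: upper tail of chi2(df = 9) at 9
  expect_equal(sel@pValue, rep(0.43727418891386693, 7), tolerance = 1e-10)
  # constant gene: variance 0, upper tail at 0 is 1
  v2 <- rbind(v, const = rep(5L, M))
  sel2 <- varianceSignificance(ExpressionMatrix(v2))
  expect_equal(sel2@variance[8], 0)
  expect_equal(sel2@pValue[8], 1)
})

test_that("a gene at 4x the median variance is strictly more significant", {
  M <- 20L
  set.seed(9)
  base <- matrix(rnorm(5 * M, 10, 1), 5, M)
  v <- rbind(base, hot = rnorm(M, 10, 2))   # ~4x variance
  rownames(v) <- c(paste0("G", 1:5), "hot")
  colnames(v) <- paste0("C", 1:M)
  sel <- varianceSignificance(ExpressionMatrix(abs(v)))
  expect_lt(sel@pValue[6], min(sel@pValue[1:5]))
  expect_error(varianceSignificance(ExpressionMatrix(
    matrix(1, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z"))))),
    "median gene variance is 0")
})

test_that("Bonferroni selection keeps significant TFs plus top-k genes", {
  # synthetic GeneSelection with controlled p-values and variances
  n <- 100L
  ids <- paste0("G", seq_len(n))
  pv <- rep(0.5, n)
  pv[1:10] <- 1e-5          # adjusted 1e-3 < 0.01 -> kept
  pv[11] <- 5e-4            # adjusted 0.05 -> dropped
  vars <- seq(n, 1)         # G1 most variable
  sel <- new("GeneSelection", geneIds = ids, variance = as.numeric(vars),
             pValue = pv, params = list())
  x <- ExpressionMatrix(matrix(1, n, 2, dimnames = list(ids, c("a", "b"))))
  kept <- selectGenes(sel, x, tfs = character(), alpha = 0.01, topK = 5L)
  expect_identical(geneIds(kept), paste0("G", 1:5))
  # significant TF outside the top-k is still kept; order is by variance
  keptTf <- selectGenes(sel, x, tfs = "G10", alpha = 0.01, topK = 5L)
  expect_identical(geneIds(keptTf), paste0("G", c(1:5, 10)))
  expect_false("G11" %in% geneIds(selectGenes(sel, x, topK = 50L)))
  sel0 <- new("GeneSelection", geneIds = ids, variance = as.numeric(vars),
              pValue = rep(0.9, n), params = list())
  expect_error(selectGenes(sel0, x, topK = 5L), "larger alpha")
})

test_that("log normalization maps 0/1/3 to 0/1/2 and is strictly monotone", {
  x <- tinyExpr(matrix(c(0, 1, 3, 7, 15, 2), 3))
  y <- logNormalize(x)
  expect_equal(exprValues(y)[1:3], c(0, 1, 2))
  v <- sort(runif(50, 0, 100))
  expect_true(all(diff(log1p(v) / log(2)) > 0))
  # natural log base option
  expect_equal(exprValues(logNormalize(x, base = exp(1)))[2, 1], log(2))
})

test_that("Gaussian perturbation is seeded, clamped and scale-accurate", {
  x <- tinyExpr(matrix(runif(300 * 40, 1, 10), 300))
  expect_identical(perturbExpression(x, 0, 1), x)
  a <- perturbExpression(x, 0.05, seed = 4)
  b <- perturbExpression(x, 0.05, seed = 4)
  expect_identical(exprValues(a), exprValues(b))
  expect_true(all(exprValues(a) >= 0))
  # with values >> sigma the clamp never triggers, so the noise sd is
  # recoverable from the differences (law of large numbers, 5% tolerance)
  d <- exprValues(a) - exprValues(x)
  expect_equal(sd(d), 0.05, tolerance = 0.05)
})

test_that("the preprocessing pipeline returns a subset in log units", {
  cfg <- syntheticConfig(nTfs = 5, nGenes = 40, nCells = 60, density = 0.1,
                         seed = 21)
  net <- simulateGRN(cfg)
  x <- simulateExpression(net, cfg)
  xp <- preprocessExpression(x, tfs = tfSet(net), alpha = 0.05, topK = 30L)
  expect_true(all(geneIds(xp) %in% geneIds(x)))
  expect_true(all(exprValues(xp) >= 0))
  expect_lte(nrow(exprValues(xp)), 35L)
})
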